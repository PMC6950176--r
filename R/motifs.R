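# IUPAC expansion; note N in the *sequence* matches only the consensus
# symbol N, never any other code (GenBank records contain runs of N and a
# degenerate consensus must not light up inside them).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

#' Promoter/terminator motif specification
#'
#' Describes one element searched by the scanner: a TATA box, gene-internal
#' A-box or B-box as an IUPAC consensus with a mismatch budget, or the Pol
#' III terminator as a minimum T-run length.
#'
#' @param name one of `"TATA"`, `"ABOX"`, `"BBOX"`, `"TERM"`.
#' @param consensus IUPAC string (ignored for `TERM`).
#' @param max_mismatch allowed mismatches (must be < consensus length).
#' @param min_run minimum run of consecutive T for `TERM` (>= 4; shorter
#'   runs do not terminate Pol III).
#' @return an object of class `motif_spec`.
#' @export
motif_spec <- function(name, consensus = NULL, max_mismatch = 0L,
                       min_run = NULL) {
  if (identical(name, "TERM")) {
    if (is.null(min_run) || min_run < 4L)
      stop_config("Pol III terminators require min_run >= 4")
    return(structure(list(name = name, min_run = as.integer(min_run)),
                     class = "motif_spec"))
  }
  if (is.null(consensus) || !nzchar(consensus))
    stop_config("motif '%s' needs a consensus", name)
  sym <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  if (!all(sym %in% names(IUPAC_SETS)))
    stop_config("invalid IUPAC character '%s' in consensus for %s",
                sym[!sym %in% names(IUPAC_SETS)][1], name)
  if (max_mismatch >= nchar(consensus))
    stop_config("max_mismatch must be smaller than the consensus length")
  structure(list(name = name, consensus = toupper(consensus),
                 max_mismatch = as.integer(max_mismatch)),
            class = "motif_spec")
}

#' Default motif set
#'
#' TATA `TATAWAW` (0 mismatches), A-box `TRGCNNARYNNG` (1 mismatch), B-box
#' `GTTCRANNC` (1 mismatch), terminator = run of >= 4 T on the sense strand.
#' The tolerances are the calibration starting point; all of them are
#' overridable through [scan_config()].
#'
#' @return named list of [motif_spec] objects.
#' @export
default_motif_specs <- function() {
  list(TATA = motif_spec("TATA", "TATAWAW", 0L),
       ABOX = motif_spec("ABOX", "TRGCNNARYNNG", 1L),
       BBOX = motif_spec("BBOX", "GTTCRANNC", 1L),
       TERM = motif_spec("TERM", min_run = 4L))
}

# logical membership matrix: rows = coded base 1..5 (A,C,G,T,N), cols =
# consensus positions
consensus_matrix <- function(consensus) {
  sym <- strsplit(consensus, "", fixed = TRUE)[[1]]
  m <- matrix(FALSE, nrow = 5, ncol = length(sym))
  for (k in seq_along(sym))
    m[match(IUPAC_SETS[[sym[k]]], BASES_DNA), k] <- TRUE
  m
}

#' Scan a sequence for an IUPAC consensus with a mismatch budget
#'
#' Reports every window whose mismatch count against the consensus is at
#' most `spec$max_mismatch`, sorted by start. `N` in the sequence counts as
#' a mismatch against every consensus symbol except `N` itself.
#'
#' @param seq normalized DNA string.
#' @param spec a [motif_spec] (not `TERM`).
#' @param offset added to reported coordinates (for scanning subsequences).
#' @return data.frame with columns `spec`, `start`, `end` (0-based
#'   half-open), `strand`, `matched`, `mismatches`.
#' @examples
#' scan_consensus("GGTATAAATGG", motif_spec("TATA", "TATAWAW", 0))
#' @export
scan_consensus <- function(seq, spec, offset = 0L) {
  empty <- data.frame(spec = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      matched = character(0), mismatches = integer(0))
  if (identical(spec$name, "TERM"))
    stop_config("use find_terminators() for TERM")
  m <- nchar(spec$consensus)
  n <- nchar(seq)
  if (n < m) return(empty)
  codes <- encode_dna(seq)
  allowed <- consensus_matrix(spec$consensus)
  npos <- n - m + 1L
  mm <- integer(npos)
  for (k in seq_len(m))
    mm <- mm + !allowed[cbind(codes[k:(k + npos - 1L)], k)]
  hit <- which(mm <= spec$max_mismatch)
  if (!length(hit)) return(empty)
  data.frame(spec = spec$name, start = offset + hit - 1L,
             end = offset + hit - 1L + m, strand = "+",
             matched = substring(seq, hit, hit + m - 1L),
             mismatches = mm[hit])
}

#' Find Pol III terminators (maximal T-runs)
#'
#' One hit per maximal run of at least `min_run` consecutive T on the sense
#' strand, spanning the full run.
#'
#' @param seq normalized DNA string.
#' @param min_run minimum run length (>= 4).
#' @param offset added to reported coordinates.
#' @return data.frame as in [scan_consensus()].
#' @examples
#' find_terminators("CGTTTTTCG", 4)
#' @export
find_terminators <- function(seq, min_run = 4L, offset = 0L) {
  if (min_run < 4L)
    stop_config("Pol III terminators require min_run >= 4, got %d", min_run)
  pat <- sprintf("T{%d,}", min_run)
  m <- gregexpr(pat, seq)[[1]]
  if (m[1] == -1L)
    return(data.frame(spec = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      matched = character(0), mismatches = integer(0)))
  len <- attr(m, "match.length")
  data.frame(spec = "TERM", start = offset + as.integer(m) - 1L,
             end = offset + as.integer(m) - 1L + len, strand = "+",
             matched = substring(seq, m, m + len - 1L),
             mismatches = 0L)
}

#' Scan a sequence for all configured motifs
#'
#' Union of TATA/A-box/B-box consensus hits and terminator runs, sorted by
#' start then motif name.
#'
#' @param seq normalized DNA string.
#' @param specs named list of [motif_spec] (default [default_motif_specs()]).
#' @param offset added to reported coordinates.
#' @return data.frame as in [scan_consensus()].
#' @export
scan_all_motifs <- function(seq, specs = default_motif_specs(), offset = 0L) {
  parts <- lapply(specs, function(sp) {
    if (identical(sp$name, "TERM")) find_terminators(seq, sp$min_run, offset)
    else scan_consensus(seq, sp, offset)
  })
  hits <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  hits <- hits[order(hits$start, hits$spec), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
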