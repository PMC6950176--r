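#' Strand-aware half-open sequence interval
#'
#' All internal coordinates in the package are 0-based half-open (`[start,
#' end)`), like BED; GFF3 output converts to 1-based inclusive at write time.
#'
#' @param seq_id name of the sequence the interval lives on.
#' @param start,end integers, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `seq_region`.
#' @export
seq_region <- function(seq_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop_config("invalid region [%s, %s) on '%s'", start, end, seq_id)
  if (!strand %in% c("+", "-"))
    stop_config("strand must be '+' or '-'")
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "seq_region")
}

#' @export
print.seq_region <- function(x, ...) {
  cat(sprintf("%s:[%d,%d)%s\n", x$seq_id, x$start, x$end, x$strand))
  invisible(x)
}

region_width <- function(r) r$end - r$start

#' Sequence record
#'
#' @param id record identifier (FASTA header token or accession.version).
#' @param seq DNA string; normalized (U to T, uppercase) on construction.
#' @param description free-text remainder of the header.
#' @param features list of `list(kind=, region=seq_region)` entries, e.g.
#'   LTR annotations from GenBank.
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(id, seq, description = "", features = list()) {
  structure(list(id = id, seq = normalize_seq(seq, id),
                 description = description, features = features),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("seq_record %s (%d nt, %d feature(s))\n",
              x$id, nchar(x$seq), length(x$features)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are normalized (U to T, uppercased) and validated against
#' \{A,C,G,T,N\}; record order is preserved. The record id is the first
#' whitespace-delimited header token.
#'
#' @param path FASTA file.
#' @return list of [seq_record] objects (empty list for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_io("FASTA file not found: %s", path)
  if (file.size(path) == 0L) return(list())
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- vector("list", length(set))
  for (i in seq_along(set))
    out[[i]] <- seq_record(ids[i], as.character(set[[i]]), desc[i])
  out
}

#' Write seq_records to FASTA
#' @param records list of [seq_record].
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  ln <- unlist(lapply(records, function(r) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    c(paste0(">", hdr), r$seq)
  }))
  if (is.null(ln)) ln <- character(0)
  writeLines(ln, path)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Minimal parser for GenBank flat files: the record id is taken from
#' `VERSION` (accession.version; `ACCESSION`/`LOCUS` as fallbacks), the
#' sequence from `ORIGIN`, and every feature whose key is `LTR` or
#' `repeat_region` is kept with its location converted from GenBank 1-based
#' inclusive to internal 0-based half-open coordinates. Only simple
#' `a..b` and `complement(a..b)` locations are interpreted.
#'
#' @param path GenBank flat file.
#' @return a [seq_record] with `features` populated.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop_io("GenBank file not found: %s", path)
  ln <- readLines(path)
  acc <- NA_character_
  vline <- grep("^VERSION", ln, value = TRUE)
  if (length(vline)) acc <- strsplit(trimws(sub("^VERSION", "", vline[1])), "\\s+")[[1]][1]
  if (is.na(acc) || !nzchar(acc)) {
    aline <- grep("^ACCESSION", ln, value = TRUE)
    if (length(aline)) acc <- strsplit(trimws(sub("^ACCESSION", "", aline[1])), "\\s+")[[1]][1]
  }
  if (is.na(acc) || !nzchar(acc)) {
    lline <- grep("^LOCUS", ln, value = TRUE)
    if (length(lline)) acc <- strsplit(trimws(sub("^LOCUS", "", lline[1])), "\\s+")[[1]][1]
  }
  defline <- grep("^DEFINITION", ln)
  desc <- if (length(defline)) trimws(sub("^DEFINITION", "", ln[defline[1]])) else ""

  oi <- grep("^ORIGIN", ln)
  if (!length(oi)) stop_io("GenBank file %s has no ORIGIN section", path)
  seq_lines <- ln[(oi[1] + 1L):length(ln)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- gsub("[0-9 ]", "", paste(seq_lines, collapse = ""))

  feats <- list()
  fi <- grep("^FEATURES", ln)
  if (length(fi)) {
    block <- ln[(fi[1] + 1L):(oi[1] - 1L)]
    key_rows <- grep("^ {1,10}\\S", block)
    for (r in key_rows) {
      key <- trimws(substr(block[r], 1, 20))
      if (!key %in% c("LTR", "repeat_region")) next
      loc <- trimws(substr(block[r], 21, nchar(block[r])))
      strand <- "+"
      m <- regmatches(loc, regexec("^(complement\\()?<?(\\d+)\\.\\.>?(\\d+)\\)?", loc))[[1]]
      if (length(m) < 4) next
      if (nzchar(m[2])) strand <- "-"
      a <- as.integer(m[3]); b <- as.integer(m[4])
      feats[[length(feats) + 1L]] <-
        list(kind = key, region = seq_region(acc, a - 1L, b, strand))
    }
  }
  seq_record(acc, seq, desc, feats)
}

#' Write a minimal GenBank flat file (synthetic fixtures)
#'
#' Emits just enough of the GenBank dialect (LOCUS, DEFINITION, ACCESSION,
#' VERSION, FEATURES, ORIGIN) for [read_genbank()] to round-trip a record.
#' Intended for test fixtures built by the synthetic-data generator, not for
#' archival records.
#'
#' @param record a [seq_record].
#' @param path output file.
#' @export
write_genbank <- function(record, path) {
  acc_base <- sub("\\.\\d+$", "", record$id)
  n <- nchar(record$seq)
  ln <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   SYN", acc_base, n),
    sprintf("DEFINITION  %s", if (nzchar(record$description))
      record$description else "synthetic record"),
    sprintf("ACCESSION   %s", acc_base),
    sprintf("VERSION     %s", record$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n))
  for (f in record$features) {
    loc <- sprintf("%d..%d", f$region$start + 1L, f$region$end)
    if (f$region$strand == "-") loc <- sprintf("complement(%s)", loc)
    ln <- c(ln, sprintf("     %-16s%s", f$kind, loc))
  }
  ln <- c(ln, "ORIGIN")
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(record$seq, s, min(s + 59L, n))
    grp <- gsub("(.{10})", "\\1 ", chunk)
    ln <- c(ln, sprintf("%9d %s", s, trimws(tolower(grp))))
  }
  ln <- c(ln, "//")
  writeLines(ln, path)
  invisible(path)
}

#' Extract the sequence of a region
#'
#' @param record a [seq_record] (or a plain DNA string).
#' @param region a [seq_region]; minus-strand regions are
#'   reverse-complemented.
#' @return DNA string.
#' @examples
#' r <- seq_record("x", "ACGTAC")
#' extract_region(r, seq_region("x", 1, 4))          # "CGT"
#' extract_region(r, seq_region("x", 1, 4, "-"))     # "ACG"
#' @export
extract_region <- function(record, region) {
  seq <- if (inherits(record, "seq_record")) record$seq else record
  if (region$end > nchar(seq))
    stop_io("region [%d,%d) out of bounds for %d nt sequence",
            region$start, region$end, nchar(seq))
  s <- substr(seq, region$start + 1L, region$end)
  if (region$strand == "-") s <- revcomp(s)
  s
}

#' Read scan regions from a BED file
#'
#' @param path 3- or 6-column BED (0-based half-open, as internal
#'   coordinates).
#' @return list of [seq_region].
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop_io("BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  lapply(seq_along(gr), function(i) {
    st <- as.character(BiocGenerics::strand(gr[i]))
    seq_region(as.character(GenomicRanges::seqnames(gr[i])),
               GenomicRanges::start(gr[i]) - 1L, GenomicRanges::end(gr[i]),
               if (st %in% c("+", "-")) st else "+")
  })
}

# GRanges (1-based inclusive) for cassettes + child elements; used by the
# GFF3 writer and by round-trip tests
cassette_granges <- function(cassettes) {
  rows <- list()
  add <- function(seqid, start0, end0, strand, type, id, parent = NA, score = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = seqid, start = start0 + 1L, end = end0, strand = strand,
      type = type, ID = id, Parent = parent, score = score,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(cassettes)) {
    cs <- cassettes[[i]]
    reg <- cs$cassette_region
    cid <- cs$id
    add(reg$seq_id, reg$start, reg$end, reg$strand, "pri_miRNA_cassette",
        cid, score = cs$score)
    tr <- cs$dumbbell$trimmed_region
    for (a in seq_along(cs$dumbbell$arm_regions)) {
      ar <- cs$dumbbell$arm_regions[[a]]
      add(ar$seq_id, ar$start, ar$end, ar$strand, "stem_loop",
          sprintf("%s:stem_loop%d", cid, a), parent = cid)
    }
    ph <- cs$promoter_hits
    if (!is.null(ph) && nrow(ph)) {
      type_map <- c(TATA = "TATA_box", ABOX = "A_box", BBOX = "B_box")
      for (r in seq_len(nrow(ph)))
        add(reg$seq_id, ph$start[r], ph$end[r], ph$strand[r],
            type_map[[ph$spec[r]]],
            sprintf("%s:%s%d", cid, tolower(ph$spec[r]), r), parent = cid)
    }
    tm <- cs$terminator
    if (!is.null(tm) && nrow(tm))
      add(reg$seq_id, tm$start[1], tm$end[1], tm$strand[1], "terminator",
          sprintf("%s:terminator", cid), parent = cid)
  }
  if (!length(rows)) {
    return(GenomicRanges::GRanges())
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$score <- df$score
  par <- as.list(df$Parent)
  par[is.na(df$Parent)] <- list(character(0))
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(par)
  gr
}

#' Write cassette annotations (GFF3) and a per-genome summary (TSV)
#'
#' The GFF3 file uses 1-based inclusive coordinates, feature type
#' `pri_miRNA_cassette` with child `TATA_box` / `A_box` / `B_box` /
#' `terminator` / `stem_loop` features, and the dumbbell MFE as the score.
#' The TSV has columns `accession`, `n_cassettes`, `n_box_cassettes`.
#'
#' @param cassettes list of cassettes (from [assemble_cassettes()]).
#' @param summaries list of [genome_summary][summarize_genome] objects.
#' @param gff_path,tsv_path output paths (either may be `NULL` to skip).
#' @export
write_outputs <- function(cassettes, summaries, gff_path, tsv_path) {
  if (!is.null(gff_path)) {
    gr <- cassette_granges(cassettes)
    ok <- tryCatch({
      rtracklayer::export(gr, gff_path, format = "gff3")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_io("cannot write GFF3 to %s", gff_path)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(
      accession = vapply(summaries, function(s) s$accession, ""),
      n_cassettes = vapply(summaries, function(s) s$n_cassettes, 0L),
      n_box_cassettes = vapply(summaries, function(s) s$n_box_cassettes, 0L))
    ok <- tryCatch({
      utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_io("cannot write TSV to %s", tsv_path)
  }
  invisible(NULL)
}
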