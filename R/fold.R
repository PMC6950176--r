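#' Minimum free energy folding
#'
#' Computes the minimum-free-energy nested secondary structure of a single
#' RNA (or DNA; T is read as U) sequence by a Zuker-style dynamic program
#' over the package's nearest-neighbour [energy model][default_energy_model].
#' Co-optimal structures are resolved by a deterministic traceback that
#' prefers pairing the 5'-most available base, the smallest partner index and
#' the smallest interior-loop offsets, so identical inputs always give the
#' identical structure string. Alternatively, structures and energies can be
#' obtained from ViennaRNA's `RNAfold` (the `"vienna"` backend); energies
#' from the two backends are not comparable number-for-number (different
#' parameter sets), only threshold classifications are.
#'
#' @param seq sequence string, 1..500 nt, alphabet A,C,G,T/U,N (N never
#'   pairs).
#' @param model an `energy_model` (builtin backend only).
#' @param backend `"builtin"` (the package DP) or `"vienna"` (`RNAfold` must
#'   be on the PATH).
#' @return an object of class `fold_result`: list with `seq` (RNA string),
#'   `dot_bracket`, `mfe` (kcal/mol), `backend`.
#' @examples
#' fold_mfe("GGGGAAAACCCC")
#' @export
fold_mfe <- function(seq, model = default_energy_model(),
                     backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop_config("fold_mfe() needs one non-empty sequence")
  n <- nchar(seq)
  if (n > 500L)
    stop_config("sequence of %d nt exceeds the 500 nt folding cap", n)
  if (backend == "vienna") {
    res <- fold_vienna(seq)
    return(new_fold_result(seq, res$db[1], res$mfe[1], "vienna"))
  }
  codes <- encode_rna(normalize_seq(seq, "fold input"))
  out <- cpp_fold_windows(codes, matrix(c(0L, n), nrow = 1), model)
  new_fold_result(seq, out$db[1], out$mfe[1], "builtin")
}

new_fold_result <- function(seq, db, mfe, backend) {
  structure(list(seq = dna_to_rna(toupper(seq)), dot_bracket = db,
                 mfe = mfe, backend = backend),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$dot_bracket, "  (", sprintf("%.2f", x$mfe),
      " kcal/mol, ", x$backend, ")\n", sep = "")
  invisible(x)
}

#' Fold many windows of one sequence
#'
#' Folds every given window of a target sequence with a single banded dynamic
#' program (band = widest window), re-using the pair matrices across windows.
#' This is the engine behind [scan_region()].
#'
#' @param seq sequence string.
#' @param windows integer matrix with columns `start`, `end` (0-based,
#'   half-open, within the sequence).
#' @param model an `energy_model`.
#' @param backend `"builtin"` or `"vienna"`.
#' @return data.frame with columns `start`, `end`, `mfe`, `db`.
#' @export
fold_windows <- function(seq, windows, model = default_energy_model(),
                         backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  if (!is.matrix(windows)) windows <- matrix(windows, ncol = 2)
  storage.mode(windows) <- "integer"
  if (nrow(windows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      mfe = numeric(0), db = character(0)))
  if (backend == "vienna") {
    subs <- substring(dna_to_rna(seq), windows[, 1] + 1L, windows[, 2])
    res <- fold_vienna(subs)
    return(data.frame(start = windows[, 1], end = windows[, 2],
                      mfe = res$mfe, db = res$db))
  }
  codes <- encode_rna(normalize_seq(seq, "fold input"))
  out <- cpp_fold_windows(codes, windows, model)
  data.frame(start = windows[, 1], end = windows[, 2],
             mfe = out$mfe, db = as.character(out$db))
}

#' Exhaustive-enumeration folding oracle
#'
#' Enumerates every nested secondary structure (allowed pairs, minimum
#' hairpin loop, interior-loop cap as in the model), scores each with
#' [eval_db_energy()], and returns the global minimum; ties are broken by the
#' lexicographically smallest dot-bracket. Limited to 24 nt -- this function
#' exists to certify the dynamic-programming folder on small inputs, not to
#' fold real candidates.
#'
#' @param seq sequence string, at most 24 nt.
#' @param model an `energy_model`.
#' @return a `fold_result`.
#' @examples
#' brute_force_fold("GGGAAACCC")
#' @export
brute_force_fold <- function(seq, model = default_energy_model()) {
  n <- nchar(seq)
  if (n < 1L || n > 24L)
    stop_config("brute_force_fold() accepts 1..24 nt, got %d", n)
  codes <- encode_rna(normalize_seq(seq, "fold input"))
  dbs <- enumerate_structures(codes, model$min_hairpin)
  e <- vapply(dbs, eval_db_energy, 0.0, seq = seq, model = model,
              USE.NAMES = FALSE)
  best <- min(e)
  cand <- dbs[e <= best + 1e-9]
  db <- sort(cand, method = "radix")[1]
  new_fold_result(seq, db, best, "brute-force")
}

# all nested structures of coded sequence over allowed pairs with minimum
# hairpin size; memoized on (i,j)
enumerate_structures <- function(codes, min_hairpin = 3L) {
  n <- length(codes)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return("")
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- paste0(".", rec(i + 1L, j))
    lo <- i + min_hairpin + 1L
    if (lo <= j) {
      for (k in lo:j) {
        if (pair_type(codes[i], codes[k]) == 0L) next
        inner <- rec(i + 1L, k - 1L)
        outer <- rec(k + 1L, j)
        res <- c(res, as.vector(outer(paste0("(", inner, ")"), outer, paste0)))
      }
    }
    memo[[key]] <- res
    res
  }
  rec(1L, n)
}

# batch RNAfold call; returns data.frame(mfe, db)
fold_vienna <- function(seqs) {
  if (Sys.which("RNAfold") == "")
    stop_config("backend 'vienna' requested but RNAfold is not on the PATH")
  inp <- tempfile(fileext = ".fa")
  on.exit(unlink(inp))
  writeLines(paste0(">s", seq_along(seqs), "\n", dna_to_rna(toupper(seqs))), inp)
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS", "--infile", inp), stdout = TRUE))
  st <- grep("^[().]+\\s+\\(", out, value = TRUE)
  if (length(st) != length(seqs))
    stop_io("RNAfold returned %d structures for %d sequences",
            length(st), length(seqs))
  db <- sub("\\s.*$", "", st)
  mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", st))
  data.frame(mfe = mfe, db = db)
}
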