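# internal sequence plumbing: coded bases are 1=A 2=C 3=G 4=U/T 5=N

BASES_RNA <- c("A", "C", "G", "U", "N")
BASES_DNA <- c("A", "C", "G", "T", "N")

# classed conditions so the CLI can map errors to exit codes
stop_config <- function(...) {
  stop(structure(class = c("dbscan_config_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}
stop_io <- function(...) {
  stop(structure(class = c("dbscan_io_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts U to T, and validates the alphabet \{A,C,G,T,N\}.
#'
#' @param seq character scalar.
#' @param id record name used in error messages.
#' @return normalized DNA string.
#' @export
normalize_seq <- function(seq, id = "sequence") {
  x <- chartr("u", "U", toupper(seq))
  x <- chartr("U", "T", x)
  bad <- regmatches(x, regexpr("[^ACGTN]", x))
  if (length(bad) && nzchar(bad))
    stop_io("record '%s' contains invalid character '%s'", id, bad)
  x
}

encode_dna <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- match(v, BASES_DNA)
  if (anyNA(m)) {
    m2 <- match(v, BASES_RNA)  # tolerate U
    m[is.na(m)] <- m2[is.na(m)]
    if (anyNA(m)) stop_io("invalid base '%s'", v[which(is.na(m))[1]])
  }
  m
}

# RNA-coded (U) view of a DNA/RNA string; same codes
encode_rna <- function(seq) encode_dna(toupper(seq))

decode_rna <- function(codes) paste(BASES_RNA[codes], collapse = "")
decode_dna <- function(codes) paste(BASES_DNA[codes], collapse = "")

#' Reverse complement of a DNA string
#' @param seq DNA string over \{A,C,G,T,N\}.
#' @return reverse complement string.
#' @export
revcomp <- function(seq) {
  x <- chartr("ACGTUN", "TGCAAN", toupper(seq))
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Convert DNA to RNA (T to U)
#' @param seq DNA string.
#' @return RNA string.
#' @export
dna_to_rna <- function(seq) chartr("Tt", "Uu", seq)

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
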