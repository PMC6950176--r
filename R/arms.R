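#' Extract candidate mature miRNA arms from a dumbbell
#'
#' Without modelling Drosha/Dicer cleavage, candidate mature arms are
#' fixed-length slices anchored at the two duplex termini of each stem-loop:
#' the 5p arm is the first `arm_length` nt of the arm region, the 3p arm the
#' last `arm_length` nt (in the cassette's own 5' to 3' orientation). The
#' experimentally described high-abundance miRNAs map to the 5' part of each
#' stem-loop, which these slices cover. Arms from arm regions shorter than
#' `arm_length` are clipped and flagged.
#'
#' @param seq sequence of the record the call lives on (plus strand).
#' @param call a [dumbbell_call][classify_dumbbell] with
#'   `passes_topology = TRUE`.
#' @param arm_length slice length, nt (default 22).
#' @param cassette_id identifier prefix for arm names.
#' @return data.frame with columns `arm_id`, `cassette_id`, `hairpin`,
#'   `arm` (`5p`/`3p`), `seq` (RNA), `seed` (positions 2--8), `short`
#'   (logical), ordered hairpin1-5p, hairpin1-3p, hairpin2-5p, hairpin2-3p.
#' @export
extract_arms <- function(seq, call, arm_length = 22L,
                         cassette_id = "cassette") {
  if (!isTRUE(call$passes_topology))
    stop_config("extract_arms() needs a call that passes topology")
  rows <- list()
  for (h in seq_along(call$arm_regions)) {
    ar <- call$arm_regions[[h]]
    aseq <- extract_region(seq, ar)  # oriented 5'->3' on the cassette strand
    L <- nchar(aseq)
    k <- min(arm_length, L)
    for (arm in c("5p", "3p")) {
      s <- if (arm == "5p") substr(aseq, 1L, k)
           else substr(aseq, L - k + 1L, L)
      s <- dna_to_rna(s)
      rows[[length(rows) + 1L]] <- data.frame(
        arm_id = sprintf("%s-h%d-%s", cassette_id, h, arm),
        cassette_id = cassette_id, hairpin = h, arm = arm, seq = s,
        seed = if (nchar(s) >= 8L) seed_of(s) else NA_character_,
        short = k < arm_length)
    }
  }
  do.call(rbind, rows)
}

#' Seed sequence of a mature miRNA
#'
#' The canonical seed: nucleotides 2--8 (a 7-mer). Position 1 is excluded,
#' so sequences differing only at their first base share a seed.
#'
#' @param seq mature miRNA sequence, length >= 8.
#' @param offset 0-based start of the seed (default 1 = position 2).
#' @param length seed length (default 7; use 6 for a 2--7 seed).
#' @return seed string.
#' @examples
#' seed_of("ACGUACGUACGUACGUACGUAC")  # "CGUACGU"
#' @export
seed_of <- function(seq, offset = 1L, length = 7L) {
  if (nchar(seq) < offset + length)
    stop_config("sequence of %d nt too short for a position %d..%d seed",
                nchar(seq), offset + 1L, offset + length)
  substr(seq, offset + 1L, offset + length)
}

#' Read a mature miRNA catalog (miRBase-style FASTA)
#'
#' @param path FASTA of mature miRNAs (RNA or DNA alphabet); the name is the
#'   first header token.
#' @return data.frame with columns `name`, `seq` (RNA).
#' @export
read_mature_fasta <- function(path) {
  recs <- read_fasta(path)
  data.frame(name = vapply(recs, function(r) r$id, ""),
             seq = vapply(recs, function(r) dna_to_rna(r$seq), ""))
}

#' Match arm seeds against a host miRNA catalog
#'
#' Reports every (arm, catalog entry) pair with exactly identical seeds,
#' sorted by arm id then catalog name.
#'
#' @param arms data.frame from [extract_arms()].
#' @param catalog data.frame with columns `name`, `seq` (entries >= 8 nt),
#'   e.g. from [read_mature_fasta()].
#' @param offset,length seed definition passed to [seed_of()].
#' @return data.frame with columns `arm_id`, `host_mirna_name`, `seed`.
#' @export
match_seeds <- function(arms, catalog, offset = 1L, length = 7L) {
  empty <- data.frame(arm_id = character(0), host_mirna_name = character(0),
                      seed = character(0))
  if (!nrow(arms) || !nrow(catalog)) return(empty)
  if (any(nchar(catalog$seq) < offset + length))
    stop_config("catalog entries shorter than the seed window")
  arms <- arms[!is.na(arms$seed) & nchar(arms$seq) >= offset + length, ,
               drop = FALSE]
  if (!nrow(arms)) return(empty)
  arm_seed <- vapply(arms$seq, seed_of, "", offset = offset,
                     length = length, USE.NAMES = FALSE)
  cat_seed <- vapply(catalog$seq, seed_of, "", offset = offset,
                     length = length, USE.NAMES = FALSE)
  out <- merge(data.frame(arm_id = arms$arm_id, seed = arm_seed),
               data.frame(host_mirna_name = catalog$name, seed = cat_seed),
               by = "seed")
  out <- out[order(out$arm_id, out$host_mirna_name),
             c("arm_id", "host_mirna_name", "seed")]
  rownames(out) <- NULL
  out
}
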