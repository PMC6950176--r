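# shared fixture builders for the test suite

# minimal dumbbell_call stand-in for merge/assembly logic tests
fake_call <- function(start, end, mfe, seq_id = "x") {
  structure(list(
    window = seq_region(seq_id, max(0L, start - 5L), end + 5L),
    fold = structure(list(mfe = mfe, dot_bracket = "", seq = ""),
                     class = "fold_result"),
    trimmed_region = seq_region(seq_id, start, end),
    arm_regions = list(), n_hairpins = 2L, basal_helix_bp = 0L,
    loop_sizes = c(3L, 3L), paired_fraction = 1,
    passes_energy = TRUE, passes_topology = TRUE),
    class = "dumbbell_call")
}

# fold_result from a given dot-bracket (for topology-only tests)
fake_fold <- function(db, mfe = -40) {
  structure(list(seq = strrep("N", nchar(db)), dot_bracket = db, mfe = mfe,
                 backend = "fixture"), class = "fold_result")
}

# background with no T anywhere: no chance TATA boxes or terminator runs
background_noT <- function(n) {
  withr::with_seed(9000 + n, paste(
    sample(c("A", "C", "G"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    collapse = ""))
}

# independent regex oracle for exact IUPAC matching (0 mismatches)
iupac_regex_starts <- function(seq, consensus) {
  cls <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGTN]")
  # N in the subject must only match consensus N
  cls_strict <- cls
  cls_strict[names(cls) != "N"] <- cls[names(cls) != "N"]
  pat <- paste(cls_strict[strsplit(consensus, "")[[1]]], collapse = "")
  m <- gregexpr(sprintf("(?=%s)", pat), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# reverse complement of an IUPAC consensus
iupac_revcomp <- function(consensus) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(consensus, "")[[1]]]), collapse = "")
}

# one deterministic planted-cassette genome used across tests
planted_genome <- function(seed = 11L, n = 800L, position = 300L,
                           spec = plant_spec()) {
  bg <- random_background(n, 0.4, seed)
  spec$rng_seed <- seed + 1L
  plant_cassette(bg, position, spec)
}
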