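#' Random LTR-like background sequence
#'
#' i.i.d. bases at a given GC fraction (default 0.4, mimicking LTR
#' composition); reproducible per seed.
#'
#' @param length sequence length (>= 0).
#' @param gc_fraction GC content in \[0, 1\].
#' @param rng_seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return DNA string.
#' @export
random_background <- function(length, gc_fraction = 0.4, rng_seed = NULL) {
  if (length < 0L) stop_config("length must be >= 0")
  if (gc_fraction < 0 || gc_fraction > 1) stop_config("gc_fraction in [0,1]")
  draw <- function() {
    if (length == 0L) return("")
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
           (1 - gc_fraction) / 2)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
          collapse = "")
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
}

#' Specification of a planted cassette
#'
#' Describes one synthetic Pol III cassette: a dumbbell of two
#' perfect-complement GC-rich stem-loops on a short basal helix, an upstream
#' TATA box, optional gene-internal A/B boxes (written into the 5' strand of
#' the stems so pairing is preserved), and a downstream T-run terminator.
#' With the defaults the dumbbell spans `2*(2*25+8) + 2 + 2*4 = 126` nt,
#' inside the 111--128 nt envelope reported for these precursors, and its
#' designed MFE under the builtin model is far below -30 kcal/mol (checked at
#' generation time; stems are re-drawn GC-richer on the rare failure).
#'
#' @param arm1_stem_bp,arm2_stem_bp stem size of each arm, bp.
#' @param loop1,loop2 hairpin loop sizes, nt (loops are A-only so they
#'   cannot pair).
#' @param basal_bp basal helix, bp.
#' @param spacer unpaired nt between the two stem-loops.
#' @param gc_stem_fraction GC content of the stems.
#' @param with_tata,with_abox,with_bbox,with_terminator element switches.
#' @param tata_offset distance (nt) from the TATA box start to the dumbbell
#'   5' edge.
#' @param term_offset distance (nt) from the dumbbell 3' edge to the
#'   terminator start.
#' @param term_run length of the terminator T-run.
#' @param bulges number of 1-nt bulges planted into arm 1 (stress case for
#'   stem aggregation).
#' @param single_hairpin build a single stem-loop instead (decoy for the
#'   dumbbell-specific scan, or a cassette for `single_hairpin_mode`).
#' @param check_fold verify at generation time that the planted structure
#'   folds into the designed topology at <= -30 kcal/mol.
#' @param rng_seed optional seed (otherwise the current RNG stream is used).
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(arm1_stem_bp = 25L, arm2_stem_bp = 25L,
                       loop1 = 8L, loop2 = 8L, basal_bp = 4L, spacer = 2L,
                       gc_stem_fraction = 0.7, with_tata = TRUE,
                       with_abox = FALSE, with_bbox = FALSE,
                       with_terminator = TRUE, tata_offset = 25L,
                       term_offset = 5L, term_run = 5L, bulges = 0L,
                       single_hairpin = FALSE, check_fold = TRUE,
                       rng_seed = NULL) {
  structure(list(arm1_stem_bp = as.integer(arm1_stem_bp),
                 arm2_stem_bp = as.integer(arm2_stem_bp),
                 loop1 = as.integer(loop1), loop2 = as.integer(loop2),
                 basal_bp = as.integer(basal_bp), spacer = as.integer(spacer),
                 gc_stem_fraction = gc_stem_fraction,
                 with_tata = isTRUE(with_tata),
                 with_abox = isTRUE(with_abox),
                 with_bbox = isTRUE(with_bbox),
                 with_terminator = isTRUE(with_terminator),
                 tata_offset = as.integer(tata_offset),
                 term_offset = as.integer(term_offset),
                 term_run = as.integer(term_run),
                 bulges = as.integer(bulges),
                 single_hairpin = isTRUE(single_hairpin),
                 check_fold = isTRUE(check_fold),
                 rng_seed = rng_seed), class = "plant_spec")
}

ABOX_REALIZATION <- "TAGCGCAACCAG"  # fits consensus TRGCNNARYNNG
BBOX_REALIZATION <- "GTTCGAATC"     # fits consensus GTTCRANNC
TATA_REALIZATION <- "TATAAAT"       # fits consensus TATAWAW

random_stem <- function(bp, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), bp, replace = TRUE, prob = p),
        collapse = "")
}

overwrite_at <- function(seq, pos1, what) {
  # pos1 is 1-based
  paste0(substr(seq, 1, pos1 - 1L), what,
         substr(seq, pos1 + nchar(what), nchar(seq)))
}

# dumbbell (or single hairpin) sequence + relative element layout
build_dumbbell <- function(spec) {
  gc <- spec$gc_stem_fraction
  stem1 <- random_stem(spec$arm1_stem_bp, gc)
  if (spec$with_abox) {
    if (spec$arm1_stem_bp < nchar(ABOX_REALIZATION) + 2L)
      stop_config("arm 1 too short to carry an A box")
    stem1 <- overwrite_at(stem1, 3L, ABOX_REALIZATION)
  }
  stem1_5 <- stem1
  if (spec$bulges > 0L) {
    at <- 5L + seq_len(spec$bulges) * 3L
    for (a in rev(at))
      stem1_5 <- paste0(substr(stem1_5, 1, a), "A",
                        substr(stem1_5, a + 1L, nchar(stem1_5)))
  }
  sl1 <- paste0(stem1_5, strrep("A", spec$loop1), revcomp(stem1))

  stem2 <- random_stem(spec$arm2_stem_bp, gc)
  if (spec$with_bbox) {
    if (spec$arm2_stem_bp < nchar(BBOX_REALIZATION) + 2L)
      stop_config("arm 2 too short to carry a B box")
    stem2 <- overwrite_at(stem2, 3L, BBOX_REALIZATION)
  }
  sl2 <- paste0(stem2, strrep("A", spec$loop2), revcomp(stem2))

  if (spec$single_hairpin) {
    basal <- if (spec$basal_bp > 0L) random_stem(spec$basal_bp, 1.0) else ""
    body <- paste0(basal, sl1, revcomp(basal))
    arm1 <- c(spec$basal_bp, spec$basal_bp + nchar(sl1))
    return(list(seq = body, arm1 = arm1, arm2 = NULL))
  }
  basal <- if (spec$basal_bp > 0L) random_stem(spec$basal_bp, 1.0) else ""
  body <- paste0(basal, sl1, strrep("A", spec$spacer), sl2, revcomp(basal))
  arm1 <- c(spec$basal_bp, spec$basal_bp + nchar(sl1))
  arm2_start <- spec$basal_bp + nchar(sl1) + spec$spacer
  arm2 <- c(arm2_start, arm2_start + nchar(sl2))
  list(seq = body, arm1 = arm1, arm2 = arm2)  # 0-based within the dumbbell
}

#' Plant a cassette into a background sequence
#'
#' Overwrites the background in place (sequence length unchanged) with the
#' designed dumbbell, TATA box, A/B boxes and terminator at the offsets
#' given by `spec`, and returns the modified sequence together with a
#' ground-truth record of every element's coordinates, the designed span and
#' the folded MFE. When `spec$check_fold` is on, the planted window is
#' folded with the builtin model and must show the designed hairpin count at
#' <= -30 kcal/mol; stems are re-drawn with increasing GC on failure.
#'
#' @param background DNA string.
#' @param position 0-based start of the dumbbell in the background.
#' @param spec a [plant_spec].
#' @return list with `seq` (modified background) and `truth` (list:
#'   `dumbbell_start`, `dumbbell_end`, `span`, `arm1`, `arm2`, `tata_start`,
#'   `term_start`, `term_end`, `has_boxes`, `mfe`, `n_hairpins`,
#'   `passes_cutoff`).
#' @export
plant_cassette <- function(background, position, spec = plant_spec()) {
  go <- function() {
    sp <- spec
    for (try in 1:20) {
      built <- build_dumbbell(sp)
      len <- nchar(built$seq)
      if (position < 0L || position + len > nchar(background))
        stop_io("cassette of %d nt does not fit at position %d", len, position)
      if (sp$with_tata && position - sp$tata_offset < 0L)
        stop_io("TATA offset extends beyond the sequence start")
      term_start <- position + len + sp$term_offset
      if (sp$with_terminator &&
          term_start + sp$term_run > nchar(background))
        stop_io("terminator extends beyond the sequence end")

      fold <- fold_mfe(built$seq)
      tr <- parse_structure(fold$dot_bracket)
      want <- if (sp$single_hairpin) 1L else 2L
      designed_ok <- tr$n_hairpins == want && fold$mfe <= -30
      if (!sp$check_fold || designed_ok) {
        seq <- background
        seq <- overwrite_at(seq, position + 1L, built$seq)
        if (sp$with_tata)
          seq <- overwrite_at(seq, position - sp$tata_offset + 1L,
                              TATA_REALIZATION)
        if (sp$with_terminator)
          seq <- overwrite_at(seq, term_start + 1L,
                              strrep("T", sp$term_run))
        truth <- list(
          dumbbell_start = position, dumbbell_end = position + len,
          span = len,
          arm1 = position + built$arm1,
          arm2 = if (is.null(built$arm2)) NULL else position + built$arm2,
          tata_start = if (sp$with_tata)
            position - sp$tata_offset else NA_integer_,
          term_start = if (sp$with_terminator) term_start else NA_integer_,
          term_end = if (sp$with_terminator)
            term_start + sp$term_run else NA_integer_,
          has_boxes_planted = sp$with_abox || sp$with_bbox,
          # effective box status under the scanner's default pair rule,
          # including chance hits, found by running the same matcher
          has_boxes = local({
            nA <- nrow(scan_consensus(built$seq, default_motif_specs()$ABOX))
            nB <- nrow(scan_consensus(built$seq, default_motif_specs()$BBOX))
            (nA >= 1 && nB >= 1) || nB >= 2
          }),
          mfe = fold$mfe, n_hairpins = tr$n_hairpins,
          passes_cutoff = fold$mfe <= -30)
        return(list(seq = seq, truth = truth))
      }
      # re-draw with progressively GC-richer stems
      sp$gc_stem_fraction <- min(1, sp$gc_stem_fraction + 0.1)
    }
    stop_io("could not realize the designed fold in 20 attempts")
  }
  if (is.null(spec$rng_seed)) go() else with_seed(spec$rng_seed, go())
}

#' Generate a benchmark dataset of synthetic genomes
#'
#' Each genome is an i.i.d. background (GC 0.4) with 0--2 planted cassettes
#' (two independent Bernoulli draws at `plant_probability`, one per slot)
#' and, optionally, a structural decoy (a strong single hairpin or a weak
#' 6-bp-arm dumbbell, alternating) that must not be called. Fully
#' reproducible per seed.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param plant_probability per-slot planting probability.
#' @param spec base [plant_spec]; box switches are drawn per cassette (the
#'   second slot of a genome carries A/B boxes).
#' @param rng_seed integer seed.
#' @param genome_length background length, nt.
#' @param decoy_probability probability of adding one decoy per genome.
#' @param out_dir when given, writes `genomes.fasta` and `truth.tsv` there.
#' @return list with `records` (list of [seq_record]), `truth` (data.frame:
#'   `genome`, `kind`, `dumbbell_start`, `dumbbell_end`, `span`,
#'   `tata_start`, `term_start`, `has_boxes`, `mfe`, `expect_cassette`) and,
#'   if written, `fasta`, `truth_tsv` paths.
#' @export
make_dataset <- function(n_genomes = 50L, plant_probability = 1.0,
                         spec = plant_spec(), rng_seed = 17L,
                         genome_length = 1500L, decoy_probability = 0.3,
                         out_dir = NULL) {
  if (n_genomes < 1L) stop_config("n_genomes must be >= 1")
  gen <- function() {
    records <- vector("list", n_genomes)
    truth <- list()
    for (g in seq_len(n_genomes)) {
      id <- sprintf("synth_%03d", g)
      seq <- random_background(genome_length, 0.4)
      plant_here <- stats::runif(2) < plant_probability
      slots <- c(sample(180:260, 1), sample(850:930, 1))
      for (s in which(plant_here)) {
        sp <- spec
        if (s == 2L) { sp$with_abox <- TRUE; sp$with_bbox <- TRUE }
        res <- plant_cassette(seq, slots[s], sp)
        seq <- res$seq
        truth[[length(truth) + 1L]] <- data.frame(
          genome = id, kind = "cassette",
          dumbbell_start = res$truth$dumbbell_start,
          dumbbell_end = res$truth$dumbbell_end, span = res$truth$span,
          tata_start = res$truth$tata_start,
          term_start = res$truth$term_start,
          has_boxes = res$truth$has_boxes, mfe = res$truth$mfe,
          expect_cassette = TRUE)
      }
      if (stats::runif(1) < decoy_probability) {
        kind <- if (g %% 2L == 0L) "hairpin_decoy" else "weak_decoy"
        dsp <- if (kind == "hairpin_decoy")
          plant_spec(arm1_stem_bp = 30L, single_hairpin = TRUE)
        else plant_spec(arm1_stem_bp = 6L, arm2_stem_bp = 6L,
                        check_fold = FALSE)
        pos <- sample(530:600, 1)
        res <- plant_cassette(seq, pos, dsp)
        seq <- res$seq
        truth[[length(truth) + 1L]] <- data.frame(
          genome = id, kind = kind,
          dumbbell_start = res$truth$dumbbell_start,
          dumbbell_end = res$truth$dumbbell_end, span = res$truth$span,
          tata_start = res$truth$tata_start,
          term_start = res$truth$term_start,
          has_boxes = res$truth$has_boxes, mfe = res$truth$mfe,
          expect_cassette = FALSE)
      }
      records[[g]] <- seq_record(id, seq, "synthetic LTR-like genome")
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(genome = character(0), kind = character(0),
                 dumbbell_start = integer(0), dumbbell_end = integer(0),
                 span = integer(0), tata_start = integer(0),
                 term_start = integer(0), has_boxes = logical(0),
                 mfe = numeric(0), expect_cassette = logical(0))
    list(records = records, truth = truth_df)
  }
  out <- with_seed(rng_seed, gen())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genomes.fasta")
    tt <- file.path(out_dir, "truth.tsv")
    write_fasta(out$records, fa)
    utils::write.table(out$truth, tt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$fasta <- fa
    out$truth_tsv <- tt
  }
  out
}

#' Compare scan results with a planted-cassette truth table
#'
#' A planted cassette counts as recovered when a reported cassette's
#' dumbbell (trimmed span) overlaps the planted dumbbell interval; reported
#' cassettes overlapping no planted dumbbell count as false calls.
#'
#' @param summaries list of [genome_summary][summarize_genome].
#' @param truth truth data.frame from [make_dataset()].
#' @return list with `sensitivity`, `false_per_genome`, `n_planted`,
#'   `n_recovered`, `n_false`, `n_genomes`.
#' @export
score_against_truth <- function(summaries, truth) {
  planted <- truth[truth$expect_cassette, , drop = FALSE]
  recovered <- 0L
  n_false <- 0L
  for (s in summaries) {
    tg <- planted[planted$genome == s$accession, , drop = FALSE]
    used <- rep(FALSE, nrow(tg))
    for (cs in s$cassettes) {
      iv <- trimmed_iv(cs$dumbbell)
      hit <- which(!used & tg$dumbbell_start < iv[2] &
                     iv[1] < tg$dumbbell_end)
      if (length(hit)) {
        used[hit[1]] <- TRUE
        recovered <- recovered + 1L
      } else {
        n_false <- n_false + 1L
      }
    }
  }
  list(sensitivity = if (nrow(planted)) recovered / nrow(planted) else NA,
       false_per_genome = n_false / length(summaries),
       n_planted = nrow(planted), n_recovered = recovered,
       n_false = n_false, n_genomes = length(summaries))
}
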