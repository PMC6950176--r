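test_that("window generation matches brute-force enumeration", {
  cfg1 <- scan_config(window_min = 100, window_max = 100, window_step = 5)
  w1 <- generate_windows(seq_region("x", 0, 100), cfg1)
  expect_equal(nrow(w1), 1)
  expect_equal(unname(w1[1, ]), c(0L, 100L))

  expect_equal(nrow(generate_windows(seq_region("x", 0, 99), cfg1)), 0)

  cfg2 <- scan_config(window_min = 100, window_max = 140, window_step = 20)
  w2 <- generate_windows(seq_region("x", 0, 150), cfg2)
  # independent double-loop enumeration
  expected <- list()
  for (s in seq(0, 150, by = 20)) for (w in c(100, 120, 140))
    if (s + w <= 150) expected[[length(expected) + 1L]] <- c(s, w = s + w)
  expected <- do.call(rbind, expected)
  expect_equal(unname(w2), unname(expected))
  # deterministic order: by start then width
  expect_true(!is.unsorted(w2[, "start"]))

  # windows honour a nonzero region offset
  w3 <- generate_windows(seq_region("x", 30, 180), cfg2)
  expect_equal(w3[, "start"] - 30L, w2[, "start"])
})

test_that("greedy deduplication keeps the best call per overlap chain", {
  # identical spans: lowest MFE survives
  two <- merge_overlapping(list(fake_call(0, 100, -38),
                                fake_call(0, 100, -45)))
  expect_length(two, 1)
  expect_equal(two[[1]]$fold$mfe, -45)

  # disjoint calls both survive, sorted by start
  disj <- merge_overlapping(list(fake_call(200, 300, -33),
                                 fake_call(0, 100, -40)))
  expect_length(disj, 2)
  expect_equal(vapply(disj, function(x) x$trimmed_region$start, 0L),
               c(0L, 200L))

  # chain A-B-C: B overlaps both, A and C disjoint, MFE(A)<MFE(C)<MFE(B)
  A <- fake_call(0, 100, -50)
  B <- fake_call(80, 180, -35)
  C <- fake_call(150, 250, -42)
  kept <- merge_overlapping(list(B, C, A))
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(x) x$fold$mfe, 0), c(-50, -42))

  expect_equal(merge_overlapping(list()), list())
})

test_that("planted cassettes are recovered with their elements", {
  pg <- planted_genome()
  rec <- seq_record("toy", pg$seq)
  gs <- scan_genome(rec)
  expect_equal(gs$n_cassettes, 1L)
  cs <- gs$cassettes[[1]]
  # recovered dumbbell overlaps the planted one
  expect_lt(cs$dumbbell$trimmed_region$start, pg$truth$dumbbell_end)
  expect_lt(pg$truth$dumbbell_start, cs$dumbbell$trimmed_region$end)
  expect_true(any(cs$promoter_hits$spec == "TATA" &
                  cs$promoter_hits$start == pg$truth$tata_start))
  expect_equal(nrow(cs$terminator), 1)
  expect_equal(cs$has_internal_boxes, pg$truth$has_boxes)
  expect_lte(cs$score, -30)
})

test_that("box-only promoters assemble without a TATA (pair rule)", {
  spec <- plant_spec(with_tata = FALSE, with_abox = TRUE, with_bbox = TRUE)
  pg <- planted_genome(seed = 21L, spec = spec)
  gs <- scan_genome(seq_record("toy", pg$seq))
  expect_equal(gs$n_cassettes, 1L)
  expect_true(gs$cassettes[[1]]$has_internal_boxes)
  expect_equal(gs$n_box_cassettes, 1L)

  # under the single-box rule a lone internal B box also suffices
  spec_b <- plant_spec(with_tata = FALSE, with_bbox = TRUE)
  pg_b <- planted_genome(seed = 22L, spec = spec_b)
  cfg_single <- scan_config(box_promoter_rule = "single")
  gs_b <- scan_genome(seq_record("toy", pg_b$seq), cfg_single)
  expect_gte(gs_b$n_cassettes, 1L)
})

test_that("a dumbbell without a nearby terminator is not a cassette", {
  # T-free background: no chance terminators or TATA boxes at all
  bg <- background_noT(800)
  res <- plant_cassette(bg, 300,
    plant_spec(with_tata = TRUE, with_terminator = FALSE, rng_seed = 31L))
  gs <- scan_genome(seq_record("toy", res$seq))
  expect_equal(gs$n_cassettes, 0L)
  # same layout with the terminator -> 1 cassette
  res2 <- plant_cassette(bg, 300,
    plant_spec(with_tata = TRUE, with_terminator = TRUE, rng_seed = 31L))
  gs2 <- scan_genome(seq_record("toy", res2$seq))
  expect_equal(gs2$n_cassettes, 1L)
})

test_that("per-genome summaries count cassettes and box-bearing cassettes", {
  s0 <- summarize_genome("acc", list())
  expect_equal(c(s0$n_cassettes, s0$n_box_cassettes), c(0L, 0L))

  pg <- planted_genome()
  gs <- scan_genome(seq_record("g", pg$seq))
  expect_lte(gs$n_box_cassettes, gs$n_cassettes)

  # two planted cassettes, second with boxes
  bg <- random_background(1500, 0.4, 41)
  r1 <- plant_cassette(bg, 200, plant_spec(rng_seed = 42L))
  r2 <- plant_cassette(r1$seq, 900,
    plant_spec(with_abox = TRUE, with_bbox = TRUE, rng_seed = 43L))
  gs2 <- scan_genome(seq_record("g2", r2$seq))
  expect_equal(gs2$n_cassettes, 2L)
  expect_equal(gs2$n_box_cassettes,
               sum(r1$truth$has_boxes, r2$truth$has_boxes))
})

test_that("scan results are deterministic and monotone in the energy cutoff", {
  pg <- planted_genome(seed = 51L)
  rec <- seq_record("g", pg$seq)
  a <- scan_genome(rec)
  b <- scan_genome(rec)
  expect_identical(a$n_cassettes, b$n_cassettes)
  expect_identical(
    lapply(a$cassettes, function(c) c(c$cassette_region$start,
                                      c$cassette_region$end, c$score)),
    lapply(b$cassettes, function(c) c(c$cassette_region$start,
                                      c$cassette_region$end, c$score)))

  counts <- vapply(c(-60, -30, -20), function(mm)
    scan_genome(rec, scan_config(mfe_max = mm))$n_cassettes, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("minus-strand scanning mirrors a reverse-complemented genome", {
  pg <- planted_genome(seed = 61L)
  fwd <- seq_record("g", pg$seq)
  rev <- seq_record("g", revcomp(pg$seq))
  n <- nchar(pg$seq)

  plus <- scan_genome(fwd, scan_config(strand = "+"))
  minus_on_rc <- scan_genome(rev, scan_config(strand = "-"))
  expect_equal(minus_on_rc$n_cassettes, plus$n_cassettes)
  # mirrored coordinates: [s,e) on + maps to [n-e, n-s) on the rc genome
  ivp <- c(plus$cassettes[[1]]$cassette_region$start,
           plus$cassettes[[1]]$cassette_region$end)
  ivm <- c(minus_on_rc$cassettes[[1]]$cassette_region$start,
           minus_on_rc$cassettes[[1]]$cassette_region$end)
  expect_equal(ivm, c(n - ivp[2], n - ivp[1]))
  expect_equal(minus_on_rc$cassettes[[1]]$cassette_region$strand, "-")
  expect_equal(minus_on_rc$cassettes[[1]]$seq, plus$cassettes[[1]]$seq)

  # both = union of + and - (no palindromic cassette here)
  both <- scan_genome(rev, scan_config(strand = "both",
                                       dedupe_identical = FALSE))
  expect_equal(both$n_cassettes,
               scan_genome(rev, scan_config(strand = "+"))$n_cassettes +
               minus_on_rc$n_cassettes)
})

test_that("identical LTR copies are reported once with deduplication on", {
  pg <- planted_genome(seed = 71L, n = 700L, position = 250L)
  # provirus-like: the same LTR sequence at both ends
  genome <- paste0(pg$seq, background_noT(300), pg$seq)
  rec <- seq_record("prov", genome)
  dedup <- scan_genome(rec)
  nodedup <- scan_genome(rec, scan_config(dedupe_identical = FALSE))
  expect_equal(nodedup$n_cassettes, 2L)
  expect_equal(dedup$n_cassettes, 1L)
})

test_that("annotated LTR features restrict scanning", {
  pg <- planted_genome(seed = 81L)
  feats <- list(list(kind = "LTR", region = seq_region("g", 150, 600)))
  rec <- seq_record("g", pg$seq, features = feats)
  gs <- scan_genome(rec)
  expect_equal(gs$n_cassettes, 1L)
  # a feature away from the cassette finds nothing
  rec2 <- seq_record("g", pg$seq, features = list(
    list(kind = "LTR", region = seq_region("g", 500, 800))))
  expect_equal(scan_genome(rec2)$n_cassettes, 0L)
})

test_that("scan configuration round-trips through its key=value file", {
  cfg <- scan_config(window_min = 110, window_max = 130, mfe_max = -25,
                     box_promoter_rule = "single", strand = "both",
                     dedupe_identical = FALSE)
  p <- withr::local_tempfile(fileext = ".config")
  write_scan_config(cfg, p)
  back <- read_scan_config(p)
  expect_equal(back$window_min, 110L)
  expect_equal(back$window_max, 130L)
  expect_equal(back$mfe_max, -25)
  expect_equal(back$box_promoter_rule, "single")
  expect_equal(back$strand, "both")
  expect_false(back$dedupe_identical)
  expect_equal(back$motif_specs$ABOX$consensus, cfg$motif_specs$ABOX$consensus)
})
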