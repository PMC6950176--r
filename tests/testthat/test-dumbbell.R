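toy_cfg <- function(...) topology_config(min_arm_stem_bp = 4L,
                                         min_paired_fraction = 0.3, ...)

test_that("two-hairpin structures with adequate arms classify as dumbbells", {
  db <- "(((((((...))))..((((...)))))))"
  cl <- classify_dumbbell(fake_fold(db), seq_region("w", 0, nchar(db)),
                          toy_cfg())
  expect_equal(cl$n_hairpins, 2L)
  expect_equal(cl$basal_helix_bp, 3L)
  expect_true(cl$passes_topology)
  expect_length(cl$arm_regions, 2)
  # arms are the two stem-loop subtrees under the multiloop
  expect_equal(cl$arm_regions[[1]]$start, 3L)
  expect_equal(cl$arm_regions[[1]]$end, 14L)
  expect_equal(cl$arm_regions[[2]]$start, 16L)
  expect_equal(cl$arm_regions[[2]]$end, 27L)
  expect_equal(cl$loop_sizes, c(3L, 3L))
})

test_that("wrong hairpin counts fail dumbbell topology", {
  one <- classify_dumbbell(fake_fold("(((...)))"), seq_region("w", 0, 9),
                           toy_cfg())
  expect_equal(one$n_hairpins, 1L)
  expect_false(one$passes_topology)

  three <- classify_dumbbell(fake_fold("((...))((...))((...))"),
                             seq_region("w", 0, 21), toy_cfg())
  expect_equal(three$n_hairpins, 3L)
  expect_false(three$passes_topology)

  none <- classify_dumbbell(fake_fold("......"), seq_region("w", 0, 6),
                            toy_cfg())
  expect_equal(none$n_hairpins, 0L)
  expect_false(none$passes_topology)
})

test_that("single-hairpin mode accepts exactly one stem-loop", {
  cfg <- topology_config(min_arm_stem_bp = 3L, single_hairpin_mode = TRUE,
                         min_paired_fraction = 0.3)
  one <- classify_dumbbell(fake_fold("(((...)))"), seq_region("w", 0, 9), cfg)
  expect_true(one$passes_topology)
  two <- classify_dumbbell(fake_fold("((((...))))((((...))))"),
                           seq_region("w", 0, 22), cfg)
  expect_false(two$passes_topology)
})

test_that("arm stem size aggregates across bulges and internal loops", {
  # arm 1: 2 bp + bulge + 2 bp = 4 bp total; arm 2: 4 bp contiguous
  db <- "((.((...))))..((((...))))"
  cl <- classify_dumbbell(fake_fold(db), seq_region("w", 0, nchar(db)),
                          toy_cfg())
  expect_true(cl$passes_topology)
  cl5 <- classify_dumbbell(fake_fold(db), seq_region("w", 0, nchar(db)),
                           topology_config(min_arm_stem_bp = 5L,
                                           min_paired_fraction = 0.3))
  expect_false(cl5$passes_topology)
})

test_that("side-by-side arms have no basal helix", {
  db <- "((((...))))..((((...))))"
  cl <- classify_dumbbell(fake_fold(db), seq_region("w", 0, nchar(db)),
                          toy_cfg())
  expect_true(cl$passes_topology)
  expect_equal(cl$basal_helix_bp, 0L)
  cfg_basal <- topology_config(min_arm_stem_bp = 4L,
                               min_basal_helix_bp = 1L,
                               min_paired_fraction = 0.3)
  expect_false(classify_dumbbell(fake_fold(db),
                                 seq_region("w", 0, nchar(db)),
                                 cfg_basal)$passes_topology)
})

test_that("classification is invariant to unpaired window padding", {
  core <- "(((((((...))))..((((...)))))))"
  padded <- paste0("......", core, "....")
  a <- classify_dumbbell(fake_fold(core), seq_region("w", 100, 100 + nchar(core)),
                         toy_cfg())
  b <- classify_dumbbell(fake_fold(padded), seq_region("w", 94, 94 + nchar(padded)),
                         toy_cfg())
  expect_equal(a$passes_topology, b$passes_topology)
  expect_equal(a$basal_helix_bp, b$basal_helix_bp)
  expect_equal(dumbbell_span(a), dumbbell_span(b))
  # absolute trimmed and arm coordinates coincide
  expect_equal(b$trimmed_region$start, a$trimmed_region$start)
  expect_equal(vapply(b$arm_regions, function(r) r$start, 0L),
               vapply(a$arm_regions, function(r) r$start, 0L))
})

test_that("dumbbell span is the trimmed paired extent", {
  # 140 nt window, first paired base at offset 6, last at offset 125
  db <- paste0(strrep(".", 6),
               strrep("(", 27), "....", strrep(")", 27), "..",
               strrep("(", 27), "......", strrep(")", 27), strrep(".", 14))
  expect_equal(nchar(db), 140)
  cl <- classify_dumbbell(fake_fold(db), seq_region("w", 0, 140),
                          toy_cfg())
  expect_true(cl$passes_topology)
  expect_equal(dumbbell_span(cl), 120L)

  pg <- planted_genome()
  f <- fold_mfe(substr(pg$seq, pg$truth$dumbbell_start + 1,
                       pg$truth$dumbbell_end))
  cl2 <- classify_dumbbell(f, seq_region("g", pg$truth$dumbbell_start,
                                         pg$truth$dumbbell_end))
  expect_true(cl2$passes_topology)
  expect_equal(dumbbell_span(cl2), pg$truth$span)

  expect_error(dumbbell_span(classify_dumbbell(fake_fold("......"),
                                               seq_region("w", 0, 6))),
               class = "dbscan_config_error")
})

test_that("energy gate follows mfe_max monotonically", {
  db <- "(((((((...))))..((((...)))))))"
  for (mfe in c(-50, -31)) {
    cl <- classify_dumbbell(fake_fold(db, mfe = mfe),
                            seq_region("w", 0, nchar(db)), toy_cfg())
    expect_true(cl$passes_energy)
  }
  cl <- classify_dumbbell(fake_fold(db, mfe = -29.9),
                          seq_region("w", 0, nchar(db)), toy_cfg())
  expect_false(cl$passes_energy)
  # relaxing the threshold never turns a passing call into a failing one
  cl2 <- classify_dumbbell(fake_fold(db, mfe = -29.9),
                           seq_region("w", 0, nchar(db)),
                           toy_cfg(mfe_max = -25))
  expect_true(cl2$passes_energy)
})
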