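test_that("FASTA reading normalizes case and U/T and preserves order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x some description", "acgu", ">b", "NNNN"), fa)
  recs <- read_fasta(fa)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$description, "some description")
  expect_equal(recs[[1]]$seq, "ACGT")
  expect_equal(vapply(recs, function(r) r$id, ""), c("x", "b"))

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_equal(read_fasta(empty), list())
})

test_that("invalid sequence characters are rejected with the record named", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">bad", "ACGXT"), fa)
  expect_error(read_fasta(fa), "bad.*X", class = "dbscan_io_error")
  expect_error(seq_record("r1", "AC-GT"), "r1")
})

test_that("FASTA write/read round-trips records", {
  recs <- list(seq_record("a", "ACGTACGT", "first"),
               seq_record("b", strrep("ACGTN", 30)))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, fa)
  back <- read_fasta(fa)
  expect_equal(vapply(back, function(r) r$seq, ""),
               vapply(recs, function(r) r$seq, ""))
  expect_equal(vapply(back, function(r) r$id, ""), c("a", "b"))
})

test_that("region extraction honours bounds and strand", {
  r <- seq_record("x", "ACGTAC")
  expect_equal(extract_region(r, seq_region("x", 1, 4)), "CGT")
  expect_equal(extract_region(r, seq_region("x", 1, 4, "-")), "ACG")
  expect_equal(extract_region(r, seq_region("x", 0, 4)), "ACGT")
  expect_error(extract_region(r, seq_region("x", 3, 9)),
               class = "dbscan_io_error")
  expect_error(seq_region("x", 4, 4), class = "dbscan_config_error")
  expect_error(seq_region("x", -1, 4), class = "dbscan_config_error")
})

test_that("GenBank features use 1-based inclusive converted to 0-based half-open", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TEST 120 bp DNA linear SYN",
    "ACCESSION   TEST",
    "VERSION     TEST.1",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     repeat_region   1..100",
    "     LTR             complement(5..20)",
    "     gene            30..50",
    "ORIGIN",
    sprintf("%9d %s", 1, paste(rep("acgtacgtac", 6), collapse = " ")),
    sprintf("%9d %s", 61, paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), gb)
  rec <- read_genbank(gb)
  expect_equal(rec$id, "TEST.1")
  expect_equal(nchar(rec$seq), 120)
  # gene features are ignored; LTR/repeat_region kept
  expect_length(rec$features, 2)
  expect_equal(rec$features[[1]]$kind, "repeat_region")
  expect_equal(rec$features[[1]]$region$start, 0L)
  expect_equal(rec$features[[1]]$region$end, 100L)
  expect_equal(rec$features[[2]]$region$strand, "-")
  expect_equal(rec$features[[2]]$region$start, 4L)
  expect_equal(rec$features[[2]]$region$end, 20L)
})

test_that("GenBank write-then-read is the identity on fixture records", {
  rec <- seq_record("SYN001.1", random_background(333, 0.4, 3),
                    "synthetic fixture",
                    features = list(
                      list(kind = "LTR", region = seq_region("SYN001.1", 0, 120)),
                      list(kind = "repeat_region",
                           region = seq_region("SYN001.1", 200, 333))))
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  back <- read_genbank(gb)
  expect_equal(back$id, rec$id)
  expect_equal(back$seq, rec$seq)
  expect_equal(length(back$features), 2)
  expect_equal(back$features[[1]]$region$start, 0L)
  expect_equal(back$features[[1]]$region$end, 120L)
})

test_that("missing ORIGIN is a format error", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS  X 10 bp", "VERSION X.1"), gb)
  expect_error(read_genbank(gb), "ORIGIN", class = "dbscan_io_error")
})

test_that("GFF3 output re-parses and maps back to internal coordinates", {
  pg <- planted_genome()
  rec <- seq_record("toy", pg$seq)
  gs <- scan_genome(rec)
  expect_gte(gs$n_cassettes, 1)
  gff <- withr::local_tempfile(fileext = ".gff3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_outputs(gs$cassettes, list(gs), gff, tsv)

  gr <- rtracklayer::import(gff, format = "gff3")
  cass <- gr[gr$type == "pri_miRNA_cassette"]
  expect_length(cass, gs$n_cassettes)
  # GFF 1-based inclusive back to 0-based half-open
  internal <- gs$cassettes[[1]]$cassette_region
  expect_equal(GenomicRanges::start(cass)[1] - 1L, internal$start)
  expect_equal(GenomicRanges::end(cass)[1], internal$end)
  expect_equal(cass$score[1], gs$cassettes[[1]]$score)
  # children present and inside the cassette
  kids <- gr[gr$type %in% c("stem_loop", "TATA_box", "terminator")]
  expect_gte(length(kids), 3)

  df <- read.delim(tsv)
  expect_equal(df$accession, "toy")
  expect_equal(df$n_cassettes, gs$n_cassettes)
})

test_that("empty cassette list still writes valid outputs with zero rows", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_outputs(list(), list(summarize_genome("acc1", list())), gff, tsv)
  expect_true(file.exists(gff))
  df <- read.delim(tsv)
  expect_equal(df$n_cassettes, 0L)
  expect_equal(df$n_box_cassettes, 0L)
  # a genome with 1 cassette and 0 boxes produces the "...\t1\t0" row shape
  pg <- planted_genome()
  gs <- scan_genome(seq_record("g1", pg$seq))
  write_outputs(gs$cassettes, list(gs), NULL, tsv)
  ln <- readLines(tsv)[2]
  expect_match(ln, sprintf("^g1\t%d\t%d$", gs$n_cassettes, gs$n_box_cassettes))
})

test_that("BED regions restrict the scan", {
  pg <- planted_genome()
  rec <- seq_record("toy", pg$seq)
  bed <- withr::local_tempfile(fileext = ".bed")
  # region covering the cassette, and one far away
  writeLines(c("toy\t200\t500\tltr1\t0\t+",
               "toy\t600\t790\tltr2\t0\t+"), bed)
  regions <- read_regions_bed(bed)
  expect_length(regions, 2)
  expect_equal(regions[[1]]$start, 200L)
  expect_equal(regions[[1]]$end, 500L)
  gs <- scan_genome(rec, regions = regions)
  expect_gte(gs$n_cassettes, 1)
})
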