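#' Cassette scan configuration
#'
#' All tunable parameters of the cassette scanner in one object. Defaults
#' realize the search for Pol III cassettes of about 130 nt: windows of
#' 100--140 nt (step 5) are folded, accepted dumbbells must reach
#' `mfe_max = -30` kcal/mol, a terminator (T-run) must begin within
#' `terminator_downstream_window` nt after the trimmed 3' end, and either a
#' TATA box 15--40 nt upstream of the trimmed 5' end or at least one
#' gene-internal A/B box inside the dumbbell is required.
#'
#' @param window_min,window_max,window_step window sweep, nt.
#' @param mfe_max energy cutoff, kcal/mol.
#' @param motif_specs named list of [motif_spec].
#' @param tata_upstream_window length-2 integer: allowed distance (nt) from
#'   the TATA box start to the trimmed dumbbell 5' end.
#' @param terminator_downstream_window max distance (nt) from the trimmed 3'
#'   end to the terminator start.
#' @param require_terminator,require_promoter element requirements.
#' @param box_promoter_rule `"pair"`: internal boxes count as a promoter
#'   only as an A-box + B-box or B-box + B-box combination (the functional
#'   gene-internal type-2 arrangement); `"single"`: any one internal box
#'   suffices. With the degenerate consensi a lone 1-mismatch box arises by
#'   chance in a quarter of 130-nt windows, so `"pair"` is the default.
#' @param strand `"+"`, `"-"` or `"both"` (cassettes are described on the
#'   provirus sense strand; both-strand scanning is available).
#' @param topology a [topology_config]; its `mfe_max` is kept in sync.
#' @param count_boxes `"cassettes"` (summary column counts box-bearing
#'   cassettes) or `"boxes"` (raw internal box hits).
#' @param dedupe_identical drop cassettes with identical sequence within one
#'   genome (5' and 3' LTRs are copies).
#' @param backend folding backend, `"builtin"` or `"vienna"`.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(window_min = 100L, window_max = 140L,
                        window_step = 5L, mfe_max = -30,
                        motif_specs = default_motif_specs(),
                        tata_upstream_window = c(15L, 40L),
                        terminator_downstream_window = 25L,
                        require_terminator = TRUE, require_promoter = TRUE,
                        box_promoter_rule = c("pair", "single"),
                        strand = c("+", "-", "both"),
                        topology = NULL, count_boxes = c("cassettes", "boxes"),
                        dedupe_identical = TRUE,
                        backend = c("builtin", "vienna")) {
  strand <- match.arg(strand)
  box_promoter_rule <- match.arg(box_promoter_rule)
  count_boxes <- match.arg(count_boxes)
  backend <- match.arg(backend)
  if (window_min > window_max) stop_config("window_min > window_max")
  if (window_step < 1L) stop_config("window_step must be >= 1")
  if (is.null(topology)) topology <- topology_config(mfe_max = mfe_max)
  topology$mfe_max <- mfe_max
  structure(list(
    window_min = as.integer(window_min), window_max = as.integer(window_max),
    window_step = as.integer(window_step), mfe_max = mfe_max,
    motif_specs = motif_specs,
    tata_upstream_window = as.integer(tata_upstream_window),
    terminator_downstream_window = as.integer(terminator_downstream_window),
    require_terminator = isTRUE(require_terminator),
    require_promoter = isTRUE(require_promoter),
    box_promoter_rule = box_promoter_rule,
    strand = strand, topology = topology, count_boxes = count_boxes,
    dedupe_identical = isTRUE(dedupe_identical), backend = backend),
    class = "scan_config")
}

#' Write or read a scan configuration as a flat key=value file
#' @param config a [scan_config].
#' @param path file path.
#' @return `read_scan_config` returns a [scan_config].
#' @export
write_scan_config <- function(config, path) {
  sp <- config$motif_specs
  ln <- c(
    sprintf("window_min = %d", config$window_min),
    sprintf("window_max = %d", config$window_max),
    sprintf("window_step = %d", config$window_step),
    sprintf("mfe_max = %g", config$mfe_max),
    sprintf("tata_consensus = %s", sp$TATA$consensus),
    sprintf("tata_max_mismatch = %d", sp$TATA$max_mismatch),
    sprintf("abox_consensus = %s", sp$ABOX$consensus),
    sprintf("abox_max_mismatch = %d", sp$ABOX$max_mismatch),
    sprintf("bbox_consensus = %s", sp$BBOX$consensus),
    sprintf("bbox_max_mismatch = %d", sp$BBOX$max_mismatch),
    sprintf("term_min_run = %d", sp$TERM$min_run),
    sprintf("tata_upstream_min = %d", config$tata_upstream_window[1]),
    sprintf("tata_upstream_max = %d", config$tata_upstream_window[2]),
    sprintf("terminator_downstream_window = %d",
            config$terminator_downstream_window),
    sprintf("require_terminator = %s", config$require_terminator),
    sprintf("require_promoter = %s", config$require_promoter),
    sprintf("box_promoter_rule = %s", config$box_promoter_rule),
    sprintf("strand = %s", config$strand),
    sprintf("min_arm_stem_bp = %d", config$topology$min_arm_stem_bp),
    sprintf("min_basal_helix_bp = %d", config$topology$min_basal_helix_bp),
    sprintf("min_paired_fraction = %g", config$topology$min_paired_fraction),
    sprintf("single_hairpin_mode = %s", config$topology$single_hairpin_mode),
    sprintf("count_boxes = %s", config$count_boxes),
    sprintf("dedupe_identical = %s", config$dedupe_identical),
    sprintf("backend = %s", config$backend))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_scan_config
#' @export
read_scan_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: %s", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "\\s*=\\s*")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  g <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  gi <- function(k, default) as.integer(g(k, default))
  gn <- function(k, default) as.numeric(g(k, default))
  gl <- function(k, default) toupper(g(k, default)) %in% c("TRUE", "YES", "1")
  specs <- list(
    TATA = motif_spec("TATA", g("tata_consensus", "TATAWAW"),
                      gi("tata_max_mismatch", 0L)),
    ABOX = motif_spec("ABOX", g("abox_consensus", "TRGCNNARYNNG"),
                      gi("abox_max_mismatch", 1L)),
    BBOX = motif_spec("BBOX", g("bbox_consensus", "GTTCRANNC"),
                      gi("bbox_max_mismatch", 1L)),
    TERM = motif_spec("TERM", min_run = gi("term_min_run", 4L)))
  scan_config(
    window_min = gi("window_min", 100L), window_max = gi("window_max", 140L),
    window_step = gi("window_step", 5L), mfe_max = gn("mfe_max", -30),
    motif_specs = specs,
    tata_upstream_window = c(gi("tata_upstream_min", 15L),
                             gi("tata_upstream_max", 40L)),
    terminator_downstream_window = gi("terminator_downstream_window", 25L),
    require_terminator = gl("require_terminator", TRUE),
    require_promoter = gl("require_promoter", TRUE),
    box_promoter_rule = g("box_promoter_rule", "pair"),
    strand = g("strand", "+"),
    topology = topology_config(
      mfe_max = gn("mfe_max", -30),
      min_arm_stem_bp = gi("min_arm_stem_bp", 8L),
      min_basal_helix_bp = gi("min_basal_helix_bp", 0L),
      min_paired_fraction = gn("min_paired_fraction", 0.5),
      single_hairpin_mode = gl("single_hairpin_mode", FALSE)),
    count_boxes = g("count_boxes", "cassettes"),
    dedupe_identical = gl("dedupe_identical", TRUE),
    backend = g("backend", "builtin"))
}

#' Enumerate fold windows over a region
#'
#' All `[i, i+w)` with `w` in `window_min..window_max` (step `window_step`)
#' and `i` stepped by `window_step` from the region start, clipped to the
#' region; ordered by start then width. A region shorter than `window_min`
#' yields no windows.
#'
#' @param region a [seq_region].
#' @param config a [scan_config].
#' @return integer matrix with columns `start`, `end` (absolute, 0-based
#'   half-open).
#' @export
generate_windows <- function(region, config = scan_config()) {
  L <- region_width(region)
  widths <- seq(config$window_min, config$window_max, by = config$window_step)
  widths <- widths[widths <= L]
  if (!length(widths))
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  rows <- list()
  starts <- seq(region$start, region$end - min(widths), by = config$window_step)
  for (s in starts) {
    w <- widths[s + widths <= region$end]
    if (length(w))
      rows[[length(rows) + 1L]] <- cbind(start = s, end = s + w)
  }
  out <- do.call(rbind, rows)
  storage.mode(out) <- "integer"
  out
}

# coordinate mapping between an oriented scan frame and the reference:
# frame coordinates are [0, L) on the scanned strand of `base`
map_frame_region <- function(r, base) {
  if (base$strand == "+")
    seq_region(base$seq_id, base$start + r$start, base$start + r$end, "+")
  else
    seq_region(base$seq_id, base$end - r$end, base$end - r$start, "-")
}

map_frame_hits <- function(hits, base) {
  if (!nrow(hits)) return(hits)
  if (base$strand == "+") {
    hits$start <- base$start + hits$start
    hits$end <- base$start + hits$end
  } else {
    new_start <- base$end - hits$end
    hits$end <- base$end - hits$start
    hits$start <- new_start
    hits$strand <- "-"
  }
  hits
}

map_frame_call <- function(cl, base) {
  cl$window <- map_frame_region(cl$window, base)
  cl$trimmed_region <- map_frame_region(cl$trimmed_region, base)
  # arm order stays 5' to 3' on the cassette's own strand
  cl$arm_regions <- lapply(cl$arm_regions, map_frame_region, base = base)
  cl
}

map_frame_cassette <- function(cs, base) {
  cs$dumbbell <- map_frame_call(cs$dumbbell, base)
  cs$cassette_region <- map_frame_region(cs$cassette_region, base)
  cs$promoter_hits <- map_frame_hits(cs$promoter_hits, base)
  cs$terminator <- map_frame_hits(cs$terminator, base)
  cs$id <- sprintf("%s_cassette_%d%s", cs$cassette_region$seq_id,
                   cs$dumbbell$trimmed_region$start,
                   if (base$strand == "-") "m" else "")
  cs
}

#' Fold and classify every window of a region
#'
#' Folds each window (single banded DP pass per region), classifies its
#' structure, and keeps windows that pass both the energy cutoff and the
#' dumbbell topology test; results are sorted by MFE then start. Minus-strand
#' regions are scanned on their reverse complement; reported coordinates are
#' mapped back to the reference (strand `-`).
#'
#' @param seq full sequence of the record the region lives on (string or
#'   [seq_record]).
#' @param region a [seq_region].
#' @param config a [scan_config].
#' @param model an `energy_model`.
#' @return list of passing [dumbbell_call][classify_dumbbell] objects.
#' @export
scan_region <- function(seq, region, config = scan_config(),
                        model = default_energy_model()) {
  calls <- scan_frame(extract_region(seq, region), region$seq_id, config,
                      model)
  lapply(calls, map_frame_call, base = region)
}

# window sweep + fold + classify inside an oriented frame [0, L)
scan_frame <- function(oseq, seq_id, config, model) {
  frame <- seq_region(seq_id, 0L, nchar(oseq))
  win <- generate_windows(frame, config)
  if (!nrow(win)) return(list())
  folded <- fold_windows(oseq, win, model, backend = config$backend)
  calls <- list()
  for (r in seq_len(nrow(folded))) {
    if (folded$mfe[r] > config$mfe_max) next  # cannot pass energy
    a <- folded$start[r]; b <- folded$end[r]
    fwin <- seq_region(seq_id, a, b, "+")
    fr <- new_fold_result(substring(oseq, a + 1L, b), folded$db[r],
                          folded$mfe[r], config$backend)
    cl <- classify_dumbbell(fr, fwin, config$topology)
    if (cl$passes_energy && cl$passes_topology)
      calls[[length(calls) + 1L]] <- cl
  }
  ord <- order(vapply(calls, function(x) x$fold$mfe, 0.0),
               vapply(calls, function(x) x$window$start, 0L))
  calls[ord]
}

trimmed_iv <- function(call)
  c(call$trimmed_region$start, call$trimmed_region$end)

#' Deduplicate overlapping dumbbell calls
#'
#' Greedy selection by ascending MFE (ties: leftmost trimmed start, then
#' narrowest); a call whose trimmed span overlaps an already selected call
#' by at least 1 nt is discarded. Output sorted by start.
#'
#' @param calls list of passing [dumbbell_call][classify_dumbbell] objects
#'   from one region.
#' @return list of retained calls.
#' @export
merge_overlapping <- function(calls) {
  if (!length(calls)) return(list())
  mfe <- vapply(calls, function(x) x$fold$mfe, 0.0)
  st <- vapply(calls, function(x) x$trimmed_region$start, 0L)
  wd <- vapply(calls, function(x) region_width(x$trimmed_region), 0L)
  keep <- list()
  for (i in order(mfe, st, wd)) {
    iv <- trimmed_iv(calls[[i]])
    clash <- any(vapply(keep, function(k) {
      kv <- trimmed_iv(k)
      iv[1] < kv[2] && kv[1] < iv[2]
    }, TRUE))
    if (!clash) keep[[length(keep) + 1L]] <- calls[[i]]
  }
  keep[order(vapply(keep, function(x) x$trimmed_region$start, 0L))]
}

#' Associate promoter and terminator elements with dumbbell calls
#'
#' A deduplicated call becomes a cassette iff (a) a terminator run begins
#' within `terminator_downstream_window` nt after the trimmed 3' end (the
#' nearest qualifying run is chosen), and (b) a TATA box starts within the
#' `tata_upstream_window` distance band upstream of the trimmed 5' end, or
#' at least one A/B box lies inside the trimmed dumbbell span. Either
#' requirement can be switched off in the config.
#'
#' @param seq full reference sequence (for cassette ids).
#' @param calls deduplicated calls (plus-strand coordinates).
#' @param motif_hits data.frame from [scan_all_motifs()] over the same
#'   coordinates.
#' @param config a [scan_config].
#' @return list of `cassette` objects: `id`, `dumbbell`, `promoter_hits`,
#'   `terminator`, `cassette_region`, `has_internal_boxes`, `n_internal_boxes`,
#'   `score` (the dumbbell MFE), `seq`.
#' @export
assemble_cassettes <- function(seq, calls, motif_hits,
                               config = scan_config()) {
  out <- list()
  for (cl in calls) {
    ts <- cl$trimmed_region$start; te <- cl$trimmed_region$end
    # a qualifying T-run overlaps the downstream window (te, te+w]; a run may
    # begin a few nt before the trimmed end when the fold absorbed flanking
    # bases or background T's extend the planted run leftwards
    term <- motif_hits[motif_hits$spec == "TERM" &
                       motif_hits$end > te &
                       motif_hits$start <= te + config$terminator_downstream_window, ,
                       drop = FALSE]
    if (nrow(term)) term <- term[which.min(pmax(term$start - te, 0L)), ,
                                 drop = FALSE]
    if (config$require_terminator && !nrow(term)) next

    dist <- ts - motif_hits$start
    tata <- motif_hits[motif_hits$spec == "TATA" &
                       dist >= config$tata_upstream_window[1] &
                       dist <= config$tata_upstream_window[2], , drop = FALSE]
    boxes <- motif_hits[motif_hits$spec %in% c("ABOX", "BBOX") &
                        motif_hits$start >= ts & motif_hits$end <= te, ,
                        drop = FALSE]
    nA <- sum(boxes$spec == "ABOX"); nB <- sum(boxes$spec == "BBOX")
    box_ok <- if (config$box_promoter_rule == "pair")
      (nA >= 1L && nB >= 1L) || nB >= 2L else nrow(boxes) > 0L
    if (config$require_promoter && !nrow(tata) && !box_ok) next

    promoter <- rbind(tata, boxes)
    cass_start <- min(ts, if (nrow(promoter)) min(promoter$start) else ts)
    cass_end <- if (nrow(term)) max(te, term$end[1]) else te
    region <- seq_region(cl$window$seq_id, cass_start, cass_end,
                         cl$window$strand)
    cs <- structure(list(
      id = sprintf("%s_cassette_%d", cl$window$seq_id, ts),
      dumbbell = cl,
      promoter_hits = promoter,
      terminator = term,
      cassette_region = region,
      has_internal_boxes = box_ok,
      n_internal_boxes = nrow(boxes),
      score = cl$fold$mfe,
      seq = substring(seq, ts + 1L, te)), class = "cassette")
    out[[length(out) + 1L]] <- cs
  }
  out
}

#' @export
print.cassette <- function(x, ...) {
  cat(sprintf("cassette %s [%d,%d) mfe=%.2f span=%d nt %s%s\n",
              x$id, x$cassette_region$start, x$cassette_region$end, x$score,
              dumbbell_span(x$dumbbell),
              if (nrow(x$promoter_hits[x$promoter_hits$spec == "TATA", ]))
                "TATA " else "",
              if (x$has_internal_boxes) "A/B-box" else ""))
  invisible(x)
}

#' Per-genome cassette summary
#'
#' @param accession genome identifier.
#' @param cassettes cassettes from all scanned regions of the genome.
#' @param count_boxes `"cassettes"`: the box column counts cassettes bearing
#'   at least one internal A/B box; `"boxes"`: it counts the raw box hits.
#' @return object of class `genome_summary`: `accession`, `n_cassettes`,
#'   `n_box_cassettes`, `cassettes`.
#' @export
summarize_genome <- function(accession, cassettes,
                             count_boxes = c("cassettes", "boxes")) {
  count_boxes <- match.arg(count_boxes)
  nb <- if (count_boxes == "cassettes")
    sum(vapply(cassettes, function(c) c$has_internal_boxes, TRUE))
  else sum(vapply(cassettes, function(c) c$n_internal_boxes, 0L))
  structure(list(accession = accession,
                 n_cassettes = length(cassettes),
                 n_box_cassettes = as.integer(nb),
                 cassettes = cassettes), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("%s\t%d cassette(s)\t%d with A/B boxes\n",
              x$accession, x$n_cassettes, x$n_box_cassettes))
  invisible(x)
}

# regions to scan for one record: annotated LTR/repeat_region features when
# present, otherwise the whole sequence
scan_regions_for <- function(record, regions = NULL) {
  if (!is.null(regions)) {
    regions <- Filter(function(r) r$seq_id == record$id, regions)
    if (length(regions)) return(regions)
  }
  feats <- Filter(function(f) f$kind %in% c("LTR", "repeat_region"),
                  record$features)
  if (length(feats)) return(lapply(feats, function(f) f$region))
  list(seq_region(record$id, 0L, nchar(record$seq)))
}

#' Scan one genome for Pol III dumbbell cassettes
#'
#' Runs the full pipeline on one record: region selection (annotated LTRs or
#' whole sequence), window sweep + folding + topology classification,
#' overlap deduplication, motif association, and optional genome-wide
#' removal of cassettes with identical sequence (the two LTRs of a provirus
#' are copies).
#'
#' @param record a [seq_record].
#' @param config a [scan_config].
#' @param regions optional list of [seq_region] restricting the scan.
#' @param model an `energy_model`.
#' @return a [genome_summary][summarize_genome].
#' @export
scan_genome <- function(record, config = scan_config(), regions = NULL,
                        model = default_energy_model()) {
  strands <- switch(config$strand, "+" = "+", "-" = "-",
                    both = c("+", "-"))
  cassettes <- list()
  for (base0 in scan_regions_for(record, regions)) {
    for (std in strands) {
      base <- seq_region(base0$seq_id, base0$start, base0$end, std)
      oseq <- extract_region(record$seq, base)
      calls <- scan_frame(oseq, record$id, config, model)
      calls <- merge_overlapping(calls)
      if (!length(calls)) next
      # promoter/terminator relations are collinear in the scanned frame;
      # assemble there, then map the finished cassette to the reference
      hits <- scan_all_motifs(oseq, config$motif_specs)
      cass <- assemble_cassettes(oseq, calls, hits, config)
      cass <- lapply(cass, map_frame_cassette, base = base)
      cassettes <- c(cassettes, cass)
    }
  }
  if (config$dedupe_identical && length(cassettes) > 1L) {
    seqs <- vapply(cassettes, function(c) c$seq, "")
    cassettes <- cassettes[!duplicated(seqs)]
  }
  summarize_genome(record$id, cassettes, config$count_boxes)
}

#' Scan several genomes
#' @param records list of [seq_record].
#' @inheritParams scan_genome
#' @return list of [genome_summary][summarize_genome].
#' @export
scan_genomes <- function(records, config = scan_config(), regions = NULL,
                         model = default_energy_model()) {
  lapply(records, scan_genome, config = config, regions = regions,
         model = model)
}

#' Run a full scan with file input and output
#'
#' Top-level entry used by the command-line interface: reads genomes from
#' FASTA and/or GenBank, optional scan regions from BED, scans every record,
#' writes GFF3 annotations, the per-genome summary TSV and a JSON run
#' manifest (tool version, resolved configuration, input checksums,
#' summaries) that makes the run reproducible.
#'
#' @param fasta,genbank input paths (at least one required; `genbank` may be
#'   a vector of files).
#' @param regions_bed optional BED path.
#' @param out_gff,out_tsv,out_manifest output paths (`NULL` to skip).
#' @param config a [scan_config].
#' @return list of [genome_summary][summarize_genome], invisibly.
#' @export
run_scan <- function(fasta = NULL, genbank = NULL, regions_bed = NULL,
                     out_gff = NULL, out_tsv = NULL, out_manifest = NULL,
                     config = scan_config()) {
  records <- list()
  if (!is.null(fasta)) records <- c(records, read_fasta(fasta))
  if (!is.null(genbank))
    records <- c(records, lapply(genbank, read_genbank))
  if (!length(records)) stop_io("no input records (need --fasta or --genbank)")
  regions <- if (!is.null(regions_bed)) read_regions_bed(regions_bed) else NULL
  summaries <- scan_genomes(records, config, regions)
  cassettes <- do.call(c, c(lapply(summaries, function(s) s$cassettes),
                            list(list())))
  write_outputs(cassettes, summaries, out_gff, out_tsv)
  if (!is.null(out_manifest)) {
    inputs <- c(fasta, genbank, regions_bed)
    manifest <- list(
      tool = "dumbbellscan",
      version = as.character(utils::packageVersion("dumbbellscan")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = config_as_list(config),
      inputs = data.frame(path = inputs,
                          md5 = unname(tools::md5sum(inputs))),
      summaries = data.frame(
        accession = vapply(summaries, function(s) s$accession, ""),
        n_cassettes = vapply(summaries, function(s) s$n_cassettes, 0L),
        n_box_cassettes = vapply(summaries,
                                 function(s) s$n_box_cassettes, 0L)))
    jsonlite::write_json(manifest, out_manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(summaries)
}

config_as_list <- function(config) {
  sp <- config$motif_specs
  list(window_min = config$window_min, window_max = config$window_max,
       window_step = config$window_step, mfe_max = config$mfe_max,
       tata_consensus = sp$TATA$consensus,
       tata_max_mismatch = sp$TATA$max_mismatch,
       abox_consensus = sp$ABOX$consensus,
       abox_max_mismatch = sp$ABOX$max_mismatch,
       bbox_consensus = sp$BBOX$consensus,
       bbox_max_mismatch = sp$BBOX$max_mismatch,
       term_min_run = sp$TERM$min_run,
       tata_upstream_window = config$tata_upstream_window,
       terminator_downstream_window = config$terminator_downstream_window,
       require_terminator = config$require_terminator,
       require_promoter = config$require_promoter,
       box_promoter_rule = config$box_promoter_rule,
       strand = config$strand,
       min_arm_stem_bp = config$topology$min_arm_stem_bp,
       min_basal_helix_bp = config$topology$min_basal_helix_bp,
       min_paired_fraction = config$topology$min_paired_fraction,
       single_hairpin_mode = config$topology$single_hairpin_mode,
       count_boxes = config$count_boxes,
       dedupe_identical = config$dedupe_identical,
       backend = config$backend)
}
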