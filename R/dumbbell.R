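#' Dumbbell topology configuration
#'
#' Thresholds deciding whether a folded window is accepted as a
#' dumbbell-shaped pri-miRNA: energy at or below `mfe_max`, exactly two
#' hairpin loops (one in `single_hairpin_mode`), at least `min_arm_stem_bp`
#' base pairs on the helix path to each hairpin (bulges and internal loops
#' within an arm are aggregated), a paired fraction over the trimmed span of
#' at least `min_paired_fraction`, and optionally a minimum basal (closing)
#' helix. The basal helix is optional by default because the published
#' precursor model shows only a short closing stem without quantifying it.
#'
#' @param mfe_max maximum (most positive) accepted MFE, kcal/mol.
#' @param min_arm_stem_bp minimum total base pairs per arm.
#' @param min_basal_helix_bp minimum pairs enclosing both arms (0 = basal
#'   helix optional).
#' @param min_paired_fraction minimum fraction of paired bases over the
#'   trimmed span, guards against two tiny hairpins in a mostly unstructured
#'   window.
#' @param single_hairpin_mode accept single stem-loops instead (the style of
#'   cassette described for bovine leukemia virus).
#' @return an object of class `topology_config`.
#' @export
topology_config <- function(mfe_max = -30, min_arm_stem_bp = 8L,
                            min_basal_helix_bp = 0L,
                            min_paired_fraction = 0.5,
                            single_hairpin_mode = FALSE) {
  if (mfe_max >= 0) stop_config("mfe_max must be negative")
  if (min_arm_stem_bp < 1L) stop_config("min_arm_stem_bp must be >= 1")
  structure(list(mfe_max = mfe_max,
                 min_arm_stem_bp = as.integer(min_arm_stem_bp),
                 min_basal_helix_bp = as.integer(min_basal_helix_bp),
                 min_paired_fraction = min_paired_fraction,
                 single_hairpin_mode = isTRUE(single_hairpin_mode)),
            class = "topology_config")
}

#' Classify a folded window as dumbbell / non-dumbbell
#'
#' Works on the trimmed structure (outside the first and last paired base,
#' flanking unpaired bases are ignored), so the call is invariant to window
#' padding. A dumbbell has exactly two hairpin loops; each arm is the
#' top-level stem-loop subtree containing one hairpin, and its stem size is
#' the total number of base pairs in that subtree (helix interruptions are
#' aggregated). The basal helix is the set of pairs enclosing both arms
#' (0 pairs when the arms sit side by side on the exterior loop).
#'
#' @param fold a [fold_result] for the window's sequence.
#' @param window a [seq_region] giving the window's absolute location.
#' @param config a [topology_config].
#' @return an object of class `dumbbell_call`: window, fold, `n_hairpins`,
#'   `basal_helix_bp`, `arm_regions` (list of [seq_region], 5' to 3'),
#'   `loop_sizes`, `paired_fraction`, `trimmed_region`, `passes_energy`,
#'   `passes_topology`.
#' @export
classify_dumbbell <- function(fold, window, config = topology_config()) {
  pt <- pair_table(fold$dot_bracket)
  n <- length(pt)
  paired <- which(pt > 0L)
  want <- if (config$single_hairpin_mode) 1L else 2L

  res <- list(window = window, fold = fold, n_hairpins = 0L,
              basal_helix_bp = 0L, arm_regions = list(),
              loop_sizes = integer(0), paired_fraction = 0,
              trimmed_region = NULL,
              passes_energy = fold$mfe <= config$mfe_max,
              passes_topology = FALSE)
  class(res) <- "dumbbell_call"
  if (!length(paired)) return(res)

  f <- min(paired); l <- max(paired)
  res$trimmed_region <- seq_region(window$seq_id, window$start + f - 1L,
                                   window$start + l, window$strand)
  res$paired_fraction <- length(paired) / (l - f + 1L)

  # hairpin loops: pairs with no pair inside
  hp <- integer(0)
  for (i in which(pt > seq_len(n))) {
    j <- pt[i]
    if (!length(loop_children(pt, i, j))) hp <- c(hp, i)
  }
  res$n_hairpins <- length(hp)
  if (length(hp) != want) return(res)

  # arms: for each hairpin, the outermost enclosing pair that does NOT
  # enclose any other hairpin
  arm_iv <- matrix(0L, nrow = length(hp), ncol = 2)
  for (a in seq_along(hp)) {
    h <- hp[a]
    enc <- which(pt > seq_len(n) & seq_len(n) <= h & pt >= pt[hp[a]])
    other <- hp[-a]
    own <- enc[vapply(enc, function(i) {
      !any(other > i & other < pt[i])
    }, TRUE)]
    arm_iv[a, ] <- c(min(own), pt[min(own)])
  }
  ord <- order(arm_iv[, 1])
  arm_iv <- arm_iv[ord, , drop = FALSE]
  hp <- hp[ord]
  res$arm_regions <- lapply(seq_len(nrow(arm_iv)), function(a)
    seq_region(window$seq_id, window$start + arm_iv[a, 1] - 1L,
               window$start + arm_iv[a, 2], window$strand))
  res$loop_sizes <- vapply(hp, function(h) pt[h] - h - 1L, 0L)

  arm_bp <- vapply(seq_len(nrow(arm_iv)), function(a) {
    iv <- arm_iv[a, ]
    sum(pt > seq_len(n) & seq_len(n) >= iv[1] & pt <= iv[2])
  }, 0L)

  # pairs enclosing all arms = basal helix (aggregated)
  res$basal_helix_bp <- sum(pt > seq_len(n) &
                            seq_len(n) < min(arm_iv[, 1]) &
                            pt > max(arm_iv[, 2]))

  res$passes_topology <-
    all(arm_bp >= config$min_arm_stem_bp) &&
    res$basal_helix_bp >= config$min_basal_helix_bp &&
    res$paired_fraction >= config$min_paired_fraction
  res
}

#' @export
print.dumbbell_call <- function(x, ...) {
  cat(sprintf(
    "dumbbell_call %s:[%d,%d) mfe=%.2f hairpins=%d basal=%dbp %s\n",
    x$window$seq_id, x$window$start, x$window$end, x$fold$mfe, x$n_hairpins,
    x$basal_helix_bp,
    if (x$passes_energy && x$passes_topology) "PASS" else "fail"))
  invisible(x)
}

#' Trimmed span of an accepted dumbbell
#'
#' Length in nt from the first to the last paired base of the structure --
#' the reported "pri-miRNA size".
#'
#' @param call a [dumbbell_call] with `passes_topology = TRUE`.
#' @return integer span in nt.
#' @export
dumbbell_span <- function(call) {
  if (!isTRUE(call$passes_topology))
    stop_config("dumbbell_span() called on a non-dumbbell window")
  region_width(call$trimmed_region)
}
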