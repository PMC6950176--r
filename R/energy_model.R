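#' Nearest-neighbour RNA folding energy model
#'
#' Constructs the energy parameter set used by [fold_mfe()] and
#' [brute_force_fold()]. The model is a simplified nearest-neighbour scheme at
#' 37 degrees C: stacking energies for the 36 ordered combinations of the six
#' allowed pairs (AU, UA, GC, CG, GU, UG), hairpin/bulge/internal-loop
#' penalties by loop size with logarithmic (Jacobson--Stockmayer style)
#' extrapolation for large loops, and an affine multiloop penalty. There are
#' no dangling ends, no coaxial stacking and no lonely-pair prohibition beyond
#' the minimum hairpin size. Interior and bulge loops are capped at
#' `max_loop` unpaired nucleotides; structures exceeding the cap are
#' disallowed (assigned `+Inf`). `N` never pairs.
#'
#' Watson--Crick stacks lie in \[-3.4, -0.9\] kcal/mol with GU stacks weaker;
#' the multiloop penalty is 3.4 + 0.4 per branch + 0.0 per unpaired base.
#' The values are implementation constants: both the dynamic-programming
#' folder and the exhaustive oracle evaluate the identical model, which is
#' what all energy assertions in the package check.
#'
#' @param max_len longest sequence the model must cover (hairpin table size).
#' @return an object of class `energy_model`: a list with elements `stack`
#'   (6x6 matrix, rows = outer pair, cols = inner pair, order AU, UA, GC, CG,
#'   GU, UG), `hairpin`, `bulge`, `internal` (penalty vectors indexed by loop
#'   size), `ml_a`, `ml_b`, `ml_c` (multiloop affine terms), `max_loop`,
#'   `min_hairpin`, `temperature`.
#' @examples
#' m <- default_energy_model()
#' m$stack["GC", "GC"]
#' @export
default_energy_model <- function(max_len = 500L) {
  pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  stack <- matrix(c(
    # inner:  AU     UA     GC     CG     GU     UG
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,   # outer AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,   # outer UA
    -2.1, -2.2, -3.3, -2.4, -1.4, -2.1,   # outer GC
    -2.1, -2.4, -3.4, -3.3, -1.5, -2.5,   # outer CG
    -1.3, -1.4, -2.5, -2.1, -0.5, -0.3,   # outer GU
    -1.0, -0.6, -1.5, -1.4, -0.3, -0.2),  # outer UG
    nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))

  kT <- 0.616  # kcal/mol at 310.15 K
  js <- function(base_e, base_n, n) base_e + 1.75 * kT * log(n / base_n)

  hairpin <- rep(Inf, max_len)
  h_small <- c(`3` = 5.4, `4` = 5.6, `5` = 5.7, `6` = 5.8, `7` = 6.0,
               `8` = 6.1, `9` = 6.4)
  hairpin[3:9] <- h_small
  if (max_len > 9) hairpin[10:max_len] <- js(6.4, 9, 10:max_len)

  max_loop <- 30L
  bulge <- numeric(max_loop)
  b_small <- c(`1` = 3.8, `2` = 2.8, `3` = 3.2, `4` = 3.6, `5` = 4.0, `6` = 4.4)
  bulge[1:6] <- b_small
  bulge[7:max_loop] <- js(4.4, 6, 7:max_loop)

  internal <- rep(Inf, max_loop)
  i_small <- c(`2` = 1.5, `3` = 1.6, `4` = 1.7, `5` = 2.0, `6` = 2.2)
  internal[2:6] <- i_small
  internal[7:max_loop] <- js(2.2, 6, 7:max_loop)

  structure(list(
    stack = stack, hairpin = hairpin, bulge = bulge, internal = internal,
    ml_a = 3.4, ml_b = 0.4, ml_c = 0.0,
    max_loop = max_loop, min_hairpin = 3L, temperature = 37),
    class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Nearest-neighbour energy model (", x$temperature, " C)\n", sep = "")
  cat("  stacks: ", min(x$stack), " .. ", max(x$stack), " kcal/mol\n", sep = "")
  cat("  min hairpin loop ", x$min_hairpin, " nt; interior/bulge cap ",
      x$max_loop, " nt\n", sep = "")
  cat("  multiloop: ", x$ml_a, " + ", x$ml_b, "/branch + ", x$ml_c,
      "/unpaired\n", sep = "")
  invisible(x)
}

#' Write or read an energy model as a plain-text parameter table
#'
#' The on-disk dialect is line-oriented `key = value`, with the stack matrix
#' as 36 `stack.<outer>.<inner>` entries and loop vectors as comma-separated
#' lists, so parameter sets can be versioned and overridden without code.
#'
#' @param model an `energy_model`.
#' @param path file path.
#' @return `read_energy_model` returns an `energy_model`.
#' @export
write_energy_model <- function(model, path) {
  pairs <- rownames(model$stack)
  ln <- c(
    sprintf("min_hairpin = %d", model$min_hairpin),
    sprintf("max_loop = %d", model$max_loop),
    sprintf("ml_a = %g", model$ml_a),
    sprintf("ml_b = %g", model$ml_b),
    sprintf("ml_c = %g", model$ml_c),
    sprintf("temperature = %g", model$temperature),
    sprintf("hairpin = %s", paste(model$hairpin, collapse = ",")),
    sprintf("bulge = %s", paste(model$bulge, collapse = ",")),
    sprintf("internal = %s", paste(model$internal, collapse = ",")))
  for (a in pairs) for (b in pairs)
    ln <- c(ln, sprintf("stack.%s.%s = %g", a, b, model$stack[a, b]))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_energy_model
#' @export
read_energy_model <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get1 <- function(k) as.numeric(vals[match(k, keys)])
  getv <- function(k) as.numeric(strsplit(vals[match(k, keys)], ",")[[1]])
  pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  for (a in pairs) for (b in pairs)
    stack[a, b] <- get1(sprintf("stack.%s.%s", a, b))
  structure(list(
    stack = stack, hairpin = getv("hairpin"), bulge = getv("bulge"),
    internal = getv("internal"), ml_a = get1("ml_a"), ml_b = get1("ml_b"),
    ml_c = get1("ml_c"), max_loop = as.integer(get1("max_loop")),
    min_hairpin = as.integer(get1("min_hairpin")),
    temperature = get1("temperature")), class = "energy_model")
}

# pair type index for coded bases (1=A,2=C,3=G,4=U,5=N); 0 = not pairable
pair_type <- function(a, b) {
  key <- a * 10L + b
  # 14=AU 41=UA 32=GC 23=CG 34=GU 43=UG
  match(key, c(14L, 41L, 32L, 23L, 34L, 43L), nomatch = 0L)
}

#' Evaluate the free energy of a given secondary structure
#'
#' Scores one dot-bracket structure on one sequence under an energy model by
#' decomposing it into its loops (hairpin, stack, bulge, internal, multiloop,
#' exterior) and summing their contributions. This loop-sum definition is the
#' single source of truth for "the energy of a structure": the
#' dynamic-programming folder minimises it and the enumeration oracle scores
#' every candidate with it. Structures containing a disallowed feature
#' (illegal pair, hairpin loop < minimum, interior loop above the cap) get
#' `+Inf`.
#'
#' @param seq DNA or RNA string.
#' @param db dot-bracket string, same length as `seq`.
#' @param model an `energy_model`.
#' @return energy in kcal/mol (possibly `Inf`).
#' @examples
#' eval_db_energy("GGGGAAAACCCC", "((((....))))", default_energy_model())
#' @export
eval_db_energy <- function(seq, db, model = default_energy_model()) {
  codes <- encode_rna(seq)
  n <- length(codes)
  if (nchar(db) != n) stop("structure and sequence lengths differ")
  pt <- pair_table(db)
  e <- 0
  closing <- c(0L, which(pt > seq_len(n)))  # 0 = exterior
  for (i in closing) {
    j <- if (i == 0L) n + 1L else pt[i]
    if (i > 0L) {
      ptype_out <- pair_type(codes[i], codes[j])
      if (ptype_out == 0L) return(Inf)
    }
    # immediate children of the loop closed by (i,j)
    kids <- integer(0)
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) {
        kids <- c(kids, k)
        k <- pt[k] + 1L
      } else k <- k + 1L
    }
    nb <- length(kids)
    if (i == 0L) {
      next  # exterior loop is free
    }
    if (nb == 0L) {
      size <- j - i - 1L
      if (size < model$min_hairpin || size > length(model$hairpin)) return(Inf)
      e <- e + model$hairpin[size]
    } else if (nb == 1L) {
      k1 <- kids[1]; l1 <- pt[k1]
      d1 <- k1 - i - 1L; d2 <- j - l1 - 1L
      if (d1 == 0L && d2 == 0L) {
        e <- e + model$stack[pair_type(codes[i], codes[j]),
                             pair_type(codes[k1], codes[l1])]
      } else {
        sz <- d1 + d2
        if (sz > model$max_loop) return(Inf)
        e <- e + if (d1 == 0L || d2 == 0L) model$bulge[sz] else model$internal[sz]
      }
    } else {
      unpaired <- (j - i - 1L) - sum(pt[kids] - kids + 1L)
      e <- e + model$ml_a + model$ml_b * nb + model$ml_c * unpaired
    }
    if (!is.finite(e)) return(Inf)
  }
  e
}
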