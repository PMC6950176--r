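#' Pair table of a dot-bracket string
#'
#' @param db dot-bracket string over `(`, `.`, `)`.
#' @return integer vector `pt` with `pt[i]` = partner of position `i`
#'   (1-based) or 0 if unpaired.
#' @export
pair_table <- function(db) {
  v <- strsplit(db, "", fixed = TRUE)[[1]]
  bad <- which(!v %in% c("(", ")", "."))
  if (length(bad))
    stop_io("invalid structure character '%s' at position %d", v[bad[1]], bad[1])
  n <- length(v)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (v[i] == "(") stack <- c(stack, i)
    else if (v[i] == ")") {
      if (!length(stack))
        stop_io("unbalanced ')' at position %d", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[j] <- i; pt[i] <- j
    }
  }
  if (length(stack))
    stop_io("unbalanced '(' at position %d", stack[length(stack)])
  pt
}

# immediate child pairs (5' positions) of the loop closed by (i,j);
# i = 0 denotes the exterior loop of a structure of length n
loop_children <- function(pt, i, j) {
  kids <- integer(0)
  k <- i + 1L
  while (k < j) {
    if (pt[k] > k) { kids <- c(kids, k); k <- pt[k] + 1L } else k <- k + 1L
  }
  kids
}

#' Parse a dot-bracket string into a loop/helix tree
#'
#' Decomposes a nested secondary structure into the standard tree of
#' alternating helix and loop nodes: the root is the exterior loop; each
#' helix is a maximal run of stacked pairs ending in a hairpin loop, an
#' internal loop/bulge (which continues into exactly one helix), or a
#' multiloop (>= 2 branches). Serializing the tree reproduces the input
#' exactly.
#'
#' @param db dot-bracket string.
#' @return an object of class `structure_tree` with elements `db`, `root`,
#'   `n_hairpins`, `n_multiloops`, `helix_lengths` (base pairs per helix,
#'   in 5' traversal order).
#' @examples
#' tr <- parse_structure("(((...)))")
#' tr$n_hairpins
#' @export
parse_structure <- function(db) {
  pt <- pair_table(db)
  n <- length(pt)
  counts <- new.env(parent = emptyenv())
  counts$hairpins <- 0L; counts$multiloops <- 0L; counts$helix <- integer(0)

  parse_helix <- function(i) {
    # maximal stacked run starting at pair (i, pt[i])
    pairs <- matrix(integer(0), ncol = 2)
    j <- pt[i]
    repeat {
      pairs <- rbind(pairs, c(i, j))
      if (i + 1L < j - 1L && pt[i + 1L] == j - 1L) { i <- i + 1L; j <- j - 1L }
      else break
    }
    counts$helix <- c(counts$helix, nrow(pairs))
    kids <- loop_children(pt, i, j)
    nb <- length(kids)
    child <- if (nb == 0L) {
      counts$hairpins <- counts$hairpins + 1L
      list(type = "hairpin", size = j - i - 1L)
    } else if (nb == 1L) {
      k <- kids[1]
      d1 <- k - i - 1L; d2 <- j - pt[k] - 1L
      list(type = if (d1 == 0L || d2 == 0L) "bulge" else "internal",
           sizes = c(d1, d2), child = parse_helix(k))
    } else {
      counts$multiloops <- counts$multiloops + 1L
      unpaired <- (j - i - 1L) - sum(pt[kids] - kids + 1L)
      list(type = "multiloop", branches = nb, unpaired = unpaired,
           children = lapply(kids, parse_helix))
    }
    list(type = "helix", pairs = pairs, child = child)
  }

  top <- loop_children(pt, 0L, n + 1L)
  root <- list(type = "exterior", length = n, children = lapply(top, parse_helix))
  structure(list(db = db, root = root, n_hairpins = counts$hairpins,
                 n_multiloops = counts$multiloops,
                 helix_lengths = counts$helix),
            class = "structure_tree")
}

#' Serialize a structure tree back to dot-bracket
#' @param tree a `structure_tree`.
#' @return the dot-bracket string.
#' @export
serialize_structure <- function(tree) {
  n <- tree$root$length
  v <- rep(".", n)
  place <- function(node) {
    if (node$type == "helix") {
      v[node$pairs[, 1]] <<- "("
      v[node$pairs[, 2]] <<- ")"
      place(node$child)
    } else if (node$type %in% c("bulge", "internal")) place(node$child)
    else if (node$type == "multiloop") lapply(node$children, place)
    invisible(NULL)
  }
  lapply(tree$root$children, place)
  paste(v, collapse = "")
}

#' @export
print.structure_tree <- function(x, ...) {
  cat("structure_tree: ", x$db, "\n  ", x$n_hairpins, " hairpin(s), ",
      x$n_multiloops, " multiloop(s), helices [",
      paste(x$helix_lengths, collapse = ", "), "] bp\n", sep = "")
  invisible(x)
}
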