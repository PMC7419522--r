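# Airway-tree geometry: data model, label/state mapping, gravity angles,
# rigid rotation and constriction editing.
#
# A tree is a data.frame with one row per segment (columns: state, label,
# parent, generation, x0..z1, length, diameter) plus a `gravity` attribute
# (unit 3-vector, default c(0, 0, -1)). States are the breadth-first
# enumeration of the traditional digit labels: the root is "1", daughters
# append "1" or "2", and within a generation labels are ordered as binary
# codes. Every non-terminal segment has exactly two daughters.

#' Convert a traditional airway label to its Markov state index
#'
#' Labels start at "1" (the trachea) and append "1"/"2" for the two
#' daughters. States enumerate labels breadth-first: generation g occupies
#' states `2^(g-1) ... 2^g - 1`, ordered by the label read as a binary code.
#'
#' @param label Character vector of digit labels ("1", "11", "122", ...).
#' @return Integer state indices.
#' @examples
#' label_to_state(c("1", "11", "12", "122"))  # 1 2 3 7
#' @export
label_to_state <- function(label) {
  if (any(!grepl("^1[12]*$", label))) {
    stop("malformed airway label: must be \"1\" followed by digits 1/2")
  }
  out <- vapply(label, function(lb) {
    g <- nchar(lb)
    code <- 0
    if (g > 1L) {
      digits <- as.integer(strsplit(substring(lb, 2L), "")[[1]]) - 1L
      code <- sum(digits * 2^((g - 2L):0L))
    }
    2^(g - 1L) + code
  }, numeric(1), USE.NAMES = FALSE)
  as.integer(out)
}

#' Convert a Markov state index back to its airway label
#'
#' Inverse of [label_to_state()].
#'
#' @param state Positive integer state indices.
#' @return Character labels.
#' @export
state_to_label <- function(state) {
  if (any(state < 1) || any(state != round(state))) {
    stop("state indices must be positive integers")
  }
  vapply(state, function(s) {
    g <- floor(log2(s)) + 1L
    code <- s - 2L^(g - 1L)
    if (g == 1L) return("1")
    bits <- integer(g - 1L)
    for (i in seq_len(g - 1L)) {
      bits[g - i] <- code %% 2L
      code <- code %/% 2L
    }
    paste0("1", paste(bits + 1L, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# order labels breadth-first (generation, then binary code);
# relies on label_to_state being monotone in that order
.label_order <- function(labels) order(label_to_state(labels))

#' Construct an airway tree from a segment table
#'
#' Validates the topology (single root, every non-root has one parent,
#' every non-terminal exactly two daughters), derives lengths from the
#' endpoints, assigns labels from the parent links if absent, and numbers
#' states breadth-first.
#'
#' @param segments A data.frame with columns `x0, y0, z0, x1, y1, z1,
#'   diameter` plus either `label` or `parent` given as row indices
#'   (NA for the root). An optional `id` column carries external ids.
#' @param gravity Gravity direction (3-vector, need not be unit length).
#' @return An object of class `airway_tree` (also a data.frame).
#' @export
airway_tree <- function(segments, gravity = c(0, 0, -1)) {
  req <- c("x0", "y0", "z0", "x1", "y1", "z1", "diameter")
  if (!all(req %in% names(segments))) {
    stop("segments must contain columns ", paste(req, collapse = ", "))
  }
  n <- nrow(segments)
  if (n < 1) stop("empty segment table")

  if (is.null(segments$label)) {
    if (is.null(segments$parent)) stop("need either `label` or `parent`")
    segments$label <- .labels_from_parents(segments$parent)
  }
  if (anyDuplicated(segments$label)) stop("duplicate airway labels")

  ord <- .label_order(segments$label)
  segments <- segments[ord, , drop = FALSE]
  lab <- segments$label
  parent_lab <- ifelse(nchar(lab) > 1L, substring(lab, 1L, nchar(lab) - 1L),
                       NA_character_)
  parent <- match(parent_lab, lab)
  if (any(is.na(parent) & nchar(lab) > 1L)) {
    stop("segment without its parent present: ",
         lab[is.na(parent) & nchar(lab) > 1L][1])
  }
  n_children <- tabulate(parent[!is.na(parent)], nbins = n)
  if (any(!n_children %in% c(0L, 2L))) {
    stop("malformed tree: every segment must have 0 or 2 daughters ",
         "(offending label ", lab[which(!n_children %in% c(0L, 2L))[1]], ")")
  }

  len <- sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2 +
              (segments$z1 - segments$z0)^2)
  if (any(len <= 0)) stop("zero-length segment")
  if (!is.null(segments$length) &&
      any(abs(segments$length - len) > 1e-9 * pmax(len, 1e-300))) {
    stop("stored length disagrees with endpoint distance")
  }
  if (any(segments$diameter <= 0)) stop("diameters must be positive")

  g <- gravity / sqrt(sum(gravity^2))
  out <- data.frame(state = seq_len(n), label = lab, parent = parent,
                    generation = nchar(lab),
                    x0 = segments$x0, y0 = segments$y0, z0 = segments$z0,
                    x1 = segments$x1, y1 = segments$y1, z1 = segments$z1,
                    length = len, diameter = segments$diameter,
                    stringsAsFactors = FALSE)
  attr(out, "gravity") <- g
  if (!is.null(segments$id)) {
    attr(out, "id_map") <- data.frame(file_id = segments$id,
                                      state = seq_len(n))
  }
  class(out) <- c("airway_tree", "data.frame")
  out
}

# assign labels breadth-first from parent row-indices (first daughter in
# input order gets suffix "1")
.labels_from_parents <- function(parent) {
  n <- length(parent)
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("exactly one root (parent = NA) required")
  lab <- character(n)
  lab[root] <- "1"
  kids <- split(seq_len(n), factor(parent, levels = seq_len(n)))
  queue <- root
  while (length(queue)) {
    p <- queue[1]
    queue <- queue[-1]
    ch <- kids[[p]]
    if (length(ch)) {
      if (length(ch) != 2L) {
        stop("malformed tree: segment has ", length(ch),
             " daughter(s); 0 or 2 required")
      }
      lab[ch] <- paste0(lab[p], c("1", "2"))
      queue <- c(queue, ch)
    }
  }
  if (any(lab == "")) stop("disconnected segments in tree")
  lab
}

#' @export
print.airway_tree <- function(x, ...) {
  term <- tree_terminals(x)
  cat(sprintf(
    "airway tree: %d segments, %d generations, %d terminal segments\n",
    nrow(x), max(x$generation), length(term)))
  cat(sprintf("  root: L = %.3g m, D = %.3g m; gravity = (%g, %g, %g)\n",
              x$length[1], x$diameter[1],
              attr(x, "gravity")[1], attr(x, "gravity")[2],
              attr(x, "gravity")[3]))
  invisible(x)
}

#' Terminal (deepest) segment states of a tree
#' @param tree An [airway_tree()].
#' @return Integer vector of terminal states.
#' @export
tree_terminals <- function(tree) {
  n_children <- tabulate(tree$parent[!is.na(tree$parent)], nbins = nrow(tree))
  which(n_children == 0L)
}

#' Daughters of every segment
#' @param tree An [airway_tree()].
#' @return A list, indexed by state, of integer daughter-state vectors.
#' @export
tree_children <- function(tree) {
  kids <- vector("list", nrow(tree))
  for (k in which(!is.na(tree$parent))) {
    p <- tree$parent[k]
    kids[[p]] <- c(kids[[p]], k)
  }
  kids
}

# unit axis vectors (flow direction, start -> end), n x 3
.tree_axes <- function(tree) {
  d <- cbind(tree$x1 - tree$x0, tree$y1 - tree$y0, tree$z1 - tree$z0)
  d / tree$length
}

#' Gravity angle of each segment
#'
#' Signed elevation of the segment axis (flow direction) from the plane
#' orthogonal to gravity: `-pi/2` when the axis is parallel to gravity
#' (flow descending), 0 when horizontal, `+pi/2` when ascending.
#'
#' @param tree An [airway_tree()].
#' @param gravity Gravity direction; defaults to the tree's own.
#' @return Numeric vector of angles in radians, one per segment.
#' @export
gravity_angle <- function(tree, gravity = attr(tree, "gravity")) {
  g <- gravity / sqrt(sum(gravity^2))
  ax <- .tree_axes(tree)
  dt <- pmin(pmax(ax %*% g, -1), 1)
  -asin(as.vector(dt))
}

#' Rigidly rotate a tree
#'
#' Rotates all endpoints about the coordinate origin by a proper orthogonal
#' matrix. Lengths, diameters and topology are unchanged, as is the gravity
#' direction (the tree moves, not the world); only the rotation origin's
#' choice is immaterial for deposition, which depends on directions alone.
#'
#' @param tree An [airway_tree()].
#' @param rotation A 3x3 proper orthogonal matrix, e.g. from
#'   [rotation_matrix()].
#' @return The rotated `airway_tree`.
#' @export
rotate_tree <- function(tree, rotation) {
  if (!is.matrix(rotation) || any(dim(rotation) != c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be a proper orthogonal 3x3 matrix")
  }
  p0 <- as.matrix(tree[, c("x0", "y0", "z0")]) %*% t(rotation)
  p1 <- as.matrix(tree[, c("x1", "y1", "z1")]) %*% t(rotation)
  tree[, c("x0", "y0", "z0")] <- p0
  tree[, c("x1", "y1", "z1")] <- p1
  tree
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis One of "x", "y", "z", or a 3-vector rotation axis.
#' @param angle Rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle)
  s <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) * c_ + s * K + (1 - c_) * tcrossprod(u)
}

#' Constrict one airway segment
#'
#' Multiplies the diameter of a single segment by a factor in (0, 1],
#' mimicking bronchoconstriction. Flow partitioning responds through the
#' fourth-power Poiseuille law, so even a modest narrowing strongly
#' diverts flow to the sibling subtree.
#'
#' @param tree An [airway_tree()].
#' @param state Segment state index to constrict.
#' @param factor Diameter multiplier in (0, 1].
#' @return The edited `airway_tree`.
#' @export
constrict_segment <- function(tree, state, factor) {
  if (!state %in% tree$state) stop("unknown state: ", state)
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 ||
      factor > 1) {
    stop("factor must lie in (0, 1]")
  }
  tree$diameter[tree$state == state] <-
    tree$diameter[tree$state == state] * factor
  tree
}

#' @export
plot.airway_tree <- function(x, plane = c("xz", "xy", "yz"), ...) {
  plane <- match.arg(plane)
  cols <- switch(plane, xz = c(1, 3), xy = c(1, 2), yz = c(2, 3))
  axes <- c("x", "y", "z")
  p0 <- as.matrix(x[, c("x0", "y0", "z0")])[, cols, drop = FALSE]
  p1 <- as.matrix(x[, c("x1", "y1", "z1")])[, cols, drop = FALSE]
  graphics::plot(range(c(p0[, 1], p1[, 1])), range(c(p0[, 2], p1[, 2])),
                 type = "n", xlab = axes[cols[1]], ylab = axes[cols[2]],
                 asp = 1, ...)
  graphics::segments(p0[, 1], p0[, 2], p1[, 1], p1[, 2],
                     lwd = pmax(0.5, x$diameter / max(x$diameter) * 4))
  invisible(x)
}
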