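# Seeded synthetic asymmetric 3D airway-tree generator. Emulates a human
# conducting-airway tree: a vertical root (trachea) with generation-dependent
# length/diameter scaling, unequal daughters (major/minor ratios) and
# randomized 3D branching directions. It is a geometric stand-in for a
# morphometric reconstruction, not an anatomical atlas: no lobar structure,
# no curvature within segments, no upper airway.

#' Generate a synthetic asymmetric 3D airway tree
#'
#' Builds a full binary tree of `n_generations` generations (`2^n - 1`
#' segments). Each daughter scales its parent's length and diameter by a
#' major or minor ratio (randomly assigned left/right), and branches off at
#' a half-angle drawn uniformly from `angle_range` with uniform azimuth
#' about the parent axis; the two daughters take opposite azimuths. The
#' root starts at the origin pointing along gravity (a descending trachea).
#' Deterministic given `seed`; the caller's RNG state is preserved.
#'
#' @param n_generations Number of generations (root = generation 1).
#' @param root_length,root_diameter Root segment dimensions, m. The
#'   defaults (0.12 m, 0.018 m) are adult-trachea-scale.
#' @param length_ratio,diameter_ratio Two-element vectors
#'   `c(major, minor)` of per-generation scaling factors in (0, 1].
#' @param angle_range Branch half-angle interval in radians (default
#'   20 to 50 degrees).
#' @param seed Integer random seed.
#' @param gravity Gravity direction for the returned tree.
#' @return An [airway_tree()] with `2^n_generations - 1` segments.
#' @examples
#' tr <- generate_airway_tree(4, seed = 1)
#' nrow(tr)  # 15
#' @export
generate_airway_tree <- function(n_generations,
                                 root_length = 0.12,
                                 root_diameter = 0.018,
                                 length_ratio = c(0.78, 0.70),
                                 diameter_ratio = c(0.78, 0.70),
                                 angle_range = c(20, 50) * pi / 180,
                                 seed = 1L,
                                 gravity = c(0, 0, -1)) {
  if (n_generations < 1) stop("n_generations must be >= 1")
  if (any(length_ratio <= 0) || any(length_ratio > 1) ||
      any(diameter_ratio <= 0) || any(diameter_ratio > 1)) {
    stop("scaling ratios must lie in (0, 1]")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  n <- 2L^n_generations - 1L
  g <- gravity / sqrt(sum(gravity^2))
  dir <- matrix(NA_real_, n, 3)
  p0 <- matrix(NA_real_, n, 3)
  len <- numeric(n)
  dia <- numeric(n)
  # state k has daughters 2k, 2k+1 in the full binary-tree numbering
  dir[1, ] <- g
  p0[1, ] <- c(0, 0, 0)
  len[1] <- root_length
  dia[1] <- root_diameter
  for (k in seq_len(n)) {
    d1 <- 2L * k
    if (d1 > n) next
    d <- dir[k, ]
    u <- .any_perp(d)
    v <- .cross3(d, u)
    phi <- stats::runif(2, angle_range[1], angle_range[2])
    psi <- stats::runif(1, 0, 2 * pi)
    major_first <- stats::runif(1) < 0.5
    rl <- if (major_first) length_ratio else rev(length_ratio)
    rd <- if (major_first) diameter_ratio else rev(diameter_ratio)
    end <- p0[k, ] + len[k] * d
    for (j in 1:2) {
      a <- psi + (j - 1) * pi
      w <- cos(phi[j]) * d + sin(phi[j]) * (cos(a) * u + sin(a) * v)
      ki <- d1 + j - 1L
      dir[ki, ] <- w / sqrt(sum(w^2))
      p0[ki, ] <- end
      len[ki] <- len[k] * rl[j]
      dia[ki] <- dia[k] * rd[j]
    }
  }
  p1 <- p0 + dir * len
  seg <- data.frame(label = state_to_label(seq_len(n)),
                    x0 = p0[, 1], y0 = p0[, 2], z0 = p0[, 3],
                    x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3],
                    diameter = dia, stringsAsFactors = FALSE)
  airway_tree(seg, gravity = gravity)
}

# any unit vector perpendicular to d
.any_perp <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .cross3(d, ref)
  u / sqrt(sum(u^2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
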