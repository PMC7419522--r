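# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# Monte-Carlo settling oracle: particles released with uniform concentration
# at the inlet of a cylindrical tube (entering flux-weighted by the
# Poiseuille profile), advected axially by the local parabolic velocity and
# settling across the section at constant speed. Trajectories are exact
# (polynomial axial displacement integrated in closed form), so the only
# error is sampling. Returns the deposited fraction and its standard error.
mc_settling_oracle <- function(Q, tb, pt, fl = fluid_air(),
                               cs = phys_constants(), n = 1e5, seed = 1) {
  set.seed(seed)
  R <- tb$diameter / 2
  U <- Q / (pi * R^2)
  v <- settling_velocity(pt, fl, cs) * abs(cos(tb$angle))
  r <- R * sqrt(runif(n))
  phi <- runif(n, 0, 2 * pi)
  x <- r * cos(phi)
  y <- r * sin(phi)
  t_wall <- (y + sqrt(R^2 - x^2)) / v
  z <- 2 * U * ((1 - x^2 / R^2) * t_wall -
                  (y^2 * t_wall - y * v * t_wall^2 + v^2 * t_wall^3 / 3) / R^2)
  dep <- z <= tb$length
  w <- 2 * (1 - r^2 / R^2)          # entering flux weight
  p <- sum(w * dep) / sum(w)
  se <- sqrt(sum((w / sum(w))^2 * (dep - p)^2))
  list(p = p, se = se)
}

# Resistor-network oracle for flow fractions: solves the Kirchhoff node
# equations of the full linear resistor tree with a dense linear solve
# (inlet at unit pressure, terminal outlets grounded), independent of the
# package's recursive parallel-combination code.
flow_fraction_oracle <- function(tree, mu = fluid_air()$viscosity) {
  n <- nrow(tree)
  R <- 128 * mu * tree$length / (pi * tree$diameter^4)
  kids <- tree_children(tree)
  internal <- which(vapply(kids, length, 1L) > 0)
  idx <- match(seq_len(n), internal)           # segment -> unknown index
  m <- length(internal)
  A <- matrix(0, m, m)
  b <- numeric(m)
  p_of <- function(k) {
    # pressure at the distal node of k as (coefficient row, constant)
    row <- numeric(m); const <- 0
    if (k %in% internal) row[idx[k]] <- 1 else const <- 0  # terminal: 0
    list(row = row, const = const)
  }
  for (ii in seq_len(m)) {
    k <- internal[ii]
    # inflow (P_prox - P_k)/R_k
    if (is.na(tree$parent[k])) {
      prox <- list(row = numeric(m), const = 1)          # inlet at P = 1
    } else {
      prox <- p_of(tree$parent[k])
    }
    own <- p_of(k)
    A[ii, ] <- A[ii, ] + (prox$row - own$row) / R[k]
    b[ii] <- b[ii] - (prox$const - own$const) / R[k]
    for (d in kids[[k]]) {
      dd <- p_of(d)
      A[ii, ] <- A[ii, ] - (own$row - dd$row) / R[d]
      b[ii] <- b[ii] + (own$const - dd$const) / R[d]
    }
  }
  P <- as.vector(solve(A, b))
  pressure <- function(k) if (k %in% internal) P[idx[k]] else 0
  Qk <- vapply(seq_len(n), function(k) {
    prox <- if (is.na(tree$parent[k])) 1 else pressure(tree$parent[k])
    (prox - pressure(k)) / R[k]
  }, numeric(1))
  Qk / Qk[1]
}

# small random tree with mildly randomized generator parameters
random_tree <- function(n_gen, seed) {
  set.seed(seed * 1000 + 7)
  generate_airway_tree(
    n_gen,
    root_length = runif(1, 0.08, 0.14),
    root_diameter = runif(1, 0.012, 0.02),
    length_ratio = sort(runif(2, 0.6, 0.9), decreasing = TRUE),
    diameter_ratio = sort(runif(2, 0.6, 0.9), decreasing = TRUE),
    seed = seed)
}

# exactly symmetric 3-generation tree: mirrored coordinates give bitwise
# identical lengths/angles within each generation, so flow splits are
# exactly 0.5 and escape telescopes generation by generation
symmetric_tree3 <- function() {
  seg <- data.frame(
    label = c("1", "11", "12", "111", "112", "121", "122"),
    x0 = c(0, 0, 0, 0.05, 0.05, -0.05, -0.05),
    y0 = 0,
    z0 = c(0, -0.1, -0.1, -0.15, -0.15, -0.15, -0.15),
    x1 = c(0, 0.05, -0.05, 0.08, 0.02, -0.08, -0.02),
    y1 = 0,
    z1 = c(-0.1, -0.15, -0.15, -0.19, -0.19, -0.19, -0.19),
    diameter = c(0.016, 0.011, 0.011, 0.0077, 0.0077, 0.0077, 0.0077),
    stringsAsFactors = FALSE)
  airway_tree(seg)
}

fixture_tree_path <- function() {
  system.file("extdata", "airway_tree_3gen_synthetic.csv",
              package = "aerodep")
}
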