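# Poiseuille resistances, recursive subtree input resistances and
# resistance-based flow partitioning at bifurcations. Laminar linear
# resistances only: no inertial or bifurcation-angle corrections, and no
# peripheral compliance (a terminal subtree's resistance is the terminal
# segment's own resistance). Flow fractions depend on geometry alone and
# scale linearly with the inlet flow.

#' Poiseuille resistance of one tube
#'
#' \eqn{R = 128 \mu L / (\pi D^4)}.
#'
#' @param L Length, m. @param D Diameter, m. @param mu Dynamic viscosity, Pa s.
#' @return Resistance in Pa s/m^3 (vectorized).
#' @export
poiseuille_resistance <- function(L, D, mu) {
  if (any(L <= 0) || any(D <= 0) || any(mu <= 0)) {
    stop("L, D and mu must be positive")
  }
  128 * mu * L / (pi * D^4)
}

#' Subtree input resistances
#'
#' For each segment, the input resistance of the subtree it roots:
#' its own Poiseuille resistance plus the parallel combination of its two
#' daughter subtrees (terminals: just the segment resistance).
#'
#' @param tree An [airway_tree()].
#' @param mu Dynamic viscosity, Pa s.
#' @param state Optional single state; if given, return that scalar.
#' @return Vector of input resistances (Pa s/m^3) indexed by state, or a
#'   scalar if `state` is given.
#' @export
input_resistance <- function(tree, mu = fluid_air()$viscosity, state = NULL) {
  r_seg <- poiseuille_resistance(tree$length, tree$diameter, mu)
  kids <- tree_children(tree)
  r_in <- r_seg
  for (k in order(tree$generation, decreasing = TRUE)) {
    ch <- kids[[k]]
    if (length(ch)) {
      r_in[k] <- r_seg[k] + 1 / (1 / r_in[ch[1]] + 1 / r_in[ch[2]])
    }
  }
  if (!is.null(state)) {
    if (!state %in% tree$state) stop("unknown state: ", state)
    return(r_in[state])
  }
  r_in
}

#' Partition an inlet flow through the tree
#'
#' Splits the flow at every bifurcation inversely to the daughter subtree
#' input resistances (the two subtrees are in parallel), giving per-segment
#' flow fractions, flows, mean velocities and Reynolds numbers. Fractions
#' depend only on geometry; identical daughters split exactly 0.5/0.5.
#'
#' @param tree An [airway_tree()].
#' @param q0 Inlet (tracheal) flow, m^3/s, `> 0`.
#' @param fluid A [fluid_air()].
#' @return An object of class `flow_state`: a data.frame with columns
#'   `state, fraction, flow, velocity, reynolds` and attributes `q0`,
#'   `viscosity`.
#' @export
partition_flows <- function(tree, q0, fluid = fluid_air()) {
  if (!is.numeric(q0) || length(q0) != 1 || q0 <= 0) stop("q0 must be > 0")
  r_in <- input_resistance(tree, fluid$viscosity)
  kids <- tree_children(tree)
  frac <- numeric(nrow(tree))
  frac[1] <- 1
  for (k in order(tree$generation)) {
    ch <- kids[[k]]
    if (length(ch)) {
      s <- r_in[ch[1]] + r_in[ch[2]]
      frac[ch[1]] <- frac[k] * r_in[ch[2]] / s
      frac[ch[2]] <- frac[k] * r_in[ch[1]] / s
    }
  }
  flow <- frac * q0
  vel <- .u_mean(flow, tree$diameter)
  out <- data.frame(state = tree$state, fraction = frac, flow = flow,
                    velocity = vel,
                    reynolds = reynolds_number(flow, tree$diameter, fluid))
  attr(out, "q0") <- q0
  attr(out, "viscosity") <- fluid$viscosity
  class(out) <- c("flow_state", "data.frame")
  out
}

#' Rescale a flow state to a new inlet flow
#'
#' Fractions are geometric and unchanged; flows, velocities and Reynolds
#' numbers scale by `q0_new / q0`.
#'
#' @param flow A `flow_state` from [partition_flows()].
#' @param q0_new New inlet flow, m^3/s, `> 0`.
#' @return The rescaled `flow_state`.
#' @export
rescale_flows <- function(flow, q0_new) {
  stopifnot(inherits(flow, "flow_state"))
  if (!is.numeric(q0_new) || length(q0_new) != 1 || q0_new <= 0) {
    stop("q0_new must be > 0")
  }
  s <- q0_new / attr(flow, "q0")
  flow$flow <- flow$flow * s
  flow$velocity <- flow$velocity * s
  flow$reynolds <- flow$reynolds * s
  attr(flow, "q0") <- q0_new
  flow
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("flow state: Q0 = %g m^3/s (%g L/s), %d segments\n",
              attr(x, "q0"), attr(x, "q0") * 1000, nrow(x)))
  cat(sprintf("  root Re = %.3g\n", x$reynolds[1]))
  invisible(x)
}
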