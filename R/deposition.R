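# High-level model interface: one call from geometry + particle + inlet flow
# to a solved deposition field, with the usual methods on the result.

#' Deposition of a particle in an airway tree at constant inlet flow
#'
#' The main entry point: partitions the inlet flow through the tree,
#' builds the absorbing Markov chain and solves it exactly for regional
#' deposition and total escape.
#'
#' @param tree An [airway_tree()].
#' @param particle An [particle()].
#' @param q0 Constant inlet (tracheal) flow, m^3/s.
#' @param fluid,constants Property bundles.
#' @return A `deposition_result` (see [solve_absorption()]) that also
#'   carries the `tree`, `flow`, `particle` and `fluid` used.
#' @examples
#' tr <- generate_airway_tree(6, seed = 2)
#' fit <- deposition(tr, particle(3.5e-6), q0 = 5e-4)
#' fit$escape
#' @export
deposition <- function(tree, particle, q0, fluid = fluid_air(),
                       constants = phys_constants()) {
  flow <- partition_flows(tree, q0, fluid)
  tmat <- build_transition_matrix(tree, flow, particle, fluid, constants)
  res <- solve_absorption(tmat)
  res$tree <- tree
  res$flow <- flow
  res$particle <- particle
  res$fluid <- fluid
  res$constants <- constants
  res
}

#' @export
print.deposition_result <- function(x, ...) {
  cat("airway deposition result\n")
  if (!is.null(x$particle)) {
    cat(sprintf("  particle: %g um; inlet flow: %g L/s\n",
                x$particle$diameter * 1e6,
                if (!is.null(x$flow)) attr(x$flow, "q0") * 1000 else NA))
  }
  cat(sprintf("  total deposition: %.4f   total escape: %.4f\n",
              sum(x$capture), x$escape))
  invisible(x)
}

#' @export
summary.deposition_result <- function(object, ...) {
  if (is.null(object$tree)) {
    return(print(object))
  }
  gen <- object$tree$generation
  by_gen <- tapply(object$capture, gen, sum)
  out <- data.frame(generation = as.integer(names(by_gen)),
                    capture = as.vector(by_gen))
  structure(list(by_generation = out, escape = object$escape,
                 n_segments = nrow(object$tree)),
            class = "summary.deposition_result")
}

#' @export
print.summary.deposition_result <- function(x, ...) {
  cat(sprintf("deposition by generation (%d segments):\n", x$n_segments))
  print(x$by_generation, row.names = FALSE)
  cat(sprintf("total escape: %.4f\n", x$escape))
  invisible(x)
}

#' @export
coef.deposition_result <- function(object, ...) object$capture

#' @export
plot.deposition_result <- function(x, ...) {
  if (is.null(x$tree)) stop("no tree attached to this result")
  gen <- x$tree$generation
  by_gen <- tapply(x$capture, gen, sum)
  graphics::barplot(by_gen, xlab = "generation",
                    ylab = "deposition probability", ...)
  invisible(x)
}

#' @export
simulate.deposition_result <- function(object, nsim = 1e5, seed = 1L, ...) {
  if (is.null(object$tree)) stop("no tree attached to this result")
  tmat <- build_transition_matrix(object$tree, object$flow, object$particle,
                                  object$fluid, object$constants)
  simulate_walkers(tmat, n = nsim, seed = seed,
                   start_state = object$start_state)
}
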