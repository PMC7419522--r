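# Inlet flow policies: per-generation optimal inlet flows, the time-stamped
# optimal waveform, and cohort evaluation of arbitrary constant or
# generation-stepped policies. Optimization is generation-local (each
# segment optimized independently, inlet-equivalents averaged per
# generation); no global joint optimization over the whole tree.

#' Construct a flow policy
#'
#' Either a constant inlet flow or a generation-indexed schedule (one flow
#' per generation, applied while the particle cohort occupies that
#' generation).
#'
#' @param q0 Constant inlet flow (m^3/s), or a vector of per-generation
#'   flows when `generation` is given.
#' @param generation Optional integer vector of generations matching `q0`.
#' @return An object of class `flow_policy`.
#' @export
flow_policy <- function(q0, generation = NULL) {
  if (is.null(generation)) {
    if (length(q0) != 1 || q0 <= 0) stop("constant policy needs one q0 > 0")
    return(structure(list(type = "constant", q0 = q0), class = "flow_policy"))
  }
  if (length(q0) != length(generation) || any(q0 <= 0)) {
    stop("need one positive q0 per generation")
  }
  if (is.unsorted(generation, strictly = TRUE)) {
    stop("generations must be strictly increasing")
  }
  steps <- data.frame(generation = as.integer(generation), q0 = q0)
  structure(list(type = "generation", steps = steps), class = "flow_policy")
}

#' @export
print.flow_policy <- function(x, ...) {
  if (x$type == "constant") {
    cat(sprintf("constant flow policy: Q0 = %g L/s\n", x$q0 * 1000))
  } else {
    cat("generation-stepped flow policy:\n")
    st <- x$steps
    st$q0_Ls <- st$q0 * 1000
    print(st, row.names = FALSE)
  }
  invisible(x)
}

#' Per-generation optimal inlet flows
#'
#' For every segment, finds the segment-local flow minimizing its capture
#' probability over the admissible local range (the inlet range scaled by
#' the segment's flow fraction), converts to the inlet-equivalent flow
#' `Q0* = Q*_segment / f_segment`, clips to the admissible inlet range and
#' averages arithmetically within each generation.
#'
#' @param tree An [airway_tree()].
#' @param particle,fluid,constants Property bundles.
#' @param q_range Admissible inlet flow interval, m^3/s.
#' @return A data.frame with columns `generation`, `q0` (mean optimal
#'   inlet-equivalent flow, m^3/s).
#' @export
optimal_generation_flows <- function(tree, particle, fluid = fluid_air(),
                                     constants = phys_constants(),
                                     q_range = c(1e-7, 1e-3)) {
  flow <- partition_flows(tree, q_range[1], fluid)  # fractions only
  theta <- gravity_angle(tree)
  q0_star <- numeric(nrow(tree))
  for (k in seq_len(nrow(tree))) {
    f <- flow$fraction[k]
    opt <- capture_minimizing_flow(
      tube(tree$length[k], tree$diameter[k], theta[k]),
      particle, fluid, constants, q_range = q_range * f)
    q0_star[k] <- min(max(opt$q_opt / f, q_range[1]), q_range[2])
  }
  means <- tapply(q0_star, tree$generation, mean)
  data.frame(generation = as.integer(names(means)), q0 = as.vector(means))
}

#' Attach a time axis to a generation-indexed policy
#'
#' Step g spans the mean residence time of generation-g segments at that
#' step's flows, `tau_g = mean(L_k / U_k)`; cumulative sums give the
#' waveform. Time zero is particle release at the trachea, not the start
#' of inspiration.
#'
#' @param policy A generation-indexed [flow_policy()] (or the data.frame
#'   from [optimal_generation_flows()]).
#' @param tree The tree the policy applies to.
#' @param fluid A [fluid_air()].
#' @return A `flow_policy` whose `steps` gain `t_start`, `t_end` columns.
#' @export
policy_to_time <- function(policy, tree, fluid = fluid_air()) {
  if (is.data.frame(policy)) {
    policy <- flow_policy(policy$q0, policy$generation)
  }
  if (policy$type != "generation") stop("need a generation-indexed policy")
  if (any(policy$steps$q0 <= 0)) stop("zero flow step")
  flow <- partition_flows(tree, 1, fluid)  # fractions; velocity at Q0 = 1
  st <- policy$steps
  tau <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    sel <- tree$generation == st$generation[i]
    if (!any(sel)) { tau[i] <- 0; next }
    u <- flow$velocity[sel] * st$q0[i]  # velocity scales linearly in Q0
    tau[i] <- mean(tree$length[sel] / u)
  }
  st$t_start <- cumsum(c(0, tau[-length(tau)]))
  st$t_end <- cumsum(tau)
  policy$steps <- st
  policy
}

#' Optimal time-varying flow policy for a tree
#'
#' Convenience wrapper: [optimal_generation_flows()] followed by
#' [policy_to_time()].
#'
#' @inheritParams optimal_generation_flows
#' @return A time-stamped generation-indexed `flow_policy`.
#' @export
optimal_flow_policy <- function(tree, particle, fluid = fluid_air(),
                                constants = phys_constants(),
                                q_range = c(1e-7, 1e-3)) {
  pol <- optimal_generation_flows(tree, particle, fluid, constants, q_range)
  policy_to_time(pol, tree, fluid)
}

#' Evaluate a flow policy on a tree
#'
#' Generation-stepped cohort evaluation: at step g all surviving particle
#' mass occupies generation g; flows are rescaled to that step's inlet
#' flow, per-segment escape probabilities are evaluated at the local
#' flows, and mass propagates down the flow split. A constant policy
#' reproduces the absorbing-chain solution exactly. Policies with fewer
#' steps than the tree depth reuse the last step's flow (with a warning).
#'
#' @param tree An [airway_tree()].
#' @param particle,fluid,constants Property bundles.
#' @param policy A [flow_policy()], or a single flow (m^3/s) meaning a
#'   constant policy.
#' @return An object of class `policy_evaluation`: list with `escape`,
#'   `capture` (per-segment), `escape_by_terminal`, `q0_by_generation`,
#'   `policy`.
#' @export
evaluate_policy <- function(tree, particle, policy, fluid = fluid_air(),
                            constants = phys_constants()) {
  if (is.numeric(policy)) policy <- flow_policy(policy)
  stopifnot(inherits(policy, "flow_policy"))
  depth <- max(tree$generation)
  if (policy$type == "constant") {
    q0_g <- rep(policy$q0, depth)
  } else {
    q0_g <- policy$steps$q0[match(seq_len(depth), policy$steps$generation)]
    if (anyNA(q0_g)) {
      last <- max(which(!is.na(q0_g)))
      if (any(is.na(q0_g[seq_len(last)]))) {
        stop("policy must cover generations from 1 without gaps")
      }
      warning("policy has fewer steps than tree depth; ",
              "reusing the last step's flow")
      q0_g[is.na(q0_g)] <- q0_g[last]
    }
  }
  flow <- partition_flows(tree, 1, fluid)
  theta <- gravity_angle(tree)
  kids <- tree_children(tree)
  n <- nrow(tree)
  mass <- numeric(n)
  mass[1] <- 1
  capture <- numeric(n)
  ebt <- numeric(n)
  for (g in seq_len(depth)) {
    sel <- which(tree$generation == g & mass > 0)
    if (!length(sel)) next
    q_loc <- flow$fraction[sel] * q0_g[g]
    p_e <- deposition_probs(
      q_loc, tube(tree$length[sel], tree$diameter[sel], theta[sel]),
      particle, fluid, constants, warn = FALSE)$p_e
    capture[sel] <- capture[sel] + mass[sel] * (1 - p_e)
    for (i in seq_along(sel)) {
      k <- sel[i]
      ch <- kids[[k]]
      if (length(ch)) {
        mass[ch] <- mass[ch] +
          mass[k] * p_e[i] * flow$fraction[ch] / flow$fraction[k]
      } else {
        ebt[k] <- ebt[k] + mass[k] * p_e[i]
      }
    }
  }
  escape <- sum(ebt)
  names(capture) <- seq_len(n)
  term <- tree_terminals(tree)
  ebt <- ebt[term]
  names(ebt) <- term
  structure(list(escape = escape, capture = capture,
                 escape_by_terminal = ebt,
                 q0_by_generation = q0_g, policy = policy),
            class = "policy_evaluation")
}

#' @export
print.policy_evaluation <- function(x, ...) {
  cat(sprintf("policy evaluation: escape = %.4f, deposition = %.4f\n",
              x$escape, sum(x$capture)))
  invisible(x)
}

#' Reference flow policies for comparison
#'
#' The four built-in policies used for escape comparisons: constant
#' minimum, constant log-midpoint, constant maximum, and the optimal
#' time-varying policy.
#'
#' @inheritParams optimal_generation_flows
#' @return A named list of [flow_policy()] objects.
#' @export
reference_policies <- function(tree, particle, fluid = fluid_air(),
                               constants = phys_constants(),
                               q_range = c(1e-7, 1e-3)) {
  list(constant_min = flow_policy(q_range[1]),
       constant_mid = flow_policy(10^mean(log10(q_range))),
       constant_max = flow_policy(q_range[2]),
       optimal = optimal_flow_policy(tree, particle, fluid, constants,
                                     q_range))
}
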