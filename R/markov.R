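# The absorbing Markov chain over airway states. State ordering: airway
# states 1..N, then one capture (absorbing) state per segment at N+1..2N,
# then a single terminal-escape absorbing state at 2N+1 representing
# alveolar delivery. From a suspended particle in segment k the chain moves
# to daughter j with probability p_e(k) * Q_j / Q_k, to k's capture state
# with 1 - p_e(k), and (for terminals) to the escape state with p_e(k).
# Rows are stochastic by construction; the transient block is strictly
# triangular in the breadth-first ordering, so absorption is solved by one
# sparse triangular system rather than time-stepping.

# per-segment escape probabilities for a tree under a flow state
.segment_escape <- function(tree, flow, particle, fluid, constants,
                            warn = FALSE) {
  tb <- tube(tree$length, tree$diameter, gravity_angle(tree))
  deposition_probs(flow$flow, tb, particle, fluid, constants,
                   warn = warn)$p_e
}

#' Build the sparse transition matrix
#'
#' @param tree An [airway_tree()].
#' @param flow A `flow_state` from [partition_flows()] on the same tree.
#' @param particle,fluid,constants Property bundles.
#' @return An object of class `transition_matrix`: a list with the sparse
#'   row-stochastic matrix `P` (dimension `2N+1`), the per-segment escape
#'   probabilities `p_e`, `n_airway`, `capture_states`, `escape_state`.
#' @export
build_transition_matrix <- function(tree, flow, particle,
                                    fluid = fluid_air(),
                                    constants = phys_constants()) {
  stopifnot(inherits(tree, "airway_tree"), inherits(flow, "flow_state"))
  if (nrow(flow) != nrow(tree) || any(flow$state != tree$state)) {
    stop("flow state does not match tree")
  }
  n <- nrow(tree)
  p_e <- .segment_escape(tree, flow, particle, fluid, constants)
  kids <- tree_children(tree)
  term <- tree_terminals(tree)
  esc <- 2L * n + 1L

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_len(n)) {
    ch <- kids[[k]]
    if (length(ch)) {
      w <- flow$flow[ch] / flow$flow[k]
      ii <- c(ii, k, k); jj <- c(jj, ch); xx <- c(xx, p_e[k] * w)
    } else {
      ii <- c(ii, k); jj <- c(jj, esc); xx <- c(xx, p_e[k])
    }
    ii <- c(ii, k); jj <- c(jj, n + k); xx <- c(xx, 1 - p_e[k])
  }
  absorb <- (n + 1L):esc
  ii <- c(ii, absorb); jj <- c(jj, absorb); xx <- c(xx, rep(1, n + 1L))
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(esc, esc))
  structure(list(P = P, p_e = p_e, n_airway = n,
                 capture_states = (n + 1L):(2L * n),
                 escape_state = esc,
                 terminals = term),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf(
    "transition matrix: %d airway states + %d capture + 1 escape (%d x %d, %d nonzeros)\n",
    x$n_airway, x$n_airway, nrow(x$P), ncol(x$P), Matrix::nnzero(x$P)))
  invisible(x)
}

#' Solve the absorbing chain for deposition and escape
#'
#' Computes the exact absorption probabilities into every per-segment
#' capture state and the terminal escape state for a particle starting
#' suspended at `start_state` (no time-stepping error). Because each
#' airway state is visited at most once, the expected-visit vector equals
#' the reach probability, and per-terminal escape contributions are
#' reported as well (needed for the scintigraphy escape cubes).
#'
#' @param tmat A [build_transition_matrix()] result.
#' @param start_state Starting airway state (default 1, the root).
#' @return An object of class `deposition_result`: list with `capture`
#'   (per-segment probabilities, indexed by state), `escape` (total escape
#'   probability), `escape_by_terminal`, `p_e`, `start_state`.
#' @export
solve_absorption <- function(tmat, start_state = 1L) {
  stopifnot(inherits(tmat, "transition_matrix"))
  n <- tmat$n_airway
  if (!start_state %in% seq_len(n)) stop("start_state must be an airway state")
  Qb <- tmat$P[seq_len(n), seq_len(n), drop = FALSE]
  Rb <- tmat$P[seq_len(n), (n + 1L):(2L * n + 1L), drop = FALSE]
  e <- numeric(n)
  e[start_state] <- 1
  # reach probabilities: (I - Q)^T x = e_start
  x <- as.vector(Matrix::solve(Matrix::t(Matrix::Diagonal(n) - Qb), e))
  absorb <- as.vector(Matrix::crossprod(Rb, x))
  capture <- absorb[seq_len(n)]
  escape <- absorb[n + 1L]
  names(capture) <- seq_len(n)
  ebt <- x[tmat$terminals] * tmat$p_e[tmat$terminals]
  names(ebt) <- tmat$terminals
  total <- sum(capture) + escape
  if (abs(total - 1) > 1e-10) {
    stop(sprintf("absorption probabilities do not conserve: total = %.12f",
                 total))
  }
  structure(list(capture = capture, escape = escape,
                 escape_by_terminal = ebt, p_e = tmat$p_e,
                 start_state = start_state),
            class = "deposition_result")
}

#' Escape probability along one root-to-terminal path
#'
#' \eqn{P_e = (Q_n/Q_0) \prod_k p_{e,k}(Q_k)}: the product of per-segment
#' escape probabilities weighted by the terminal flow fraction.
#'
#' @param tree,flow,particle,fluid,constants As in
#'   [build_transition_matrix()].
#' @param path Integer vector of states from the root to a terminal (each
#'   consecutive pair parent/daughter).
#' @return Path escape probability.
#' @export
path_escape <- function(tree, flow, particle, path, fluid = fluid_air(),
                        constants = phys_constants()) {
  if (path[1] != 1L) stop("path must start at the root")
  if (any(path < 1) || any(path > nrow(tree)) ||
      (length(path) > 1 &&
       !isTRUE(all(tree$parent[path[-1]] == path[-length(path)])))) {
    stop("path is not a connected root-to-terminal chain")
  }
  p_e <- .segment_escape(tree, flow, particle, fluid, constants)
  prod(p_e[path]) * flow$fraction[path[length(path)]]
}

#' Total escape probability by path enumeration
#'
#' Sums [path_escape()] over all root-to-terminal paths. Must agree with
#' the linear-solve escape from [solve_absorption()]; the two routes are
#' kept independent as a cross-check.
#'
#' @inheritParams path_escape
#' @return Total escape probability.
#' @export
total_escape <- function(tree, flow, particle, fluid = fluid_air(),
                         constants = phys_constants()) {
  p_e <- .segment_escape(tree, flow, particle, fluid, constants)
  term <- tree_terminals(tree)
  total <- 0
  for (t in term) {
    path <- t
    while (!is.na(tree$parent[path[1]])) path <- c(tree$parent[path[1]], path)
    total <- total + prod(p_e[path]) * flow$fraction[t]
  }
  total
}

#' Monte-Carlo random walkers on the chain
#'
#' Simulates `n` independent particles through the transition matrix and
#' tallies their absorbing states: a stochastic cross-check of
#' [solve_absorption()].
#'
#' @param tmat A [build_transition_matrix()] result.
#' @param n Number of walkers.
#' @param seed Integer seed (caller's RNG state is preserved).
#' @param start_state Starting airway state.
#' @return A list with `capture` (per-segment observed frequencies),
#'   `escape` (observed escape frequency) and `n`.
#' @export
simulate_walkers <- function(tmat, n = 1e5, seed = 1L, start_state = 1L) {
  stopifnot(inherits(tmat, "transition_matrix"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  N <- tmat$n_airway
  cur <- rep.int(as.integer(start_state), n)
  repeat {
    trans <- cur <= N
    if (!any(trans)) break
    for (s in unique(cur[trans])) {
      idx <- which(trans & cur == s)
      row <- tmat$P[s, ]
      nz <- which(row > 0)
      cur[idx] <- if (length(nz) == 1L) nz else {
        sample(nz, length(idx), replace = TRUE, prob = row[nz])
      }
    }
  }
  cap <- tabulate(cur - N, nbins = N + 1L)
  list(capture = cap[seq_len(N)] / n, escape = cap[N + 1L] / n, n = n)
}
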