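# Single-segment deposition physics: sedimentation, inertial impaction and
# Brownian diffusion kernels, their combination into an escape probability,
# and the flow minimizing capture in one tube. All inputs are SI.

#' Aerosol particle
#'
#' @param diameter Particle diameter \eqn{d_p} in metres.
#' @param density Particle density \eqn{\rho_p} in kg/m^3. Defaults to
#'   unit density (water), the usual convention for pharmaceutical aerosols.
#' @return An object of class `aero_particle`.
#' @examples
#' particle(3.5e-6)
#' @export
particle <- function(diameter, density = 1000) {
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0) {
    stop("`diameter` must be a single positive number (metres)")
  }
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("`density` must be a single positive number (kg/m^3)")
  }
  structure(list(diameter = diameter, density = density),
            class = "aero_particle")
}

#' @export
print.aero_particle <- function(x, ...) {
  cat(sprintf("aerosol particle: d_p = %g um, rho_p = %g kg/m^3\n",
              x$diameter * 1e6, x$density))
  invisible(x)
}

#' Carrier fluid (default: dry air at body temperature)
#'
#' @param viscosity Dynamic viscosity \eqn{\mu} in Pa s.
#' @param density Fluid density \eqn{\rho} in kg/m^3.
#' @param temperature Absolute temperature in K (default 37 C).
#' @param mean_free_path Gas mean free path in metres, used by the
#'   Cunningham slip correction.
#' @return An object of class `aero_fluid`.
#' @export
fluid_air <- function(viscosity = 1.9e-5, density = 1.14,
                      temperature = 310.15, mean_free_path = 7.0e-8) {
  vals <- c(viscosity, density, temperature, mean_free_path)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all fluid properties must be positive and finite")
  }
  structure(list(viscosity = viscosity, density = density,
                 temperature = temperature, mean_free_path = mean_free_path),
            class = "aero_fluid")
}

#' Physical constants
#'
#' @param g Gravitational acceleration, m/s^2.
#' @param k_B Boltzmann constant, J/K.
#' @return An object of class `aero_constants`.
#' @export
phys_constants <- function(g = 9.80665, k_B = 1.380649e-23) {
  if (g <= 0 || k_B <= 0) stop("constants must be positive")
  structure(list(g = g, k_B = k_B), class = "aero_constants")
}

#' Cylindrical tube specification
#'
#' Describes one airway segment as a straight cylinder. `angle` is the signed
#' elevation of the tube axis above the horizontal plane, in radians:
#' 0 for a horizontal tube, `-pi/2` when the axis is parallel to gravity
#' (flow descending), `+pi/2` when ascending.
#'
#' @param length Tube length L in metres. May be a vector.
#' @param diameter Tube diameter D in metres. May be a vector.
#' @param angle Gravity angle theta in radians, in `[-pi/2, pi/2]`.
#' @return An object of class `tube_spec`.
#' @export
tube <- function(length, diameter, angle = 0) {
  if (any(!is.finite(length)) || any(length <= 0)) stop("length must be > 0")
  if (any(!is.finite(diameter)) || any(diameter <= 0)) stop("diameter must be > 0")
  if (any(!is.finite(angle)) || any(abs(angle) > pi / 2 + 1e-12)) {
    stop("angle must lie in [-pi/2, pi/2]")
  }
  structure(list(length = length, diameter = diameter, angle = angle),
            class = "tube_spec")
}

#' Cunningham slip correction factor
#'
#' Knudsen-regime correction to Stokes drag,
#' \eqn{C_c = 1 + (2\lambda/d_p)(A_1 + A_2 e^{-A_3 d_p/(2\lambda)})}.
#' Approaches 1 in the continuum limit (large particles) and grows without
#' bound for nanoparticles.
#'
#' @param d_p Particle diameter, m. Vectorized.
#' @param mean_free_path Gas mean free path \eqn{\lambda}, m.
#' @param A Three slip coefficients; the defaults are the standard
#'   Knudsen-regime values.
#' @return Dimensionless factor `>= 1`.
#' @export
cunningham_correction <- function(d_p, mean_free_path = 7.0e-8,
                                  A = c(1.257, 0.4, 1.1)) {
  if (any(d_p <= 0) || any(mean_free_path <= 0)) {
    stop("d_p and mean_free_path must be positive")
  }
  kn2 <- 2 * mean_free_path / d_p
  1 + kn2 * (A[1] + A[2] * exp(-A[3] / kn2))
}

#' Stokes settling velocity
#'
#' Terminal settling velocity under gravity,
#' \eqn{v_s = \rho_p g d_p^2 C_c / (18 \mu)}, neglecting air buoyancy.
#'
#' @param particle,fluid,constants See [particle()], [fluid_air()],
#'   [phys_constants()].
#' @return Settling velocity in m/s.
#' @export
settling_velocity <- function(particle, fluid = fluid_air(),
                              constants = phys_constants()) {
  cc <- cunningham_correction(particle$diameter, fluid$mean_free_path)
  particle$density * constants$g * particle$diameter^2 * cc /
    (18 * fluid$viscosity)
}

#' Reynolds number of the tube flow
#'
#' \eqn{Re = 4 \rho Q / (\pi D \mu)}.
#'
#' @param Q Volumetric flow, m^3/s. Vectorized.
#' @param D Tube diameter, m.
#' @param fluid See [fluid_air()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(Q, D, fluid = fluid_air()) {
  if (any(Q < 0)) stop("Q must be >= 0")
  if (any(D <= 0)) stop("D must be > 0")
  4 * fluid$density * Q / (pi * D * fluid$viscosity)
}

# mean cross-sectional velocity
.u_mean <- function(Q, D) Q / (pi * (D / 2)^2)

# cos/sin of the gravity angle with exact zeros at the axis-aligned and
# horizontal orientations (cos(pi/2) is 6e-17 in floating point; a tube
# parallel to gravity must give exactly zero sedimentation)
.cos_theta <- function(th) {
  ct <- cos(th)
  ct[abs(ct) < 1e-12] <- 0
  ct
}

# Eq. for p_s as a function of the settling parameter kappa (already >= 0);
# kappa is clipped to [0,1]: kappa >= 1 means the settling time is shorter
# than the transit time, i.e. certain capture.
.p_sed_from_kappa <- function(kappa) {
  k <- pmin(kappa, 1)
  s <- sqrt(pmax(1 - k^(2 / 3), 0))
  p <- (2 / pi) * (2 * k * s - k^(1 / 3) * s + asin(pmin(k^(1 / 3), 1)))
  p <- pmin(pmax(p, 0), 1)
  p[kappa >= 1] <- 1
  p
}

#' Sedimentation deposition probability
#'
#' Probability that a particle deposits by gravitational settling while
#' transiting a cylindrical tube under Poiseuille flow. The settling
#' parameter is \eqn{\kappa = (3/4) (v_s/\bar U)(L/D) |\cos\theta|},
#' clipped to `[0, 1]` before the closed-form expression is applied.
#' `Q = 0` is treated as infinite residence time (certain capture).
#'
#' The closed form assumes \eqn{d_p \ll d_s} where
#' \eqn{d_s = \sqrt{72 Q \mu / (|\sin\theta| \rho_p g \pi D^2)}}; a warning
#' is emitted when `d_p > 0.1 d_s`.
#'
#' @param Q Volumetric flow, m^3/s (vectorized, `>= 0`).
#' @param tube A [tube()].
#' @param particle,fluid,constants Property bundles.
#' @param warn Emit the validity-bound warning?
#' @return Probability vector in `[0, 1]`.
#' @export
sedimentation_probability <- function(Q, tube, particle, fluid = fluid_air(),
                                      constants = phys_constants(),
                                      warn = TRUE) {
  stopifnot(inherits(tube, "tube_spec"))
  if (any(Q < 0)) stop("Q must be >= 0")
  n <- max(length(Q), length(tube$length), length(tube$diameter),
           length(tube$angle))
  Q <- rep_len(Q, n)
  L <- rep_len(tube$length, n)
  D <- rep_len(tube$diameter, n)
  th <- rep_len(tube$angle, n)

  v_s <- settling_velocity(particle, fluid, constants)
  ct <- .cos_theta(th)
  kappa <- rep(Inf, n)
  pos <- Q > 0
  kappa[pos] <- 0.75 * (v_s / .u_mean(Q[pos], D[pos])) *
    (L[pos] / D[pos]) * abs(ct[pos])
  if (warn) {
    d_s <- .settling_bound(Q, D, th, particle, fluid, constants)
    if (any(particle$diameter > 0.1 * d_s)) {
      warning("particle diameter exceeds 0.1 * d_s: sedimentation ",
              "closed form outside its validity bound")
    }
  }
  .p_sed_from_kappa(kappa)
}

# validity bound d_s for the sedimentation closed form; Inf for horizontal
# tubes or zero flow (where the bound is moot)
.settling_bound <- function(Q, D, theta, particle, fluid, constants) {
  den <- abs(sin(theta)) * particle$density * constants$g * pi * D^2
  ifelse(den == 0 | Q == 0, Inf, sqrt(72 * Q * fluid$viscosity / den))
}

#' Stokes number
#'
#' \eqn{Stk = U_0 \rho_p d_p^2 C_c / (18 \mu D)} with \eqn{U_0} the mean
#' cross-sectional velocity \eqn{Q / (\pi (D/2)^2)}.
#'
#' @inheritParams reynolds_number
#' @param particle,fluid Property bundles.
#' @return Dimensionless Stokes number (vectorized over `Q`, `D`).
#' @export
stokes_number <- function(Q, D, particle, fluid = fluid_air()) {
  if (any(Q < 0)) stop("Q must be >= 0")
  if (any(D <= 0)) stop("D must be > 0")
  cc <- cunningham_correction(particle$diameter, fluid$mean_free_path)
  .u_mean(Q, D) * particle$density * particle$diameter^2 * cc /
    (18 * fluid$viscosity * D)
}

#' Impaction deposition probability
#'
#' Linear impaction law \eqn{p_i = 1.606\,Stk + 0.0023}, clipped to
#' `[0, 1]`. The linear law is validated for `Stk < 0.15`; a warning is
#' emitted above that.
#'
#' @param Stk Stokes number (vectorized, `>= 0`).
#' @param warn Emit the linear-range warning?
#' @return Probability vector in `[0, 1]`.
#' @export
impaction_probability <- function(Stk, warn = TRUE) {
  if (any(Stk < 0)) stop("Stk must be >= 0")
  if (warn && any(Stk > 0.15)) {
    warning("Stk > 0.15: outside the validated linear impaction range")
  }
  pmin(1.606 * Stk + 0.0023, 1)
}

#' Dimensionless diffusion parameter
#'
#' \eqn{\Delta = \frac{k_B T C_c}{3\pi\mu d_p} \frac{L}{\bar U}
#' \frac{1}{4 (D/2)^2}}: the particle's Brownian diffusivity
#' non-dimensionalized by the residence time and tube radius. `Q = 0` gives
#' `Inf` (infinite residence; certain diffusive capture downstream).
#'
#' @inheritParams sedimentation_probability
#' @return Dimensionless vector.
#' @export
diffusion_parameter <- function(Q, tube, particle, fluid = fluid_air(),
                                constants = phys_constants()) {
  stopifnot(inherits(tube, "tube_spec"))
  if (any(Q < 0)) stop("Q must be >= 0")
  n <- max(length(Q), length(tube$length), length(tube$diameter))
  Q <- rep_len(Q, n)
  L <- rep_len(tube$length, n)
  D <- rep_len(tube$diameter, n)
  cc <- cunningham_correction(particle$diameter, fluid$mean_free_path)
  diffusivity <- constants$k_B * fluid$temperature * cc /
    (3 * pi * fluid$viscosity * particle$diameter)
  out <- rep(Inf, n)
  pos <- Q > 0
  out[pos] <- diffusivity * L[pos] /
    (.u_mean(Q[pos], D[pos]) * 4 * (D[pos] / 2)^2)
  out
}

#' Diffusion deposition probability
#'
#' Four-exponential Poiseuille-flow expression for deposition by Brownian
#' motion; exactly 1 at and above the threshold `Delta >= 0.16853`. The
#' printed threshold introduces a small discontinuity (the series evaluates
#' to about 0.93 just below it); it is applied exactly as stated.
#'
#' @param Delta Dimensionless diffusion parameter (vectorized, `>= 0`).
#' @return Probability vector in `[0, 1]`.
#' @export
diffusion_probability <- function(Delta) {
  if (any(Delta < 0)) stop("Delta must be >= 0")
  p <- 1 - 0.819 * exp(-14.63 * Delta) - 0.0967 * exp(-89.22 * Delta) -
    0.0325 * exp(-228 * Delta) - 0.0509 * exp(-125.9 * Delta^(2 / 3))
  p <- pmin(pmax(p, 0), 1)
  p[Delta >= 0.16853] <- 1
  p
}

#' Combined escape and capture probability
#'
#' Treats the three deposition mechanisms as independent:
#' \eqn{p_e = (1 - p_s)(1 - p_i)(1 - p_d)}, \eqn{p_c = 1 - p_e}.
#'
#' @param p_s,p_i,p_d Per-mechanism deposition probabilities in `[0, 1]`.
#' @return A list with components `p_e` and `p_c`.
#' @export
escape_probability <- function(p_s, p_i, p_d) {
  probs <- c(p_s, p_i, p_d)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all deposition probabilities must lie in [0, 1]")
  }
  p_e <- (1 - p_s) * (1 - p_i) * (1 - p_d)
  list(p_e = p_e, p_c = 1 - p_e)
}

#' All deposition probabilities and diagnostics for one tube
#'
#' Evaluates the three deposition kernels and their combination for a tube
#' and flow, returning the probabilities together with the diagnostic
#' dimensionless groups. `Q = 0` follows the infinite-residence convention:
#' `p_s = p_d = 1` and `p_i = 0.0023`.
#'
#' @inheritParams sedimentation_probability
#' @return An object of class `deposition_probs`: a list of vectors
#'   `p_s`, `p_i`, `p_d`, `p_e`, `p_c`, `kappa`, `Stk`, `Delta`, `Re`,
#'   `U_mean`, `v_s`, `C_c`, `d_s`.
#' @export
deposition_probs <- function(Q, tube, particle, fluid = fluid_air(),
                             constants = phys_constants(), warn = TRUE) {
  stopifnot(inherits(tube, "tube_spec"), inherits(particle, "aero_particle"))
  if (any(Q < 0)) stop("Q must be >= 0")
  n <- max(length(Q), length(tube$length), length(tube$diameter),
           length(tube$angle))
  Q <- rep_len(Q, n)
  L <- rep_len(tube$length, n)
  D <- rep_len(tube$diameter, n)
  th <- rep_len(tube$angle, n)

  v_s <- settling_velocity(particle, fluid, constants)
  cc <- cunningham_correction(particle$diameter, fluid$mean_free_path)
  U <- .u_mean(Q, D)
  ct <- .cos_theta(th)
  kappa <- ifelse(Q > 0, 0.75 * (v_s / U) * (L / D) * abs(ct), Inf)
  Stk <- stokes_number(Q, D, particle, fluid)
  Delta <- diffusion_parameter(Q, tube(L, D, th), particle, fluid, constants)
  d_s <- .settling_bound(Q, D, th, particle, fluid, constants)
  if (warn && any(particle$diameter > 0.1 * d_s)) {
    warning("particle diameter exceeds 0.1 * d_s: sedimentation ",
            "closed form outside its validity bound")
  }
  p_s <- .p_sed_from_kappa(kappa)
  p_i <- impaction_probability(Stk, warn = warn)
  p_d <- diffusion_probability(Delta)
  esc <- escape_probability(p_s, p_i, p_d)
  structure(list(p_s = p_s, p_i = p_i, p_d = p_d,
                 p_e = esc$p_e, p_c = esc$p_c,
                 kappa = kappa, Stk = Stk, Delta = Delta,
                 Re = reynolds_number(Q, D, fluid),
                 U_mean = U, v_s = v_s, C_c = cc, d_s = d_s),
            class = "deposition_probs")
}

#' @export
print.deposition_probs <- function(x, ...) {
  cat("deposition probabilities (", length(x$p_e), " flow point",
      if (length(x$p_e) != 1) "s", "):\n", sep = "")
  print(data.frame(p_s = x$p_s, p_i = x$p_i, p_d = x$p_d, p_e = x$p_e),
        ...)
  invisible(x)
}

#' Flow minimizing the capture probability in one tube
#'
#' Minimizes \eqn{p_c(Q) = 1 - p_e(Q)} over an admissible flow interval.
#' A 200-point log-spaced grid seeds a bounded scalar minimization in
#' `log10(Q)`; boundary minima are legitimate results. The tradeoff being
#' minimized: sedimentation and diffusion decrease with flow while
#' impaction increases, so micron particles have an interior optimum and
#' nanoparticles are driven towards the fast end of the range.
#'
#' @param tube A [tube()] with scalar fields.
#' @param particle,fluid,constants Property bundles.
#' @param q_range Admissible flow interval, m^3/s (default the
#'   physiological 0.0001 to 1 L/s).
#' @param n_grid Seed grid size.
#' @param tol Relative tolerance on Q.
#' @return A list with `q_opt` (m^3/s) and `p_c` (the minimized capture
#'   probability).
#' @export
capture_minimizing_flow <- function(tube, particle, fluid = fluid_air(),
                                    constants = phys_constants(),
                                    q_range = c(1e-7, 1e-3),
                                    n_grid = 200, tol = 1e-4) {
  if (length(q_range) != 2 || any(!is.finite(q_range)) ||
      q_range[1] <= 0 || q_range[2] <= q_range[1]) {
    stop("q_range must be a positive increasing interval")
  }
  obj <- function(lq) {
    deposition_probs(10^lq, tube, particle, fluid, constants,
                     warn = FALSE)$p_c
  }
  lg <- seq(log10(q_range[1]), log10(q_range[2]), length.out = n_grid)
  pc <- obj(lg)
  i <- which.min(pc)
  lo <- lg[max(i - 1L, 1L)]
  hi <- lg[min(i + 1L, n_grid)]
  opt <- stats::optimize(function(x) obj(x), c(lo, hi),
                         tol = tol / log(10))
  if (opt$objective <= pc[i]) {
    list(q_opt = 10^opt$minimum, p_c = opt$objective)
  } else {
    list(q_opt = 10^lg[i], p_c = pc[i])
  }
}
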