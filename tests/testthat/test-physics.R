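pt8 <- particle(8e-6)
pt035 <- particle(0.35e-6)
tb <- benchmark_tube()

test_that("Cunningham slip correction has the right limits and magnitudes", {
  expect_equal(cunningham_correction(1), 1, tolerance = 1e-6)
  expect_equal(cunningham_correction(8e-6), 1.022, tolerance = 1e-3)
  expect_gt(cunningham_correction(0.035e-6), 5)
  expect_error(cunningham_correction(-1e-6), "positive")
  # monotone decreasing towards the continuum limit
  d <- 10^seq(-8, -4, length.out = 50)
  expect_true(all(diff(cunningham_correction(d)) < 0))
})

test_that("settling velocity follows Stokes law", {
  # hand arithmetic: rho_p g d^2 C_c / (18 mu) for the 8 um particle
  expect_equal(settling_velocity(pt8), 1.9e-3, tolerance = 0.02)
  # d^2 scaling where slip is negligible
  v1 <- settling_velocity(particle(100e-6))
  v2 <- settling_velocity(particle(200e-6))
  expect_equal(v2 / v1, 4, tolerance = 1e-3)
  expect_lt(settling_velocity(particle(1e-9)), 1e-8)
})

test_that("sedimentation probability: exact limits and conventions", {
  # axis parallel to gravity: no sedimentation, exactly
  expect_identical(
    sedimentation_probability(1e-4, tube(0.063, 0.0135, -pi / 2), pt8), 0)
  # zero flow: infinite residence, certain capture
  expect_identical(sedimentation_probability(0, tb, pt8), 1)
  # settling time shorter than transit (kappa clipped at 1): exactly 1
  expect_identical(sedimentation_probability(1e-9, tb, pt8), 1)
  expect_error(sedimentation_probability(-1, tb, pt8), "Q")
  # validity-bound warning for a big particle in a tilted tube at low flow
  expect_warning(
    sedimentation_probability(1e-6, tube(0.01, 0.002, pi / 4),
                              particle(80e-6)),
    "validity")
})

test_that("sedimentation matches the Monte-Carlo settling oracle", {
  cases <- list(
    list(Q = 2e-5, tb = tb, pt = pt8),
    list(Q = 1e-4, tb = tb, pt = pt8),
    list(Q = 2e-6, tb = tb, pt = pt8),
    list(Q = 5e-5, tb = tube(0.04, 0.008, pi / 6), pt = particle(5e-6)),
    list(Q = 1e-5, tb = tube(0.09, 0.018, -pi / 5), pt = particle(10e-6))
  )
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    p <- sedimentation_probability(cs$Q, cs$tb, cs$pt, warn = FALSE)
    mc <- mc_settling_oracle(cs$Q, cs$tb, cs$pt, n = 1e5, seed = 40 + i)
    expect_lt(abs(p - mc$p), 3 * mc$se)
  }
})

test_that("Stokes number and linear impaction law", {
  expect_identical(stokes_number(0, 0.0135, pt8), 0)
  stk <- stokes_number(1e-3, 0.0135, pt8)
  expect_equal(stk, 0.099, tolerance = 0.01)
  expect_lt(stk, 0.15)
  # nanoparticle impaction negligible at any physiological flow
  expect_lt(stokes_number(1e-3, 0.0135, pt035), 1e-3)
  expect_equal(impaction_probability(0), 0.0023)
  expect_equal(impaction_probability(0.1), 1.606 * 0.1 + 0.0023)
  expect_identical(impaction_probability(10, warn = FALSE), 1)
  expect_warning(impaction_probability(0.2), "0.15")
  expect_error(impaction_probability(-0.1), "Stk")
})

test_that("diffusion parameter scales as 1/Q and ignores density/angle", {
  d1 <- diffusion_parameter(1e-5, tb, pt035)
  d2 <- diffusion_parameter(2e-5, tb, pt035)
  expect_equal(d1 / d2, 2, tolerance = 1e-12)
  # independent hand arithmetic: (kB T Cc / 3 pi mu dp) * L / (U D^2)
  fl <- fluid_air()
  cc <- cunningham_correction(0.35e-6)
  U <- 1e-4 / (pi * (0.0135 / 2)^2)
  expected <- (1.380649e-23 * 310.15 * cc / (3 * pi * fl$viscosity * 0.35e-6)) *
    0.063 / (U * 0.0135^2)
  expect_equal(diffusion_parameter(1e-4, tb, pt035), expected,
               tolerance = 1e-10)
  expect_identical(
    diffusion_parameter(1e-4, tb, pt035),
    diffusion_parameter(1e-4, tube(0.063, 0.0135, -pi / 3),
                        particle(0.35e-6, density = 5000)))
  expect_identical(diffusion_parameter(0, tb, pt035), Inf)
})

test_that("diffusion probability: threshold, floor and series value", {
  expect_identical(diffusion_probability(0.16853), 1)
  expect_identical(diffusion_probability(0.5), 1)
  expect_equal(diffusion_probability(0), 0.0009, tolerance = 1e-12)
  # independent evaluation of the four-term sum at Delta = 0.05
  expected <- 1 - 0.819 * exp(-14.63 * 0.05) - 0.0967 * exp(-89.22 * 0.05) -
    0.0325 * exp(-228 * 0.05) - 0.0509 * exp(-125.9 * 0.05^(2 / 3))
  expect_equal(diffusion_probability(0.05), expected)
  expect_error(diffusion_probability(-0.1), "Delta")
})

test_that("combined escape probability is the independence product", {
  expect_equal(escape_probability(0, 0, 0)$p_e, 1)
  expect_equal(escape_probability(1, 0.3, 0.9)$p_e, 0)
  expect_equal(escape_probability(0.1, 0.2, 0.3)$p_e, 0.504)
  # symmetric under permutation of the three mechanisms
  expect_equal(escape_probability(0.1, 0.2, 0.3)$p_e,
               escape_probability(0.3, 0.1, 0.2)$p_e)
  expect_equal(escape_probability(0.25, 0.5, 0)$p_c,
               1 - escape_probability(0.25, 0.5, 0)$p_e)
  expect_error(escape_probability(1.2, 0, 0), "\\[0, 1\\]")
})

test_that("Reynolds number definition and linearity", {
  expect_identical(reynolds_number(0, 0.0135), 0)
  fl <- fluid_air()
  expect_equal(reynolds_number(5e-4, 0.0135),
               4 * fl$density * 5e-4 / (pi * 0.0135 * fl$viscosity))
  expect_equal(reynolds_number(2e-4, 0.01) / reynolds_number(1e-4, 0.01), 2)
})

test_that("all probabilities stay in [0,1] over randomized inputs", {
  set.seed(101)
  for (i in 1:40) {
    tbr <- tube(runif(1, 1e-3, 0.2), runif(1, 5e-4, 0.02),
                runif(1, -pi / 2, pi / 2))
    ptr <- particle(10^runif(1, -8, -5), runif(1, 500, 3000))
    Q <- 10^runif(1, -8, -2)
    dp <- deposition_probs(Q, tbr, ptr, warn = FALSE)
    probs <- c(dp$p_s, dp$p_i, dp$p_d, dp$p_e, dp$p_c)
    expect_true(all(probs >= 0 & probs <= 1))
    expect_equal(dp$p_e, (1 - dp$p_s) * (1 - dp$p_i) * (1 - dp$p_d))
  }
})

test_that("kernel monotonicity in flow: p_s, p_d fall, p_i rises", {
  Q <- 10^seq(-7, -3, length.out = 60)
  for (pt in list(pt8, pt035)) {
    dp <- deposition_probs(Q, tb, pt, warn = FALSE)
    expect_true(all(diff(dp$p_s) <= 0))
    expect_true(all(diff(dp$p_d) <= 0))
    expect_true(all(diff(dp$p_i) >= 0))
  }
})

test_that("zero-flow convention in the combined bundle", {
  dp <- deposition_probs(0, tb, pt8, warn = FALSE)
  expect_identical(dp$p_s, 1)
  expect_identical(dp$p_d, 1)
  expect_equal(dp$p_i, 0.0023)
  expect_identical(dp$p_e, 0)
})

test_that("capture-minimizing flow agrees with a brute-force grid oracle", {
  grid_oracle <- function(tb, pt, q_range) {
    q <- 10^seq(log10(q_range[1]), log10(q_range[2]), length.out = 2000)
    pc <- deposition_probs(q, tb, pt, warn = FALSE)$p_c
    q[which.min(pc)]
  }
  step <- (log10(1e-3) - log10(1e-7)) / 1999
  for (pt in list(pt8, particle(3.5e-6), pt035)) {
    qo <- grid_oracle(tb, pt, c(1e-7, 1e-3))
    qs <- capture_minimizing_flow(tb, pt)$q_opt
    expect_lt(abs(log10(qs) - log10(qo)), step * 1.01)
  }
  # 8 um particle: interior minimum, not at either end of the range
  q8 <- capture_minimizing_flow(tb, pt8)$q_opt
  expect_gt(q8, 2e-7)
  expect_lt(q8, 9e-4)
  expect_error(capture_minimizing_flow(tb, pt8, q_range = c(1e-3, 1e-7)),
               "q_range")
})
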