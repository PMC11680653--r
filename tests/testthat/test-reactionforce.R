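test_that("flat and linear potentials give constant forces", {
  xi <- seq(-3, 3, length.out = 41)
  for (m in c("spline", "central_difference")) {
    expect_equal(forceProfile(ircProfile(xi, rep(2, 41)), m), rep(0, 41),
                 tolerance = 1e-8)
    expect_equal(forceProfile(ircProfile(xi, 1.7 * xi), m), rep(-1.7, 41),
                 tolerance = 1e-8)
  }
})

test_that("the spline force of a quadratic is exact to tight tolerance", {
  xi <- seq(-2, 2, length.out = 81)
  rf <- forceProfile(ircProfile(xi, xi^2), "spline")
  expect_equal(rf, -2 * xi, tolerance = 1e-6)
})

test_that("sech-squared critical points match the closed form", {
  g <- makeIrcProfile(E0 = 10, L = 1, n = 201)
  cp <- criticalPoints(g$profile)
  a0 <- atanh(1 / sqrt(3))
  expect_equal(unname(cp["alpha"]), -a0, tolerance = 0.002 / a0)
  expect_equal(unname(cp["beta"]), 0, tolerance = 1e-3)
  expect_equal(unname(cp["gamma"]), a0, tolerance = 0.002 / a0)
  # mirror symmetry
  expect_equal(unname(cp["alpha"] + cp["gamma"]), 0, tolerance = 1e-3)
})

test_that("asymmetric profiles match a brute-force extremum search", {
  g <- makeIrcProfile(E0 = 12, delta = -6, L = 0.9, n = 301)
  cp <- criticalPoints(g$profile)
  A <- -6; B <- (sqrt(12) + sqrt(18))^2
  Vfun <- function(x) { y <- exp(x / 0.9); A * y / (1 + y) + B * y / (1 + y)^2 }
  bf <- bruteForceCriticalPoints(Vfun, min(ircCoordinate(g$profile)),
                                 max(ircCoordinate(g$profile)))
  expect_equal(unname(cp), unname(bf), tolerance = 1e-3)
  # and the generator's closed-form annotation agrees
  expect_equal(unname(cp),
               c(g$truth$alpha, g$truth$beta, g$truth$gamma), tolerance = 1e-3)
})

test_that("zone energies decompose the activation energies additively", {
  g <- makeIrcProfile(E0 = 10, L = 1, n = 201)
  cp <- criticalPoints(g$profile)
  z <- zoneDecomposition(g$profile, cp["alpha"], cp["beta"], cp["gamma"])
  expect_equal(unname(z["act_forward"]),
               unname(z["prep_forward"] + z["transition_forward"]))
  expect_equal(unname(z["act_reverse"]),
               unname(z["prep_reverse"] + z["transition_reverse"]))
  # the sech-squared barrier splits 2/3 preparation, 1/3 transition
  expect_equal(unname(z["prep_forward"]), 2 / 3 * 10, tolerance = 0.01)
  expect_equal(unname(z["transition_forward"]), 1 / 3 * 10, tolerance = 0.01)
})

test_that("tabulated zone components sum to the printed activation energies", {
  zones <- curatedDcafData("zone_energies")
  out <- activationFromZones(zones)
  expect_equal(out$act_forward, c(5.89, 6.40, 4.31))
  # the first compound's tabulated reverse barrier carries a final-digit
  # rounding inconsistency (components sum to 16.37, table prints 16.38)
  expect_equal(out$act_reverse, c(16.37, 16.24, 18.24))
  # preparation-step and H-transfer asymmetries from the same cells
  expect_equal(out$prep_reverse - out$prep_forward, c(5.20, 3.73, 5.08),
               tolerance = 1e-8)
  expect_equal(out$transition_reverse - out$transition_forward,
               c(5.28, 6.11, 8.85), tolerance = 1e-8)
})

test_that("work integrals are consistent with the energy bookkeeping", {
  g <- makeIrcProfile(E0 = 10, L = 1, n = 201)
  cp <- criticalPoints(g$profile)
  z <- zoneDecomposition(g$profile, cp["alpha"], cp["beta"], cp["gamma"])
  w <- workIntegrals(g$profile, cp["alpha"], cp["beta"], cp["gamma"])
  expect_equal(unname(w["W1"] + w["W2"]), -unname(z["act_forward"]),
               tolerance = 1e-4)
  V <- ircEnergy(g$profile)
  expect_equal(sum(w), -(V[length(V)] - V[1]), tolerance = 1e-3)
  # mirror symmetry: W1 = -W4 and W2 = -W3
  expect_equal(unname(w["W1"]), -unname(w["W4"]), tolerance = 1e-4)
  expect_equal(unname(w["W2"]), -unname(w["W3"]), tolerance = 1e-4)
  # 2/3 - 1/3 split shows up as a 2:1 area ratio
  expect_equal(abs(w[["W1"]]) / abs(w[["W2"]]), 2.0, tolerance = 0.01)
})

test_that("parameter recovery survives mild noise with the spline method", {
  for (seed in 1:5) {
    g <- makeIrcProfile(E0 = 10, delta = -4, L = 1, n = 301,
                        noiseSd = 0.01, seed = seed)   # 0.1% of the barrier
    fa <- analyzeReactionForce(g$profile)
    cp <- criticalCoords(fa)
    dx <- diff(ircCoordinate(g$profile))[1]
    expect_lt(abs(cp["alpha"] - g$truth$alpha), 3 * dx)
    expect_lt(abs(cp["beta"] - g$truth$beta), 3 * dx)
    expect_lt(abs(cp["gamma"] - g$truth$gamma), 3 * dx)
    z <- zoneEnergies(fa)
    expect_equal(unname(z["act_forward"]), g$truth$act_forward,
                 tolerance = 0.01)
    expect_equal(unname(z["act_reverse"]), g$truth$act_reverse,
                 tolerance = 0.01)
    # components inherit the critical-point localisation error
    # (|RF(alpha)| * dalpha), so they carry a looser band than the
    # activation energies
    expect_lt(abs(z["prep_forward"] - g$truth$prep_forward),
              0.03 * g$truth$act_forward)
  }
})

test_that("degenerate profiles are rejected with clear errors", {
  xi <- seq(-3, 3, length.out = 41)
  expect_error(ircProfile(1:5, 1:5), "at least 7")
  expect_error(ircProfile(c(1, 2, 2, 3, 4, 5, 6), rep(1, 7)), "increasing")
  expect_error(criticalPoints(ircProfile(xi, xi)), "no transition state")
  monotone <- ircProfile(xi, exp(xi))
  expect_error(criticalPoints(monotone), "no transition state")
  expect_false(singleBarrier(monotone))
})

test_that("hartree input converts to kcal/mol", {
  xi <- seq(-6, 6, length.out = 101)
  Vh <- 10 / cosh(xi)^2 / 627.5095
  p <- ircProfile(xi, Vh, units = "hartree")
  expect_equal(max(ircEnergy(p)), 10, tolerance = 1e-6)
})
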