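test_that("fitted-parameter pKa is a linear map with the bundled coefficients", {
  p <- fpaParameters()
  expect_equal(p$m[p$group == "phenol"], 0.316)
  expect_equal(p$C0[p$group == "amine"], -121.000)
  expect_equal(pkaFromFPA(0, "phenol"), -81.497)
  expect_equal(pkaFromFPA(281.89, "phenol"), 7.58, tolerance = 1e-3)
  expect_equal(pkaFromFPA(265.10, "thiol"), 0.002, tolerance = 1e-2)
  expect_error(pkaFromFPA(100, "ketone"), "known groups")
})

test_that("ladder fractions reproduce the tabulated physiological speciation", {
  sys16 <- dcafAcidBaseSystems()[["dCAF-16"]]
  f16 <- speciationFractions(sys16, 7.4)
  expect_equal(f16$fraction[f16$species == "mono-anion"], 0.6027, tolerance = 0.005)
  expect_equal(f16$fraction[f16$species == "di-anion"], 0.3973, tolerance = 0.005)
  f2 <- speciationFractions(dcafAcidBaseSystems()[["dCAF-2"]], 7.4)
  expect_equal(f2$fraction[f2$species == "mono-anion"], 0.7764, tolerance = 0.005)
  expect_equal(f2$fraction[f2$species == "di-anion"], 0.2235, tolerance = 0.005)
  expect_equal(sum(f16$fraction), 1, tolerance = 1e-12)
})

test_that("a monoprotic acid at pH = pKa splits half and half", {
  f <- speciationFractions(acidBaseSystem("x", 5), 5)
  expect_equal(f$fraction, c(0.5, 0.5))
})

test_that("ladder model matches the numeric equilibrium oracle", {
  set.seed(42)
  for (i in 1:100) {
    case <- makeSpeciationCase(pH = runif(1, 0, 14))
    f <- speciationFractions(case$system, case$pH)
    expect_equal(f$fraction, unname(case$expected), tolerance = 1e-10)
  }
})

test_that("adjacent species curves cross at the intervening pKa", {
  sys <- acidBaseSystem("x", c(4.2, 9.1))
  at1 <- speciationFractions(sys, 4.2)
  expect_equal(at1$fraction[1], at1$fraction[2], tolerance = 1e-12)
  at2 <- speciationFractions(sys, 9.1)
  expect_equal(at2$fraction[2], at2$fraction[3], tolerance = 1e-12)
})

test_that("distribution profiles are consistent, normalised and single-peaked", {
  sys <- acidBaseSystem("x", c(3.5, 7.1, 11.0))
  one <- distributionProfile(sys, 7.4)
  expect_equal(one, speciationFractions(sys, 7.4))
  grid <- seq(0, 14, by = 0.05)
  prof <- distributionProfile(sys, grid)
  sums <- tapply(prof$fraction, prof$pH, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  for (sp in speciesLabels(sys)) {
    y <- prof$fraction[prof$species == sp]
    ipk <- which.max(y)
    expect_true(all(diff(y[seq_len(ipk)]) >= -1e-12))       # rises to the peak
    expect_true(all(diff(y[ipk:length(y)]) <= 1e-12))       # then falls
  }
  expect_error(distributionProfile(sys, c(7, 3)), "sorted")
})

test_that("extreme ladders collapse onto a single protonation state", {
  high <- makeSpeciationCase(nSteps = 3, pH = 0.5, seed = 1)
  fhigh <- speciationFractions(high$system, 0.5)
  lowsys <- acidBaseSystem("low", c(0.5, 1.5, 2.5))
  flow <- speciationFractions(lowsys, 13)
  expect_gt(fhigh$fraction[1], 0.9)                # neutral dominates
  expect_gt(flow$fraction[4], 0.99)                # fully deprotonated
})

test_that("non-monotone ladders are rejected", {
  expect_error(acidBaseSystem("x", c(7.1, 3.2)), "increasing")
  expect_error(equilibriumFractions(c(5, 5), 7), "increasing")
})

test_that("the stated pKa uncertainty shifts fractions by a bounded amount", {
  sys <- dcafAcidBaseSystems()[["dCAF-16"]]
  sens <- speciationSensitivity(sys, 7.4)
  expect_true(all(abs(sens$delta_fraction) < 0.12))
  expect_true(all(c("perturbed_pka", "shift", "species") %in% names(sens)))
  # perturbing a pKa far from the working pH barely moves anything
  far <- sens[sens$perturbed_pka == 3, ]
  expect_true(all(abs(far$delta_fraction) < 0.01))
})
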