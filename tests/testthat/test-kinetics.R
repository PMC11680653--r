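test_that("the Eyring prefactor and barrier dependence are exact", {
  expect_equal(tstRate(0), 6.212e12, tolerance = 1e-3)
  expect_equal(tstRate(15.20), 44.7, tolerance = 0.01)
  expect_equal(tstRate(10, sigma = 2), 2 * tstRate(10))
  expect_equal(tstRate(10, kappa = 3), 3 * tstRate(10))
  expect_error(tstRate(10, kappa = 0.5), "cannot slow")
  expect_error(tstRate(10, sigma = 0), "sigma")
  expect_error(tstRate(10, temperature = -1), "positive")
})

test_that("Wigner correction matches its closed form and classical limit", {
  expect_equal(wignerKappa(1500), 3.18, tolerance = 0.01 / 3.18)
  expect_equal(wignerKappa(1e-6), 1, tolerance = 1e-10)
  expect_gt(wignerKappa(1500, 200), wignerKappa(1500, 400))  # colder tunnels more
})

test_that("Eckart transmission agrees with a numeric Schroedinger solve", {
  w2k <- physicalConstants()$wavenumber_to_kcal
  cases <- list(c(8, 8, 1.0), c(10, 4, 0.8), c(6, 12, 1.2))
  for (cs in cases) {
    V1 <- cs[1]; V2 <- cs[2]; L <- cs[3]
    for (Efrac in c(0.6, 0.9, 1.1)) {
      E <- max(V1, V1 - V2 + 0.5) * Efrac
      if (E <= max(0, V1 - V2)) next
      ode <- odeEckart(V1, V2, L, E)
      P <- eckartTransmission(E, V1, V2, nu_cm = ode$hnu / w2k)
      expect_equal(P, ode$P, tolerance = 1e-4)
    }
  }
})

test_that("Eckart ZCT kappa matches dense-quadrature oracle on random barriers", {
  set.seed(11)
  for (i in 1:12) {
    V1 <- runif(1, 4, 18); V2 <- runif(1, 4, 18); nu <- runif(1, 600, 2200)
    expect_equal(eckartKappa(V1, V2, nu), trapKappa(V1, V2, nu),
                 tolerance = 1e-3)
  }
  # symmetric barrier case specifically
  expect_equal(eckartKappa(10, 10, 1500), trapKappa(10, 10, 1500),
               tolerance = 1e-3)
})

test_that("tunneling corrections stay above one and die off classically", {
  expect_gte(eckartKappa(12, 12, 1800), 1)
  expect_equal(eckartKappa(12, 12, 5), 1, tolerance = 1e-3)
  expect_equal(tunnelingKappa("none"), 1)
  expect_equal(tunnelingKappa("wigner", nu_cm = 1500), wignerKappa(1500))
  # hotter means more classical
  expect_gt(eckartKappa(12, 12, 1500, 250), eckartKappa(12, 12, 1500, 600))
  expect_error(tunnelingKappa("eckart_zct", 10, 1500, NA), "reverse barrier")
  expect_error(tunnelingKappa("wigner", 10, -5), "wavenumber")
})

test_that("Marcus barrier has its symmetric and activationless points", {
  expect_equal(marcusBarrier(0, 40), 10)          # lambda / 4
  expect_equal(marcusBarrier(-40, 40), 0)         # dG = -lambda
  expect_equal(marcusBarrier(10, 40), 15.625)
  expect_error(marcusBarrier(10, -1), "positive")
})

test_that("Stokes-Einstein and Smoluchowski reproduce reference magnitudes", {
  D <- diffusionCoefficient(298.15, 8.91e-4, 2e-10)
  expect_equal(D, 1.23e-9, tolerance = 0.01)
  expect_equal(diffusionCoefficient(298.15, 2 * 8.91e-4, 2e-10), D / 2)
  expect_equal(diffusionCoefficient(298.15, 8.91e-4, 4e-10), D / 2)
  kD <- smoluchowskiRate(4e-10, 2.45e-9)
  expect_equal(kD, 7.42e9, tolerance = 0.01)
  expect_equal(smoluchowskiRate(8e-10, 2.45e-9), 2 * kD)
  expect_equal(smoluchowskiRate(4e-10, 4.9e-9), 2 * kD)
  # a typical solute pair in water sits in the diffusion-limited decade
  Dpair <- diffusionCoefficient(298.15, 8.91e-4, 3.5e-10) +
    diffusionCoefficient(298.15, 8.91e-4, 2.0e-10)
  kTyp <- smoluchowskiRate(5.5e-10, Dpair)
  expect_gt(kTyp, 1e9); expect_lt(kTyp, 1e10)
  expect_error(diffusionCoefficient(298.15, 8.91e-4, -1), "positive")
  expect_error(smoluchowskiRate(0, 1e-9), "positive")
})

test_that("Collins-Kimball interpolation has the right limits", {
  expect_equal(apparentRate(1e5, 1e9), 1e5, tolerance = 1e-4)
  expect_equal(apparentRate(Inf, 8e9), 8e9)
  expect_equal(apparentRate(5e9, 5e9), 2.5e9)
  expect_error(apparentRate(0, 0), "undefined")
  # monotone in k_act and bounded by k_D
  ks <- apparentRate(10^seq(3, 14), 7.9e9)
  expect_true(all(diff(ks) > 0))
  expect_true(all(ks <= 7.9e9))
})

test_that("species totals reproduce the tabulated per-channel sums", {
  rates <- curatedDcafData("channel_rates")
  d82w <- rates[rates$compound == "dCAF-82" & rates$solvent == "water" &
                  rates$species == "neutral", ]
  expect_equal(signif(speciesTotalRate(d82w$k), 3), 6.12e5)
  d2pe <- rates[rates$compound == "dCAF-2" & rates$solvent == "pentylethanoate" &
                  rates$species == "neutral", ]
  expect_equal(signif(speciesTotalRate(d2pe$k), 3), 3.65e3)
  expect_equal(speciesTotalRate(42), 42)
  mixed <- data.frame(species = c("neutral", "mono-anion"), k_app = c(1, 2))
  expect_error(speciesTotalRate(mixed), "mixed species")
})

test_that("global coefficients are molar-fraction-weighted totals", {
  f2 <- speciationFractions(dcafAcidBaseSystems()[["dCAF-2"]], 7.4)
  rates <- curatedDcafData("channel_rates")
  tot <- function(cmp) {
    t <- rates[rates$compound == cmp & rates$solvent == "water", ]
    sapply(split(t$k, t$species), sum)
  }
  k2 <- globalRate(tot("dCAF-2"), setNames(f2$fraction, f2$species))
  expect_equal(k2, 1.76e9, tolerance = 0.02)
  f16 <- speciationFractions(dcafAcidBaseSystems()[["dCAF-16"]], 7.4)
  k16 <- globalRate(tot("dCAF-16"), setNames(f16$fraction, f16$species))
  expect_equal(k16, 3.19e9, tolerance = 0.02)
  expect_equal(globalRate(c(neutral = 5e4), c(neutral = 1)), 5e4)
  expect_error(globalRate(c(neutral = 1, `mono-anion` = 2), c(neutral = 1)),
               "mono-anion")
  # the weighted mean lies between the per-species extremes
  tt <- tot("dCAF-16")
  expect_gte(k16, min(tt)); expect_lte(k16, max(tt))
})

test_that("rate assembly round-trips the synthetic generator's ground truth", {
  gen <- makeChannelTable(seed = 5)
  rep <- suppressMessages(assembleRates(gen$channels, speciation = gen$speciation))
  ch <- channelRates(rep)
  truth <- gen$truth$channels
  key <- function(d) paste(d$species, d$solvent, d$mechanism, d$site)
  m <- match(key(ch), key(truth))
  expect_false(anyNA(m))
  expect_equal(ch$k_app, truth$k_app[m], tolerance = 1e-10)
  tt <- speciesTotals(rep); tg <- gen$truth$totals
  m2 <- match(paste(tt$species, tt$solvent), paste(tg$species, tg$solvent))
  expect_equal(tt$k_total, tg$k_total[m2], tolerance = 1e-10)
  gg <- globalRates(rep); gt <- gen$truth$global
  m3 <- match(gg$solvent, gt$solvent)
  expect_equal(gg$k_global, gt$k_global[m3], tolerance = 1e-10)
  # every RAF channel was drawn endergonic, so none survives the filter
  expect_false(any(ch$mechanism == "RAF"))
  expect_true(all(excludedChannels(rep)$reason %in%
                    c("endergonic", "barrier unavailable")))
  # the barrier-less di-anion channel is diffusion-controlled
  bl <- ch[ch$barrierless, ]
  expect_true(all(bl$diffusion_limited))
  expect_equal(bl$k_app, bl$k_D)
  # k_app never exceeds either control regime
  expect_true(all(ch$k_app <= pmin(ch$k_act * (1 + 1e-12), ch$k_D)))
})

test_that("an all-endergonic table leaves an empty rate report", {
  gen <- makeChannelTable(nSitesHAT = 0, barrierless = FALSE, seed = 9)
  raf <- gen$channels[gen$channels$mechanism == "RAF", ]
  rep <- suppressMessages(assembleRates(raf))
  expect_equal(nrow(channelRates(rep)), 0L)
  expect_equal(nrow(speciesTotals(rep)), 0L)
  # with the filter off they all come back
  rep2 <- assembleRates(raf, feasibilityFilter = FALSE)
  expect_equal(nrow(channelRates(rep2)), nrow(raf))
})
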