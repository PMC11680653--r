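test_that("two inequivalent sites with one substituent give four derivatives", {
  sc <- inequivalentScaffold()
  d <- enumerateDerivatives(sc)
  expect_equal(nrow(d), 4L)
  expect_setequal(paste(d$R1, d$R2), c("H H", "H F", "F H", "F F"))
  expect_false(anyDuplicated(d$smiles) > 0)
})

test_that("empty library yields exactly the parent compound", {
  sc <- scaffoldSpec("Oc1ccc({R1})cc1{R2}", c("R1", "R2"))
  d <- enumerateDerivatives(sc)
  expect_equal(nrow(d), 1L)
  expect_equal(d$R1, "H")
  expect_equal(d$smiles, canonicalSmiles("Oc1ccccc1"), ignore_attr = TRUE)
})

test_that("raw pattern space has (|library|+1)^sites entries", {
  caf <- caffeicAcidScaffold()
  raw <- enumerateDerivatives(caf, canonicalize = FALSE)
  expect_equal(nrow(raw), (7 + 1)^5)
  one <- enumerateDerivatives(caf, maxSubstitutions = 1)
  expect_equal(nrow(one), 1 + 5 * 7)  # parent + each group at each site
})

test_that("enumeration is deterministic and dedups equivalent placements", {
  sc <- inequivalentScaffold()
  expect_identical(enumerateDerivatives(sc), enumerateDerivatives(sc))
  # benzene para-substitution: the two sites are equivalent, so H/F and F/H
  # collapse onto one canonical structure
  eq <- scaffoldSpec("c1ccc({R1})cc1{R2}", c("R1", "R2"),
                     data.frame(name = "F", smiles = "[*]F"))
  expect_equal(nrow(enumerateDerivatives(eq)), 3L)
})

test_that("pattern filter hook and maxSubstitutions restrict the cohort", {
  sc <- inequivalentScaffold()
  expect_equal(nrow(enumerateDerivatives(sc, maxSubstitutions = 0)), 1L)
  noR2 <- enumerateDerivatives(sc, patternFilter = function(p) p[["R2"]] == "H")
  expect_equal(nrow(noR2), 2L)
  expect_true(all(noR2$R2 == "H"))
})

test_that("invalid fragments and cores are rejected with informative errors", {
  expect_error(scaffoldSpec("Oc1ccc({R1})cc1", "R1",
                            data.frame(name = "bad", smiles = "F")),
               "attachment")
  expect_error(scaffoldSpec("Oc1ccc({R1})cc1", "R1",
                            data.frame(name = "two", smiles = "[*]C[*]")),
               "exactly one")
  expect_error(scaffoldSpec("Oc1ccc(cc1", "R1"), "token|parsable")
  expect_error(canonicalSmiles("C1CC"), "unparsable")
})

test_that("descriptors match known molecular values", {
  d <- computeDescriptors(c(caffeic = "OC(=O)C=Cc1cc(O)c(O)cc1",
                            methane = "C"))
  expect_equal(d$MW[1], 180.16, tolerance = 1e-3)
  expect_equal(d$AtX[1], 13L)
  expect_equal(d$HBD[1], 3L)
  expect_equal(d$HBA[1], 4L)
  # methane: no heteroatoms, no rotors
  expect_equal(d$HBD[2], 0L)
  expect_equal(d$HBA[2], 0L)
  expect_equal(d$RB[2], 0L)
  expect_error(computeDescriptors("C1CC"), "unparsable")
})

test_that("rule boundaries are inclusive and aggregate is a conjunction", {
  base <- data.frame(MW = 300, logP = 2, HBD = 2, HBA = 5, MR = 80,
                     AtX = 30, RB = 4, PSA = 80)
  r <- checkDruglikeness(base)
  expect_true(r$lipinski_pass && r$ghose_pass && r$veber_pass)
  # HBD exactly 5 still passes the rule of five
  r5 <- checkDruglikeness(transform(base, HBD = 5))
  expect_true(r5$lipinski_pass)
  # the lower Ghose boundary passes exactly
  gl <- checkDruglikeness(data.frame(MW = 160, logP = -0.4, HBD = 2, HBA = 5,
                                     MR = 40, AtX = 20, RB = 4, PSA = 80))
  expect_true(gl$ghose_pass)
  # a single violation fails only its own criterion
  mw <- checkDruglikeness(transform(base, MW = 600))
  expect_false(mw$lipinski_pass)
  expect_false(mw$lipinski_MW)
  expect_true(mw$lipinski_logP && mw$lipinski_HBD && mw$lipinski_HBA)
  expect_false(mw$ghose_pass)   # 600 also breaks the Ghose MW window
  expect_true(mw$veber_pass)
})

test_that("flipping one compliant value past its bound flips one criterion", {
  base <- data.frame(MW = 300, logP = 2, HBD = 2, HBA = 5, MR = 80,
                     AtX = 30, RB = 4, PSA = 80)
  r0 <- checkDruglikeness(base)
  flips <- list(logP = 5.7, HBA = 11, RB = 11, PSA = 141)
  for (prop in names(flips)) {
    d <- base; d[[prop]] <- flips[[prop]]
    r1 <- checkDruglikeness(d)
    crit <- grep(paste0("_", prop, "$"), names(r0), value = TRUE)
    changed <- names(r0)[unlist(r0) != unlist(r1)]
    expect_setequal(setdiff(changed, grep("_pass$", changed, value = TRUE)),
                    crit)
  }
})

test_that("incomplete descriptor records are rejected, never silently passed", {
  expect_error(checkDruglikeness(data.frame(MW = 300)), "incomplete")
  expect_error(checkDruglikeness(data.frame(MW = 300, logP = NA, HBD = 2,
                                            HBA = 5, MR = 80, AtX = 30,
                                            RB = 4, PSA = 80)),
               "incomplete")
})
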