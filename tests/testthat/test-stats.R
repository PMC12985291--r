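# Detection-rate aggregation, z-test, abstention rule, tallies.

test_that("detection rates aggregate Successful and Partial numerators", {
  t1 <- loadFixture("table1")
  expect_equal(nrow(t1), 18L)
  expect_equal(sum(t1$n_parcels), 48L)
  at2 <- detectionRate(t1, "AT.2")
  expect_equal(at2$detected, 10L); expect_equal(at2$percent, 20.83)
  at3 <- detectionRate(t1, "AT.3")
  expect_equal(at3$detected, 27L); expect_equal(at3$percent, 56.25)
  single <- data.frame(consignment = 1, n_parcels = 5, at2_detected = 0)
  expect_equal(detectionRate(single, "AT.2")$percent, 0)
  expect_error(detectionRate(t1, "AT.9"), "unknown algorithm")
})

test_that("consignment outcomes round-trip the fixture's detected counts", {
  t1 <- loadFixture("table1")
  expect_equal(vapply(seq_len(nrow(t1)), function(i)
    consignmentOutcome(t1$at3_detected[i], t1$n_parcels[i]), ""),
    t1$at3_outcome)
  expect_equal(vapply(seq_len(nrow(t1)), function(i)
    consignmentOutcome(t1$at2_detected[i], t1$n_parcels[i]), ""),
    t1$at2_outcome)
  expect_identical(consignmentOutcome(5, 5), "Successful")
  expect_identical(consignmentOutcome(0, 3), "Failed")
  expect_identical(consignmentOutcome(2, 4), "Partial")
})

test_that("z-test matches its closed form, prop.test and antisymmetry", {
  r <- twoProportionZTest(10, 48, 27, 48)
  expect_equal(signif(pValue(r), 2), 1.8e-4)
  # cross-check against the chi-square test without continuity correction
  pt <- prop.test(c(10, 27), c(48, 48), correct = FALSE)
  expect_equal(zStatistic(r)^2, unname(pt$statistic), tolerance = 1e-12)
  # equal proportions: z = 0, p = 0.5
  r0 <- twoProportionZTest(5, 10, 5, 10)
  expect_equal(zStatistic(r0), 0)
  expect_equal(pValue(r0), 0.5)
  # antisymmetry and one-tailed complementarity
  a <- twoProportionZTest(7, 30, 15, 33)
  b <- twoProportionZTest(15, 33, 7, 30)
  expect_equal(zStatistic(a), -zStatistic(b))
  expect_equal(pValue(a) + pValue(b), 1)
  expect_error(twoProportionZTest(0, 10, 0, 10), "degenerate")
})

test_that("extreme z-test agrees with a permutation oracle", {
  r <- twoProportionZTest(0, 10, 10, 10)
  set.seed(1)
  nPerm <- 1e6
  # permuting 10 successes over 20 subjects: x2 ~ hypergeometric
  x2 <- rhyper(nPerm, 10, 10, 10)
  pPerm <- mean(x2 - (10 - x2) >= 10)   # diff as extreme as observed
  mcSd <- sqrt(pPerm * (1 - pPerm) / nPerm)
  expect_lt(abs(pValue(r) - pPerm), 3 * mcSd)
})

test_that("abstention rule follows threshold and band overlap", {
  expect_identical(applyUndeterminedRule(rep(0.90, 100) + seq(-.01, .01, length.out = 100)),
                   "wild")
  expect_identical(applyUndeterminedRule(ensembleProbsFor(0.60, 0.05)),
                   "undetermined")   # below the 65% threshold
  expect_identical(applyUndeterminedRule(c(rep(0.36, 5), rep(0.96, 5))),
                   "undetermined")   # mean 0.66 but the +/-SD bands overlap
  expect_identical(applyUndeterminedRule(ensembleProbsFor(0.18, 0.06)),
                   "captive")
  expect_error(applyUndeterminedRule(0.9), "2 ensemble")
  # symmetry under wild <-> captive relabelling
  for (m in c(0.2, 0.55, 0.8)) for (s in c(0.05, 0.1)) {
    p <- ensembleProbsFor(m, s)
    lab <- applyUndeterminedRule(p)
    flip <- applyUndeterminedRule(1 - p)
    expect_identical(flip, switch(lab, wild = "captive", captive = "wild",
                                  undetermined = "undetermined"))
  }
})

test_that("provenance summary truncates percentages and reproduces Table 2", {
  calls <- loadFixture("table2_calls")
  s <- provenanceSummary(calls)
  sc <- s[s$species == "T. scincoides", ]
  expect_equal(sc$percent[match(c("wild", "captive", "undetermined"), sc$label)],
               c(10, 50, 40))
  ru <- s[s$species == "T. rugosa", ]
  expect_equal(ru$percent[match(c("wild", "captive", "undetermined"), ru$label)],
               c(26, 34, 39))
  # counts sum to n; truncation bound < 1 point
  expect_true(all(tapply(s$count, s$species, sum) == tapply(s$n, s$species, unique)))
  expect_true(all(s$percent <= 100 &
                    (100 * s$count / s$n) - s$percent < 1))
  one <- data.frame(species = "x", label = rep("wild", 3))
  expect_equal(provenanceSummary(one)$percent, c(100, 0, 0))
})

test_that("seizure summary tallies the register as given", {
  reg <- loadFixture("seizures")
  s <- seizureSummary(reg)
  expect_equal(names(s$speciesCounts)[1], "Tiliqua rugosa")
  expect_equal(unname(s$speciesCounts[1]), 40L)
  expect_equal(s$nConsignments, 18L)
  constructed <- data.frame(specimen_id = 1:100, species = "x",
                            consignment = 1,
                            outcome = rep(c("rehomed", "euthanized"),
                                          c(83, 17)))
  sc <- seizureSummary(constructed)
  expect_equal(unname(sc$outcomePercent[c("rehomed", "euthanized")]), c(83, 17))
  empty <- seizureSummary(data.frame())
  expect_equal(empty$nAnimals, 0L)
})
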