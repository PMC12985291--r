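# Spectrum model, attenuation, kerma and the dosimetry chain.

test_that("spectrum respects energy conservation and linearity", {
  s10 <- modelSpectrum(beamSpec(10, 78.03, NA, 0, 20))
  expect_true(all(fluence(s10)[energyGrid(s10) > 10] == 0))
  sA <- modelSpectrum(beamSpec(40, 60, NA, 0, 10))
  sB <- modelSpectrum(beamSpec(40, 120, NA, 0, 10))
  expect_equal(fluence(sB), 2 * fluence(sA))
  sC <- modelSpectrum(beamSpec(40, 60, NA, 0, 20))
  expect_equal(fluence(sC), 2 * fluence(sA))
  expect_error(modelSpectrum(beamSpec(50, 60, "Xx", 1, 20)), "filter")
})

test_that("filtered/unfiltered fluence ratio matches single-energy Beer-Lambert", {
  unf <- modelSpectrum(beamSpec(50, 60.8, NA, 0, 20))
  fil <- modelSpectrum(beamSpec(50, 60.8, "Cu", 0.35, 20))
  i20 <- which.min(abs(energyGrid(unf) - 20))
  e20 <- energyGrid(unf)[i20]
  muCu <- massAttenuation(materialComposition(c(Cu = 1), 8.96, 0.35), e20)
  expect_equal(fluence(fil)[i20] / fluence(unf)[i20],
               exp(-muCu * 8.96 * 0.035), tolerance = 1e-12)
})

test_that("mixture rule reduces to the element and mass fractions sum to 1", {
  mf <- massFractions(keratinLayer())
  expect_equal(sum(mf), 1, tolerance = 1e-6)
  expect_equal(unname(round(mf[c("C", "H", "N", "O", "S")], 3)),
               c(0.406, 0.072, 0.140, 0.341, 0.040), tolerance = 2e-3)
  # pure-element material equals the element's own table values
  al <- materialComposition(c(Al = 1), 2.699, 1)
  for (e in c(10, 20, 40)) {
    cu2 <- materialComposition(c(Al = 2), 2.699, 1)  # counts cancel
    expect_equal(massAttenuation(al, e), massAttenuation(cu2, e))
  }
  # keratin coefficient decreases with energy below any edge
  mus <- massAttenuation(keratinLayer(), c(10, 15, 20, 30, 40))
  expect_true(all(diff(mus) < 0))
  expect_error(massAttenuation(materialComposition(c(U = 1), 19, 1), 20),
               "element")
  expect_error(massAttenuation(keratinLayer(), 2000), "range")
})

test_that("transmit obeys identity, closed form and monotonicity", {
  s <- modelSpectrum(beamSpec(40, 60.75, "Al", 2, 20))
  t0 <- transmit(s, keratinLayer(thickness = 0))
  expect_equal(t0$fluxFraction, 1)
  expect_equal(fluence(t0$spectrum), fluence(s))

  # monoenergetic spectrum: fraction equals the hand Beer-Lambert value
  mono <- new("XraySpectrum", energy = 20, fluence = 1000)
  tk <- transmit(mono, keratinLayer())
  expect_equal(tk$fluxFraction,
               exp(-massAttenuation(keratinLayer(), 20) * 1.32 * 0.05),
               tolerance = 1e-12)
  expect_equal(tk$doseFraction, tk$fluxFraction, tolerance = 1e-12)

  # decreasing in thickness and density
  fr <- vapply(c(0.1, 0.5, 1, 2), function(th)
    transmit(s, keratinLayer(thickness = th))$doseFraction, numeric(1))
  expect_true(all(diff(fr) < 0))
  dense <- materialComposition(c(C = 27, H = 57, N = 8, O = 17, S = 1),
                               density = 2.64, thickness = 0.5)
  expect_lt(transmit(s, dense)$doseFraction,
            transmit(s, keratinLayer())$doseFraction)
  expect_error(transmit(s, keratinLayer(thickness = -1)), "thickness|>= 0")
})

test_that("air kerma is zero on empty spectra, additive, and matches the
           single-energy closed form", {
  z <- new("XraySpectrum", energy = c(10, 20), fluence = c(0, 0))
  expect_equal(airKerma(z), 0)
  a <- modelSpectrum(beamSpec(40, 60, NA, 0, 10))
  b <- modelSpectrum(beamSpec(40, 30, NA, 0, 10))
  ab <- new("XraySpectrum", energy = energyGrid(a),
            fluence = fluence(a) + fluence(b))
  expect_equal(airKerma(ab), airKerma(a) + airKerma(b))
  mono <- new("XraySpectrum", energy = 30, fluence = 5)
  muen30 <- wildtrace:::.muEn("air", 30)
  expect_equal(airKerma(mono), 5 * 30 * muen30)
})

test_that("spectrum integrals are stable under grid refinement", {
  coarse <- softTissueDose(geoChemProtocol(), grid = 0.5)
  fine <- softTissueDose(geoChemProtocol(), grid = 0.05)
  expect_lt(abs(coarse@transmittedFraction - fine@transmittedFraction) /
              fine@transmittedFraction, 0.005)
})

test_that("the dosimetry chain honours its normalisation contracts", {
  res <- softTissueDose(geoChemProtocol())
  expect_equal(res@surfaceKerma, 227)
  expect_equal(softTissueDoseMgy(res), 227 * res@transmittedFraction)
  # vanishing-attenuation limit: the fraction reduces to the water/air
  # energy-absorption coefficient ratio (~1.04), i.e. 1 up to that ratio
  thin <- softTissueDose(geoChemProtocol(), keratin = keratinLayer(0),
                         softTissue = waterLayer(1e-6))
  expect_equal(thin@transmittedFraction, 1, tolerance = 0.05)
  expect_equal(thin@keratinFluxFraction, 1)
  # doubling all durations leaves the normalised dose unchanged
  doubled <- lapply(geoChemProtocol(), function(b) {
    b@duration <- b@duration * 2; b
  })
  expect_equal(softTissueDoseMgy(softTissueDose(doubled)),
               softTissueDoseMgy(res), tolerance = 1e-12)
  expect_error(softTissueDose(list()), "empty")
})

test_that("irradiated fraction computes honestly from geometry", {
  expect_equal(irradiatedFraction(geometrySpec()), 0.1125)   # 4500/40000
  full <- geometrySpec(c(100, 20, 20), c(20, 20), 20)
  expect_equal(irradiatedFraction(full) * 5, 1.0)   # full cross-section = 1/5 length
  expect_equal(irradiatedFraction(geometrySpec(irradiatedDepth = 10)),
               0.1125 / 2)
  expect_error(geometrySpec(beamFootprint = c(25, 25)), "exceeds")
  expect_identical(PAPER_F_IRR, 0.045)
})

test_that("effective and combined dose are exact arithmetic", {
  expect_equal(wildtrace:::roundHalfUp(effectiveDose(71, 0.045), 1), 3.2)
  expect_equal(effectiveDose(71, 0.045), 3.195)
  expect_equal(effectiveDose(12.3, 1.0), 12.3)
  expect_equal(effectiveDose(0, 0.5), 0)
  # invariant to splitting f into footprint x depth factors
  expect_equal(effectiveDose(effectiveDose(71, 0.5), 0.09),
               effectiveDose(71, 0.045))
  expect_error(effectiveDose(71, 1.5), "f must")
  expect_equal(combinedExposure(5, 3.2), 8.2)
  expect_equal(combinedExposure(0, 3.2), 3.2)
  expect_equal(combinedExposure(5, 0), 5)
})

test_that("slice exposure arithmetic is exact", {
  expect_equal(sliceExposureTime(2, 0.5), 4)
  expect_equal(sliceExposureTime(1, 1), 1)
  expect_equal(sliceExposureTime(4, 0.5), 8)
  expect_error(sliceExposureTime(0, 1), "> 0")
})

test_that("scintillator summary excludes controls and handles missing cells", {
  s <- summarizeScintillator(loadFixture("table3"))
  surf <- s[s$depth == "surface", ]
  expect_equal(surf$n, 4L)
  expect_equal(surf$mean_uSv, mean(c(189.4, 175.1, 174, 250.5)))
  expect_equal(surf$mean_mSv_reported, 0.2)
  deep <- s[s$depth == "depth10mm", ]
  expect_equal(deep$n, 3L)   # the missing cell is excluded
  expect_equal(deep$mean_mSv_reported, 0.2)
  one <- data.frame(treatment = c("Control", "Specimen 1"),
                    surface_uSv = c(999, 42))
  expect_equal(summarizeScintillator(one)$mean_uSv, 42)
  allNA <- data.frame(treatment = "Specimen 1", surface_uSv = NA_real_)
  expect_error(summarizeScintillator(allNA), "missing")
})
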