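# Synthetic phantom, provenance-table and scintillator generators.

test_that("empty parcel is constant background with empty mask", {
  lv <- makeParcel(phantomSpec(gridShape = 32L, animalClass = "none",
                               clutterCount = 0L, noiseSd = 0, seed = 1))
  expect_equal(length(unique(as.numeric(intensities(lv)))), 1L)
  expect_false(any(truthMask(lv)))
  expect_identical(animalLabel(lv), "none")
})

test_that("parcel generation is deterministic for a fixed seed", {
  sp <- phantomSpec(gridShape = 48L, animalClass = "lizard", animalScale = 55,
                    clutterCount = 3L, seed = 99)
  a <- makeParcel(sp); b <- makeParcel(sp)
  expect_identical(intensities(a), intensities(b))
  expect_identical(truthMask(a), truthMask(b))
  c <- makeParcel(phantomSpec(gridShape = 48L, animalClass = "lizard",
                              animalScale = 55, clutterCount = 3L, seed = 100))
  expect_false(identical(intensities(a), intensities(c)))
})

test_that("lizard mask volume is within 20% of the analytic body+tail volume", {
  for (seed in 1:5) {
    sp <- phantomSpec(gridShape = 96L, animalClass = "lizard",
                      animalScale = 120, clutterCount = 0L, noiseSd = 0,
                      seed = seed)
    lv <- makeParcel(sp)
    vox <- sum(truthMask(lv)) * prod(spacing(lv))
    expect_lt(abs(vox - analyticAnimalVolume("lizard", 120)) /
                analyticAnimalVolume("lizard", 120), 0.20)
  }
})

test_that("animal voxels lie inside the organic range before noise", {
  for (cls in c("lizard", "fish", "bird")) {
    sp <- phantomSpec(gridShape = 64L, animalClass = cls, animalScale = 80,
                      clutterCount = 4L, noiseSd = 0, seed = 7)
    lv <- makeParcel(sp)
    vals <- intensities(lv)[truthMask(lv)]
    expect_true(all(vals >= 900 & vals <= 1400))
  }
})

test_that("oversized animals are rejected with the axis named", {
  expect_error(
    makeParcel(phantomSpec(gridShape = 32L, animalClass = "lizard",
                           animalScale = 500, seed = 1)),
    "axis [xyz]")
})

test_that("corpus class counts follow the requested proportions", {
  tmpl <- phantomSpec(gridShape = 32L, animalScale = 36, clutterCount = 0L)
  corpus <- makeCorpus(10, c(lizard = 0.5, none = 0.5), tmpl, seed = 5)
  counts <- table(vapply(corpus, animalLabel, ""))
  expect_equal(as.integer(counts[c("lizard", "none")]), c(5L, 5L))

  corpus <- makeCorpus(10, c(lizard = 0.4, fish = 0.3, bird = 0.3), tmpl,
                       seed = 6)
  counts <- table(vapply(corpus, animalLabel, ""))
  expect_equal(as.integer(counts[c("lizard", "fish", "bird")]), c(4L, 3L, 3L))
  expect_error(makeCorpus(0, c(lizard = 1), tmpl), "positive")
})

test_that("provenance table carries a class effect only when asked", {
  tab <- makeProvenanceTable(60, nElements = 8, classEffect = 3, seed = 2)
  el <- tab$features[[tab$informative[1]]]
  expect_gt(mean(el[tab$origin == "wild"]), mean(el[tab$origin == "captive"]))
  # large effect: a linear classifier on informative elements separates well
  df <- data.frame(y = as.integer(tab$origin == "wild"),
                   log(tab$features[tab$informative] + 1e-9))
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial))
  acc <- mean((fitted(fit) > 0.5) == df$y)
  expect_gt(acc, 0.95)
  expect_error(makeProvenanceTable(10, classEffect = -1), "non-negative")
  expect_error(makeProvenanceTable(0), "positive")
})

test_that("null provenance table shows no class signal in most seeds", {
  hits <- 0L
  for (seed in 1:20) {
    tab <- makeProvenanceTable(40, nElements = 4, classEffect = 0, seed = seed)
    p <- wilcox.test(tab$features$el01 ~ tab$origin, exact = FALSE)$p.value
    hits <- hits + (p < 0.05)
  }
  expect_lte(hits, 2L)   # ~alpha = 0.05: >=90% of seeds show no signal
})

test_that("scintillator generator honours sd, truncation and missing rows", {
  r0 <- makeScintillatorReadings(5, 100, 0, seed = 1)
  expect_true(all(r0$reading_uSv == 100))
  r <- makeScintillatorReadings(4, 197, 30, seed = 3)
  expect_lt(abs(mean(r$reading_uSv) - 197), 3 * 30 / sqrt(4))
  rt <- makeScintillatorReadings(200, 5, 20, seed = 4)
  expect_true(all(rt$reading_uSv >= 0))
  rm <- makeScintillatorReadings(4, 197, 30, seed = 3, missing = 2)
  expect_true(is.na(rm$reading_uSv[2]))
  expect_error(makeScintillatorReadings(4, 197, -1), "sd")
})
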