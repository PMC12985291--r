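# Segmentation, morphological opening and connected-component labelling.

test_that("segmentation below the organic range yields an empty mask", {
  v <- ScanVolume(array(100, c(32, 32, 32)), 1)
  expect_false(any(segmentOrganic(v, c(900, 1400), openingRadius = 0)))
})

test_that("opening radius 0 is exactly the threshold mask", {
  set.seed(8)
  arr <- array(runif(20^3, 0, 2000), c(20, 20, 20))
  v <- ScanVolume(arr, 1)
  expect_identical(segmentOrganic(v, c(900, 1400), 0),
                   arr >= 900 & arr <= 1400)
})

test_that("opening removes a thin bridge but preserves the spheres", {
  d <- c(24, 24, 24)
  m <- sphereMask(d, c(7, 12, 12), 4) | sphereMask(d, c(17, 12, 12), 4)
  bridge <- array(FALSE, d); bridge[10:14, 12, 12] <- TRUE
  arr <- array(0, d); arr[m | bridge] <- 1000
  v <- ScanVolume(arr, 1)
  got <- segmentOrganic(v, c(900, 1400), openingRadius = 2)
  expect_identical(got, bruteOpening(m | bridge, 2))
  expect_length(labelComponents(got, minBlobVoxels = 10), 2L)
  expect_false(any(got[12, 12, 12]))   # bridge voxel gone
})

test_that("segmentation recovers at least 90% of a phantom's truth mask", {
  lv <- makeParcel(phantomSpec(gridShape = 96L, animalClass = "lizard",
                               animalScale = 120, clutterCount = 4L, seed = 5))
  mask <- segmentOrganic(scanVolume(lv), c(900, 1400), openingRadius = 1)
  recall <- sum(mask & truthMask(lv)) / sum(truthMask(lv))
  expect_gte(recall, 0.9)
})

test_that("two disjoint spheres give two blobs; single voxel kept at size 1", {
  d <- c(20, 20, 20)
  m <- sphereMask(d, c(6, 6, 6), 3) | sphereMask(d, c(15, 15, 15), 3)
  expect_length(labelComponents(m, minBlobVoxels = 5), 2L)
  s <- array(FALSE, c(8, 8, 8)); s[4, 4, 4] <- TRUE
  blobs <- labelComponents(s, minBlobVoxels = 1L)
  expect_length(blobs, 1L)
  expect_equal(voxelCount(blobs[[1]]), 1L)
  expect_length(labelComponents(array(FALSE, c(4, 4, 4))), 0L)
})

test_that("component labelling matches the flood-fill oracle on random masks", {
  set.seed(42)
  for (rep in 1:100) {
    d <- sample(6:16, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < runif(1, 0.1, 0.5), d)
    oracle <- floodFillLabels(mask)
    blobs <- labelComponents(mask, minBlobVoxels = 1L)
    # same number of components
    expect_equal(length(blobs), max(oracle))
    # identical partition: each blob's voxels carry exactly one oracle label
    seen <- integer(0)
    for (b in blobs) {
      labs <- unique(oracle[voxelCoords(b)])
      expect_length(labs, 1L)
      seen <- c(seen, labs)
    }
    expect_setequal(seen, seq_len(max(oracle)))
    # union of blobs = mask
    expect_equal(sum(vapply(blobs, voxelCount, integer(1))), sum(mask))
  }
})

test_that("connectivity 6 splits diagonal touches that 26 joins", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_length(labelComponents(m, minBlobVoxels = 1, connectivity = 26L), 1L)
  expect_length(labelComponents(m, minBlobVoxels = 1, connectivity = 6L), 2L)
})

test_that("blob features follow their closed-form values", {
  # uniform cube: sd 0, compactness 1, histogram mass in bin 1
  arr <- array(0, c(12, 12, 12)); arr[3:8, 3:8, 3:8] <- 1000
  v <- ScanVolume(arr, 1)
  b <- labelComponents(arr > 0, 1, minBlobVoxels = 1)[[1]]
  f <- blobFeatures(b, v)
  expect_equal(unname(f["sd"]), 0)
  expect_equal(unname(f["compactness"]), 1)
  expect_equal(unname(f["hist1"]), 1)
  expect_equal(unname(f["count"]), 216)

  # 1 x 1 x 10 rod at 1 mm: elongation 10
  arr <- array(0, c(4, 4, 14)); arr[2, 2, 3:12] <- 1000
  v <- ScanVolume(arr, 1)
  b <- labelComponents(arr > 0, 1, minBlobVoxels = 1)[[1]]
  f <- blobFeatures(b, v)
  expect_equal(unname(f["elongation"]), 10)
  expect_equal(unname(f["volume_mm3"]), 10)

  # histogram normalisation on arbitrary blobs
  set.seed(11)
  arr <- array(runif(10^3, 900, 1400), c(10, 10, 10))
  v <- ScanVolume(arr, 2)
  b <- labelComponents(array(TRUE, c(10, 10, 10)), 2, minBlobVoxels = 1)[[1]]
  f <- blobFeatures(b, v)
  expect_equal(sum(f[paste0("hist", 1:8)]), 1, tolerance = 1e-9)
  expect_equal(unname(f["volume_mm3"]), 1000 * 8)
})
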