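# MIP projection, embedding, and the two classifier families.

test_that("MIP of a single bright voxel peaks at that value on all axes", {
  arr <- array(0, c(16, 16, 16)); arr[5:11, 5:11, 5:11] <- 500
  arr[8, 8, 8] <- 1234
  v <- ScanVolume(arr, 1)
  b <- labelComponents(arr > 0, 1, minBlobVoxels = 1)[[1]]
  for (img in mipProject(v, b, resample = FALSE))
    expect_equal(max(img), 1234)
  # bilinear resampling may only smooth, never overshoot
  for (img in projections(mipProject(v, b)))
    expect_lte(max(img), 1234 + 1e-9)
})

test_that("MIP of a uniform cube is constant over the cube footprint", {
  arr <- array(0, c(20, 20, 20)); arr[5:12, 5:12, 5:12] <- 777
  v <- ScanVolume(arr, 1)
  b <- labelComponents(arr > 0, 1, minBlobVoxels = 1)[[1]]
  for (img in mipProject(v, b, resample = FALSE))
    expect_setequal(unique(as.numeric(img)), 777)   # bbox = cube: all 777
  for (img in projections(mipProject(v, b))) {
    expect_identical(dim(img), c(128L, 128L))
    expect_true(all(img >= 0 & img <= 777 + 1e-9))
    expect_equal(max(img), 777)   # interior samples keep the plateau value
  }
})

test_that("pre-resampling projections equal the nested-loop maxima", {
  set.seed(21)
  for (rep in 1:30) {
    d <- sample(5:12, 3, replace = TRUE)
    arr <- array(runif(prod(d), 900, 1400), d)
    mask <- array(runif(prod(d)) < 0.4, d)
    if (!any(mask)) next
    v <- ScanVolume(arr, 1)
    blobs <- labelComponents(mask, 1, minBlobVoxels = 1L)
    b <- blobs[[1]]
    raw <- mipProject(v, b, resample = FALSE)
    # the oracle works on the blob's masked bounding box
    bb <- boundingBox(b)
    sub <- arr[bb["min", 1]:bb["max", 1], bb["min", 2]:bb["max", 2],
               bb["min", 3]:bb["max", 3], drop = FALSE]
    inBlob <- array(FALSE, dim(sub))
    inBlob[sweep(voxelCoords(b), 2, bb["min", ] - 1L)] <- TRUE
    sub[!inBlob] <- 0
    for (ax in 1:3)
      expect_equal(raw[[ax]], as.matrix(bruteMip(sub, ax)))
  }
})

test_that("embedding is deterministic, 160-long and non-degenerate", {
  img <- matrix(runif(128 * 128), 128, 128)
  e1 <- embedProjection(img)
  e2 <- embedProjection(img)
  expect_identical(e1, e2)
  expect_length(e1, 160L)
  img2 <- img; img2[64, 64] <- img2[64, 64] + 1
  expect_false(identical(e1, embedProjection(img2)))
  expect_error(embedProjection(matrix(0, 64, 64)), "128")
})

test_that("AT.2 is deterministic, separable on toy data, and rejects bad input", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  colnames(x) <- c("a", "b")
  y <- rep(c("Lizard", "NotWildlife"), each = 20)
  m1 <- at2Train(x, y, nTrees = 50, seed = 9)
  m2 <- at2Train(x, y, nTrees = 50, seed = 9)
  p1 <- at2Classify(m1, x); p2 <- at2Classify(m2, x)
  expect_identical(p1, p2)
  pred <- colnames(p1)[max.col(p1)]
  expect_equal(mean(pred == y), 1)            # 100% training accuracy
  expect_true(all(abs(rowSums(p1) - 1) < 1e-9))
  expect_error(at2Train(x, rep("Lizard", 40)), "2 classes")
  expect_error(at2Classify(m1, c(a = 1)), "length")
})

test_that("AT.2 on shuffled labels stays near chance on held-out data", {
  set.seed(2)
  n <- 60
  x <- matrix(rnorm(n * 4), n)
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c("Lizard", "NotWildlife"), each = n / 2)
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    ys <- sample(y)
    tr <- sample(n, n / 2)
    m <- at2Train(x[tr, ], ys[tr], nTrees = 60, seed = s)
    p <- at2Classify(m, x[-tr, ])
    mean(colnames(p)[max.col(p)] == ys[-tr])
  }, numeric(1))
  # chance is 0.5; binomial sd for 30 held-out cases ~ 0.091
  expect_lt(abs(mean(accs) - 0.5), 3 * 0.091 / sqrt(20))
})

test_that("AT.3 enforces its architecture contract and learns separable data", {
  set.seed(4)
  x <- rbind(matrix(rnorm(60 * 480, 0), 60), matrix(rnorm(60 * 480, 0.6), 60))
  y <- rep(c("Lizard", "NotWildlife"), each = 60)
  expect_error(at3Train(x, y, layerSizes = c(64, 32)), "five")
  expect_error(at3Train(x[, 1:100], y), "480")
  tr <- c(1:45, 61:105)
  m <- at3Train(x[tr, ], y[tr], seed = 5, epochs = 60)
  expect_length(m@history, 60L)
  expect_lt(m@history[60], m@history[1])       # loss decreases
  p <- at3Classify(m, x[-tr, ])
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_gt(mean(colnames(p)[max.col(p)] == y[-tr]), 0.8)
  # determinism: identical final loss on a duplicate run
  m2 <- at3Train(x[tr, ], y[tr], seed = 5, epochs = 60)
  expect_identical(m@history, m2@history)
})

test_that("parcel decisions respect the threshold contract", {
  # volume with no organic content -> no blobs -> not detected
  v <- ScanVolume(array(100, c(32, 32, 32)), 2)
  set.seed(1)
  x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  colnames(x) <- c("a", "b")
  dummy <- at2Train(x, rep(c("Lizard", "NotWildlife"), each = 10), nTrees = 20)
  expect_false(isDetected(classifyParcel(v, dummy)))
  expect_error(classifyParcel(v, NULL), "model")
  expect_error(classifyParcel(v, dummy, threshold = 1.0 + 1e-9), "threshold")
})

test_that("parcel detection rate equals blob recall on single-blob parcels", {
  tmpl <- phantomSpec(gridShape = 64L, clutterCount = 0L)
  volumes <- lapply(1:8, function(i) {
    sp <- tmpl
    sp@animalClass <- c("lizard", "fish")[(i %% 2) + 1]
    sp@animalScale <- 80
    sp@seed <- i
    makeParcel(sp)
  })
  corpus <- buildBlobCorpus(volumes)
  expect_equal(nrow(corpus$features), 8L)   # single blob per parcel
  m <- at2Train(corpus$features, corpus$labels, nTrees = 100, seed = 1)
  decisions <- vapply(volumes, function(lv)
    isDetected(classifyParcel(scanVolume(lv), m, threshold = 0.5)), logical(1))
  p <- at2Classify(m, corpus$features)
  blobRecall <- mean(apply(p[, wildlifeClasses()], 1, max) >= 0.5)
  expect_equal(mean(decisions), blobRecall)
})
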