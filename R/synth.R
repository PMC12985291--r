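# Synthetic parcel phantoms, provenance tables and scintillator readings.
#
# The generators emulate the statistical structure the downstream stages
# assume (organic-intensity animal-shaped inclusions among clutter of varying
# radiodensity) -- not CT physics. Geometry is parametric and deliberately
# crude; class separability, not realism, is the contract.

.AXIS_LETTERS <- c("x", "y", "z")
.BACKGROUND <- 100

# local-frame animal silhouettes; U, V, W are mm coordinate arrays relative
# to the animal centre, U along the body axis
.animalMask <- function(class, S, U, V, W) {
  switch(class,
    lizard = {
      body <- (U / (0.30 * S))^2 + (V / (0.11 * S))^2 + (W / (0.09 * S))^2 <= 1
      # tapered tail: cone from the rear of the body
      inTail <- U >= 0.28 * S & U <= 0.75 * S
      rTail <- 0.06 * S * pmax(0, (0.75 * S - U)) / (0.47 * S)
      tail <- inTail & (V^2 + W^2 <= rTail^2)
      # four limb stubs: cylinders along +/- v at fore and hind body
      limb <- array(FALSE, dim(U))
      for (ul in c(-0.18, 0.18) * S) {
        cyl <- (U - ul)^2 + (W + 0.05 * S)^2 <= (0.03 * S)^2
        limb <- limb | (cyl & abs(V) >= 0.08 * S & abs(V) <= 0.20 * S)
      }
      body | tail | limb
    },
    fish = {
      (U / (0.50 * S))^2 + (V / (0.12 * S))^2 + (W / (0.20 * S))^2 <= 1
    },
    bird = {
      body <- (U / (0.28 * S))^2 + (V / (0.14 * S))^2 + (W / (0.16 * S))^2 <= 1
      neck <- U >= 0.20 * S & U <= 0.46 * S &
        (V^2 + (W - 0.08 * S)^2 <= (0.045 * S)^2)
      inBeak <- U >= 0.46 * S & U <= 0.56 * S
      rBeak <- 0.035 * S * pmax(0, (0.56 * S - U)) / (0.10 * S)
      beak <- inBeak & (V^2 + (W - 0.08 * S)^2 <= rBeak^2)
      body | neck | beak
    },
    stop("unknown animal class: ", class)
  )
}

# symmetric half-extents (mm) the silhouette needs along its local axes
.animalHalfExtents <- function(class, S) {
  switch(class,
    lizard = c(0.77, 0.22, 0.12) * S,
    fish   = c(0.51, 0.13, 0.21) * S,
    bird   = c(0.58, 0.16, 0.18) * S,
    stop("unknown animal class: ", class)
  )
}

#' Analytic animal phantom volume
#'
#' Closed-form volume (mm^3) of the main analytic components of each phantom
#' class (ellipsoid body plus tail cone for the lizard); limb stubs and the
#' bird's neck are excluded. Used as the oracle for voxelised mask volumes.
#'
#' @param class `"lizard"`, `"fish"` or `"bird"`.
#' @param scale Animal length in mm.
#' @return Volume in mm^3.
#' @examples
#' analyticAnimalVolume("lizard", 160)
#' @export
analyticAnimalVolume <- function(class, scale) {
  S <- scale
  switch(class,
    lizard = 4 / 3 * pi * 0.30 * 0.11 * 0.09 * S^3 +
      1 / 3 * pi * (0.06 * S)^2 * (0.47 * S),
    fish = 4 / 3 * pi * 0.50 * 0.12 * 0.20 * S^3,
    bird = 4 / 3 * pi * 0.28 * 0.14 * 0.16 * S^3,
    stop("unknown animal class: ", class)
  )
}

#' Generate one synthetic parcel volume
#'
#' Builds a labelled 3D radiodensity phantom: a constant background, an
#' optional animal-shaped inclusion whose noise-free intensity lies inside the
#' organic range, clutter objects (boxes, cylinders, thin high-density wires)
#' that never overwrite animal voxels, and additive Gaussian noise. Fully
#' deterministic for a fixed `seed`.
#'
#' @param spec A [PhantomSpec-class] object.
#' @return A [LabelledVolume-class] object.
#' @examples
#' lv <- makeParcel(phantomSpec(gridShape = 48L, animalClass = "lizard",
#'                              animalScale = 60, clutterCount = 2L, seed = 3))
#' animalLabel(lv)
#' @export
makeParcel <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@gridShape
  vs <- spec@voxelSize
  extent <- d * vs
  set.seed(spec@seed)

  vol <- array(.BACKGROUND, dim = d)
  mask <- array(FALSE, dim = d)

  # voxel-centre coordinates in mm
  cx <- (seq_len(d[1]) - 0.5) * vs[1]
  cy <- (seq_len(d[2]) - 0.5) * vs[2]
  cz <- (seq_len(d[3]) - 0.5) * vs[3]
  X <- array(cx, dim = d)
  Y <- array(rep(cy, each = d[1]), dim = d)
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)
  coordArrays <- list(X, Y, Z)

  if (spec@animalClass != "none") {
    S <- spec@animalScale
    half <- .animalHalfExtents(spec@animalClass, S)
    perm <- sample(3L)       # local axis u, v, w -> global axes
    flip <- sample(c(-1, 1), 3L, replace = TRUE)
    for (j in 1:3) {
      g <- perm[j]
      if (2 * half[j] + 2 * vs[g] > extent[g])
        stop(sprintf(
          "animal_scale %g mm exceeds the grid extent along axis %s (%g mm needed, %g mm available)",
          S, .AXIS_LETTERS[g], 2 * half[j] + 2 * vs[g], extent[g]))
    }
    ctr <- numeric(3)
    for (j in 1:3) {
      g <- perm[j]
      lo <- half[j] + vs[g]; hi <- extent[g] - half[j] - vs[g]
      jlo <- max(lo, 0.35 * extent[g]); jhi <- min(hi, 0.65 * extent[g])
      ctr[g] <- if (jlo <= jhi) stats::runif(1, jlo, jhi)
                else stats::runif(1, lo, hi)
    }
    U <- flip[1] * (coordArrays[[perm[1]]] - ctr[perm[1]])
    V <- flip[2] * (coordArrays[[perm[2]]] - ctr[perm[2]])
    W <- flip[3] * (coordArrays[[perm[3]]] - ctr[perm[3]])
    mask <- .animalMask(spec@animalClass, S, U, V, W)
    rng <- spec@organicRange
    level <- stats::runif(1, rng[1] + 0.15 * diff(rng), rng[2] - 0.15 * diff(rng))
    vol[mask] <- level
  }

  if (spec@clutterCount > 0L) {
    for (k in seq_len(spec@clutterCount)) {
      type <- sample(c("box", "cylinder", "wire"), 1L)
      rngIdx <- sample(length(spec@clutterRanges), 1L)
      rng <- spec@clutterRanges[[rngIdx]]
      level <- stats::runif(1, rng[1], rng[2])
      cc <- stats::runif(3, 0.15, 0.85) * extent
      obj <- switch(type,
        box = {
          hs <- stats::runif(3, 5, 25)
          abs(X - cc[1]) <= hs[1] & abs(Y - cc[2]) <= hs[2] &
            abs(Z - cc[3]) <= hs[3]
        },
        cylinder = {
          ax <- sample(3L, 1L)
          r <- stats::runif(1, 3, 10); len <- stats::runif(1, 20, 60)
          others <- setdiff(1:3, ax)
          A <- coordArrays[[others[1]]]; B <- coordArrays[[others[2]]]
          (A - cc[others[1]])^2 + (B - cc[others[2]])^2 <= r^2 &
            abs(coordArrays[[ax]] - cc[ax]) <= len / 2
        },
        wire = {
          ax <- sample(3L, 1L)
          r <- stats::runif(1, 1, 2.5); len <- stats::runif(1, 40, 100)
          others <- setdiff(1:3, ax)
          A <- coordArrays[[others[1]]]; B <- coordArrays[[others[2]]]
          (A - cc[others[1]])^2 + (B - cc[others[2]])^2 <= r^2 &
            abs(coordArrays[[ax]] - cc[ax]) <= len / 2
        })
      obj <- obj & !mask   # clutter never replaces animal voxels
      vol[obj] <- level
    }
  }

  if (spec@noiseSd > 0) {
    vol <- vol + stats::rnorm(length(vol), 0, spec@noiseSd)
    vol[vol < 0] <- 0
    vol[vol > 4095] <- 4095
  }

  new("LabelledVolume",
      volume = ScanVolume(vol, spec@voxelSize),
      truthMask = mask,
      label = if (any(mask)) spec@animalClass else "none")
}

#' Generate a corpus of labelled parcels
#'
#' Class counts follow `classMix` by largest-remainder apportionment (exact
#' when `n * proportion` is integral); per-item seeds are derived from the
#' master seed, and item order is a seeded shuffle of the class labels.
#'
#' @param n Number of parcels (> 0).
#' @param classMix Named numeric of class proportions summing to 1; names from
#'   `"lizard"`, `"fish"`, `"bird"`, `"none"`.
#' @param specTemplate [PhantomSpec-class] whose geometry/noise settings are
#'   reused for every parcel (class and seed are overridden).
#' @param seed Master integer seed.
#' @return List of [LabelledVolume-class] objects of length `n`.
#' @examples
#' corpus <- makeCorpus(4, c(lizard = 0.5, none = 0.5),
#'                      phantomSpec(gridShape = 48L, animalScale = 60,
#'                                  clutterCount = 1L), seed = 11)
#' table(vapply(corpus, animalLabel, ""))
#' @export
makeCorpus <- function(n, classMix, specTemplate = phantomSpec(), seed = 1L) {
  if (n <= 0) stop("n must be a positive integer")
  if (abs(sum(classMix) - 1) > 1e-8) stop("classMix proportions must sum to 1")
  if (is.null(names(classMix))) stop("classMix must be named")

  exact <- n * classMix
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  labels <- rep(names(classMix), times = counts)

  set.seed(seed)
  labels <- sample(labels)
  itemSeeds <- sample.int(.Machine$integer.max - 1L, n)

  lapply(seq_len(n), function(i) {
    sp <- specTemplate
    sp@animalClass <- labels[i]
    sp@seed <- itemSeeds[i]
    makeParcel(sp)
  })
}

#' Generate a synthetic elemental provenance table
#'
#' Per-class log-normal elemental concentrations (percent scale) for a panel
#' of elements; a stated subset of elements carries a wild-vs-captive class
#' shift of `classEffect` standard deviations on the log scale.
#'
#' @param nSpecimens Number of specimens (> 0); classes are balanced.
#' @param nElements Number of elements (>= 2); default 42.
#' @param classEffect Non-negative separation, in log-scale standard
#'   deviations, applied to the informative elements for wild specimens.
#' @param seed Integer seed.
#' @param nInformative Number of leading elements carrying the class effect.
#' @return List with `features` (data.frame, columns `el01`..), `origin`
#'   (factor wild/captive) and `informative` (column names carrying signal).
#' @examples
#' tab <- makeProvenanceTable(10, nElements = 6, classEffect = 2, seed = 1)
#' head(tab$features)
#' @export
makeProvenanceTable <- function(nSpecimens, nElements = 42L, classEffect = 1,
                                seed = 1L, nInformative = 6L) {
  if (nSpecimens <= 0) stop("nSpecimens must be positive")
  if (nElements < 2) stop("nElements must be >= 2")
  if (classEffect < 0) stop("classEffect must be non-negative")
  nInformative <- min(nInformative, nElements)
  set.seed(seed)

  origin <- factor(rep(c("wild", "captive"), length.out = nSpecimens),
                   levels = c("wild", "captive"))
  origin <- origin[sample(nSpecimens)]
  logMu <- stats::runif(nElements, log(0.01), log(5))   # percent scale
  logSd <- stats::runif(nElements, 0.3, 0.8)

  mat <- matrix(0, nSpecimens, nElements)
  for (e in seq_len(nElements)) {
    shift <- if (e <= nInformative) classEffect * logSd[e] else 0
    mu <- logMu[e] + ifelse(origin == "wild", shift, 0)
    mat[, e] <- exp(stats::rnorm(nSpecimens, mu, logSd[e]))
  }
  mat[mat < 0] <- 0
  cols <- sprintf("el%02d", seq_len(nElements))
  colnames(mat) <- cols
  list(features = as.data.frame(mat), origin = origin,
       informative = cols[seq_len(nInformative)])
}

#' Generate synthetic scintillator readings
#'
#' Gaussian readings truncated at 0 (rejection sampling), in microsievert,
#' with optional missing entries recorded as `NA`.
#'
#' @param n Number of specimen readings.
#' @param baselineUsv Mean reading in microsievert (>= 0).
#' @param sdUsv Standard deviation in microsievert (>= 0).
#' @param seed Integer seed.
#' @param missing Integer indices whose reading is missing (`NA`).
#' @return data.frame with columns `specimen` and `reading_uSv`.
#' @examples
#' makeScintillatorReadings(4, 197, 30, seed = 5)
#' @export
makeScintillatorReadings <- function(n, baselineUsv, sdUsv, seed = 1L,
                                     missing = integer(0)) {
  if (baselineUsv < 0) stop("baselineUsv must be >= 0")
  if (sdUsv < 0) stop("sdUsv must be >= 0")
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  r <- stats::rnorm(n, baselineUsv, sdUsv)
  while (any(r < 0)) {
    bad <- r < 0
    r[bad] <- stats::rnorm(sum(bad), baselineUsv, sdUsv)
  }
  if (sdUsv == 0) r <- rep(baselineUsv, n)
  r[missing] <- NA_real_
  data.frame(specimen = seq_len(n), reading_uSv = r)
}
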