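# Corpus harness: labelled blob tables and the AT.2-vs-AT.3 benchmark.

#' Build a labelled blob corpus from synthetic parcels
#'
#' Processes each labelled volume with the shared detection front end and
#' labels every surviving blob by overlap with the generator's truth mask: a
#' blob whose voxels are at least half truth voxels inherits the parcel's
#' animal class, everything else is `NotWildlife`.
#'
#' @param volumes List of [LabelledVolume-class] objects.
#' @param organicRange,openingRadius,minBlobVoxels,backend Passed to
#'   [parcelBlobs()].
#' @return List with `features`, `embeddings`, `labels` (factor over
#'   [blobClasses()]) and `parcel` (index of the source volume per blob).
#' @examples
#' corpus <- makeCorpus(2, c(fish = 0.5, none = 0.5),
#'                      phantomSpec(gridShape = 48L, animalScale = 60,
#'                                  clutterCount = 1L), seed = 4)
#' bc <- buildBlobCorpus(corpus)
#' table(bc$labels)
#' @export
buildBlobCorpus <- function(volumes, organicRange = c(900, 1400),
                            openingRadius = 1, minBlobVoxels = 30L,
                            backend = "pooled_rp") {
  classMap <- c(lizard = "Lizard", fish = "Fish", bird = "Birds")
  feats <- embs <- list(); labs <- character(0); parcel <- integer(0)
  for (i in seq_along(volumes)) {
    lv <- volumes[[i]]
    pb <- parcelBlobs(scanVolume(lv), organicRange, openingRadius,
                      minBlobVoxels, backend)
    if (length(pb$blobs) == 0L) next
    truth <- truthMask(lv)
    lbl <- vapply(pb$blobs, function(b) {
      frac <- mean(truth[voxelCoords(b)])
      if (frac >= 0.5 && animalLabel(lv) != "none")
        classMap[[animalLabel(lv)]]
      else "NotWildlife"
    }, character(1))
    feats[[length(feats) + 1]] <- pb$features
    embs[[length(embs) + 1]] <- pb$embeddings
    labs <- c(labs, lbl)
    parcel <- c(parcel, rep(i, length(lbl)))
  }
  list(features = do.call(rbind, feats), embeddings = do.call(rbind, embs),
       labels = factor(labs, levels = blobClasses()), parcel = parcel)
}

#' Benchmark AT.2 against AT.3 on a synthetic corpus
#'
#' Generates the default benchmark corpus, builds the labelled blob table,
#' splits it by parcel into train and held-out sets, trains both classifier
#' families, and reports held-out blob accuracies. Deterministic for a fixed
#' seed.
#'
#' The benchmark corpus deliberately differs from the bare [phantomSpec()]
#' defaults in two respects that make the comparison meaningful: a clutter
#' radiodensity band overlapping the organic range is present (so
#' `NotWildlife` blobs exist and the rejection path is exercised -- screening
#' produces false positives precisely because organic-looking clutter
#' exists), and the animal scale is drawn per parcel from `scaleRange`
#' (specimens in a screening stream vary in size, and a fixed scale would
#' let absolute blob volume act as a class give-away).
#'
#' @param n Number of parcels; default 200.
#' @param seed Master seed; default 42.
#' @param classMix Parcel class proportions (may include `none`).
#' @param specTemplate Template [PhantomSpec-class]; class, seed and scale
#'   are overridden per parcel.
#' @param scaleRange Per-parcel animal length range in mm; default
#'   `c(100, 160)`.
#' @param holdout Fraction of parcels held out; default 0.3.
#' @param nTrees AT.2 forest size.
#' @param epochs AT.3 training epochs.
#' @return List with `at2Accuracy`, `at3Accuracy`, `chance` (majority-class
#'   frequency of the held-out labels), the two models, the blob corpus and
#'   the held-out indices.
#' @examples
#' \donttest{
#' bm <- runDetectionBenchmark(n = 24, seed = 1,
#'   specTemplate = phantomSpec(gridShape = 64L, clutterCount = 2L),
#'   scaleRange = c(60, 100))
#' bm$at2Accuracy; bm$at3Accuracy
#' }
#' @export
runDetectionBenchmark <- function(n = 200L, seed = 42L,
                                  classMix = c(lizard = 0.3, fish = 0.2,
                                               bird = 0.2, none = 0.3),
                                  specTemplate = phantomSpec(
                                    clutterRanges = list(c(400, 900),
                                                         c(3000, 4095),
                                                         c(950, 1350))),
                                  scaleRange = c(100, 160),
                                  holdout = 0.3, nTrees = 300L,
                                  epochs = 600L) {
  corpus <- .streamBlobCorpus(n, classMix, specTemplate, scaleRange, seed)

  set.seed(seed + 1L)
  parcels <- unique(corpus$parcel)
  heldParcels <- sample(parcels, size = max(1L, round(holdout * length(parcels))))
  test <- corpus$parcel %in% heldParcels
  if (!any(test) || all(test)) stop("degenerate train/held-out split")

  at2 <- at2Train(corpus$features[!test, , drop = FALSE],
                  droplevels(corpus$labels[!test]), nTrees = nTrees,
                  seed = seed)
  at3 <- at3Train(corpus$embeddings[!test, , drop = FALSE],
                  droplevels(corpus$labels[!test]), seed = seed,
                  epochs = epochs)

  p2 <- at2Classify(at2, corpus$features[test, , drop = FALSE])
  p3 <- at3Classify(at3, corpus$embeddings[test, , drop = FALSE])
  truth <- as.character(corpus$labels[test])
  pred2 <- colnames(p2)[max.col(p2, ties.method = "first")]
  pred3 <- colnames(p3)[max.col(p3, ties.method = "first")]

  list(at2Accuracy = mean(pred2 == truth),
       at3Accuracy = mean(pred3 == truth),
       chance = max(table(truth)) / length(truth),
       nHeldOut = length(truth),
       at2Model = at2, at3Model = at3,
       corpus = corpus, heldOut = which(test))
}

# benchmark corpus, streamed one parcel at a time so memory stays bounded:
# makeCorpus contracts (largest-remainder counts, seeded shuffle, derived
# per-item seeds) plus a per-parcel animal-scale draw
.streamBlobCorpus <- function(n, classMix, specTemplate, scaleRange, seed) {
  if (n <= 0) stop("n must be a positive integer")
  if (abs(sum(classMix) - 1) > 1e-8) stop("classMix proportions must sum to 1")
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
  scales <- stats::runif(n, scaleRange[1], scaleRange[2])

  parts <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specTemplate
    sp@animalClass <- labels[i]
    sp@animalScale <- scales[i]
    sp@seed <- itemSeeds[i]
    lv <- makeParcel(sp)
    part <- buildBlobCorpus(list(lv))
    if (!is.null(part$features) && nrow(part$features)) {
      part$parcel <- rep(i, nrow(part$features))
      parts[[i]] <- part
    }
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  list(features = do.call(rbind, lapply(parts, `[[`, "features")),
       embeddings = do.call(rbind, lapply(parts, `[[`, "embeddings")),
       labels = factor(unlist(lapply(parts, function(p) as.character(p$labels))),
                       levels = blobClasses()),
       parcel = unlist(lapply(parts, `[[`, "parcel")))
}
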