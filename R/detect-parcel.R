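# Parcel-level decisions: segment, extract blobs, score, threshold.

#' Extract blobs and their features from a volume
#'
#' Runs the shared front end of both pipelines: organic thresholding,
#' morphological opening, connected-component labelling, then per-blob
#' hand-crafted features and MIP-triplet embeddings.
#'
#' @param volume A [ScanVolume-class].
#' @param organicRange Radiodensity range of organic material.
#' @param openingRadius Opening ball radius in voxels.
#' @param minBlobVoxels Minimum blob size kept.
#' @param backend Embedding backend (see [embedProjection()]).
#' @return List with `blobs` (list of [Blob-class]), `features` (matrix) and
#'   `embeddings` (matrix); zero-row matrices when no blob survives.
#' @examples
#' lv <- makeParcel(phantomSpec(gridShape = 48L, animalClass = "fish",
#'                              animalScale = 60, clutterCount = 0L, seed = 2))
#' pb <- parcelBlobs(scanVolume(lv))
#' nrow(pb$features)
#' @export
parcelBlobs <- function(volume, organicRange = c(900, 1400), openingRadius = 1,
                        minBlobVoxels = 30L, backend = "pooled_rp") {
  mask <- segmentOrganic(volume, organicRange, openingRadius)
  blobs <- labelComponents(mask, spacing(volume), minBlobVoxels)
  if (length(blobs) == 0L) {
    return(list(blobs = list(),
                features = matrix(0, 0, 17,
                                  dimnames = list(NULL, blobFeatureNames())),
                embeddings = matrix(0, 0, 480)))
  }
  features <- t(vapply(blobs, blobFeatures, numeric(17), volume = volume))
  embeddings <- t(vapply(blobs, function(b)
    embedTriplet(mipProject(volume, b), backend), numeric(480)))
  list(blobs = blobs, features = features, embeddings = embeddings)
}

#' Classify a parcel volume
#'
#' Scores every segmented blob with the supplied model (AT.2 over features or
#' AT.3 over embeddings) and flags the parcel as detected when any blob's
#' maximum wildlife-class (Lizard/Fish/Birds) probability reaches the
#' threshold.
#'
#' @param volume A [ScanVolume-class].
#' @param model An [AT2Model-class] or [AT3Model-class].
#' @param threshold Detection threshold in `[0, 1]`; default 0.5.
#' @param ... Passed to [parcelBlobs()].
#' @return A [ParcelDecision-class].
#' @examples
#' # see runDetectionBenchmark for an end-to-end example
#' @export
classifyParcel <- function(volume, model, threshold = 0.5, ...) {
  if (missing(model) || is.null(model)) stop("a trained model is required")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  pb <- parcelBlobs(volume, ...)
  if (length(pb$blobs) == 0L) {
    return(new("ParcelDecision", detected = FALSE,
               scores = matrix(0, 0, 4, dimnames = list(NULL, blobClasses())),
               threshold = threshold))
  }
  scores <- if (is(model, "AT2Model")) at2Classify(model, pb$features)
            else if (is(model, "AT3Model")) at3Classify(model, pb$embeddings)
            else stop("model must be an AT2Model or AT3Model")
  wild <- apply(scores[, wildlifeClasses(), drop = FALSE], 1, max)
  new("ParcelDecision", detected = any(wild >= threshold), scores = scores,
      threshold = threshold)
}

#' Serialize a parcel decision
#'
#' Writes the per-blob class scores and the parcel-level outcome as JSON
#' and/or CSV.
#'
#' @param decision A [ParcelDecision-class].
#' @param jsonPath,csvPath Output paths (either may be `NULL`).
#' @return Invisibly, the per-blob score data.frame.
#' @examples
#' d <- new("ParcelDecision", detected = FALSE,
#'          scores = matrix(0, 0, 4, dimnames = list(NULL, blobClasses())),
#'          threshold = 0.5)
#' writeDecision(d, jsonPath = tempfile(fileext = ".json"))
#' @export
writeDecision <- function(decision, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(decision, "ParcelDecision"))
  tab <- as.data.frame(blobScores(decision))
  tab <- cbind(blob = seq_len(nrow(tab)), tab)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(detected = isDetected(decision),
                              threshold = decision@threshold,
                              blobs = tab),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(csvPath))
    utils::write.csv(tab, csvPath, row.names = FALSE)
  invisible(tab)
}
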