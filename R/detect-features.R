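# Hand-crafted blob features: intensity distribution, size and shape.

#' Blob feature vector
#'
#' Fixed-length, documented feature ordering used by the random-forest
#' classifier:
#' \enumerate{
#'   \item `mean`, `sd` of blob voxel intensities;
#'   \item `hist1`..`hist8`: 8-bin histogram of blob intensities, normalised
#'     to sum to 1, over the blob's own intensity range (equal-width bins; a
#'     constant blob puts all mass in bin 1);
#'   \item `count`: voxel count; `volume_mm3`: physical volume;
#'   \item `extent_x/y/z`: axis-aligned physical extents in mm (bounding box,
#'     voxel centres plus one voxel);
#'   \item `elongation`: largest extent / smallest extent (sorted, so the
#'     value is rotation-convention-free for axis-aligned shapes);
#'   \item `compactness`: voxel count / bounding-box voxel volume, in (0, 1].
#' }
#'
#' @param blob A [Blob-class].
#' @param volume The source [ScanVolume-class].
#' @return Named numeric vector of length 17.
#' @examples
#' v <- ScanVolume(array(1000, c(8, 8, 8)), 1)
#' b <- labelComponents(array(TRUE, c(8, 8, 8)), 1, minBlobVoxels = 1)[[1]]
#' blobFeatures(b, v)[c("sd", "compactness")]
#' @export
blobFeatures <- function(blob, volume) {
  stopifnot(is(blob, "Blob"), is(volume, "ScanVolume"))
  cds <- voxelCoords(blob)
  d <- dim(intensities(volume))
  if (any(cds < 1L) || any(cds[, 1] > d[1]) || any(cds[, 2] > d[2]) ||
      any(cds[, 3] > d[3]))
    stop("blob voxels fall outside the volume")
  vals <- intensities(volume)[cds]
  m <- mean(vals)
  s <- if (length(vals) > 1L) stats::sd(vals) else 0
  if (is.na(s)) s <- 0
  rng <- range(vals)
  if (diff(rng) == 0) {
    h <- c(1, rep(0, 7))
  } else {
    br <- seq(rng[1], rng[2], length.out = 9L)
    h <- as.numeric(table(cut(vals, br, include.lowest = TRUE)))
    h <- h / sum(h)
  }
  bb <- boundingBox(blob)
  extVox <- bb["max", ] - bb["min", ] + 1L
  extMm <- extVox * spacing(blob)
  sorted <- sort(extMm)
  elong <- sorted[3] / sorted[1]
  compact <- voxelCount(blob) / prod(extVox)
  out <- c(mean = m, sd = s,
           stats::setNames(h, paste0("hist", 1:8)),
           count = voxelCount(blob), volume_mm3 = physicalVolume(blob),
           extent_x = unname(extMm[1]), extent_y = unname(extMm[2]),
           extent_z = unname(extMm[3]),
           elongation = unname(elong), compactness = compact)
  out
}

#' Names of the blob feature vector, in order
#' @return Character vector of length 17.
#' @examples blobFeatureNames()
#' @export
blobFeatureNames <- function() {
  c("mean", "sd", paste0("hist", 1:8), "count", "volume_mm3",
    "extent_x", "extent_y", "extent_z", "elongation", "compactness")
}
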