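# Maximum-intensity projections and the fixed projection embedding.

#' Maximum-intensity projections of a blob
#'
#' Crops the volume to the blob's bounding box, masks non-blob voxels to the
#' background value, takes the per-pixel maximum along each of the three
#' orthogonal axes, pads each projection to a square (preserving aspect
#' ratio), and bilinearly resamples to 128 x 128.
#'
#' @param volume The source [ScanVolume-class].
#' @param blob A non-empty [Blob-class].
#' @param background Value used outside the blob; default 0.
#' @param resample If `FALSE`, return the raw per-axis maxima of the masked
#'   bounding box (a list of three matrices) without padding or resampling;
#'   intended for validation against brute-force projection.
#' @return A [ProjectionTriplet-class], or a list of three matrices when
#'   `resample = FALSE`.
#' @examples
#' m <- array(FALSE, c(16, 16, 16)); m[4:12, 6:10, 7:9] <- TRUE
#' v <- ScanVolume(array(1000, c(16, 16, 16)), 1)
#' b <- labelComponents(m, 1, minBlobVoxels = 1)[[1]]
#' tp <- mipProject(v, b)
#' @export
mipProject <- function(volume, blob, background = 0, resample = TRUE) {
  stopifnot(is(volume, "ScanVolume"), is(blob, "Blob"))
  if (voxelCount(blob) == 0L) stop("empty blob")
  bb <- boundingBox(blob)
  sub <- intensities(volume)[bb["min", 1]:bb["max", 1],
                             bb["min", 2]:bb["max", 2],
                             bb["min", 3]:bb["max", 3], drop = FALSE]
  local <- sweep(voxelCoords(blob), 2, bb["min", ] - 1L)
  keep <- array(FALSE, dim(sub))
  keep[local] <- TRUE
  sub[!keep] <- background

  raw <- lapply(1:3, function(ax) {
    proj <- apply(sub, setdiff(1:3, ax), max)
    if (!is.matrix(proj)) proj <- as.matrix(proj)
    proj
  })
  if (!resample) return(raw)
  imgs <- lapply(raw, .padSquareResize, size = 128L, background = background)
  new("ProjectionTriplet", images = imgs, blobId = blob@id, axisOrder = 1:3)
}

# pad a matrix to square (centred) and bilinearly resample to size x size
.padSquareResize <- function(m, size, background = 0) {
  if (!is.matrix(m)) m <- as.matrix(m)
  nr <- nrow(m); nc <- ncol(m)
  s <- max(nr, nc)
  sq <- matrix(background, s, s)
  r0 <- floor((s - nr) / 2); c0 <- floor((s - nc) / 2)
  sq[r0 + seq_len(nr), c0 + seq_len(nc)] <- m
  if (s == size) return(sq)
  out <- EBImage::resize(sq, w = size, h = size, filter = "bilinear")
  matrix(as.numeric(out), size, size)
}

# the fixed Gaussian projection bank behind the default embedding backend;
# built once per session under an internal seed, so the mapping is a fixed
# linear operator independent of user RNG state
.embedCache <- new.env(parent = emptyenv())

.embedMatrix <- function(inDim = 1024L, outDim = 160L) {
  key <- sprintf("P_%d_%d", inDim, outDim)
  if (is.null(.embedCache[[key]])) {
    .embedCache[[key]] <- withLocalSeed(20230731L, {
      matrix(stats::rnorm(inDim * outDim, 0, 1 / sqrt(inDim)), outDim, inDim)
    })
  }
  .embedCache[[key]]
}

#' Embed a 128 x 128 projection into a 160-dimensional feature vector
#'
#' The contract is shape and determinism: the same image always maps to the
#' same length-160 vector. The default (and only built-in) backend performs
#' 4 x 4 average pooling to 32 x 32 followed by a fixed Gaussian linear
#' projection to 160 dimensions, generated once under an internal seed --
#' the dependency-free random-projection backend. Alternative feature
#' extractors (e.g. a pretrained convolutional backbone) can be plugged in by
#' passing a function as `backend`.
#'
#' @param image Numeric 128 x 128 matrix.
#' @param backend `"pooled_rp"` (default) or a function `image -> numeric(160)`.
#' @return Numeric vector of length 160.
#' @examples
#' e <- embedProjection(matrix(0, 128, 128))
#' length(e)
#' @export
embedProjection <- function(image, backend = "pooled_rp") {
  if (!is.matrix(image) || !identical(dim(image), c(128L, 128L)))
    stop("image must be exactly 128 x 128")
  if (is.function(backend)) {
    v <- backend(image)
    if (length(v) != 160L) stop("backend must return a vector of length 160")
    return(as.numeric(v))
  }
  if (!identical(backend, "pooled_rp")) stop("unknown backend: ", backend)
  # 4x4 average pooling to 32 x 32
  pooled <- .blockMean(image, 4L)
  v <- as.numeric(.embedMatrix(1024L, 160L) %*% as.numeric(pooled))
  v
}

.blockMean <- function(m, f) {
  n <- nrow(m) / f
  # average over f x f blocks via two fold steps
  m1 <- rowsum(m, rep(seq_len(n), each = f)) / f
  t(rowsum(t(m1), rep(seq_len(n), each = f)) / f)
}

#' Embed a projection triplet
#'
#' Concatenates the three per-axis 160-d embeddings into the 480-d input of
#' the AT.3 dense head.
#'
#' @param triplet A [ProjectionTriplet-class].
#' @param backend Passed to [embedProjection()].
#' @return Numeric vector of length 480.
#' @examples
#' # see embedProjection
#' @export
embedTriplet <- function(triplet, backend = "pooled_rp") {
  stopifnot(is(triplet, "ProjectionTriplet"))
  unlist(lapply(projections(triplet), embedProjection, backend = backend),
         use.names = FALSE)
}
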