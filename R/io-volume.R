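# Volume I/O: NRRD (native reader/writer) and NIfTI (via RNifti).

#' Read / write a volume
#'
#' `writeVolume()` writes a [ScanVolume-class] to NRRD (default flavour:
#' attached raw little-endian doubles) or NIfTI (via the RNifti package,
#' double datatype); `readVolume()` reads either back. The round trip
#' preserves intensities and (possibly anisotropic) voxel spacing exactly.
#'
#' @param volume A [ScanVolume-class].
#' @param path File path ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @return `readVolume()` returns a [ScanVolume-class]; `writeVolume()`
#'   returns `path` invisibly.
#' @examples
#' v <- ScanVolume(array(runif(8^3), c(8, 8, 8)), c(1, 2, 3))
#' f <- tempfile(fileext = ".nrrd")
#' writeVolume(v, f)
#' identical(intensities(readVolume(f)), intensities(v))
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "ScanVolume"))
  ext <- .volumeFormat(path)
  if (ext == "nrrd") .writeNrrd(volume, path)
  else .writeNifti(volume, path)
  invisible(path)
}

#' @rdname writeVolume
#' @param path File path to read.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- .volumeFormat(path)
  if (ext == "nrrd") .readNrrd(path) else .readNifti(path)
}

.volumeFormat <- function(path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else stop("unsupported volume extension (supported: .nrrd, .nii, .nii.gz): ",
            path)
}

.writeNrrd <- function(volume, path) {
  arr <- intensities(volume)
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# wildtrace volume",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.17g %.17g %.17g", spacing(volume)[1],
                   spacing(volume)[2], spacing(volume)[3]),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
}

.readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("malformed NRRD header: no blank terminator")
    if (line == "") break
    hdr <- c(hdr, line)
  }
  if (!grepl("^NRRD", hdr[1])) stop("malformed NRRD header: missing magic")
  field <- function(name) {
    ln <- grep(paste0("^", name, ": "), hdr, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    sub(paste0("^", name, ": "), "", ln[1])
  }
  type <- field("type")
  if (is.null(type) || !type %in% c("double", "float", "short"))
    stop("unsupported NRRD type: ", type)
  enc <- field("encoding")
  if (!identical(enc, "raw")) stop("unsupported NRRD encoding: ", enc)
  sizes <- as.integer(strsplit(field("sizes"), " +")[[1]])
  sp <- field("spacings")
  if (is.null(sp)) stop("NRRD header missing spacings")
  sp <- as.numeric(strsplit(sp, " +")[[1]])
  endian <- field("endian")
  n <- prod(sizes)
  what <- if (type == "short") integer() else numeric()
  size <- switch(type, double = 8L, float = 4L, short = 2L)
  vals <- readBin(con, what, n = n, size = size,
                  endian = if (identical(endian, "big")) "big" else "little")
  if (length(vals) != n) stop("malformed NRRD: truncated data block")
  ScanVolume(array(as.numeric(vals), dim = sizes), sp)
}

.writeNifti <- function(volume, path) {
  arr <- intensities(volume)
  attr(arr, "pixdim") <- spacing(volume)
  RNifti::writeNifti(arr, path, datatype = "double")
}

.readNifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header has no usable voxel spacing")
  ScanVolume(array(as.numeric(img), dim = dim(img)[1:3]), sp)
}

#' Write a corpus manifest
#'
#' Writes each labelled volume of a corpus to `dir` (NRRD) together with a
#' `manifest.csv` (id, file, label, seed) so a corpus can be re-read without
#' regenerating it.
#'
#' @param corpus List of [LabelledVolume-class] objects.
#' @param dir Output directory (created if needed).
#' @param seeds Optional integer vector of the per-item generator seeds.
#' @return Path of the manifest, invisibly.
#' @examples
#' corpus <- makeCorpus(2, c(fish = 1), phantomSpec(gridShape = 32L,
#'   animalScale = 40, clutterCount = 0L), seed = 1)
#' writeCorpus(corpus, tempfile())
#' @export
writeCorpus <- function(corpus, dir, seeds = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(corpus), function(i) {
    f <- sprintf("parcel_%04d.nrrd", i)
    writeVolume(scanVolume(corpus[[i]]), file.path(dir, f))
    data.frame(id = i, file = f, label = animalLabel(corpus[[i]]),
               seed = if (length(seeds) >= i) seeds[i] else NA_integer_)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
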