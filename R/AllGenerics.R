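#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Slot access from
#' user code should always go through these rather than `@`.
#'
#' @param x An object of one of the package's S4 classes.
#' @param object An object of one of the package's S4 classes.
#' @return The slot value; see the class documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))

#' @rdname accessors
#' @export
setGeneric("animalLabel", function(x) standardGeneric("animalLabel"))

#' @rdname accessors
#' @export
setGeneric("scanVolume", function(x) standardGeneric("scanVolume"))

#' @rdname accessors
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))

#' @rdname accessors
#' @export
setGeneric("boundingBox", function(x) standardGeneric("boundingBox"))

#' @rdname accessors
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' @rdname accessors
#' @export
setGeneric("physicalVolume", function(x) standardGeneric("physicalVolume"))

#' @rdname accessors
#' @export
setGeneric("projections", function(x) standardGeneric("projections"))

#' @rdname accessors
#' @export
setGeneric("energyGrid", function(x) standardGeneric("energyGrid"))

#' @rdname accessors
#' @export
setGeneric("fluence", function(x) standardGeneric("fluence"))

#' @rdname accessors
#' @export
setGeneric("massFractions", function(x) standardGeneric("massFractions"))

#' @rdname accessors
#' @export
setGeneric("isDetected", function(x) standardGeneric("isDetected"))

#' @rdname accessors
#' @export
setGeneric("blobScores", function(x) standardGeneric("blobScores"))

#' @rdname accessors
#' @export
setGeneric("effectiveDoseMsv", function(x) standardGeneric("effectiveDoseMsv"))

#' @rdname accessors
#' @export
setGeneric("softTissueDoseMgy", function(x) standardGeneric("softTissueDoseMgy"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("zStatistic", function(x) standardGeneric("zStatistic"))
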