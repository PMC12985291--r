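#' @rdname accessors
#' @export
setMethod("intensities", "ScanVolume", function(x) x@intensities)

#' @rdname accessors
#' @export
setMethod("spacing", "ScanVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("intensities", "LabelledVolume", function(x) x@volume@intensities)

#' @rdname accessors
#' @export
setMethod("spacing", "LabelledVolume", function(x) x@volume@spacing)

#' @rdname accessors
#' @export
setMethod("scanVolume", "LabelledVolume", function(x) x@volume)

#' @rdname accessors
#' @export
setMethod("truthMask", "LabelledVolume", function(x) x@truthMask)

#' @rdname accessors
#' @export
setMethod("animalLabel", "LabelledVolume", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("voxelCoords", "Blob", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("spacing", "Blob", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("voxelCount", "Blob", function(x) nrow(x@coords))

#' Tight per-axis bounding box of a blob
#'
#' @rdname accessors
#' @export
setMethod("boundingBox", "Blob", function(x) {
  rbind(min = apply(x@coords, 2, min), max = apply(x@coords, 2, max))
})

#' Physical blob volume (mm^3): voxel count times voxel volume
#'
#' @rdname accessors
#' @export
setMethod("physicalVolume", "Blob", function(x) {
  nrow(x@coords) * prod(x@spacing)
})

#' @rdname accessors
#' @export
setMethod("projections", "ProjectionTriplet", function(x) x@images)

#' @rdname accessors
#' @export
setMethod("energyGrid", "XraySpectrum", function(x) x@energy)

#' @rdname accessors
#' @export
setMethod("fluence", "XraySpectrum", function(x) x@fluence)

#' Elemental mass fractions of a material
#'
#' Mass fractions computed from the chemical formula and standard atomic
#' weights; they sum to 1.
#'
#' @rdname accessors
#' @export
setMethod("massFractions", "MaterialComposition", function(x) {
  w <- .atomicWeights[names(x@formula)]
  if (anyNA(w))
    stop("unknown element(s): ",
         paste(names(x@formula)[is.na(w)], collapse = ", "))
  mf <- w * x@formula / sum(w * x@formula)
  names(mf) <- names(x@formula)
  mf
})

#' @rdname accessors
#' @export
setMethod("isDetected", "ParcelDecision", function(x) x@detected)

#' @rdname accessors
#' @export
setMethod("blobScores", "ParcelDecision", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("effectiveDoseMsv", "DoseResult", function(x) x@effectiveDose)

#' @rdname accessors
#' @export
setMethod("softTissueDoseMgy", "DoseResult", function(x) x@softTissueDose)

#' @rdname accessors
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("zStatistic", "TestResult", function(x) x@zStatistic)

setMethod("show", "ScanVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("ScanVolume: %d x %d x %d voxels at %s mm\n", d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "LabelledVolume", function(object) {
  show(object@volume)
  cat(sprintf("  label: %s (%d truth voxels)\n", object@label,
              sum(object@truthMask)))
})

setMethod("show", "Blob", function(object) {
  bb <- boundingBox(object)
  cat(sprintf("Blob #%d: %d voxels (%.0f mm^3), bbox %s\n", object@id,
              voxelCount(object), physicalVolume(object),
              paste(bb["max", ] - bb["min", ] + 1L, collapse = " x ")))
})

setMethod("show", "XraySpectrum", function(object) {
  cat(sprintf("XraySpectrum: %d bins, %.1f-%.1f keV, total fluence %.3g\n",
              length(object@energy), min(object@energy), max(object@energy),
              sum(object@fluence)))
})

setMethod("show", "BeamSpec", function(object) {
  filt <- if (is.na(object@filterElement)) "no filter"
          else sprintf("%s %.3g mm", object@filterElement, object@filterThickness)
  cat(sprintf("BeamSpec: %g kV, %g uA, %s, %g s\n", object@voltage,
              object@current, filt, object@duration))
})

setMethod("show", "DoseResult", function(object) {
  cat("pXRF dose model result\n")
  cat(sprintf("  surface air kerma        : %.1f mGy\n", object@surfaceKerma))
  cat(sprintf("  keratin flux transmission: %.3f\n", object@keratinFluxFraction))
  cat(sprintf("  soft-tissue fraction     : %.3f of surface kerma\n",
              object@transmittedFraction))
  cat(sprintf("  soft-tissue dose         : %.1f mGy\n", object@softTissueDose))
  cat(sprintf("  irradiated fraction      : %.4f\n", object@irradiatedFraction))
  cat(sprintf("  effective dose           : %.1f mSv (%.1f mSv/mGy)\n",
              object@effectiveDose, object@kermaToEffective))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("One-tailed two-proportion z-test (%s)\n", object@tail))
  cat(sprintf("  p1 = %.4f, p2 = %.4f\n", object@estimates[1],
              object@estimates[2]))
  cat(sprintf("  z = %.4f, p = %.3g\n", object@zStatistic, object@pValue))
})

setMethod("show", "ParcelDecision", function(object) {
  cat(sprintf("ParcelDecision: %s (%d blobs, threshold %.2f)\n",
              if (object@detected) "DETECTED" else "clear",
              nrow(object@scores), object@threshold))
})

setMethod("show", "TrialReport", function(object) {
  cat("TrialReport with sections:",
      paste(names(object@sections), collapse = ", "), "\n")
  cat("  seed:", object@metadata$seed,
      " package:", object@metadata$package_version, "\n")
})
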