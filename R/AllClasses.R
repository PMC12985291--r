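#' ScanVolume: a reconstructed 3D radiodensity volume
#'
#' The unit of parcel scanning: a 3D grid of radiodensity values (arbitrary
#' 12-bit-like units on \[0, 4095\]) with a physical voxel spacing in mm.
#'
#' @slot intensities 3D numeric array of radiodensity values.
#' @slot spacing Numeric length-3, mm per voxel along each axis (all > 0).
#' @exportClass ScanVolume
setClass("ScanVolume",
  representation(intensities = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@intensities)) != 3L)
      return("intensities must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    TRUE
  }
)

#' Construct a ScanVolume
#'
#' @param intensities 3D numeric array of radiodensity values.
#' @param spacing Voxel spacing in mm; a scalar is recycled to all three axes.
#' @return A [ScanVolume-class] object.
#' @examples
#' v <- ScanVolume(array(0, c(8, 8, 8)), spacing = 2)
#' dim(intensities(v))
#' @export
ScanVolume <- function(intensities, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ScanVolume", intensities = intensities, spacing = as.numeric(spacing))
}

#' PhantomSpec: parameters of a synthetic parcel phantom
#'
#' Describes one synthetic parcel: grid geometry, the animal class and size,
#' clutter content, the radiodensity range of organic material, and noise.
#' Defaults follow a 12-bit CT-like intensity convention: organic material on
#' \[900, 1400\], plastics \[400, 900\], dense metal \[3000, 4095\].
#'
#' @slot gridShape Integer length-3, voxels per axis (all >= 32).
#' @slot voxelSize Numeric length-3, mm per voxel.
#' @slot animalClass One of `"lizard"`, `"fish"`, `"bird"`, `"none"`.
#' @slot animalScale Animal body length in mm.
#' @slot clutterCount Number of clutter objects.
#' @slot organicRange Numeric length-2 `[low, high]` radiodensity of organics.
#' @slot clutterRanges List of `[low, high]` radiodensity ranges for clutter.
#' @slot noiseSd Additive Gaussian noise standard deviation (radiodensity units).
#' @slot seed Integer RNG seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    gridShape = "integer", voxelSize = "numeric", animalClass = "character",
    animalScale = "numeric", clutterCount = "integer", organicRange = "numeric",
    clutterRanges = "list", noiseSd = "numeric", seed = "integer"
  ),
  validity = function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 32L))
      return("gridShape must be 3 integers, all >= 32")
    if (any(object@voxelSize <= 0)) return("voxelSize must be positive")
    if (!object@animalClass %in% c("lizard", "fish", "bird", "none"))
      return("animalClass must be one of lizard, fish, bird, none")
    if (object@organicRange[1] >= object@organicRange[2])
      return("organicRange must satisfy low < high")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@clutterCount < 0L) return("clutterCount must be >= 0")
    TRUE
  }
)

#' Construct a PhantomSpec
#'
#' @param gridShape Voxels per axis (scalar or length 3); default 128.
#' @param voxelSize mm per voxel (scalar or length 3); default 2.
#' @param animalClass `"lizard"`, `"fish"`, `"bird"` or `"none"`.
#' @param animalScale Animal length in mm; default 160.
#' @param clutterCount Number of clutter objects; default 6.
#' @param organicRange Radiodensity range of organic material.
#' @param clutterRanges List of radiodensity ranges used for clutter objects.
#' @param noiseSd Additive Gaussian noise sd; default 30.
#' @param seed Integer seed; default 1.
#' @return A [PhantomSpec-class] object.
#' @examples
#' phantomSpec(animalClass = "lizard", seed = 7)
#' @export
phantomSpec <- function(gridShape = 128L, voxelSize = 2, animalClass = "none",
                        animalScale = 160, clutterCount = 6L,
                        organicRange = c(900, 1400),
                        clutterRanges = list(c(400, 900), c(3000, 4095)),
                        noiseSd = 30, seed = 1L) {
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("PhantomSpec",
    gridShape = as.integer(gridShape), voxelSize = as.numeric(voxelSize),
    animalClass = animalClass, animalScale = as.numeric(animalScale),
    clutterCount = as.integer(clutterCount),
    organicRange = as.numeric(organicRange),
    clutterRanges = clutterRanges, noiseSd = as.numeric(noiseSd),
    seed = as.integer(seed))
}

#' LabelledVolume: a synthetic volume with ground truth
#'
#' @slot volume A [ScanVolume-class].
#' @slot truthMask Logical 3D array marking animal voxels (same shape).
#' @slot label Animal class of the phantom (`"none"` when absent).
#' @exportClass LabelledVolume
setClass("LabelledVolume",
  representation(volume = "ScanVolume", truthMask = "array", label = "character"),
  validity = function(object) {
    if (!identical(dim(object@truthMask), dim(object@volume@intensities)))
      return("truthMask must have the same shape as the volume")
    if (!is.logical(object@truthMask)) return("truthMask must be logical")
    empty <- !any(object@truthMask)
    if (identical(object@label, "none") != empty)
      return("label is 'none' if and only if truthMask is empty")
    TRUE
  }
)

#' Blob: a segmented 3D connected component
#'
#' A maximal 26-connected set of organic-range voxels, the unit of candidate
#' concealed-object classification.
#'
#' @slot coords Integer matrix (n x 3) of voxel coordinates (1-based).
#' @slot spacing Voxel spacing in mm of the source volume.
#' @slot id Integer blob identifier within its volume.
#' @exportClass Blob
setClass("Blob",
  representation(coords = "matrix", spacing = "numeric", id = "integer"),
  validity = function(object) {
    if (ncol(object@coords) != 3L) return("coords must be an n x 3 matrix")
    if (nrow(object@coords) < 1L) return("a Blob must contain at least one voxel")
    TRUE
  }
)

#' ProjectionTriplet: three orthogonal MIP images of a blob
#'
#' @slot images List of three 128 x 128 numeric matrices (projections along
#'   axes 1, 2, 3 of the volume).
#' @slot blobId Integer id of the source blob.
#' @slot axisOrder Integer permutation recording the projection axis order.
#' @exportClass ProjectionTriplet
setClass("ProjectionTriplet",
  representation(images = "list", blobId = "integer", axisOrder = "integer"),
  validity = function(object) {
    if (length(object@images) != 3L) return("exactly three projections required")
    ok <- vapply(object@images, function(m) identical(dim(m), c(128L, 128L)),
                 logical(1))
    if (!all(ok)) return("each projection must be exactly 128 x 128")
    TRUE
  }
)

#' ParcelDecision: parcel-level detection outcome
#'
#' @slot detected Logical; whether any blob crosses the wildlife threshold.
#' @slot scores Numeric matrix (blobs x classes) of class probabilities.
#' @slot threshold Detection threshold applied to the wildlife classes.
#' @exportClass ParcelDecision
setClass("ParcelDecision",
  representation(detected = "logical", scores = "matrix", threshold = "numeric"),
  validity = function(object) {
    if (object@threshold < 0 || object@threshold > 1)
      return("threshold must lie in [0, 1]")
    TRUE
  }
)

#' AT2Model: random-forest blob classifier
#'
#' Wraps a bagged decision-tree ensemble over hand-crafted blob features
#' (intensity distribution, size and shape), together with a versioned
#' manifest making the artefact self-describing.
#'
#' @slot fit The underlying `randomForest` fit.
#' @slot featureNames Character vector of expected feature names, in order.
#' @slot classes Character vector of class labels.
#' @slot manifest List: format version, seed, training size.
#' @exportClass AT2Model
setClass("AT2Model",
  representation(fit = "ANY", featureNames = "character", classes = "character",
                 manifest = "list"))

#' AT3Model: five-layer dense head over MIP embeddings
#'
#' @slot weights List of layer weight matrices and bias vectors.
#' @slot layerSizes Integer vector of the five hidden layer widths.
#' @slot classes Character vector of class labels.
#' @slot history Numeric vector of per-epoch training cross-entropy.
#' @slot manifest List: format version, seed, training size, backend.
#' @exportClass AT3Model
setClass("AT3Model",
  representation(weights = "list", layerSizes = "integer", classes = "character",
                 history = "numeric", manifest = "list"))

#' BeamSpec: one pXRF beam setting
#'
#' @slot voltage Accelerating voltage in kV (> 0).
#' @slot current Tube current in microampere.
#' @slot filterElement Chemical symbol of the filter, or `NA` for none.
#' @slot filterThickness Filter thickness in mm (0 for none).
#' @slot duration Beam time in seconds (> 0).
#' @exportClass BeamSpec
setClass("BeamSpec",
  representation(voltage = "numeric", current = "numeric",
                 filterElement = "character", filterThickness = "numeric",
                 duration = "numeric"),
  validity = function(object) {
    if (object@voltage <= 0) return("voltage must be > 0")
    if (object@duration <= 0) return("duration must be > 0")
    if (object@filterThickness < 0) return("filterThickness must be >= 0")
    TRUE
  }
)

#' Construct a BeamSpec
#'
#' @param voltage kV accelerating voltage.
#' @param current Tube current, microampere.
#' @param filterElement Filter element symbol (e.g. `"Al"`, `"Cu"`) or `NA`.
#' @param filterThickness Filter thickness in mm.
#' @param duration Beam duration in seconds.
#' @return A [BeamSpec-class] object.
#' @examples
#' beamSpec(40, 60.75, "Al", 2, 20)
#' @export
beamSpec <- function(voltage, current, filterElement = NA_character_,
                     filterThickness = 0, duration = 20) {
  new("BeamSpec", voltage = voltage, current = current,
      filterElement = as.character(filterElement),
      filterThickness = filterThickness, duration = duration)
}

#' XraySpectrum: modelled photon fluence per energy bin
#'
#' @slot energy keV bin centres (0.5 keV grid by default).
#' @slot fluence Photons per bin (arbitrary scale, proportional to uA.s).
#' @exportClass XraySpectrum
setClass("XraySpectrum",
  representation(energy = "numeric", fluence = "numeric"),
  validity = function(object) {
    if (length(object@energy) != length(object@fluence))
      return("energy and fluence must have equal length")
    if (any(object@fluence < 0)) return("fluence must be non-negative")
    TRUE
  }
)

#' MaterialComposition: a homogeneous attenuating layer
#'
#' @slot formula Named numeric vector of atom counts per formula unit.
#' @slot density Mass density in g/cm^3 (> 0).
#' @slot thickness Layer thickness in mm (>= 0).
#' @exportClass MaterialComposition
setClass("MaterialComposition",
  representation(formula = "numeric", density = "numeric", thickness = "numeric"),
  validity = function(object) {
    if (is.null(names(object@formula)) || any(object@formula <= 0))
      return("formula must be a named vector of positive atom counts")
    if (object@density <= 0) return("density must be > 0")
    if (object@thickness < 0) return("thickness must be >= 0")
    TRUE
  }
)

#' Construct a MaterialComposition
#'
#' @param formula Named numeric vector of atom counts, e.g.
#'   `c(C = 27, H = 57, N = 8, O = 17, S = 1)`.
#' @param density g/cm^3.
#' @param thickness mm.
#' @return A [MaterialComposition-class] object.
#' @examples
#' keratinLayer()
#' @export
materialComposition <- function(formula, density, thickness) {
  new("MaterialComposition", formula = formula, density = density,
      thickness = thickness)
}

#' GeometrySpec: specimen and beam exposure geometry
#'
#' @slot specimenDims Specimen bounding prism, mm (length, width, depth).
#' @slot beamFootprint Incident beam cross-section, mm x mm.
#' @slot irradiatedDepth Depth of the irradiated column, mm.
#' @exportClass GeometrySpec
setClass("GeometrySpec",
  representation(specimenDims = "numeric", beamFootprint = "numeric",
                 irradiatedDepth = "numeric"),
  validity = function(object) {
    if (any(c(object@specimenDims, object@beamFootprint,
              object@irradiatedDepth) <= 0))
      return("all geometry dimensions must be > 0")
    if (object@beamFootprint[1] > object@specimenDims[2] ||
        object@beamFootprint[2] > object@specimenDims[3])
      return("beam footprint exceeds the specimen cross-section")
    TRUE
  }
)

#' Construct a GeometrySpec
#'
#' Defaults are the trial's lizard geometry: a 100 x 20 x 20 mm prism with a
#' 15 x 15 mm beam footprint irradiating the full 20 mm depth.
#'
#' @param specimenDims Length, width, depth of the specimen prism in mm.
#' @param beamFootprint Beam cross-section in mm (width, height).
#' @param irradiatedDepth Irradiated depth in mm.
#' @return A [GeometrySpec-class] object.
#' @examples
#' irradiatedFraction(geometrySpec())
#' @export
geometrySpec <- function(specimenDims = c(100, 20, 20),
                         beamFootprint = c(15, 15), irradiatedDepth = 20) {
  new("GeometrySpec", specimenDims = specimenDims,
      beamFootprint = beamFootprint, irradiatedDepth = irradiatedDepth)
}

#' DoseResult: all derived doses for one pXRF protocol
#'
#' @slot surfaceKerma Surface air kerma, mGy.
#' @slot transmittedFraction Fraction of the surface kerma delivered as mean
#'   soft-tissue dose (dimensionless, in \[0, 1\]).
#' @slot keratinFluxFraction Photon-number-weighted transmission of the keratin
#'   layer alone.
#' @slot keratinDoseFraction Kerma-weighted transmission of the keratin layer
#'   alone.
#' @slot softTissueDose Mean absorbed dose in the soft-tissue layer, mGy.
#' @slot irradiatedFraction Irradiated-volume fraction used for effective dose.
#' @slot effectiveDose Effective dose, mSv.
#' @slot kermaToEffective Conversion factor, mSv per mGy.
#' @exportClass DoseResult
setClass("DoseResult",
  representation(surfaceKerma = "numeric", transmittedFraction = "numeric",
                 keratinFluxFraction = "numeric", keratinDoseFraction = "numeric",
                 softTissueDose = "numeric", irradiatedFraction = "numeric",
                 effectiveDose = "numeric", kermaToEffective = "numeric"),
  validity = function(object) {
    # the water-dose / air-kerma coefficient ratio (~1.04) lets the
    # fraction marginally exceed 1 in the vanishing-attenuation limit
    if (object@transmittedFraction < 0 || object@transmittedFraction > 1.1)
      return("transmittedFraction must lie in [0, 1.1]")
    if (object@keratinFluxFraction < 0 || object@keratinFluxFraction > 1)
      return("keratinFluxFraction must lie in [0, 1]")
    TRUE
  }
)

#' TestResult: a one-tailed two-proportion z-test outcome
#'
#' @slot zStatistic The pooled-variance z statistic.
#' @slot pValue Upper-tail standard-normal p-value of z.
#' @slot tail Direction of the one-sided alternative.
#' @slot estimates Named numeric: the two sample proportions.
#' @exportClass TestResult
setClass("TestResult",
  representation(zStatistic = "numeric", pValue = "numeric", tail = "character",
                 estimates = "numeric"),
  validity = function(object) {
    if (object@pValue <= 0 || object@pValue >= 1)
      return("pValue must lie in (0, 1)")
    TRUE
  }
)

#' TrialReport: consolidated pipeline report
#'
#' Each section records, for every number, whether it came from a shipped
#' fixture or from fresh computation, so table values and model outputs are
#' never silently conflated.
#'
#' @slot sections Named list of report sections (detection, dose, stats).
#' @slot provenance Named character: `"fixture"` or `"computed"` per entry.
#' @slot metadata List: seed, config hash, package version.
#' @exportClass TrialReport
setClass("TrialReport",
  representation(sections = "list", provenance = "character", metadata = "list"))
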