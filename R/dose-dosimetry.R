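# The dosimetry chain: surface-kerma normalisation, keratin attenuation,
# soft-tissue dose, irradiated-volume fraction, effective and combined dose.

#' Soft-tissue dose behind the keratin layer
#'
#' Implements the analytic exposure chain for a multi-beam pXRF protocol:
#' each beam's spectrum is modelled ([modelSpectrum()]), the total incident
#' air kerma (beams weighted by their current x duration through the
#' spectrum scale) is normalised to the measured surface air kerma, the
#' spectra are attenuated through the keratin layer (Beer-Lambert), and the
#' soft-tissue dose is the mean absorbed dose in a water layer of the given
#' thickness behind the keratin: per energy bin,
#' fluence x E x (mu_en/rho)_water x (1 - exp(-mu L)) / (mu L).
#'
#' The returned `transmittedFraction` is the soft-tissue dose as a fraction
#' of the surface kerma; the keratin layer's own flux- and kerma-weighted
#' transmissions are reported separately and are substantially higher (above
#' 8 keV a 0.5 mm keratin layer transmits most of the kerma -- the headline
#' soft-tissue fraction only emerges once the depth-averaging over the
#' soft-tissue layer is included).
#'
#' @param beams List of [BeamSpec-class] objects (non-empty).
#' @param keratin The keratin [MaterialComposition-class]; its `thickness`
#'   is the scale-layer path.
#' @param measuredSurfaceKerma Measured surface air kerma in mGy (> 0);
#'   default 227 (the trial's 60 s protocol measurement).
#' @param softTissue Water-equivalent layer behind the keratin; default
#'   [waterLayer()] (20 mm).
#' @param ... Passed to [modelSpectrum()] (grid, eMin, lLines).
#' @return A [DoseResult-class] with `irradiatedFraction`, `effectiveDose`
#'   and `kermaToEffective` unset (`NA`); see [withEffectiveDose()].
#' @examples
#' softTissueDoseMgy(softTissueDose(geoChemProtocol()))
#' @export
softTissueDose <- function(beams, keratin = keratinLayer(),
                           measuredSurfaceKerma = 227,
                           softTissue = waterLayer(), ...) {
  if (length(beams) == 0L) stop("empty beam list")
  if (measuredSurfaceKerma <= 0) stop("measuredSurfaceKerma must be > 0")

  kermaU <- softU <- fluxNum <- fluxDen <- kerKerma <- 0
  for (beam in beams) {
    sp <- modelSpectrum(beam, ...)
    e <- energyGrid(sp)
    n <- fluence(sp)
    kermaBins <- n * e * .muEn("air", e)
    kermaU <- kermaU + sum(kermaBins)

    tr <- transmit(sp, keratin)
    fluxNum <- fluxNum + sum(fluence(tr$spectrum))
    fluxDen <- fluxDen + sum(n)
    kerKerma <- kerKerma + tr$doseFraction * sum(kermaBins)

    muW <- massAttenuation(softTissue, e) * softTissue@density
    L <- softTissue@thickness / 10           # cm
    slab <- (1 - exp(-muW * L)) / (muW * L)  # depth-average factor
    softU <- softU +
      sum(fluence(tr$spectrum) * e * .muEn("water", e) * slab)
  }
  frac <- softU / kermaU
  new("DoseResult",
      surfaceKerma = measuredSurfaceKerma,
      transmittedFraction = frac,
      keratinFluxFraction = fluxNum / fluxDen,
      keratinDoseFraction = kerKerma / kermaU,
      softTissueDose = measuredSurfaceKerma * frac,
      irradiatedFraction = NA_real_, effectiveDose = NA_real_,
      kermaToEffective = NA_real_)
}

#' Irradiated-volume fraction from exposure geometry
#'
#' Beam footprint area x irradiated depth, divided by the specimen prism
#' volume -- always computed from the supplied geometry, never silently
#' overridden. For the trial's printed dimensions (15 x 15 mm footprint,
#' 20 mm depth, 100 x 20 x 20 mm specimen) this gives 0.1125; the trial's
#' printed 4.5% is available separately as [PAPER_F_IRR].
#'
#' @param geom A [GeometrySpec-class].
#' @return Dimensionless fraction in (0, 1].
#' @examples
#' irradiatedFraction(geometrySpec())   # 0.1125
#' @export
irradiatedFraction <- function(geom) {
  stopifnot(is(geom, "GeometrySpec"))
  validObject(geom)
  prod(geom@beamFootprint) * geom@irradiatedDepth / prod(geom@specimenDims)
}

#' Effective dose from localised soft-tissue dose
#'
#' The exact product: soft-tissue dose (mGy) x irradiated-volume fraction x
#' kerma-to-effective conversion (mSv per mGy, default 1.0).
#'
#' @param softTissueDoseMgy Localised soft-tissue absorbed dose, mGy.
#' @param f Irradiated-volume fraction in `[0, 1]`.
#' @param kermaToEffective Conversion factor, mSv per mGy; default 1.0.
#' @return Effective dose in mSv (unrounded; reporting rounds half-up to one
#'   decimal).
#' @examples
#' effectiveDose(71, PAPER_F_IRR)   # 3.195
#' @export
effectiveDose <- function(softTissueDoseMgy, f, kermaToEffective = 1.0) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  softTissueDoseMgy * f * kermaToEffective
}

#' Fill the effective-dose fields of a DoseResult
#'
#' @param result A [DoseResult-class] from [softTissueDose()].
#' @param f Irradiated-volume fraction; default the printed [PAPER_F_IRR].
#' @param kermaToEffective mSv per mGy; default 1.0.
#' @return The completed [DoseResult-class].
#' @examples
#' withEffectiveDose(softTissueDose(geoChemProtocol()))
#' @export
withEffectiveDose <- function(result, f = PAPER_F_IRR, kermaToEffective = 1.0) {
  stopifnot(is(result, "DoseResult"))
  result@irradiatedFraction <- f
  result@kermaToEffective <- kermaToEffective
  result@effectiveDose <- effectiveDose(result@softTissueDose, f,
                                        kermaToEffective)
  result
}

#' Combined whole-trial exposure
#'
#' Sum of the CT scan bound and the pXRF effective dose, both in mSv.
#'
#' @param ctDoseMsv CT exposure bound; default 5 (manufacturer's
#'   conservative per-scan bound).
#' @param pxrfEffectiveMsv pXRF effective dose in mSv.
#' @return Total exposure in mSv.
#' @examples
#' combinedExposure(5, 3.2)   # 8.2
#' @export
combinedExposure <- function(ctDoseMsv = 5, pxrfEffectiveMsv) {
  if (ctDoseMsv < 0 || pxrfEffectiveMsv < 0) stop("doses must be >= 0")
  ctDoseMsv + pxrfEffectiveMsv
}

#' Exposure time of a feature crossing the CT beam curtain
#'
#' Beam width divided by belt speed, converted to milliseconds: a 2 mm
#' feature crossing a 2 mm curtain at 0.5 m/s is exposed for 4 ms.
#'
#' @param beamWidthMm Beam width in mm (> 0).
#' @param beltSpeedMs Belt speed in m/s (> 0).
#' @return Exposure time in ms.
#' @examples
#' sliceExposureTime(2, 0.5)   # 4
#' @export
sliceExposureTime <- function(beamWidthMm, beltSpeedMs) {
  if (beamWidthMm <= 0 || beltSpeedMs <= 0)
    stop("beam width and belt speed must be > 0")
  beamWidthMm / beltSpeedMs   # mm / (m/s) = ms
}

#' Summarise scintillator readings per depth
#'
#' Means over the non-missing specimen rows at each depth, with control rows
#' excluded, reported both in the instrument's microsievert and in mSv
#' (rounded half-up to one decimal for the reporting column).
#'
#' @param table data.frame with columns `treatment` and one or more
#'   `*_uSv` reading columns; rows whose treatment contains "Control"
#'   (case-insensitive) are excluded from specimen means.
#' @return data.frame with one row per depth: `depth`, `n`, `mean_uSv`,
#'   `mean_mSv`, `mean_mSv_reported`.
#' @examples
#' summarizeScintillator(loadFixture("table3"))
#' @export
summarizeScintillator <- function(table) {
  stopifnot(is.data.frame(table), "treatment" %in% colnames(table))
  cols <- grep("_uSv$", colnames(table), value = TRUE)
  if (length(cols) == 0L) stop("no *_uSv reading columns found")
  spec <- !grepl("control", table$treatment, ignore.case = TRUE)
  out <- lapply(cols, function(cl) {
    v <- table[[cl]][spec]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      stop("all specimen entries missing at depth ", cl)
    data.frame(depth = sub("_uSv$", "", cl), n = length(v),
               mean_uSv = mean(v), mean_mSv = mean(v) / 1000,
               mean_mSv_reported = roundHalfUp(mean(v) / 1000, 1))
  })
  do.call(rbind, out)
}
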