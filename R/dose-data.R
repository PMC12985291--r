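# Embedded attenuation data and standard material definitions.

.doseCache <- new.env(parent = emptyenv())

.muTable <- function() {
  if (is.null(.doseCache$mu)) {
    .doseCache$mu <- utils::read.csv(
      system.file("extdata", "coefficients", "mass_attenuation.csv",
                  package = "wildtrace", mustWork = TRUE),
      comment.char = "#")
  }
  .doseCache$mu
}

.muEnTable <- function() {
  if (is.null(.doseCache$muen)) {
    .doseCache$muen <- utils::read.csv(
      system.file("extdata", "coefficients", "mass_energy_absorption.csv",
                  package = "wildtrace", mustWork = TRUE),
      comment.char = "#")
  }
  .doseCache$muen
}

# elemental mu/rho at given energies (keV), log-log interpolated
.elementMu <- function(element, energy) {
  tab <- .muTable()
  if (!element %in% colnames(tab))
    stop("element missing from the embedded attenuation tables: ", element)
  loglogInterp(tab$energy_keV, tab[[element]], energy)
}

# mu_en/rho for "air" or "water"
.muEn <- function(medium, energy) {
  tab <- .muEnTable()
  if (!medium %in% colnames(tab)) stop("unknown medium: ", medium)
  loglogInterp(tab$energy_keV, tab[[medium]], energy)
}

#' The keratin scale layer
#'
#' Average keratin composition C27 H57 N8 O17 S1 at 1.32 g/cm^3; the default
#' thickness is the 0.5 mm scale layer of the dosimetry model.
#'
#' @param thickness Layer thickness in mm.
#' @return A [MaterialComposition-class].
#' @examples
#' massFractions(keratinLayer())
#' @export
keratinLayer <- function(thickness = 0.5) {
  materialComposition(c(C = 27, H = 57, N = 8, O = 17, S = 1),
                      density = 1.32, thickness = thickness)
}

#' A water layer (soft-tissue surrogate)
#'
#' @param thickness Layer thickness in mm; default the 20 mm soft-tissue
#'   depth of the specimen model.
#' @return A [MaterialComposition-class].
#' @examples
#' waterLayer()
#' @export
waterLayer <- function(thickness = 20) {
  materialComposition(c(H = 2, O = 1), density = 1.0, thickness = thickness)
}

#' Printed irradiated-volume fraction of the trial's exposure geometry
#'
#' The trial reports an irradiated-volume fraction of approximately 4.5% for
#' its 15 x 15 x 20 mm irradiated column inside a 100 x 20 x 20 mm specimen
#' prism. Note that the fraction computed honestly from those dimensions is
#' 4500/40000 = 0.1125 (see [irradiatedFraction()]); the two statements are
#' arithmetically incompatible, so the printed value is exposed here as an
#' explicit named constant and is never silently substituted for the
#' geometric computation.
#'
#' @format A number, 0.045.
#' @examples
#' PAPER_F_IRR
#' @export
PAPER_F_IRR <- 0.045

#' Mass attenuation coefficient of a material
#'
#' Mixture rule: the mass-fraction-weighted sum of elemental mass attenuation
#' coefficients, with mass fractions derived from the chemical formula and
#' standard atomic weights.
#'
#' @param material A [MaterialComposition-class].
#' @param energy Photon energy (keV), scalar or vector; must lie inside the
#'   embedded table range.
#' @return mu/rho in cm^2/g, same length as `energy`.
#' @examples
#' massAttenuation(keratinLayer(), c(10, 20, 40))
#' @export
massAttenuation <- function(material, energy) {
  stopifnot(is(material, "MaterialComposition"))
  mf <- massFractions(material)
  mus <- vapply(names(mf), function(el) .elementMu(el, energy),
                numeric(length(energy)))
  if (length(energy) == 1L) sum(mus * mf) else as.numeric(mus %*% mf)
}
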