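# Shipped fixtures encoding the trial's printed tables.

.fixtureFiles <- c(
  table1 = "table1.csv",
  table2_calls = "table2_calls_synthetic.csv",
  table3 = "table3.csv",
  beams = "beams.csv",
  seizures = "seizures_synthetic.csv"
)

#' Load a shipped fixture table
#'
#' Typed access to the fixture tables shipped with the package:
#' \describe{
#'   \item{`table1`}{Per-consignment detection outcomes of the screening
#'     trial (18 consignments, 48 parcels) with Successful/Partial/Failed
#'     outcomes and detected-parcel numerators for both algorithms.}
#'   \item{`table2_calls`}{Per-specimen provenance calls equivalent to the
#'     trial's published summary counts (10 + 23 specimens). Only the label
#'     counts are published; the per-specimen ensemble means/SDs in this
#'     fixture are synthetic reconstructions (hence the `_synthetic` file
#'     name), and the `label` column is recomputed through
#'     [applyUndeterminedRule()] on deterministic 100-model probability
#'     vectors (see [ensembleProbsFor()]).}
#'   \item{`table3`}{Scintillator readings (microsievert) per treatment;
#'     the unmeasured cell is `NA`.}
#'   \item{`beams`}{The three-beam pXRF protocol as [BeamSpec-class]s.}
#'   \item{`seizures`}{Synthetic seizure register whose per-species counts
#'     follow the trial report's printed values.}
#' }
#'
#' @param name One of `"table1"`, `"table2_calls"`, `"table3"`, `"beams"`,
#'   `"seizures"`.
#' @return A data.frame, except `"beams"` which returns a list of
#'   [BeamSpec-class] objects.
#' @examples
#' nrow(loadFixture("table1"))
#' @export
loadFixture <- function(name) {
  if (!name %in% names(.fixtureFiles))
    stop("unknown fixture: ", name, " (available: ",
         paste(names(.fixtureFiles), collapse = ", "), ")")
  path <- system.file("extdata", "fixtures", .fixtureFiles[[name]],
                      package = "wildtrace", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  switch(name,
    table1 = tab,
    table3 = tab,
    seizures = tab,
    beams = lapply(seq_len(nrow(tab)), function(i) {
      beamSpec(tab$voltage_kV[i], tab$current_uA[i],
               if (is.na(tab$filter_element[i]) || tab$filter_element[i] == "")
                 NA_character_ else tab$filter_element[i],
               tab$filter_mm[i], tab$duration_s[i])
    }),
    table2_calls = {
      lbl <- vapply(seq_len(nrow(tab)), function(i)
        applyUndeterminedRule(
          ensembleProbsFor(tab$mean_wild[i], tab$sd_wild[i])), character(1))
      if (!identical(lbl, tab$label))
        stop("fixture labels inconsistent with the abstention rule")
      tab$label <- lbl
      tab
    })
}

#' Deterministic ensemble probability vector with exact mean and SD
#'
#' Reconstructs a 100-model wild-probability vector for one specimen from
#' its summary mean and standard deviation: a standardised symmetric
#' equally-spaced grid scaled to the requested moments. Deterministic, no
#' RNG involved; used to expand the synthetic provenance-call fixture into
#' inputs for [applyUndeterminedRule()].
#'
#' @param mean Ensemble mean wild probability.
#' @param sd Ensemble standard deviation.
#' @param nModels Ensemble size; default 100.
#' @return Numeric vector of length `nModels` in `[0, 1]` with sample mean
#'   `mean` and sample SD `sd`.
#' @examples
#' p <- ensembleProbsFor(0.82, 0.06)
#' c(mean(p), sd(p))
#' @export
ensembleProbsFor <- function(mean, sd, nModels = 100L) {
  z <- seq(-1, 1, length.out = nModels)
  z <- z / stats::sd(z)
  p <- mean + sd * z
  if (any(p < 0 | p > 1))
    stop("mean/sd combination leaves [0, 1]; choose a smaller sd")
  p
}
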