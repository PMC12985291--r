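# Trial-level statistics: detection-rate aggregation, the one-tailed
# two-proportion z-test, the provenance abstention rule and seizure tallies.

.algoColumn <- function(records, algorithm) {
  key <- tolower(gsub("[^A-Za-z0-9]", "", algorithm))   # "AT.2" -> "at2"
  col <- paste0(key, "_detected")
  if (!col %in% colnames(records))
    stop("unknown algorithm: ", algorithm)
  col
}

#' Overall detection rate of an algorithm
#'
#' Sums detected-parcel counts (Successful and Partial numerators) and parcel
#' totals over consignment records, reporting the percentage to two decimals.
#'
#' @param records data.frame of consignment records with columns
#'   `consignment`, `n_parcels` and one `<algo>_detected` count column per
#'   algorithm (see [loadFixture()] `"table1"`).
#' @param algorithm Algorithm name, e.g. `"AT.2"` or `"AT3"`.
#' @return List with `detected`, `total` and `percent`.
#' @examples
#' detectionRate(loadFixture("table1"), "AT.3")
#' @export
detectionRate <- function(records, algorithm) {
  col <- .algoColumn(records, algorithm)
  if (any(records[[col]] < 0 | records[[col]] > records$n_parcels))
    stop("detected counts must lie in [0, n_parcels]")
  detected <- sum(records[[col]])
  total <- sum(records$n_parcels)
  list(detected = detected, total = total,
       percent = roundHalfUp(100 * detected / total, 2))
}

#' Consignment-level outcome category
#'
#' All parcels detected: Successful; none: Failed; otherwise Partial.
#'
#' @param detected Detected-parcel count.
#' @param nParcels Parcels in the consignment.
#' @return `"Successful"`, `"Partial"` or `"Failed"`.
#' @examples
#' consignmentOutcome(2, 4)
#' @export
consignmentOutcome <- function(detected, nParcels) {
  if (detected < 0 || detected > nParcels || nParcels <= 0)
    stop("need 0 <= detected <= nParcels and nParcels > 0")
  if (detected == nParcels) "Successful"
  else if (detected == 0) "Failed"
  else "Partial"
}

#' One-tailed two-proportion z-test (pooled variance)
#'
#' Tests the null that the second proportion is not higher than the first,
#' with the pooled-variance statistic and no continuity correction:
#' `z = (x2/n2 - x1/n1) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` where
#' `phat = (x1 + x2) / (n1 + n2)`; the p-value is the upper tail of the
#' standard normal at `z`.
#'
#' @param x1,n1 Successes and trials of the first (baseline) proportion.
#' @param x2,n2 Successes and trials of the second proportion.
#' @return A [TestResult-class].
#' @examples
#' pValue(twoProportionZTest(10, 48, 27, 48))   # ~0.00018
#' @export
twoProportionZTest <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("n1 and n2 must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("need 0 <= xi <= ni")
  phat <- (x1 + x2) / (n1 + n2)
  if (phat == 0 || phat == 1)
    stop("degenerate pooled proportion (0 or 1)")
  z <- (x2 / n2 - x1 / n1) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  new("TestResult", zStatistic = z,
      pValue = stats::pnorm(z, lower.tail = FALSE),
      tail = "second proportion greater",
      estimates = c(p1 = x1 / n1, p2 = x2 / n2))
}

#' Ensemble abstention rule for provenance calls
#'
#' Given one specimen's per-model probabilities of wild origin, the call is
#' `wild` only when the ensemble mean reaches the threshold AND the
#' mean +/- SD band clears the complementary (captive) band; `captive` under
#' the symmetric condition; otherwise `undetermined`. The complementary
#' class's dispersion equals the wild dispersion because per-model captive
#' probabilities are one minus the wild probabilities.
#'
#' @param ensembleProbs Numeric vector (length >= 2) of per-model wild
#'   probabilities in `[0, 1]`.
#' @param threshold Abstention threshold; default 0.65.
#' @return `"wild"`, `"captive"` or `"undetermined"`.
#' @examples
#' applyUndeterminedRule(rep(0.9, 100))
#' @export
applyUndeterminedRule <- function(ensembleProbs, threshold = 0.65) {
  if (length(ensembleProbs) < 2L)
    stop("at least 2 ensemble models are required")
  if (any(ensembleProbs < 0 | ensembleProbs > 1))
    stop("probabilities must lie in [0, 1]")
  mW <- mean(ensembleProbs)
  sW <- stats::sd(ensembleProbs)
  mC <- 1 - mW
  sC <- sW
  if (mW >= threshold && (mW - sW) > (mC + sC)) "wild"
  else if (mC >= threshold && (mC - sC) > (mW + sW)) "captive"
  else "undetermined"
}

#' Per-species provenance summary
#'
#' Counts and percentages of wild / captive / undetermined calls per species.
#' Percentages use truncation toward zero (`floor(100 k / n)`), the
#' convention that reproduces the trial's printed summary table cells
#' exactly (8/23 -> 34, 9/23 -> 39).
#'
#' @param calls data.frame with columns `species` and `label` (values
#'   wild/captive/undetermined).
#' @return data.frame with one row per species x label: `species`, `label`,
#'   `count`, `n`, `percent`.
#' @examples
#' provenanceSummary(loadFixture("table2_calls"))
#' @export
provenanceSummary <- function(calls) {
  stopifnot(all(c("species", "label") %in% colnames(calls)))
  labs <- c("wild", "captive", "undetermined")
  if (!all(calls$label %in% labs)) stop("unknown labels present")
  out <- lapply(split(calls, calls$species), function(g) {
    if (nrow(g) == 0L) stop("empty call list for a species")
    data.frame(species = g$species[1], label = labs,
               count = as.integer(table(factor(g$label, labs))),
               n = nrow(g),
               percent = floor(100 * as.integer(table(factor(g$label, labs))) /
                                 nrow(g)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Seizure register tallies
#'
#' Per-species counts, per-species consignment frequencies, and outcome
#' percentages (rounded half-up to whole percent over records with a known
#' outcome).
#'
#' @param records data.frame with columns `specimen_id`, `species`,
#'   `consignment` and `outcome` (one of rehomed / euthanized /
#'   dead_on_arrival).
#' @return List with `nAnimals`, `nConsignments`, `speciesCounts` (sorted
#'   decreasing), `consignmentsPerSpecies` and `outcomePercent`.
#' @examples
#' seizureSummary(loadFixture("seizures"))
#' @export
seizureSummary <- function(records) {
  if (nrow(records) == 0L) {
    return(list(nAnimals = 0L, nConsignments = 0L,
                speciesCounts = integer(0), consignmentsPerSpecies = integer(0),
                outcomePercent = numeric(0)))
  }
  stopifnot(all(c("species", "consignment", "outcome") %in% colnames(records)))
  sc <- sort(table(records$species), decreasing = TRUE)
  cps <- vapply(split(records$consignment, records$species),
                function(x) length(unique(x)), integer(1))
  oc <- table(records$outcome)
  list(nAnimals = nrow(records),
       nConsignments = length(unique(records$consignment)),
       speciesCounts = sc,
       consignmentsPerSpecies = sort(cps, decreasing = TRUE),
       outcomePercent = roundHalfUp(100 * as.numeric(oc) / sum(oc), 0) |>
         stats::setNames(names(oc)))
}
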