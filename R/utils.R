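# Internal helpers shared across modules.

# standard atomic weights (g/mol) for the elements the dose model supports
.atomicWeights <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    Al = 26.982, Ar = 39.948, Cu = 63.546)

#' The four blob classes
#'
#' The three wildlife subcategories plus a rejection class for clutter blobs,
#' in the canonical column order used by every classifier in the package.
#'
#' @return Character vector of length 4.
#' @examples
#' blobClasses()
#' @export
blobClasses <- function() c("Lizard", "Fish", "Birds", "NotWildlife")

#' @rdname blobClasses
#' @export
wildlifeClasses <- function() c("Lizard", "Fish", "Birds")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps fixed internal constructions
# (e.g. the embedding projection) independent of user RNG state.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# log-log interpolation of tabulated coefficients; the convention used by
# standard attenuation-coefficient compilations
loglogInterp <- function(energyTab, valueTab, energy) {
  if (any(energy < min(energyTab)) || any(energy > max(energyTab)))
    stop(sprintf("energy outside table range [%.3g, %.3g] keV",
                 min(energyTab), max(energyTab)))
  exp(stats::approx(log(energyTab), log(valueTab), log(energy),
                    ties = "ordered")$y)
}

# shift a 3D logical array by an integer offset, padding with FALSE
shiftMask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { src[[a]] <- seq_len(d[a] - o); dst[[a]] <- src[[a]] + o }
    else        { src[[a]] <- seq(1 - o, d[a]);  dst[[a]] <- src[[a]] + o }
    if (length(src[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    mask[src[[1]], src[[2]], src[[3]]]
  out
}

# integer offsets of a discrete ball of given radius (voxels)
ballOffsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

# validate a probability vector over blobClasses()
checkClassScores <- function(p) {
  stopifnot(length(p) == 4L, all(p >= 0), all(p <= 1),
            abs(sum(p) - 1) < 1e-9)
  invisible(p)
}

# round half-up at `digits` decimals; reporting convention for printed doses
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
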