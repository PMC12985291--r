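# AT.3 dense head: five fully connected layers and a softmax output over the
# concatenated MIP embeddings. Implemented directly with matrix arithmetic
# (ReLU hidden activations, cross-entropy loss, Adam updates), seeded and
# fully deterministic.

.at3Forward <- function(W, x) {
  # x: n x d matrix; returns list of activations, last entry = softmax probs
  acts <- list(x)
  nl <- length(W$weights)
  for (l in seq_len(nl)) {
    z <- acts[[l]] %*% W$weights[[l]] +
      matrix(W$biases[[l]], nrow(acts[[l]]), length(W$biases[[l]]), byrow = TRUE)
    acts[[l + 1]] <- if (l < nl) pmax(z, 0) else .softmax(z)
  }
  acts
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the AT.3 dense head
#'
#' Exactly five fully connected hidden layers followed by a softmax output
#' layer, trained with cross-entropy loss and Adam on the 480-dimensional
#' concatenated projection embeddings. Initialisation and minibatch order are
#' seeded; the per-epoch loss history is retained.
#'
#' @param embeddings Numeric matrix (n x 480) of triplet embeddings.
#' @param labels Factor or character of blob classes.
#' @param layerSizes Integer vector of exactly five hidden-layer widths;
#'   default `c(320, 160, 80, 40, 20)`.
#' @param seed Integer seed.
#' @param epochs Training epochs; default 300.
#' @param learningRate Adam step size; default 1e-3.
#' @param weightDecay L2 penalty; default 1e-4.
#' @return An [AT3Model-class].
#' @examples
#' x <- rbind(matrix(rnorm(50 * 480), 50), matrix(rnorm(50 * 480, 2), 50))
#' m <- at3Train(x, rep(c("Lizard", "NotWildlife"), each = 50), epochs = 20)
#' @export
at3Train <- function(embeddings, labels, layerSizes = c(320L, 160L, 80L, 40L, 20L),
                     seed = 1L, epochs = 300L, learningRate = 1e-3,
                     weightDecay = 1e-4) {
  embeddings <- as.matrix(embeddings)
  if (ncol(embeddings) != 480L)
    stop("embeddings must have 480 columns (3 x 160)")
  if (length(layerSizes) != 5L)
    stop("exactly five fully connected hidden layers are required")
  labels <- factor(labels)
  classes <- levels(labels)
  y <- as.integer(labels)
  n <- nrow(embeddings)
  sizes <- c(480L, as.integer(layerSizes), length(classes))

  set.seed(seed)
  weights <- biases <- vector("list", length(sizes) - 1L)
  for (l in seq_along(weights)) {
    fanIn <- sizes[l]
    weights[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                        sqrt(2 / fanIn)),
                           sizes[l], sizes[l + 1])
    biases[[l]] <- rep(0, sizes[l + 1])
  }
  W <- list(weights = weights, biases = biases)

  # feature standardisation (stored for prediction)
  mu <- colMeans(embeddings)
  sg <- apply(embeddings, 2, stats::sd)
  sg[sg == 0 | is.na(sg)] <- 1
  X <- sweep(sweep(embeddings, 2, mu), 2, sg, "/")

  oneHot <- matrix(0, n, length(classes))
  oneHot[cbind(seq_len(n), y)] <- 1

  mW <- lapply(W$weights, function(w) w * 0); vW <- mW
  mB <- lapply(W$biases, function(b) b * 0); vB <- mB
  b1 <- 0.9; b2 <- 0.999; epsl <- 1e-8
  history <- numeric(epochs)
  step <- 0
  batch <- min(64L, n)

  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      acts <- .at3Forward(W, X[idx, , drop = FALSE])
      nl <- length(W$weights)
      delta <- (acts[[nl + 1]] - oneHot[idx, , drop = FALSE]) / length(idx)
      step <- step + 1
      corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
      for (l in rev(seq_len(nl))) {
        wOld <- W$weights[[l]]
        gW <- crossprod(acts[[l]], delta) + weightDecay * wOld
        gB <- colSums(delta)
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
        vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
        W$weights[[l]] <- wOld -
          learningRate * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + epsl)
        W$biases[[l]] <- W$biases[[l]] -
          learningRate * (mB[[l]] / corr1) / (sqrt(vB[[l]] / corr2) + epsl)
        if (l > 1L)
          delta <- (delta %*% t(wOld)) * (acts[[l]] > 0)
      }
    }
    probs <- .at3Forward(W, X)[[length(W$weights) + 1]]
    history[ep] <- -mean(log(pmax(probs[cbind(seq_len(n), y)], 1e-12)))
  }

  new("AT3Model", weights = c(W, list(mu = mu, sigma = sg)),
      layerSizes = as.integer(layerSizes), classes = classes,
      history = history,
      manifest = list(format = "wildtrace-at3/1", seed = seed, n_train = n,
                      epochs = epochs, backend = "pooled_rp",
                      package_version = as.character(utils::packageVersion("wildtrace"))))
}

#' Classify triplet embeddings with an AT.3 model
#'
#' @param model An [AT3Model-class].
#' @param embeddings A single 480-vector or an n x 480 matrix.
#' @return Matrix of class probabilities over [blobClasses()] (rows sum to 1).
#' @examples
#' # see at3Train
#' @export
at3Classify <- function(model, embeddings) {
  stopifnot(is(model, "AT3Model"))
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1)
  if (ncol(embeddings) != 480L)
    stop(sprintf("embedding length %d does not match the 480-d input",
                 ncol(embeddings)))
  X <- sweep(sweep(embeddings, 2, model@weights$mu), 2, model@weights$sigma, "/")
  W <- list(weights = model@weights$weights, biases = model@weights$biases)
  p <- .at3Forward(W, X)[[length(W$weights) + 1]]
  colnames(p) <- model@classes
  .expandScores(p, model@classes)
}
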