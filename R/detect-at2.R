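# AT.2: bagged decision-tree (random forest) blob classifier.

#' Train the AT.2 random-forest classifier
#'
#' Fits a random forest (bootstrap-sampled decision trees whose class votes
#' are averaged at prediction time) over hand-crafted blob features.
#' Deterministic for a fixed seed.
#'
#' @param features Numeric matrix or data.frame of blob features, columns
#'   named as in [blobFeatureNames()].
#' @param labels Factor or character of blob classes (see [blobClasses()]).
#' @param nTrees Number of trees; default 500.
#' @param seed Integer seed.
#' @return An [AT2Model-class].
#' @examples
#' x <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
#' colnames(x) <- c("f1", "f2")
#' m <- at2Train(x, rep(c("Lizard", "NotWildlife"), each = 10), nTrees = 25)
#' @export
at2Train <- function(features, labels, nTrees = 500L, seed = 1L) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("training corpus must contain at least 2 classes")
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length")
  set.seed(seed)
  fit <- randomForest::randomForest(x = features, y = labels, ntree = nTrees)
  new("AT2Model", fit = fit, featureNames = colnames(features),
      classes = levels(labels),
      manifest = list(format = "wildtrace-at2/1", seed = seed,
                      n_train = nrow(features), n_trees = nTrees,
                      package_version = as.character(utils::packageVersion("wildtrace"))))
}

#' Classify blob features with an AT.2 model
#'
#' @param model An [AT2Model-class].
#' @param features A single feature vector, or a matrix/data.frame of rows.
#' @return Matrix of class probabilities (rows sum to 1) with one column per
#'   class in [blobClasses()] (absent-in-training classes get probability 0).
#' @examples
#' x <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
#' colnames(x) <- c("f1", "f2")
#' m <- at2Train(x, rep(c("Lizard", "NotWildlife"), each = 10), nTrees = 25)
#' at2Classify(m, c(f1 = 0, f2 = 0))
#' @export
at2Classify <- function(model, features) {
  stopifnot(is(model, "AT2Model"))
  if (is.null(dim(features))) {
    if (length(features) != length(model@featureNames))
      stop(sprintf("feature length %d does not match training length %d",
                   length(features), length(model@featureNames)))
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, model@featureNames))
  }
  features <- as.data.frame(features)
  if (ncol(features) != length(model@featureNames))
    stop(sprintf("feature length %d does not match training length %d",
                 ncol(features), length(model@featureNames)))
  colnames(features) <- model@featureNames
  p <- stats::predict(model@fit, features, type = "prob")
  .expandScores(p, model@classes)
}

# expand a probability matrix to the canonical 4-class column set
.expandScores <- function(p, trainedClasses) {
  out <- matrix(0, nrow(p), length(blobClasses()),
                dimnames = list(NULL, blobClasses()))
  known <- intersect(colnames(p), blobClasses())
  out[, known] <- p[, known]
  extra <- setdiff(colnames(p), blobClasses())
  if (length(extra))   # classes outside the canonical set fold into rejection
    out[, "NotWildlife"] <- out[, "NotWildlife"] + rowSums(p[, extra, drop = FALSE])
  sw <- rowSums(out)
  out / ifelse(sw == 0, 1, sw)
}
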