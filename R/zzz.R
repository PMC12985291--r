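#' wildtrace: concealed-wildlife screening, dosimetry and trial statistics
#'
#' Computational spine of an end-to-end wildlife-trafficking screening
#' workflow: synthetic 3D parcel phantoms, organic segmentation and blob
#' classification (a random-forest feature pipeline and a MIP-embedding
#' dense-head pipeline), an analytic pXRF spectrum/dosimetry model for
#' lizards behind a keratin scale layer, and the trial-level statistics.
#'
#' @keywords internal
#' @import methods
#' @importFrom stats approx pnorm rnorm runif sd setNames predict
#' @importFrom utils read.csv write.csv modifyList packageVersion
#' @importFrom jsonlite write_json toJSON read_json
#' @importFrom igraph make_empty_graph add_edges components
#' @importFrom randomForest randomForest
#' @importFrom RNifti readNifti writeNifti pixdim
#' @importFrom EBImage resize
#' @importFrom yaml read_yaml
#' @rawNamespace exportMethods(show)
"_PACKAGE"
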