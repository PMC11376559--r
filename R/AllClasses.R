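#' @import methods
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

setClassUnion("array_OR_NULL", c("array", "NULL"))

#' SpatialSection: a spatial transcriptomics section
#'
#' Container for one spot-based spatial transcriptomics section: a gene x
#' spot count matrix (standard Bioconductor orientation), per-spot 2-D
#' coordinates, and an optional registered H&E tissue image. Extends
#' \linkS4class{SingleCellExperiment}, so all of its assay/colData/rowData
#' machinery applies.
#'
#' @slot spatialCoords numeric matrix with one row per spot and columns
#'   \code{pxl_row}, \code{pxl_col} (pixel coordinates, row/column order).
#' @slot tissueImage optional H x W x 3 numeric array with values in
#'   0--255, or \code{NULL} when no image is available.
#'
#' @seealso [SpatialSection()] for the constructor, [readVisium()] to build
#'   one from a Space Ranger directory, [simulateSection()] for synthetic
#'   sections.
#' @export
setClass("SpatialSection",
  contains = "SingleCellExperiment",
  slots = c(spatialCoords = "matrix", tissueImage = "array_OR_NULL")
)

setValidity("SpatialSection", function(object) {
  msg <- NULL
  cts <- SummarizedExperiment::assay(object, "counts")
  if (nrow(object@spatialCoords) != ncol(object))
    msg <- c(msg, "spatialCoords must have one row per spot")
  if (ncol(object@spatialCoords) != 2L)
    msg <- c(msg, "spatialCoords must have exactly 2 columns")
  if (any(cts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "spot identifiers (colnames) must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers (rownames) must be unique")
  img <- object@tissueImage
  if (!is.null(img) && (length(dim(img)) != 3L || dim(img)[3] != 3L))
    msg <- c(msg, "tissueImage must be an H x W x 3 array")
  if (is.null(msg)) TRUE else msg
})

#' SpotFeatures: PCA-reduced expression features
#'
#' The node-attribute matrix X shared by all graph views: spots in rows,
#' retained principal components in columns, derived from library-size
#' normalised, log-transformed, scaled highly variable genes.
#'
#' @slot X numeric matrix, spots x components; rownames are spot ids.
#' @slot hvgMask named logical vector over the filtered gene set; TRUE for
#'   genes selected as highly variable.
#' @slot pcaComponents integer, number of retained components
#'   (\code{ncol(X)}).
#'
#' @seealso [preprocessSection()]
#' @export
setClass("SpotFeatures",
  slots = c(X = "matrix", hvgMask = "logical", pcaComponents = "integer")
)

setValidity("SpotFeatures", function(object) {
  msg <- NULL
  if (object@pcaComponents != ncol(object@X))
    msg <- c(msg, "pcaComponents must equal ncol(X)")
  if (!all(is.finite(object@X)))
    msg <- c(msg, "X must be finite")
  if (is.null(msg)) TRUE else msg
})

#' ViewGraph: a binary spot-similarity graph for one view
#'
#' Symmetric binary adjacency over spots for one of the three views
#' (spatial proximity, expression similarity, histology similarity). Stored
#' sparse; the diagonal is zero -- self-loops are added only inside the
#' model as G' = G + I.
#'
#' @slot adj \code{dgCMatrix}, symmetric, entries in \{0, 1\}, zero diagonal.
#' @slot viewName one of \code{"spatial"}, \code{"expression"},
#'   \code{"histology"}.
#' @slot k the neighbours-per-spot parameter used to build the graph.
#'
#' @seealso [buildSpatialGraph()], [buildExpressionGraph()],
#'   [buildHistologyGraph()]
#' @export
setClass("ViewGraph",
  slots = c(adj = "dgCMatrix", viewName = "character", k = "integer")
)

setValidity("ViewGraph", function(object) {
  msg <- NULL
  a <- object@adj
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (!Matrix::isSymmetric(a)) msg <- c(msg, "adjacency must be symmetric")
  if (length(a@x) && !all(a@x %in% c(0, 1)))
    msg <- c(msg, "adjacency entries must be 0/1")
  if (any(Matrix::diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
  if (!object@viewName %in% c("spatial", "expression", "histology"))
    msg <- c(msg, "viewName must be spatial/expression/histology")
  if (is.null(msg)) TRUE else msg
})

#' HistologyFeatures: per-spot texture and intensity features
#'
#' Nine handcrafted image features per spot: six gray-level co-occurrence
#' (GLCM) texture statistics of the CLAHE-equalised grayscale patch --
#' contrast, dissimilarity, homogeneity, angular second moment (ASM),
#' entropy, correlation -- plus the mean R, G, B intensities of the raw
#' patch.
#'
#' @slot F numeric matrix, spots x 9; colnames are the feature names.
#'
#' @seealso [extractHistologyFeatures()], [buildHistologyGraph()]
#' @export
setClass("HistologyFeatures", slots = c(F = "matrix"))

setValidity("HistologyFeatures", function(object) {
  msg <- NULL
  if (!all(is.finite(object@F))) msg <- c(msg, "features must be finite")
  need <- c("contrast", "dissimilarity", "homogeneity", "ASM", "entropy",
            "correlation", "mean_R", "mean_G", "mean_B")
  if (!identical(colnames(object@F), need))
    msg <- c(msg, paste("colnames must be:", paste(need, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' ModelState: all trainable parameters of the multi-view model
#'
#' @slot views named list, one element per active view; each view holds
#'   \code{enc} and \code{dec} lists of layers, each layer a list with the
#'   weight matrix \code{W} and the attention parameter vectors \code{ts}
#'   (own node) and \code{tr} (neighbour node).
#' @slot beta numeric view-fusion weights, non-negative, summing to 1.
#' @slot centroids k x d_z matrix of cluster centroids (empty before the
#'   clustering phase).
#' @slot alpha Student-t degrees of freedom of the soft assignment.
#' @slot rho per-view trade-off weights of the distribution-consistency
#'   loss.
#'
#' @export
setClass("ModelState",
  slots = c(views = "list", beta = "numeric", centroids = "matrix",
            alpha = "numeric", rho = "numeric")
)

setValidity("ModelState", function(object) {
  msg <- NULL
  if (length(object@beta) != length(object@views))
    msg <- c(msg, "beta must have one weight per view")
  if (abs(sum(object@beta) - 1) > 1e-8 || any(object@beta < 0))
    msg <- c(msg, "beta must be non-negative and sum to 1")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be positive")
  if (is.null(msg)) TRUE else msg
})

#' ViewEmbedding: per-view encoder outputs
#'
#' @slot layers list of per-layer embedding matrices H^(l) (spots x d_l).
#' @slot Z the low-dimensional view embedding (final encoder layer output).
#' @slot attention list of per-layer row-stochastic attention matrices Y
#'   (sparse on the self-looped edge pattern), or an empty list when
#'   attention is disabled.
#' @slot viewName name of the graph view the embedding belongs to.
#'
#' @export
setClass("ViewEmbedding",
  slots = c(layers = "list", Z = "matrix", attention = "list",
            viewName = "character")
)

#' DomainAssignment: soft and hard spatial-domain assignments
#'
#' @slot Z fused spot embedding (spots x d_z).
#' @slot Q Student-t soft assignment of the fused embedding (spots x k).
#' @slot Qm list of per-view soft assignments.
#' @slot P sharpened target distribution (spots x k).
#' @slot labels integer domain label per spot (argmax of P rows, 1-based).
#'
#' @export
setClass("DomainAssignment",
  slots = c(Z = "matrix", Q = "matrix", Qm = "list", P = "matrix",
            labels = "integer")
)

setValidity("DomainAssignment", function(object) {
  msg <- NULL
  if (nrow(object@Q) != nrow(object@P) || ncol(object@Q) != ncol(object@P))
    msg <- c(msg, "Q and P must have identical shapes")
  if (length(object@labels) != nrow(object@P))
    msg <- c(msg, "labels must have one entry per spot")
  if (is.null(msg)) TRUE else msg
})
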