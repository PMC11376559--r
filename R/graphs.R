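## Exact k-nearest-neighbour edge list with stable ascending-index
## tie-breaks: for each point, the k smallest Euclidean distances to the
## other points, equidistant candidates taken in index order.
knnEdges <- function(X, k) {
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 spots to build a k-NN graph")
  if (k > n - 1L) {
    warning("k (", k, ") exceeds n - 1; clipping to ", n - 1L)
    k <- n - 1L
  }
  d2 <- as.matrix(stats::dist(X))^2
  diag(d2) <- Inf
  nbr <- vapply(seq_len(n), function(i)
    order(d2[i, ], seq_len(n))[seq_len(k)], integer(k))
  list(i = rep(seq_len(n), each = k), j = as.vector(nbr), k = k)
}

## union-symmetrised binary adjacency from a directed k-NN edge list
symmetrizeUnion <- function(edges, n, viewName, k) {
  a <- Matrix::sparseMatrix(i = edges$i, j = edges$j, x = 1,
                            dims = c(n, n))
  a <- a + Matrix::t(a)
  a@x[] <- 1
  methods::new("ViewGraph", adj = methods::as(a, "generalMatrix"),
               viewName = viewName, k = as.integer(k))
}

#' Build the spatial-adjacency view graph
#'
#' For each spot, edges to its \code{k} nearest spots by Euclidean
#' distance between spatial coordinates; symmetrised by union (an edge is
#' kept if either endpoint ranks the other among its top \code{k}).
#'
#' @param x a [SpatialSection-class] or a spot x 2 coordinate matrix.
#' @param k neighbours per spot (default 10).
#' @return A [ViewGraph-class] with \code{viewName = "spatial"}.
#' @export
buildSpatialGraph <- function(x, k = 10) {
  coords <- if (methods::is(x, "SpatialSection")) spatialCoords(x) else
    as.matrix(x)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  e <- knnEdges(coords, k)
  symmetrizeUnion(e, nrow(coords), "spatial", e$k)
}

#' Build the gene-expression-similarity view graph
#'
#' k-NN graph in a 50-dimensional expression space (the leading
#' \code{nPCsGraph} columns of the PCA features), Euclidean metric,
#' union-symmetrised.
#'
#' @param features a [SpotFeatures-class].
#' @param k neighbours per spot (default 10).
#' @param nPCsGraph dimensionality of the expression space used for the
#'   neighbour search (default 50; clipped to the available components).
#' @return A [ViewGraph-class] with \code{viewName = "expression"}.
#' @export
buildExpressionGraph <- function(features, k = 10, nPCsGraph = 50) {
  X <- featureMatrix(features)
  if (nPCsGraph > ncol(X)) {
    warning("nPCsGraph clipped to the ", ncol(X), " available components")
    nPCsGraph <- ncol(X)
  }
  e <- knnEdges(X[, seq_len(nPCsGraph), drop = FALSE], k)
  symmetrizeUnion(e, nrow(X), "expression", e$k)
}

#' Build the histology-image-similarity view graph
#'
#' Robust-scales each feature column (centre by median, scale by IQR),
#' then builds the union-symmetrised Euclidean k-NN graph.
#'
#' @param hfeat a [HistologyFeatures-class].
#' @param k neighbours per spot (default 10).
#' @return A [ViewGraph-class] with \code{viewName = "histology"}.
#' @export
buildHistologyGraph <- function(hfeat, k = 10) {
  Fs <- robustScale(hfeat@F)
  e <- knnEdges(Fs, k)
  symmetrizeUnion(e, nrow(Fs), "histology", e$k)
}

## (x - median) / IQR per column; zero-IQR columns keep scale 1
robustScale <- function(m) {
  med <- apply(m, 2L, stats::median)
  iqr <- apply(m, 2L, stats::IQR)
  if (any(iqr == 0)) {
    warning("zero interquartile range in column(s) ",
            paste(which(iqr == 0), collapse = ", "), "; scale set to 1")
    iqr[iqr == 0] <- 1
  }
  sweep(sweep(m, 2L, med), 2L, iqr, `/`)
}

#' @rdname adjacency
#' @param x a \code{ViewGraph}
#' @return \code{adjacency}: the sparse symmetric 0/1 adjacency matrix.
#' @export
setMethod("adjacency", "ViewGraph", function(x) x@adj)

#' @rdname viewName
#' @param x a \code{ViewGraph}
#' @return \code{viewName}: which view the graph encodes.
#' @export
setMethod("viewName", "ViewGraph", function(x) x@viewName)

#' @export
setMethod("show", "ViewGraph", function(object) {
  cat("ViewGraph <", object@viewName, ">: ", nrow(object@adj), " spots, ",
      length(object@adj@x) / 2, " undirected edges (k = ", object@k,
      ")\n", sep = "")
  invisible(NULL)
})

#' Export / import a view graph
#'
#' The adjacency goes to a Matrix Market file, the metadata (view name,
#' k, spot-ordering hash) to a JSON sidecar.
#'
#' @param graph a [ViewGraph-class].
#' @param path file prefix; \code{<path>.mtx} and \code{<path>.json} are
#'   written/read.
#' @return `exportViewGraph`: \code{path} invisibly; `importViewGraph`:
#'   the [ViewGraph-class].
#' @export
exportViewGraph <- function(graph, path) {
  Matrix::writeMM(adjacency(graph), paste0(path, ".mtx"))
  jsonlite::write_json(
    list(view_name = graph@viewName, k = graph@k,
         n_spots = nrow(adjacency(graph))),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname exportViewGraph
#' @export
importViewGraph <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  a <- Matrix::readMM(paste0(path, ".mtx"))
  a <- methods::as(methods::as(methods::as(a, "dMatrix"),
                               "CsparseMatrix"), "generalMatrix")
  methods::new("ViewGraph", adj = a, viewName = meta$view_name,
               k = as.integer(meta$k))
}
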