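#' Preprocess a section into spot features
#'
#' The standard pipeline feeding the model: (1) drop genes detected in
#' fewer than \code{minCells} spots; (2) library-size normalise each spot
#' to the median library size, then log1p; (3) rank genes by binned
#' normalised dispersion and keep the top \code{nHVG} highly variable
#' genes; (4) scale each gene to zero mean / unit variance; (5) PCA to
#' \code{nPCs} components. The PCA uses an exact singular value
#' decomposition with a deterministic sign convention, so the result is
#' bit-reproducible and independent of spot order (up to row permutation).
#'
#' @param section a [SpatialSection-class].
#' @param nHVG number of highly variable genes to keep (default 2000).
#' @param nPCs number of principal components to retain (default 1000;
#'   clipped with a warning to what the data can support).
#' @param minCells minimum number of spots a gene must be detected in
#'   (default 5).
#'
#' @return A [SpotFeatures-class] with \code{X} (spots x \code{nPCs}),
#'   the HVG mask over the filtered gene set, and the retained component
#'   count.
#' @examples
#' sec <- simulateSection(nRows = 8, nCols = 8, nGenes = 60, seed = 1)
#' sf <- preprocessSection(sec, nHVG = 40, nPCs = 10)
#' dim(featureMatrix(sf))
#' @export
preprocessSection <- function(section, nHVG = 2000, nPCs = 1000,
                              minCells = 5) {
  counts <- spotCounts(section)                  # spots x genes, sparse
  nSpots <- nrow(counts)
  detected <- Matrix::colSums(counts > 0)
  keep <- detected >= minCells
  if (!any(keep))
    stop("empty-data error: all genes removed by the min-cells filter")
  counts <- counts[, keep, drop = FALSE]

  ## library-size normalisation to the median library, then log1p
  lib <- Matrix::rowSums(counts)
  lib[lib == 0] <- 1
  target <- stats::median(lib)
  norm <- counts / lib * target

  ## dispersion-based HVG ranking on the normalised (pre-log) matrix
  mu <- Matrix::colMeans(norm)
  v <- colVarsSparse(norm, mu)
  disp <- ifelse(mu > 0, v / mu, 0)
  if (all(disp == 0))
    warning("zero-variance data: no highly variable genes distinguishable")
  nHVGeff <- nHVG
  if (nHVG > ncol(norm)) {
    warning("nHVG (", nHVG, ") exceeds the ", ncol(norm),
            " surviving genes; clipping")
    nHVGeff <- ncol(norm)
  }
  hvgScore <- binnedDispersion(mu, disp, nBins = 20L)
  hvgIdx <- order(hvgScore, decreasing = TRUE)[seq_len(nHVGeff)]
  hvgMask <- logical(ncol(norm))
  hvgMask[hvgIdx] <- TRUE
  names(hvgMask) <- colnames(norm)

  logm <- as.matrix(log1p(norm[, hvgMask, drop = FALSE]))

  ## per-gene scaling; zero-variance genes stay at zero
  sds <- apply(logm, 2L, stats::sd)
  sds[sds == 0] <- 1
  scaled <- scale(logm, center = TRUE, scale = sds)

  maxRank <- min(nSpots - 1L, ncol(scaled))
  if (nPCs > maxRank) {
    warning("nPCs (", nPCs, ") exceeds the available rank (", maxRank,
            "); clipping")
    nPCs <- maxRank
  }
  sv <- svd(scaled, nu = nPCs, nv = nPCs)
  ## deterministic sign: largest-|loading| entry of each right singular
  ## vector is made positive (invariant to spot order)
  flip <- vapply(seq_len(nPCs), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  X <- sweep(sv$u[, seq_len(nPCs), drop = FALSE], 2L,
             sv$d[seq_len(nPCs)] * flip, `*`)
  rownames(X) <- rownames(counts)
  colnames(X) <- paste0("PC", seq_len(nPCs))
  methods::new("SpotFeatures", X = X, hvgMask = hvgMask,
               pcaComponents = as.integer(nPCs))
}

## column variances of a sparse matrix without densifying
colVarsSparse <- function(m, mu = Matrix::colMeans(m)) {
  n <- nrow(m)
  (Matrix::colSums(m^2) - n * mu^2) / (n - 1)
}

## z-score log-dispersions within equal-frequency mean bins
binnedDispersion <- function(mu, disp, nBins = 20L) {
  score <- rep(-Inf, length(mu))
  ok <- mu > 0 & disp > 0
  if (!any(ok)) return(score)
  qs <- unique(stats::quantile(mu[ok], probs = seq(0, 1, length.out = nBins + 1)))
  bin <- cut(mu[ok], breaks = qs, include.lowest = TRUE)
  ld <- log(disp[ok])
  z <- stats::ave(ld, bin, FUN = function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) x - mean(x) else (x - mean(x)) / s
  })
  score[ok] <- z
  score
}

#' @rdname featureMatrix
#' @param x a \code{SpotFeatures}
#' @return \code{featureMatrix}: the spots x components matrix X.
#' @export
setMethod("featureMatrix", "SpotFeatures", function(x) x@X)

#' @export
setMethod("show", "SpotFeatures", function(object) {
  cat("SpotFeatures:", nrow(object@X), "spots x", object@pcaComponents,
      "components (", sum(object@hvgMask), "HVGs )\n")
  invisible(NULL)
})

#' Estimate the number of spatial domains by Louvain clustering
#'
#' Convenience used only when the caller does not supply the domain
#' count: runs Louvain community detection at default resolution on a
#' spot graph and returns the number of communities.
#'
#' @param features a [SpotFeatures-class] (used only for a consistency
#'   check on the spot count).
#' @param graph a [ViewGraph-class] over the same spots.
#' @return Number of communities (positive integer).
#' @export
estimateNDomains <- function(features, graph) {
  n <- nrow(featureMatrix(features))
  if (nrow(adjacency(graph)) != n)
    stop("graph and features cover different numbers of spots")
  if (n == 1L) return(1L)
  a <- adjacency(graph)
  if (length(a@x) == 0L) {
    warning("graph has no edges; returning one domain per spot")
    return(n)
  }
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  length(unique(igraph::membership(igraph::cluster_louvain(g))))
}

#' Export spot features as a portable text container
#'
#' Writes \code{X} as TSV (spot ids in the first column) plus a JSON
#' sidecar with the HVG names and component count.
#'
#' @param features a [SpotFeatures-class].
#' @param path output file prefix; \code{<path>.tsv} and
#'   \code{<path>.json} are written.
#' @return \code{path}, invisibly.
#' @export
exportSpotFeatures <- function(features, path) {
  X <- featureMatrix(features)
  utils::write.table(data.frame(spot_id = rownames(X), X,
                                check.names = FALSE),
                     paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(pca_components = features@pcaComponents,
         hvg = names(features@hvgMask)[features@hvgMask]),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
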