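## Per-view propagation cache: self-looped edge list (sorted by source)
## and the symmetrically normalised operator D^{-1/2} G' D^{-1/2}.
graphPrep <- function(graph) {
  a <- adjacency(graph)
  n <- nrow(a)
  gp <- a + Matrix::Diagonal(n)
  deg <- Matrix::rowSums(gp)
  dinv <- 1 / sqrt(deg)
  Pn <- Matrix::Diagonal(n, dinv) %*% gp %*% Matrix::Diagonal(n, dinv)
  tp <- methods::as(gp, "TsparseMatrix")
  o <- order(tp@i, tp@j)
  ei <- tp@i[o] + 1L
  ej <- tp@j[o] + 1L
  ## segment boundaries for fast per-node sums: ei is sorted and every
  ## node occurs (self-loops), likewise ej after reordering
  eiEnds <- cumsum(tabulate(ei, n))
  ejOrder <- order(ej, method = "radix")
  ejEnds <- cumsum(tabulate(ej, n))
  list(n = n, ei = ei, ej = ej, eiEnds = eiEnds, ejOrder = ejOrder,
       ejEnds = ejEnds, Pn = methods::as(Pn, "generalMatrix"))
}

## sum of v over contiguous sorted segments ending at 'ends'
segSum <- function(v, ends) {
  cs <- cumsum(v)
  diff(c(0, cs[ends]))
}

#' Attention coefficients over a view graph
#'
#' Computes the row-stochastic attention matrix Y of one layer: per-node
#' scalar scores \eqn{s = H W t_s} (own node) and \eqn{r = H W t_r}
#' (neighbour node) combine on every edge of the self-looped graph as
#' \eqn{U_{ij} = \mathrm{sigmoid}(s_i + r_j)}, then each node's scores are
#' soft-maxed over its neighbour set (self-loop included), giving rows
#' that sum to 1. A node with no neighbours keeps only its self-loop with
#' weight 1.
#'
#' @param H spot x d input features of the layer.
#' @param graph a [ViewGraph-class] over the same spots.
#' @param ts,tr attention parameter vectors of length \code{ncol(W)}.
#' @param W the layer's weight matrix (d x d').
#' @return Sparse spot x spot row-stochastic matrix Y, nonzero exactly on
#'   the self-looped edge pattern.
#' @export
attentionCoefficients <- function(H, graph, ts, tr, W) {
  prep <- graphPrep(graph)
  HW <- H %*% W
  att <- attentionValues(HW, prep, ts, tr)
  Matrix::sparseMatrix(i = prep$ei, j = prep$ej, x = att$y,
                       dims = c(prep$n, prep$n))
}

## edge-level attention forward; returns u (sigmoid scores) and y
## (row-softmaxed weights) aligned with prep$ei/prep$ej
attentionValues <- function(HW, prep, ts, tr) {
  s <- drop(HW %*% ts)
  r <- drop(HW %*% tr)
  u <- 1 / (1 + exp(-(s[prep$ei] + r[prep$ej])))
  eu <- exp(u)
  denom <- segSum(eu, prep$eiEnds)
  list(u = u, y = eu / denom[prep$ei])
}

#' One graph convolution layer
#'
#' Computes \eqn{\sigma(\hat{P} H W)} where the propagation operator
#' \eqn{\hat{P}} is the symmetrically normalised self-looped adjacency
#' \eqn{D^{-1/2} (G + I) D^{-1/2}}, or the row-stochastic attention
#' matrix Y when one is supplied.
#'
#' @param H spot x d input matrix.
#' @param graph a [ViewGraph-class].
#' @param W d x d' weight matrix.
#' @param attention optional sparse attention matrix Y (as returned by
#'   [attentionCoefficients()]); \code{NULL} for the normalised adjacency.
#' @param activation \code{"relu"} (hidden layers) or \code{"identity"}
#'   (bottleneck/output).
#' @return spot x d' output matrix.
#' @export
gcnLayer <- function(H, graph, W, attention = NULL,
                     activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(H) != nrow(W))
    stop("dimension error: ncol(H) = ", ncol(H), " but nrow(W) = ", nrow(W))
  if (nrow(H) != nrow(adjacency(graph)))
    stop("dimension error: H and graph cover different numbers of spots")
  P <- if (is.null(attention)) graphPrep(graph)$Pn else attention
  A <- as.matrix(P %*% (H %*% W))
  if (activation == "relu") pmax(A, 0) else A
}

#' Encode spot features through each view's GCN stack
#'
#' Per view, stacks the encoder GCN layers (ReLU hidden, linear
#' bottleneck), modulated by per-layer attention when enabled. The
#' bottleneck output is the low-dimensional view embedding Z_m.
#'
#' @param X a [SpotFeatures-class] or a plain spot x d matrix.
#' @param graphs list of [ViewGraph-class], one per active view.
#' @param state a [ModelState-class] with matching view count.
#' @param attention logical; use the learned attention propagation
#'   (default TRUE).
#' @return List of [ViewEmbedding-class], one per view.
#' @export
encodeViews <- function(X, graphs, state, attention = TRUE) {
  if (methods::is(X, "SpotFeatures")) X <- featureMatrix(X)
  if (length(graphs) != length(state@views))
    stop("alignment error: ", length(graphs), " graphs for ",
         length(state@views), " parameterised views")
  lapply(seq_along(graphs), function(m) {
    prep <- graphPrep(graphs[[m]])
    if (nrow(X) != prep$n)
      stop("alignment error: X rows do not match graph ", m)
    cache <- forwardStack(X, prep, state@views[[m]]$enc, attention)
    methods::new("ViewEmbedding",
                 layers = lapply(cache, `[[`, "Hout"),
                 Z = cache[[length(cache)]]$Hout,
                 attention = if (attention)
                   lapply(cache, `[[`, "Y") else list(),
                 viewName = viewName(graphs[[m]]))
  })
}

#' Decode view embeddings back to the feature space
#'
#' Mirrors the encoder: per view, the decoder GCN stack maps Z_m back to
#' a reconstruction X'_m with the shape of X.
#'
#' @param embeddings list of [ViewEmbedding-class] from [encodeViews()].
#' @param graphs list of [ViewGraph-class], aligned with
#'   \code{embeddings}.
#' @param state a [ModelState-class].
#' @param attention logical; as in [encodeViews()].
#' @return List of reconstruction matrices X'_m.
#' @export
decodeViews <- function(embeddings, graphs, state, attention = TRUE) {
  lapply(seq_along(embeddings), function(m) {
    prep <- graphPrep(graphs[[m]])
    cache <- forwardStack(embeddings[[m]]@Z, prep,
                          state@views[[m]]$dec, attention)
    cache[[length(cache)]]$Hout
  })
}

## forward through a list of layers (each list(W, ts, tr)); ReLU on all
## but the last layer; caches everything the backward pass needs
forwardStack <- function(H, prep, layers, attention) {
  nl <- length(layers)
  caches <- vector("list", nl)
  for (l in seq_len(nl)) {
    W <- layers[[l]]$W
    HW <- H %*% W
    if (attention) {
      att <- attentionValues(HW, prep, layers[[l]]$ts, layers[[l]]$tr)
      Y <- Matrix::sparseMatrix(i = prep$ei, j = prep$ej, x = att$y,
                                dims = c(prep$n, prep$n))
      A <- as.matrix(Y %*% HW)
    } else {
      att <- NULL
      Y <- NULL
      A <- as.matrix(prep$Pn %*% HW)
    }
    Hout <- if (l < nl) pmax(A, 0) else A
    caches[[l]] <- list(Hprev = H, HW = HW, A = A, Hout = Hout,
                        u = att$u, y = att$y, Y = Y)
    H <- Hout
  }
  caches
}

## backward through a forwardStack cache; returns gradient w.r.t. the
## stack input and per-layer parameter gradients
backwardStack <- function(dHout, caches, prep, layers, attention) {
  nl <- length(caches)
  grads <- vector("list", nl)
  dH <- dHout
  for (l in rev(seq_len(nl))) {
    cc <- caches[[l]]
    dA <- if (l < nl) dH * (cc$A > 0) else dH
    if (attention) {
      dHW <- as.matrix(Matrix::crossprod(cc$Y, dA))
      ## dY restricted to the edge pattern, then softmax + sigmoid back
      x <- dA[prep$ei, , drop = FALSE] * cc$HW[prep$ej, , drop = FALSE]
      dYv <- .rowSums(x, nrow(x), ncol(x))
      srow <- segSum(dYv * cc$y, prep$eiEnds)
      du <- cc$y * (dYv - srow[prep$ei])
      dv <- du * cc$u * (1 - cc$u)
      ds <- segSum(dv, prep$eiEnds)
      dr <- segSum(dv[prep$ejOrder], prep$ejEnds)
      dHW <- dHW + outer(ds, layers[[l]]$ts) + outer(dr, layers[[l]]$tr)
      dts <- drop(crossprod(cc$HW, ds))
      dtr <- drop(crossprod(cc$HW, dr))
    } else {
      dHW <- as.matrix(prep$Pn %*% dA)      # Pn symmetric
      dts <- numeric(length(layers[[l]]$ts))
      dtr <- numeric(length(layers[[l]]$tr))
    }
    grads[[l]] <- list(W = crossprod(cc$Hprev, dHW), ts = dts, tr = dtr)
    dH <- dHW %*% t(layers[[l]]$W)
  }
  list(dInput = dH, layers = grads)
}

#' Fuse view embeddings into the clustering embedding
#'
#' Convex combination \eqn{Z = \sum_m \beta_m Z_m}; \code{beta} is
#' renormalised with a warning when it does not sum to 1.
#'
#' @param embeddings list of [ViewEmbedding-class] or plain matrices of
#'   identical shape.
#' @param beta numeric fusion weights, one per embedding.
#' @return The fused spot x d_z matrix Z.
#' @export
fuseEmbeddings <- function(embeddings, beta) {
  Zs <- lapply(embeddings, function(e)
    if (methods::is(e, "ViewEmbedding")) e@Z else e)
  if (length(beta) != length(Zs))
    stop("beta must have one weight per embedding")
  if (any(beta < 0)) stop("beta must be non-negative")
  if (abs(sum(beta) - 1) > 1e-8) {
    warning("beta does not sum to 1; renormalising")
    beta <- beta / sum(beta)
  }
  Reduce(`+`, Map(function(Z, b) b * Z, Zs, beta))
}

#' Student-t soft assignment of embeddings to centroids
#'
#' \deqn{q_{ij} = \frac{(1 + \|z_i - \mu_j\|^2/\alpha)^{-(\alpha+1)/2}}
#'   {\sum_{j'} (1 + \|z_i - \mu_{j'}\|^2/\alpha)^{-(\alpha+1)/2}}}
#'
#' @param Z spot x d embedding matrix.
#' @param centroids k x d centroid matrix.
#' @param alpha Student-t degrees of freedom (default 1).
#' @return spot x k matrix Q with rows summing to 1.
#' @export
softAssign <- function(Z, centroids, alpha = 1) {
  if (nrow(centroids) == 0L) stop("need at least one centroid")
  if (alpha <= 0) stop("alpha must be positive")
  K <- studentKernel(Z, centroids, alpha)
  K / rowSums(K)
}

## pairwise squared distances and the Student-t kernel
pairDist2 <- function(Z, centroids) {
  d2 <- outer(rowSums(Z^2), rowSums(centroids^2), `+`) -
    2 * tcrossprod(Z, centroids)
  pmax(d2, 0)
}

studentKernel <- function(Z, centroids, alpha) {
  (1 + pairDist2(Z, centroids) / alpha)^(-(alpha + 1) / 2)
}

## backward of sum(dQ * Q) through softAssign w.r.t. Z and centroids
softAssignBackward <- function(Z, centroids, alpha, dQ) {
  d2 <- pairDist2(Z, centroids)
  B <- 1 + d2 / alpha
  K <- B^(-(alpha + 1) / 2)
  S <- rowSums(K)
  Q <- K / S
  dK <- (dQ - rowSums(dQ * Q)) / S
  C <- dK * (-(alpha + 1) / (2 * alpha)) * B^(-(alpha + 3) / 2)
  dZ <- 2 * (rowSums(C) * Z - C %*% centroids)
  dMu <- -2 * (crossprod(C, Z) - colSums(C) * centroids)
  list(dZ = dZ, dMu = dMu)
}

#' Target distribution for self-training
#'
#' Sharpens and frequency-corrects a soft assignment:
#' \deqn{p_{ij} = \frac{q_{ij}^2 / f_j}{\sum_{j'} q_{ij'}^2 / f_{j'}}}
#' with cluster frequencies \eqn{f_j = \sum_i q_{ij}}. An empty cluster
#' (zero column) is excluded with a warning.
#'
#' @param Q spot x k soft-assignment matrix, rows summing to 1.
#' @return spot x k matrix P with rows summing to 1; per-row maxima are
#'   at least those of Q (sharper).
#' @export
targetDistribution <- function(Q) {
  f <- colSums(Q)
  if (any(f == 0)) {
    warning("empty cluster(s) ", paste(which(f == 0), collapse = ", "),
            " excluded from the target distribution")
    f[f == 0] <- Inf
  }
  Wq <- sweep(Q^2, 2L, f, `/`)
  Wq / rowSums(Wq)
}

#' Hard labels from the target distribution
#'
#' \eqn{y_i = \arg\max_j p_{ij}}; ties break to the lowest cluster index.
#'
#' @param P spot x k matrix of assignment probabilities.
#' @return Integer vector of 1-based domain labels.
#' @export
assignLabels <- function(P) {
  as.integer(max.col(P, ties.method = "first"))
}

#' Composite training loss
#'
#' \code{Le}: summed squared Frobenius reconstruction error over views;
#' \code{Lgr}: geometric consistency, \eqn{\sum_{i \ne j} \|Z_i -
#' Z_j\|_F^2} over ordered view pairs (each unordered pair counted
#' twice); \code{Lpd}: distribution consistency, \eqn{\sum_m \rho_m
#' \|Q_m - P\|_F^2}. The total is their sum.
#'
#' @param X spot x d feature matrix.
#' @param reconstructions list of X'_m matrices.
#' @param viewZ list of view embeddings Z_m (matrices).
#' @param Qm list of per-view soft assignments.
#' @param P target distribution.
#' @param rho per-view trade-off weight(s), recycled to the view count.
#' @return List with \code{total}, \code{Le}, \code{Lgr}, \code{Lpd}.
#' @export
totalLoss <- function(X, reconstructions, viewZ, Qm, P, rho = 1) {
  M <- length(reconstructions)
  rho <- rep_len(rho, M)
  Le <- sum(vapply(reconstructions, function(Xr) sum((X - Xr)^2),
                   numeric(1)))
  Lgr <- 0
  if (length(viewZ) > 1L)
    for (i in seq_along(viewZ)) for (j in seq_along(viewZ))
      if (i != j) Lgr <- Lgr + sum((viewZ[[i]] - viewZ[[j]])^2)
  Lpd <- sum(vapply(seq_along(Qm), function(m)
    rho[m] * sum((Qm[[m]] - P)^2), numeric(1)))
  list(total = Le + Lgr + Lpd, Le = Le, Lgr = Lgr, Lpd = Lpd)
}
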