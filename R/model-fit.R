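#' Training configuration
#'
#' Collects every tunable of [fitMVST()] in one flat object.
#'
#' @param hiddenDims integer vector of hidden encoder widths (default
#'   256; the decoder mirrors them).
#' @param dz bottleneck width d_z of the view embeddings (default 64).
#' @param lrPretrain,epochsPretrain Adam learning rate and epoch budget
#'   of the reconstruction-only pretraining phase (1e-3, 200).
#' @param lrJoint,epochsJoint Adam learning rate and epoch budget of the
#'   joint clustering phase (1e-4, 200).
#' @param pRefresh epochs between refreshes of the target distribution P
#'   (default 20).
#' @param beta view-fusion weights; \code{NULL} for equal weights over
#'   the active views.
#' @param rho per-view trade-off weight of the distribution-consistency
#'   loss (default 1).
#' @param alpha Student-t degrees of freedom (default 1).
#' @param attention use the learned attention propagation (default TRUE);
#'   FALSE restores the pure symmetrically normalised convolution.
#' @param seed integer seed governing every random draw of the fit.
#' @param earlyStop stop the joint phase when fewer than
#'   \code{labelTol} of labels change between consecutive P refreshes
#'   (default FALSE: fixed epoch budget).
#' @param labelTol label-change fraction for \code{earlyStop}
#'   (default 0.001).
#' @return A list of class \code{MVSTConfig}.
#' @export
mvstConfig <- function(hiddenDims = 256L, dz = 64L,
                       lrPretrain = 1e-3, epochsPretrain = 200L,
                       lrJoint = 1e-4, epochsJoint = 200L,
                       pRefresh = 20L, beta = NULL, rho = 1,
                       alpha = 1, attention = TRUE, seed = 0L,
                       earlyStop = FALSE, labelTol = 1e-3) {
  cfg <- list(hiddenDims = as.integer(hiddenDims), dz = as.integer(dz),
              lrPretrain = lrPretrain, epochsPretrain = as.integer(epochsPretrain),
              lrJoint = lrJoint, epochsJoint = as.integer(epochsJoint),
              pRefresh = as.integer(pRefresh), beta = beta, rho = rho,
              alpha = alpha, attention = isTRUE(attention),
              seed = as.integer(seed), earlyStop = isTRUE(earlyStop),
              labelTol = labelTol)
  class(cfg) <- "MVSTConfig"
  cfg
}

## Glorot-uniform weight init; attention vectors start at zero, which
## makes the initial attention uniform over each neighbour set
initLayer <- function(din, dout) {
  lim <- sqrt(6 / (din + dout))
  list(W = matrix(stats::runif(din * dout, -lim, lim), din, dout),
       ts = numeric(dout), tr = numeric(dout))
}

initViews <- function(d0, hiddenDims, dz, nViews) {
  encDims <- c(d0, hiddenDims, dz)
  decDims <- rev(encDims)
  lapply(seq_len(nViews), function(m) {
    list(enc = lapply(seq_len(length(encDims) - 1L), function(l)
           initLayer(encDims[l], encDims[l + 1L])),
         dec = lapply(seq_len(length(decDims) - 1L), function(l)
           initLayer(decDims[l], decDims[l + 1L])))
  })
}

## elementwise Adam over a flattened parameter tree
adamInit <- function(theta) list(m = numeric(length(theta)),
                                 v = numeric(length(theta)), t = 0L)

adamStep <- function(theta, grad, st, lr, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mhat <- st$m / (1 - b1^st$t)
  vhat <- st$v / (1 - b2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), st = st)
}

## deterministic farthest-point (maximin) seeding + Lloyd iterations;
## invariant to spot order up to exact distance ties
initCentroids <- function(Z, k) {
  n <- nrow(Z)
  idx <- which.max(rowSums(Z^2))
  d2 <- rowSums((Z - matrix(Z[idx, ], n, ncol(Z), byrow = TRUE))^2)
  while (length(idx) < k) {
    nxt <- which.max(d2)
    idx <- c(idx, nxt)
    d2 <- pmin(d2, rowSums((Z - matrix(Z[nxt, ], n, ncol(Z),
                                       byrow = TRUE))^2))
  }
  km <- suppressWarnings(
    stats::kmeans(Z, centers = Z[idx, , drop = FALSE], iter.max = 100L,
                  algorithm = "Lloyd"))
  km$centers
}

## forward pass over all views; returns per-view caches, Z_m list and
## reconstructions
forwardAll <- function(X, preps, views, attention) {
  lapply(seq_along(views), function(m) {
    enc <- forwardStack(X, preps[[m]], views[[m]]$enc, attention)
    Z <- enc[[length(enc)]]$Hout
    dec <- forwardStack(Z, preps[[m]], views[[m]]$dec, attention)
    list(enc = enc, dec = dec, Z = Z,
         Xrec = dec[[length(dec)]]$Hout)
  })
}

#' Fit the multi-view model and assign spatial domains
#'
#' Two-phase training. Phase 1 pretrains the per-view graph
#' convolutional autoencoders on the reconstruction loss alone. The view
#' embeddings are then fused and cluster centroids are initialised by
#' deterministic farthest-point-seeded k-means. Phase 2 trains jointly on
#' the composite loss (reconstruction + geometric consistency +
#' distribution consistency), with the target distribution P refreshed
#' from the fused embedding on a fixed interval and treated as a
#' constant between refreshes. All randomness derives from
#' \code{config$seed}, so a fit is fully reproducible.
#'
#' @param X a [SpotFeatures-class] or spot x d feature matrix.
#' @param graphs list of [ViewGraph-class] (1--3 active views) over the
#'   same spots.
#' @param nDomains number of spatial domains k; \code{NULL} to estimate
#'   via [estimateNDomains()] on the first graph.
#' @param config a [mvstConfig()] list.
#' @return List with \code{state} ([ModelState-class]),
#'   \code{assignment} ([DomainAssignment-class]) and \code{lossTrace}
#'   (data.frame of per-epoch loss components).
#' @examples
#' sec <- simulateSection(nRows = 8, nCols = 8, nGenes = 60, seed = 1)
#' sf <- preprocessSection(sec, nHVG = 40, nPCs = 10)
#' gs <- list(buildSpatialGraph(sec, k = 4),
#'            buildExpressionGraph(sf, k = 4, nPCsGraph = 10))
#' cfg <- mvstConfig(hiddenDims = 8, dz = 4, epochsPretrain = 5,
#'                   epochsJoint = 5, seed = 1)
#' fit <- fitMVST(sf, gs, nDomains = 3, config = cfg)
#' table(domainLabels(fit$assignment))
#' @export
fitMVST <- function(X, graphs, nDomains = NULL, config = mvstConfig()) {
  feats <- X
  if (methods::is(X, "SpotFeatures")) X <- featureMatrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  M <- length(graphs)
  if (M < 1L) stop("need at least one view graph")
  for (g in graphs)
    if (nrow(adjacency(g)) != n)
      stop("alignment error: graph '", viewName(g),
           "' covers ", nrow(adjacency(g)), " spots, features cover ", n)
  if (is.null(nDomains)) {
    if (!methods::is(feats, "SpotFeatures"))
      stop("nDomains is required when X is a plain matrix")
    nDomains <- estimateNDomains(feats, graphs[[1L]])
  }
  if (nDomains < 2L) stop("nDomains must be at least 2")
  if (nDomains > n) stop("nDomains exceeds the number of spots")
  beta <- config$beta
  if (is.null(beta)) beta <- rep(1 / M, M)
  if (length(beta) != M)
    stop("beta must have one weight per active view")
  if (abs(sum(beta) - 1) > 1e-8) {
    warning("beta does not sum to 1; renormalising")
    beta <- beta / sum(beta)
  }
  rho <- rep_len(config$rho, M)

  set.seed(config$seed)
  preps <- lapply(graphs, graphPrep)
  views <- initViews(ncol(X), config$hiddenDims, config$dz, M)
  att <- config$attention
  trace <- list()

  checkFinite <- function(loss, phase, epoch) {
    bad <- names(loss)[!vapply(loss, is.finite, logical(1))]
    if (length(bad))
      stop("divergence: non-finite loss component(s) ",
           paste(bad, collapse = ", "), " at ", phase, " epoch ", epoch)
  }

  ## ---- phase 1: reconstruction-only pretraining -----------------------
  theta <- unlist(views)
  ast <- adamInit(theta)
  for (epoch in seq_len(config$epochsPretrain)) {
    fw <- forwardAll(X, preps, views, att)
    Le <- sum(vapply(fw, function(f) sum((X - f$Xrec)^2), numeric(1)))
    checkFinite(list(Le = Le), "pretraining", epoch)
    gviews <- lapply(seq_len(M), function(m) {
      dXrec <- 2 * (fw[[m]]$Xrec - X)
      bdec <- backwardStack(dXrec, fw[[m]]$dec, preps[[m]],
                            views[[m]]$dec, att)
      benc <- backwardStack(bdec$dInput, fw[[m]]$enc, preps[[m]],
                            views[[m]]$enc, att)
      list(enc = benc$layers, dec = bdec$layers)
    })
    upd <- adamStep(theta, unlist(gviews), ast, config$lrPretrain)
    theta <- upd$theta; ast <- upd$st
    views <- utils::relist(theta, views)
    trace[[length(trace) + 1L]] <-
      data.frame(phase = "pretrain", epoch = epoch, total = Le,
                 Le = Le, Lgr = 0, Lpd = 0)
  }

  ## ---- centroid initialisation on the fused embedding -----------------
  fw <- forwardAll(X, preps, views, att)
  Zs <- lapply(fw, `[[`, "Z")
  Zfused <- fuseEmbeddings(Zs, beta)
  centroids <- initCentroids(Zfused, nDomains)

  ## ---- phase 2: joint training ----------------------------------------
  params <- list(views = views, centroids = centroids)
  theta <- unlist(params)
  ast <- adamInit(theta)
  P <- NULL
  prevLabels <- NULL
  for (epoch in seq_len(config$epochsJoint)) {
    fw <- forwardAll(X, preps, params$views, att)
    Zs <- lapply(fw, `[[`, "Z")
    Zfused <- fuseEmbeddings(Zs, beta)
    if (is.null(P) || (epoch - 1L) %% config$pRefresh == 0L) {
      Qfused <- softAssign(Zfused, params$centroids, config$alpha)
      P <- targetDistribution(Qfused)
      labels <- assignLabels(P)
      if (config$earlyStop && !is.null(prevLabels) &&
          mean(labels != prevLabels) < config$labelTol) break
      prevLabels <- labels
    }
    Qm <- lapply(Zs, softAssign, centroids = params$centroids,
                 alpha = config$alpha)
    loss <- totalLoss(X, lapply(fw, `[[`, "Xrec"), Zs, Qm, P, rho)
    checkFinite(loss, "joint", epoch)

    dMu <- 0
    gviews <- vector("list", M)
    for (m in seq_len(M)) {
      dXrec <- 2 * (fw[[m]]$Xrec - X)
      bdec <- backwardStack(dXrec, fw[[m]]$dec, preps[[m]],
                            params$views[[m]]$dec, att)
      dZ <- bdec$dInput
      for (j in seq_len(M)) if (j != m)
        dZ <- dZ + 4 * (Zs[[m]] - Zs[[j]])
      sb <- softAssignBackward(Zs[[m]], params$centroids, config$alpha,
                               2 * rho[m] * (Qm[[m]] - P))
      dZ <- dZ + sb$dZ
      dMu <- dMu + sb$dMu
      benc <- backwardStack(dZ, fw[[m]]$enc, preps[[m]],
                            params$views[[m]]$enc, att)
      gviews[[m]] <- list(enc = benc$layers, dec = bdec$layers)
    }
    grads <- list(views = gviews, centroids = dMu)
    upd <- adamStep(theta, unlist(grads), ast, config$lrJoint)
    theta <- upd$theta; ast <- upd$st
    params <- utils::relist(theta, params)
    trace[[length(trace) + 1L]] <-
      data.frame(phase = "joint", epoch = epoch, total = loss$total,
                 Le = loss$Le, Lgr = loss$Lgr, Lpd = loss$Lpd)
  }

  ## ---- final assignment ------------------------------------------------
  fw <- forwardAll(X, preps, params$views, att)
  Zs <- lapply(fw, `[[`, "Z")
  Zfused <- fuseEmbeddings(Zs, beta)
  Qfused <- softAssign(Zfused, params$centroids, config$alpha)
  P <- targetDistribution(Qfused)
  labels <- assignLabels(P)
  Qm <- lapply(Zs, softAssign, centroids = params$centroids,
               alpha = config$alpha)
  rownames(Zfused) <- rownames(X)
  names(labels) <- rownames(X)

  state <- methods::new("ModelState", views = params$views, beta = beta,
                        centroids = params$centroids, alpha = config$alpha,
                        rho = rho)
  assignment <- methods::new("DomainAssignment", Z = Zfused, Q = Qfused,
                             Qm = Qm, P = P, labels = labels)
  list(state = state, assignment = assignment,
       lossTrace = do.call(rbind, trace))
}

#' @rdname domainLabels
#' @param x a \code{DomainAssignment}
#' @return \code{domainLabels}: named integer vector of 1-based domain
#'   labels per spot.
#' @export
setMethod("domainLabels", "DomainAssignment", function(x) x@labels)

#' @export
setMethod("show", "DomainAssignment", function(object) {
  cat("DomainAssignment:", nrow(object@P), "spots,",
      ncol(object@P), "domains\n")
  print(table(domain = object@labels))
  invisible(NULL)
})

#' @export
setMethod("show", "ModelState", function(object) {
  dims <- vapply(object@views[[1]]$enc, function(l) ncol(l$W), integer(1))
  cat("ModelState:", length(object@views), "views; encoder widths:",
      paste(dims, collapse = " -> "), "\n")
  cat("  beta:", paste(signif(object@beta, 3), collapse = ", "),
      " alpha:", object@alpha, "\n")
  invisible(NULL)
})
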