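## Independent brute-force oracles used across the suite. These stay
## deliberately naive (double loops, dense algebra) so they share no code
## with the implementation they check.

## exhaustive k-NN: per point, sort all distances, stable index ties
bruteKNN <- function(X, k) {
  n <- nrow(X)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- rep(NA_real_, n)
    for (j in seq_len(n)) if (j != i)
      d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    nbr <- order(d, seq_len(n), na.last = TRUE)[seq_len(k)]
    adj[i, nbr] <- 1
  }
  pmax(adj, t(adj))                      # union symmetrisation
}

## dense step-by-step GCN layer: normalise, multiply, activate
denseGCN <- function(H, A, W, relu = TRUE) {
  n <- nrow(A)
  Gp <- A + diag(n)
  D <- diag(1 / sqrt(rowSums(Gp)))
  out <- D %*% Gp %*% D %*% H %*% W
  if (relu) pmax(out, 0) else out
}

## scalar-by-scalar masked attention softmax over G' = G + I
handAttention <- function(H, A, ts, tr, W) {
  n <- nrow(A)
  Gp <- A + diag(n)
  HW <- H %*% W
  s <- as.vector(HW %*% ts)
  r <- as.vector(HW %*% tr)
  Y <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbr <- which(Gp[i, ] != 0)
    u <- vapply(nbr, function(j) 1 / (1 + exp(-(s[i] + r[j]))),
                numeric(1))
    Y[i, nbr] <- exp(u) / sum(exp(u))
  }
  Y
}

## loop-based GLCM with the package's documented convention: quantise,
## count pairs along one offset, symmetrise, normalise
handGLCM <- function(g, levels, dr, dc) {
  q <- pmin(floor(pmax(pmin(g, 1), 0) * levels), levels - 1) + 1
  m <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      m[q[r, cc], q[r2, c2]] <- m[q[r, cc], q[r2, c2]] + 1
    }
  }
  m <- m + t(m)
  m / sum(m)
}

## Student-t soft assignment, scalar arithmetic
handSoftAssign <- function(Z, mu, alpha) {
  n <- nrow(Z); k <- nrow(mu)
  Q <- matrix(0, n, k)
  for (i in seq_len(n)) {
    kern <- vapply(seq_len(k), function(j)
      (1 + sum((Z[i, ] - mu[j, ])^2) / alpha)^(-(alpha + 1) / 2),
      numeric(1))
    Q[i, ] <- kern / sum(kern)
  }
  Q
}

handTargetDistribution <- function(Q) {
  f <- colSums(Q)
  P <- matrix(0, nrow(Q), ncol(Q))
  for (i in seq_len(nrow(Q))) {
    w <- Q[i, ]^2 / f
    P[i, ] <- w / sum(w)
  }
  P
}

## a small random ViewGraph over n spots (connected enough for tests)
randomViewGraph <- function(n, k = 3, seed = 1,
                            viewName = "spatial") {
  set.seed(seed)
  buildSpatialGraph(matrix(rnorm(n * 2), n, 2), k = k)
}

## a minimal ModelState built from explicit layer lists
makeState <- function(views, beta = NULL, centroids = matrix(0, 0, 0),
                      alpha = 1, rho = 1) {
  if (is.null(beta)) beta <- rep(1 / length(views), length(views))
  methods::new("ModelState", views = views, beta = beta,
               centroids = centroids, alpha = alpha,
               rho = rep_len(rho, length(views)))
}

randomLayers <- function(dims, seed = 1) {
  set.seed(seed)
  lapply(seq_len(length(dims) - 1L), function(l)
    list(W = matrix(rnorm(dims[l] * dims[l + 1L], sd = 0.5),
                    dims[l], dims[l + 1L]),
         ts = rnorm(dims[l + 1L], sd = 0.3),
         tr = rnorm(dims[l + 1L], sd = 0.3)))
}
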