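test_that("gcnLayer reduces to identity propagation on an isolated node", {
  g <- methods::new("ViewGraph",
                    adj = methods::as(methods::as(Matrix::Matrix(0, 1, 1, sparse = TRUE),
                                                  "CsparseMatrix"), "generalMatrix"),
                    viewName = "spatial", k = 1L)
  H <- matrix(c(2, -3), 1, 2)
  out <- gcnLayer(H, g, diag(2), activation = "identity")
  expect_equal(out, H)
})

test_that("gcnLayer matches the 2-node closed form", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  g <- methods::new("ViewGraph",
                    adj = methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                                  "CsparseMatrix"), "generalMatrix"),
                    viewName = "spatial", k = 1L)
  H <- matrix(c(1, 0), 2, 1)
  out <- gcnLayer(H, g, matrix(1), activation = "identity")
  ## D^{-1/2} G' D^{-1/2} = [[1/2, 1/2], [1/2, 1/2]]
  expect_equal(out, matrix(c(0.5, 0.5), 2, 1))
})

test_that("gcnLayer matches the dense brute-force oracle", {
  g <- randomViewGraph(10, k = 3, seed = 30)
  A <- as.matrix(adjacency(g))
  set.seed(31)
  H <- matrix(rnorm(10 * 4), 10, 4)
  W <- matrix(rnorm(4 * 3), 4, 3)
  expect_equal(gcnLayer(H, g, W, activation = "relu"),
               denseGCN(H, A, W, relu = TRUE), tolerance = 1e-12)
  expect_equal(gcnLayer(H, g, W, activation = "identity"),
               denseGCN(H, A, W, relu = FALSE), tolerance = 1e-12)
  expect_error(gcnLayer(H, g, matrix(0, 5, 3)), "dimension error")
})

test_that("attention softmax behaves on singleton and uniform neighbourhoods", {
  g <- randomViewGraph(8, k = 2, seed = 32)
  set.seed(33)
  H <- matrix(rnorm(8 * 3), 8, 3)
  W <- matrix(rnorm(3 * 2), 3, 2)
  ## zero attention parameters -> uniform over each neighbour set
  Y <- attentionCoefficients(H, g, numeric(2), numeric(2), W)
  Yd <- as.matrix(Y)
  Gp <- as.matrix(adjacency(g)) + diag(8)
  expect_equal(Yd > 0, Gp > 0)
  deg <- rowSums(Gp)
  expect_equal(Yd, Gp / deg, tolerance = 1e-12)
  ## uniform attention equals row-normalised mean aggregation over G'
  expect_equal(gcnLayer(H, g, W, attention = Y, activation = "identity"),
               (Gp / deg) %*% H %*% W, tolerance = 1e-12)
  ## an isolated node keeps only its self-loop, weight 1
  g1 <- methods::new("ViewGraph",
                     adj = methods::as(methods::as(Matrix::Matrix(0, 3, 3, sparse = TRUE),
                                                   "CsparseMatrix"), "generalMatrix"),
                     viewName = "spatial", k = 1L)
  Y1 <- as.matrix(attentionCoefficients(matrix(rnorm(9), 3, 3), g1,
                                        rnorm(2), rnorm(2),
                                        matrix(rnorm(6), 3, 2)))
  expect_equal(Y1, diag(3))
})

test_that("attention coefficients match the scalar-by-scalar oracle", {
  g <- randomViewGraph(5, k = 2, seed = 34)
  set.seed(35)
  H <- matrix(rnorm(5 * 3), 5, 3)
  W <- matrix(rnorm(3 * 2), 3, 2)
  ts <- rnorm(2); tr <- rnorm(2)
  Y <- as.matrix(attentionCoefficients(H, g, ts, tr, W))
  expect_equal(Y, handAttention(H, as.matrix(adjacency(g)), ts, tr, W),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(Y)), rep(1, 5), tolerance = 1e-12)
})

test_that("softAssign follows the Student-t formula", {
  ## equidistant from two centroids -> (1/2, 1/2)
  Z <- matrix(c(0, 0), 1, 2)
  mu <- rbind(c(1, 0), c(-1, 0))
  expect_equal(softAssign(Z, mu)[1, ], c(0.5, 0.5))
  ## at a centroid, far other centroid -> probability ~ 1
  mu2 <- rbind(c(0, 0), c(1e6, 0))
  expect_gt(softAssign(Z, mu2)[1, 1], 1 - 1e-10)
  ## alpha = 1, distances 1 and 2: kernels 1/2, 1/5 -> q = (5/7, 2/7)
  mu3 <- rbind(c(1, 0), c(2, 0))
  expect_equal(softAssign(Z, mu3, alpha = 1)[1, ], c(5 / 7, 2 / 7),
               tolerance = 1e-12)
  ## random case against the scalar oracle, rows sum to one
  set.seed(36)
  Zr <- matrix(rnorm(12 * 3), 12, 3)
  mur <- matrix(rnorm(4 * 3), 4, 3)
  Q <- softAssign(Zr, mur, alpha = 2)
  expect_equal(Q, handSoftAssign(Zr, mur, 2), tolerance = 1e-12)
  expect_equal(rowSums(Q), rep(1, 12), tolerance = 1e-12)
  expect_error(softAssign(Zr, mur[0, , drop = FALSE]), "centroid")
})

test_that("target distribution sharpens and renormalises", {
  ## symmetric rows with equal frequencies stay symmetric
  Q <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(targetDistribution(Q), Q)
  ## hand-computed sharpening at equal frequencies
  Q2 <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  P2 <- targetDistribution(Q2)
  expect_equal(P2[1, ], c(0.81 / 0.82, 0.01 / 0.82), tolerance = 1e-12)
  ## random valid Q: rows sum to 1, matches the scalar oracle, and with
  ## equal cluster frequencies rows get sharper
  set.seed(37)
  Qr <- matrix(rexp(20 * 4), 20, 4)
  Qr <- Qr / rowSums(Qr)
  Pr <- targetDistribution(Qr)
  expect_equal(rowSums(Pr), rep(1, 20), tolerance = 1e-12)
  expect_equal(Pr, handTargetDistribution(Qr), tolerance = 1e-12)
  expect_true(all(apply(targetDistribution(Q2), 1, max) >=
                    apply(Q2, 1, max)))
  ## empty cluster excluded with a warning
  Q0 <- cbind(Qr[, 1:3] / rowSums(Qr[, 1:3]), 0)
  expect_warning(P0 <- targetDistribution(Q0), "empty cluster")
  expect_equal(P0[, 4], rep(0, 20))
  expect_equal(rowSums(P0), rep(1, 20), tolerance = 1e-12)
})

test_that("fusion is the documented convex combination", {
  set.seed(38)
  Zs <- lapply(1:3, function(i) matrix(rnorm(10 * 4), 10, 4))
  expect_equal(fuseEmbeddings(Zs, c(1, 0, 0)), Zs[[1]])
  expect_equal(fuseEmbeddings(list(Zs[[1]], Zs[[1]], Zs[[1]]),
                              c(0.2, 0.5, 0.3)), Zs[[1]],
               tolerance = 1e-12)
  beta <- c(0.3, 0.3, 0.4)
  expect_equal(fuseEmbeddings(Zs, beta),
               beta[1] * Zs[[1]] + beta[2] * Zs[[2]] + beta[3] * Zs[[3]],
               tolerance = 1e-12)
  expect_warning(f <- fuseEmbeddings(Zs, c(1, 1, 2)), "renormalising")
  expect_equal(f, fuseEmbeddings(Zs, c(0.25, 0.25, 0.5)))
})

test_that("label assignment is argmax with lowest-index ties", {
  expect_identical(assignLabels(matrix(c(0.2, 0.7, 0.1), 1)), 2L)
  expect_identical(assignLabels(matrix(c(0.5, 0.5), 1)), 1L)
  set.seed(39)
  P <- matrix(rexp(50 * 5), 50, 5)
  P <- P / rowSums(P)
  oracle <- vapply(seq_len(50), function(i) {
    best <- 1L
    for (j in 2:5) if (P[i, j] > P[i, best]) best <- j
    best
  }, integer(1))
  expect_identical(assignLabels(P), oracle)
})

test_that("loss components add up and vanish at the global minimum", {
  set.seed(40)
  X <- matrix(rnorm(8 * 5), 8, 5)
  Zs <- lapply(1:3, function(i) matrix(rnorm(8 * 2), 8, 2))
  Qm <- lapply(1:3, function(i) {
    q <- matrix(rexp(8 * 2), 8, 2); q / rowSums(q)
  })
  P <- targetDistribution(Qm[[1]])
  recons <- lapply(1:3, function(i) X + matrix(rnorm(40, sd = .1), 8, 5))
  l <- totalLoss(X, recons, Zs, Qm, P, rho = c(1, 2, 0.5))
  expect_identical(l$total, l$Le + l$Lgr + l$Lpd)
  expect_true(l$total >= 0)
  ## constructed global minimum
  l0 <- totalLoss(X, list(X, X), list(Zs[[1]], Zs[[1]]),
                  list(P, P), P)
  expect_equal(l0$total, 0)
  ## single active view: no geometric consistency term
  l1 <- totalLoss(X, recons[1], Zs[1], Qm[1], P)
  expect_identical(l1$Lgr, 0)
  ## ||Z1 - Z2||_F = 2 -> ordered-pair sum is 8
  Za <- matrix(0, 2, 2)
  Zb <- matrix(c(2, 0, 0, 0), 2, 2)
  l2 <- totalLoss(X[1:2, 1:2], list(), list(Za, Zb), list(), P[1:2, ])
  expect_equal(l2$Lgr, 8)
})

test_that("encode/decode stacks match layer-level oracles", {
  g <- randomViewGraph(6, k = 2, seed = 41)
  set.seed(42)
  X <- matrix(rnorm(6 * 4), 6, 4)
  ## L = 1 encoder equals a single gcnLayer
  st <- makeState(list(list(enc = list(list(W = matrix(rnorm(8), 4, 2),
                                            ts = numeric(2),
                                            tr = numeric(2))),
                            dec = list(list(W = matrix(rnorm(8), 2, 4),
                                            ts = numeric(4),
                                            tr = numeric(4))))),
                  beta = 1)
  emb <- encodeViews(X, list(g), st, attention = FALSE)
  expect_length(emb, 1)
  expect_equal(emb[[1]]@Z,
               gcnLayer(X, g, st@views[[1]]$enc[[1]]$W,
                        activation = "identity"))
  ## reconstruction has the shape of X, and equals the two-product oracle
  rec <- decodeViews(emb, list(g), st, attention = FALSE)
  expect_identical(dim(rec[[1]]), dim(X))
  A <- as.matrix(adjacency(g))
  Pn <- {
    Gp <- A + diag(6); D <- diag(1 / sqrt(rowSums(Gp))); D %*% Gp %*% D
  }
  expect_equal(rec[[1]],
               Pn %*% (Pn %*% X %*% st@views[[1]]$enc[[1]]$W) %*%
                 st@views[[1]]$dec[[1]]$W,
               tolerance = 1e-12)
  ## zero weights propagate to all-zero embeddings
  st0 <- makeState(list(list(enc = list(list(W = matrix(0, 4, 2),
                                             ts = numeric(2),
                                             tr = numeric(2))),
                             dec = list())), beta = 1)
  expect_true(all(encodeViews(X, list(g), st0,
                              attention = FALSE)[[1]]@Z == 0))
  ## ablation: two graphs give exactly two embeddings
  st2 <- makeState(list(
    list(enc = randomLayers(c(4, 2), seed = 1), dec = list()),
    list(enc = randomLayers(c(4, 2), seed = 2), dec = list())))
  expect_length(encodeViews(X, list(g, g), st2, attention = FALSE), 2)
})

test_that("orthogonal encoder/transposed decoder reconstructs on a self-loop graph", {
  ## edgeless graph: G' = I, propagation is the identity
  g <- methods::new("ViewGraph",
                    adj = methods::as(methods::as(Matrix::Matrix(0, 5, 5, sparse = TRUE),
                                                  "CsparseMatrix"), "generalMatrix"),
                    viewName = "spatial", k = 1L)
  set.seed(43)
  Wq <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  st <- makeState(list(list(
    enc = list(list(W = Wq, ts = numeric(4), tr = numeric(4))),
    dec = list(list(W = t(Wq), ts = numeric(4), tr = numeric(4))))),
    beta = 1)
  X <- matrix(rnorm(20), 5, 4)
  emb <- encodeViews(X, list(g), st, attention = FALSE)
  rec <- decodeViews(emb, list(g), st, attention = FALSE)
  expect_equal(rec[[1]], X, tolerance = 1e-10)
})

test_that("attention rows sum to 1 through the full encoder stack", {
  g <- randomViewGraph(12, k = 3, seed = 44)
  st <- makeState(list(list(enc = randomLayers(c(5, 4, 2), seed = 45),
                            dec = randomLayers(c(2, 4, 5), seed = 46))))
  set.seed(47)
  X <- matrix(rnorm(12 * 5), 12, 5)
  emb <- encodeViews(X, list(g), st, attention = TRUE)
  for (Y in emb[[1]]@attention) {
    expect_equal(unname(Matrix::rowSums(Y)), rep(1, 12), tolerance = 1e-6)
    ## nonzero exactly on the self-looped edge pattern
    expect_equal(as.matrix(Y) > 0,
                 (as.matrix(adjacency(g)) + diag(12)) > 0)
  }
})

test_that("analytic gradients match finite differences", {
  ## a tiny two-view model with attention, full composite loss
  set.seed(48)
  n <- 6; d0 <- 4; k <- 3
  graphs <- list(randomViewGraph(n, k = 2, seed = 49),
                 randomViewGraph(n, k = 2, seed = 50))
  X <- matrix(rnorm(n * d0), n, d0)
  views <- lapply(1:2, function(m) list(
    enc = randomLayers(c(d0, 3, 2), seed = 50 + m),
    dec = randomLayers(c(2, 3, d0), seed = 60 + m)))
  centroids <- matrix(rnorm(k * 2), k, 2)
  params <- list(views = views, centroids = centroids)
  preps <- lapply(graphs, MVST:::graphPrep)
  beta <- c(0.4, 0.6); rho <- c(1, 0.5); alpha <- 1
  Pfix <- {
    q <- matrix(rexp(n * k), n, k); targetDistribution(q / rowSums(q))
  }
  lossOf <- function(theta) {
    pp <- utils::relist(theta, params)
    fw <- MVST:::forwardAll(X, preps, pp$views, TRUE)
    Zs <- lapply(fw, `[[`, "Z")
    Qm <- lapply(Zs, softAssign, centroids = pp$centroids, alpha = alpha)
    totalLoss(X, lapply(fw, `[[`, "Xrec"), Zs, Qm, Pfix, rho)$total
  }
  ## analytic gradient assembled the same way the training loop does
  fw <- MVST:::forwardAll(X, preps, views, TRUE)
  Zs <- lapply(fw, `[[`, "Z")
  Qm <- lapply(Zs, softAssign, centroids = centroids, alpha = alpha)
  dMu <- 0
  gviews <- vector("list", 2)
  for (m in 1:2) {
    dXrec <- 2 * (fw[[m]]$Xrec - X)
    bdec <- MVST:::backwardStack(dXrec, fw[[m]]$dec, preps[[m]],
                                 views[[m]]$dec, TRUE)
    dZ <- bdec$dInput
    for (j in 1:2) if (j != m) dZ <- dZ + 4 * (Zs[[m]] - Zs[[j]])
    sb <- MVST:::softAssignBackward(Zs[[m]], centroids, alpha,
                                    2 * rho[m] * (Qm[[m]] - Pfix))
    dZ <- dZ + sb$dZ
    dMu <- dMu + sb$dMu
    benc <- MVST:::backwardStack(dZ, fw[[m]]$enc, preps[[m]],
                                 views[[m]]$enc, TRUE)
    gviews[[m]] <- list(enc = benc$layers, dec = bdec$layers)
  }
  analytic <- unlist(list(views = gviews, centroids = dMu))
  theta0 <- unlist(params)
  set.seed(51)
  probe <- sample(length(theta0), 80)
  h <- 1e-6
  for (idx in probe) {
    tp <- theta0; tp[idx] <- tp[idx] + h
    tm <- theta0; tm[idx] <- tm[idx] - h
    fd <- (lossOf(tp) - lossOf(tm)) / (2 * h)
    expect_lt(abs(analytic[idx] - fd), 1e-4 * max(1, abs(fd)))
  }
})
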