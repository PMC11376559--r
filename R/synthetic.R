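#' Simulate a Visium-like section with planted spatial domains
#'
#' Generates everything the pipeline consumes, with known ground truth:
#' spots on a hexagonal-offset grid, negative-binomial counts with
#' domain-specific marker up-regulation, and a fake stained image whose
#' per-domain colour tint makes the histology view informative of the
#' planted domains. Planted labels are stored in
#' \code{colData(section)$domain}.
#'
#' Count model: gene base means are log-normal around \code{baseMean};
#' each domain up-regulates its own disjoint marker set by
#' \code{foldChange}; counts are drawn negative-binomial with dispersion
#' \code{dispersion} (variance \eqn{\mu + \mu^2 \cdot dispersion}). The
#' image paints each spot's neighbourhood with a stain-like base colour
#' plus the domain tint and per-pixel Gaussian noise.
#'
#' @param nRows,nCols grid dimensions (default 30 x 30).
#' @param nDomains number of planted domains (default 3).
#' @param domainGeometry \code{"layered"} (contiguous bands across rows),
#'   \code{"blocks"} (checkerboard-like rectangular blocks) or
#'   \code{"voronoi"} (regions of random seed spots).
#' @param nGenes total genes (default 500).
#' @param nMarkersPerDomain marker genes per domain (default 50).
#' @param markerFoldChange multiplicative marker effect (default 5).
#' @param baseMean negative-binomial mean scale (default 2).
#' @param dispersion negative-binomial dispersion (default 0.5).
#' @param imageDomainTint per-domain RGB offset matrix (nDomains x 3,
#'   values in -127..127), or \code{NULL} for evenly spread hue tints.
#' @param imageNoiseSd per-pixel Gaussian noise on the image (default 10).
#' @param pixelSpacing pixel distance between neighbouring spots
#'   (default 20).
#' @param seed integer seed; the section is bit-reproducible given it.
#' @return A [SpatialSection-class] with planted labels in
#'   \code{colData()$domain}.
#' @examples
#' sec <- simulateSection(nRows = 10, nCols = 10, seed = 1)
#' table(sec$domain)
#' @export
simulateSection <- function(nRows = 30, nCols = 30, nDomains = 3,
                            domainGeometry = c("layered", "blocks",
                                               "voronoi"),
                            nGenes = 500, nMarkersPerDomain = 50,
                            markerFoldChange = 5, baseMean = 2,
                            dispersion = 0.5, imageDomainTint = NULL,
                            imageNoiseSd = 10, pixelSpacing = 20,
                            seed = 1) {
  domainGeometry <- match.arg(domainGeometry)
  nSpots <- nRows * nCols
  if (nDomains > nSpots) stop("nDomains exceeds the number of spots")
  if (nDomains * nMarkersPerDomain > nGenes)
    stop("marker sets exceed the total gene count")
  stopifnot(markerFoldChange > 0, baseMean > 0, dispersion > 0)
  set.seed(seed)

  ## hexagonal-offset grid in pixel units
  gi <- rep(seq_len(nRows), each = nCols)
  gj <- rep(seq_len(nCols), times = nRows)
  px_row <- gi * pixelSpacing * sqrt(3) / 2
  px_col <- (gj + 0.5 * (gi %% 2)) * pixelSpacing
  coords <- cbind(pxl_row = px_row, pxl_col = px_col)

  domain <- switch(domainGeometry,
    layered = as.integer(ceiling(gi / nRows * nDomains)),
    blocks = {
      nb <- ceiling(sqrt(nDomains))
      br <- ceiling(gi / nRows * nb)
      bc <- ceiling(gj / nCols * nb)
      as.integer(((br - 1L) * nb + bc - 1L) %% nDomains + 1L)
    },
    voronoi = {
      seeds <- sample.int(nSpots, nDomains)
      d2 <- outer(rowSums(coords^2), rowSums(coords[seeds, , drop = FALSE]^2),
                  `+`) - 2 * tcrossprod(coords, coords[seeds, , drop = FALSE])
      max.col(-d2, ties.method = "first")
    })

  ## counts: NB with domain-specific marker up-regulation
  baseMu <- stats::rlnorm(nGenes, meanlog = log(baseMean), sdlog = 0.5)
  markers <- split(seq_len(nDomains * nMarkersPerDomain),
                   rep(seq_len(nDomains), each = nMarkersPerDomain))
  mu <- matrix(baseMu, nSpots, nGenes, byrow = TRUE)
  for (d in seq_len(nDomains))
    mu[domain == d, markers[[d]]] <- mu[domain == d, markers[[d]]] *
      markerFoldChange
  counts <- matrix(stats::rnbinom(nSpots * nGenes, mu = mu,
                                  size = 1 / dispersion),
                   nSpots, nGenes)

  ## fake stained image: base stain + per-domain tint + pixel noise
  if (is.null(imageDomainTint)) {
    hue <- seq(0, 2 * pi, length.out = nDomains + 1L)[seq_len(nDomains)]
    imageDomainTint <- cbind(40 * cos(hue), 40 * cos(hue + 2 * pi / 3),
                             40 * cos(hue + 4 * pi / 3))
  }
  H <- ceiling(max(px_row) + pixelSpacing)
  W <- ceiling(max(px_col) + pixelSpacing)
  ## nearest grid row/col per pixel recovers the domain cheaply
  prow <- pmin(pmax(round(seq_len(H) / (pixelSpacing * sqrt(3) / 2)), 1L),
               nRows)
  img <- array(0, dim = c(H, W, 3))
  base <- c(200, 160, 185)                       # eosin-like background
  for (ch in 1:3) {
    tintRow <- matrix(0, H, W)
    for (r in seq_len(H)) {
      pcol <- pmin(pmax(round(seq_len(W) / pixelSpacing -
                                0.5 * (prow[r] %% 2)), 1L), nCols)
      dom <- domain[(prow[r] - 1L) * nCols + pcol]
      tintRow[r, ] <- imageDomainTint[dom, ch]
    }
    img[, , ch] <- pmin(pmax(base[ch] + tintRow +
                               matrix(stats::rnorm(H * W, 0, imageNoiseSd),
                                      H, W), 0), 255)
  }

  spotIds <- sprintf("spot_%03d_%03d", gi, gj)
  section <- SpatialSection(counts, coords, image = img,
                            spotIds = spotIds,
                            geneIds = sprintf("gene%04d", seq_len(nGenes)),
                            spotsInRows = TRUE)
  section$domain <- domain
  S4Vectors::metadata(section)$markers <- markers
  section
}

#' Random dropout corruption of the count matrix
#'
#' Independently sets each count to zero with probability \code{ratio},
#' emulating increased expression-matrix sparsity. Ratios above 0.7 are
#' rejected: beyond that the matrix becomes too sparse for the feature
#' pipeline the model requires.
#'
#' @param section a [SpatialSection-class].
#' @param ratio dropout probability per entry, in [0, 0.7].
#' @param seed integer seed; the mask is deterministic given it.
#' @return A new [SpatialSection-class] with the corrupted counts.
#' @export
applyDropout <- function(section, ratio, seed = 1) {
  if (ratio < 0) stop("dropout ratio must be non-negative")
  if (ratio > 0.7)
    stop("dropout ratio capped at 0.7: beyond it the matrix is too ",
         "sparse for the model's feature requirements")
  if (ratio == 0) return(section)
  set.seed(seed)
  cts <- SummarizedExperiment::assay(section, "counts")
  ## zeros stay zero, so masking the nonzero entries suffices
  keep <- stats::rbinom(length(cts@x), 1L, 1 - ratio)
  cts@x <- cts@x * keep
  cts <- Matrix::drop0(cts)
  out <- section
  SummarizedExperiment::assay(out, "counts") <- cts
  out
}

#' Additive Poisson noise on the count matrix
#'
#' Adds an independent Poisson draw to every count, with mean
#' \eqn{\lambda = \mathrm{level} \times \mathrm{mean\ expression}}. The
#' mean expression is the grand mean of the count matrix by default, or
#' per-gene means with \code{meanMode = "per_gene"}.
#'
#' @param section a [SpatialSection-class].
#' @param level noise level (positive fraction of the mean, e.g. 0.1--0.9).
#' @param seed integer seed.
#' @param meanMode \code{"grand"} or \code{"per_gene"}.
#' @return A new [SpatialSection-class]; counts remain non-negative
#'   integers and never decrease.
#' @export
applyPoissonNoise <- function(section, level, seed = 1,
                              meanMode = c("grand", "per_gene")) {
  meanMode <- match.arg(meanMode)
  if (level < 0) stop("noise level must be non-negative")
  set.seed(seed)
  cts <- as.matrix(SummarizedExperiment::assay(section, "counts"))
  lambda <- if (meanMode == "grand") rep(level * mean(cts), length(cts))
            else rep(level * rowMeans(cts), times = ncol(cts))
  noise <- stats::rpois(length(cts), lambda)
  out <- section
  SummarizedExperiment::assay(out, "counts") <-
    methods::as(methods::as(cts + noise, "CsparseMatrix"), "generalMatrix")
  out
}
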