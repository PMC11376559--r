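#' Extract per-spot histology texture and intensity features
#'
#' For every spot, a square patch of side \code{patchPx} pixels centred on
#' the spot coordinate (clipped at image borders) is cut from the tissue
#' image. The grayscale patch is contrast-normalised with CLAHE, a
#' gray-level co-occurrence matrix (GLCM) is accumulated over it, and six
#' texture statistics are computed -- contrast, dissimilarity,
#' homogeneity, angular second moment, entropy, correlation -- plus the
#' mean R, G, B intensities of the raw patch.
#'
#' GLCM convention: 64 gray levels, offset distance 1, the four angles
#' 0/45/90/135 degrees, symmetric and normalised co-occurrence matrix;
#' statistics are averaged over the angles. Entropy is
#' \eqn{-\sum p \log_2 p} over nonzero cells. When \code{patchPx = NULL}
#' and Space Ranger scale factors are attached to the section, the patch
#' side defaults to the spot diameter.
#'
#' @param section a [SpatialSection-class] with a tissue image.
#' @param patchPx patch side length in pixels (default 50).
#' @param clahe apply contrast-limited adaptive histogram equalisation to
#'   each grayscale patch before the GLCM (default TRUE; skipped for
#'   patches under 8 px).
#' @return A [HistologyFeatures-class], spots x 9.
#' @export
extractHistologyFeatures <- function(section, patchPx = 50, clahe = TRUE) {
  img <- tissueImage(section)
  if (is.null(img))
    stop("section has no tissue image; run the 2-view ablation ",
         "(views spatial + expression) instead")
  if (is.null(patchPx)) {
    sf <- S4Vectors::metadata(section)$scalefactors
    patchPx <- if (!is.null(sf$spot_diameter_fullres))
      max(8L, round(sf$spot_diameter_fullres)) else 50L
  }
  xy <- spatialCoords(section)
  H <- dim(img)[1]; W <- dim(img)[2]
  bad <- xy[, 1] < 1 | xy[, 1] > H | xy[, 2] < 1 | xy[, 2] > W
  if (any(bad))
    stop("spot(s) outside image bounds: ",
         paste(utils::head(rownames(xy)[bad], 5), collapse = ", "))
  half <- patchPx %/% 2
  gray <- 0.2125 * img[, , 1] + 0.7154 * img[, , 2] + 0.0721 * img[, , 3]
  out <- matrix(NA_real_, nrow(xy), 9,
                dimnames = list(rownames(xy),
                                c("contrast", "dissimilarity", "homogeneity",
                                  "ASM", "entropy", "correlation",
                                  "mean_R", "mean_G", "mean_B")))
  for (s in seq_len(nrow(xy))) {
    r0 <- max(1L, round(xy[s, 1]) - half); r1 <- min(H, round(xy[s, 1]) + half)
    c0 <- max(1L, round(xy[s, 2]) - half); c1 <- min(W, round(xy[s, 2]) + half)
    g <- gray[r0:r1, c0:c1, drop = FALSE] / 255
    if (clahe && min(dim(g)) >= 8L) {
      ## tile count 2 needs even dims; trim at most one row/column
      g2 <- g[seq_len(nrow(g) - nrow(g) %% 2L),
              seq_len(ncol(g) - ncol(g) %% 2L), drop = FALSE]
      g <- EBImage::clahe(g2, nx = 2, ny = 2, limit = 2)
    }
    out[s, 1:6] <- glcmStats(glcmMatrix(g, levels = 64L))
    out[s, 7:9] <- c(mean(img[r0:r1, c0:c1, 1]),
                     mean(img[r0:r1, c0:c1, 2]),
                     mean(img[r0:r1, c0:c1, 3]))
  }
  methods::new("HistologyFeatures", F = out)
}

#' Gray-level co-occurrence matrix of a grayscale patch
#'
#' Quantises a [0,1] grayscale matrix to \code{levels} bins and counts
#' co-occurring level pairs at offset distance 1 along each requested
#' angle. Each angle's matrix is made symmetric (counts accumulated in
#' both directions) and normalised to sum to 1.
#'
#' @param g numeric matrix in [0,1] (rows = image rows).
#' @param levels number of gray levels (default 64).
#' @param angles offset angles in degrees; subset of \code{c(0,45,90,135)}.
#' @return A list of \code{levels x levels} normalised symmetric GLCMs,
#'   one per angle.
#' @export
glcmMatrix <- function(g, levels = 64L, angles = c(0, 45, 90, 135)) {
  q <- pmin(floor(pmax(pmin(g, 1), 0) * levels), levels - 1L) + 1L
  nr <- nrow(q); nc <- ncol(q)
  ## (dr, dc) per angle, image convention: row down, col right
  offs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
               `90` = c(-1L, 0L), `135` = c(-1L, -1L))
  lapply(as.character(angles), function(a) {
    d <- offs[[a]]
    rs <- seq_len(nr); cs <- seq_len(nc)
    rOK <- rs[rs + d[1] >= 1 & rs + d[1] <= nr]
    cOK <- cs[cs + d[2] >= 1 & cs + d[2] <= nc]
    m <- matrix(0, levels, levels)
    if (length(rOK) && length(cOK)) {
      from <- q[rOK, cOK, drop = FALSE]
      to <- q[rOK + d[1], cOK + d[2], drop = FALSE]
      tab <- table(factor(from, levels = seq_len(levels)),
                   factor(to, levels = seq_len(levels)))
      m <- unclass(tab) + t(unclass(tab))
      m <- m / sum(m)
    }
    m
  })
}

#' Texture statistics of a (list of) normalised GLCM(s)
#'
#' @param glcm a normalised GLCM matrix or a list of them (statistics are
#'   averaged over the list).
#' @return Named vector: contrast, dissimilarity, homogeneity, ASM,
#'   entropy, correlation.
#' @export
glcmStats <- function(glcm) {
  if (!is.list(glcm)) glcm <- list(glcm)
  one <- function(p) {
    L <- nrow(p)
    i <- row(p) - 1; j <- col(p) - 1
    mui <- sum(i * p); muj <- sum(j * p)
    vi <- sum((i - mui)^2 * p); vj <- sum((j - muj)^2 * p)
    corr <- if (vi * vj > 1e-15)
      sum((i - mui) * (j - muj) * p) / sqrt(vi * vj) else 1
    nz <- p[p > 0]
    c(contrast = sum(p * (i - j)^2),
      dissimilarity = sum(p * abs(i - j)),
      homogeneity = sum(p / (1 + (i - j)^2)),
      ASM = sum(p^2),
      entropy = -sum(nz * log2(nz)),
      correlation = corr)
  }
  rowMeans(vapply(glcm, one, numeric(6)))
}

#' Export histology features as CSV
#'
#' @param hfeat a [HistologyFeatures-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
exportHistologyFeatures <- function(hfeat, path) {
  utils::write.csv(data.frame(spot_id = rownames(hfeat@F), hfeat@F,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
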