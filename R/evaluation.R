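#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions via pair counting on
#' the contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} -
#'   [\sum_i \binom{a_i}{2}\sum_j \binom{b_j}{2}] / \binom{n}{2}}
#'   {\frac12[\sum_i\binom{a_i}{2}+\sum_j\binom{b_j}{2}] -
#'   [\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}] / \binom{n}{2}}}
#'
#' Identical partitions (up to relabelling) score 1; random labellings
#' score about 0. Spots with a missing (NA) truth or predicted label are
#' excluded with a message. When both partitions have a single cluster
#' the denominator degenerates; 1 is returned by convention.
#'
#' @param truth,predicted label vectors of equal length (any atomic
#'   type; labelling is arbitrary).
#' @return ARI in [-1, 1].
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjustedRandIndex <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  ok <- !is.na(truth) & !is.na(predicted)
  if (!all(ok)) {
    message(sum(!ok), " spot(s) without annotation excluded from ARI")
    truth <- truth[ok]; predicted <- predicted[ok]
  }
  n <- length(truth)
  if (n < 2L) stop("need at least 2 annotated spots")
  tab <- table(truth, predicted)
  sumNij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expIdx <- sumA * sumB / choose(n, 2)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expIdx) return(1)               # both single-cluster
  (sumNij - expIdx) / (maxIdx - expIdx)
}

#' Contingency table of two partitions
#'
#' @param truth,predicted label vectors of equal length.
#' @return Integer matrix n_ij: truth classes in rows, predicted
#'   clusters in columns.
#' @export
partitionContingency <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  unclass(table(truth, predicted))
}
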