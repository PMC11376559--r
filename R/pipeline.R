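#' Run the full spatial-domain pipeline on a section
#'
#' Orchestrates preprocess -> graph construction -> model fit -> labels
#' for any subset of the three views. With an output directory, writes
#' \code{labels.csv} (spot_id, domain), \code{embedding.tsv} (fused Z),
#' \code{loss_trace.csv}, and a \code{config.json} echo carrying the
#' seed, so a run can be reproduced exactly.
#'
#' @param input a [SpatialSection-class] or a path to a Space Ranger
#'   directory for [readVisium()].
#' @param nDomains number of spatial domains; \code{NULL} to estimate by
#'   Louvain clustering on the first active view's graph.
#' @param views character subset of
#'   \code{c("spatial", "expression", "histology")} (order defines the
#'   view order; at least one).
#' @param config a [mvstConfig()].
#' @param nHVG,nPCs,minCells preprocessing parameters (see
#'   [preprocessSection()]).
#' @param k neighbours per spot for all graphs (default 10).
#' @param patchPx histology patch side in pixels; \code{NULL} for
#'   spot-diameter auto mode.
#' @param out optional output directory.
#' @return List: \code{section}, \code{features}, \code{graphs},
#'   \code{fit} (the [fitMVST()] result), \code{labels}, \code{nDomains}.
#' @export
runMVST <- function(input, nDomains = NULL,
                    views = c("spatial", "expression", "histology"),
                    config = mvstConfig(), nHVG = 2000, nPCs = 1000,
                    minCells = 5, k = 10, patchPx = 50, out = NULL) {
  views <- match.arg(views, c("spatial", "expression", "histology"),
                     several.ok = TRUE)
  if (length(views) < 1L) stop("at least one view must be active")
  section <- if (methods::is(input, "SpatialSection")) input else
    readVisium(input)
  features <- preprocessSection(section, nHVG = nHVG, nPCs = nPCs,
                                minCells = minCells)
  graphs <- lapply(views, function(v) switch(v,
    spatial = buildSpatialGraph(section, k = k),
    expression = buildExpressionGraph(
      features, k = k, nPCsGraph = min(50L, features@pcaComponents)),
    histology = buildHistologyGraph(
      extractHistologyFeatures(section, patchPx = patchPx), k = k)))
  fit <- fitMVST(features, graphs, nDomains = nDomains, config = config)
  labels <- domainLabels(fit$assignment)
  if (is.null(nDomains)) nDomains <- ncol(fit$assignment@P)

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(spot_id = names(labels), domain = labels),
                     file.path(out, "labels.csv"), row.names = FALSE,
                     quote = FALSE)
    Z <- fit$assignment@Z
    utils::write.table(data.frame(spot_id = rownames(Z), Z,
                                  check.names = FALSE),
                       file.path(out, "embedding.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.csv(fit$lossTrace, file.path(out, "loss_trace.csv"),
                     row.names = FALSE, quote = FALSE)
    echo <- c(unclass(config),
              list(views = views, n_domains = nDomains, n_hvg = nHVG,
                   n_pcs = nPCs, min_cells = minCells, k = k,
                   package_version = as.character(
                     utils::packageVersion("MVST"))))
    jsonlite::write_json(echo, file.path(out, "config.json"),
                         auto_unbox = TRUE, null = "null")
  }
  list(section = section, features = features, graphs = graphs,
       fit = fit, labels = labels, nDomains = nDomains)
}
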