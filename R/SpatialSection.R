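#' Construct a SpatialSection
#'
#' @param counts gene x spot count matrix (dense or sparse); dimnames give
#'   gene and spot identifiers. A spot x gene matrix is accepted when
#'   \code{spotsInRows = TRUE}.
#' @param coords spot x 2 numeric matrix of (pixel row, pixel column)
#'   coordinates, rows aligned with the spots of \code{counts}.
#' @param image optional H x W x 3 tissue image, values 0--255 (a 0--1
#'   image is rescaled).
#' @param spotIds,geneIds identifiers used when \code{counts} lacks
#'   dimnames.
#' @param spotsInRows set TRUE when \code{counts} is spot x gene.
#'
#' @return A [SpatialSection-class] object.
#' @examples
#' cts <- matrix(rpois(50, 2), nrow = 10,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
#' xy <- cbind(pxl_row = 1:5, pxl_col = 1:5)
#' SpatialSection(cts, xy)
#' @export
SpatialSection <- function(counts, coords, image = NULL, spotIds = NULL,
                           geneIds = NULL, spotsInRows = FALSE) {
  if (spotsInRows) counts <- Matrix::t(counts)
  if (!is.null(spotIds)) colnames(counts) <- spotIds
  if (!is.null(geneIds)) rownames(counts) <- geneIds
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("spot", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(colnames(coords))) colnames(coords) <- c("pxl_row", "pxl_col")
  rownames(coords) <- colnames(counts)
  if (!is.null(image)) {
    image <- normalizeImage(image)
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
  methods::new("SpatialSection", sce, spatialCoords = coords,
               tissueImage = image)
}

## accept 0-1 or 0-255, grayscale or RGB; store 0-255 H x W x 3
normalizeImage <- function(image) {
  image <- as.array(image)
  if (length(dim(image)) == 2L)
    image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  if (dim(image)[3] > 3L) image <- image[, , 1:3, drop = FALSE]
  if (max(image) <= 1) image <- image * 255
  image
}

#' @rdname spatialCoords
#' @param x a \code{SpatialSection}
#' @return \code{spatialCoords}: spot x 2 coordinate matrix.
#' @export
setMethod("spatialCoords", "SpatialSection", function(x) x@spatialCoords)

#' @rdname tissueImage
#' @param x a \code{SpatialSection}
#' @return \code{tissueImage}: the H x W x 3 image array, or \code{NULL}.
#' @export
setMethod("tissueImage", "SpatialSection", function(x) x@tissueImage)

#' @rdname spotCounts
#' @param x a \code{SpatialSection}
#' @return \code{spotCounts}: the count matrix oriented spot x gene
#'   (sparse).
#' @export
setMethod("spotCounts", "SpatialSection", function(x)
  Matrix::t(SummarizedExperiment::assay(x, "counts")))

#' @export
setMethod("show", "SpatialSection", function(object) {
  cat("SpatialSection:", ncol(object), "spots x", nrow(object), "genes\n")
  cat("  image:", if (is.null(object@tissueImage)) "none" else
    paste(dim(object@tissueImage)[1:2], collapse = " x "), "\n")
  if ("domain" %in% colnames(SummarizedExperiment::colData(object)))
    cat("  planted domains:",
        length(unique(object$domain)), "\n")
  invisible(NULL)
})

setMethod("[", c("SpatialSection", "ANY", "ANY"), function(x, i, j, ...,
                                                           drop = FALSE) {
  out <- methods::callNextMethod()
  if (!missing(j)) {
    jj <- if (is.character(j)) match(j, colnames(x)) else seq_len(ncol(x))[j]
    out@spatialCoords <- x@spatialCoords[jj, , drop = FALSE]
  }
  out
})

#' Read a 10X Visium Space Ranger directory
#'
#' Expects the Space Ranger layout: a Matrix Market count matrix
#' (\code{matrix.mtx[.gz]}) with \code{barcodes.tsv[.gz]} and
#' \code{features.tsv[.gz]} (or \code{genes.tsv}), either directly under
#' \code{path} or in a \code{filtered_feature_bc_matrix}/\code{raw_feature_bc_matrix}
#' subdirectory, plus a tissue-position table
#' (\code{tissue_positions[_list].csv}, directly or under \code{spatial/}).
#' A PNG/TIFF tissue image is attached when present. Spots flagged as not
#' under tissue are dropped.
#'
#' @param path directory containing the section.
#' @return A [SpatialSection-class].
#' @export
readVisium <- function(path) {
  if (!dir.exists(path)) stop("input directory not found: ", path)
  findFile <- function(names, dirs = c(".", "filtered_feature_bc_matrix",
                                       "raw_feature_bc_matrix", "spatial")) {
    for (d in dirs) for (nm in names) {
      f <- file.path(path, d, nm)
      if (file.exists(f)) return(f)
    }
    NULL
  }
  mtx <- findFile(c("matrix.mtx", "matrix.mtx.gz"))
  if (is.null(mtx)) stop("input-format error: no matrix.mtx[.gz] under ", path)
  bcf <- findFile(c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(bcf)) stop("input-format error: no barcodes.tsv[.gz] under ", path)
  ftf <- findFile(c("features.tsv", "features.tsv.gz", "genes.tsv",
                    "genes.tsv.gz"))
  if (is.null(ftf)) stop("input-format error: no features.tsv[.gz] under ", path)
  posf <- findFile(c("tissue_positions.csv", "tissue_positions_list.csv"))
  if (is.null(posf))
    stop("input-format error: no tissue_positions[_list].csv under ", path)

  m <- Matrix::readMM(mtx)                       # genes x barcodes
  barcodes <- readLines(bcf)
  features <- utils::read.delim(ftf, header = FALSE,
                                stringsAsFactors = FALSE)
  geneIds <- if (ncol(features) >= 2) make.unique(features[[2]]) else
    features[[1]]
  if (nrow(m) != length(geneIds) || ncol(m) != length(barcodes))
    stop("consistency error: matrix dimensions do not match ",
         "features/barcodes listings")

  ## tissue_positions.csv has a header; tissue_positions_list.csv does not
  first <- readLines(posf, n = 1L)
  hasHeader <- grepl("barcode", first, ignore.case = TRUE)
  pos <- utils::read.csv(posf, header = hasHeader,
                         stringsAsFactors = FALSE)
  if (!hasHeader)
    colnames(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                       "pxl_row_in_fullres", "pxl_col_in_fullres")
  idx <- match(barcodes, pos$barcode)
  if (anyNA(idx))
    stop("consistency error: ", sum(is.na(idx)),
         " barcode(s) in the matrix are absent from the position table")
  pos <- pos[idx, , drop = FALSE]
  keep <- pos$in_tissue == 1
  m <- m[, keep, drop = FALSE]
  coords <- cbind(pxl_row = as.numeric(pos$pxl_row_in_fullres[keep]),
                  pxl_col = as.numeric(pos$pxl_col_in_fullres[keep]))

  imgf <- findFile(c("tissue_hires_image.png", "tissue_lowres_image.png",
                     "tissue_image.png", "image.png", "tissue_image.tiff",
                     "image.tiff"))
  image <- NULL
  if (!is.null(imgf)) {
    image <- if (grepl("\\.png$", imgf)) png::readPNG(imgf) else
      as.array(EBImage::imageData(EBImage::readImage(imgf)))
    if (grepl("\\.tiff?$", imgf) && length(dim(image)) == 3L)
      image <- aperm(image, c(2, 1, 3))          # EBImage stores x,y
  }
  section <- SpatialSection(m, coords, image = image,
                            spotIds = barcodes[keep], geneIds = geneIds)
  scf <- findFile("scalefactors_json.json")
  if (!is.null(scf))
    S4Vectors::metadata(section)$scalefactors <-
      jsonlite::read_json(scf, simplifyVector = TRUE)
  section
}

#' Write a SpatialSection as a Space Ranger-style directory
#'
#' Emits \code{matrix.mtx}, \code{barcodes.tsv}, \code{features.tsv},
#' \code{spatial/tissue_positions.csv} and, when an image is attached,
#' \code{spatial/tissue_image.png}, so the directory round-trips through
#' [readVisium()]. Planted domain labels (colData column \code{domain}, if
#' present) are written to \code{truth_labels.csv}.
#'
#' @param section a [SpatialSection-class].
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
writeVisium <- function(section, path) {
  dir.create(file.path(path, "spatial"), recursive = TRUE,
             showWarnings = FALSE)
  cts <- SummarizedExperiment::assay(section, "counts")
  Matrix::writeMM(cts, file.path(path, "matrix.mtx"))
  writeLines(colnames(section), file.path(path, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = rownames(section), name = rownames(section),
               type = "Gene Expression"),
    file.path(path, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  xy <- spatialCoords(section)
  pos <- data.frame(barcode = colnames(section), in_tissue = 1L,
                    array_row = 0L, array_col = 0L,
                    pxl_row_in_fullres = xy[, 1],
                    pxl_col_in_fullres = xy[, 2])
  utils::write.csv(pos, file.path(path, "spatial", "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  img <- tissueImage(section)
  if (!is.null(img))
    png::writePNG(img / 255, file.path(path, "spatial", "tissue_image.png"))
  if ("domain" %in% colnames(SummarizedExperiment::colData(section)))
    utils::write.csv(
      data.frame(spot_id = colnames(section), domain = section$domain),
      file.path(path, "truth_labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}
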