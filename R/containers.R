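# Lightweight S3 containers for the pipeline's intermediate data.

#' Spot-resolution expression matrix
#'
#' Sparse triplet table of deduplicated molecule counts per gene and spot.
#'
#' @param data `data.table` (or coercible) with columns `gene`, `x`, `y`,
#'   `count`; one row per (gene, spot), counts >= 1.
#' @param pitch_nm Centre-to-centre spot distance in nanometres.
#' @return Object of class `SpotMatrix`.
#' @export
spot_matrix <- function(data, pitch_nm = 500L) {
  dt <- data.table::as.data.table(data)
  req <- c("gene", "x", "y", "count")
  if (!all(req %in% names(dt))) {
    abort_input("SpotMatrix needs columns gene, x, y, count")
  }
  dt <- dt[count > 0, .(count = sum(count)), by = .(gene, x, y)]
  if (nrow(dt) && (any(dt$x < 0) || any(dt$y < 0))) {
    abort_input("spot coordinates must be non-negative")
  }
  data.table::setkey(dt, gene, x, y)
  structure(list(data = dt, pitch_nm = as.integer(pitch_nm)),
            class = "SpotMatrix")
}

#' @export
print.SpotMatrix <- function(x, ...) {
  cat(sprintf("SpotMatrix: %d triplets, %d genes, %d spots, pitch %d nm\n",
              nrow(x$data), data.table::uniqueN(x$data$gene),
              data.table::uniqueN(x$data[, .(x, y)]), x$pitch_nm))
  invisible(x)
}

#' Bin-resolution expression matrix
#'
#' As [spot_matrix()] but aggregated over square bins of `bin_size` x
#' `bin_size` spots (DNBs).
#'
#' @param data `data.table` with columns `gene`, `bin_x`, `bin_y`, `count`.
#' @param bin_size Bin edge in spots (20 for developmental hearts, 50 for
#'   adult).
#' @param pitch_nm Spot pitch of the source matrix.
#' @return Object of class `BinMatrix`.
#' @export
bin_matrix <- function(data, bin_size, pitch_nm = 500L) {
  dt <- data.table::as.data.table(data)
  req <- c("gene", "bin_x", "bin_y", "count")
  if (!all(req %in% names(dt))) {
    abort_input("BinMatrix needs columns gene, bin_x, bin_y, count")
  }
  dt <- dt[count > 0, .(count = sum(count)), by = .(gene, bin_x, bin_y)]
  if (nrow(dt) && (any(dt$bin_x < 0) || any(dt$bin_y < 0))) {
    abort_input("bin indices must be non-negative")
  }
  data.table::setkey(dt, gene, bin_x, bin_y)
  structure(list(data = dt, bin_size = as.integer(bin_size),
                 pitch_nm = as.integer(pitch_nm)),
            class = "BinMatrix")
}

#' @export
print.BinMatrix <- function(x, ...) {
  cat(sprintf("BinMatrix: %d triplets, %d genes, %d bins (bin %d, pitch %d nm)\n",
              nrow(x$data), data.table::uniqueN(x$data$gene),
              data.table::uniqueN(x$data[, .(bin_x, bin_y)]),
              x$bin_size, x$pitch_nm))
  invisible(x)
}

#' Cell-by-gene expression container
#'
#' Sparse gene x cell count matrix with per-cell metadata. QC metrics
#' (nUMI = column sum, nFeatures = column nonzero count, mito_fraction =
#' mitochondrial counts / nUMI) are recomputed from the matrix so they can
#' never drift from it.
#'
#' @param counts `dgCMatrix` (genes x cells) with dimnames.
#' @param meta `data.frame`/`data.table` with one row per cell, containing at
#'   least `barcode` and `stage`; extra truth columns are preserved.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return Object of class `CellExpr` with elements `counts`, `meta`,
#'   `mito_prefix`.
#' @export
cell_expr <- function(counts, meta, mito_prefix = "mt-") {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    abort_input("counts must carry gene rownames and cell colnames")
  }
  counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  meta <- data.table::as.data.table(meta)
  if (!all(c("barcode", "stage") %in% names(meta))) {
    abort_input("meta needs columns barcode and stage")
  }
  if (nrow(meta) != ncol(counts) ||
      !identical(as.character(meta$barcode), as.character(colnames(counts)))) {
    abort_input("meta rows must match counts columns (same barcodes, same order)")
  }
  mito <- startsWith(rownames(counts), mito_prefix)
  numi <- Matrix::colSums(counts)
  meta$nUMI <- as.numeric(numi)
  meta$nFeatures <- Matrix::colSums(counts > 0)
  meta$mito_fraction <- ifelse(numi > 0,
                               Matrix::colSums(counts[mito, , drop = FALSE]) / numi,
                               0)
  structure(list(counts = counts, meta = meta, mito_prefix = mito_prefix),
            class = "CellExpr")
}

#' @export
print.CellExpr <- function(x, ...) {
  cat(sprintf("CellExpr: %d genes x %d cells, stages: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$meta$stage)), collapse = ", ")))
  invisible(x)
}

#' Number of cells in a CellExpr
#' @param ce A [cell_expr()] object.
#' @return Integer cell count.
#' @export
n_cells <- function(ce) ncol(ce$counts)

# Subset a CellExpr by a logical/integer cell index, keeping meta in sync.
subset_cells <- function(ce, idx) {
  cell_expr(ce$counts[, idx, drop = FALSE],
            ce$meta[idx, !c("nUMI", "nFeatures", "mito_fraction"),
                    with = FALSE],
            mito_prefix = ce$mito_prefix)
}

#' Ordered stack of RGB section images
#'
#' @param images List of numeric arrays `height x width x 3` with values in
#'   0--255.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param dz_um Section thickness (slice spacing) in micrometres.
#' @return Object of class `SectionStack`.
#' @export
section_stack <- function(images, pixel_size_um = 1, dz_um = 10) {
  if (!length(images)) abort_input("section stack must contain >= 1 image")
  dims <- vapply(images, function(im) dim(im)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort_input("all section images must share dimensions")
  }
  structure(list(images = images, pixel_size_um = pixel_size_um,
                 dz_um = dz_um),
            class = "SectionStack")
}

#' @export
print.SectionStack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("SectionStack: %d slices of %dx%d px (%.3g um/px, dz %.3g um)\n",
              length(x$images), d[1], d[2], x$pixel_size_um, x$dz_um))
  invisible(x)
}

#' 3D scalar volume on a regular grid
#'
#' @param data Numeric 3D array indexed `[y, x, z]`.
#' @param spacing Numeric `c(dx_um, dy_um, dz_um)`.
#' @param origin Numeric `c(x0, y0, z0)`; default zeros.
#' @return Object of class `Volume`.
#' @export
volume_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) abort_input("volume data must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort_input("spacing must be three positive numbers")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "Volume")
}

#' @export
print.Volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Volume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um\n",
              d[2], d[1], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}
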