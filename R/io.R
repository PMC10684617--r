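# Plain-text readers/writers for the pipeline's external formats.

#' Write a spot or bin matrix as GEM-style TSV
#'
#' Tab-separated with header `geneID  x  y  MIDCount`; bin matrices write
#' their bin indices as `x`/`y` and record `bin_size` in a leading comment.
#'
#' @param m A [spot_matrix()] or [bin_matrix()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gem <- function(m, path) {
  if (inherits(m, "BinMatrix")) {
    hdr <- sprintf("#pitch_nm=%d bin_size=%d", m$pitch_nm, m$bin_size)
    out <- m$data[, .(geneID = gene, x = bin_x, y = bin_y, MIDCount = count)]
  } else if (inherits(m, "SpotMatrix")) {
    hdr <- sprintf("#pitch_nm=%d", m$pitch_nm)
    out <- m$data[, .(geneID = gene, x, y, MIDCount = count)]
  } else {
    abort_input("write_gem expects a SpotMatrix or BinMatrix")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("geneID", "x", "y", "MIDCount"), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(out, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a GEM-style TSV
#'
#' @param path File written by [write_gem()] (or any
#'   `geneID/x/y/MIDCount` TSV; a missing comment line implies pitch 500 and
#'   spot resolution).
#' @return A [spot_matrix()] or, when the header records a `bin_size`, a
#'   [bin_matrix()].
#' @export
read_gem <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L)
  pitch <- 500L
  bin_size <- NA_integer_
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    pm <- regmatches(first, regexec("pitch_nm=(\\d+)", first))[[1]]
    if (length(pm) == 2L) pitch <- as.integer(pm[2])
    bm <- regmatches(first, regexec("bin_size=(\\d+)", first))[[1]]
    if (length(bm) == 2L) bin_size <- as.integer(bm[2])
  }
  dt <- data.table::fread(path, skip = skip, sep = "\t", header = TRUE,
                          colClasses = list(character = "geneID"))
  if (is.na(bin_size)) {
    spot_matrix(dt[, .(gene = geneID, x, y, count = MIDCount)],
                pitch_nm = pitch)
  } else {
    bin_matrix(dt[, .(gene = geneID, bin_x = x, bin_y = y, count = MIDCount)],
               bin_size = bin_size, pitch_nm = pitch)
  }
}

#' Write synthetic reads as TSV
#'
#' Columns: `cid`, `mid`, `quals` (phred+33 ASCII string), `gene`.
#'
#' @param reads `data.table` with those columns (as from [gen_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  data.table::fwrite(reads[, .(cid, mid, quals, gene)], path, sep = "\t")
  invisible(path)
}

#' Read a reads TSV written by [write_reads()]
#' @param path Input path.
#' @return `data.table` with columns `cid`, `mid`, `quals`, `gene`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  data.table::fread(path, sep = "\t", header = TRUE,
                    colClasses = "character")
}

#' Write / read a CID whitelist
#'
#' Tab-separated `cid`, `x`, `y`: one spatial barcode per chip spot.
#'
#' @param wl `data.table` with columns `cid`, `x`, `y`.
#' @param path File path.
#' @return `path` (writer) or the whitelist `data.table` (reader).
#' @export
write_whitelist <- function(wl, path) {
  data.table::fwrite(wl[, .(cid, x, y)], path, sep = "\t")
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  data.table::fread(path, sep = "\t", header = TRUE,
                    colClasses = list(character = "cid"))
}

#' Write a CellExpr as MTX plus TSV sidecars
#'
#' Emits `matrix.mtx` (genes x cells), `features.tsv`, `barcodes.tsv` and
#' `metadata.tsv` under `dir`.
#'
#' @param ce A [cell_expr()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cellexpr <- function(ce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(ce$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(ce$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(ce$counts), file.path(dir, "barcodes.tsv"))
  data.table::fwrite(ce$meta, file.path(dir, "metadata.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a CellExpr written by [write_cellexpr()]
#' @param dir Directory holding `matrix.mtx` and sidecars.
#' @param mito_prefix Mitochondrial gene-name prefix.
#' @return A [cell_expr()] object.
#' @export
read_cellexpr <- function(dir, mito_prefix = "mt-") {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) abort_input(sprintf("no matrix.mtx under %s", dir))
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- data.table::fread(file.path(dir, "metadata.tsv"), sep = "\t")
  drop <- intersect(c("nUMI", "nFeatures", "mito_fraction"), names(meta))
  if (length(drop)) meta <- meta[, !drop, with = FALSE]
  cell_expr(counts, meta, mito_prefix = mito_prefix)
}

#' Write / read a section stack as numbered PNG files
#'
#' Slices are written as `slice_001.png`, `slice_002.png`, ... (8-bit RGB).
#'
#' @param stack A [section_stack()] object.
#' @param dir Directory for the PNGs (created if needed).
#' @param pixel_size_um,dz_um Geometry to attach on read.
#' @return `dir` (writer) or a [section_stack()] (reader).
#' @export
write_sections <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$images)) {
    png::writePNG(stack$images[[i]] / 255,
                  file.path(dir, sprintf("slice_%03d.png", i)))
  }
  writeLines(c(sprintf("pixel_size_um\t%.10g", stack$pixel_size_um),
               sprintf("dz_um\t%.10g", stack$dz_um)),
             file.path(dir, "geometry.tsv"))
  invisible(dir)
}

#' @rdname write_sections
#' @export
read_sections <- function(dir, pixel_size_um = NULL, dz_um = NULL) {
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) abort_input(sprintf("no slice_*.png under %s", dir))
  geom <- file.path(dir, "geometry.tsv")
  if (file.exists(geom)) {
    g <- data.table::fread(geom, header = FALSE)
    vals <- stats::setNames(g$V2, g$V1)
    pixel_size_um <- pixel_size_um %||% as.numeric(vals[["pixel_size_um"]])
    dz_um <- dz_um %||% as.numeric(vals[["dz_um"]])
  }
  images <- lapply(files, function(f) {
    im <- png::readPNG(f)
    if (length(dim(im)) == 2L) im <- array(rep(im, 3), c(dim(im), 3))
    round(im[, , 1:3, drop = FALSE] * 255)
  })
  section_stack(images, pixel_size_um = pixel_size_um %||% 1,
                dz_um = dz_um %||% 10)
}
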