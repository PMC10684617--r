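# Stage-aware single-cell QC, normalisation, marker scoring, Dbh selection.

#' Stage-aware quality-control filter
#'
#' A cell is kept iff `nUMI >= 300`, `nFeatures >= 270`, and its
#' mitochondrial fraction does not exceed its stage's ceiling (inclusive at
#' equality). Ceilings rise with developmental stage to track mitochondrial
#' biogenesis in maturing cardiomyocytes; see [stage_thresholds()].
#'
#' @param ce A [cell_expr()].
#' @param th Thresholds as from [stage_thresholds()] (override to customise).
#' @return Filtered [cell_expr()]; attribute `"attrition"` records how many
#'   cells each criterion removed.
#' @export
filter_cells <- function(ce, th = stage_thresholds()) {
  if (!inherits(ce, "CellExpr")) abort_input("ce must be a CellExpr")
  unknown <- setdiff(unique(ce$meta$stage), names(th$mito_max))
  if (length(unknown)) {
    abort_input(sprintf("unknown stage(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  m <- ce$meta
  pass_numi <- m$nUMI >= th$numi_min
  pass_nfeat <- m$nFeatures >= th$nfeat_min
  pass_mito <- m$mito_fraction <= th$mito_max[m$stage]
  keep <- pass_numi & pass_nfeat & pass_mito
  out <- subset_cells(ce, keep)
  attr(out, "attrition") <- data.table::data.table(
    criterion = c("nUMI", "nFeatures", "mito_fraction", "all"),
    n_failed = c(sum(!pass_numi), sum(!pass_nfeat), sum(!pass_mito),
                 sum(!keep)),
    n_in = nrow(m), n_out = sum(keep))
  out
}

#' Median-library normalisation
#'
#' Each cell's counts are scaled to the median library size and
#' log-transformed: `log1p(count / nUMI * median(nUMI))`. Deterministic and
#' scale-invariant per cell (doubling a cell's counts leaves its profile
#' unchanged).
#'
#' @param ce A filtered [cell_expr()].
#' @return Sparse genes x cells matrix of normalised expression.
#' @export
normalize_counts <- function(ce) {
  if (!inherits(ce, "CellExpr")) abort_input("ce must be a CellExpr")
  if (ncol(ce$counts) == 0L) abort_input("cannot normalise an empty matrix")
  numi <- ce$meta$nUMI
  if (any(numi == 0)) abort_input("cells with zero counts; filter first")
  scale <- stats::median(numi) / numi
  norm <- ce$counts %*% Matrix::Diagonal(x = scale)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(ce$counts)
  norm
}

#' Marker-score cell typing
#'
#' Marker genes are z-scored across cells on the normalised matrix; a
#' type's score per cell is the mean z of its `hi` markers minus the mean z
#' of its `lo` markers. Each cell is labelled with the argmax type; exact
#' ties are left unassigned (`NA`).
#'
#' @param norm Normalised genes x cells matrix (from [normalize_counts()]).
#' @param markers Marker table (`type`, `gene`, `direction`); default
#'   [default_marker_table()].
#' @return List: `label` (character per cell, `NA` for ties), `scores`
#'   (types x cells matrix).
#' @export
score_cell_types <- function(norm, markers = default_marker_table()) {
  markers <- data.table::as.data.table(markers)
  present <- markers$gene %in% rownames(norm)
  if (!any(present)) abort_input("no marker genes present in the matrix")
  markers <- markers[present]
  expr <- as.matrix(norm[unique(markers$gene), , drop = FALSE])
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (expr - mu) / sdv
  types <- unique(markers$type)
  scores <- matrix(0, length(types), ncol(norm),
                   dimnames = list(types, colnames(norm)))
  for (t in types) {
    hi <- markers[type == t & direction == "hi", gene]
    lo <- markers[type == t & direction == "lo", gene]
    s <- colMeans(z[hi, , drop = FALSE])
    if (length(lo)) s <- s - colMeans(z[lo, , drop = FALSE])
    scores[t, ] <- s
  }
  top <- apply(scores, 2L, max)
  n_top <- colSums(abs(sweep(scores, 2L, top)) < 1e-12)
  label <- types[apply(scores, 2L, which.max)]
  label[n_top > 1L] <- NA_character_
  list(label = label, scores = scores)
}

#' Select Dbh-positive cells
#'
#' Keeps cells whose raw Dbh count is greater than zero (selection is on raw
#' counts, not normalised values).
#'
#' @param ce A [cell_expr()].
#' @param gene Gene used for selection (default `"Dbh"`).
#' @return A [cell_expr()] subset.
#' @export
select_dbh_positive <- function(ce, gene = "Dbh") {
  if (!inherits(ce, "CellExpr")) abort_input("ce must be a CellExpr")
  if (!gene %in% rownames(ce$counts)) {
    abort_input(sprintf("gene '%s' absent from the matrix", gene))
  }
  pos <- as.vector(ce$counts[gene, ] > 0)
  subset_cells(ce, pos)
}
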