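# Dbh-status x cell-type contingency analysis and spatial co-localisation.

#' Pearson chi-squared test of Dbh status against cell type
#'
#' Builds the observed type x {Dbh+, Dbh-} table after removing excluded
#' types, computes the Pearson statistic `sum((O - E)^2 / E)` without
#' continuity correction, and derives the p-value from the chi-squared
#' survival function with `df = (rows - 1) * (cols - 1)`.
#'
#' @param labels Character/factor vector of per-cell type labels (`NA`
#'   dropped).
#' @param dbh_status Logical vector: `TRUE` = Dbh-positive.
#' @param excluded_types Types removed before tabulation (default
#'   [default_excluded_types()]).
#' @return Object of class `ContingencyResult`: `chi2`, `df`, `p`, `n`,
#'   `table`, `expected`, `excluded_types`.
#' @export
contingency_test <- function(labels, dbh_status,
                             excluded_types = default_excluded_types()) {
  if (length(labels) != length(dbh_status)) {
    abort_input("labels and dbh_status must have equal length")
  }
  keep <- !is.na(labels) & !labels %in% excluded_types
  labels <- as.character(labels[keep])
  dbh <- dbh_status[keep]
  types <- sort(unique(labels))
  if (length(types) < 2L) {
    abort_input("need >= 2 retained cell types for the independence test")
  }
  O <- cbind(dbh_pos = vapply(types, function(t) sum(labels == t & dbh),
                              numeric(1)),
             dbh_neg = vapply(types, function(t) sum(labels == t & !dbh),
                              numeric(1)))
  rownames(O) <- types
  if (any(colSums(O) == 0)) {
    abort_input("both Dbh statuses must be present to test independence")
  }
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  chi2 <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 n = as.integer(n), table = O, expected = E,
                 excluded_types = excluded_types),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: X2 = %.4g, df = %d, p = %.3g, n = %d\n",
              x$chi2, x$df, x$p, x$n))
  invisible(x)
}

#' Serialise a ContingencyResult to JSON
#' @param x A [contingency_test()] result.
#' @return JSON string.
#' @export
contingency_json <- function(x) {
  jsonlite::toJSON(list(
    chi2 = x$chi2, df = x$df, p = x$p, n = x$n,
    table = as.data.frame(x$table),
    excluded_types = x$excluded_types), auto_unbox = TRUE, digits = NA)
}

#' Per-type Dbh-positive percentages
#'
#' `pct(type) = 100 * Dbh-positive cells / cells of that type`, plus the
#' overall percentage across all cells.
#'
#' @param labels Per-cell type labels.
#' @param dbh_status Logical Dbh status.
#' @return List: `per_type` (`data.table`: `type`, `n`, `n_dbh_pos`, `pct`)
#'   and `overall` (percentage over all cells).
#' @export
type_enrichment_percentages <- function(labels, dbh_status) {
  if (!length(labels)) abort_input("empty input")
  dt <- data.table::data.table(type = as.character(labels),
                               dbh = as.logical(dbh_status))
  per_type <- dt[!is.na(type),
                 .(n = .N, n_dbh_pos = sum(dbh)), by = type][
                 , pct := 100 * n_dbh_pos / n][order(type)]
  list(per_type = per_type,
       overall = 100 * sum(dt$dbh, na.rm = TRUE) / nrow(dt))
}

# Dense per-bin count vectors for a pair of genes over all retained bins.
# With require_present = FALSE a gene without stored counts is treated as
# all-zero (the sparse container only holds nonzero triplets).
bin_pair_counts <- function(bm, gene_a, gene_b, require_present = TRUE) {
  if (require_present) {
    for (g in c(gene_a, gene_b)) {
      if (!g %in% bm$data$gene) {
        abort_input(sprintf("gene '%s' absent from the bin matrix", g))
      }
    }
  }
  bins <- unique(bm$data[, .(bin_x, bin_y)])
  a <- bm$data[gene == gene_a][bins, on = c("bin_x", "bin_y")]
  b <- bm$data[gene == gene_b][bins, on = c("bin_x", "bin_y")]
  list(bins = bins,
       a = data.table::fifelse(is.na(a$count), 0, as.numeric(a$count)),
       b = data.table::fifelse(is.na(b$count), 0, as.numeric(b$count)))
}

#' Spatial co-localisation of two genes over bins
#'
#' Jaccard index over bins positive for each gene (count >=
#' `pos_threshold`) and Spearman rank correlation over all retained bins.
#'
#' @param bm A [bin_matrix()] (post-QC).
#' @param gene_a,gene_b Gene identifiers.
#' @param pos_threshold Minimum count calling a bin positive (default 1).
#' @return Object of class `ColocSummary`: `jaccard`, `rank_corr`,
#'   `n_bins`, `n_pos_a`, `n_pos_b`, `genes`.
#' @export
spatial_overlap <- function(bm, gene_a, gene_b, pos_threshold = 1L) {
  if (!inherits(bm, "BinMatrix")) abort_input("bm must be a BinMatrix")
  pc <- bin_pair_counts(bm, gene_a, gene_b)
  pos_a <- pc$a >= pos_threshold
  pos_b <- pc$b >= pos_threshold
  union <- sum(pos_a | pos_b)
  jac <- if (union == 0) 0 else sum(pos_a & pos_b) / union
  rc <- suppressWarnings(stats::cor(pc$a, pc$b, method = "spearman"))
  structure(list(jaccard = jac, rank_corr = rc, n_bins = nrow(pc$bins),
                 n_pos_a = sum(pos_a), n_pos_b = sum(pos_b),
                 genes = c(gene_a, gene_b)),
            class = "ColocSummary")
}

#' @export
print.ColocSummary <- function(x, ...) {
  cat(sprintf("Coloc %s vs %s: Jaccard %.3f, Spearman %.3f over %d bins\n",
              x$genes[1], x$genes[2], x$jaccard, x$rank_corr, x$n_bins))
  invisible(x)
}

#' Majority region label per bin
#'
#' Collapses a spot-level region raster to bin resolution by majority vote
#' (ties broken by the alphabetically first label).
#'
#' @param region_map Character matrix indexed `[y + 1, x + 1]` over spots.
#' @param bin_size Bin edge in spots.
#' @return `data.table` with columns `bin_x`, `bin_y`, `region`.
#' @export
bin_region_map <- function(region_map, bin_size) {
  n_y <- nrow(region_map); n_x <- ncol(region_map)
  dt <- data.table::data.table(
    region = as.vector(region_map),
    bin_x = rep(0:(n_x - 1L), each = n_y) %/% as.integer(bin_size),
    bin_y = rep(0:(n_y - 1L), times = n_x) %/% as.integer(bin_size))
  dt[, .N, by = .(bin_x, bin_y, region)][
    order(bin_x, bin_y, -N, region)][
    , .SD[1L], by = .(bin_x, bin_y)][, .(bin_x, bin_y, region)]
}

#' Lineage-reporter proxy versus real-time expression by region
#'
#' Compares a reporter-proxy transcript (Wpre, marking the Dbh lineage) with
#' real-time Dbh expression across anatomical regions: per-region means of
#' both genes over bins, with a region flagged discordant when the proxy
#' mean lies above its across-region median while the real-time mean lies
#' below its own median (lineage signal without current expression, as in
#' the SAN).
#'
#' @param bm A [bin_matrix()].
#' @param proxy_gene,realtime_gene Gene identifiers (defaults `"Wpre"`,
#'   `"Dbh"`).
#' @param region_map Bin-level regions (`data.table` `bin_x`, `bin_y`,
#'   `region`, as from [bin_region_map()]).
#' @return Object of class `ColocSummary` with `per_region`
#'   (`data.table`: `region`, `n_bins`, `mean_proxy`, `mean_realtime`)
#'   and `discordant_regions`.
#' @export
reporter_proxy_map <- function(bm, proxy_gene = "Wpre",
                               realtime_gene = "Dbh", region_map) {
  if (missing(region_map) || is.null(region_map)) {
    abort_input("region_map is required")
  }
  pc <- bin_pair_counts(bm, proxy_gene, realtime_gene,
                        require_present = FALSE)
  dt <- cbind(pc$bins, proxy = pc$a, realtime = pc$b)
  dt <- region_map[dt, on = c("bin_x", "bin_y")]
  dt <- dt[!is.na(region) & region != "background"]
  per_region <- dt[, .(n_bins = .N, mean_proxy = mean(proxy),
                       mean_realtime = mean(realtime)), by = region][
                       order(region)]
  med_p <- stats::median(per_region$mean_proxy)
  med_r <- stats::median(per_region$mean_realtime)
  per_region[, discordant := mean_proxy > med_p & mean_realtime < med_r]
  structure(list(per_region = per_region,
                 discordant_regions = per_region[discordant == TRUE, region],
                 genes = c(proxy_gene, realtime_gene)),
            class = c("ReporterProxyMap"))
}

#' @export
print.ReporterProxyMap <- function(x, ...) {
  cat(sprintf("Reporter proxy map (%s vs %s): %d regions, discordant: %s\n",
              x$genes[1], x$genes[2], nrow(x$per_region),
              if (length(x$discordant_regions))
                paste(x$discordant_regions, collapse = ", ") else "none"))
  invisible(x)
}
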