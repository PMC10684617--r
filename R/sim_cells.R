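# Synthetic droplet single-cell generator with planted types, Dbh status
# and stage-dependent mitochondrial load.

#' Generate a synthetic cell x gene count matrix with truth labels
#'
#' Cells are assigned a lineage type (proportions from the configuration), a
#' true Dbh status (Bernoulli with the planted per-type fraction), a depth
#' factor (log-normal, with a configured fraction of under-sampled cells),
#' and negative-binomial counts in which each type's `hi` markers are
#' enriched by `marker_multiplier` and its `lo` markers depleted by the same
#' factor. Mitochondrial gene counts are added afterwards so that the
#' realised mitochondrial fraction follows the stage's Beta distribution.
#'
#' The nuclear part of the simulation is driven by `cfg$seed` alone, so two
#' stages generated from the same configuration share identical type
#' sequences and nuclear counts; the stage affects only the mitochondrial
#' draw (seeded by `seed` plus the stage index).
#'
#' @param cfg A [sim_config()].
#' @param stage Stage code, one of [ccs_stages()].
#' @param n_cells Number of cells (> 0).
#' @return A [cell_expr()] whose `meta` carries truth columns `type_true`,
#'   `dbh_true`, `mito_target`, `lowdepth`, and whose attribute
#'   `"planted_fractions"` records the per-type Dbh-positive probabilities
#'   used.
#' @export
gen_cells <- function(cfg, stage, n_cells) {
  if (!inherits(cfg, "sim_config")) abort_config("cfg must be a sim_config")
  if (!stage %in% ccs_stages()) {
    abort_config(sprintf("unknown stage '%s'", stage))
  }
  if (length(n_cells) != 1L || n_cells <= 0) {
    abort_config("n_cells must be a positive integer")
  }
  n_cells <- as.integer(n_cells)
  genes <- cfg$cell_genes
  n_genes <- length(genes)
  types <- ccs_cell_types()

  set.seed(cfg$seed)
  type <- sample(types, n_cells, replace = TRUE,
                 prob = cfg$type_proportions)
  dbh_true <- stats::rbinom(n_cells, 1L, cfg$dbh_pos_fraction[type]) == 1L
  depth <- exp(stats::rnorm(n_cells, 0, cfg$depth_sdlog))
  lowdepth <- stats::runif(n_cells) < cfg$lowdepth_frac
  depth[lowdepth] <- depth[lowdepth] * cfg$lowdepth_scale

  # Per-gene multiplier by type from the marker table.
  mk <- default_marker_table()
  mk <- mk[gene %in% genes]
  mult <- matrix(1, n_genes, length(types), dimnames = list(genes, types))
  mult[cbind(match(mk$gene, genes), match(mk$type, types))] <-
    ifelse(mk$direction == "hi", cfg$marker_multiplier,
           1 / cfg$marker_multiplier)

  mito <- startsWith(genes, "mt-")
  mu <- cfg$cell_base_mean * mult[, match(type, types), drop = FALSE]
  mu <- sweep(mu, 2L, depth, `*`)
  mu[mito, ] <- 0                        # mitochondrial load added below
  mu["Dbh", ] <- 0                       # Dbh driven by planted status
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = cfg$dispersion),
                   nrow = n_genes, ncol = n_cells)
  counts["Dbh" == genes, ] <- ifelse(dbh_true, 1L + stats::rpois(n_cells, 0.7), 0L)

  # Stage-specific mitochondrial counts on a separate stream.
  set.seed(cfg$seed + 1000L * match(stage, ccs_stages()))
  md <- cfg$mito_fraction_dist[[stage]]
  mito_target <- stats::rbeta(n_cells, md$mean * md$conc,
                              (1 - md$mean) * md$conc)
  nuclear <- colSums(counts)
  mito_total <- round(nuclear * mito_target / (1 - mito_target))
  mito_genes <- which(mito)
  if (length(mito_genes)) {
    for (j in which(mito_total > 0)) {
      alloc <- tabulate(sample.int(length(mito_genes), mito_total[j],
                                   replace = TRUE),
                        nbins = length(mito_genes))
      counts[mito_genes, j] <- alloc
    }
  }

  dimnames(counts) <- list(genes,
                           sprintf("%s_cell%05d", stage, seq_len(n_cells)))
  sparse <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  meta <- data.table::data.table(
    barcode = colnames(counts), stage = stage,
    type_true = type, dbh_true = dbh_true,
    mito_target = mito_target, lowdepth = lowdepth)
  ce <- cell_expr(sparse, meta)
  attr(ce, "planted_fractions") <- cfg$dbh_pos_fraction
  ce
}
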