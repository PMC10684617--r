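# Simulation configuration: the study conditions every generator draws from.

#' Developmental stages covered by the pipeline
#'
#' Embryonic (E8.5--E16.5) and postnatal (P3) stages, ordered by development.
#'
#' @return Character vector of stage codes.
#' @export
ccs_stages <- function() {
  c("E8.5", "E10.5", "E12.5", "E14.5", "E16.5", "P3")
}

#' Cardiomyocyte-lineage cell types
#'
#' The 15 lineage types used throughout: early/progenitor populations
#' (heart fields `HF`, primary heart tube `pHT`, developing cardiomyocytes
#' `Dev-CM`, endocardial-gene-rich cardiomyocytes `ED-CM`, `Misc`), immature
#' working myocardium (`iAM`, `iVM`), trabecular ventricular myocardium
#' (`eVM-trab`, `VM-trab`), mature working myocardium (`AM`, `VM`), and the
#' cardiac conduction system (`SAN`, `AVN`, `PKJ`, `AM-CCS`).
#'
#' @return Character vector of 15 type labels.
#' @export
ccs_cell_types <- function() {
  c("HF", "pHT", "Dev-CM", "ED-CM", "Misc",
    "iAM", "iVM", "eVM-trab", "VM-trab", "AM", "VM",
    "SAN", "AVN", "PKJ", "AM-CCS")
}

#' Cell types excluded from the independence test
#'
#' Early populations in which Dbh expression is essentially absent before
#' E10.5; excluding them leaves 10 tested types (df = 9 against the two
#' Dbh-status columns).
#'
#' @return Character vector of 5 type labels.
#' @export
default_excluded_types <- function() {
  c("HF", "pHT", "Dev-CM", "ED-CM", "Misc")
}

#' Default planted Dbh-positive fraction per cell type
#'
#' Conduction-system types carry substantially higher fractions than working
#' myocardium (PKJ 12.76%, AVN 12.14%, SAN 8.39%, AM-CCS 3.82% versus
#' AM 2.13%, VM 3.90%, VM-trab 4.18%, eVM-trab 2.26%); early populations are
#' near zero.
#'
#' @return Named numeric vector over [ccs_cell_types()].
#' @export
default_dbh_fractions <- function() {
  c("HF" = 0.001, "pHT" = 0.001, "Dev-CM" = 0.001, "ED-CM" = 0.001,
    "Misc" = 0.001,
    "iAM" = 0.010, "iVM" = 0.010,
    "eVM-trab" = 0.0226, "VM-trab" = 0.0418, "AM" = 0.0213, "VM" = 0.0390,
    "SAN" = 0.0839, "AVN" = 0.1214, "PKJ" = 0.1276, "AM-CCS" = 0.0382)
}

# Relative abundance of each type in a simulated dissociation.
default_type_proportions <- function() {
  c("HF" = 0.04, "pHT" = 0.04, "Dev-CM" = 0.05, "ED-CM" = 0.03,
    "Misc" = 0.02,
    "iAM" = 0.07, "iVM" = 0.09,
    "eVM-trab" = 0.06, "VM-trab" = 0.08, "AM" = 0.18, "VM" = 0.26,
    "SAN" = 0.02, "AVN" = 0.02, "PKJ" = 0.02, "AM-CCS" = 0.02)
}

#' Default marker table
#'
#' Cell-type marker genes with direction (`hi`/`lo`), e.g. ventricular
#' Myl2-hi/Myh7-hi/Kcne1-hi/Myl7-lo, atrial Myl7-hi/Myh6-hi/Nppa-hi/Sln-hi,
#' sinoatrial Shox2/Hcn4/Smoc2-hi. Used both to plant enrichment in
#' [gen_cells()] and as the default for [score_cell_types()].
#'
#' @return `data.table` with columns `type`, `gene`, `direction`.
#' @export
default_marker_table <- function() {
  rbind_markers <- function(type, hi, lo = character()) {
    data.table::data.table(
      type = type,
      gene = c(hi, lo),
      direction = c(rep("hi", length(hi)), rep("lo", length(lo))))
  }
  data.table::rbindlist(list(
    rbind_markers("VM",       c("Myl2", "Myh7", "Kcne1", "Tnni3"), "Myl7"),
    rbind_markers("AM",       c("Myl7", "Myh6", "Nppa", "Sln")),
    rbind_markers("SAN",      c("Shox2", "Hcn4", "Smoc2", "Vsnl1")),
    rbind_markers("AVN",      c("Cacna2d2", "Rgs6", "Hcn4", "Msx2")),
    rbind_markers("PKJ",      c("Cntn2", "Gja5", "Id2", "Slit2")),
    rbind_markers("AM-CCS",   c("Tbx3", "Cpne5", "Gnao1", "Smpx")),
    rbind_markers("VM-trab",  c("Bmp10", "Sema3a", "Nppb", "Adm")),
    rbind_markers("eVM-trab", c("Bmp10", "Mest", "Igf2", "H19")),
    rbind_markers("iAM",      c("Actc1", "Angpt1", "Kcnj3", "Stard10")),
    rbind_markers("iVM",      c("Tnni1", "Pln", "Mb", "Casq2")),
    rbind_markers("HF",       c("Hand1", "Wnt2", "Osr1", "Foxf1")),
    rbind_markers("pHT",      c("Acta2", "Tagln", "Pmp22", "Cnn1")),
    rbind_markers("Dev-CM",   c("Mki67", "Top2a", "Ccnb1", "Birc5")),
    rbind_markers("ED-CM",    c("Npr3", "Cdh5", "Pecam1", "Emcn")),
    rbind_markers("Misc",     c("Col1a1", "Postn", "Dcn", "Gsn"))))
}

#' Default stage-wise mitochondrial ceilings and QC floors
#'
#' Mitochondrial-fraction ceilings rise with developmental stage
#' (E8.5/E10.5: 5%, E12.5: 7.5%, E14.5: 10%, E16.5: 15%, P3: 20%);
#' floors are nUMI >= 300 and nFeatures >= 270.
#'
#' @return List with `mito_max` (named numeric over stages), `numi_min`,
#'   `nfeat_min`.
#' @export
stage_thresholds <- function() {
  list(
    mito_max = c("E8.5" = 0.05, "E10.5" = 0.05, "E12.5" = 0.075,
                 "E14.5" = 0.10, "E16.5" = 0.15, "P3" = 0.20),
    numi_min = 300,
    nfeat_min = 270)
}

# Beta parameters (mean, concentration) of the per-cell mitochondrial
# fraction, per stage: means at 0.6x the stage ceiling so each stage's
# filter removes a realistic upper tail.
default_mito_dist <- function() {
  th <- stage_thresholds()$mito_max
  lapply(th, function(ceiling) list(mean = 0.6 * ceiling, conc = 25))
}

#' Default spatial region map
#'
#' A label raster on an `n x n` spot grid sketching a coronal heart section:
#' an ellipse of tissue with atrial myocardium (AM) above ventricular (VM),
#' a sinoatrial-node patch (SAN), an atrioventricular-node patch (AVN), a
#' His-bundle strip (His) descending from the AVN, two Purkinje bands (PKJ)
#' in the ventricles, and background outside the tissue.
#'
#' @param n Spots per grid edge.
#' @return Character matrix `n x n` with entries in
#'   `{"SAN","AVN","His","PKJ","AM","VM","background"}`.
#' @export
default_region_map <- function(n) {
  xi <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)   # column coord
  yi <- matrix(rep(seq_len(n) - 0.5, times = n), n, n)  # row coord
  cx <- n / 2; cy <- n / 2
  inside <- ((xi - cx) / (0.38 * n))^2 + ((yi - cy) / (0.46 * n))^2 <= 1
  reg <- matrix("background", n, n)
  reg[inside & yi <  0.35 * n] <- "AM"
  reg[inside & yi >= 0.35 * n] <- "VM"
  pkj <- inside & yi >= 0.60 * n & yi <= 0.82 * n &
    (abs(xi - 0.32 * n) < 0.05 * n | abs(xi - 0.68 * n) < 0.05 * n)
  reg[pkj] <- "PKJ"
  his <- inside & abs(xi - cx) < 0.03 * n & yi >= 0.42 * n & yi <= 0.62 * n
  reg[his] <- "His"
  avn <- inside & ((xi - cx)^2 + (yi - 0.40 * n)^2) <= (0.05 * n)^2
  reg[avn] <- "AVN"
  san <- inside & ((xi - 0.66 * n)^2 + (yi - 0.20 * n)^2) <= (0.06 * n)^2
  reg[san] <- "SAN"
  reg
}

#' Default regional gene-enrichment multipliers
#'
#' Mean-count multipliers applied on top of the negative-binomial base mean,
#' by region and gene. CCS markers (Hcn4, Cntn2, Cacna2d2, Gja5, Id2) are
#' concentrated in their canonical compartments; Dbh is highest in the
#' ventricular CCS (His/PKJ/AVN) while the lineage-reporter proxy Wpre is
#' highest in the SAN, reproducing the real-time-versus-lineage discordance.
#' Background spots scale all genes by `background_scale`.
#'
#' @return Named list: `multipliers` (region -> named gene multipliers) and
#'   `background_scale`.
#' @export
default_spatial_enrichment <- function() {
  list(
    multipliers = list(
      SAN = c(Hcn4 = 8, Shox2 = 6, Smoc2 = 6, Cacna2d2 = 2, Dbh = 3,
              Wpre = 8, Myl7 = 2),
      AVN = c(Hcn4 = 6, Cacna2d2 = 6, Rgs6 = 5, Cntn2 = 3, Dbh = 6,
              Wpre = 5),
      His = c(Cntn2 = 8, Cacna2d2 = 4, Id2 = 3, Hcn4 = 3, Dbh = 6,
              Wpre = 4),
      PKJ = c(Cntn2 = 8, Gja5 = 6, Id2 = 5, Cacna2d2 = 3, Dbh = 6,
              Wpre = 4),
      AM  = c(Myl7 = 4, Myh6 = 3, Nppa = 3, Sln = 3, Gja5 = 2, Dbh = 1.5,
              Wpre = 1.5),
      VM  = c(Myl2 = 4, Myh7 = 3, Kcne1 = 2, Dbh = 1.5, Wpre = 1.5)),
    background_scale = 0.05)
}

# Gene panel: named genes first (markers, spatial genes, Dbh/Wpre,
# mitochondrial), padded with filler genes up to n_genes.
default_gene_panel <- function(n_genes) {
  mito <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Cytb", "mt-Atp6")
  named <- unique(c("Dbh", "Wpre", "Tnnt2",
                    default_marker_table()$gene,
                    unlist(lapply(default_spatial_enrichment()$multipliers,
                                  names), use.names = FALSE),
                    mito))
  if (n_genes < length(named)) {
    abort_config(sprintf(
      "n_genes must be at least %d to hold the named gene panel",
      length(named)))
  }
  n_fill <- n_genes - length(named)
  c(named, if (n_fill > 0) sprintf("Filler%03d", seq_len(n_fill)))
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. Identical
#' configurations (including `seed`) produce bit-identical outputs.
#'
#' @param seed Integer seed; every generator derives its random stream from
#'   it.
#' @param n_spots_side Spots per grid edge of the spatial chip.
#' @param pitch_nm Centre-to-centre spot distance in nanometres (500 or 715).
#' @param n_genes Total genes in the simulated panel (named genes plus
#'   filler).
#' @param region_map Character matrix assigning each spot a region label;
#'   default [default_region_map()].
#' @param enrichment Regional gene multipliers as from
#'   [default_spatial_enrichment()].
#' @param dbh_pos_fraction Named per-type probability that a cell has a
#'   Dbh count > 0; default [default_dbh_fractions()].
#' @param mito_fraction_dist Per-stage Beta parameters
#'   (`list(mean, conc)`) of the cell mitochondrial fraction.
#' @param affine_truth Optional list of per-slice rigid perturbations, each
#'   `list(rotation_deg, dx, dy)`; `NULL` draws them uniformly within
#'   `affine_limits` at generation time (seeded), with slice 1 held at
#'   identity.
#' @param affine_limits Numeric `c(max_abs_rotation_deg, max_abs_shift_px)`
#'   for drawn perturbations.
#' @param noise_sd Additive Gaussian noise (grey levels) on section images.
#' @param base_mean Negative-binomial base mean per spot and gene.
#' @param dispersion Negative-binomial size parameter.
#' @param dup_mean Poisson mean of extra PCR duplicate reads per molecule.
#' @param cid_sub1,cid_sub2 Fractions of reads carrying 1 or 2 CID
#'   substitutions.
#' @param mid_n_rate Fraction of reads whose MID gains an `N` base.
#' @param mid_lowq_rate Fraction of reads whose MID gains three bases with
#'   quality below 10.
#' @param cell_base_mean Negative-binomial base mean per cell and gene for
#'   [gen_cells()].
#' @param n_cell_genes Genes in the single-cell panel (named genes plus
#'   filler); sized so that healthy cells clear the nFeatures floor with
#'   margin.
#' @param lowdepth_frac Fraction of cells simulated as under-sampled
#'   (depth scaled by `lowdepth_scale`), the population the nUMI/nFeatures
#'   floors exist to remove.
#' @param lowdepth_scale Depth multiplier of under-sampled cells.
#' @param depth_sdlog Log-normal sd of the per-cell depth factor.
#' @param marker_multiplier Mean multiplier of a type's `hi` markers (its
#'   `lo` markers are divided by the same factor).
#' @param type_proportions Named sampling proportions over
#'   [ccs_cell_types()].
#' @param cid_len,mid_len Barcode and molecular-identifier lengths.
#' @param speckle_density Within-tissue fraction of speckled (nuclei-like)
#'   blue pixels on sections.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_spots_side = 100L,
                       pitch_nm = 500L,
                       n_genes = 80L,
                       region_map = NULL,
                       enrichment = default_spatial_enrichment(),
                       dbh_pos_fraction = default_dbh_fractions(),
                       mito_fraction_dist = default_mito_dist(),
                       affine_truth = NULL,
                       affine_limits = c(8, 8),
                       noise_sd = 2,
                       base_mean = 0.4,
                       dispersion = 4,
                       dup_mean = 1,
                       cid_sub1 = 0.05,
                       cid_sub2 = 0.02,
                       mid_n_rate = 0.01,
                       mid_lowq_rate = 0.02,
                       cell_base_mean = 2,
                       n_cell_genes = 600L,
                       lowdepth_frac = 0.08,
                       lowdepth_scale = 0.1,
                       depth_sdlog = 0.25,
                       marker_multiplier = 5,
                       type_proportions = default_type_proportions(),
                       cid_len = 25L,
                       mid_len = 10L,
                       speckle_density = 0.85) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed)) {
    abort_config("seed must be a single integer")
  }
  if (!pitch_nm %in% c(500L, 715L)) {
    abort_config("pitch_nm must be 500 or 715")
  }
  if (n_spots_side < 4L) abort_config("n_spots_side must be >= 4")
  probs <- c(cid_sub1, cid_sub2, mid_n_rate, mid_lowq_rate,
             dbh_pos_fraction, speckle_density)
  if (any(probs < 0 | probs > 1)) {
    abort_config("all probabilities must lie in [0, 1]")
  }
  if (cid_sub1 + cid_sub2 + mid_n_rate + mid_lowq_rate > 1) {
    abort_config("read corruption fractions must sum to at most 1")
  }
  if (noise_sd < 0) abort_config("noise_sd must be non-negative")
  if (is.null(region_map)) region_map <- default_region_map(n_spots_side)
  if (!is.matrix(region_map) ||
      !all(dim(region_map) == c(n_spots_side, n_spots_side))) {
    abort_config("region_map must be an n_spots_side x n_spots_side matrix")
  }
  types <- ccs_cell_types()
  if (!all(types %in% names(dbh_pos_fraction))) {
    abort_config("dbh_pos_fraction must name every cell type")
  }
  if (!all(names(mito_fraction_dist) %in% ccs_stages()) ||
      !all(ccs_stages() %in% names(mito_fraction_dist))) {
    abort_config("mito_fraction_dist must name every stage")
  }
  cfg <- list(
    seed = as.integer(seed), n_spots_side = as.integer(n_spots_side),
    pitch_nm = as.integer(pitch_nm), n_genes = as.integer(n_genes),
    region_map = region_map, enrichment = enrichment,
    dbh_pos_fraction = dbh_pos_fraction[types],
    mito_fraction_dist = mito_fraction_dist,
    affine_truth = affine_truth, affine_limits = affine_limits,
    noise_sd = noise_sd, base_mean = base_mean, dispersion = dispersion,
    dup_mean = dup_mean, cid_sub1 = cid_sub1, cid_sub2 = cid_sub2,
    mid_n_rate = mid_n_rate, mid_lowq_rate = mid_lowq_rate,
    cell_base_mean = cell_base_mean, n_cell_genes = as.integer(n_cell_genes),
    lowdepth_frac = lowdepth_frac, lowdepth_scale = lowdepth_scale,
    depth_sdlog = depth_sdlog, marker_multiplier = marker_multiplier,
    type_proportions = type_proportions[types],
    cid_len = as.integer(cid_len), mid_len = as.integer(mid_len),
    speckle_density = speckle_density,
    genes = default_gene_panel(n_genes),
    cell_genes = default_gene_panel(n_cell_genes))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("sim_config: seed %d, %dx%d spots (pitch %d nm), %d genes, ",
           "corruption %.1f%%/%.1f%% CID 1/2-sub\n"),
    x$seed, x$n_spots_side, x$n_spots_side, x$pitch_nm, x$n_genes,
    100 * x$cid_sub1, 100 * x$cid_sub2))
  invisible(x)
}
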