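# End-to-end orchestration with provenance and per-filter attrition logs.

default_run_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "stereo", "scqc", "enrich", "recon3d", "report"),
    out_dir = NULL,
    simulate = list(n_spots_side = 60L, n_genes = 80L, stage = "P3",
                    n_cells = 4000L, n_slices = 8L, size_px = 96L),
    stereo = list(bin_size = 20L, min_bins = 5L,
                  density_metric = "genes", input_dir = NULL),
    scqc = list(input_dir = NULL),
    enrich = list(exclude_types = default_excluded_types(),
                  pos_threshold = 1L),
    recon3d = list(downsample_factor = 1L, gain = 1, bias = 0,
                   dz_um = 10, input_dir = NULL))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

stage_manifest_entry <- function(stage, params, inputs, outputs) {
  list(stage = stage, params = params,
       inputs = lapply(inputs, function(f)
         list(path = f, md5 = unname(tools::md5sum(f)))),
       outputs = outputs,
       package_version = as.character(utils::packageVersion("ccsmap")))
}

#' Run the pipeline end to end
#'
#' Executes the requested stages (`simulate`, `stereo`, `scqc`, `enrich`,
#' `recon3d`, `report`) in dependency order. Every run directory receives
#' the exact configuration (`config.yaml`), a machine-readable stage
#' manifest with input hashes (`manifest.json`), and an attrition log
#' recording counts in/out for every filter (`attrition.tsv`). Reruns from
#' the saved configuration are bit-identical for the deterministic stages.
#'
#' @param config A configuration list (or path to a YAML file) overriding
#'   the defaults; must provide `out_dir`. Stage inputs default to the
#'   outputs of the `simulate` stage inside the same run; a stage run
#'   without its dependency (and without an explicit `input_dir`) raises a
#'   dependency error.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  if (is.null(cfg$out_dir)) abort_config("config must set out_dir")
  known <- c("simulate", "stereo", "scqc", "enrich", "recon3d", "report")
  if (!all(cfg$stages %in% known)) {
    abort_config(sprintf("unknown stage(s): %s",
                         paste(setdiff(cfg$stages, known), collapse = ", ")))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))

  manifest <- list()
  attrition <- list()
  results <- list()
  sim <- NULL

  if ("simulate" %in% cfg$stages) {
    sdir <- file.path(cfg$out_dir, "simulate")
    dir.create(sdir, showWarnings = FALSE)
    sc <- sim_config(seed = cfg$seed,
                     n_spots_side = cfg$simulate$n_spots_side,
                     n_genes = cfg$simulate$n_genes)
    sim <- gen_reads(sc)
    write_reads(sim$reads, file.path(sdir, "reads.tsv"))
    write_whitelist(sim$whitelist, file.path(sdir, "whitelist.tsv"))
    write_gem(sim$truth, file.path(sdir, "truth_spots.gem"))
    cells <- gen_cells(sc, cfg$simulate$stage, cfg$simulate$n_cells)
    write_cellexpr(cells, file.path(sdir, "cells"))
    sections <- gen_sections(sc, cfg$simulate$n_slices,
                             cfg$simulate$size_px)
    write_sections(sections$stack, file.path(sdir, "sections"))
    results$simulate <- list(config = sc, truth = sim$truth,
                             cells = cells, sections = sections)
    manifest$simulate <- stage_manifest_entry(
      "simulate", cfg$simulate, character(),
      list(reads = "simulate/reads.tsv", whitelist = "simulate/whitelist.tsv",
           truth = "simulate/truth_spots.gem", cells = "simulate/cells",
           sections = "simulate/sections"))
  }

  if ("stereo" %in% cfg$stages) {
    in_dir <- cfg$stereo$input_dir %||% file.path(cfg$out_dir, "simulate")
    reads_path <- file.path(in_dir, "reads.tsv")
    wl_path <- file.path(in_dir, "whitelist.tsv")
    if (!file.exists(reads_path) || !file.exists(wl_path)) {
      abort_dependency(
        "stereo stage needs reads.tsv and whitelist.tsv (run simulate or set stereo$input_dir)")
    }
    reads <- read_reads(reads_path)
    wl <- read_whitelist(wl_path)
    st <- process_stereo(reads, wl, bin_size = cfg$stereo$bin_size,
                         min_bins = cfg$stereo$min_bins,
                         density_metric = cfg$stereo$density_metric)
    stdir <- file.path(cfg$out_dir, "stereo")
    dir.create(stdir, showWarnings = FALSE)
    write_gem(st$spots, file.path(stdir, "spots.gem"))
    write_gem(st$bins, file.path(stdir, "bins.gem"))
    results$stereo <- st
    attrition$stereo <- st$attrition
    manifest$stereo <- stage_manifest_entry(
      "stereo", cfg$stereo, c(reads_path, wl_path),
      list(spots = "stereo/spots.gem", bins = "stereo/bins.gem"))
  }

  if ("scqc" %in% cfg$stages) {
    in_dir <- cfg$scqc$input_dir %||%
      file.path(cfg$out_dir, "simulate", "cells")
    if (!file.exists(file.path(in_dir, "matrix.mtx"))) {
      abort_dependency(
        "scqc stage needs a cell matrix (run simulate or set scqc$input_dir)")
    }
    ce <- read_cellexpr(in_dir)
    filtered <- filter_cells(ce)
    norm <- normalize_counts(filtered)
    typed <- score_cell_types(norm)
    filtered$meta$type <- typed$label
    dbh_pos <- select_dbh_positive(filtered)
    qdir <- file.path(cfg$out_dir, "scqc")
    dir.create(qdir, showWarnings = FALSE)
    write_cellexpr(filtered, file.path(qdir, "filtered"))
    write_cellexpr(dbh_pos, file.path(qdir, "dbh_positive"))
    results$scqc <- list(filtered = filtered, dbh_positive = dbh_pos)
    attrition$scqc <- attr(filtered, "attrition")
    manifest$scqc <- stage_manifest_entry(
      "scqc", cfg$scqc, file.path(in_dir, "matrix.mtx"),
      list(filtered = "scqc/filtered", dbh_positive = "scqc/dbh_positive"))
  }

  if ("enrich" %in% cfg$stages) {
    if (is.null(results$scqc)) {
      abort_dependency("enrich stage needs scqc output in the same run")
    }
    filtered <- results$scqc$filtered
    labels <- filtered$meta$type
    dbh <- as.vector(filtered$counts["Dbh", ] > 0)
    test <- contingency_test(labels, dbh,
                             excluded_types = cfg$enrich$exclude_types)
    pct <- type_enrichment_percentages(labels, dbh)
    edir <- file.path(cfg$out_dir, "enrich")
    dir.create(edir, showWarnings = FALSE)
    data.table::fwrite(pct$per_type, file.path(edir, "percentages.tsv"),
                       sep = "\t")
    writeLines(contingency_json(test), file.path(edir, "contingency.json"))
    results$enrich <- list(test = test, percentages = pct)
    coloc <- NULL
    if (!is.null(results$stereo)) {
      bm <- results$stereo$bins
      genes_present <- unique(bm$data$gene)
      if (all(c("Dbh", "Cntn2") %in% genes_present)) {
        coloc <- spatial_overlap(bm, "Dbh", "Cntn2",
                                 pos_threshold = cfg$enrich$pos_threshold)
        results$enrich$coloc <- coloc
      }
      if (all(c("Dbh", "Wpre") %in% genes_present) &&
          !is.null(results$simulate)) {
        rmap <- bin_region_map(results$simulate$config$region_map,
                               bm$bin_size)
        results$enrich$proxy <- reporter_proxy_map(bm, region_map = rmap)
      }
    }
    manifest$enrich <- stage_manifest_entry(
      "enrich", cfg$enrich, character(),
      list(percentages = "enrich/percentages.tsv",
           contingency = "enrich/contingency.json"))
  }

  if ("recon3d" %in% cfg$stages) {
    in_dir <- cfg$recon3d$input_dir %||%
      file.path(cfg$out_dir, "simulate", "sections")
    if (!dir.exists(in_dir)) {
      abort_dependency(
        "recon3d stage needs section images (run simulate or set recon3d$input_dir)")
    }
    stack <- read_sections(in_dir)
    rec <- reconstruct_sections(stack,
                                downsample_factor = cfg$recon3d$downsample_factor,
                                gain = cfg$recon3d$gain,
                                bias = cfg$recon3d$bias)
    rdir <- file.path(cfg$out_dir, "recon3d")
    dir.create(rdir, showWarnings = FALSE)
    write_vtk(rec$volume, file.path(rdir, "volume.vtk"))
    results$recon3d <- rec
    manifest$recon3d <- stage_manifest_entry(
      "recon3d", cfg$recon3d[names(cfg$recon3d) != "input_dir"], character(),
      list(volume = "recon3d/volume.vtk"))
  }

  if ("report" %in% cfg$stages) {
    report <- list(seed = cfg$seed, stages_run = cfg$stages)
    if (!is.null(results$enrich)) {
      report$chi2 <- results$enrich$test$chi2
      report$df <- results$enrich$test$df
      report$p <- results$enrich$test$p
      report$overall_dbh_pct <- results$enrich$percentages$overall
    }
    if (!is.null(results$stereo)) {
      report$bins_retained <-
        data.table::uniqueN(results$stereo$bins$data[, .(bin_x, bin_y)])
    }
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$report <- report
  }

  if (length(attrition)) {
    data.table::fwrite(
      data.table::rbindlist(attrition, idcol = "stage", fill = TRUE),
      file.path(cfg$out_dir, "attrition.tsv"), sep = "\t")
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, manifest = manifest,
                 config = cfg, out_dir = cfg$out_dir))
}
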