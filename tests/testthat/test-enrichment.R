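# Contingency analysis, per-type percentages, spatial co-localisation.

test_that("the lineage design with five exclusions yields df = 9", {
  cfg <- sim_config(seed = 51)
  ce <- gen_cells(cfg, "P3", 6000)
  res <- contingency_test(ce$meta$type_true, ce$meta$dbh_true)
  expect_equal(res$df, 9L)
  expect_equal(nrow(res$table), 10L)
  expect_false(any(default_excluded_types() %in% rownames(res$table)))
  expect_equal(res$n, sum(!ce$meta$type_true %in% default_excluded_types()))
  expect_error(contingency_test(rep("A", 5), rep(TRUE, 5),
                                excluded_types = character()),
               class = "ccsmap_input_error")
})

test_that("proportional tables give zero statistic; known table matches", {
  # Rows with identical proportions: chi2 = 0, p = 1.
  lab <- rep(c("A", "B"), each = 100)
  dbh <- rep(c(TRUE, FALSE), times = c(20, 80))
  dbh <- c(dbh[1:100], dbh[1:100])
  res0 <- contingency_test(lab, dbh, excluded_types = character())
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)
  # 2x2 [[10,20],[30,40]] -> chi2 = 0.7937 (hand application of sum((O-E)^2/E)).
  lab2 <- rep(c("r1", "r2"), times = c(30, 70))
  dbh2 <- c(rep(c(TRUE, FALSE), c(10, 20)), rep(c(TRUE, FALSE), c(30, 40)))
  res2 <- contingency_test(lab2, dbh2, excluded_types = character())
  expect_equal(res2$chi2, oracle_chi2(matrix(c(10, 30, 20, 40), 2)))
  expect_equal(res2$chi2, 0.79365, tolerance = 1e-4)
})

test_that("the statistic matches brute force and chisq.test on small tables", {
  set.seed(61)
  for (r in 2:5) {
    for (rep in 1:60) {
      O <- matrix(sample(0:50, r * 2, TRUE), r, 2)
      if (any(rowSums(O) == 0) || any(colSums(O) == 0)) next
      lab <- rep(sprintf("t%d", seq_len(r)), times = rowSums(O))
      dbh <- unlist(lapply(seq_len(r), function(i)
        rep(c(TRUE, FALSE), times = O[i, ])))
      res <- contingency_test(lab, dbh, excluded_types = character())
      expect_equal(res$chi2, oracle_chi2(O), tolerance = 1e-10)
      ref <- suppressWarnings(chisq.test(O, correct = FALSE))
      expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(res$p, unname(ref$p.value), tolerance = 1e-10)
      expect_equal(res$df, unname(ref$parameter))
    }
  }
})

test_that("the permutation null matches the analytic p-value", {
  set.seed(71)
  lab <- sample(c("A", "B", "C"), 240, TRUE)
  dbh <- runif(240) < ifelse(lab == "A", 0.28, 0.20)
  obs <- contingency_test(lab, dbh, excluded_types = character())
  perm <- replicate(1000, {
    contingency_test(lab, sample(dbh), excluded_types = character())$chi2
  })
  p_emp <- mean(perm >= obs$chi2)
  mc_se <- sqrt(obs$p * (1 - obs$p) / 1000)
  expect_lt(abs(p_emp - obs$p), 4 * mc_se + 0.01)
})

test_that("per-type percentages are exact and sum-consistent", {
  lab <- rep(c("X", "Y"), times = c(100, 50))
  dbh <- c(rep(c(TRUE, FALSE), c(2, 98)), rep(TRUE, 50))
  pct <- type_enrichment_percentages(lab, dbh)
  expect_equal(pct$per_type[type == "X", pct], 2.00)
  expect_equal(pct$per_type[type == "Y", pct], 100)
  expect_equal(sum(pct$per_type$pct * pct$per_type$n) / 100, sum(dbh))
  expect_equal(pct$overall, 100 * 52 / 150)
  all_pos <- type_enrichment_percentages(lab, rep(TRUE, 150))
  expect_true(all(all_pos$per_type$pct == 100))
  expect_error(type_enrichment_percentages(character(), logical()),
               class = "ccsmap_input_error")
})

test_that("planted per-type fractions are recovered within 3 binomial SEs", {
  cfg <- sim_config(seed = 81)
  ce <- gen_cells(cfg, "P3", 15000)
  pct <- type_enrichment_percentages(ce$meta$type_true, ce$meta$dbh_true)
  planted <- default_dbh_fractions()
  for (t in c("PKJ", "AVN", "SAN", "AM", "VM")) {
    row <- pct$per_type[type == t]
    se <- sqrt(planted[[t]] * (1 - planted[[t]]) / row$n)
    expect_lt(abs(row$pct / 100 - planted[[t]]), 3 * se)
  }
})

test_that("spatial overlap separates co-localised from control genes", {
  # Identical gene: perfect agreement.
  dt <- data.table::data.table(
    gene = rep(c("Dbh", "Ctrl"), each = 6),
    bin_x = rep(0:5, 2), bin_y = 0L,
    count = c(3, 3, 3, 0, 0, 1, 1, 1, 1, 1, 1, 1))
  bm <- bin_matrix(dt, bin_size = 20L)
  self <- spatial_overlap(bm, "Dbh", "Dbh")
  expect_equal(self$jaccard, 1)
  expect_equal(self$rank_corr, 1)
  # Disjoint positive sets.
  dj <- bin_matrix(data.table::data.table(
    gene = rep(c("a", "b"), each = 3),
    bin_x = c(0:2, 3:5), bin_y = 0L, count = 1L), bin_size = 20L)
  expect_equal(spatial_overlap(dj, "a", "b")$jaccard, 0)
  expect_error(spatial_overlap(bm, "Dbh", "absent"),
               class = "ccsmap_input_error")

  # Planted geometry: Dbh and Cntn2 share CCS bins; a uniform control does
  # not follow them.
  cfg <- sim_config(seed = 91, n_spots_side = 60)
  g <- gen_reads(cfg)
  st <- process_stereo(g$reads, g$whitelist, bin_size = 4L)
  cc <- spatial_overlap(st$bins, "Dbh", "Cntn2")
  ctrl <- spatial_overlap(st$bins, "Dbh", "Tnnt2")
  expect_gt(cc$rank_corr, ctrl$rank_corr)
})

test_that("the reporter proxy map flags lineage-only regions", {
  cfg <- sim_config(seed = 93, n_spots_side = 60)
  g <- gen_reads(cfg)
  st <- process_stereo(g$reads, g$whitelist, bin_size = 4L)
  rmap <- bin_region_map(cfg$region_map, 4L)
  res <- reporter_proxy_map(st$bins, region_map = rmap)
  # Wpre is planted SAN-high while Dbh is SAN-low: SAN is discordant.
  expect_true("SAN" %in% res$discordant_regions)
  # The proxy run against itself finds nothing discordant.
  self <- reporter_proxy_map(st$bins, proxy_gene = "Dbh",
                             realtime_gene = "Dbh", region_map = rmap)
  expect_length(self$discordant_regions, 0)
  # An all-zero proxy yields no discordant regions.
  zero <- reporter_proxy_map(st$bins, proxy_gene = "NotPresent",
                             realtime_gene = "Dbh", region_map = rmap)
  expect_length(zero$discordant_regions, 0)
  expect_true(all(zero$per_region$mean_proxy == 0))
  expect_error(reporter_proxy_map(st$bins), class = "ccsmap_input_error")
})
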