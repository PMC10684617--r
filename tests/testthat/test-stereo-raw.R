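# Stereo-seq raw processing: barcode matching, MID filtering, dedup,
# binning, bin/gene QC.

wl3 <- data.table::data.table(
  cid = c("AAAA", "CCCC", "AACC"),
  x = c(0L, 1L, 2L), y = c(0L, 0L, 1L))

test_that("CID matching follows the one-mismatch contract", {
  # Exact hit.
  expect_equal(match_cid("AAAA", wl3)$x, 0L)
  # Unique distance-1 hit.
  hit <- match_cid("AAAT", wl3)
  expect_equal(c(hit$x, hit$y), c(0L, 0L))
  # Distance 1 from two entries ("AAAC" matches AAAA and AACC) -> drop.
  expect_true(is.na(match_cid("AAAC", wl3)$x))
  # Distance 2 from everything -> drop.
  expect_true(is.na(match_cid("GGTT", wl3)$x))
  # Length mismatch is an input error.
  expect_error(match_cid("AAA", wl3), class = "ccsmap_input_error")
})

test_that("CID matching agrees with an exhaustive Hamming scan", {
  cfg <- sim_config(seed = 21, n_spots_side = 22)
  g <- gen_reads(cfg)
  queries <- unique(g$reads$cid)
  queries <- queries[seq(1, length(queries), length.out = 300)]
  got <- match_cid(queries, g$whitelist)
  want_idx <- vapply(queries, oracle_match, integer(1),
                     wl_cids = g$whitelist$cid, USE.NAMES = FALSE)
  expect_identical(got$x, g$whitelist$x[want_idx])
  expect_identical(got$y, g$whitelist$y[want_idx])
})

test_that("MID filter drops N bases and more than two low-quality bases", {
  expect_true(filter_mid("ACGTACGTAC", rep(30, 10)))
  expect_false(filter_mid("ACGTNCGTAC", rep(30, 10)))
  # Exactly two bases below 10 keep; three drop; 10 itself is not low.
  expect_true(filter_mid("ACGTACGTAC", c(9, 9, rep(30, 8))))
  expect_false(filter_mid("ACGTACGTAC", c(9, 9, 9, rep(30, 7))))
  expect_true(filter_mid("ACGTACGTAC", c(10, 10, 10, rep(30, 7))))
  # Phred-string interface agrees with the numeric one.
  q <- intToUtf8(33 + c(9, 9, 9, rep(30, 7)))
  expect_false(filter_mid("ACGTACGTAC", q))
  expect_equal(filter_mid(c("AC", "AN"), c("II", "II")), c(TRUE, FALSE))
})

test_that("deduplication counts distinct MIDs per gene and spot", {
  reads <- data.table::data.table(
    gene = "g1", x = 0L, y = 0L, mid = c("AAAA", "AAAA", "CCCC"))
  expect_equal(dedup_counts(reads)$data$count, 2L)
  empty <- dedup_counts(reads[0])
  expect_equal(nrow(empty$data), 0L)

  # 500 random reads against a set-cardinality oracle.
  set.seed(42)
  rnd <- data.table::data.table(
    gene = sample(c("a", "b", "c"), 500, TRUE),
    x = sample(0:3, 500, TRUE), y = sample(0:3, 500, TRUE),
    mid = sample(c("AA", "AC", "AG", "AT", "CA"), 500, TRUE))
  got <- dedup_counts(rnd)$data
  df <- as.data.frame(rnd)
  want <- aggregate(mid ~ gene + x + y, df,
                    FUN = function(m) length(unique(m)))
  want <- want[order(want$gene, want$x, want$y), ]
  expect_equal(got$count,
               want$mid[match(paste(got$gene, got$x, got$y),
                              paste(want$gene, want$x, want$y))])
})

test_that("binning uses floor division and conserves per-gene totals", {
  sm <- spot_matrix(data.table::data.table(
    gene = "g", x = c(0L, 19L, 20L, 39L, 40L), y = 0L, count = 1:5))
  bm <- bin_spots(sm, 20L)
  expect_equal(bm$data$bin_x, c(0L, 1L, 2L))
  expect_equal(bm$data$count, c(1L + 2L, 3L + 4L, 5L))
  # bin_size 1 is the identity.
  b1 <- bin_spots(sm, 1L)
  expect_equal(b1$data$count, sm$data$count)
  expect_error(bin_spots(sm, 0L), class = "ccsmap_input_error")

  set.seed(11)
  for (rep in 1:5) {
    sm <- spot_matrix(data.table::data.table(
      gene = sample(letters[1:4], 200, TRUE),
      x = sample(0:99, 200, TRUE), y = sample(0:99, 200, TRUE),
      count = sample(1:9, 200, TRUE)))
    bm <- bin_spots(sm, 7L)
    tot_in <- sm$data[, .(tot = sum(count)), by = gene][order(gene)]
    tot_out <- bm$data[, .(tot = sum(count)), by = gene][order(gene)]
    expect_equal(tot_in, tot_out)
    # Composition: bin(a) then rebin(b) equals bin(a * b).
    ab <- rebin(bin_spots(sm, 4L), 5L)
    once <- bin_spots(sm, 20L)
    expect_equal(ab$data, once$data)
    expect_equal(ab$bin_size, once$bin_size)
  }
})

test_that("density-based bin QC separates planted low and high modes", {
  set.seed(33)
  # Unimodal: everything kept, no threshold.
  uni <- make_density_bins(rpois(400, 120))
  res_u <- filter_bins_density(uni)
  expect_true(is.na(res_u$threshold))
  expect_equal(nrow(res_u$kept$data), nrow(uni$data))
  # Single bin kept.
  one <- make_density_bins(5L)
  expect_equal(nrow(filter_bins_density(one)$kept$data), 5L)
  # Planted two-mode mixture.
  n_low <- 300; n_high <- 700
  vals <- c(rpois(n_low, 10), rpois(n_high, 300))
  mix <- make_density_bins(vals)
  res <- filter_bins_density(mix)
  kept_bins <- unique(res$kept$data[, .(bin_x, bin_y)])
  kept_id <- kept_bins$bin_y * 100L + kept_bins$bin_x
  high_id <- which(seq_along(vals) > n_low) - 1L
  low_id <- which(seq_along(vals) <= n_low) - 1L
  expect_gte(mean(high_id %in% kept_id), 0.99)
  expect_gte(mean(!(low_id %in% kept_id)), 0.95)
  expect_true(res$threshold > 10 && res$threshold < 300)
})

test_that("minimum-bin gene filter is exact at the boundary and idempotent", {
  dt <- data.table::rbindlist(list(
    data.table::data.table(gene = "four", bin_x = 0:3, bin_y = 0L, count = 1L),
    data.table::data.table(gene = "five", bin_x = 0:4, bin_y = 1L, count = 1L)))
  bm <- bin_matrix(dt, bin_size = 20L)
  out <- filter_genes_minbins(bm, 5L)
  expect_identical(unique(out$data$gene), "five")
  expect_identical(filter_genes_minbins(out, 5L)$data, out$data)
})

test_that("the full raw chain reproduces truth on corruption-free reads", {
  cfg <- sim_config(seed = 17, n_spots_side = 30, cid_sub1 = 0,
                    cid_sub2 = 0, mid_n_rate = 0, mid_lowq_rate = 0)
  g <- gen_reads(cfg)
  st <- process_stereo(g$reads, g$whitelist, bin_size = 1L, min_bins = 1L,
                       bin_qc = FALSE)
  expect_identical(st$spots$data, g$truth$data)
  expect_equal(st$attrition[filter == "cid_match", n_in - n_out], 0L)
  expect_equal(st$attrition[filter == "mid_quality", n_in - n_out], 0L)
})

test_that("single-substitution CID errors are recovered to the true spot", {
  cfg <- sim_config(seed = 19, n_spots_side = 25, cid_sub1 = 0.15,
                    cid_sub2 = 0, mid_n_rate = 0, mid_lowq_rate = 0)
  g <- gen_reads(cfg)
  coords <- match_cid(g$reads$cid, g$whitelist)
  sub1 <- g$ledger$corruption == "cid_sub1"
  assigned <- !is.na(coords$x)
  # All corrupted reads are recovered (no ambiguous collisions at this
  # whitelist density), and to the correct spot.
  expect_true(all(assigned[sub1]))
  expect_true(all(coords$x[sub1] == g$reads$true_x[sub1] &
                    coords$y[sub1] == g$reads$true_y[sub1]))
})
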