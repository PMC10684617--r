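# Independent oracles, deliberately implemented with different algorithms
# (and mostly base R) than the package code they check.

# Exhaustive Hamming scan barcode matcher: computes the distance of a query
# to every whitelist barcode and applies the same rule as the matcher
# (exact hit wins; otherwise a unique distance-1 hit; else unassigned).
oracle_match <- function(query, wl_cids) {
  qv <- utf8ToInt(query)
  d <- vapply(wl_cids, function(b) sum(utf8ToInt(b) != qv), integer(1),
              USE.NAMES = FALSE)
  if (any(d == 0L)) return(which(d == 0L)[1])
  one <- which(d == 1L)
  if (length(one) == 1L) one else NA_integer_
}

# Queue-based BFS flood fill from the border over background pixels
# (4-connectivity); returns the hole-filled mask.
oracle_fill_holes <- function(mask) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  visited <- matrix(FALSE, h, w)
  queue <- integer(0)
  for (i in seq_len(h)) for (j in c(1L, w)) {
    if (!m[i, j]) queue <- c(queue, (j - 1L) * h + i)
  }
  for (j in seq_len(w)) for (i in c(1L, h)) {
    if (!m[i, j]) queue <- c(queue, (j - 1L) * h + i)
  }
  queue <- unique(queue)
  visited[queue] <- TRUE
  head <- 1L
  while (head <= length(queue)) {
    idx <- queue[head]; head <- head + 1L
    i <- (idx - 1L) %% h + 1L
    j <- (idx - 1L) %/% h + 1L
    for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L),
                    c(i, j + 1L))) {
      ni <- nb[1]; nj <- nb[2]
      if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
          !m[ni, nj] && !visited[ni, nj]) {
        visited[ni, nj] <- TRUE
        queue <- c(queue, (nj - 1L) * h + ni)
      }
    }
  }
  m | !visited
}

# Element-by-element Pearson chi-squared statistic on an observed table.
oracle_chi2 <- function(O) {
  n <- sum(O)
  stat <- 0
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(ncol(O))) {
      e <- sum(O[i, ]) * sum(O[, j]) / n
      stat <- stat + (O[i, j] - e)^2 / e
    }
  }
  stat
}

# A tiny CellExpr with fully controlled QC metrics: each cell is given an
# exact nuclear count, number of expressed genes, and mitochondrial count.
make_qc_cells <- function(specs) {
  n_genes <- max(vapply(specs, function(s) s$nfeat, numeric(1))) + 1L
  genes <- c("mt-1", sprintf("g%04d", seq_len(n_genes)))
  counts <- matrix(0, length(genes), length(specs),
                   dimnames = list(genes, sprintf("c%03d", seq_along(specs))))
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    nuclear <- s$numi - s$mito
    nfeat_nuc <- s$nfeat - (s$mito > 0)
    stopifnot(nuclear >= nfeat_nuc)
    counts[1L + seq_len(nfeat_nuc), k] <- 1
    counts[2L, k] <- counts[2L, k] + (nuclear - nfeat_nuc)
    counts["mt-1", k] <- s$mito
  }
  meta <- data.frame(barcode = colnames(counts),
                     stage = vapply(specs, function(s) s$stage,
                                    character(1)))
  cell_expr(Matrix::Matrix(counts, sparse = TRUE), meta)
}

# Bin matrix with a planted per-bin distinct-gene count distribution:
# each bin expresses `n_genes[i]` distinct genes at count 1.
make_density_bins <- function(n_genes_per_bin, gene_pool = 1000L,
                              bin_size = 20L) {
  rows <- lapply(seq_along(n_genes_per_bin), function(i) {
    k <- min(n_genes_per_bin[i], gene_pool)
    if (k == 0L) return(NULL)
    data.frame(gene = sprintf("g%04d", sample.int(gene_pool, k)),
               bin_x = (i - 1L) %% 100L, bin_y = (i - 1L) %/% 100L,
               count = 1L)
  })
  bin_matrix(do.call(rbind, rows), bin_size = bin_size)
}
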