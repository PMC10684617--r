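# Stereo-seq raw processing: CID matching, MID filtering, deduplication,
# bin aggregation, and bin/gene quality control.

#' Match spatial barcodes (CIDs) against a whitelist with one mismatch
#'
#' An exact whitelist hit is always accepted. Otherwise all single-base
#' substitutions are considered: a barcode matching exactly one whitelist
#' entry at Hamming distance 1 is assigned to that entry's spot; zero or
#' multiple distance-1 candidates leave the barcode unassigned (ambiguous
#' hits are dropped, the conservative demultiplexing convention).
#'
#' @param cid Character vector of barcodes (same length as whitelist
#'   barcodes).
#' @param wl Whitelist `data.table` with columns `cid`, `x`, `y` (unique
#'   coordinates per barcode).
#' @return `data.table` with one row per input barcode: `cid`, `x`, `y`
#'   (`NA` when unassigned).
#' @export
match_cid <- function(cid, wl) {
  if (!all(c("cid", "x", "y") %in% names(wl))) {
    abort_input("whitelist needs columns cid, x, y")
  }
  bl <- nchar(wl$cid[1])
  if (any(nchar(cid) != bl)) {
    abort_input("barcode length does not match whitelist barcode length")
  }
  hit <- match(cid, wl$cid)
  miss <- which(is.na(hit))
  if (length(miss)) {
    bases <- c("A", "C", "G", "T")
    # Whitelist index per 1-substitution variant, over all positions/bases.
    cand <- matrix(NA_integer_, length(miss), 0L)
    cand_list <- vector("list", bl * 3L)
    k <- 0L
    mcid <- cid[miss]
    for (pos in seq_len(bl)) {
      cur <- substr(mcid, pos, pos)
      for (shift in 1:3) {
        idx <- (match(cur, bases) - 1L + shift) %% 4L + 1L
        var <- mcid
        substr(var, pos, pos) <- bases[idx]
        k <- k + 1L
        cand_list[[k]] <- match(var, wl$cid)
      }
    }
    cand <- do.call(cbind, cand_list)
    nhits <- rowSums(!is.na(cand))
    unique_hit <- nhits == 1L
    if (any(unique_hit)) {
      first <- apply(cand[unique_hit, , drop = FALSE], 1L,
                     function(r) r[!is.na(r)][1])
      hit[miss[unique_hit]] <- first
    }
  }
  data.table::data.table(cid = cid, x = wl$x[hit], y = wl$y[hit])
}

#' MID quality filter
#'
#' A molecular identifier is dropped when it contains an `N` base or when
#' more than two of its bases have quality score below 10.
#'
#' @param mid Character vector of MIDs.
#' @param quals Base qualities: a numeric vector (single MID), a list of
#'   numeric vectors, or a character vector of phred+33 strings.
#' @return Logical vector: `TRUE` = keep.
#' @export
filter_mid <- function(mid, quals) {
  if (is.numeric(quals)) {
    if (length(mid) != 1L) {
      abort_input("numeric quals imply a single MID")
    }
    quals <- list(quals)
  } else if (is.character(quals)) {
    if (any(nchar(quals) != nchar(mid))) {
      abort_input("quality strings must match MID lengths")
    }
    low <- vapply(quals, function(q) {
      sum(as.integer(charToRaw(q)) - 33L < 10L)
    }, integer(1), USE.NAMES = FALSE)
    return(!grepl("N", mid, fixed = TRUE) & low <= 2L)
  }
  if (any(lengths(quals) != nchar(mid))) {
    abort_input("quality vectors must match MID lengths")
  }
  low <- vapply(quals, function(q) sum(q < 10), integer(1))
  !grepl("N", mid, fixed = TRUE) & low <= 2L
}

#' Deduplicate reads into molecule counts
#'
#' For each gene at each spot, reads sharing a MID are collapsed to a single
#' molecule; the count is the number of distinct MIDs.
#'
#' @param reads `data.table` with columns `gene`, `x`, `y`, `mid` (every
#'   read already assigned to a spot).
#' @param pitch_nm Spot pitch recorded in the output.
#' @return A [spot_matrix()].
#' @export
dedup_counts <- function(reads, pitch_nm = 500L) {
  reads <- data.table::as.data.table(reads)
  if (!all(c("gene", "x", "y", "mid") %in% names(reads))) {
    abort_input("reads need columns gene, x, y, mid")
  }
  if (nrow(reads) == 0L) {
    return(spot_matrix(data.table::data.table(
      gene = character(), x = integer(), y = integer(), count = integer()),
      pitch_nm = pitch_nm))
  }
  if (anyNA(reads$x) || anyNA(reads$y)) {
    abort_input("dedup_counts requires every read to carry a spot")
  }
  counts <- unique(reads, by = c("gene", "x", "y", "mid"))[
    , .(count = .N), by = .(gene, x, y)]
  spot_matrix(counts, pitch_nm = pitch_nm)
}

#' Aggregate spots into square bins
#'
#' Bin index is `floor(coordinate / bin_size)` on each axis (half-open
#' bins); counts are summed per gene and bin, so per-gene totals are
#' conserved.
#'
#' @param sm A [spot_matrix()].
#' @param bin_size Bin edge in spots (>= 1); 20 for developmental hearts,
#'   50 for adult.
#' @return A [bin_matrix()].
#' @export
bin_spots <- function(sm, bin_size) {
  if (!inherits(sm, "SpotMatrix")) abort_input("sm must be a SpotMatrix")
  if (bin_size < 1L) abort_input("bin_size must be >= 1")
  bin_size <- as.integer(bin_size)
  binned <- sm$data[, .(count = sum(count)),
                    by = .(gene, bin_x = x %/% bin_size,
                           bin_y = y %/% bin_size)]
  bin_matrix(binned, bin_size = bin_size, pitch_nm = sm$pitch_nm)
}

#' Re-bin a bin matrix by a further factor
#'
#' Composing [bin_spots()] with sizes `a` then `b` equals a single binning
#' with `a * b`.
#'
#' @param bm A [bin_matrix()].
#' @param factor Additional bin factor (>= 1).
#' @return A [bin_matrix()] with `bin_size = bm$bin_size * factor`.
#' @export
rebin <- function(bm, factor) {
  if (!inherits(bm, "BinMatrix")) abort_input("bm must be a BinMatrix")
  if (factor < 1L) abort_input("factor must be >= 1")
  factor <- as.integer(factor)
  binned <- bm$data[, .(count = sum(count)),
                    by = .(gene, bin_x = bin_x %/% factor,
                           bin_y = bin_y %/% factor)]
  bin_matrix(binned, bin_size = bm$bin_size * factor,
             pitch_nm = bm$pitch_nm)
}

#' Exclude low-complexity bins via the bin density distribution
#'
#' Per-bin values (distinct genes by default, or total counts) are modelled
#' on a log1p scale with a Gaussian kernel density estimate (Silverman's
#' rule-of-thumb bandwidth). When the density shows two or more modes, the
#' threshold is placed at the density minimum between the two largest modes
#' and bins below it (the minor low-count peak) are excluded; a unimodal
#' distribution keeps every bin.
#'
#' @param bm A [bin_matrix()] with >= 1 bin.
#' @param metric `"genes"` (distinct genes per bin, nFeature-like) or
#'   `"counts"` (total counts per bin).
#' @return List: `kept` ([bin_matrix()] of retained bins), `threshold`
#'   (on the original scale; `NA` when unimodal), `excluded`
#'   (`data.table` of dropped bins), `diagnostics` (per-bin values and the
#'   density object).
#' @export
filter_bins_density <- function(bm, metric = c("genes", "counts")) {
  if (!inherits(bm, "BinMatrix")) abort_input("bm must be a BinMatrix")
  metric <- match.arg(metric)
  if (nrow(bm$data) == 0L) abort_input("bin matrix is empty")
  per_bin <- if (metric == "genes") {
    bm$data[, .(value = data.table::uniqueN(gene)), by = .(bin_x, bin_y)]
  } else {
    bm$data[, .(value = sum(count)), by = .(bin_x, bin_y)]
  }
  lv <- log1p(per_bin$value)
  threshold <- NA_real_
  dens <- NULL
  if (nrow(per_bin) >= 3L && stats::sd(lv) > 0) {
    dens <- stats::density(lv, bw = "nrd0")
    y <- dens$y
    is_peak <- c(FALSE, diff(sign(diff(y))) == -2, FALSE)
    peaks <- which(is_peak)
    if (length(peaks) >= 2L) {
      top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
      valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
      threshold <- expm1(dens$x[valley])
    }
  }
  if (is.na(threshold)) {
    kept_bins <- per_bin
    excluded <- per_bin[0]
  } else {
    keep <- per_bin$value > threshold
    kept_bins <- per_bin[keep]
    excluded <- per_bin[!keep]
  }
  kept <- bm$data[kept_bins[, .(bin_x, bin_y)], on = c("bin_x", "bin_y"),
                  nomatch = NULL]
  list(kept = bin_matrix(kept, bin_size = bm$bin_size,
                         pitch_nm = bm$pitch_nm),
       threshold = threshold,
       excluded = excluded,
       diagnostics = list(per_bin = per_bin, density = dens,
                          metric = metric))
}

#' Discard genes expressed in too few bins
#'
#' A gene is kept iff it has counts in at least `min_bins` bins.
#'
#' @param bm A [bin_matrix()].
#' @param min_bins Minimum bins with nonzero count (default 5).
#' @return A [bin_matrix()] restricted to the retained genes.
#' @export
filter_genes_minbins <- function(bm, min_bins = 5L) {
  if (!inherits(bm, "BinMatrix")) abort_input("bm must be a BinMatrix")
  if (min_bins < 1L) abort_input("min_bins must be >= 1")
  nb <- bm$data[count > 0, .(n_bins = .N), by = gene]
  keep <- nb[n_bins >= min_bins, gene]
  bin_matrix(bm$data[gene %in% keep], bin_size = bm$bin_size,
             pitch_nm = bm$pitch_nm)
}

#' Full Stereo-seq raw-processing chain
#'
#' CID matching (1 mismatch), MID quality filter, MID deduplication, bin
#' aggregation, density-based bin exclusion, and minimum-bin gene filtering,
#' with per-filter attrition accounting.
#'
#' @param reads Read `data.table` (`cid`, `mid`, `quals`, `gene`).
#' @param whitelist Whitelist `data.table` (`cid`, `x`, `y`).
#' @param bin_size Bin edge in spots.
#' @param min_bins Minimum bins per gene.
#' @param pitch_nm Spot pitch.
#' @param density_metric Passed to [filter_bins_density()].
#' @param bin_qc Apply the density-based bin exclusion (default `TRUE`).
#' @return List: `spots` ([spot_matrix()] after dedup), `bins` (final
#'   [bin_matrix()]), `bin_threshold`, `attrition` (`data.table` of reads /
#'   bins / genes in and out at every filter).
#' @export
process_stereo <- function(reads, whitelist, bin_size = 20L, min_bins = 5L,
                           pitch_nm = 500L,
                           density_metric = c("genes", "counts"),
                           bin_qc = TRUE) {
  density_metric <- match.arg(density_metric)
  reads <- data.table::as.data.table(reads)
  n0 <- nrow(reads)
  coords <- match_cid(reads$cid, whitelist)
  assigned <- !is.na(coords$x)
  reads <- cbind(reads[, .(gene, mid, quals)],
                 coords[, .(x, y)])[assigned]
  n_cid <- nrow(reads)
  keep_mid <- filter_mid(reads$mid, reads$quals)
  reads <- reads[keep_mid]
  n_mid <- nrow(reads)
  spots <- dedup_counts(reads, pitch_nm = pitch_nm)
  bins <- bin_spots(spots, bin_size)
  n_bins0 <- data.table::uniqueN(bins$data[, .(bin_x, bin_y)])
  threshold <- NA_real_
  if (bin_qc) {
    qc <- filter_bins_density(bins, metric = density_metric)
    bins <- qc$kept
    threshold <- qc$threshold
  }
  n_bins1 <- data.table::uniqueN(bins$data[, .(bin_x, bin_y)])
  n_genes0 <- data.table::uniqueN(bins$data$gene)
  bins <- filter_genes_minbins(bins, min_bins)
  n_genes1 <- data.table::uniqueN(bins$data$gene)
  attrition <- data.table::data.table(
    filter = c("cid_match", "mid_quality", "bin_density", "gene_min_bins"),
    unit = c("reads", "reads", "bins", "genes"),
    n_in = c(n0, n_cid, n_bins0, n_genes0),
    n_out = c(n_cid, n_mid, n_bins1, n_genes1))
  list(spots = spots, bins = bins, bin_threshold = threshold,
       attrition = attrition)
}
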