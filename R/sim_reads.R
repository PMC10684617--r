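# Synthetic Stereo-seq-style read generator with a recorded corruption ledger.

# n random fixed-length sequences over ACGT, vectorised column-wise.
random_seqs <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return(character())
  cols <- replicate(len, sample(alphabet, n, replace = TRUE),
                    simplify = FALSE)
  do.call(paste0, cols)
}

# Replace position `pos` of each string with a base different from the
# current one (uniform over the other three).
substitute_base <- function(seqs, pos) {
  bases <- c("A", "C", "G", "T")
  cur <- substr(seqs, pos, pos)
  shift <- sample.int(3L, length(seqs), replace = TRUE)
  idx <- (match(cur, bases) - 1L + shift) %% 4L + 1L
  substr(seqs, pos, pos) <- bases[idx]
  seqs
}

phred_chars <- function(q) {
  vapply(q, function(x) rawToChar(as.raw(33L + x)), character(1))
}

#' Convert a phred+33 quality string to integer scores
#' @param quals Character vector of quality strings.
#' @return List of integer vectors (one per string).
#' @export
phred_to_int <- function(quals) {
  lapply(quals, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Generate synthetic sequencing reads with known truth
#'
#' Emits CID/MID/quality/gene read records for a spatial chip. Per-spot,
#' per-gene molecule counts are negative-binomial with regionally enriched
#' means; each molecule receives a random MID and `1 + Poisson(dup_mean)`
#' duplicate reads. A configured fraction of reads is corrupted (1 or 2 CID
#' substitutions, an `N` in the MID, or three low-quality MID bases) and
#' every corruption is recorded in a ledger, so downstream filters can be
#' audited read by read.
#'
#' @param cfg A [sim_config()].
#' @return List with elements:
#'   `reads` (`data.table`: `read_id`, `cid`, `mid`, `quals`, `gene`, plus
#'   truth columns `true_x`, `true_y`),
#'   `truth` (the [spot_matrix()] of distinct molecules per gene and spot),
#'   `whitelist` (`data.table`: `cid`, `x`, `y`),
#'   `ledger` (`data.table`: `read_id`, `corruption` in
#'   `{"none","cid_sub1","cid_sub2","mid_n","mid_lowq"}`).
#' @export
gen_reads <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort_config("cfg must be a sim_config")
  set.seed(cfg$seed)
  n <- cfg$n_spots_side
  n_spots <- n * n

  # Whitelist: one unique barcode per spot.
  cid <- random_seqs(n_spots, cfg$cid_len)
  while (anyDuplicated(cid)) {
    dup <- which(duplicated(cid))
    cid[dup] <- random_seqs(length(dup), cfg$cid_len)
  }
  whitelist <- data.table::data.table(
    cid = cid,
    x = rep(0:(n - 1L), times = n),
    y = rep(0:(n - 1L), each = n))

  # Region-dependent NB means. region_map is indexed [y + 1, x + 1].
  region <- cfg$region_map[cbind(whitelist$y + 1L, whitelist$x + 1L)]
  enr <- cfg$enrichment
  regions <- unique(region)
  mult <- matrix(1, nrow = cfg$n_genes, ncol = length(regions),
                 dimnames = list(cfg$genes, regions))
  for (r in regions) {
    if (r == "background") {
      mult[, r] <- enr$background_scale
    } else if (!is.null(enr$multipliers[[r]])) {
      m <- enr$multipliers[[r]]
      mult[names(m)[names(m) %in% cfg$genes], r] <-
        m[names(m) %in% cfg$genes]
    }
  }
  mu <- cfg$base_mean * mult[, match(region, regions), drop = FALSE]
  counts <- stats::rnbinom(length(mu), mu = as.vector(mu),
                           size = cfg$dispersion)

  nz <- which(counts > 0L)
  gene_idx <- (nz - 1L) %% cfg$n_genes + 1L
  spot_idx <- (nz - 1L) %/% cfg$n_genes + 1L
  mol <- data.table::data.table(
    gene = cfg$genes[rep(gene_idx, counts[nz])],
    spot = rep(spot_idx, counts[nz]))
  mol[, `:=`(x = whitelist$x[spot], y = whitelist$y[spot])]
  mol[, mid := random_seqs(.N, cfg$mid_len)]

  truth <- spot_matrix(
    unique(mol, by = c("gene", "x", "y", "mid"))[
      , .(count = .N), by = .(gene, x, y)],
    pitch_nm = cfg$pitch_nm)

  # Duplicate reads per molecule.
  n_copies <- 1L + stats::rpois(nrow(mol), cfg$dup_mean)
  reads <- mol[rep(seq_len(nrow(mol)), n_copies)]
  reads[, read_id := seq_len(.N)]
  reads[, cid := whitelist$cid[spot]]
  qual_alphabet <- phred_chars(30:40)
  qcols <- replicate(cfg$mid_len,
                     sample(qual_alphabet, nrow(reads), replace = TRUE),
                     simplify = FALSE)
  reads[, quals := do.call(paste0, qcols)]

  # Corruption classes are disjoint per read.
  u <- stats::runif(nrow(reads))
  p <- cumsum(c(cfg$cid_sub1, cfg$cid_sub2, cfg$mid_n_rate,
                cfg$mid_lowq_rate))
  corruption <- rep("none", nrow(reads))
  corruption[u < p[4]] <- "mid_lowq"
  corruption[u < p[3]] <- "mid_n"
  corruption[u < p[2]] <- "cid_sub2"
  corruption[u < p[1]] <- "cid_sub1"

  i1 <- which(corruption == "cid_sub1")
  if (length(i1)) {
    pos <- sample.int(cfg$cid_len, length(i1), replace = TRUE)
    reads$cid[i1] <- substitute_base(reads$cid[i1], pos)
  }
  i2 <- which(corruption == "cid_sub2")
  if (length(i2)) {
    pos1 <- sample.int(cfg$cid_len, length(i2), replace = TRUE)
    off <- sample.int(cfg$cid_len - 1L, length(i2), replace = TRUE)
    pos2 <- (pos1 - 1L + off) %% cfg$cid_len + 1L
    s <- substitute_base(reads$cid[i2], pos1)
    reads$cid[i2] <- substitute_base(s, pos2)
  }
  im <- which(corruption == "mid_n")
  if (length(im)) {
    pos <- sample.int(cfg$mid_len, length(im), replace = TRUE)
    mids <- reads$mid[im]
    substr(mids, pos, pos) <- "N"
    reads$mid[im] <- mids
  }
  iq <- which(corruption == "mid_lowq")
  if (length(iq)) {
    # Three consecutive low-quality (q in 2..9) bases.
    start <- sample.int(cfg$mid_len - 2L, length(iq), replace = TRUE)
    low <- phred_chars(2:9)
    qs <- reads$quals[iq]
    for (k in 0:2) {
      substr(qs, start + k, start + k) <-
        sample(low, length(iq), replace = TRUE)
    }
    reads$quals[iq] <- qs
  }

  ledger <- data.table::data.table(read_id = reads$read_id,
                                   corruption = corruption)
  out_reads <- reads[, .(read_id, cid, mid, quals, gene,
                         true_x = x, true_y = y)]
  list(reads = out_reads, truth = truth, whitelist = whitelist,
       ledger = ledger)
}
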