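# SNP quality-control pipeline: fixed-order filter chain with per-step
# attrition reporting.  Thresholds follow standard DArT practice for
# reduced-representation SNP data: loci with call rate below 90% (individuals
# below 80%), mean depth below 5, technical repeatability below 95%; one SNP
# per sequenced tag; paralog removal at normalized Hamming distance <= 0.25;
# HWE exact-test removal at p < 1e-5 within any population; LD pruning at
# r^2 > 0.80; then loci with more than 10% missing data or minor allele
# frequency below 2%.

#' Default quality-control configuration
#'
#' @param min_locus_call_rate loci with call rate strictly below this are
#'   removed (default 0.90).
#' @param min_indiv_call_rate individuals strictly below this (default 0.80).
#' @param min_depth loci with mean depth strictly below this (default 5).
#' @param min_repeatability loci strictly below this (default 0.95).
#' @param one_snp_per_tag keep a single SNP per sequenced tag (default TRUE).
#' @param hamming_threshold tag pairs at normalized Hamming distance at or
#'   below this are treated as paralogous duplicates (default 0.25).
#' @param hwe_alpha loci with an exact-test p-value strictly below this in any
#'   population are removed (default 1e-5).
#' @param ld_r2_max locus pairs with genotypic r-squared strictly above this
#'   are pruned (default 0.80).
#' @param max_locus_missing loci with strictly more than this fraction missing
#'   are removed (default 0.10).
#' @param min_maf loci with minor allele frequency strictly below this are
#'   removed (default 0.02).
#' @param ld_window,ld_step sliding-window size and step (in loci) for LD
#'   pruning (defaults 50 and 5).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_locus_call_rate = 0.90,
                          min_indiv_call_rate = 0.80,
                          min_depth = 5,
                          min_repeatability = 0.95,
                          one_snp_per_tag = TRUE,
                          hamming_threshold = 0.25,
                          hwe_alpha = 1e-5,
                          ld_r2_max = 0.80,
                          max_locus_missing = 0.10,
                          min_maf = 0.02,
                          ld_window = 50L,
                          ld_step = 5L) {
  rates <- c(min_locus_call_rate, min_indiv_call_rate, min_repeatability,
             hamming_threshold, hwe_alpha, ld_r2_max, max_locus_missing,
             min_maf)
  if (any(rates < 0 | rates > 1)) stop("all rate thresholds must lie in [0,1]")
  ld_window <- as.integer(ld_window); ld_step <- as.integer(ld_step)
  if (ld_step < 1L || ld_window < ld_step)
    stop("need ld_window >= ld_step >= 1")
  structure(list(min_locus_call_rate = min_locus_call_rate,
                 min_indiv_call_rate = min_indiv_call_rate,
                 min_depth = min_depth,
                 min_repeatability = min_repeatability,
                 one_snp_per_tag = one_snp_per_tag,
                 hamming_threshold = hamming_threshold,
                 hwe_alpha = hwe_alpha,
                 ld_r2_max = ld_r2_max,
                 max_locus_missing = max_locus_missing,
                 min_maf = min_maf,
                 ld_window = ld_window,
                 ld_step = ld_step),
            class = "filter_config")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: given the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n_hom_ref <- as.integer(n_hom_ref); n_het <- as.integer(n_het)
  n_hom_alt <- as.integer(n_hom_alt)
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("counts must be >= 0")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("undefined input: no genotypes observed")
  n_alt <- 2L * n_hom_alt + n_het
  n_minor <- min(n_alt, 2L * n - n_alt)
  if (n_minor == 0L) return(1)
  # heterozygote counts compatible with the minor-allele count
  hs <- seq(n_minor %% 2L, n_minor, by = 2L)
  # log P(h | n, n_minor) up to a constant:
  # multinomial count of genotype configurations times 2^h
  logp <- lgamma(n + 1) - lgamma((n_minor - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma(n - (n_minor + hs) / 2 + 1) + hs * log(2)
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- which(hs == n_het)
  if (length(obs) == 0) stop("heterozygote count incompatible with alleles")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Minor allele frequency of one locus
#'
#' @param x a [genotype_matrix()].
#' @param locus locus id or column index.
#' @return minor allele frequency in `[0, 0.5]`, missing-aware.
#' @export
maf <- function(x, locus) {
  g <- x$calls[, locus]
  g <- g[g != MISSING]
  if (length(g) == 0) stop("undefined input: locus has no non-missing calls")
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

#' Genotypic linkage-disequilibrium r-squared between two loci
#'
#' Squared Pearson correlation of genotype codes over the individuals
#' non-missing at both loci (composite/genotypic r-squared).
#'
#' @param x a [genotype_matrix()].
#' @param locus_a,locus_b locus ids or column indices.
#' @return r-squared in `[0, 1]`, or `NA` if either locus is constant on the
#'   shared non-missing set (treated as "not prunable" by callers).
#' @export
ld_r2 <- function(x, locus_a, locus_b) {
  a <- x$calls[, locus_a]; b <- x$calls[, locus_b]
  ok <- a != MISSING & b != MISSING
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2 || var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Sliding-window greedy LD pruning
#'
#' Within each window, while any retained pair exceeds `ld_r2_max`, the member
#' of the worst pair with the lower call rate is removed (ties remove the
#' later locus); the window then advances by `ld_step` loci.
#'
#' @param x a [genotype_matrix()].
#' @param config a [filter_config()].
#' @return character vector of retained locus ids.
#' @export
ld_prune <- function(x, config = filter_config()) {
  calls <- x$calls
  L <- ncol(calls)
  if (L < 2) return(colnames(calls))
  cr <- locus_call_rate(calls)
  removed <- logical(L)
  starts <- seq(1L, max(1L, L - 1L), by = config$ld_step)
  for (s in starts) {
    win <- s:min(L, s + config$ld_window - 1L)
    repeat {
      act <- win[!removed[win]]
      if (length(act) < 2) break
      worst <- NULL; worst_r2 <- config$ld_r2_max
      for (ii in seq_len(length(act) - 1)) {
        for (jj in (ii + 1):length(act)) {
          r2 <- ld_r2(x, act[ii], act[jj])
          if (!is.na(r2) && r2 > worst_r2) {
            worst_r2 <- r2; worst <- c(act[ii], act[jj])
          }
        }
      }
      if (is.null(worst)) break
      drop <- if (cr[worst[1]] < cr[worst[2]]) worst[1] else
        if (cr[worst[2]] < cr[worst[1]]) worst[2] else max(worst)
      removed[drop] <- TRUE
    }
  }
  colnames(calls)[!removed]
}

# normalized Hamming distance between two equal-length strings
hamming_dist <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  mean(va != vb)
}

#' Paralog filtering by tag-sequence Hamming distance
#'
#' Tag pairs whose normalized Hamming distance is at or below `threshold` are
#' treated as putative paralogous duplicates: the lower-call-rate member is
#' dropped (ties drop the later locus).  Pairs are resolved most-similar
#' first; loci without a tag sequence pass, and pairs of unequal tag lengths
#' are skipped (counted in the `"skipped_pairs"` attribute).
#'
#' @param metadata a [locus_metadata()].
#' @param threshold normalized Hamming distance cutoff (default 0.25).
#' @return character vector of retained locus ids, with attribute
#'   `"skipped_pairs"`.
#' @export
hamming_filter <- function(metadata, threshold = 0.25) {
  has_seq <- !is.na(metadata$tag_sequence)
  ids <- metadata$locus_id
  idx <- which(has_seq)
  skipped <- 0L
  if (length(idx) >= 2) {
    pr <- combn(idx, 2)
    dist <- numeric(ncol(pr)); keep_pair <- logical(ncol(pr))
    for (k in seq_len(ncol(pr))) {
      a <- metadata$tag_sequence[pr[1, k]]
      b <- metadata$tag_sequence[pr[2, k]]
      if (nchar(a) != nchar(b)) { skipped <- skipped + 1L; next }
      dist[k] <- hamming_dist(a, b)
      keep_pair[k] <- dist[k] <= threshold
    }
    pr <- pr[, keep_pair, drop = FALSE]
    dist <- dist[keep_pair]
    ord <- order(dist)
    removed <- logical(nrow(metadata))
    for (k in ord) {
      i <- pr[1, k]; j <- pr[2, k]
      if (removed[i] || removed[j]) next
      cri <- metadata$call_rate[i]; crj <- metadata$call_rate[j]
      drop <- if (cri < crj) i else if (crj < cri) j else max(i, j)
      removed[drop] <- TRUE
    }
    ids <- ids[!removed]
  }
  attr(ids, "skipped_pairs") <- skipped
  ids
}

# keep one SNP per tag: highest call rate, ties -> smallest position_in_tag,
# then locus order
one_snp_per_tag <- function(metadata) {
  keep <- logical(nrow(metadata))
  for (tg in unique(metadata$tag_id)) {
    rows <- which(metadata$tag_id == tg)
    best <- rows[order(-metadata$call_rate[rows],
                       metadata$position_in_tag[rows], rows)][1]
    keep[best] <- TRUE
  }
  metadata$locus_id[keep]
}

# per-population HWE p-values for every locus; returns min over populations
hwe_min_p <- function(x) {
  pops <- unique(x$population)
  L <- ncol(x$calls)
  minp <- rep(1, L)
  for (pp in pops) {
    sub <- x$calls[x$population == pp, , drop = FALSE]
    for (l in seq_len(L)) {
      g <- sub[, l]; g <- g[g != MISSING]
      if (length(g) == 0) next
      p <- hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
      minp[l] <- min(minp[l], p)
    }
  }
  minp
}

#' Apply the full quality-control filter chain
#'
#' Applies, in order: monomorphic-locus removal, locus call rate, individual
#' call rate, mean depth, repeatability, one SNP per tag, tag-sequence
#' (paralog) Hamming filter, per-population HWE exact test, sliding-window LD
#' pruning, locus missingness, and minor allele frequency.  Metadata-based
#' steps (depth, repeatability, tag, Hamming) are skipped with zero removals
#' when `metadata` is `NULL`.  The chain never raises on an emptied matrix;
#' it completes with a zero-remaining report.
#'
#' @param x a [genotype_matrix()].
#' @param metadata optional [locus_metadata()] covering the loci of `x`.
#' @param config a [filter_config()].
#' @return list with elements `matrix` (filtered [genotype_matrix()]) and
#'   `report` (a `filter_report` data.frame: step, loci_removed,
#'   individuals_removed, loci_remaining, individuals_remaining).
#' @export
apply_filters <- function(x, metadata = NULL, config = filter_config()) {
  steps <- list()
  note <- function(step, cur) {
    steps[[length(steps) + 1]] <<- data.frame(
      step = step,
      loci_removed = if (length(steps)) steps[[length(steps)]]$loci_remaining -
        ncol(cur$calls) else ncol(x$calls) - ncol(cur$calls),
      individuals_removed = if (length(steps))
        steps[[length(steps)]]$individuals_remaining - nrow(cur$calls) else
          nrow(x$calls) - nrow(cur$calls),
      loci_remaining = ncol(cur$calls),
      individuals_remaining = nrow(cur$calls),
      stringsAsFactors = FALSE)
  }
  keep_loci <- function(cur, ids) {
    if (length(ids) == 0)
      genotype_matrix(cur$calls[, 0, drop = FALSE], cur$population) else
        cur[, ids]
  }
  cur <- x

  # 1. monomorphic (includes all-missing loci)
  freq <- locus_freq(cur$calls)
  poly <- !is.na(freq) & freq > 0 & freq < 1
  cur <- keep_loci(cur, colnames(cur$calls)[poly])
  note("monomorphic", cur)

  # 2. locus call rate
  ids <- colnames(cur$calls)[locus_call_rate(cur$calls) >=
                               config$min_locus_call_rate]
  cur <- keep_loci(cur, ids)
  note("locus_call_rate", cur)

  # 3. individual call rate
  if (nrow(cur$calls) > 0 && ncol(cur$calls) > 0) {
    keep <- indiv_call_rate(cur$calls) >= config$min_indiv_call_rate
    cur <- cur[rownames(cur$calls)[keep], ]
  }
  note("indiv_call_rate", cur)

  meta_for <- function(cur) metadata[match(colnames(cur$calls),
                                           metadata$locus_id), , drop = FALSE]

  # 4. depth
  if (!is.null(metadata)) {
    m <- meta_for(cur)
    ids <- colnames(cur$calls)[is.na(m$mean_depth) |
                                 m$mean_depth >= config$min_depth]
    cur <- keep_loci(cur, ids)
  }
  note("min_depth", cur)

  # 5. repeatability
  if (!is.null(metadata)) {
    m <- meta_for(cur)
    ids <- colnames(cur$calls)[is.na(m$repeatability) |
                                 m$repeatability >= config$min_repeatability]
    cur <- keep_loci(cur, ids)
  }
  note("repeatability", cur)

  # 6. one SNP per tag
  if (!is.null(metadata) && config$one_snp_per_tag && ncol(cur$calls) > 0) {
    m <- meta_for(cur)
    # use realized call rate so the choice reflects the current matrix
    m$call_rate <- locus_call_rate(cur$calls)
    cur <- keep_loci(cur, one_snp_per_tag(m))
  }
  note("one_snp_per_tag", cur)

  # 7. Hamming paralog filter
  if (!is.null(metadata) && ncol(cur$calls) > 0) {
    m <- meta_for(cur)
    m$call_rate <- locus_call_rate(cur$calls)
    cur <- keep_loci(cur, as.vector(hamming_filter(m,
                                                   config$hamming_threshold)))
  }
  note("hamming", cur)

  # 8. HWE within any population
  if (ncol(cur$calls) > 0) {
    minp <- hwe_min_p(cur)
    cur <- keep_loci(cur, colnames(cur$calls)[minp >= config$hwe_alpha])
  }
  note("hwe", cur)

  # 9. LD pruning
  if (ncol(cur$calls) > 1) cur <- keep_loci(cur, ld_prune(cur, config))
  note("ld_prune", cur)

  # 10. locus missingness
  if (ncol(cur$calls) > 0) {
    missf <- 1 - locus_call_rate(cur$calls)
    cur <- keep_loci(cur,
                     colnames(cur$calls)[missf <= config$max_locus_missing])
  }
  note("locus_missingness", cur)

  # 11. minor allele frequency
  if (ncol(cur$calls) > 0) {
    mafs <- vapply(seq_len(ncol(cur$calls)), function(l) {
      g <- cur$calls[, l]; g <- g[g != MISSING]
      if (length(g) == 0) return(0)
      p <- sum(g) / (2 * length(g)); min(p, 1 - p)
    }, 0)
    cur <- keep_loci(cur, colnames(cur$calls)[mafs >= config$min_maf])
  }
  note("maf", cur)

  report <- do.call(rbind, steps)
  class(report) <- c("filter_report", "data.frame")
  list(matrix = cur, report = report)
}
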