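# Diversity and differentiation statistics: per-population heterozygosity,
# inbreeding, standardized multilocus heterozygosity, rarefied allelic
# richness; Weir & Cockerham (1984) theta with permutation tests; AMOVA
# variance components on genotype distances; and PhiST on sequence distances.

# Weir-Cockerham (1984) per-locus variance components (a, b, c) for the
# alternate allele, from per-population matrices (populations x loci) of
# sample sizes (diploids), allele frequencies and heterozygote fractions.
wc_abc <- function(n_mat, p_mat, h_mat) {
  use <- colSums(n_mat > 0) >= 2
  r_eff <- colSums(n_mat > 0)
  nbar <- colSums(n_mat) / pmax(r_eff, 1)
  nc <- (colSums(n_mat) - colSums(n_mat^2) / pmax(colSums(n_mat), 1)) /
    pmax(r_eff - 1, 1)
  pbar <- colSums(n_mat * p_mat) / pmax(colSums(n_mat), 1)
  s2 <- colSums(n_mat * sweep(p_mat, 2, pbar)^2) /
    pmax((r_eff - 1) * nbar, 1e-300)
  hbar <- colSums(n_mat * h_mat) / pmax(colSums(n_mat), 1)

  a <- nbar / pmax(nc, 1e-300) *
    (s2 - (pbar * (1 - pbar) - s2 * (r_eff - 1) / pmax(r_eff, 1) - hbar / 4) /
       pmax(nbar - 1, 1e-300))
  b <- nbar / pmax(nbar - 1, 1e-300) *
    (pbar * (1 - pbar) - s2 * (r_eff - 1) / pmax(r_eff, 1) -
       hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  bad <- !use | nbar <= 1 | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; c_[bad] <- NA_real_
  list(a = a, b = b, c = c_)
}

# components from a genotype-call matrix with MISSING and a population vector
wc_components <- function(calls, pop) {
  pops <- unique(pop)
  r <- length(pops)
  if (r < 2) stop("Weir-Cockerham components need >= 2 populations")
  L <- ncol(calls)
  n_mat <- p_mat <- h_mat <- matrix(0, r, L)
  for (k in seq_len(r)) {
    sub <- calls[pop == pops[k], , drop = FALSE]
    sub[sub == MISSING] <- NA_integer_
    n_mat[k, ] <- colSums(!is.na(sub))
    p_mat[k, ] <- colSums(sub, na.rm = TRUE) / (2 * pmax(n_mat[k, ], 1))
    h_mat[k, ] <- colSums(sub == 1L, na.rm = TRUE) / pmax(n_mat[k, ], 1)
  }
  wc_abc(n_mat, p_mat, h_mat)
}

# multilocus WC theta (ratio of averages); NA-safe
wc_theta_multilocus <- function(calls, pop) {
  comp <- wc_components(calls, pop)
  ok <- !is.na(comp$a)
  den <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (!is.finite(den) || den == 0) return(NA_real_)
  sum(comp$a[ok]) / den
}

# per-locus WC theta
wc_theta_per_locus <- function(calls, pop) {
  comp <- wc_components(calls, pop)
  den <- comp$a + comp$b + comp$c
  theta <- comp$a / den
  theta[!is.finite(theta)] <- NA_real_
  theta
}

#' Per-population diversity indices
#'
#' Computes, for each population: sample size, observed (Ho) and unbiased
#' expected (He) heterozygosity averaged across loci (with per-locus SDs),
#' the inbreeding coefficient FIS (multilocus ratio `1 - sum(Ho_l)/sum(He_l)`
#' with unbiased He), mean multilocus heterozygosity (MLH), standardized
#' multilocus heterozygosity (sMLH, see [smlh()]), and rarefied allelic
#' richness (AR, see [allelic_richness()]).
#'
#' @param x a [genotype_matrix()].
#' @param rarefaction_size gene-copy count for allelic-richness rarefaction;
#'   defaults to twice the smallest population sample size.
#' @return a `data.frame`, one row per population, columns `population`, `N`,
#'   `MLH`, `AR`, `AR_sd`, `sMLH`, `sMLH_sd`, `FIS`, `He`, `He_sd`, `Ho`,
#'   `Ho_sd`.  Populations of size 1 get `NA` statistics.
#' @export
diversity_table <- function(x, rarefaction_size = NULL) {
  pops <- unique(x$population)
  if (is.null(rarefaction_size))
    rarefaction_size <- 2L * min(table(x$population))
  ar_all <- allelic_richness(x, rarefaction_size)
  sm_all <- smlh(x)
  out <- lapply(pops, function(pp) {
    sub <- x$calls[x$population == pp, , drop = FALSE]
    N <- nrow(sub)
    if (N < 2) {
      return(data.frame(population = pp, N = N, MLH = NA_real_, AR = NA_real_,
                        AR_sd = NA_real_, sMLH = NA_real_, sMLH_sd = NA_real_,
                        FIS = NA_real_, He = NA_real_, He_sd = NA_real_,
                        Ho = NA_real_, Ho_sd = NA_real_,
                        stringsAsFactors = FALSE))
    }
    m <- sub
    m[m == MISSING] <- NA_integer_
    n_l <- colSums(!is.na(m))
    keep <- n_l > 0
    p_l <- colSums(m, na.rm = TRUE) / (2 * n_l)
    ho_l <- colSums(m == 1L, na.rm = TRUE) / n_l
    he_l <- 2 * p_l * (1 - p_l) * (2 * n_l) / pmax(2 * n_l - 1, 1)
    mlh_i <- rowSums(m == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(m)), 1)
    sm_i <- sm_all[rownames(sub)]
    arl <- ar_all$per_locus[[pp]]
    data.frame(population = pp, N = N,
               MLH = mean(mlh_i),
               AR = mean(arl, na.rm = TRUE), AR_sd = sd(arl, na.rm = TRUE),
               sMLH = mean(sm_i, na.rm = TRUE), sMLH_sd = sd(sm_i, na.rm = TRUE),
               FIS = 1 - sum(ho_l[keep]) / sum(he_l[keep]),
               He = mean(he_l[keep]), He_sd = sd(he_l[keep]),
               Ho = mean(ho_l[keep]), Ho_sd = sd(ho_l[keep]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standardized multilocus heterozygosity
#'
#' For each individual: the fraction of its typed loci that are heterozygous,
#' divided by the mean observed heterozygosity of those same loci across all
#' individuals typed there.  The population mean of sMLH is ~1 when
#' missingness is homogeneous.
#'
#' @param x a [genotype_matrix()].
#' @return named numeric vector, one value per individual (`NA` for an
#'   individual typed at no loci).
#' @export
smlh <- function(x) {
  if (nrow(x$calls) < 2) stop("sMLH needs at least 2 individuals")
  m <- x$calls
  m[m == MISSING] <- NA_integer_
  het <- m == 1L
  mean_het_l <- colMeans(het, na.rm = TRUE)
  typed <- !is.na(m)
  num <- rowSums(het, na.rm = TRUE)
  den <- typed %*% ifelse(is.na(mean_het_l), 0, mean_het_l)
  out <- as.vector(num / den)
  out[rowSums(typed) == 0] <- NA_real_
  setNames(out, rownames(m))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles per locus in a random subsample of `g`
#' gene copies: `AR = sum_i [1 - choose(N - N_i, g) / choose(N, g)]` over
#' alleles i, averaged across loci within each population.  For biallelic
#' data AR lies in `[1, 2]`.  Loci with fewer than `g` non-missing gene copies
#' in a population are skipped (counted in the result).
#'
#' @param x a [genotype_matrix()].
#' @param g standardized gene-copy count (default twice the smallest
#'   population sample size).
#' @return list with `table` (data.frame population, AR, AR_sd, n_loci_used,
#'   n_loci_skipped) and `per_locus` (named list of per-locus AR vectors).
#' @export
allelic_richness <- function(x, g = NULL) {
  if (is.null(g)) g <- 2L * min(table(x$population))
  g <- as.integer(g)
  pops <- unique(x$population)
  per_locus <- list()
  rows <- lapply(pops, function(pp) {
    sub <- x$calls[x$population == pp, , drop = FALSE]
    m <- sub
    m[m == MISSING] <- NA_integer_
    n_cop <- 2 * colSums(!is.na(m))
    alt <- colSums(m, na.rm = TRUE)
    refc <- n_cop - alt
    ok <- n_cop >= g & n_cop > 0
    ar <- rep(NA_real_, ncol(m))
    ar[ok] <- (1 - exp(lchoose(n_cop[ok] - refc[ok], g) -
                         lchoose(n_cop[ok], g))) +
      (1 - exp(lchoose(n_cop[ok] - alt[ok], g) - lchoose(n_cop[ok], g)))
    per_locus[[pp]] <<- setNames(ar, colnames(m))
    data.frame(population = pp, AR = mean(ar, na.rm = TRUE),
               AR_sd = sd(ar, na.rm = TRUE),
               n_loci_used = sum(ok), n_loci_skipped = sum(!ok),
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), per_locus = per_locus)
}

#' Pairwise Weir-Cockerham FST with permutation p-values
#'
#' Multilocus ratio-of-averages theta (Weir & Cockerham 1984) for every pair
#' of populations; the p-value is the fraction of label permutations (within
#' the pair) whose theta is at least the observed one.
#'
#' @param x a [genotype_matrix()].
#' @param n_permutations number of permutations (default 999; 0 skips tests).
#' @param seed integer seed for the permutations.
#' @return list with `fst` (symmetric matrix, zero diagonal) and `p_value`
#'   (matrix, `NA` on the diagonal).  Pairs with a single-individual
#'   population get `NA`.
#' @export
wc_fst_pairwise <- function(x, n_permutations = 999, seed = 1) {
  pops <- unique(x$population)
  k <- length(pops)
  if (k < 2) stop("need >= 2 populations")
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  set.seed(seed)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sel <- x$population %in% c(pops[i], pops[j])
      calls <- x$calls[sel, , drop = FALSE]
      pop <- x$population[sel]
      if (min(table(pop)) < 2) {
        fst[i, j] <- fst[j, i] <- NA_real_
        next
      }
      obs <- wc_theta_multilocus(calls, pop)
      fst[i, j] <- fst[j, i] <- obs
      if (n_permutations > 0 && is.finite(obs)) {
        ge <- 0L
        for (b in seq_len(n_permutations)) {
          th <- wc_theta_multilocus(calls, sample(pop))
          if (is.finite(th) && th >= obs) ge <- ge + 1L
        }
        pv[i, j] <- pv[j, i] <- (ge + 1) / (n_permutations + 1)
      }
    }
  }
  list(fst = fst, p_value = pv)
}

# AMOVA variance components from a squared-distance matrix (sequence mode)
amova_components <- function(d2, pop) {
  pops <- unique(pop)
  N <- length(pop)
  k <- length(pops)
  ss_total <- sum(d2[upper.tri(d2)], na.rm = TRUE) / N
  ss_within <- 0
  for (pp in pops) {
    idx <- which(pop == pp)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)], na.rm = TRUE) /
        length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- k - 1
  df_within <- N - k
  sigma_w <- ss_within / max(df_within, 1)
  n0 <- (N - sum(table(pop)^2) / N) / max(k - 1, 1)
  sigma_a <- (ss_among / max(df_among, 1) - sigma_w) / n0
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       ss_among = ss_among, ss_within = ss_within,
       df_among = df_among, df_within = df_within,
       phi = sigma_a / (sigma_a + sigma_w))
}

# three-level genotypic AMOVA components from allele counts (gametic sums of
# squares; missing calls handled per locus by using the available counts)
amova_genotype_components <- function(calls, pop) {
  m <- calls
  m[m == MISSING] <- NA_integer_
  N <- nrow(m)
  pops <- unique(pop)
  k <- length(pops)
  A <- colSums(m, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(m))
  ss_total <- sum(ifelse(n2 > 0, A * (n2 - A) / pmax(n2, 1), 0))
  ss_wp <- 0
  for (pp in pops) {
    sm <- m[pop == pp, , drop = FALSE]
    a <- colSums(sm, na.rm = TRUE)
    nn <- 2 * colSums(!is.na(sm))
    ss_wp <- ss_wp + sum(ifelse(nn > 0, a * (nn - a) / pmax(nn, 1), 0))
  }
  ss_wi <- sum(m == 1L, na.rm = TRUE) / 2
  df_a <- k - 1; df_b <- N - k; df_w <- N
  sigma_w <- ss_wi / df_w
  sigma_b <- ((ss_wp - ss_wi) / max(df_b, 1) - sigma_w) / 2
  sizes <- 2 * as.numeric(table(pop))
  c_a <- (sum(sizes) - sum(sizes^2) / sum(sizes)) / max(df_a, 1)
  sigma_a <- ((ss_total - ss_wp) / max(df_a, 1) - sigma_w - 2 * sigma_b) /
    c_a
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_w = sigma_w,
       ss = c(among = ss_total - ss_wp, among_individuals = ss_wp - ss_wi,
              within_individuals = ss_wi),
       df = c(among = df_a, among_individuals = df_b,
              within_individuals = df_w),
       phi = sigma_a / (sigma_a + sigma_b + sigma_w))
}

#' AMOVA on SNP genotypes
#'
#' Three-level analysis of molecular variance on squared allele-count
#' differences (among populations, among individuals within populations,
#' within individuals), computed from per-locus allele and heterozygote
#' counts with pairwise deletion of missing calls.  Including the
#' within-individual level puts the fixation index (among-population fraction
#' of total molecular variance) on the same gametic scale as Weir-Cockerham
#' theta.  The p-value permutes individuals among populations.
#'
#' @param x a [genotype_matrix()].
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return an `amova_result` list: `components` (named variance components),
#'   `ss`, `df`, `fst`, `p_value`, `n_permutations`.
#' @export
amova <- function(x, n_permutations = 999, seed = 1) {
  if (length(unique(x$population)) < 2)
    stop("AMOVA needs >= 2 populations")
  obs <- amova_genotype_components(x$calls, x$population)
  pv <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- amova_genotype_components(x$calls, sample(x$population))
      if (perm$phi >= obs$phi) ge <- ge + 1L
    }
    pv <- (ge + 1) / (n_permutations + 1)
  }
  structure(list(components = c(among = obs$sigma_a,
                                among_individuals = obs$sigma_b,
                                within_individuals = obs$sigma_w),
                 ss = obs$ss, df = obs$df, fst = obs$phi, index = "FST",
                 p_value = pv, n_permutations = n_permutations),
            class = "amova_result")
}

amova_from_dist <- function(d2, pop, n_permutations, seed, index = "FST") {
  obs <- amova_components(d2, pop)
  pv <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- amova_components(d2, sample(pop))
      if (perm$phi >= obs$phi) ge <- ge + 1L
    }
    pv <- (ge + 1) / (n_permutations + 1)
  }
  structure(list(components = c(among = obs$sigma_a, within = obs$sigma_w),
                 ss = c(among = obs$ss_among, within = obs$ss_within),
                 df = c(among = obs$df_among, within = obs$df_within),
                 fst = obs$phi, index = index, p_value = pv,
                 n_permutations = n_permutations),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA:", x$index, "=", format(x$fst, digits = 4),
      if (!is.na(x$p_value)) paste0("(p = ", format(x$p_value, digits = 3),
                                    ", ", x$n_permutations, " permutations)"),
      "\n")
  cat("variance components:",
      paste(names(x$components), format(x$components, digits = 4),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' PhiST from a haplotype alignment
#'
#' Sequence-mode AMOVA: pairwise nucleotide differences (positions where both
#' sequences have an unambiguous character) are used as squared distances,
#' and PhiST is the among-population fraction of the total molecular variance.
#'
#' @param alignment a [haplotype_alignment()].
#' @param n_permutations number of individual-label permutations.
#' @param seed integer seed.
#' @return an `amova_result` (index "PhiST").  All-identical sequences give an
#'   error (zero total variance).
#' @export
phi_st <- function(alignment, n_permutations = 999, seed = 1) {
  if (length(unique(alignment$population)) < 2)
    stop("PhiST needs >= 2 populations")
  seqs <- strsplit(alignment$sequences, "")
  n <- length(seqs)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- seqs[[i]]; b <- seqs[[j]]
      ok <- a != "N" & b != "N"
      d2[i, j] <- d2[j, i] <- sum(a[ok] != b[ok])
    }
  }
  if (all(d2 == 0))
    stop("PhiST undefined: all sequences identical (zero total variance)")
  amova_from_dist(d2, alignment$population, n_permutations, seed,
                  index = "PhiST")
}
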