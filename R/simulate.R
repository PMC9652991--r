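# Synthetic-data generators: every input the pipeline needs is produced in
# code — coalescent genotypes under the demographic model family, hybrid
# swarms with known categories, island-model neutral loci, mtDNA-like
# haplotype alignments, and pre-QC fixtures with planted filter violations
# and an independently computed ground-truth attrition report.

#' Simulate genotypes under a two-population demographic model
#'
#' Draws unlinked biallelic loci from structured-coalescent gene trees under
#' the model's epoch structure, placing one mutation per locus proportionally
#' to branch length (infinite-sites thinning), so every locus segregates in
#' the combined sample.  Deterministic given `seed`.
#'
#' @param spec a [model_spec()].
#' @param params named vector/list of the model's free parameters.
#' @param n_per_pop diploid individuals sampled per population (length-2
#'   vector or scalar).
#' @param n_loci number of loci.
#' @param seed integer seed.
#' @param pop_names labels for the two populations (default `pop1`, `pop2`).
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(spec, params, n_per_pop, n_loci, seed = 1,
                               pop_names = c("pop1", "pop2")) {
  n_per_pop <- rep_len(as.integer(n_per_pop), 2)
  eps <- model_epochs(spec, params)
  tip_deme <- rep(1:2, times = 2 * n_per_pop)
  al <- .coal_sim_loci_cpp(as.integer(tip_deme), eps, as.integer(n_loci),
                           seed)
  odd <- seq(1, nrow(al), 2)
  calls <- al[odd, , drop = FALSE] + al[odd + 1, , drop = FALSE]
  pops <- rep(pop_names, times = n_per_pop)
  ids <- paste0(pops, "_", unlist(lapply(n_per_pop, seq_len)))
  dimnames(calls) <- list(ids, paste0("locus", seq_len(n_loci)))
  genotype_matrix(calls, setNames(pops, ids))
}

#' Simulate genotypes under a symmetric finite island model
#'
#' All demes have relative size 1 and each deme receives total scaled
#' migration `migration` (2*N*m) split equally among the other demes.
#'
#' @param n_demes number of demes.
#' @param migration total scaled immigration rate per deme.
#' @param n_per_deme diploids sampled per deme.
#' @param n_loci number of loci.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with populations `deme1..demeK`.
#' @export
simulate_island_genotypes <- function(n_demes, migration, n_per_deme, n_loci,
                                      seed = 1) {
  M <- matrix(migration / (n_demes - 1), n_demes, n_demes)
  diag(M) <- 0
  eps <- island_epochs(rep(1, n_demes), M)
  tip_deme <- rep(seq_len(n_demes), each = 2 * n_per_deme)
  al <- .coal_sim_loci_cpp(as.integer(tip_deme), eps, as.integer(n_loci),
                           seed)
  odd <- seq(1, nrow(al), 2)
  calls <- al[odd, , drop = FALSE] + al[odd + 1, , drop = FALSE]
  pops <- rep(paste0("deme", seq_len(n_demes)), each = n_per_deme)
  ids <- paste0(pops, "_", rep(seq_len(n_per_deme), n_demes))
  dimnames(calls) <- list(ids, paste0("locus", seq_len(n_loci)))
  genotype_matrix(calls, setNames(pops, ids))
}

#' Configuration for a hybrid swarm
#'
#' @param counts named integer vector of individuals per category; names from
#'   `P0`, `P1`, `F1`, `F2`, `BC0`, `BC1`.
#' @param n_loci number of loci.
#' @param fixed_difference fraction of loci fixed for alternate alleles
#'   between the parental pools (the remainder share a common frequency).
#' @param target_fst alternatively, a Balding-Nichols divergence target for
#'   all loci (used when `fixed_difference` is `NULL`).
#' @param seed integer seed.
#' @return a `swarm_config` list.
#' @export
swarm_config <- function(counts, n_loci, fixed_difference = NULL,
                         target_fst = NULL, seed = 1) {
  if (is.null(fixed_difference) && is.null(target_fst))
    stop("give fixed_difference or target_fst")
  bad <- setdiff(names(counts), hybrid_categories()$name)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  if (any(counts < 0) || n_loci < 1) stop("counts >= 0 and n_loci >= 1")
  structure(list(counts = counts, n_loci = as.integer(n_loci),
                 fixed_difference = fixed_difference,
                 target_fst = target_fst, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Simulate a hybrid swarm with known categories
#'
#' Parental allele frequencies are drawn to hit the configured divergence;
#' pure parentals are Hardy-Weinberg draws from their pool, F1 individuals
#' take one allele from each pool per locus, F2 individuals two independent
#' F1-gamete draws, and backcrosses one F1 gamete plus one parental gamete.
#'
#' @param config a [swarm_config()].
#' @return a [genotype_matrix()] whose population labels are the true
#'   categories, with the parental allele frequencies in attribute
#'   `"parental_freqs"`.
#' @export
simulate_hybrid_swarm <- function(config) {
  set.seed(config$seed)
  L <- config$n_loci
  if (!is.null(config$fixed_difference)) {
    nfix <- round(config$fixed_difference * L)
    pA <- pB <- runif(L, 0.15, 0.85)
    if (nfix > 0) {
      pA[seq_len(nfix)] <- 0
      pB[seq_len(nfix)] <- 1
    }
  } else {
    f <- config$target_fst
    if (f <= 0) {
      warning("zero parental divergence: hybrid categories unidentifiable")
      f <- 1e-6
    }
    pbar <- runif(L, 0.15, 0.85)
    a <- pbar * (1 - f) / f
    b <- (1 - pbar) * (1 - f) / f
    pA <- rbeta(L, a, b)
    pB <- rbeta(L, a, b)
  }
  gam <- function(p) rbinom(L, 1, p)          # one gamete from a pool
  f1gam <- function() {                       # one gamete from the F1 pool
    from_a <- runif(L) < 0.5
    ifelse(from_a, gam(pA), gam(pB))
  }
  draw <- function(cat) {
    switch(cat,
           P0 = gam(pA) + gam(pA),
           P1 = gam(pB) + gam(pB),
           F1 = gam(pA) + gam(pB),
           F2 = f1gam() + f1gam(),
           BC0 = f1gam() + gam(pA),
           BC1 = f1gam() + gam(pB))
  }
  cats <- rep(names(config$counts), times = config$counts)
  calls <- t(vapply(cats, draw, integer(L)))
  ids <- paste0(cats, "_", unlist(lapply(config$counts, seq_len)))
  dimnames(calls) <- list(ids, paste0("locus", seq_len(L)))
  out <- genotype_matrix(calls, setNames(cats, ids))
  attr(out, "parental_freqs") <- cbind(pA = pA, pB = pB)
  out
}

#' Simulate an mtDNA-like two-clade haplotype alignment
#'
#' Two clade ancestors diverge from a random root by a Poisson number of
#' substitutions (expectation `divergence`, split equally between the two
#' stems); each haplotype then accumulates `within_divergence` expected
#' substitutions from its clade ancestor under a symmetric single-parameter
#' substitution model.
#'
#' @param divergence expected substitutions separating the clade ancestors.
#' @param n_per_pop haplotypes per clade.
#' @param seq_length alignment length in bp.
#' @param seed integer seed.
#' @param within_divergence expected substitutions from clade ancestor to
#'   each tip (default 1).
#' @return a [haplotype_alignment()] with populations `clade1`, `clade2`.
#' @export
simulate_mtdna <- function(divergence, n_per_pop, seq_length, seed = 1,
                           within_divergence = 1) {
  if (divergence < 0) stop("divergence must be >= 0")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mutate <- function(s, expected) {
    k <- rpois(1, expected)
    if (k > 0) {
      pos <- sample.int(length(s), min(k, length(s)))
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    }
    s
  }
  root <- sample(bases, seq_length, replace = TRUE)
  anc1 <- mutate(root, divergence / 2)
  anc2 <- mutate(root, divergence / 2)
  seqs <- character(2 * n_per_pop)
  for (i in seq_len(n_per_pop)) {
    seqs[i] <- paste(mutate(anc1, within_divergence), collapse = "")
    seqs[n_per_pop + i] <- paste(mutate(anc2, within_divergence),
                                 collapse = "")
  }
  pops <- rep(c("clade1", "clade2"), each = n_per_pop)
  names(seqs) <- paste0(pops, "_", rep(seq_len(n_per_pop), 2))
  haplotype_alignment(seqs, setNames(pops, names(seqs)))
}

#' @importFrom stats rpois
NULL

# ---- QC fixture ------------------------------------------------------------

# independent brute-force HWE exact p (naive factorial enumeration)
bf_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n2 + n1
  nm <- min(na, 2 * n - na)
  if (nm == 0) return(1)
  hs <- seq(nm %% 2, nm, by = 2)
  pr <- vapply(hs, function(h) {
    factorial(n) / (factorial((nm - h) / 2) * factorial(h) *
                      factorial(n - (nm + h) / 2)) * 2^h
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[hs == n1]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' Pre-QC fixture with planted filter violations
#'
#' Builds a clean Hardy-Weinberg base matrix (two populations sharing allele
#' frequencies) and plants one violation set per QC rule: monomorphic loci,
#' low-call-rate loci and individuals, low-depth and low-repeatability loci,
#' duplicate-tag SNPs, a near-duplicate tag-sequence pair, heterozygote-free
#' HWE violators, perfectly correlated locus copies, a locus whose
#' missingness crosses 10% only after the low-call individuals are removed,
#' and sub-2%-MAF loci.  The expected per-step attrition is recomputed from
#' the finished matrix by an independent brute-force pass over each rule.
#'
#' @param seed integer seed.
#' @param n_clean number of clean base loci (default 60).
#' @return list with `matrix`, `metadata`, `expected_loci` (ids expected to
#'   survive [apply_filters()]), `expected_individuals`, and
#'   `expected_report` (step/removal data.frame).
#' @export
make_qc_fixture <- function(seed = 1, n_clean = 60) {
  set.seed(seed)
  n_ind <- 40L
  pops <- rep(c("A", "B"), each = 20)
  ids <- paste0(pops, sprintf("%02d", rep(1:20, 2)))

  rand_tag <- function() paste(sample(c("A", "C", "G", "T"), 20,
                                      replace = TRUE), collapse = "")
  hw_locus <- function() {
    p <- runif(1, 0.25, 0.75)
    rbinom(n_ind, 2, p)
  }

  cols <- list(); meta <- list()
  add <- function(id, g, depth = 20, rep_avg = 0.99, tag = NULL,
                  pos = 10L, seq = NULL) {
    cols[[id]] <<- as.integer(g)
    meta[[id]] <<- data.frame(locus_id = id, mean_depth = depth,
                              repeatability = rep_avg,
                              tag_id = if (is.null(tag)) paste0("tag_", id)
                                       else tag,
                              position_in_tag = pos,
                              tag_sequence = if (is.null(seq)) rand_tag()
                                             else seq,
                              stringsAsFactors = FALSE)
  }

  # clean base loci
  for (i in seq_len(n_clean)) add(sprintf("clean%02d", i), hw_locus())

  # low-call-rate individuals: A01 missing at clean01-20, A02 at clean21-40
  lowcall_ind <- c("A01", "A02")

  # monomorphic loci
  for (i in 1:3) add(sprintf("mono%d", i), rep(0L, n_ind))

  # low locus call rate: 5 of 40 missing (in individuals kept throughout)
  for (i in 1:3) {
    g <- hw_locus(); g[6:10] <- MISSING
    add(sprintf("lowcr%d", i), g)
  }

  # low depth / low repeatability
  for (i in 1:3) add(sprintf("lowdepth%d", i), hw_locus(), depth = 3)
  for (i in 1:3) add(sprintf("lowrep%d", i), hw_locus(), rep_avg = 0.90)

  # duplicate-tag SNPs: second SNP of the tag has one missing call
  for (i in 1:2) {
    tg <- paste0("dup_tag", i)
    add(sprintf("tagdup%da", i), hw_locus(), tag = tg, pos = 5L)
    g <- hw_locus(); g[12] <- MISSING
    add(sprintf("tagdup%db", i), g, tag = tg, pos = 15L)
  }

  # near-duplicate tag sequences (2/20 mismatches); the 'b' member has a
  # missing call, hence the lower call rate, and is dropped
  base_tag <- rand_tag()
  near_tag <- base_tag
  substr(near_tag, 1, 1) <- "A"; substr(near_tag, 2, 2) <- "C"
  if (near_tag == base_tag) substr(near_tag, 3, 3) <-
      if (substr(base_tag, 3, 3) == "G") "T" else "G"
  add("ham_a", hw_locus(), seq = base_tag)
  g <- hw_locus(); g[13] <- MISSING
  add("ham_b", g, seq = near_tag)

  # HWE violators: heterozygote-free 50/50 split within each population
  for (i in 1:2) {
    g <- integer(n_ind)
    g[pops == "A"] <- rep(c(0L, 2L), 10)[sample.int(20)]
    g[pops == "B"] <- rep(c(0L, 2L), 10)[sample.int(20)]
    add(sprintf("hwe%d", i), g)
  }

  # LD: exact copies of two clean loci, placed adjacent to their sources
  add("ldcopy1", cols[["clean45"]])
  add("ldcopy2", cols[["clean46"]])

  # missingness > 10% only after individual removal: 4/40 now, 4/38 later
  g <- hw_locus(); g[30:33] <- MISSING
  add("latemiss", g)

  # sub-2% MAF: one heterozygote among 40 individuals (1/80 copies)
  for (i in 1:2) {
    g <- rep(0L, n_ind); g[20 + i] <- 1L
    add(sprintf("lowmaf%d", i), g)
  }

  calls <- do.call(cbind, cols)
  rownames(calls) <- ids
  # order: keep insertion order but move the LD copies next to their sources
  ord <- colnames(calls)
  ord <- ord[ord != "ldcopy1" & ord != "ldcopy2"]
  ord <- append(ord, "ldcopy1", after = which(ord == "clean45"))
  ord <- append(ord, "ldcopy2", after = which(ord == "clean46"))
  calls <- calls[, ord]

  # plant the low-call individuals (clean loci only)
  calls["A01", sprintf("clean%02d", 1:20)] <- MISSING
  calls["A02", sprintf("clean%02d", 21:40)] <- MISSING

  metadata <- do.call(rbind, meta)
  metadata <- metadata[match(colnames(calls), metadata$locus_id), ]
  metadata <- locus_metadata(metadata$locus_id,
                             call_rate = colMeans(calls != MISSING),
                             repeatability = metadata$repeatability,
                             mean_depth = metadata$mean_depth,
                             tag_id = metadata$tag_id,
                             position_in_tag = metadata$position_in_tag,
                             tag_sequence = metadata$tag_sequence)
  x <- genotype_matrix(calls, setNames(pops, ids))

  gt <- qc_ground_truth(calls, metadata, pops)
  list(matrix = x, metadata = metadata,
       expected_loci = gt$loci, expected_individuals = gt$individuals,
       expected_report = gt$report)
}

# Independent sequential brute-force over every QC rule, mirroring the
# documented filter order with naive per-rule code.
qc_ground_truth <- function(calls, metadata, pops,
                            cfg = list(locus_cr = 0.90, ind_cr = 0.80,
                                       depth = 5, rep = 0.95, ham = 0.25,
                                       hwe = 1e-5, r2 = 0.80, miss = 0.10,
                                       maf = 0.02, win = 50L, step = 5L)) {
  loci <- colnames(calls); inds <- rownames(calls)
  report <- list()
  note <- function(step) {
    report[[length(report) + 1]] <<- data.frame(
      step = step, loci_remaining = length(loci),
      individuals_remaining = length(inds), stringsAsFactors = FALSE)
  }
  sub <- function() calls[inds, loci, drop = FALSE]
  cr_of <- function(v) mean(v != MISSING)
  freq_of <- function(v) {
    v <- v[v != MISSING]
    if (!length(v)) return(NA_real_)
    sum(v) / (2 * length(v))
  }

  # 1 monomorphic
  keep <- vapply(loci, function(l) {
    f <- freq_of(sub()[, l]); !is.na(f) && f > 0 && f < 1
  }, TRUE)
  loci <- loci[keep]; note("monomorphic")
  # 2 locus call rate
  loci <- loci[vapply(loci, function(l) cr_of(sub()[, l]) >= cfg$locus_cr,
                      TRUE)]
  note("locus_call_rate")
  # 3 individual call rate
  inds <- inds[vapply(inds, function(i) cr_of(sub()[i, ]) >= cfg$ind_cr,
                      TRUE)]
  note("indiv_call_rate")
  # 4 depth, 5 repeatability
  md <- function(l, col) metadata[metadata$locus_id == l, col]
  loci <- loci[vapply(loci, function(l) md(l, "mean_depth") >= cfg$depth,
                      TRUE)]
  note("min_depth")
  loci <- loci[vapply(loci, function(l)
    md(l, "repeatability") >= cfg$rep, TRUE)]
  note("repeatability")
  # 6 one SNP per tag (highest realized call rate; ties by position, order)
  tags <- vapply(loci, function(l) md(l, "tag_id"), "")
  keep <- rep(FALSE, length(loci))
  for (tg in unique(tags)) {
    rows <- which(tags == tg)
    crv <- vapply(rows, function(r) cr_of(sub()[, loci[r]]), 0)
    posv <- vapply(rows, function(r) md(loci[r], "position_in_tag"), 0L)
    keep[rows[order(-crv, posv, rows)][1]] <- TRUE
  }
  loci <- loci[keep]; note("one_snp_per_tag")
  # 7 hamming: all-pairs check, most-similar first
  seqs <- vapply(loci, function(l) md(l, "tag_sequence"), "")
  removed <- rep(FALSE, length(loci))
  pairs <- NULL
  for (i in seq_along(loci)) for (j in seq_along(loci)) {
    if (i >= j || is.na(seqs[i]) || is.na(seqs[j])) next
    if (nchar(seqs[i]) != nchar(seqs[j])) next
    dd <- mean(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]])
    if (dd <= cfg$ham) pairs <- rbind(pairs, c(i, j, dd))
  }
  if (!is.null(pairs)) for (k in order(pairs[, 3])) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (removed[i] || removed[j]) next
    cri <- cr_of(sub()[, loci[i]]); crj <- cr_of(sub()[, loci[j]])
    removed[if (cri < crj) i else if (crj < cri) j else max(i, j)] <- TRUE
  }
  loci <- loci[!removed]; note("hamming")
  # 8 HWE within any population
  keep <- vapply(loci, function(l) {
    for (pp in unique(pops)) {
      v <- sub()[pops[match(inds, rownames(calls))] == pp, l]
      v <- v[v != MISSING]
      if (!length(v)) next
      if (bf_hwe_p(sum(v == 0), sum(v == 1), sum(v == 2)) < cfg$hwe)
        return(FALSE)
    }
    TRUE
  }, TRUE)
  loci <- loci[keep]; note("hwe")
  # 9 LD pruning (windowed, worst pair first, lower call rate removed)
  removed <- rep(FALSE, length(loci))
  starts <- seq(1L, max(1L, length(loci) - 1L), by = cfg$step)
  for (s in starts) {
    win <- s:min(length(loci), s + cfg$win - 1L)
    repeat {
      act <- win[!removed[win]]
      if (length(act) < 2) break
      worst <- NULL; wr2 <- cfg$r2
      for (ii in seq_len(length(act) - 1)) for (jj in (ii + 1):length(act)) {
        a <- sub()[, loci[act[ii]]]; b <- sub()[, loci[act[jj]]]
        ok <- a != MISSING & b != MISSING
        if (sum(ok) < 2 || var(a[ok]) == 0 || var(b[ok]) == 0) next
        r2 <- cor(a[ok], b[ok])^2
        if (r2 > wr2) { wr2 <- r2; worst <- c(act[ii], act[jj]) }
      }
      if (is.null(worst)) break
      cra <- cr_of(sub()[, loci[worst[1]]])
      crb <- cr_of(sub()[, loci[worst[2]]])
      removed[if (cra < crb) worst[1] else if (crb < cra) worst[2] else
        max(worst)] <- TRUE
    }
  }
  loci <- loci[!removed]; note("ld_prune")
  # 10 missingness
  loci <- loci[vapply(loci, function(l)
    mean(sub()[, l] == MISSING) <= cfg$miss, TRUE)]
  note("locus_missingness")
  # 11 MAF
  loci <- loci[vapply(loci, function(l) {
    f <- freq_of(sub()[, l]); min(f, 1 - f) >= cfg$maf
  }, TRUE)]
  note("maf")

  list(loci = loci, individuals = inds, report = do.call(rbind, report))
}
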