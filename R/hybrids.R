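# NewHybrids-style Bayesian classification of individuals into the six
# two-generation hybrid categories.  Each category is defined by its expected
# proportions of locus-wise ancestry pairs (both alleles from parental pool 0,
# one from each, both from pool 1); a Gibbs sampler alternates between
# category assignments, latent per-locus ancestry configurations, and the two
# parental allele-frequency vectors under Jeffreys Beta(1/2, 1/2) priors.

#' The six hybrid categories and their ancestry-pair proportions
#'
#' `g00`, `g01`, `g11` give the expected fractions of loci at which an
#' individual of the category carries two pool-0 alleles, one allele from
#' each pool, or two pool-1 alleles.  Rows sum to one.
#'
#' @return data.frame with columns `name`, `g00`, `g01`, `g11` for categories
#'   P0, P1, F1, F2, BC0 (F1 x P0) and BC1 (F1 x P1).
#' @export
hybrid_categories <- function() {
  data.frame(name = c("P0", "P1", "F1", "F2", "BC0", "BC1"),
             g00 = c(1, 0, 0, 0.25, 0.5, 0),
             g01 = c(0, 0, 1, 0.50, 0.5, 0.5),
             g11 = c(0, 1, 0, 0.25, 0, 0.5),
             stringsAsFactors = FALSE)
}

# genotype probabilities given ancestry pair, as L x 3 matrices
ancestry_genotype_probs <- function(p0, p1) {
  list(a00 = cbind((1 - p0)^2, 2 * p0 * (1 - p0), p0^2),
       a01 = cbind((1 - p0) * (1 - p1),
                   p0 * (1 - p1) + p1 * (1 - p0),
                   p0 * p1),
       a11 = cbind((1 - p1)^2, 2 * p1 * (1 - p1), p1^2))
}

run_hybrid_chain <- function(G, gtab, z_known, p0_init, p1_init, sweeps,
                             burnin, thin, seed) {
  set.seed(seed)
  n <- nrow(G); L <- ncol(G)
  ncat <- nrow(gtab)
  idx <- G + 1L
  typed <- !is.na(G)
  lcol <- col(G)
  p0 <- p0_init; p1 <- p1_init
  post <- matrix(0, n, ncat)
  n_rec <- 0L
  z <- rep(4L, n)  # start everyone as F2 (uninformative middle)
  z[!is.na(z_known)] <- z_known[!is.na(z_known)]
  lookup <- function(P, a) {
    m <- matrix(NA_real_, n, L)
    m[typed] <- P[[a]][cbind(lcol[typed], idx[typed])]
    m
  }
  for (s in seq_len(sweeps)) {
    P <- ancestry_genotype_probs(p0, p1)
    M00 <- lookup(P, "a00"); M01 <- lookup(P, "a01"); M11 <- lookup(P, "a11")
    # category log-likelihoods
    ll <- matrix(0, n, ncat)
    for (cc in seq_len(ncat)) {
      mix <- gtab$g00[cc] * M00 + gtab$g01[cc] * M01 + gtab$g11[cc] * M11
      ll[, cc] <- rowSums(log(mix), na.rm = TRUE)
    }
    pr <- exp(ll - apply(ll, 1, max))
    pr <- pr / rowSums(pr)
    # sample categories (fixed for known individuals)
    u <- runif(n)
    cum <- t(apply(pr, 1, cumsum))
    z_new <- max.col(cum >= u, ties.method = "first")
    z <- ifelse(is.na(z_known), z_new, z_known)
    # sample ancestry configuration per (individual, locus)
    w00 <- gtab$g00[z] * M00
    w01 <- gtab$g01[z] * M01
    w11 <- gtab$g11[z] * M11
    wt <- w00 + w01 + w11
    u2 <- matrix(runif(n * L), n, L) * wt
    a01 <- u2 >= w00 & u2 < w00 + w01
    a11 <- u2 >= w00 + w01
    a00 <- !(a01 | a11) & typed
    a01 <- a01 & typed; a11 <- a11 & typed
    # allele-origin counts per locus
    Gm <- G; Gm[!typed] <- 0L
    alt0 <- colSums(a00 * Gm) ; ref0 <- colSums(a00 * (2L - Gm))
    alt1 <- colSums(a11 * Gm) ; ref1 <- colSums(a11 * (2L - Gm))
    # mixed-ancestry loci: one allele from each pool
    hom0 <- a01 & Gm == 0L  # both pools contribute a reference allele
    hom2 <- a01 & Gm == 2L
    het <- a01 & Gm == 1L
    ref0 <- ref0 + colSums(hom0); ref1 <- ref1 + colSums(hom0)
    alt0 <- alt0 + colSums(hom2); alt1 <- alt1 + colSums(hom2)
    if (any(het)) {
      # the single alternate allele came from pool 0 w.p. p0(1-p1)/norm
      pr_alt0 <- (p0 * (1 - p1)) / (p0 * (1 - p1) + p1 * (1 - p0))
      pick <- matrix(runif(n * L), n, L) <
        matrix(pr_alt0, n, L, byrow = TRUE)
      alt0 <- alt0 + colSums(het & pick)
      ref1 <- ref1 + colSums(het & pick)
      alt1 <- alt1 + colSums(het & !pick)
      ref0 <- ref0 + colSums(het & !pick)
    }
    p0 <- rbeta(L, 0.5 + alt0, 0.5 + ref0)
    p1 <- rbeta(L, 0.5 + alt1, 0.5 + ref1)
    p0 <- pmin(1 - 1e-9, pmax(1e-9, p0))
    p1 <- pmin(1 - 1e-9, pmax(1e-9, p1))
    if (s > burnin && (s - burnin) %% thin == 0) {
      post <- post + pr
      n_rec <- n_rec + 1L
    }
  }
  post / n_rec
}

#' Classify individuals into hybrid categories
#'
#' Gibbs sampler over per-individual category assignments (P0, P1, F1, F2 and
#' the two backcrosses), latent locus-wise ancestry configurations, and the
#' two parental allele-frequency vectors with Jeffreys Beta(1/2, 1/2) priors.
#' Genotype likelihoods for each category mix the parental Hardy-Weinberg
#' genotype laws according to the category's ancestry-pair proportions
#' ([hybrid_categories()]).  The matrix is typically restricted to the most
#' differentiated loci between the parental populations first
#' ([top_fst_loci()]).
#'
#' @param x a [genotype_matrix()] (usually restricted to selected loci).
#' @param parental character vector of the two parental population labels;
#'   the first is category P0.
#' @param sweeps Gibbs sweeps per chain (default 20000).
#' @param burnin discarded sweeps (default 5000).
#' @param thin recording interval (default 10).
#' @param n_chains independent chains (default 3).
#' @param seed integer seed.
#' @param known optional character vector, named by individual id, fixing
#'   individuals to `"P0"` or `"P1"` (the NewHybrids "z option"); default
#'   none.
#' @return a `hybrid_posterior` list: `posterior` (individuals x 6, rows sum
#'   to 1, averaged over chains), `modal` (named character), `diagnostics`
#'   (per-individual max SD across chains plus a `mixing_flag` when any
#'   exceeds 0.1), and the run settings.
#' @export
hybrid_classify <- function(x, parental, sweeps = 20000, burnin = 5000,
                            thin = 10, n_chains = 3, seed = 1, known = NULL) {
  stopifnot(length(parental) == 2)
  if (!all(parental %in% x$population))
    stop("both parental populations must be present")
  if (sweeps <= burnin)
    stop("sweeps must exceed burnin")
  if (ncol(x$calls) < 50)
    warning("fewer than 50 loci; hybrid categories may be poorly resolved")
  gtab <- hybrid_categories()
  G <- calls_na(x)
  z_known <- rep(NA_integer_, nrow(G))
  names(z_known) <- rownames(G)
  if (!is.null(known)) {
    bad <- setdiff(names(known), rownames(G))
    if (length(bad)) stop("unknown individual in 'known': ",
                          paste(bad, collapse = ", "))
    z_known[names(known)] <- match(known, gtab$name)
  }
  # anchor the labels: initial frequencies from the parental samples
  init_freq <- function(pop) {
    sub <- G[x$population == pop, , drop = FALSE]
    p <- colMeans(sub, na.rm = TRUE) / 2
    p[is.na(p)] <- 0.5
    pmin(0.99, pmax(0.01, p))
  }
  p0i <- init_freq(parental[1])
  p1i <- init_freq(parental[2])
  chains <- lapply(seq_len(n_chains), function(ch)
    run_hybrid_chain(G, gtab, z_known, p0i, p1i, sweeps, burnin, thin,
                     seed + 104729 * (ch - 1)))
  post <- Reduce(`+`, chains) / n_chains
  rownames(post) <- rownames(G)
  colnames(post) <- gtab$name
  chain_sd <- if (n_chains > 1) {
    arr <- simplify2array(chains)
    apply(apply(arr, c(1, 2), sd), 1, max)
  } else rep(0, nrow(G))
  names(chain_sd) <- rownames(G)
  structure(list(posterior = post,
                 modal = setNames(gtab$name[max.col(post)], rownames(G)),
                 diagnostics = list(chain_sd = chain_sd,
                                    mixing_flag = any(chain_sd > 0.1),
                                    sweeps = sweeps, burnin = burnin,
                                    thin = thin, n_chains = n_chains,
                                    seed = seed),
                 categories = gtab),
            class = "hybrid_posterior")
}

#' @export
print.hybrid_posterior <- function(x, ...) {
  cat("hybrid_posterior:", nrow(x$posterior), "individuals,",
      x$diagnostics$n_chains, "chains x", x$diagnostics$sweeps, "sweeps\n")
  if (x$diagnostics$mixing_flag)
    cat("WARNING: between-chain posterior SD > 0.1 for some individuals\n")
  tab <- table(x$modal)
  cat("modal categories:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
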