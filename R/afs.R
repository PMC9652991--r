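# Joint allele frequency spectrum machinery: construction from genotype
# matrices with hypergeometric projection, minor-allele folding, and the
# Poisson composite likelihood with its analytically profiled scale (theta).

#' Construct a joint allele frequency spectrum
#'
#' @param entries (n1+1) x (n2+1) matrix of non-negative counts/expectations,
#'   entry `[i+1, j+1]` holding the mass of variants with i derived (or
#'   minor) copies in population 1 and j in population 2.
#' @param folded logical: is the spectrum folded onto minor-allele
#'   orientation?
#' @param mask logical matrix of the same shape; `TRUE` cells are excluded
#'   from sums and likelihoods.  The fixed corners `(0,0)` and `(n1,n2)` are
#'   always masked.
#' @return a `joint_afs` object.
#' @export
joint_afs <- function(entries, folded = FALSE, mask = NULL) {
  entries <- as.matrix(entries)
  if (any(entries < 0)) stop("AFS entries must be non-negative")
  n1 <- nrow(entries) - 1L; n2 <- ncol(entries) - 1L
  if (is.null(mask)) mask <- matrix(FALSE, n1 + 1, n2 + 1)
  mask[1, 1] <- TRUE
  mask[n1 + 1, n2 + 1] <- TRUE
  structure(list(entries = entries, n1 = n1, n2 = n2, folded = folded,
                 mask = mask),
            class = "joint_afs")
}

#' @export
print.joint_afs <- function(x, ...) {
  cat("joint_afs: sample sizes (", x$n1, ",", x$n2, ") gene copies,",
      if (x$folded) "folded," else "unfolded,",
      "total unmasked mass", format(afs_total(x), digits = 6), "\n")
  invisible(x)
}

#' Total unmasked mass of a spectrum
#' @param x a [joint_afs()].
#' @return numeric scalar.
#' @export
afs_total <- function(x) sum(x$entries[!x$mask])

#' Fold a joint spectrum onto minor-allele orientation
#'
#' Cells `(i, j)` and `(n1-i, n2-j)` are combined onto the cell with the
#' smaller total allele count (ties keep the cell with smaller i; a
#' self-symmetric cell keeps its own mass); the mirrored cell is masked.
#' Folding conserves the total unmasked mass.
#'
#' @param x an unfolded [joint_afs()].
#' @return a folded `joint_afs`.
#' @export
fold_afs <- function(x) {
  if (x$folded) return(x)
  n1 <- x$n1; n2 <- x$n2
  e <- x$entries
  v <- attr(x, "mc_var")
  out <- matrix(0, n1 + 1, n2 + 1)
  vout <- if (!is.null(v)) matrix(0, n1 + 1, n2 + 1) else NULL
  mask <- matrix(FALSE, n1 + 1, n2 + 1)
  half <- (n1 + n2) / 2
  for (i in 0:n1) for (j in 0:n2) {
    mi <- n1 - i; mj <- n2 - j
    tot <- i + j
    keep <- tot < half || (tot == half && (i < mi || (i == mi && j <= mj)))
    if (i == mi && j == mj) {
      out[i + 1, j + 1] <- e[i + 1, j + 1]
      if (!is.null(v)) vout[i + 1, j + 1] <- v[i + 1, j + 1]
    } else if (keep) {
      out[i + 1, j + 1] <- e[i + 1, j + 1] + e[mi + 1, mj + 1]
      if (!is.null(v))
        vout[i + 1, j + 1] <- v[i + 1, j + 1] + v[mi + 1, mj + 1]
    } else {
      mask[i + 1, j + 1] <- TRUE
    }
  }
  mask <- mask | x$mask  # carry input mask through
  res <- joint_afs(out, folded = TRUE, mask = mask)
  if (!is.null(vout)) attr(res, "mc_var") <- vout
  res
}

#' Project a spectrum down to smaller sample sizes
#'
#' Hypergeometric down-sampling: every cell's mass is redistributed according
#' to the expected composition of a random subsample of `(m1, m2)` gene
#' copies.  The projection preserves total mass (including the mass that
#' becomes monomorphic and lands in the masked corners).
#'
#' @param x an unfolded [joint_afs()].
#' @param m1,m2 target gene-copy counts (`m1 <= n1`, `m2 <= n2`).
#' @return an unfolded `joint_afs` of shape `(m1+1) x (m2+1)`.
#' @export
project_afs <- function(x, m1, m2) {
  if (x$folded) stop("project unfolded spectra, then fold")
  if (m1 > x$n1 || m2 > x$n2) stop("projection sizes exceed sample sizes")
  W1 <- outer(0:x$n1, 0:m1,
              function(i, a) dhyper(a, i, x$n1 - i, m1))
  W2 <- outer(0:x$n2, 0:m2,
              function(j, b) dhyper(b, j, x$n2 - j, m2))
  out <- t(W1) %*% x$entries %*% W2
  joint_afs(out, folded = FALSE)
}

#' Folded joint AFS from a genotype matrix
#'
#' Builds the two-population spectrum at a fixed projection: each locus
#' contributes its hypergeometric-expected projected entry mass computed from
#' the non-missing allele counts in the two populations, absorbing missing
#' data.  Loci with fewer available gene copies than the projection in either
#' population are dropped (counted in the `"n_dropped"` attribute).  The
#' spectrum is folded and corner-masked.
#'
#' @param x a [genotype_matrix()].
#' @param popA,popB population labels (popA indexes the rows).
#' @param projection integer vector `c(n1, n2)` of gene copies.
#' @return a folded [joint_afs()] with attribute `n_dropped`.
#' @export
afs_from_matrix <- function(x, popA, popB, projection = c(20L, 20L)) {
  n1 <- as.integer(projection[1]); n2 <- as.integer(projection[2])
  gA <- calls_na(x)[x$population == popA, , drop = FALSE]
  gB <- calls_na(x)[x$population == popB, , drop = FALSE]
  if (nrow(gA) == 0 || nrow(gB) == 0) stop("empty population")
  cA <- 2 * colSums(!is.na(gA)); dA <- colSums(gA, na.rm = TRUE)
  cB <- 2 * colSums(!is.na(gB)); dB <- colSums(gB, na.rm = TRUE)
  ok <- cA >= n1 & cB >= n2
  ent <- matrix(0, n1 + 1, n2 + 1)
  for (l in which(ok)) {
    w1 <- dhyper(0:n1, dA[l], cA[l] - dA[l], n1)
    w2 <- dhyper(0:n2, dB[l], cB[l] - dB[l], n2)
    ent <- ent + w1 %o% w2
  }
  out <- fold_afs(joint_afs(ent, folded = FALSE))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Poisson composite log-likelihood of a data spectrum given a model spectrum
#'
#' The model spectrum is on an arbitrary relative scale; its optimal scale
#' `theta_hat = sum(data)/sum(model)` over unmasked cells is profiled
#' analytically, and the log-likelihood is
#' `sum d*log(theta_hat*m) - theta_hat*m - log(d!)` over unmasked cells.
#' Model cells equal to zero where the data are positive are floored at
#' 1e-30 (the number of floored cells is reported).
#'
#' @param data,model [joint_afs()] objects of identical shape, fold state and
#'   mask.
#' @param floor lower bound applied to model cells before taking logs
#'   (default 1e-30; Monte-Carlo model spectra should floor at their
#'   resolution limit instead, see [fit_model()]).
#' @param debias when `TRUE` and the model spectrum carries a `"mc_var"`
#'   attribute (as produced by [expected_afs()]), the plug-in log terms are
#'   corrected for Monte-Carlo noise by the second-order term
#'   `d * var(m) / (2 m^2)` (clipped at `d/2`); without it, the concavity of
#'   the log makes noisy spectra look systematically worse, and models that
#'   spread their mass over many small cells are penalized the most.
#' @return list with `loglik`, `theta_hat` and `n_floored`.
#' @export
afs_loglik <- function(data, model, floor = 1e-30, debias = FALSE) {
  if (data$n1 != model$n1 || data$n2 != model$n2)
    stop("data and model spectra have different shapes")
  if (data$folded != model$folded)
    stop("data and model spectra have different fold states")
  use <- !(data$mask | model$mask)
  d <- data$entries[use]
  m <- model$entries[use]
  sm <- sum(m)
  if (sm <= 0) stop("model spectrum has no unmasked mass")
  theta_hat <- sum(d) / sm
  n_floored <- sum(m <= floor & d > 0)
  m <- pmax(m, floor)
  mu <- theta_hat * m
  ll <- sum(d * log(mu) - mu - lgamma(d + 1))
  if (debias) {
    v <- attr(model, "mc_var")
    if (!is.null(v)) {
      v <- v[use]
      ll <- ll + sum(d * pmin(0.5, v / (2 * m^2)))
    }
  }
  list(loglik = ll, theta_hat = theta_hat, n_floored = n_floored)
}
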