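# The two-population demographic model family: a split from an ancestral
# population of size N_ref at time T1 (backwards, in 2*N_ref generations),
# with optional secondary contact / migration cessation and population size
# change at a nested time T2 < T1.  Sizes (nu) are relative to N_ref and
# migration rates are population-scaled (2*N_ref*m), following the joint-AFS
# diffusion conventions.

model_names <- c("SNM_split", "S_nomig", "S_asymig", "S_nomig_secont",
                 "secont_asymig_size", "S_asymig_size", "S_nomig_size")

model_free_params <- list(
  SNM_split = c("T1"),
  S_nomig = c("nu1", "nu2", "T1"),
  S_asymig = c("nu1", "nu2", "m12", "m21", "T1"),
  S_nomig_secont = c("nu1", "nu2", "m12", "m21", "T1", "T2"),
  secont_asymig_size = c("nu1", "nu2", "nu1b", "nu2b", "m12", "m21",
                         "T1", "T2"),
  S_asymig_size = c("nu1", "nu2", "nu1b", "nu2b", "m12", "m21", "T1", "T2"),
  S_nomig_size = c("nu1", "nu2", "nu1b", "nu2b", "T1", "T2"))

#' Demographic model specification
#'
#' Available models (all begin with a split of the ancestral population,
#' size 1, at time `T1`):
#' * `SNM_split` - split into two populations of ancestral size; no
#'   migration, no further events (only `T1` free).
#' * `S_nomig` - split into sizes `nu1`, `nu2`; complete isolation.
#' * `S_asymig` - split with asymmetric migration `m12`, `m21` throughout.
#' * `S_nomig_secont` - isolation from `T1` until `T2`, then secondary
#'   contact with migration `m12`, `m21`.
#' * `secont_asymig_size` - isolation until `T2`; at `T2` sizes change to
#'   `nu1b`, `nu2b` and migration begins.
#' * `S_asymig_size` - migration from `T1` until `T2`; at `T2` migration
#'   ceases and sizes change to `nu1b`, `nu2b`.
#' * `S_nomig_size` - never any migration; sizes change to `nu1b`, `nu2b`
#'   at `T2`.
#'
#' `m12` is the scaled rate of migration into population 1 from population 2
#' (forward in time), and `T1 > T2 > 0` is required wherever both appear.
#'
#' @param name one of the model names above (case-sensitive).
#' @return a `model_spec` object with elements `name` and `free_params`.
#' @export
model_spec <- function(name) {
  if (!name %in% model_names)
    stop("unknown model '", name, "'; available: ",
         paste(model_names, collapse = ", "))
  structure(list(name = name, free_params = model_free_params[[name]]),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$name, "- free parameters:",
      paste(x$free_params, collapse = ", "), "\n")
  invisible(x)
}

mk_epoch <- function(t_end, nu, M, popmap = seq_along(nu)) {
  list(t_end = t_end, popmap = as.integer(popmap), nu = as.numeric(nu),
       M = M)
}

# backward migration matrix from forward scaled rates: M[a, b] is the rate at
# which a lineage in a traces back to b, equal to the forward rate into a
# from b
mmat2 <- function(m12 = 0, m21 = 0) matrix(c(0, m21, m12, 0), 2, 2)

# assemble the epoch list for the coalescent engine
model_epochs <- function(spec, params) {
  p <- as.list(params)
  need <- spec$free_params
  missing_p <- setdiff(need, names(p))
  if (length(missing_p))
    stop("missing parameter(s): ", paste(missing_p, collapse = ", "))
  for (nm in need) if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
    stop("parameter ", nm, " must be positive and finite")
  two_epoch <- "T2" %in% need
  if (two_epoch && !(p$T1 > p$T2))
    stop("parameter-order error: T1 must exceed T2")
  anc <- mk_epoch(Inf, c(1, 1), mmat2(0, 0), popmap = c(1, 1))
  eps <- switch(spec$name,
    SNM_split = list(mk_epoch(p$T1, c(1, 1), mmat2(0, 0))),
    S_nomig = list(mk_epoch(p$T1, c(p$nu1, p$nu2), mmat2(0, 0))),
    S_asymig = list(mk_epoch(p$T1, c(p$nu1, p$nu2), mmat2(p$m12, p$m21))),
    S_nomig_secont = list(
      mk_epoch(p$T2, c(p$nu1, p$nu2), mmat2(p$m12, p$m21)),
      mk_epoch(p$T1, c(p$nu1, p$nu2), mmat2(0, 0))),
    secont_asymig_size = list(
      mk_epoch(p$T2, c(p$nu1b, p$nu2b), mmat2(p$m12, p$m21)),
      mk_epoch(p$T1, c(p$nu1, p$nu2), mmat2(0, 0))),
    S_asymig_size = list(
      mk_epoch(p$T2, c(p$nu1b, p$nu2b), mmat2(0, 0)),
      mk_epoch(p$T1, c(p$nu1, p$nu2), mmat2(p$m12, p$m21))),
    S_nomig_size = list(
      mk_epoch(p$T2, c(p$nu1b, p$nu2b), mmat2(0, 0)),
      mk_epoch(p$T1, c(p$nu1, p$nu2), mmat2(0, 0))))
  c(eps, list(anc))
}

#' Expected joint AFS of a demographic model
#'
#' Monte-Carlo structured-coalescent expectation: genealogies of the sampled
#' gene copies are simulated under the model's epoch structure, and every
#' branch contributes its length to the spectrum cell indexed by its
#' descendant counts in the two populations.  The result is the expected
#' spectrum per unit mutation rate (relative scale; the composite-likelihood
#' scale theta is profiled in [afs_loglik()]).  Deterministic given `seed`,
#' which lets one fit reuse common random numbers across parameter
#' evaluations.
#'
#' @param spec a [model_spec()].
#' @param params named numeric vector/list of the model's free parameters.
#' @param sizes integer vector `c(n1, n2)` of sampled gene copies.
#' @param n_replicates Monte-Carlo genealogies (default 10000).
#' @param seed integer seed.
#' @return an unfolded [joint_afs()] on a relative scale.
#' @export
expected_afs <- function(spec, params, sizes = c(20L, 20L),
                         n_replicates = 10000, seed = 1) {
  eps <- model_epochs(spec, params)
  res <- .coal_expected_jafs_cpp(as.integer(sizes[1]), as.integer(sizes[2]),
                                 eps, as.integer(n_replicates), seed)
  out <- joint_afs(res$mean, folded = FALSE)
  # Monte-Carlo variance of each cell mean; folded alongside the spectrum
  # and used by afs_loglik(debias = TRUE)
  attr(out, "mc_var") <- res$var
  out
}

#' Convert scaled demographic parameters to biological units
#'
#' Given the composite-likelihood scale `theta = 4*N_ref*mu*L`, the reference
#' population size is `N_ref = theta / (4*mu*L)`; times in `2*N_ref`
#' generations convert to generations and years; scaled migration rates
#' `m_ij = 2*N_ref*m` convert to per-generation migrant fractions
#' `m_ij / (2*N_ref)` and effective migrant numbers `m_ij * nu_i / 2` per
#' generation.
#'
#' @param params named vector/list with `theta` and any of `nu1`, `nu2`,
#'   `m12`, `m21`, `T1`, `T2`.
#' @param mu per-site per-generation mutation rate (default 8e-8).
#' @param L effective number of assayed sites.
#' @param generation_time generation time in years (default 1).
#' @return list of converted quantities (`N_ref`, `*_generations`, `*_years`,
#'   migrant fractions and effective migrant numbers).
#' @export
to_biological_units <- function(params, mu = 8e-8, L, generation_time = 1) {
  p <- as.list(params)
  if (is.null(p$theta)) stop("'theta' required")
  if (missing(L) || !(L > 0)) stop("effective sequence length L required")
  if (!(mu > 0) || !(generation_time > 0))
    stop("mu and generation_time must be positive")
  N_ref <- p$theta / (4 * mu * L)
  out <- list(N_ref = N_ref, mu = mu, L = L,
              generation_time = generation_time)
  for (tn in c("T1", "T2")) {
    if (!is.null(p[[tn]])) {
      out[[paste0(tn, "_generations")]] <- p[[tn]] * 2 * N_ref
      out[[paste0(tn, "_years")]] <- p[[tn]] * 2 * N_ref * generation_time
    }
  }
  if (!is.null(p$m12)) {
    out$m12_fraction_per_generation <- p$m12 / (2 * N_ref)
    if (!is.null(p$nu1)) out$m12_effective_migrants <- p$m12 * p$nu1 / 2
  }
  if (!is.null(p$m21)) {
    out$m21_fraction_per_generation <- p$m21 / (2 * N_ref)
    if (!is.null(p$nu2)) out$m21_effective_migrants <- p$m21 * p$nu2 / 2
  }
  out
}

#' Invert a biological-units report back to scaled parameters
#'
#' Algebraic inverse of [to_biological_units()] for the quantities it
#' produces; useful for checking unit conversions.
#'
#' @param report a list produced by [to_biological_units()].
#' @return named list with `theta` and any recoverable `T1`, `T2`, `m12`,
#'   `m21`.
#' @export
from_biological_units <- function(report) {
  N_ref <- report$N_ref
  out <- list(theta = N_ref * 4 * report$mu * report$L)
  for (tn in c("T1", "T2")) {
    g <- report[[paste0(tn, "_generations")]]
    if (!is.null(g)) out[[tn]] <- g / (2 * N_ref)
  }
  if (!is.null(report$m12_fraction_per_generation))
    out$m12 <- report$m12_fraction_per_generation * 2 * N_ref
  if (!is.null(report$m21_fraction_per_generation))
    out$m21 <- report$m21_fraction_per_generation * 2 * N_ref
  out
}
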