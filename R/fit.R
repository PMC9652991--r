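# Composite-likelihood fitting of demographic models to a folded joint AFS.
#
# The expected spectrum comes from a Monte-Carlo coalescent engine, so the
# objective is a deterministic but approximate surface for any fixed engine
# seed (common random numbers).  Three facts shape the search design:
# low-replicate surfaces are biased between models (empty Monte-Carlo cells
# are floored; the concavity of the log additionally penalizes noisy cells),
# so the searching stages use a noise-debiased likelihood while every
# decision between candidates is made on a large-replicate plain surface;
# the likelihood is multimodal along the split-duration axis and in the
# migration direction, while "shape" parameters (sizes, rates, event time)
# transfer usefully between modes; and conditional optima found on the cheap
# surface sit several log-likelihood units away from their plain-surface
# positions, so the leading profile points are re-refined at higher
# replicates before the final choice.

default_bounds <- function(spec) {
  b <- list()
  for (nm in spec$free_params) {
    b[[nm]] <- switch(substr(nm, 1, 1),
                      n = c(1e-3, 100),   # nu
                      m = c(1e-5, 50),
                      T = c(1e-3, 50))
  }
  b
}

# internal parameterization: T1 is replaced by dT = T1 - T2 when T2 is free,
# guaranteeing the epoch ordering during unconstrained log-space search
to_internal <- function(spec, params) {
  p <- unlist(params)[spec$free_params]
  if ("T2" %in% spec$free_params) {
    p["T1"] <- p["T1"] - p["T2"]
    names(p)[names(p) == "T1"] <- "dT"
  }
  log(p)
}

from_internal <- function(spec, ip) {
  p <- exp(ip)
  if ("dT" %in% names(p)) {
    p["T1"] <- p["dT"] + p["T2"]
    p <- p[names(p) != "dT"]
  }
  p[spec$free_params]
}

internal_bounds <- function(spec, bounds) {
  b <- bounds
  if ("T2" %in% spec$free_params) {
    b$dT <- b$T1
    b$T1 <- NULL
    b <- b[c(setdiff(spec$free_params, c("T1", "T2")), "T2", "dT")]
  } else {
    b <- b[spec$free_params]
  }
  b
}

#' Fit a demographic model to a folded joint AFS
#'
#' Maximizes the Poisson composite likelihood ([afs_loglik()]) of the data
#' spectrum under the model's Monte-Carlo expected spectrum ([expected_afs()]),
#' with common random numbers fixing the engine within each replicate level
#' and model cells floored at the Monte-Carlo resolution limit (a fixed
#' fraction of one genealogy's average contribution).
#'
#' The search runs in log-parameter space, with `T1` reparameterized as
#' `T2 + dT` so the epoch ordering always holds:
#' 1. random log-uniform starts are screened and the best refined by
#'    Nelder-Mead;
#' 2. the incumbent is improved by rounds of log-normally perturbed restarts;
#' 3. the split duration is profiled: at each of `profile_levels` fixed
#'    durations, a coarse grid over the event time and migration rates seeds
#'    a conditional Nelder-Mead over the remaining parameters, started from
#'    the incumbent's shape (sizes and migration transfer well between
#'    likelihood basins, whereas free search rarely crosses them);
#' 4. incumbent and profile candidates are arbitrated on the
#'    `finish_replicates` surface, and the winner is polished and its split
#'    duration re-profiled there (conditionally re-optimized by
#'    continuation).
#'
#' @param data a folded [joint_afs()] (from [afs_from_matrix()]).
#' @param spec a [model_spec()].
#' @param bounds named list of `c(lower, upper)` per free parameter
#'   (defaults: nu in `[1e-3, 100]`, m in `[1e-5, 50]`, T in `[1e-3, 50]`).
#' @param seed integer seed (drives the random starts and the engine's
#'   common random numbers).
#' @param n_screen random starts screened (default 100).
#' @param n_start screened starts refined by Nelder-Mead (default 4).
#' @param n_perturb perturbed restarts around the incumbents (default 3).
#' @param profile_levels split durations (dT, or T1 for single-epoch models)
#'   at which hop grids seed conditional refinements (default 0.15, 25).
#' @param screen_replicates,search_replicates,polish_replicates,finish_replicates
#'   Monte-Carlo genealogies per likelihood evaluation in the successive
#'   stages (defaults 3000, 6000, 20000, 120000); the searching stages use
#'   the noise-debiased likelihood, while arbitration, the final profile and
#'   the reported value use the plain likelihood on the `finish_replicates`
#'   surface, where the Monte-Carlo bias is negligible.
#' @param maxit Nelder-Mead iteration cap per pass (default 200).
#' @param start optional named vector of starting values; screening then
#'   perturbs this point instead of drawing uniformly.
#' @param verbose print per-stage progress (incumbents, arbitration scores,
#'   split-duration profile).
#' @return a `fit_result`: `model`, `params` (named vector), `loglik`,
#'   `theta_hat`, `AIC`, `k`, `converged`, `at_bound`, `trace`, `seed`,
#'   `data_fingerprint`.
#' @export
fit_model <- function(data, spec, bounds = default_bounds(spec), seed = 1,
                      n_screen = 100, n_start = 4, n_perturb = 3,
                      profile_levels = c(0.15, 25),
                      screen_replicates = 3000, search_replicates = 6000,
                      polish_replicates = 20000, finish_replicates = 120000,
                      maxit = 200, start = NULL, verbose = FALSE) {
  if (!inherits(data, "joint_afs")) stop("'data' must be a joint_afs")
  if (!data$folded) stop("fit folded spectra (fold_afs)")
  ib <- internal_bounds(spec, bounds)
  lo <- log(vapply(ib, `[`, 0, 1)); hi <- log(vapply(ib, `[`, 0, 2))
  npar <- length(lo)
  pnames <- names(lo)
  taxis <- which(pnames == if ("dT" %in% pnames) "dT" else "T1")
  m_idx <- which(startsWith(pnames, "m"))
  t2_idx <- which(pnames == "T2")
  set.seed(seed)
  engine_seed <- sample.int(2^31 - 4, 1)
  sizes <- c(data$n1, data$n2)

  objective <- function(ip, reps, eseed = engine_seed, debias = TRUE) {
    ipc <- pmin(hi, pmax(lo, ip))
    pen <- 1e4 * sum((ip - ipc)^2)
    params <- from_internal(spec, setNames(ipc, pnames))
    model <- fold_afs(expected_afs(spec, params, sizes, reps, eseed))
    model$entries <- pmax(model$entries, 0.25 * sum(model$entries) / reps)
    -afs_loglik(data, model, debias = debias)$loglik + pen
  }
  nm <- function(ip, reps, passes = 1, it = maxit) {
    if (npar == 1) {
      o <- optim(ip, objective, reps = reps, method = "Brent",
                 lower = lo, upper = hi)
      return(list(ip = o$par, v = o$value))
    }
    for (i in seq_len(passes)) {
      o <- optim(ip, objective, reps = reps, method = "Nelder-Mead",
                 control = list(maxit = it))
      ip <- o$par
    }
    list(ip = pmin(hi, pmax(lo, ip)), v = o$value)
  }

  # --- stage 1: screen random starts, refine the best by Nelder-Mead
  draw_start <- function() {
    if (!is.null(start))
      pmin(hi, pmax(lo, to_internal(spec, start) +
                      runif(npar, -log(3), log(3))))
    else runif(npar, lo, hi)
  }
  cand <- matrix(vapply(seq_len(n_screen), function(i) draw_start(),
                        numeric(npar)),
                 nrow = n_screen, ncol = npar, byrow = TRUE)
  vals <- apply(cand, 1, objective, reps = screen_replicates)
  stage1 <- list()
  for (i in order(vals)[seq_len(min(n_start, n_screen))]) {
    o <- nm(cand[i, ], screen_replicates)
    stage1[[length(stage1) + 1]] <- list(ip = o$ip,
                                         v = objective(o$ip,
                                                       search_replicates))
  }
  # keep the two best *distinct* optima as incumbents: different local modes
  # (e.g. the two gene-flow directions) carry different fitted shapes, and
  # the split-duration profile below is only as good as the shape it starts
  # from
  ord1 <- order(vapply(stage1, `[[`, 0, "v"))
  incs <- list(stage1[[ord1[1]]])
  for (i in ord1[-1]) {
    if (length(incs) >= 2) break
    if (sqrt(sum((stage1[[i]]$ip - incs[[1]]$ip)^2)) > 1)
      incs[[2]] <- stage1[[i]]
  }

  # --- stage 2: perturbation rounds around each incumbent
  for (e in seq_along(incs)) {
    n_pert_e <- ceiling(n_perturb / length(incs))
    for (s in seq_len(n_pert_e)) {
      ip0 <- pmin(hi, pmax(lo, incs[[e]]$ip + runif(npar, -log(2), log(2))))
      o <- nm(ip0, search_replicates)
      if (o$v < incs[[e]]$v) incs[[e]] <- o
    }
  }
  screen_best <- min(vapply(incs, `[[`, 0, "v"))

  # migration-direction-swapped variants join the pool: the two gene-flow
  # directions form separate likelihood modes that local search rarely
  # crosses
  cands <- lapply(incs, `[[`, "ip")
  if (length(m_idx) == 2) {
    ip0 <- incs[[1]]$ip
    ip0[m_idx] <- ip0[rev(m_idx)]
    cands[[length(cands) + 1]] <- nm(pmin(hi, pmax(lo, ip0)),
                                     search_replicates)$ip
  }

  # --- stage 3: conditional profile along the split-duration axis, seeded
  # from every incumbent shape
  if (npar > 1) {
    t2_grid <- if (length(t2_idx))
      log(c(0.01, 0.05, 0.2, 1)) else numeric(0)
    m_grid <- log(c(1e-4, 0.3, 3, 20))
    free_idx <- setdiff(seq_len(npar), taxis)
    nu_idx <- which(startsWith(pnames, "nu"))
    cond_refine <- function(ip) {
      fcond <- function(x) {
        ip2 <- ip; ip2[free_idx] <- x
        objective(ip2, search_replicates)
      }
      x <- ip[free_idx]
      for (pass in 1:2) {
        o <- optim(x, fcond, method = "Nelder-Mead",
                   control = list(maxit = round(0.6 * maxit)))
        x <- o$par
      }
      ip[free_idx] <- x
      pmin(hi, pmax(lo, ip))
    }
    event_grid <- function(base) {
      hops <- list(base)
      grid_dims <- c(if (length(t2_idx)) list(t2 = t2_grid) else NULL,
                     lapply(m_idx, function(j) m_grid))
      if (length(grid_dims)) {
        combos <- expand.grid(grid_dims)
        for (r in seq_len(nrow(combos))) {
          ip <- base
          cidx <- c(if (length(t2_idx)) t2_idx else NULL, m_idx)
          ip[cidx] <- as.numeric(combos[r, ])
          hops[[length(hops) + 1]] <- pmin(hi, pmax(lo, ip))
        }
      }
      hops
    }
    # hop grids at fixed profile levels, with coarse population-size anchors
    # at the deepest level, so a misfitted incumbent shape cannot lock the
    # search out of the deep-split basin; the top hops are refined
    # conditionally (split duration frozen) and join the arbitration pool
    for (lev in profile_levels) {
      deepest <- lev == max(profile_levels)
      base <- incs[[1]]$ip
      base[taxis] <- min(hi[taxis], max(lo[taxis], log(lev)))
      hops <- if (deepest && length(nu_idx) > 0) {
        nu_levels <- log(c(0.1, 0.5, 2.5))
        first_pair <- nu_idx[nu_idx %in% which(pnames %in% c("nu1", "nu2"))]
        second_pair <- setdiff(nu_idx, first_pair)
        hh <- list()
        for (a in nu_levels) for (b in nu_levels) {
          ip <- base
          if (length(second_pair)) {
            # size-change models: anchor the two epochs' size pairs
            ip[first_pair] <- a
            ip[second_pair] <- b
          } else {
            ip[first_pair] <- c(a, b)
          }
          hh <- c(hh, event_grid(ip))
        }
        if (length(incs) > 1) {
          alt <- incs[[2]]$ip
          alt[taxis] <- base[taxis]
          hh <- c(hh, event_grid(alt))
        }
        hh
      } else {
        c(event_grid(base),
          if (length(incs) > 1) {
            alt <- incs[[2]]$ip
            alt[taxis] <- base[taxis]
            event_grid(alt)
          })
      }
      hv <- vapply(hops, objective, 0, reps = search_replicates)
      n_ref <- if (deepest) 2L else 1L
      for (i in order(hv)[seq_len(n_ref)])
        cands[[length(cands) + 1]] <- cond_refine(hops[[i]])
    }
  }

  # --- stage 4: arbitrate on the smoothest surface; at this replicate level
  # the plain likelihood is nearly unbiased, so no noise correction is used
  score_high <- function(ip)
    objective(ip, finish_replicates, engine_seed + 1, debias = FALSE)
  cv <- vapply(cands, score_high, 0)
  if (verbose) {
    for (ci in seq_along(cands)) {
      pp <- from_internal(spec, setNames(cands[[ci]], pnames))
      message(sprintf("candidate %d: score %.1f  %s", ci, cv[ci],
                      paste(names(pp), signif(pp, 3), sep = "=",
                            collapse = " ")))
    }
  }
  best_ip <- cands[[which.min(cv)]]

  # --- stage 5: global profile of the split duration, with the remaining
  # parameters conditionally re-optimized; every grid point starts from the
  # best of the pooled shapes transplanted to that duration (a good shape
  # discovered at any duration then seeds every other), the top profile
  # points are re-refined on a larger-replicate plain surface (the cheap
  # debiased surface is good for travel but its conditional optima sit
  # several units off), and the final value is the profile argmax on the
  # `finish_replicates` surface
  if (npar > 1) {
    free_idx <- setdiff(seq_len(npar), taxis)
    tgrid <- log(c(0.05, 0.3, 1.2, 4, 9, 16, 28))
    tgrid <- unique(pmin(hi[taxis], pmax(lo[taxis], tgrid)))
    ordg <- order(abs(tgrid - best_ip[taxis]))
    done <- c(list(best_ip), cands[order(cv)[seq_len(min(3, length(cv)))]])
    cond_nm <- function(ip, reps, it, debias) {
      fcond <- function(x) {
        ip2 <- ip; ip2[free_idx] <- x
        objective(ip2, reps, debias = debias)
      }
      o <- optim(ip[free_idx], fcond, method = "Nelder-Mead",
                 control = list(maxit = it))
      ip[free_idx] <- o$par
      pmin(hi, pmax(lo, ip))
    }
    prof <- list()
    for (gi in ordg) {
      dists <- vapply(done, function(z) abs(z[taxis] - tgrid[gi]), 0)
      starts5 <- c(list(done[[which.min(dists)]]),
                   done[seq_len(min(3, length(done)))])
      starts5 <- lapply(starts5, function(z) {
        z[taxis] <- tgrid[gi]
        z
      })
      # refine from the two most distinct transplanted shapes: a shape that
      # only pays off after its event times adjust can look terrible on a
      # single evaluation, so start value alone must not choose the seed
      sv <- vapply(starts5, objective, 0, reps = search_replicates)
      pick <- which.min(sv)
      dd <- vapply(starts5, function(z)
        sqrt(sum((z - starts5[[pick]])^2)), 0)
      pick2 <- if (any(dd > 1)) which(dd > 1)[which.min(sv[dd > 1])] else
        NA_integer_
      best <- NULL
      for (pk in c(pick, pick2)) {
        if (is.na(pk)) next
        ipk <- cond_nm(starts5[[pk]], search_replicates,
                       round(0.3 * maxit), debias = TRUE)
        vk <- objective(ipk, search_replicates)
        if (is.null(best) || vk < best$v) best <- list(ip = ipk, v = vk)
      }
      ip <- best$ip
      done[[length(done) + 1]] <- ip
      prof[[length(prof) + 1]] <- ip
    }
    prof[[length(prof) + 1]] <- best_ip
    pv <- vapply(prof, score_high, 0)
    if (verbose) {
      for (pi in seq_along(prof))
        message(sprintf("profile dT=%.3f: score %.1f",
                        exp(prof[[pi]][taxis]), pv[pi]))
    }
    # re-refine the best profile point of each split-duration region (the
    # cheap surface's conditional optima sit several units off, and by
    # different amounts in different regions, so a single global top-k taken
    # before the plain refinement could drop the eventual winner)
    regions <- cut(vapply(prof, `[[`, 0, taxis),
                   breaks = log(c(1e-4, 1, 20, 1e3)))
    top <- unique(c(vapply(split(seq_along(prof), regions), function(ix) {
      if (length(ix) == 0) return(NA_integer_)
      ix[which.min(pv[ix])]
    }, 0L), which.min(pv)))
    top <- top[!is.na(top)]
    for (pi in top) {
      ip <- prof[[pi]]
      for (pass in 1:2) {  # restarted simplex on the plain surface
        ip <- cond_nm(ip, polish_replicates, round(0.3 * maxit),
                      debias = FALSE)
      }
      prof[[length(prof) + 1]] <- ip
      pv <- c(pv, score_high(ip))
      if (verbose)
        message(sprintf("re-refined dT=%.3f: score %.1f", exp(ip[taxis]),
                        pv[length(pv)]))
    }
    best_ip <- prof[[which.min(pv)]]
    # local refinement of the split duration on the same surface
    for (span in c(0.3, 0.1)) {
      grid <- pmin(hi[taxis], pmax(lo[taxis],
                                   best_ip[taxis] + seq(-span, span,
                                                        length.out = 5)))
      gv <- vapply(grid, function(g) {
        ip2 <- best_ip; ip2[taxis] <- g
        score_high(ip2)
      }, 0)
      best_ip[taxis] <- grid[which.min(gv)]
    }
  }
  names(best_ip) <- pnames

  params <- from_internal(spec, best_ip)
  model <- fold_afs(expected_afs(spec, params, sizes, finish_replicates,
                                 engine_seed + 2))
  model$entries <- pmax(model$entries,
                        0.25 * sum(model$entries) / finish_replicates)
  fin <- afs_loglik(data, model)
  k <- length(spec$free_params) + 1L  # profiled theta counts as a parameter
  at_bound <- any(abs(best_ip - lo) < 1e-6 | abs(best_ip - hi) < 1e-6)
  structure(list(model = spec$name, params = params,
                 loglik = fin$loglik, theta_hat = fin$theta_hat,
                 AIC = 2 * k - 2 * fin$loglik, k = k,
                 converged = !at_bound, at_bound = at_bound,
                 trace = data.frame(stage = c("incumbent", "arbitration",
                                              "final"),
                                    negloglik = c(screen_best, min(cv),
                                                  -fin$loglik)),
                 seed = seed,
                 data_fingerprint = c(n1 = data$n1, n2 = data$n2,
                                      total = afs_total(data))),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", x$model, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " AIC:", format(x$AIC, digits = 8),
      " theta_hat:", format(x$theta_hat, digits = 6), "\n")
  cat("  params:", paste(names(x$params),
                         format(x$params, digits = 4), sep = "=",
                         collapse = ", "), "\n")
  if (x$at_bound) cat("  WARNING: optimum at a parameter bound\n")
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' @param fits list of `fit_result` objects fitted to the same data.
#' @return data.frame ranked by ascending AIC with `delta_AIC` and Akaike
#'   weights.
#' @export
model_select <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  fps <- lapply(fits, `[[`, "data_fingerprint")
  if (length(unique(vapply(fps, paste, "", collapse = "/"))) > 1)
    stop("fits were made on different data spectra")
  df <- data.frame(model = vapply(fits, `[[`, "", "model"),
                   k = as.integer(vapply(fits, function(f)
                     as.numeric(f$k), 0)),
                   loglik = vapply(fits, `[[`, 0, "loglik"),
                   AIC = vapply(fits, `[[`, 0, "AIC"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$AIC), ]
  df$delta_AIC <- df$AIC - df$AIC[1]
  w <- exp(-df$delta_AIC / 2)
  df$weight <- w / sum(w)
  rownames(df) <- NULL
  df
}
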