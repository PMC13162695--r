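#' Monte-Carlo expected site frequency spectrum
#'
#' Estimates the per-cell probabilities of the joint SFS under a scenario
#' template at a given parameter vector, by simulating `n_sims` unlinked
#' SNP genealogies (one mutation each, branch drawn proportional to
#' length). Probabilities are over unmasked (polymorphic) cells and sum to
#' one; cells with zero simulated mass are floored at `1 / (10 * n_sims)`
#' and the tensor renormalized, so composite likelihoods stay finite.
#'
#' @param template A `model_template` from [get_template()].
#' @param theta Named parameter vector (must pass
#'   [validate_parameters()]).
#' @param sizes Haploid sample sizes, named by the template's observed
#'   populations.
#' @param n_sims Number of simulated SNPs.
#' @param seed Integer seed.
#' @return An `sfs_tensor` of probabilities (attribute `n_sims`).
#' @export
expected_sfs <- function(template, theta, sizes, n_sims, seed) {
  stop_if_not(n_sims >= 1, "n_sims must be >= 1")
  if (!is.null(names(theta))) theta <- theta[template$par_names]
  theta <- unname(theta)
  msgs <- check_theta(template, theta)
  if (length(msgs) > 0) {
    rlang::abort(paste0("invalid parameters: ",
                        paste(msgs, collapse = "; ")))
  }
  stop_if_not(all(template$obs_pops %in% names(sizes)),
              "`sizes` must name every observed population")
  names(theta) <- template$par_names
  enc <- template$encode_fast(theta)
  nsamp <- setNames(integer(length(enc$pops)), enc$pops)
  nsamp[template$obs_pops] <- as.integer(sizes[template$obs_pops])
  counts <- cpp_sfs_counts(enc$Ne0, enc$mig, enc$ev_time, enc$ev_kind,
                           enc$ev_a, enc$ev_b, enc$ev_par,
                           as.integer(nsamp),
                           as.integer(n_sims), as.double(mix_seed(seed)))
  dims <- unname(sizes[template$obs_pops]) + 1L
  p <- array(as.double(counts), dim = dims)
  out <- new_sfs(p, template$obs_pops, folded = FALSE)
  out$counts <- floor_and_normalize(out$counts, out$mask, n_sims)
  attr(out, "n_sims") <- n_sims
  out
}

floor_and_normalize <- function(p, mask, n_sims) {
  open <- !mask
  tot <- sum(p[open])
  p[open] <- p[open] / tot
  floor_v <- 1 / (10 * n_sims)
  z <- open & p <= 0
  p[z] <- floor_v
  p[open] <- p[open] / sum(p[open])
  p[mask] <- 0
  p
}

#' Composite log10-likelihood of an observed spectrum
#'
#' `composite_loglik()` computes `sum(m_i * log10(p_i))` over unmasked
#' cells; `saturated_loglik()` is the maximum attainable (observed)
#' likelihood `sum(m_i * log10(m_i / S))` with `0 * log(0) = 0`.
#'
#' @param obs An `sfs_tensor` of observed counts.
#' @param p An `sfs_tensor` of cell probabilities on the same dimensions.
#' @return Log10 likelihood (a scalar).
#' @export
composite_loglik <- function(obs, p) {
  stop_if_not(identical(dim(obs$counts), dim(p$counts)),
              "observed and expected SFS dimensions differ")
  open <- !obs$mask & !p$mask
  m <- obs$counts[open]
  pr <- p$counts[open]
  stop_if_not(sum(m) > 0, "observed spectrum has no unmasked sites")
  stop_if_not(all(pr[m > 0] > 0),
              "zero expected probability at an observed cell")
  sum(m[m > 0] * log10(pr[m > 0]))
}

#' @rdname composite_loglik
#' @export
saturated_loglik <- function(obs) {
  m <- obs$counts[!obs$mask]
  S <- sum(m)
  stop_if_not(S > 0, "observed spectrum has no unmasked sites")
  m <- m[m > 0]
  sum(m * log10(m / S))
}

# Fingerprint of an observed spectrum so model comparisons can check they
# were fitted to the same data.
sfs_fingerprint <- function(obs) {
  v <- as.vector(obs$counts)
  sprintf("%d:%.6g:%.6g", length(v), sum(v),
          sum(v * seq_along(v)) %% 1e9)
}

#' Fit a demographic scenario to an observed spectrum
#'
#' Multi-run composite-likelihood optimization in the fastsimcoal mould,
#' adapted for noisy Monte-Carlo objectives. Each of `n_runs` runs starts
#' from a random in-bounds parameter vector and performs
#' `n_cycles_initial` optimization cycles (one expected-SFS estimation
#' per cycle, driving a Nelder-Mead simplex) at the reduced
#' `n_sims_initial` precision, with a run-specific seed. All runs are
#' then scored at full `n_sims` precision under a seed shared by every
#' run and model (common random numbers, so comparisons are not washed
#' out by simulation noise), and the best `n_polish` runs continue for
#' the remaining `n_cycles_total - n_cycles_initial` cycles at full
#' precision under the shared seed. Steps leaving the bounds or
#' violating ordering constraints are rejected. The best run is finally
#' re-evaluated with `n_sims_final` simulations under an independent
#' shared seed; that refined value is the model's headline likelihood.
#'
#' @param obs Observed `sfs_tensor` (counts). If folded, expected spectra
#'   are folded before the likelihood.
#' @param n_cycles_initial,n_cycles_total Optimization cycles (initial
#'   reduced-precision stage per run, then the full-precision polish
#'   stage for the leading runs).
#' @param template A `model_template`.
#' @param n_sims Simulated SNPs per likelihood evaluation in the full
#'   stage.
#' @param n_runs Independent random-start runs.
#' @param seed Integer seed.
#' @param n_sims_initial Simulations per evaluation in the initial stage.
#' @param n_sims_final Simulations for the final common-seed evaluation
#'   of the best run.
#' @param n_polish Number of leading runs that enter the full-precision
#'   polish stage.
#' @return An `sfs_fit`: tibble of runs (sorted by `lnL_est` descending;
#'   see [tidy.sfs_fit()]) plus settings. `delta = lnL_obs - lnL_est`
#'   (log10 units, lower is better); `AIC = 2k - 2 ln(10) lnL_est`. The
#'   top row's likelihood is the refined evaluation (`refined = TRUE`);
#'   other rows carry the shared-seed score of their run.
#' @export
fit_model <- function(obs, template, n_cycles_initial = 25,
                      n_cycles_total = 65, n_sims = 10000, n_runs = 20,
                      seed = 1, n_sims_initial = max(500, n_sims %/% 10),
                      n_sims_final = 10 * n_sims, n_polish = 2) {
  stop_if_not(inherits(obs, "sfs_tensor"), "obs must be an sfs_tensor")
  sizes <- setNames(dim(obs$counts) - 1L, obs$pops)
  stop_if_not(setequal(obs$pops, template$obs_pops),
              "observed populations do not match the template")
  stop_if_not(n_cycles_total >= n_cycles_initial,
              "n_cycles_total must be >= n_cycles_initial")
  lnL_obs <- saturated_loglik(obs)
  k <- template$k
  n_polish <- min(n_polish, n_runs)

  eval_lnL <- function(theta, ns, eseed) {
    p <- expected_sfs(template, theta, sizes, ns, eseed)
    if (obs$folded) p <- fold_probs(p)
    composite_loglik(obs, p)
  }
  to_z <- function(th) ifelse(template$log10, log10(th), th)
  from_z <- function(z) {
    th <- ifelse(template$log10, 10 ^ z, z)
    names(th) <- template$par_names
    th
  }
  # minimized objective; invalid parameters are infinitely bad
  obj <- function(z, ns, eseed) {
    th <- from_z(z)
    if (!params_valid(template, th)) return(Inf)
    -eval_lnL(th, ns, eseed)
  }
  step_coarse <- ifelse(template$log10, 0.5, 0.15)
  step_fine <- ifelse(template$log10, 0.25, 0.08)
  shared_seed <- mix_seed(seed, 999)
  final_seed <- mix_seed(seed, 777)

  cand <- vector("list", n_runs)
  score <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- mix_seed(seed, r)
    z0 <- with_local_seed(run_seed, to_z(sample_start(template)))
    o1 <- nelder_mead(function(z) obj(z, n_sims_initial, run_seed),
                      z0, step_coarse, max(n_cycles_initial, k + 2))
    cand[[r]] <- o1$par
    score[r] <- -obj(o1$par, n_sims, shared_seed)
  }
  polish_evals <- n_cycles_total - n_cycles_initial
  if (polish_evals >= k + 2) {
    for (r in order(score, decreasing = TRUE)[seq_len(n_polish)]) {
      o2 <- nelder_mead(function(z) obj(z, n_sims, shared_seed),
                        cand[[r]], step_fine, polish_evals)
      if (-o2$value >= score[r]) {
        cand[[r]] <- o2$par
        score[r] <- -o2$value
      }
    }
  }
  res <- purrr::map_dfr(seq_len(n_runs), function(r) {
    th <- from_z(cand[[r]])
    tibble(model_id = template$id, run = r,
           !!!setNames(as.list(th), names(th)),
           lnL_est = score[r], lnL_obs = lnL_obs,
           converged = is.finite(score[r]), refined = FALSE,
           seed = mix_seed(seed, r))
  })
  res <- dplyr::arrange(res, dplyr::desc(.data$lnL_est))
  best_theta <- as.numeric(res[1, template$par_names])
  names(best_theta) <- template$par_names
  res$lnL_est[1] <- eval_lnL(best_theta, n_sims_final, final_seed)
  res$refined[1] <- TRUE
  res$delta <- lnL_obs - res$lnL_est
  res$AIC <- 2 * k - 2 * log(10) * res$lnL_est
  structure(
    list(results = res, model_id = template$id, k = k,
         params = template$params$name, lnL_obs = lnL_obs,
         fingerprint = sfs_fingerprint(obs), folded = obs$folded,
         settings = list(n_cycles_initial = n_cycles_initial,
                         n_cycles_total = n_cycles_total, n_sims = n_sims,
                         n_runs = n_runs, seed = seed,
                         n_sims_final = n_sims_final,
                         n_polish = n_polish)),
    class = "sfs_fit")
}

# Fold an expected-probability tensor (fold cells, then re-mask).
fold_probs <- function(p) {
  fold_sfs(new_sfs(p$counts, p$pops, folded = FALSE))
}

# Nelder-Mead with an explicit initial simplex step and a fixed budget of
# objective evaluations (the noisy-objective analogue of optimization
# cycles: every evaluation re-estimates the expected SFS).
nelder_mead <- function(fn, z0, step, max_evals) {
  k <- length(z0)
  X <- matrix(rep(z0, each = k + 1), nrow = k + 1)
  for (i in seq_len(k)) X[i + 1, i] <- X[i + 1, i] + step[i]
  Fv <- apply(X, 1, fn)
  ne <- k + 1
  while (ne < max_evals) {
    o <- order(Fv)
    X <- X[o, , drop = FALSE]
    Fv <- Fv[o]
    ctr <- colMeans(X[seq_len(k), , drop = FALSE])
    xr <- ctr + (ctr - X[k + 1, ])
    fr <- fn(xr)
    ne <- ne + 1
    if (fr < Fv[1]) {
      xe <- ctr + 2 * (ctr - X[k + 1, ])
      fe <- fn(xe)
      ne <- ne + 1
      if (fe < fr) {
        X[k + 1, ] <- xe
        Fv[k + 1] <- fe
      } else {
        X[k + 1, ] <- xr
        Fv[k + 1] <- fr
      }
    } else if (fr < Fv[k]) {
      X[k + 1, ] <- xr
      Fv[k + 1] <- fr
    } else {
      xc <- ctr + 0.5 * (X[k + 1, ] - ctr)
      fc <- fn(xc)
      ne <- ne + 1
      if (fc < Fv[k + 1]) {
        X[k + 1, ] <- xc
        Fv[k + 1] <- fc
      } else {
        for (i in 2:(k + 1)) {  # shrink toward the incumbent
          X[i, ] <- X[1, ] + 0.5 * (X[i, ] - X[1, ])
          Fv[i] <- fn(X[i, ])
          ne <- ne + 1
        }
      }
    }
  }
  o <- order(Fv)
  list(par = X[o[1], ], value = Fv[o[1]])
}

#' @export
print.sfs_fit <- function(x, ...) {
  b <- x$results[1, ]
  cat("<sfs_fit> ", x$model_id, " (k = ", x$k, "), ",
      nrow(x$results), " runs; best lnL_est = ",
      format(b$lnL_est, digits = 6), ", delta = ",
      format(b$delta, digits = 4), ", AIC = ",
      format(b$AIC, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Tidy methods for fitted scenario objects
#'
#' `tidy()` returns one row per optimization run (best first);
#' `glance()` a one-row summary of the best run.
#'
#' @param x An `sfs_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sfs_fit <- function(x, ...) x$results

#' @rdname tidy.sfs_fit
#' @export
glance.sfs_fit <- function(x, ...) {
  b <- x$results[1, ]
  tibble(model_id = x$model_id, k = x$k, lnL_est = b$lnL_est,
         lnL_obs = b$lnL_obs, delta = b$delta, AIC = b$AIC,
         n_runs = nrow(x$results))
}

#' Rank competing fitted scenarios
#'
#' Ranks by ascending delta-likelihood (primary criterion; lower = closer
#' to the saturated likelihood) with ascending AIC reported alongside;
#' exact ties break toward fewer parameters.
#'
#' @param fits A list of `sfs_fit` objects fitted to the same observed
#'   spectrum.
#' @return A tibble, best model first, with columns `model_id`, `k`,
#'   `lnL_est`, `delta`, `AIC`, `rank` and `rank_aic`.
#' @export
compare_models <- function(fits) {
  stop_if_not(length(fits) >= 2, "need at least two fits")
  fps <- vapply(fits, function(f) f$fingerprint, character(1))
  stop_if_not(length(unique(fps)) == 1,
              "fits were not made against the same observed spectrum")
  tab <- purrr::map_dfr(fits, glance)
  tab <- dplyr::arrange(tab, .data$delta, .data$AIC, .data$k)
  tab$rank <- seq_len(nrow(tab))
  tab$rank_aic <- rank(tab$AIC, ties.method = "first")
  tab
}

#' Parametric bootstrap confidence intervals
#'
#' Resamples `S` sites from the expected spectrum at the best-fit
#' parameters, refits each replicate, and reports percentile intervals.
#'
#' @param fit An `sfs_fit` (its best run seeds the resampling model).
#' @param template The matching `model_template`.
#' @param sizes Haploid sizes named by observed populations.
#' @param S Number of sites per bootstrap replicate.
#' @param n_boot Bootstrap replicates (>= 2).
#' @param n_runs_per_boot Optimization runs per replicate.
#' @param seed Integer seed.
#' @param level Interval coverage (default 0.95).
#' @param ... Passed to [fit_model()] (cycle counts, simulation sizes).
#' @return A tibble with one row per parameter: point estimate, `lower`,
#'   `upper`, and the bootstrap replicate estimates as a list column.
#' @export
bootstrap_ci <- function(fit, template, sizes, S, n_boot = 100,
                         n_runs_per_boot = 2, seed = 1, level = 0.95, ...) {
  stop_if_not(n_boot >= 2, "n_boot must be >= 2")
  best <- as.numeric(fit$results[1, fit$params])
  names(best) <- fit$params
  p <- expected_sfs(template, best, sizes,
                    n_sims = fit$settings$n_sims_final,
                    seed = mix_seed(seed, 0))
  open <- !p$mask
  probs <- p$counts[open]
  est <- matrix(NA_real_, nrow = n_boot, ncol = length(best),
                dimnames = list(NULL, fit$params))
  for (b in seq_len(n_boot)) {
    m <- with_local_seed(mix_seed(seed, b), {
      stats::rmultinom(1, size = S, prob = probs)[, 1]
    })
    counts <- array(0, dim = dim(p$counts))
    counts[open] <- m
    obs_b <- new_sfs(counts, p$pops, folded = FALSE)
    fb <- fit_model(obs_b, template, n_runs = n_runs_per_boot,
                    seed = mix_seed(seed, 1000 + b), ...)
    est[b, ] <- as.numeric(fb$results[1, fit$params])
  }
  a <- (1 - level) / 2
  purrr::map_dfr(seq_along(best), function(j) {
    tibble(param = fit$params[j], estimate = best[j],
           lower = unname(quantile(est[, j], a)),
           upper = unname(quantile(est[, j], 1 - a)),
           boot = list(est[, j]))
  })
}
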