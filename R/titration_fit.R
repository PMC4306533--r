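#' Fit settings for titration regression
#'
#' @param protein_nominal nominal total protein concentration, uM; the
#'   fitted active concentration is bounded above by twice this value.
#' @param correct logical; apply [correct_titration()] before fitting.
#' @param kas_starts multi-start grid of association-constant starting
#'   values, uM^-1. Tight binders put the optimum in a shallow valley of
#'   the objective; starting from several orders of magnitude and keeping
#'   the best avoids that failure mode.
#' @param max_iter Levenberg-Marquardt iteration cap per start (the
#'   function-evaluation cap is 100x this).
#' @param seed optional integer seed (reserved for randomized multi-start
#'   jitter; the default grid is deterministic).
#' @return list of settings.
#' @export
fit_settings <- function(protein_nominal = 0.1, correct = FALSE,
                         kas_starts = c(0.1, 1, 10, 100),
                         max_iter = 200, seed = NULL) {
  stopifnot(protein_nominal > 0, all(kas_starts > 0))
  list(protein_nominal = protein_nominal, correct = correct,
       kas_starts = kas_starts, max_iter = max_iter, seed = seed)
}

#' Estimate binding parameters from a titration curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' [minpack.lm::nls.lm()]) of the depletion-isotherm fluorescence model to
#' the observed intensities, estimating `{kas, p0_act, f0, delta_f,
#' f_lig}` jointly. Box bounds encode the physics: `kas > 0`,
#' `0 < p0_act <= 2 * protein_nominal`, `delta_f >= 0`, `f_lig >= 0`.
#' Starting values are data-driven (`f0` from the first point, `f_lig`
#' from the terminal slope, `delta_f` from the observed quench amplitude)
#' with `kas` multi-started over `settings$kas_starts`; the best optimum
#' is kept. Standard errors come from the local curvature of the
#' objective at the optimum, scaled by the residual variance.
#'
#' The active protein concentration is fitted, not fixed at nominal; for
#' very weak binders the quench amplitude and `p0_act` are poorly
#' separable, which shows up as a large `p0_act` standard error in the
#' diagnostics rather than being silently resolved.
#'
#' @param curve a [titration_curve()], intensities already corrected
#'   unless `settings$correct` is `TRUE`.
#' @param settings a [fit_settings()] list.
#' @return an object of class `fit_result` with elements `params`
#'   ([binding_parameters()]), `se` (named vector), `rss`, `n_points`,
#'   `converged`, `residuals`.
#' @export
fit_titration <- function(curve, settings = fit_settings()) {
  stopifnot(inherits(curve, "titration_curve"))
  if (isTRUE(settings$correct)) curve <- correct_titration(curve)
  L <- curve$points$ligand_total
  F_obs <- curve$points$fluorescence_raw
  n <- length(L)
  if (n < 6) stop("fewer than 6 points: cannot fit 5 parameters")
  if (diff(range(F_obs)) <= .Machine$double.eps * max(1, abs(F_obs[1])))
    stop("all fluorescence values are equal: delta_f (and the binding ",
         "signal) is not identifiable from this curve")
  if (!is.null(settings$seed)) set.seed(settings$seed)

  nominal <- settings$protein_nominal
  f0_init <- F_obs[1]
  f_lig_init <- max(0, (F_obs[n] - F_obs[n - 1]) / max(L[n] - L[n - 1],
                                                       .Machine$double.eps))
  delta_f_init <- max((f0_init - min(F_obs)) / nominal, 1e-6)

  resid_fn <- function(par) {
    p <- binding_parameters(par[["kas"]], par[["p0_act"]], par[["f0"]],
                            par[["delta_f"]], par[["f_lig"]])
    F_obs - model_fluorescence(p, L)
  }
  lower <- c(kas = 1e-10, p0_act = 1e-9, f0 = 0, delta_f = 0, f_lig = 0)
  upper <- c(kas = Inf, p0_act = 2 * nominal, f0 = Inf, delta_f = Inf,
             f_lig = Inf)
  ctrl <- minpack.lm::nls.lm.control(maxiter = settings$max_iter,
                                     maxfev = 100 * settings$max_iter)

  best <- NULL
  for (k0 in settings$kas_starts) {
    start <- c(kas = k0, p0_act = nominal, f0 = f0_init,
               delta_f = delta_f_init, f_lig = f_lig_init)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  # A stalled run (iteration cap on a flat ridge) is polished by a fresh
  # restart from its own optimum; LM then either certifies convergence
  # immediately or improves further.
  if (!is.null(best) && !best$info %in% 1:3) {
    polish <- tryCatch(
      minpack.lm::nls.lm(par = best$par, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (!is.null(polish) && polish$deviance <= best$deviance) best <- polish
  }
  if (is.null(best))
    return(structure(list(params = NULL,
                          se = setNames(rep(NA_real_, 5), names(lower)),
                          rss = NA_real_, n_points = n, converged = FALSE,
                          residuals = rep(NA_real_, n)),
                     class = "fit_result"))

  par <- best$par
  params <- binding_parameters(par[["kas"]], par[["p0_act"]], par[["f0"]],
                               par[["delta_f"]], par[["f_lig"]])
  dof <- max(n - length(par), 1)
  sigma2 <- best$deviance / dof
  # Covariance from the local curvature (J'J). When a nuisance direction
  # is flat -- e.g. the delta_f / p0_act trade-off of a weak binder --
  # J'J is singular; the Moore-Penrose pseudoinverse then gives the
  # curvature-based SE within the identifiable subspace while the flat
  # directions surface as very large SEs on the parameters involved.
  se <- tryCatch({
    covar <- tryCatch(solve(best$hessian),
                      error = function(e) MASS::ginv(best$hessian))
    sqrt(pmax(diag(covar), 0) * sigma2)
  }, error = function(e) rep(NA_real_, length(par)))
  names(se) <- names(par)

  structure(list(params = params, se = se, rss = best$deviance,
                 n_points = n, converged = best$info %in% 1:3,
                 residuals = as.numeric(best$fvec)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (is.null(x$params)) {
    cat("<fit_result> optimizer failed on all starts\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<fit_result> kas = %.4g +/- %.2g uM^-1 (p0_act %.3g uM, %d points, rss %.3g%s)\n",
    x$params$kas, x$se[["kas"]], x$params$p0_act, x$n_points, x$rss,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Inverse-variance weighted average of replicate estimates
#'
#' Pools replicate association constants with weights equal to the
#' reciprocal squared standard error:
#' `kas = sum(k_i / s_i^2) / sum(1 / s_i^2)`,
#' `se = sqrt(1 / sum(1 / s_i^2))`. Exact ties in the weights need no
#' special handling; a zero standard error is rejected (add jitter or
#' collapse exact replicates first).
#'
#' @param kas numeric vector of replicate estimates, uM^-1.
#' @param kas_se matching standard errors, each > 0.
#' @return list with pooled `kas`, `kas_se`, and `n_replicates`.
#' @examples
#' weighted_average(c(10, 20), c(1, 2))  # kas 12.0, se 0.894
#' @export
weighted_average <- function(kas, kas_se) {
  if (length(kas) == 0L) stop("no replicates to pool")
  if (length(kas) != length(kas_se))
    stop("kas and kas_se must have the same length")
  if (any(!is.finite(kas_se)) || any(kas_se <= 0))
    stop("every kas_se must be finite and > 0 ",
         "(zero-SE replicates cannot be inverse-variance weighted; ",
         "jitter them or pool exact replicates first)")
  w <- 1 / kas_se^2
  list(kas = sum(kas * w) / sum(w),
       kas_se = sqrt(1 / sum(w)),
       n_replicates = length(kas))
}

#' Aggregate per-curve fits into affinity records
#'
#' Groups fitted association constants by protein x ligand x buffer cell
#' and pools each group with [weighted_average()], yielding one affinity
#' record per cell (the shape of a published association-constant table).
#'
#' @param fits data frame with columns `protein_id`, `ligand`,
#'   `buffer_tag`, `kas`, `kas_se` (one row per fitted replicate); see
#'   [fits_to_table()] for building it from `fit_result` objects.
#' @return data frame of affinity records: `protein_id`, `ligand`,
#'   `buffer_tag`, `kas`, `kas_se`, `n_replicates`.
#' @export
aggregate_affinity <- function(fits) {
  req <- c("protein_id", "ligand", "buffer_tag", "kas", "kas_se")
  if (!all(req %in% names(fits)))
    stop("fits must have columns: ", paste(req, collapse = ", "))
  key <- interaction(fits$protein_id, fits$ligand, fits$buffer_tag,
                     drop = TRUE, sep = "\r")
  out <- lapply(split(fits, key), function(g) {
    pooled <- weighted_average(g$kas, g$kas_se)
    data.frame(protein_id = g$protein_id[1], ligand = g$ligand[1],
               buffer_tag = g$buffer_tag[1], kas = pooled$kas,
               kas_se = pooled$kas_se, n_replicates = pooled$n_replicates,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$protein_id, out$ligand, out$buffer_tag), , drop = FALSE]
}

#' Tabulate per-curve fit results
#'
#' @param curves list of [titration_curve()] objects.
#' @param fits matching list of [fit_titration()] results.
#' @return data frame with one row per curve: identity columns plus
#'   `kas`, `kas_se`, `converged`.
#' @export
fits_to_table <- function(curves, fits) {
  stopifnot(length(curves) == length(fits))
  rows <- Map(function(cv, ft) {
    data.frame(protein_id = cv$protein_id, ligand = cv$ligand,
               buffer_tag = cv$buffer_tag,
               kas = if (is.null(ft$params)) NA_real_ else ft$params$kas,
               kas_se = ft$se[["kas"]],
               converged = ft$converged, stringsAsFactors = FALSE)
  }, curves, fits)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
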