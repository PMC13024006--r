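# Multi-run statistics: per-slice mean and standard error of the mean
# across independent Monte Carlo runs, and first-order (delta-method)
# propagation of (alpha, beta, D) uncertainties into the survival.

#' Aggregate a depth-dependent quantity over independent runs
#'
#' Per slice, the mean over runs and the standard error of the mean
#' `sem = sqrt( sum((x_i - mean)^2) / (n (n - 1)) )`.  For `quantity =
#' "dose"` the runs may be dose profiles or mixed-field spectra (summed per
#' slice); for `"alpha"`/`"beta"` the runs must be spectra and a
#' radiosensitivity table must be supplied (the per-run mixed coefficients
#' are aggregated).  Slices where a coefficient is undefined in any run
#' (zero total dose) yield `NA` mean and sem.
#'
#' @param runs a [run_set()] with n >= 2 runs
#' @param quantity one of `"dose"`, `"alpha"`, `"beta"`
#' @param table a [radiosensitivity_table()] (required for alpha/beta)
#' @return an object of class `aggregated_quantity`: list with `grid`,
#'   `quantity`, numeric `mean` and `sem` per slice, and `n_runs`
#' @export
aggregate_runs <- function(runs, quantity = c("dose", "alpha", "beta"),
                           table = NULL) {
  stopifnot(inherits(runs, "run_set"))
  quantity <- match.arg(quantity)
  n <- length(runs$runs)
  if (n < 2L) stop("need at least 2 runs to estimate the run-to-run sem")
  grid <- runs$runs[[1]]$grid
  per_run <- function(r) {
    if (quantity == "dose") {
      if (inherits(r, "dose_profile")) r$values
      else total_dose_profile(r)$values
    } else {
      if (!inherits(r, "mixed_field_spectrum"))
        stop("alpha/beta aggregation needs mixed_field_spectrum runs")
      if (is.null(table))
        stop("alpha/beta aggregation needs a radiosensitivity table")
      mx <- mix_spectrum(r, table, warn = FALSE)
      if (quantity == "alpha") mx$alpha else mx$beta
    }
  }
  X <- vapply(runs$runs, per_run, numeric(grid$n_slices))
  X <- matrix(X, nrow = grid$n_slices)
  m <- rowMeans(X)
  sem <- sqrt(rowSums((X - m)^2) / (n * (n - 1)))
  structure(list(grid = grid, quantity = quantity, mean = m, sem = sem,
                 n_runs = n),
            class = "aggregated_quantity")
}

#' @export
print.aggregated_quantity <- function(x, ...) {
  cat(sprintf("aggregated_quantity [%s]: %d slices over %d runs\n",
              x$quantity, x$grid$n_slices, x$n_runs))
  invisible(x)
}

#' First-order propagation of uncertainties into the LQ survival
#'
#' Delta-method result for `S = exp(-alpha D - beta D^2)` with independent
#' uncertainties on alpha, beta and D:
#' `sigma_S = S * sqrt( D^2 s_a^2 + D^4 s_b^2 + (alpha + 2 beta D)^2 s_D^2 )`.
#' Exactly zero when all three sigmas are zero, and homogeneous of degree one
#' in the input sigmas.
#'
#' @param alpha,beta LQ coefficients (1/Gy, 1/Gy^2)
#' @param dose_Gy absorbed dose (Gy), non-negative
#' @param sigma_alpha,sigma_beta,sigma_dose non-negative uncertainties
#' @param survival surviving fraction `S` (pass the already-computed value so
#'   the propagation stays consistent with it); defaults to
#'   `survival_lq(alpha, beta, dose_Gy)`
#' @return sigma of the surviving fraction (vectorised)
#' @export
propagate_survival_sigma <- function(alpha, beta, dose_Gy,
                                     sigma_alpha, sigma_beta, sigma_dose,
                                     survival = survival_lq(alpha, beta,
                                                            dose_Gy)) {
  if (any(dose_Gy < 0)) stop("dose must be non-negative")
  if (any(c(sigma_alpha, sigma_beta, sigma_dose) < 0))
    stop("sigmas must be non-negative")
  survival * sqrt(dose_Gy^2 * sigma_alpha^2 +
                  dose_Gy^4 * sigma_beta^2 +
                  (alpha + 2 * beta * dose_Gy)^2 * sigma_dose^2)
}

#' Radiobiological depth summary of a run set, with uncertainties
#'
#' The full per-slice chain for one transport engine: aggregate dose, alpha
#' and beta over the runs, compute survival from the mean coefficients at
#' the mean dose, propagate the run-to-run sems into sigma_S, and derive RBE
#' and Gy-Eq dose.  Slices with undefined coefficients (zero dose) carry
#' survival 1, sigma 0, RBE `NA`, Gy-Eq 0.
#'
#' @param runs a [run_set()] of mixed-field spectra
#' @param table a [radiosensitivity_table()]
#' @param cell a [cell_line()]; defaults to the table's cell line
#' @return data.frame with columns `depth_mm`, `dose`, `sigma_dose`,
#'   `alpha`, `sigma_alpha`, `beta`, `sigma_beta`, `survival`,
#'   `sigma_survival`, `rbe`, `gyeq`
#' @export
bio_summary <- function(runs, table, cell = table$cell_line) {
  stopifnot(inherits(runs, "run_set"), runs$kind == "spectrum")
  ad <- aggregate_runs(runs, "dose")
  aa <- aggregate_runs(runs, "alpha", table)
  ab <- aggregate_runs(runs, "beta", table)
  ok <- !is.na(aa$mean) & !is.na(ab$mean) & ad$mean > 0
  n <- ad$grid$n_slices
  surv <- rep(1, n); sig_s <- numeric(n)
  rbe <- rep(NA_real_, n); gyeq <- numeric(n)
  surv[ok] <- survival_lq(aa$mean[ok], ab$mean[ok], ad$mean[ok])
  sig_s[ok] <- propagate_survival_sigma(aa$mean[ok], ab$mean[ok], ad$mean[ok],
                                        aa$sem[ok], ab$sem[ok], ad$sem[ok],
                                        surv[ok])
  if (any(ok)) {
    rg <- rbe_gyeq(aa$mean[ok], ab$mean[ok], ad$mean[ok], cell)
    rbe[ok] <- rg$rbe
    gyeq[ok] <- rg$gyeq_Gy
  }
  data.frame(depth_mm = slice_centers(ad$grid),
             dose = ad$mean, sigma_dose = ad$sem,
             alpha = aa$mean, sigma_alpha = aa$sem,
             beta = ab$mean, sigma_beta = ab$sem,
             survival = surv, sigma_survival = sig_s,
             rbe = rbe, gyeq = gyeq)
}
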