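# Profile comparison statistics: RMSE, 1D gamma index with DD/DTA criteria,
# global normalization, dose threshold and TG-218-style verdicts, plus the
# LQ sensitivity factor linking relative dose and survival differences.

#' Root mean square error between two equal-length sequences
#'
#' `RMSE = sqrt( sum((a_i - b_i)^2) / N )`; symmetric in its arguments and a
#' metric (satisfies the triangle inequality).
#'
#' @param reference,evaluation numeric vectors of equal length >= 1
#' @return non-negative scalar
#' @export
rmse <- function(reference, evaluation) {
  if (length(reference) != length(evaluation) || length(reference) < 1L)
    stop("rmse needs two equal-length sequences of length >= 1")
  sqrt(mean((reference - evaluation)^2))
}

#' Gamma-index acceptance criteria
#'
#' @param dd_fraction dose-difference criterion as a fraction of the global
#'   normalization (e.g. 0.03 for 3 percent)
#' @param dta_mm distance-to-agreement criterion in mm (e.g. 2.0)
#' @param threshold_fraction dose threshold as a fraction of the global
#'   normalization; reference points below it are not evaluated (default 0.10)
#' @param normalization only `"global_max"` (of the reference) is supported
#' @return an object of class `gamma_criteria`
#' @export
gamma_criteria <- function(dd_fraction = 0.03, dta_mm = 2.0,
                           threshold_fraction = 0.10,
                           normalization = "global_max") {
  stopifnot(dd_fraction > 0, dta_mm > 0,
            threshold_fraction >= 0, threshold_fraction < 1,
            identical(normalization, "global_max"))
  structure(list(dd_fraction = dd_fraction, dta_mm = dta_mm,
                 threshold_fraction = threshold_fraction,
                 normalization = normalization),
            class = "gamma_criteria")
}

gamma_verdict <- function(pass_rate) {
  if (pass_rate >= 95) "good" else if (pass_rate >= 90) "acceptable" else "fail"
}

gamma_setup <- function(reference, evaluation, criteria) {
  stopifnot(inherits(reference, "dose_profile"),
            inherits(evaluation, "dose_profile"),
            inherits(criteria, "gamma_criteria"))
  if (!grids_equal(reference$grid, evaluation$grid))
    stop("profiles on different grids")
  zc <- slice_centers(reference$grid)
  rv <- reference$values
  norm <- max(rv)
  if (norm <= 0) stop("reference profile is identically zero")
  mask <- rv >= criteria$threshold_fraction * norm
  if (!any(mask))
    stop("no reference point above the dose threshold: gamma undefined")
  list(zc = zc, rv = rv, norm = norm, mask = mask,
       dta = criteria$dta_mm, dd_abs = criteria$dd_fraction * norm,
       ev = evaluation$values)
}

gamma_wrap <- function(gam, setup, criteria) {
  ev <- gam[setup$mask]
  structure(list(gamma_values = ev, evaluated_mask = setup$mask,
                 pass_rate_percent = 100 * mean(ev <= 1),
                 mean_gamma = mean(ev),
                 verdict = gamma_verdict(100 * mean(ev <= 1)),
                 criteria = criteria),
            class = "gamma_result")
}

#' 1D gamma-index analysis of an evaluation profile against a reference
#'
#' Global normalization to the reference maximum; reference points below
#' `threshold_fraction` of it are excluded.  For each evaluated reference
#' point at depth `z_r`, gamma is the minimum over evaluation positions
#' `z_e` in `z_r +/- 4*DTA` (clipped to the grid) of
#' `sqrt( ((z_e - z_r)/DTA)^2 + ((E(z_e) - R(z_r))/(DD * norm))^2 )`, where
#' `E` is the continuous piecewise-linear interpolant of the evaluation
#' profile.  On each linear segment of `E` the objective is an exact
#' quadratic in `z_e`, so the minimum is found analytically per segment and
#' the search is exact (no discretization of the search position).  Pass
#' rate is the percentage of evaluated points with gamma <= 1; the verdict
#' is `"good"` above 95 percent, `"acceptable"` above 90 percent, else
#' `"fail"`.
#'
#' @param reference,evaluation [dose_profile()] objects on one grid
#' @param criteria a [gamma_criteria()]
#' @return an object of class `gamma_result` with fields `gamma_values`
#'   (evaluated points only), `evaluated_mask`, `pass_rate_percent`,
#'   `mean_gamma`, `verdict`
#' @export
gamma_1d <- function(reference, evaluation, criteria = gamma_criteria()) {
  s <- gamma_setup(reference, evaluation, criteria)
  window <- 4 * s$dta
  # knots of the piecewise-linear evaluation curve, extended flat beyond the
  # grid so windows reaching past the ends see the clamped endpoint value
  zk <- c(s$zc[1] - window - 1, s$zc, s$zc[length(s$zc)] + window + 1)
  ek <- c(s$ev[1], s$ev, s$ev[length(s$ev)])
  z0 <- zk[-length(zk)]; z1 <- zk[-1]
  e0 <- ek[-length(ek)]
  slope <- (ek[-1] - e0) / (z1 - z0)
  A <- 1 / s$dta^2
  gam <- rep(NA_real_, length(s$zc))
  for (i in which(s$mask)) {
    zr <- s$zc[i]; rr <- s$rv[i]
    lo <- pmax(z0, zr - window); hi <- pmin(z1, zr + window)
    keep <- which(lo <= hi)
    B <- (slope[keep] / s$dd_abs)^2
    # stationary point of A (z-zr)^2 + ((e0 + slope (z-z0) - rr)/dd)^2,
    # clamped to the segment-window intersection
    zstar <- (A * zr + B * z0[keep] -
                slope[keep] * (e0[keep] - rr) / s$dd_abs^2) / (A + B)
    zstar <- pmin(pmax(zstar, lo[keep]), hi[keep])
    dz <- zstar - zr
    de <- e0[keep] + slope[keep] * (zstar - z0[keep]) - rr
    gam[i] <- sqrt(min(A * dz^2 + (de / s$dd_abs)^2))
  }
  gamma_wrap(gam, s, criteria)
}

#' Brute-force 1D gamma (test oracle)
#'
#' Same contract as [gamma_1d()], evaluated by exhaustive minimisation over a
#' dense candidate grid (step DTA/100, window +/- 10*DTA, clipped to the
#' grid) with a final golden-section polish of the best candidate's
#' bracketing interval.  Kept deliberately independent of the analytic
#' per-segment search in [gamma_1d()]; quadratically slower.
#'
#' @inheritParams gamma_1d
#' @return a `gamma_result`
#' @export
gamma_1d_bruteforce <- function(reference, evaluation,
                                criteria = gamma_criteria()) {
  s <- gamma_setup(reference, evaluation, criteria)
  step <- s$dta / 100
  window <- 10 * s$dta
  e_fun <- stats::approxfun(s$zc, s$ev, rule = 2)
  zmin <- s$zc[1]; zmax <- s$zc[length(s$zc)]
  gam <- rep(NA_real_, length(s$zc))
  for (i in which(s$mask)) {
    zr <- s$zc[i]; rr <- s$rv[i]
    cand <- seq(max(zmin, zr - window), min(zmax, zr + window), by = step)
    if (!(zr %in% cand)) cand <- sort(c(cand, zr))
    obj <- function(z) ((z - zr) / s$dta)^2 + ((e_fun(z) - rr) / s$dd_abs)^2
    g2 <- obj(cand)
    j <- which.min(g2)
    best <- g2[j]
    lo <- cand[max(1L, j - 1L)]; hi <- cand[min(length(cand), j + 1L)]
    if (hi > lo)
      best <- min(best, stats::optimize(obj, lower = lo, upper = hi,
                                        tol = 1e-10)$objective)
    gam[i] <- sqrt(best)
  }
  gamma_wrap(gam, s, criteria)
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "gamma_result: %d points, pass %.1f%%, mean gamma %.3f -> %s\n",
    length(x$gamma_values), x$pass_rate_percent, x$mean_gamma, x$verdict))
  invisible(x)
}

#' LQ sensitivity factor linking relative dose and survival differences
#'
#' Multiplier `k` in `dS/S = -k * dD/D` for the LQ survival.  The commonly
#' quoted first-order factor is `alpha*D + beta*D^2` (variant
#' `"as_printed"`); the exact logarithmic derivative of `S(D)` gives
#' `alpha*D + 2*beta*D^2` (variant `"exact_derivative"`).  Both coincide in
#' the linear limit beta = 0.  A factor below 1 attenuates dose differences
#' in the biological endpoint.
#'
#' @param alpha,beta LQ coefficients
#' @param dose_Gy dose (Gy), non-negative
#' @param variant `"as_printed"` or `"exact_derivative"`
#' @return the non-negative factor, vectorised
#' @export
sensitivity_factor <- function(alpha, beta, dose_Gy,
                               variant = c("as_printed",
                                           "exact_derivative")) {
  variant <- match.arg(variant)
  if (any(dose_Gy < 0)) stop("dose must be non-negative")
  if (variant == "as_printed") alpha * dose_Gy + beta * dose_Gy^2
  else alpha * dose_Gy + 2 * beta * dose_Gy^2
}

#' Bundle RMSE and gamma analysis of a profile pair
#'
#' RMSE is computed on the full common support (all slices, as-given
#' values); gamma per [gamma_1d()] with the supplied criteria.
#'
#' @param reference,evaluation [dose_profile()] objects on one grid
#' @param criteria a [gamma_criteria()]
#' @param label free-text metadata (ion, depth window, cell line)
#' @return an object of class `comparison_report` with fields `label`,
#'   `rmse`, `gamma`, `criteria`
#' @export
compare_profiles <- function(reference, evaluation,
                             criteria = gamma_criteria(), label = "") {
  r <- rmse(reference$values, evaluation$values)
  g <- gamma_1d(reference, evaluation, criteria)
  structure(list(label = label, rmse = r, gamma = g, criteria = criteria),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "comparison_report [%s]: RMSE %.4g, pass %.1f%%, mean gamma %.3f -> %s\n",
    x$label, x$rmse, x$gamma$pass_rate_percent, x$gamma$mean_gamma,
    x$gamma$verdict))
  invisible(x)
}

#' Write comparison reports to CSV
#'
#' One row per report, columns
#' `label,rmse,pass_rate_percent,mean_gamma,verdict`; the criteria of the
#' first report are echoed as `# dd=`, `# dta_mm=`, `# threshold=`.
#'
#' @param reports a `comparison_report` or list of them
#' @param path output path
#' @export
write_report_csv <- function(reports, path) {
  if (inherits(reports, "comparison_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L)
  cr <- reports[[1]]$criteria
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dd=%s", fmt_full(cr$dd_fraction)),
               sprintf("# dta_mm=%s", fmt_full(cr$dta_mm)),
               sprintf("# threshold=%s", fmt_full(cr$threshold_fraction)),
               "label,rmse,pass_rate_percent,mean_gamma,verdict"), con)
  for (r in reports)
    writeLines(paste(r$label, fmt_full(r$rmse),
                     fmt_full(r$gamma$pass_rate_percent),
                     fmt_full(r$gamma$mean_gamma),
                     r$gamma$verdict, sep = ","), con)
  invisible(NULL)
}

#' Read a comparison-report CSV (see [write_report_csv()])
#' @param path file path
#' @return data.frame of report rows with the criteria as attributes
#' @export
read_report_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read report: ", path)
  meta <- read_meta_lines(path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  attr(df, "dd") <- as.numeric(meta$dd)
  attr(df, "dta_mm") <- as.numeric(meta$dta_mm)
  attr(df, "threshold") <- as.numeric(meta$threshold)
  df
}
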