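# Fixture builders shared across the test files.  Everything is generated in
# code; no binary fixtures.

# small mixed-field spectrum on an n-slice grid: one proton record per slice
flat_proton_spectrum <- function(n = 5, dose = 1, energy = 50) {
  g <- depth_grid(n)
  mixed_field_spectrum(g, data.frame(
    slice_index = 0:(n - 1), species = "p",
    energy_MeV_per_u = energy, dose_Gy_per_primary = dose))
}

# two-node table for one species, for hand-checkable interpolation
two_node_table <- function(cell = cell_line("toy", 0.2, 0.02),
                           species = "p", e = c(10, 100),
                           alpha = c(0.2, 0.4), beta = c(0.01, 0.09)) {
  radiosensitivity_table(cell, data.frame(
    species = species, energy_MeV_per_u = e, alpha = alpha, beta = beta))
}

# smooth positive profile: baseline + Gaussian bumps, on a 1 mm grid.
# Slopes are kept gentle (widths >= 8 mm) so the discretized gamma searches
# are well inside their resolution.
random_smooth_profile <- function(n = 80, k = 3) {
  z <- (seq_len(n) - 0.5)
  v <- rep(0.15, n)
  for (j in seq_len(k)) {
    c0 <- stats::runif(1, 0.2 * n, 0.8 * n)
    w <- stats::runif(1, 8, 15)
    a <- stats::runif(1, 0.4, 1.0)
    v <- v + a * exp(-(z - c0)^2 / (2 * w^2))
  }
  dose_profile(depth_grid(n), v)
}

# paired reference/evaluation: evaluation is the reference translated by a
# sub-mm shift, rescaled by a few percent, plus a smooth relative warp
random_profile_pair <- function(n = 80) {
  ref <- random_smooth_profile(n)
  z <- slice_centers(ref$grid)
  shift <- stats::runif(1, -1, 1)
  scale <- 1 + stats::runif(1, -0.03, 0.03)
  warp <- 1 + 0.02 * sin(z / stats::runif(1, 10, 20))
  v <- stats::approx(z, ref$values, xout = z - shift, rule = 2)$y
  list(ref = ref, eval = dose_profile(ref$grid, v * scale * warp))
}

# translate a profile by delta mm (linear resampling, clamped ends)
translate_profile <- function(profile, delta_mm) {
  z <- slice_centers(profile$grid)
  dose_profile(profile$grid,
               stats::approx(z, profile$values, xout = z - delta_mm,
                             rule = 2)$y,
               unit_tag = profile$unit_tag)
}

# synthetic tables for the two built-in cell lines
scc_table <- function() synth_alpha_beta_table(
  synth_radbio_params(cell_line_scc()))
chordoma_table <- function() synth_alpha_beta_table(
  synth_radbio_params(cell_line_chordoma()))
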