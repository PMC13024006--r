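# Analytic pristine Bragg-peak kernels and SOBP design.
#
# Range-energy relation: R = (A/Z^2) * a * E^p with E in MeV/u,
# a = 0.0024 cm, p = 1.755 (power-law fit for ions in water, calibrated so
# the proton energy windows 46.2-58.2, 77.9-101.8 and 115.5-145.5 MeV map
# onto distal edges of 3, 8 and 15 cm).
# The pristine depth-dose kernel is the power-law stopping term
# 1/(R - z)^(1 - 1/p) convolved numerically with a Gaussian range-straggling
# kernel of width sigma_R = 0.012 * R^0.935 cm, plus an optional exponential
# fragmentation tail beyond R for Z > 1 ions.

.range_a_cm <- 0.0024
.range_p <- 1.755
.tail_decay_cm <- 3.0   # e-folding length of the fragment tail beyond R

#' Primary ion species
#'
#' @param token one of `"p"`, `"He"`, `"C"` (built-in mass/charge), or any
#'   canonical species token with explicit `A` and `Z`
#' @param A mass number (optional for the built-ins)
#' @param Z charge number (optional for the built-ins)
#' @return an object of class `ion_species`
#' @export
ion_species <- function(token, A = NULL, Z = NULL) {
  builtin <- list(p = c(1L, 1L), He = c(4L, 2L), Li = c(7L, 3L),
                  Be = c(9L, 4L), B = c(11L, 5L), C = c(12L, 6L))
  if (is.null(A) || is.null(Z)) {
    if (!token %in% names(builtin))
      stop("no built-in A/Z for species \"", token, "\"; supply A and Z")
    A <- builtin[[token]][1]
    Z <- builtin[[token]][2]
  }
  A <- as.integer(A); Z <- as.integer(Z)
  stopifnot(Z >= 1L, A >= Z)
  structure(list(token = token, mass_number_A = A, charge_Z = Z),
            class = "ion_species")
}

#' Range in water from kinetic energy per nucleon
#'
#' Power-law range-energy fit `R = (A/Z^2) * a * E^p` with `a = 0.0024` cm and
#' `p = 1.755`, `E` in MeV/u, calibrated against clinical proton beam data
#' (46.2-58.2 MeV spanning a 2-3 cm plateau, 77.9-101.8 MeV for 5-8 cm,
#' 115.5-145.5 MeV for 10-15 cm).  For protons and He (A/Z^2 = 1) the ranges
#' at equal E/u coincide.
#'
#' @param ion an [ion_species()]
#' @param energy_MeV_per_u kinetic energy per nucleon (MeV/u), vectorised
#' @return range in cm of water
#' @export
energy_to_range <- function(ion, energy_MeV_per_u) {
  stopifnot(inherits(ion, "ion_species"))
  if (any(energy_MeV_per_u <= 0)) stop("energy must be positive")
  (ion$mass_number_A / ion$charge_Z^2) * .range_a_cm *
    energy_MeV_per_u^.range_p
}

#' Kinetic energy per nucleon from residual range (inverse of
#' [energy_to_range()])
#' @param ion an [ion_species()]
#' @param range_cm residual range in cm of water, vectorised
#' @return energy in MeV/u
#' @export
range_to_energy <- function(ion, range_cm) {
  stopifnot(inherits(ion, "ion_species"))
  if (any(range_cm <= 0)) stop("range must be positive")
  (range_cm / (.range_a_cm * ion$mass_number_A / ion$charge_Z^2))^(1 / .range_p)
}

#' Range-straggling width
#' @param range_cm range in cm
#' @return Gaussian sigma in cm (`0.012 * R^0.935`)
#' @export
range_straggling_sigma <- function(range_cm) 0.012 * range_cm^0.935

#' Analytic pristine Bragg curve on a depth grid
#'
#' The unconvolved stopping term is proportional to `1/(R - z)^(1 - 1/p)`
#' for `z < R` (an integrable singularity at the range).  It is numerically
#' convolved with a Gaussian of sigma `0.012 R^0.935` cm (range straggling).
#' For Z > 1 ions an exponential fragmentation tail is added beyond R with
#' amplitude `tail_fraction` relative to the entrance dose and an e-folding
#' length of 3 cm.  The curve is normalized to unit entrance dose (first
#' slice).
#'
#' @param ion an [ion_species()]
#' @param energy_MeV_per_u beam kinetic energy per nucleon
#' @param grid a [depth_grid()] covering at least `[0, R + 1 cm]`
#' @param tail_fraction fragment-tail amplitude relative to entrance dose
#'   (ignored for protons; default 0)
#' @return an object of class `pristine_kernel` with fields `ion`,
#'   `energy_MeV_per_u`, `depth_dose` (a [dose_profile()]) and `range_cm`
#' @export
pristine_bragg_curve <- function(ion, energy_MeV_per_u, grid,
                                 tail_fraction = 0) {
  stopifnot(inherits(ion, "ion_species"), inherits(grid, "depth_grid"),
            tail_fraction >= 0)
  R <- energy_to_range(ion, energy_MeV_per_u)  # cm
  extent_cm <- (grid$origin_mm + grid$n_slices * grid$slice_thickness_mm) / 10
  if (extent_cm < R + 1.0)
    stop(sprintf("grid too short: extends to %.2f cm but needs %.2f cm",
                 extent_cm, R + 1.0))
  z_cm <- slice_centers(grid) / 10
  sig <- range_straggling_sigma(R)
  # midpoint quadrature over the stopping term on a fine internal grid;
  # the 1/(R-u)^(1-1/p) singularity at u = R is integrable
  h <- min(sig / 4, 0.01)
  u <- seq(h / 2, R - h / 2, by = h)
  d0 <- (R - u)^(-(1 - 1 / .range_p))
  w <- d0 * h
  dose <- as.vector(exp(-outer(z_cm, u, "-")^2 / (2 * sig^2)) %*% w) /
    (sqrt(2 * pi) * sig)
  if (ion$charge_Z > 1L && tail_fraction > 0) {
    entrance <- dose[1]
    beyond <- z_cm > R
    dose[beyond] <- dose[beyond] +
      tail_fraction * entrance * exp(-(z_cm[beyond] - R) / .tail_decay_cm)
  }
  dose <- dose / dose[1]
  structure(list(ion = ion, energy_MeV_per_u = energy_MeV_per_u,
                 depth_dose = dose_profile(grid, dose, sigma = 0),
                 range_cm = R, tail_fraction = tail_fraction),
            class = "pristine_kernel")
}

#' Pristine kernels with ranges evenly spanning a plateau
#'
#' Convenience constructor: `n_beams` energies whose ranges are evenly spaced
#' between the proximal plateau edge and the distal edge plus one
#' range-straggling width (so the straggled peak of the deepest beam can hold
#' the plateau through its last slice), or between the ranges of an explicit
#' energy window `e_min`/`e_max` in MeV/u.
#'
#' @param ion an [ion_species()]
#' @param plateau_mm numeric `c(d1, d2)` plateau interval in mm
#' @param grid a [depth_grid()]
#' @param n_beams number of monoenergetic beams (default 12)
#' @param tail_fraction passed to [pristine_bragg_curve()]
#' @param e_min,e_max optional energy window in MeV/u overriding the
#'   plateau-derived window
#' @return list of `pristine_kernel`, sorted by energy
#' @export
sobp_kernels <- function(ion, plateau_mm, grid, n_beams = 12,
                         tail_fraction = 0, e_min = NULL, e_max = NULL) {
  stopifnot(length(plateau_mm) == 2L, plateau_mm[1] < plateau_mm[2],
            n_beams >= 1L)
  if (is.null(e_min) || is.null(e_max)) {
    r_lo <- plateau_mm[1] / 10
    r_hi <- plateau_mm[2] / 10
    r_hi <- r_hi + range_straggling_sigma(r_hi)
  } else {
    r_lo <- energy_to_range(ion, e_min)
    r_hi <- energy_to_range(ion, e_max)
  }
  ranges <- seq(r_lo, r_hi, length.out = n_beams)
  energies <- range_to_energy(ion, ranges)
  lapply(energies, function(e)
    pristine_bragg_curve(ion, e, grid, tail_fraction))
}

#' SOBP plan: beam energies, non-negative weights, plateau, prescription
#' @param ion an [ion_species()]
#' @param energies_MeV_per_u beam energies (MeV/u), increasing
#' @param weights non-negative beam weights, same length
#' @param plateau_mm numeric `c(d1, d2)` in mm
#' @param prescription_Gy plateau dose prescription (default 2 Gy)
#' @return an object of class `sobp_plan`
#' @export
sobp_plan <- function(ion, energies_MeV_per_u, weights, plateau_mm,
                      prescription_Gy = 2.0) {
  stopifnot(inherits(ion, "ion_species"),
            length(energies_MeV_per_u) == length(weights),
            all(weights >= 0), length(plateau_mm) == 2L,
            plateau_mm[1] < plateau_mm[2], prescription_Gy > 0)
  ord <- order(energies_MeV_per_u)
  structure(list(ion = ion,
                 energies_MeV_per_u = as.numeric(energies_MeV_per_u[ord]),
                 weights = as.numeric(weights[ord]),
                 plateau_mm = as.numeric(plateau_mm),
                 prescription_Gy = as.numeric(prescription_Gy)),
            class = "sobp_plan")
}

plateau_slice_idx <- function(grid, plateau_mm) {
  z <- slice_centers(grid)
  which(z >= plateau_mm[1] & z <= plateau_mm[2])
}

#' Design SOBP weights for a flat plateau
#'
#' Non-negative least squares over the plateau slices: minimises
#' `sum_plateau (sum_k w_k kernel_k(z) - 1)^2` subject to `w >= 0`
#' (via [pracma::lsqnonneg()]).  With >= 10 kernels whose ranges evenly span
#' the plateau the resulting ripple (max relative deviation from the plateau
#' mean) is below 2 percent.
#'
#' @param kernels list of [pristine_bragg_curve()] kernels on one grid
#' @param plateau_mm numeric `c(d1, d2)` plateau interval in mm
#' @param prescription_Gy stored in the returned plan (default 2 Gy)
#' @return an [sobp_plan()] with the fitted weights (unit plateau target;
#'   apply [normalize_to_prescription()] to the composed profile, or
#'   [scale_plan_weights()] for absolute doses)
#' @export
design_sobp_weights <- function(kernels, plateau_mm, prescription_Gy = 2.0) {
  stopifnot(length(kernels) >= 1L,
            all(vapply(kernels, inherits, logical(1), "pristine_kernel")))
  grid <- kernels[[1]]$depth_dose$grid
  ranges <- vapply(kernels, function(k) k$range_cm, numeric(1))
  if (max(ranges) * 10 < plateau_mm[1])
    stop("infeasible plateau: all kernel ranges are proximal to it")
  idx <- plateau_slice_idx(grid, plateau_mm)
  if (length(idx) < 1L) stop("plateau contains no slice centers")
  A <- vapply(kernels, function(k) k$depth_dose$values[idx],
              numeric(length(idx)))
  A <- matrix(A, nrow = length(idx))
  if (length(kernels) == 1L) {
    w <- sum(A) / sum(A^2)   # closed-form 1D least squares, w >= 0
  } else {
    w <- pracma::lsqnonneg(A, rep(1, length(idx)))$x
  }
  energies <- vapply(kernels, function(k) k$energy_MeV_per_u, numeric(1))
  sobp_plan(kernels[[1]]$ion, energies, w, plateau_mm, prescription_Gy)
}

#' Compose the SOBP depth-dose profile from a plan and its kernels
#'
#' Per-slice weighted sum of the kernel depth-dose curves; linear in the
#' weights.
#'
#' @param plan an [sobp_plan()]
#' @param kernels kernels matching the plan beams one-to-one (by energy)
#' @return a [dose_profile()]
#' @export
compose_sobp <- function(plan, kernels) {
  stopifnot(inherits(plan, "sobp_plan"))
  energies <- vapply(kernels, function(k) k$energy_MeV_per_u, numeric(1))
  ord <- order(energies)
  kernels <- kernels[ord]
  energies <- energies[ord]
  if (length(kernels) != length(plan$energies_MeV_per_u) ||
      any(abs(energies - plan$energies_MeV_per_u) >
          1e-9 * pmax(1, plan$energies_MeV_per_u)))
    stop("kernels do not match plan beams one-to-one")
  grid <- kernels[[1]]$depth_dose$grid
  vals <- numeric(grid$n_slices)
  for (i in seq_along(kernels))
    vals <- vals + plan$weights[i] * kernels[[i]]$depth_dose$values
  dose_profile(grid, vals, sigma = 0)
}

#' Ripple of a profile over a plateau
#' @param profile a [dose_profile()]
#' @param plateau_mm numeric `c(d1, d2)` in mm
#' @return max relative deviation from the plateau mean (dimensionless)
#' @export
sobp_ripple <- function(profile, plateau_mm) {
  idx <- plateau_slice_idx(profile$grid, plateau_mm)
  v <- profile$values[idx]
  max(abs(v - mean(v))) / mean(v)
}

#' Scale a profile so the plateau mean equals the prescription
#'
#' Scale factor `prescription / mean(plateau values)` applied to values and
#' sigma alike; idempotent on an already-normalized profile.
#'
#' @param profile a [dose_profile()]
#' @param plateau_mm numeric `c(d1, d2)` in mm
#' @param prescription_Gy target plateau mean dose (Gy)
#' @return the scaled [dose_profile()] (unit tag `absolute_Gy`)
#' @export
normalize_to_prescription <- function(profile, plateau_mm,
                                      prescription_Gy = 2.0) {
  idx <- plateau_slice_idx(profile$grid, plateau_mm)
  if (length(idx) < 1L) stop("plateau contains no slice centers")
  m <- mean(profile$values[idx])
  if (m <= 0) stop("plateau mean dose is zero; cannot normalize")
  s <- prescription_Gy / m
  dose_profile(profile$grid, profile$values * s, profile$sigma * s,
               unit_tag = "absolute_Gy")
}

#' Rescale plan weights so the composed plateau mean equals the prescription
#' @param plan an [sobp_plan()]
#' @param kernels matching kernels
#' @return the plan with rescaled weights
#' @export
scale_plan_weights <- function(plan, kernels) {
  prof <- compose_sobp(plan, kernels)
  idx <- plateau_slice_idx(prof$grid, plan$plateau_mm)
  m <- mean(prof$values[idx])
  if (m <= 0) stop("plateau mean dose is zero; cannot scale weights")
  plan$weights <- plan$weights * plan$prescription_Gy / m
  plan
}

#' Compose two opposing irradiation fields
#'
#' Depth-mirrors field B (slice `i` maps to `n - 1 - i`, i.e. the beam enters
#' from the distal phantom face) and concatenates its records with field A;
#' the total dose is the sum of the two.
#'
#' @param field_a,field_b [mixed_field_spectrum()] objects on the same grid
#' @param phantom_length_mm phantom length; must match the grid extent
#' @return a [mixed_field_spectrum()]
#' @export
compose_opposing_fields <- function(field_a, field_b, phantom_length_mm) {
  stopifnot(inherits(field_a, "mixed_field_spectrum"),
            inherits(field_b, "mixed_field_spectrum"))
  g <- field_a$grid
  if (!grids_equal(g, field_b$grid)) stop("fields on different grids")
  extent <- g$n_slices * g$slice_thickness_mm
  if (abs(phantom_length_mm - extent) > 1e-6)
    stop(sprintf("phantom_length_mm %.6g inconsistent with grid extent %.6g",
                 phantom_length_mm, extent))
  rb <- field_b$records
  if (nrow(rb)) rb$slice_index <- g$n_slices - 1L - rb$slice_index
  mixed_field_spectrum(g, rbind(field_a$records, rb))
}

# ---- plan file I/O ----------------------------------------------------------

#' Write an SOBP plan to CSV
#'
#' Columns `energy_MeV_per_u,weight` with metadata lines `# ion=`,
#' `# plateau_mm=d1:d2`, `# prescription_Gy=`.
#' @param plan an [sobp_plan()]
#' @param path output path
#' @export
write_plan_csv <- function(plan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# ion=%s", plan$ion$token),
               sprintf("# plateau_mm=%s:%s", fmt_full(plan$plateau_mm[1]),
                       fmt_full(plan$plateau_mm[2])),
               sprintf("# prescription_Gy=%s", fmt_full(plan$prescription_Gy)),
               "energy_MeV_per_u,weight",
               paste(fmt_full(plan$energies_MeV_per_u),
                     fmt_full(plan$weights), sep = ",")), con)
  invisible(NULL)
}

#' Read an SOBP plan from CSV (see [write_plan_csv()])
#' @param path file path
#' @return an [sobp_plan()]
#' @export
read_plan_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read plan: ", path)
  meta <- read_meta_lines(path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (is.null(meta$ion) || is.null(meta$plateau_mm))
    stop("plan CSV must carry # ion= and # plateau_mm= metadata")
  plat <- as.numeric(strsplit(meta$plateau_mm, ":", fixed = TRUE)[[1]])
  presc <- if (is.null(meta$prescription_Gy)) 2.0
           else as.numeric(meta$prescription_Gy)
  sobp_plan(ion_species(meta$ion), df$energy_MeV_per_u, df$weight, plat, presc)
}
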