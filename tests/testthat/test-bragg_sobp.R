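# energies from Table-style clinical windows: MeV (total) and stated
# distal SOBP edges, used to sanity-check the range-energy fit
clinical_windows <- data.frame(
  ion = rep(c("p", "He", "C"), each = 3),
  A = rep(c(1, 4, 12), each = 3),
  d1_cm = rep(c(2, 5, 10), 3), d2_cm = rep(c(3, 8, 15), 3),
  e_min = c(46.2, 77.9, 115.5, 182, 308, 460, 998, 1730, 2610),
  e_max = c(58.2, 101.8, 145.5, 229, 404, 581, 1270, 2290, 3330))

test_that("range-energy fit lands within 1 cm of clinical distal edges", {
  for (i in seq_len(nrow(clinical_windows))) {
    row <- clinical_windows[i, ]
    r <- energy_to_range(ion_species(row$ion), row$e_max / row$A)
    expect_lt(abs(r - row$d2_cm), 1.0)
  }
})

test_that("range scaling law: He matches protons, inversion round-trips", {
  p <- ion_species("p"); he <- ion_species("He"); c12 <- ion_species("C")
  e <- c(10, 50, 100, 200)
  expect_equal(energy_to_range(he, e), energy_to_range(p, e))  # A/Z^2 = 1
  expect_lt(max(energy_to_range(c12, e) / energy_to_range(p, e)), 0.5)
  expect_equal(range_to_energy(p, energy_to_range(p, e)), e)
  expect_error(energy_to_range(p, -1), "positive")
})

test_that("pristine proton kernel is peaked near the range and falls fast", {
  p <- ion_species("p")
  grid <- depth_grid(90)
  k <- pristine_bragg_curve(p, range_to_energy(p, 8), grid)
  v <- k$depth_dose$values
  z <- slice_centers(grid)
  ipk <- which.max(v)
  expect_lt(abs(z[ipk] - k$range_cm * 10), 1.0)        # peak within 1 mm of R
  expect_true(all(diff(v[seq_len(ipk)]) > -1e-12))      # monotone rise
  expect_equal(v[1], 1)                                 # unit entrance dose
  sig_mm <- range_straggling_sigma(k$range_cm) * 10
  beyond <- z > z[ipk] + 3 * sig_mm
  expect_lt(max(v[beyond]), 0.01 * v[ipk])              # < 1% past 3 sigma
  expect_error(pristine_bragg_curve(p, range_to_energy(p, 9), grid), "short")
})

test_that("carbon kernel carries a fragmentation tail beyond the range", {
  c12 <- ion_species("C")
  grid <- depth_grid(120)
  k <- pristine_bragg_curve(c12, range_to_energy(c12, 8), grid,
                            tail_fraction = 0.1)
  z <- slice_centers(grid)
  expect_gt(k$depth_dose$values[which.min(abs(z - (k$range_cm * 10 + 20)))], 0)
  k0 <- pristine_bragg_curve(c12, range_to_energy(c12, 8), grid,
                             tail_fraction = 0)
  expect_lt(max(k0$depth_dose$values[z > k0$range_cm * 10 + 20]), 1e-6)
})

test_that("single-kernel design normalizes the peak slice", {
  p <- ion_species("p")
  grid <- depth_grid(40)
  k <- pristine_bragg_curve(p, range_to_energy(p, 2.5), grid)
  pk <- slice_centers(grid)[which.max(k$depth_dose$values)]
  plan <- design_sobp_weights(list(k), c(pk - 0.5, pk + 0.5))
  expect_equal(plan$weights, 1 / max(k$depth_dose$values), tolerance = 1e-10)
})

test_that("clinical-window proton plan is flat to 2% and weights non-negative", {
  sob <- build_sobp("p", c(20, 30), n_beams = 12, e_min = 46.2, e_max = 58.2)
  expect_true(all(sob$plan$weights >= 0))
  expect_lt(sobp_ripple(sob$profile, c(20, 30)), 0.02)
  idx <- slice_centers(sob$grid) >= 20 & slice_centers(sob$grid) <= 30
  expect_equal(mean(sob$profile$values[idx]), 2.0, tolerance = 1e-12)
  # distal 80% -> 20% fall-off well under 5 mm for the shallow proton case
  fall <- distal_falloff_depth(sob$profile, c(20, 30), 0.2) -
    distal_falloff_depth(sob$profile, c(20, 30), 0.8)
  expect_lt(fall, 5)
  expect_error(design_sobp_weights(sob$kernels, c(200, 300)), "infeasible")
})

test_that("composition is linear and matches a brute-force loop sum", {
  sob <- build_sobp("p", c(20, 30), n_beams = 12)
  plan <- sob$plan
  composed <- compose_sobp(plan, sob$kernels)
  # independent summation oracle
  oracle <- numeric(sob$grid$n_slices)
  for (i in seq_along(sob$kernels)) {
    ki <- sob$kernels[[i]]
    j <- which(abs(plan$energies_MeV_per_u - ki$energy_MeV_per_u) < 1e-9)
    oracle <- oracle + plan$weights[j] * ki$depth_dose$values
  }
  expect_equal(composed$values, oracle, tolerance = 1e-12)
  plan2 <- plan; plan2$weights <- 2 * plan$weights
  expect_equal(compose_sobp(plan2, sob$kernels)$values, 2 * composed$values)
  plan0 <- plan; plan0$weights <- 0 * plan$weights
  expect_equal(compose_sobp(plan0, sob$kernels)$values,
               numeric(sob$grid$n_slices))
})

test_that("prescription normalization is idempotent and hits the target", {
  sob <- build_sobp("p", c(20, 30))
  prof <- normalize_to_prescription(sob$profile, c(20, 30), 2.0)
  idx <- plateau_idx <- which(slice_centers(prof$grid) >= 20 &
                              slice_centers(prof$grid) <= 30)
  expect_equal(mean(prof$values[idx]), 2.0, tolerance = 1e-12)
  again <- normalize_to_prescription(prof, c(20, 30), 2.0)
  expect_equal(again$values, prof$values, tolerance = 1e-14)
  half <- normalize_to_prescription(prof, c(20, 30), 1.0)
  expect_equal(half$values, prof$values / 2)
})

test_that("opposing-field composition mirrors, conserves and symmetrizes", {
  g <- depth_grid(5)
  mk <- function(doses) mixed_field_spectrum(g, data.frame(
    slice_index = 0:4, species = "p", energy_MeV_per_u = 50,
    dose_Gy_per_primary = doses))
  a <- mk(c(5, 4, 3, 2, 1))
  b <- mk(c(5, 4, 3, 2, 1))
  comp <- compose_opposing_fields(a, b, 5)
  tot <- total_dose_profile(comp)$values
  expect_equal(tot, rev(tot), tolerance = 1e-12)                 # symmetric
  expect_equal(tot, c(5, 4, 3, 2, 1) + c(1, 2, 3, 4, 5))         # hand sum
  expect_equal(sum(tot), sum(a$records$dose_Gy_per_primary) +
                 sum(b$records$dose_Gy_per_primary))             # conserved
  empty <- mixed_field_spectrum(g, data.frame(
    slice_index = integer(), species = character(),
    energy_MeV_per_u = numeric(), dose_Gy_per_primary = numeric()))
  expect_equal(total_dose_profile(compose_opposing_fields(a, empty, 5))$values,
               total_dose_profile(a)$values)
  expect_error(compose_opposing_fields(a, b, 7), "inconsistent")
})

test_that("plan CSV round-trips energies, weights and metadata", {
  sob <- build_sobp("C", c(20, 30))
  f <- withr::local_tempfile(fileext = ".csv")
  write_plan_csv(sob$plan, f)
  plan2 <- read_plan_csv(f)
  expect_identical(plan2$energies_MeV_per_u, sob$plan$energies_MeV_per_u)
  expect_identical(plan2$weights, sob$plan$weights)
  expect_identical(plan2$ion$token, "C")
  expect_identical(plan2$plateau_mm, c(20, 30))
})
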