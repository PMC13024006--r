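test_that("alpha/beta ratios of the built-in cell lines", {
  expect_equal(round(alpha_beta_ratio(cell_line_scc()), 2), 12.68)
  expect_equal(round(alpha_beta_ratio(cell_line_chordoma()), 2), 2.37)
  expect_equal(alpha_beta_ratio(cell_line("x", 1, 1)), 1.0)
})

test_that("lookup interpolates alpha and sqrt(beta) in log-energy", {
  tab <- two_node_table(e = c(10, 100), alpha = c(0.2, 0.4),
                        beta = c(0.01, 0.09))
  # grid nodes reproduce stored values exactly
  at10 <- lookup_alpha_beta(tab, "p", 10)
  expect_equal(at10$alpha, 0.2)
  expect_equal(at10$beta, 0.01)
  # log-midpoint: alpha is the plain midpoint, beta via sqrt-averaging
  mid <- lookup_alpha_beta(tab, "p", sqrt(10 * 100))
  expect_equal(mid$alpha, 0.3)
  expect_equal(mid$beta, ((sqrt(0.01) + sqrt(0.09)) / 2)^2)  # 0.04, not 0.05
  # outside the grid clamps to the endpoint, with a warning
  expect_warning(lo <- lookup_alpha_beta(tab, "p", 1), "clamped")
  expect_equal(lo$alpha, 0.2)
  # absent species (incl. "other") falls back to photon coefficients
  expect_warning(ab <- lookup_alpha_beta(tab, "other", 50), "photon")
  expect_equal(ab$alpha, tab$cell_line$alpha_x)
  expect_equal(ab$beta, tab$cell_line$beta_x)
  expect_error(lookup_alpha_beta(tab, "p", -5), "positive")
})

test_that("Zaider-Rossi mixing: identity, hand case, invariances", {
  one <- mix_coefficients(1, 0.2, 0.05)
  expect_identical(one$alpha, 0.2)
  expect_identical(one$beta, 0.05)
  # hand evaluation: beta is the dose-averaged sqrt, squared — NOT 0.05
  mx <- mix_coefficients(c(1, 1), c(0.1, 0.3), c(0.01, 0.09))
  expect_equal(mx$alpha, 0.2)
  expect_equal(mx$beta, 0.04)
  # order invariance and zero-dose component invariance
  mx2 <- mix_coefficients(c(1, 1, 0), c(0.3, 0.1, 9), c(0.09, 0.01, 9))
  expect_equal(mx2$alpha, mx$alpha)
  expect_equal(mx2$beta, mx$beta)
  # splitting a component in two with the same coefficients changes nothing
  mx3 <- mix_coefficients(c(0.5, 0.5, 1), c(0.1, 0.1, 0.3),
                          c(0.01, 0.01, 0.09))
  expect_equal(mx3$alpha, mx$alpha)
  expect_equal(mx3$beta, mx$beta)
  expect_error(mix_coefficients(c(0, 0), c(1, 1), c(1, 1)), "zero")
})

test_that("mixed beta lies between the component extremes", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    d <- stats::runif(n, 0.01, 2)
    b <- stats::runif(n, 0.001, 0.2)
    mx <- mix_coefficients(d, stats::runif(n, 0.05, 1), b)
    expect_gte(mx$beta, min(b) - 1e-12)
    expect_lte(mx$beta, max(b) + 1e-12)
  }
})

test_that("LQ survival closed forms at 2 Gy photon fields", {
  expect_equal(survival_lq(0, 0, 5), 1)
  expect_equal(survival_lq(0.379, 0.0299, 0), 1)
  expect_equal(survival_lq(0.379, 0.0299, 2), exp(-0.8776))
  expect_equal(survival_lq(0.379, 0.0299, 2), 0.4158, tolerance = 1e-4)
  expect_equal(survival_lq(0.1567, 0.0661, 2), 0.5611, tolerance = 1e-4)
  expect_error(survival_lq(0.1, 0.01, -1), "non-negative")
})

test_that("RBE/Gy-Eq: photon identity, quadratic inversion, round-trip", {
  ch <- cell_line_chordoma()
  # a field with exactly photon coefficients has RBE 1, Gy-Eq = dose
  rg <- rbe_gyeq(ch$alpha_x, ch$beta_x, 1.5, ch)
  expect_equal(rg$rbe, 1.0, tolerance = 1e-12)
  expect_equal(rg$gyeq_Gy, 1.5, tolerance = 1e-12)
  # chordoma, E = alpha*D + beta*D^2 = 1.0 at D = 1.5 Gy
  a <- (1.0 - ch$beta_x * 1.5^2) / 1.5   # alpha chosen so E = 1 exactly
  rg2 <- rbe_gyeq(a, ch$beta_x, 1.5, ch)
  expect_equal(rg2$gyeq_Gy, 2.881, tolerance = 1e-3)
  expect_equal(rg2$rbe, 1.921, tolerance = 1e-3)
  # iso-effect round-trip
  expect_equal(survival_lq(ch$alpha_x, ch$beta_x, rg2$gyeq_Gy),
               survival_lq(a, ch$beta_x, 1.5), tolerance = 1e-10)
  # linear limit: beta -> 0 gives rbe -> alpha / alpha_x
  sc <- cell_line("lin", 0.3, 1e-12)
  expect_equal(rbe_gyeq(0.6, 0, 2, sc)$rbe, 2, tolerance = 1e-6)
  # zero dose: flagged RBE, zero Gy-Eq
  z <- rbe_gyeq(0.5, 0.05, 0, ch)
  expect_true(is.na(z$rbe))
  expect_equal(z$gyeq_Gy, 0)
})

test_that("RBE round-trip holds over random draws", {
  set.seed(11)
  cell <- cell_line_scc()
  a <- stats::runif(1000, 0.05, 2)
  b <- stats::runif(1000, 0.001, 0.3)
  d <- stats::runif(1000, 0.1, 6)
  rg <- rbe_gyeq(a, b, d, cell)
  expect_equal(survival_lq(cell$alpha_x, cell$beta_x, rg$gyeq_Gy),
               survival_lq(a, b, d), tolerance = 1e-10)
  expect_equal(rg$gyeq_Gy, d * rg$rbe, tolerance = 1e-12)
})

test_that("mix_spectrum matches the per-slice oracle and flags empty slices", {
  tab <- two_node_table()
  g <- depth_grid(3)
  s <- mixed_field_spectrum(g, data.frame(
    slice_index = c(0, 0, 2), species = "p",
    energy_MeV_per_u = c(10, 100, 10),
    dose_Gy_per_primary = c(1, 1, 2)))
  mx <- mix_spectrum(s, tab)
  oracle <- mix_coefficients(c(1, 1), c(0.2, 0.4), c(0.01, 0.09))
  expect_equal(mx$alpha[1], oracle$alpha)
  expect_equal(mx$beta[1], oracle$beta)
  expect_true(is.na(mx$alpha[2]))        # zero-dose slice flagged undefined
  expect_equal(mx$alpha[3], 0.2)
  expect_equal(mx$dose, c(2, 0, 2))
})

test_that("bio_profile: photon fallback, Gy-Eq identity, dose monotonicity", {
  cell <- cell_line_scc()
  tab <- radiosensitivity_table(cell, data.frame(
    species = "He", energy_MeV_per_u = c(1, 10), alpha = c(1, 1),
    beta = c(0.01, 0.01)))
  # pure-"other" spectrum at uniform 2 Gy -> flat photon survival
  g <- depth_grid(4)
  s <- mixed_field_spectrum(g, data.frame(
    slice_index = 0:3, species = "other", energy_MeV_per_u = 1,
    dose_Gy_per_primary = 2))
  bp <- suppressWarnings(bio_profile(s, tab))
  expect_equal(bp$slices$survival,
               rep(survival_lq(cell$alpha_x, cell$beta_x, 2), 4))
  expect_equal(bp$slices$rbe, rep(1, 4), tolerance = 1e-12)
  expect_equal(bp$slices$gyeq, bp$slices$dose * bp$slices$rbe)
  # alpha increasing with depth (via decreasing energy) -> survival minimum
  # at the distal end of a uniform-dose segment
  tab2 <- two_node_table(species = "p", e = c(5, 200),
                         alpha = c(0.9, 0.1), beta = c(0.05, 0.01))
  s2 <- mixed_field_spectrum(g, data.frame(
    slice_index = 0:3, species = "p",
    energy_MeV_per_u = c(150, 80, 30, 8),   # slowing down with depth
    dose_Gy_per_primary = 2))
  bp2 <- bio_profile(s2, tab2)
  expect_equal(which.min(bp2$slices$survival), 4L)
  expect_true(all(diff(bp2$slices$survival) < 0))
})

test_that("radiosensitivity table CSV round-trips", {
  tab <- scc_table()
  f <- withr::local_tempfile(fileext = ".csv")
  write_radiosensitivity_csv(tab, f)
  tab2 <- read_radiosensitivity_csv(f)
  expect_equal(tab2$cell_line$alpha_x, tab$cell_line$alpha_x)
  expect_identical(names(tab2$by_species), names(tab$by_species))
  for (sp in names(tab$by_species))
    expect_equal(tab2$by_species[[sp]]$alpha, tab$by_species[[sp]]$alpha)
  q1 <- lookup_alpha_beta(tab, "C", 37)
  q2 <- lookup_alpha_beta(tab2, "C", 37)
  expect_equal(q1$alpha, q2$alpha)
  expect_equal(q1$beta, q2$beta)
})
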