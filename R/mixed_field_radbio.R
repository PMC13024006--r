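# Mixed-field radiobiology: dose-averaged linear-quadratic coefficients
# (Zaider-Rossi mixing), cell survival, RBE and Gy-Eq dose.
#
# For a voxel receiving dose D_i from radiation component i with LQ
# coefficients (alpha_i, beta_i), the mixed-field coefficients are
#   alpha = sum(alpha_i D_i) / sum(D_i)
#   beta  = ( sum(sqrt(beta_i) D_i) / sum(D_i) )^2
# and survival at the voxel's TOTAL dose D is S = exp(-alpha D - beta D^2).

#' Cell line with photon radiosensitivity coefficients
#'
#' @param name cell line label
#' @param alpha_x photon linear coefficient (1/Gy), positive
#' @param beta_x photon quadratic coefficient (1/Gy^2), positive
#' @return an object of class `cell_line`
#' @export
cell_line <- function(name, alpha_x, beta_x) {
  stopifnot(is.character(name), alpha_x > 0, beta_x > 0)
  structure(list(name = name, alpha_x = as.numeric(alpha_x),
                 beta_x = as.numeric(beta_x)),
            class = "cell_line")
}

#' Built-in tumour cell lines
#'
#' Squamous Cell Carcinoma (radiosensitive, alpha_x = 0.379 / Gy,
#' beta_x = 0.0299 / Gy^2, alpha/beta = 12.68 Gy) and human chordoma
#' (radioresistant, alpha_x = 0.1567 / Gy, beta_x = 0.0661 / Gy^2,
#' alpha/beta = 2.37 Gy).
#'
#' @return a [cell_line()]
#' @export
cell_line_scc <- function() cell_line("SCC", 0.379, 0.0299)

#' @rdname cell_line_scc
#' @export
cell_line_chordoma <- function() cell_line("chordoma", 0.1567, 0.0661)

#' alpha/beta ratio of a cell line (Gy)
#' @param cell a [cell_line()]
#' @return `alpha_x / beta_x` in Gy
#' @export
alpha_beta_ratio <- function(cell) {
  stopifnot(inherits(cell, "cell_line"))
  cell$alpha_x / cell$beta_x
}

#' Per-species, energy-indexed radiosensitivity table
#'
#' Holds the LQ coefficients (alpha_i, beta_i) for monoenergetic beams of
#' each species, indexed by kinetic energy per nucleon.  Queries interpolate
#' alpha and sqrt(beta) linearly in log(energy); species without entries
#' (including `"other"`) fall back to the photon coefficients of the cell
#' line, which keeps the mixing denominator equal to the total physical dose.
#'
#' @param cell a [cell_line()]
#' @param entries data.frame with columns `species`, `energy_MeV_per_u`,
#'   `alpha_Gy-1` (or `alpha`), `beta_Gy-2` (or `beta`); energies strictly
#'   increasing within each species
#' @return an object of class `radiosensitivity_table`
#' @export
radiosensitivity_table <- function(cell, entries) {
  stopifnot(inherits(cell, "cell_line"), is.data.frame(entries))
  nm <- names(entries)
  nm[nm == "alpha_Gy-1"] <- "alpha"
  nm[nm == "beta_Gy-2"] <- "beta"
  names(entries) <- nm
  need <- c("species", "energy_MeV_per_u", "alpha", "beta")
  if (!all(need %in% names(entries)))
    stop("entries must have columns ", paste(need, collapse = ", "))
  entries <- entries[, need]
  entries$species <- as.character(entries$species)
  if (any(entries$energy_MeV_per_u <= 0)) stop("energies must be positive")
  if (any(entries$alpha < 0) || any(entries$beta < 0))
    stop("alpha and beta must be non-negative")
  by_sp <- split(entries, entries$species)
  for (sp in names(by_sp)) {
    e <- by_sp[[sp]]$energy_MeV_per_u
    if (is.unsorted(e, strictly = TRUE))
      stop("energies must be strictly increasing within species ", sp)
  }
  structure(list(cell_line = cell, by_species = by_sp),
            class = "radiosensitivity_table")
}

#' @export
print.radiosensitivity_table <- function(x, ...) {
  cat(sprintf("radiosensitivity_table for %s (alpha/beta = %.2f Gy): %s\n",
              x$cell_line$name, alpha_beta_ratio(x$cell_line),
              paste(sprintf("%s[%d]", names(x$by_species),
                            vapply(x$by_species, nrow, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Look up LQ coefficients for one species at given energies
#'
#' Linear interpolation of alpha and of sqrt(beta) in log(energy).  Energies
#' outside the tabulated grid are clamped to the nearest endpoint with a
#' warning; species not in the table (including `"other"`) return the photon
#' coefficients.
#'
#' @param table a [radiosensitivity_table()]
#' @param species single canonical species token
#' @param energy_MeV_per_u positive energies (MeV/u), vectorised
#' @param warn warn on clamped energies and photon fallback (default TRUE)
#' @return list with numeric fields `alpha` and `beta`
#' @export
lookup_alpha_beta <- function(table, species, energy_MeV_per_u, warn = TRUE) {
  stopifnot(inherits(table, "radiosensitivity_table"), length(species) == 1L)
  if (any(energy_MeV_per_u <= 0)) stop("energy must be positive")
  tab <- table$by_species[[species]]
  if (is.null(tab)) {
    if (warn)
      warning("species \"", species,
              "\" not in table; using photon coefficients")
    n <- length(energy_MeV_per_u)
    return(list(alpha = rep(table$cell_line$alpha_x, n),
                beta = rep(table$cell_line$beta_x, n)))
  }
  le <- log(energy_MeV_per_u)
  lg <- log(tab$energy_MeV_per_u)
  outside <- le < lg[1] | le > lg[length(lg)]
  if (any(outside) && warn)
    warning(sum(outside), " energie(s) outside the ", species,
            " grid; clamped to the nearest endpoint")
  if (nrow(tab) == 1L) {
    alpha <- rep(tab$alpha, length(le))
    beta <- rep(tab$beta, length(le))
  } else {
    alpha <- stats::approx(lg, tab$alpha, xout = le, rule = 2)$y
    beta <- stats::approx(lg, sqrt(tab$beta), xout = le, rule = 2)$y^2
  }
  list(alpha = alpha, beta = beta)
}

#' Dose-averaged LQ coefficients of a mixed field
#'
#' Zaider-Rossi mixing: `alpha = sum(alpha_i D_i)/sum(D_i)` and
#' `beta = (sum(sqrt(beta_i) D_i)/sum(D_i))^2` — the square root of beta is
#' dose-averaged, then squared.
#'
#' @param doses non-negative component doses `D_i`, total > 0
#' @param alphas,betas component coefficients, same length
#' @return list with fields `alpha`, `beta`
#' @export
mix_coefficients <- function(doses, alphas, betas) {
  n <- length(doses)
  if (n < 1L || length(alphas) != n || length(betas) != n)
    stop("doses, alphas, betas must have equal length >= 1")
  if (any(doses < 0)) stop("component doses must be non-negative")
  if (any(alphas < 0) || any(betas < 0))
    stop("component coefficients must be non-negative")
  tot <- sum(doses)
  if (tot <= 0) stop("total dose is zero: mixed coefficients undefined")
  if (n == 1L) return(list(alpha = alphas, beta = betas))  # exact identity
  list(alpha = sum(alphas * doses) / tot,
       beta = (sum(sqrt(betas) * doses) / tot)^2)
}

#' Per-slice mixed LQ coefficients of a spectrum
#'
#' Applies [lookup_alpha_beta()] to every record and [mix_coefficients()] in
#' every slice.  Slices with zero total dose get `NA` coefficients (flagged
#' undefined; downstream survival treats them as fully surviving and
#' comparisons exclude them).
#'
#' @param spectrum a [mixed_field_spectrum()]
#' @param table a [radiosensitivity_table()]
#' @param warn passed to [lookup_alpha_beta()]
#' @return data.frame with one row per slice: `slice_index` (0-based),
#'   `dose`, `alpha`, `beta`
#' @export
mix_spectrum <- function(spectrum, table, warn = TRUE) {
  stopifnot(inherits(spectrum, "mixed_field_spectrum"),
            inherits(table, "radiosensitivity_table"))
  n <- spectrum$grid$n_slices
  rec <- spectrum$records
  out <- data.frame(slice_index = 0:(n - 1L), dose = 0,
                    alpha = NA_real_, beta = NA_real_)
  if (nrow(rec)) {
    al <- numeric(nrow(rec)); be <- numeric(nrow(rec))
    for (sp in unique(rec$species)) {
      i <- rec$species == sp
      ab <- lookup_alpha_beta(table, sp, rec$energy_MeV_per_u[i], warn = warn)
      al[i] <- ab$alpha
      be[i] <- ab$beta
    }
    d <- rec$dose_Gy_per_primary
    g <- rec$slice_index
    tot <- rowsum(d, g); sa <- rowsum(al * d, g); sb <- rowsum(sqrt(be) * d, g)
    idx <- as.integer(rownames(tot)) + 1L
    pos <- tot[, 1] > 0
    out$dose[idx] <- tot[, 1]
    out$alpha[idx[pos]] <- (sa[, 1] / tot[, 1])[pos]
    out$beta[idx[pos]] <- ((sb[, 1] / tot[, 1])^2)[pos]
  }
  out
}

#' Linear-quadratic cell survival
#'
#' `S = exp(-alpha*D - beta*D^2)`, monotone non-increasing in dose.
#'
#' @param alpha linear coefficient (1/Gy)
#' @param beta quadratic coefficient (1/Gy^2)
#' @param dose_Gy absorbed dose (Gy), non-negative; vectorised
#' @return surviving fraction in (0, 1]
#' @export
survival_lq <- function(alpha, beta, dose_Gy) {
  if (any(dose_Gy < 0)) stop("dose must be non-negative")
  exp(-alpha * dose_Gy - beta * dose_Gy^2)
}

#' RBE and Gy-Eq dose at equal survival
#'
#' Given mixed-field coefficients (alpha, beta) and dose D, the photon
#' iso-effect dose solves `alpha_x D_x + beta_x D_x^2 = alpha D + beta D^2`:
#' `D_x = (-alpha_x + sqrt(alpha_x^2 + 4 beta_x E)) / (2 beta_x)` with
#' `E = alpha D + beta D^2`.  RBE = D_x / D and the Gy-Eq dose is D_x itself
#' (the photon dose giving the same survival).  At zero dose RBE is
#' undefined (`NA`) and Gy-Eq is 0.
#'
#' @param alpha,beta mixed-field LQ coefficients, vectorised
#' @param dose_Gy absorbed dose (Gy), non-negative
#' @param cell a [cell_line()] supplying alpha_x, beta_x
#' @return list with numeric fields `rbe` and `gyeq_Gy`
#' @export
rbe_gyeq <- function(alpha, beta, dose_Gy, cell) {
  stopifnot(inherits(cell, "cell_line"))
  if (any(dose_Gy < 0)) stop("dose must be non-negative")
  E <- alpha * dose_Gy + beta * dose_Gy^2
  # rationalized form of (-a_x + sqrt(a_x^2 + 4 b_x E)) / (2 b_x): avoids
  # the subtractive cancellation when beta_x*E << alpha_x^2
  dx <- 2 * E / (cell$alpha_x + sqrt(cell$alpha_x^2 + 4 * cell$beta_x * E))
  rbe <- ifelse(dose_Gy > 0, dx / dose_Gy, NA_real_)
  gyeq <- ifelse(dose_Gy > 0, dx, 0)
  list(rbe = rbe, gyeq_Gy = gyeq)
}

#' Full radiobiological depth profile of a mixed-field spectrum
#'
#' Per slice: total dose, mixed LQ coefficients, survival at the slice total
#' dose, RBE and Gy-Eq dose.  Zero-dose slices carry survival 1, RBE `NA`
#' and Gy-Eq 0.
#'
#' @param spectrum a [mixed_field_spectrum()]
#' @param table a [radiosensitivity_table()]
#' @param cell a [cell_line()]; defaults to the table's cell line
#' @param warn passed to [lookup_alpha_beta()]
#' @return an object of class `bio_profile`: list with `grid`, and a
#'   data.frame `slices` with columns `depth_mm`, `dose`, `alpha`, `beta`,
#'   `survival`, `sigma_survival`, `rbe`, `gyeq`
#' @export
bio_profile <- function(spectrum, table, cell = table$cell_line, warn = TRUE) {
  mx <- mix_spectrum(spectrum, table, warn = warn)
  ok <- !is.na(mx$alpha)
  surv <- rep(1, nrow(mx))
  surv[ok] <- survival_lq(mx$alpha[ok], mx$beta[ok], mx$dose[ok])
  rbe <- rep(NA_real_, nrow(mx)); gyeq <- numeric(nrow(mx))
  if (any(ok)) {
    rg <- rbe_gyeq(mx$alpha[ok], mx$beta[ok], mx$dose[ok], cell)
    rbe[ok] <- rg$rbe
    gyeq[ok] <- rg$gyeq_Gy
  }
  slices <- data.frame(depth_mm = slice_centers(spectrum$grid),
                       dose = mx$dose, alpha = mx$alpha, beta = mx$beta,
                       survival = surv, sigma_survival = 0,
                       rbe = rbe, gyeq = gyeq)
  structure(list(grid = spectrum$grid, cell_line = cell, slices = slices),
            class = "bio_profile")
}

#' @export
print.bio_profile <- function(x, ...) {
  cat(sprintf("bio_profile (%s): %d slices, min survival %.4g\n",
              x$cell_line$name, x$grid$n_slices, min(x$slices$survival)))
  invisible(x)
}

# ---- radiosensitivity table I/O --------------------------------------------

#' Write a radiosensitivity table to CSV
#'
#' Columns `species,energy_MeV_per_u,alpha_Gy-1,beta_Gy-2` with metadata
#' `# cell_line=`, `# alpha_x=`, `# beta_x=`.
#' @param table a [radiosensitivity_table()]
#' @param path output path
#' @export
write_radiosensitivity_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cl <- table$cell_line
  writeLines(c(sprintf("# cell_line=%s", cl$name),
               sprintf("# alpha_x=%s", fmt_full(cl$alpha_x)),
               sprintf("# beta_x=%s", fmt_full(cl$beta_x)),
               "species,energy_MeV_per_u,alpha_Gy-1,beta_Gy-2"), con)
  for (sp in names(table$by_species)) {
    t <- table$by_species[[sp]]
    writeLines(paste(sp, fmt_full(t$energy_MeV_per_u),
                     fmt_full(t$alpha), fmt_full(t$beta), sep = ","), con)
  }
  invisible(NULL)
}

#' Read a radiosensitivity table from CSV (see
#' [write_radiosensitivity_csv()])
#' @param path file path
#' @return a [radiosensitivity_table()]
#' @export
read_radiosensitivity_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read radiosensitivity table: ", path)
  meta <- read_meta_lines(path)
  if (is.null(meta$cell_line) || is.null(meta$alpha_x) || is.null(meta$beta_x))
    stop("table CSV must carry # cell_line=, # alpha_x=, # beta_x= metadata")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  radiosensitivity_table(
    cell_line(meta$cell_line, as.numeric(meta$alpha_x),
              as.numeric(meta$beta_x)),
    df)
}
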