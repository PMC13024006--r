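# Depth-grid and profile data model plus CSV readers/writers.
#
# Geometry convention: 1D water phantom scored in uniform slices along the
# beam axis.  Files report slice CENTERS; slice i covers the half-open
# interval [origin + i*dz, origin + (i+1)*dz).  slice_index is 0-based in
# files and in the record table, matching the scorer convention.

#' Canonical species tokens recognised by the mixed-field machinery
#' @keywords internal
.species_tokens <- c("p", "He", "Li", "Be", "B", "C", "other")

# alias map from common MC output labels to the canonical tokens
.species_aliases <- c(
  p = "p", H = "p", H1 = "p", proton = "p", protons = "p",
  He = "He", He3 = "He", He4 = "He", alpha = "He", helium = "He",
  Li = "Li", Li6 = "Li", Li7 = "Li", lithium = "Li",
  Be = "Be", Be7 = "Be", Be9 = "Be", Be10 = "Be", beryllium = "Be",
  B = "B", B10 = "B", B11 = "B", boron = "B",
  C = "C", C11 = "C", C12 = "C", C13 = "C", carbon = "C",
  other = "other"
)

#' Uniform depth grid along the beam axis
#'
#' Slice centers are `origin_mm + (i + 0.5) * slice_thickness_mm` for
#' `i = 0, ..., n_slices - 1`; slice `i` covers the half-open interval
#' `[origin + i*dz, origin + (i+1)*dz)`.
#'
#' @param n_slices positive integer number of scoring slices
#' @param slice_thickness_mm slice thickness in mm (default 1.0)
#' @param origin_mm depth of the phantom entrance in mm (default 0)
#' @return an object of class `depth_grid`
#' @export
depth_grid <- function(n_slices, slice_thickness_mm = 1.0, origin_mm = 0.0) {
  n_slices <- as.integer(n_slices)
  stopifnot(length(n_slices) == 1L, n_slices >= 1L,
            is.numeric(slice_thickness_mm), slice_thickness_mm > 0,
            is.numeric(origin_mm), length(origin_mm) == 1L)
  structure(list(n_slices = n_slices,
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "depth_grid")
}

#' Slice-center depths of a grid
#' @param grid a [depth_grid()]
#' @return numeric vector of slice-center depths in mm
#' @export
slice_centers <- function(grid) {
  stopifnot(inherits(grid, "depth_grid"))
  grid$origin_mm + (seq_len(grid$n_slices) - 0.5) * grid$slice_thickness_mm
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf("depth_grid: %d slices x %.6g mm, origin %.6g mm\n",
              x$n_slices, x$slice_thickness_mm, x$origin_mm))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_slices == b$n_slices &&
    abs(a$slice_thickness_mm - b$slice_thickness_mm) <= tol &&
    abs(a$origin_mm - b$origin_mm) <= tol
}

#' Depth-dose (or derived quantity) profile on a grid
#'
#' @param grid a [depth_grid()]
#' @param values per-slice non-negative values (Gy, or dimensionless when
#'   normalized)
#' @param sigma per-slice uncertainties, same units; recycled from a scalar
#' @param unit_tag `"absolute_Gy"` or `"normalized"`
#' @return an object of class `dose_profile`
#' @export
dose_profile <- function(grid, values, sigma = 0,
                         unit_tag = c("absolute_Gy", "normalized")) {
  stopifnot(inherits(grid, "depth_grid"))
  unit_tag <- match.arg(unit_tag)
  values <- as.numeric(values)
  if (length(sigma) == 1L) sigma <- rep(as.numeric(sigma), length(values))
  sigma <- as.numeric(sigma)
  if (length(values) != grid$n_slices)
    stop("profile length ", length(values), " does not match grid (",
         grid$n_slices, " slices)")
  if (length(sigma) != length(values))
    stop("sigma length does not match values")
  if (any(!is.finite(values)) || any(values < 0))
    stop("profile values must be finite and non-negative")
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("profile sigma must be finite and non-negative")
  structure(list(grid = grid, values = values, sigma = sigma,
                 unit_tag = unit_tag),
            class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf("dose_profile [%s]: %d slices, max %.4g, total %.4g\n",
              x$unit_tag, x$grid$n_slices, max(x$values), sum(x$values)))
  invisible(x)
}

#' Normalize species labels to the canonical token set
#'
#' Common Monte Carlo output labels (`"H"`, `"He4"`, `"C12"`, ...) are mapped
#' to the seven canonical tokens; anything unrecognised folds into `"other"`
#' with a warning, so that per-slice dose sums stay complete.
#'
#' @param species character vector of species labels
#' @return character vector of canonical tokens
#' @export
normalize_species <- function(species) {
  species <- as.character(species)
  out <- unname(.species_aliases[species])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown species token(s) mapped to \"other\": ",
            paste(unique(species[unknown]), collapse = ", "))
    out[unknown] <- "other"
  }
  out
}

#' Per-depth mixed-field dose spectrum
#'
#' Container for the per-slice dose decomposition by particle species and
#' kinetic energy per nucleon: one record per (slice, species, energy)
#' component, the inputs of the dose-averaged coefficient mixing.
#'
#' @param grid a [depth_grid()]
#' @param records data.frame with columns `slice_index` (0-based integer),
#'   `species`, `energy_MeV_per_u`, `dose_Gy_per_primary`
#' @return an object of class `mixed_field_spectrum`
#' @export
mixed_field_spectrum <- function(grid, records) {
  stopifnot(inherits(grid, "depth_grid"), is.data.frame(records))
  need <- c("slice_index", "species", "energy_MeV_per_u", "dose_Gy_per_primary")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records <- records[, need, drop = FALSE]
  records$slice_index <- as.integer(records$slice_index)
  records$species <- as.character(records$species)
  records$energy_MeV_per_u <- as.numeric(records$energy_MeV_per_u)
  records$dose_Gy_per_primary <- as.numeric(records$dose_Gy_per_primary)
  if (nrow(records)) {
    if (any(records$slice_index < 0L | records$slice_index >= grid$n_slices))
      stop("slice_index out of range [0, ", grid$n_slices, ")")
    if (any(!records$species %in% .species_tokens))
      stop("species must be canonical tokens; use normalize_species() first")
    if (any(records$energy_MeV_per_u <= 0))
      stop("energy_MeV_per_u must be positive")
    if (any(records$dose_Gy_per_primary < 0))
      stop("dose_Gy_per_primary must be non-negative")
  }
  rownames(records) <- NULL
  structure(list(grid = grid, records = records),
            class = "mixed_field_spectrum")
}

#' @export
print.mixed_field_spectrum <- function(x, ...) {
  cat(sprintf("mixed_field_spectrum: %d records on %d slices; species: %s\n",
              nrow(x$records), x$grid$n_slices,
              paste(sort(unique(x$records$species)), collapse = ", ")))
  invisible(x)
}

#' Set of repeated independent runs of one quantity
#'
#' @param runs list (length >= 2) of `dose_profile` or `mixed_field_spectrum`
#'   objects sharing one grid
#' @param n_primaries_per_run number of primary particles per run (metadata)
#' @return an object of class `run_set`
#' @export
run_set <- function(runs, n_primaries_per_run = NA_real_) {
  stopifnot(is.list(runs), length(runs) >= 2L)
  is_prof <- vapply(runs, inherits, logical(1), "dose_profile")
  is_spec <- vapply(runs, inherits, logical(1), "mixed_field_spectrum")
  if (!(all(is_prof) || all(is_spec)))
    stop("runs must all be dose_profile or all mixed_field_spectrum")
  g <- runs[[1]]$grid
  for (r in runs[-1]) if (!grids_equal(g, r$grid)) stop("runs on different grids")
  structure(list(runs = runs, n_primaries_per_run = n_primaries_per_run,
                 kind = if (all(is_prof)) "profile" else "spectrum"),
            class = "run_set")
}

# ---- CSV helpers ------------------------------------------------------------

read_meta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  metas <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (m in metas) {
    m <- sub("^#\\s*", "", m)
    eq <- regexpr("=", m, fixed = TRUE)
    if (eq > 0) kv[[substr(m, 1, eq - 1)]] <- substring(m, eq + 1)
  }
  kv
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Read a depth profile from CSV
#'
#' Expects columns `depth_mm,value,sigma`, with depths at slice centers of a
#' uniform grid; `#`-prefixed metadata lines (e.g. `# unit=normalized`) are
#' honoured.
#'
#' @param path file path
#' @return a [dose_profile()]
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read profile: ", path)
  meta <- read_meta_lines(path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  need <- c("depth_mm", "value", "sigma")
  if (!all(need %in% names(df)))
    stop("profile CSV must have header depth_mm,value,sigma")
  depth <- as.numeric(df$depth_mm)
  n <- length(depth)
  if (n == 0L) stop("empty profile file")
  if (n >= 2L) {
    dz <- diff(depth)
    thickness <- dz[1]
    if (any(abs(dz - thickness) > 1e-6))
      stop("non-uniform depth spacing: cannot reconstruct a uniform grid")
  } else {
    thickness <- 1.0   # single-slice files assume the default 1 mm slice
  }
  origin <- depth[1] - thickness / 2
  grid <- depth_grid(n, thickness, origin)
  if (any(abs(slice_centers(grid) - depth) > 1e-6))
    stop("depths are not consistent slice centers of a uniform grid")
  unit <- if (identical(meta$unit, "normalized")) "normalized" else "absolute_Gy"
  dose_profile(grid, df$value, df$sigma, unit_tag = unit)
}

#' Write a depth profile to CSV
#'
#' Fixed column order `depth_mm,value,sigma` at full float precision
#' (round-trip exact); the unit tag is recorded as `# unit=...`.
#'
#' @param profile a [dose_profile()]
#' @param path output file path
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "dose_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit=%s", profile$unit_tag), con)
  writeLines("depth_mm,value,sigma", con)
  writeLines(paste(fmt_full(slice_centers(profile$grid)),
                   fmt_full(profile$values),
                   fmt_full(profile$sigma), sep = ","), con)
  invisible(NULL)
}

#' Read a mixed-field spectrum from CSV
#'
#' Expects header `slice_index,species,energy_MeV_per_u,dose_Gy_per_primary`
#' with 0-based slice indices validated against `grid`.  Species labels are
#' passed through [normalize_species()]; unrecognised labels fold into
#' `"other"` with a warning.
#'
#' @param path file path
#' @param grid the [depth_grid()] the records refer to
#' @return a [mixed_field_spectrum()]
#' @export
read_spectrum_csv <- function(path, grid) {
  if (!file.exists(path)) stop("cannot read spectrum: ", path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  need <- c("slice_index", "species", "energy_MeV_per_u", "dose_Gy_per_primary")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have header ", paste(need, collapse = ","))
  df$species <- normalize_species(df$species)
  mixed_field_spectrum(grid, df)
}

#' Write a mixed-field spectrum to CSV
#' @param spectrum a [mixed_field_spectrum()]
#' @param path output file path
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mixed_field_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("slice_index,species,energy_MeV_per_u,dose_Gy_per_primary", con)
  r <- spectrum$records
  writeLines(paste(r$slice_index, r$species,
                   fmt_full(r$energy_MeV_per_u),
                   fmt_full(r$dose_Gy_per_primary), sep = ","), con)
  invisible(NULL)
}

#' Total physical dose per slice of a mixed-field spectrum
#'
#' Sums record doses within each slice (the denominator of the dose-averaged
#' coefficient mixing); slices without records get zero dose.
#'
#' @param spectrum a [mixed_field_spectrum()]
#' @return a [dose_profile()] with zero sigma
#' @export
total_dose_profile <- function(spectrum) {
  stopifnot(inherits(spectrum, "mixed_field_spectrum"))
  n <- spectrum$grid$n_slices
  tot <- numeric(n)
  if (nrow(spectrum$records)) {
    s <- rowsum(spectrum$records$dose_Gy_per_primary,
                group = spectrum$records$slice_index)
    tot[as.integer(rownames(s)) + 1L] <- s[, 1]
  }
  dose_profile(spectrum$grid, tot, sigma = 0)
}
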