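# High-level workflow wiring: one-call SOBP construction, paired-code
# comparison, and the file-to-file commands behind the command-line script.

#' Build a prescription-normalized SOBP in one call
#'
#' Chooses a 1 mm depth grid long enough for the deepest beam, builds the
#' pristine kernels (ranges evenly spanning the plateau, or an explicit
#' energy window), fits the non-negative plateau weights and rescales them so
#' the composed plateau mean equals the prescription.
#'
#' @param ion_token `"p"`, `"He"` or `"C"` (or an [ion_species()])
#' @param plateau_mm numeric `c(d1, d2)` plateau interval in mm
#' @param prescription_Gy plateau dose (default 2 Gy)
#' @param n_beams number of monoenergetic beams; default `NULL` picks one
#'   beam per mm of plateau span plus one (at least 12), so the plateau
#'   least-squares system is under-determined and the fit can null the
#'   inter-peak ripple
#' @param tail_fraction fragment-tail amplitude; defaults to 0.1 for Z > 1
#'   ions and 0 for protons
#' @param e_min,e_max optional energy window in MeV/u
#' @return list with `plan` (weights in absolute Gy), `kernels`, `profile`
#'   (the composed, prescription-normalized [dose_profile()]) and `grid`
#' @export
build_sobp <- function(ion_token, plateau_mm, prescription_Gy = 2.0,
                       n_beams = NULL, tail_fraction = NULL,
                       e_min = NULL, e_max = NULL) {
  ion <- if (inherits(ion_token, "ion_species")) ion_token
         else ion_species(ion_token)
  if (is.null(n_beams))
    n_beams <- max(12, ceiling(diff(plateau_mm)) + 1)
  if (is.null(tail_fraction))
    tail_fraction <- if (ion$charge_Z > 1L) 0.1 else 0
  r_max <- if (is.null(e_max)) plateau_mm[2] / 10
           else energy_to_range(ion, e_max)
  # margin: straggling width of the deepest beam, the 1 cm kernel-domain
  # requirement, and head-room for mm-scale range perturbations downstream
  grid <- depth_grid(ceiling(r_max * 10 + 10 * range_straggling_sigma(r_max)
                             + 14), 1.0, 0.0)
  kernels <- sobp_kernels(ion, plateau_mm, grid, n_beams = n_beams,
                          tail_fraction = tail_fraction,
                          e_min = e_min, e_max = e_max)
  plan <- design_sobp_weights(kernels, plateau_mm, prescription_Gy)
  plan <- scale_plan_weights(plan, kernels)
  list(plan = plan, kernels = kernels,
       profile = compose_sobp(plan, kernels), grid = grid)
}

agg_to_profile <- function(agg, unit_tag = "absolute_Gy") {
  dose_profile(agg$grid, agg$mean, agg$sem, unit_tag = unit_tag)
}

#' Compare the paired output of two transport codes
#'
#' Runs the full statistical analysis on a `generate_code_pair()`-style pair:
#' aggregates each code's runs, compares the mean dose profiles (divided by
#' the reference plateau mean, so an ideal profile has plateau value 1) with
#' RMSE and gamma at the dose criteria, and for each supplied
#' radiosensitivity table compares the survival depth profiles (with
#' run-to-run sigma) at the survival criteria.
#'
#' @param pair list with `code_a` (reference) and `code_b` [run_set()]s
#' @param plateau_mm plateau interval used for the dose normalization
#' @param tables named list of [radiosensitivity_table()] objects, one per
#'   cell line (may be empty)
#' @param dose_criteria [gamma_criteria()] for dose (default 3 percent /
#'   2 mm, 10 percent threshold)
#' @param survival_criteria [gamma_criteria()] for survival (default
#'   2 percent / 2 mm, no threshold)
#' @param label prefix for the report labels
#' @return list with `dose` (a `comparison_report`) and `survival` (named
#'   list of `comparison_report`s per table)
#' @export
compare_code_pair <- function(pair, plateau_mm, tables = list(),
                              dose_criteria = gamma_criteria(0.03, 2.0, 0.10),
                              survival_criteria = gamma_criteria(0.02, 2.0, 0),
                              label = "") {
  dose_a <- aggregate_runs(pair$code_a, "dose")
  dose_b <- aggregate_runs(pair$code_b, "dose")
  idx <- plateau_slice_idx(dose_a$grid, plateau_mm)
  m <- mean(dose_a$mean[idx])
  ref <- dose_profile(dose_a$grid, dose_a$mean / m, dose_a$sem / m,
                      unit_tag = "normalized")
  ev <- dose_profile(dose_b$grid, dose_b$mean / m, dose_b$sem / m,
                     unit_tag = "normalized")
  out <- list(dose = compare_profiles(ref, ev, dose_criteria,
                                      label = paste0(label, "dose")),
              survival = list())
  for (nm in names(tables)) {
    sa <- bio_summary(pair$code_a, tables[[nm]])
    sb <- bio_summary(pair$code_b, tables[[nm]])
    pa <- dose_profile(dose_a$grid, sa$survival, sa$sigma_survival,
                       unit_tag = "normalized")
    pb <- dose_profile(dose_b$grid, sb$survival, sb$sigma_survival,
                       unit_tag = "normalized")
    out$survival[[nm]] <- compare_profiles(pa, pb, survival_criteria,
                                           label = paste0(label, nm))
  }
  out
}

# ---- file-to-file commands (used by the command-line script) ---------------

#' Design an SOBP and write the plan and composed profile
#'
#' @param ion_token,plateau_mm,prescription_Gy,n_beams,tail_fraction,e_min,e_max
#'   as in [build_sobp()]
#' @param out_plan,out_profile output CSV paths
#' @return the [build_sobp()] result, invisibly
#' @export
cmd_sobp_design <- function(ion_token, plateau_mm, prescription_Gy = 2.0,
                            n_beams = 12, tail_fraction = NULL,
                            e_min = NULL, e_max = NULL,
                            out_plan = "plan.csv",
                            out_profile = "profile.csv") {
  res <- build_sobp(ion_token, plateau_mm, prescription_Gy, n_beams,
                    tail_fraction, e_min, e_max)
  write_plan_csv(res$plan, out_plan)
  write_profile_csv(res$profile, out_profile)
  invisible(res)
}

#' Compute survival, RBE and Gy-Eq profiles from spectrum and table files
#'
#' @param spectrum_csv mixed-field spectrum CSV
#' @param table_csv radiosensitivity table CSV
#' @param n_slices,slice_thickness_mm,origin_mm grid of the spectrum
#' @param out_csv output CSV with columns depth_mm, dose, alpha, beta,
#'   survival, sigma_survival, rbe, gyeq
#' @return the [bio_profile()], invisibly
#' @export
cmd_bio <- function(spectrum_csv, table_csv, n_slices,
                    slice_thickness_mm = 1.0, origin_mm = 0.0,
                    out_csv = "bio.csv") {
  grid <- depth_grid(n_slices, slice_thickness_mm, origin_mm)
  spec <- read_spectrum_csv(spectrum_csv, grid)
  table <- read_radiosensitivity_csv(table_csv)
  bp <- bio_profile(spec, table)
  utils::write.csv(bp$slices, out_csv, row.names = FALSE, quote = FALSE)
  invisible(bp)
}

#' Compare two profile files and write a comparison report
#'
#' @param reference_csv,evaluation_csv profile CSVs on the same grid
#' @param dd,dta_mm,threshold gamma criteria (defaults 0.03, 2, 0.10)
#' @param label report label
#' @param out_csv output report CSV
#' @return the `comparison_report`, invisibly
#' @export
cmd_compare <- function(reference_csv, evaluation_csv, dd = 0.03,
                        dta_mm = 2.0, threshold = 0.10, label = "",
                        out_csv = "report.csv") {
  ref <- read_profile_csv(reference_csv)
  ev <- read_profile_csv(evaluation_csv)
  rep <- compare_profiles(ref, ev, gamma_criteria(dd, dta_mm, threshold),
                          label = label)
  write_report_csv(rep, out_csv)
  invisible(rep)
}

#' Generate a paired-code dataset and write the mean profiles
#'
#' @param ion_token,plateau_mm,prescription_Gy as in [build_sobp()]
#' @param range_shift_mm,tail_scale,noise_rel,n_runs,seed as in
#'   [perturbation_params()]
#' @param out_a,out_b output profile CSV paths (per-code mean dose with
#'   run-to-run sem in the sigma column)
#' @return the pair of run sets, invisibly
#' @export
cmd_pair_generate <- function(ion_token, plateau_mm, prescription_Gy = 2.0,
                              range_shift_mm = 0.5, tail_scale = 1.1,
                              noise_rel = 0.01, n_runs = 5, seed = 1,
                              out_a = "code_a.csv", out_b = "code_b.csv") {
  sob <- build_sobp(ion_token, plateau_mm, prescription_Gy)
  pert <- perturbation_params(range_shift_mm, tail_scale, noise_rel,
                              n_runs, seed)
  pair <- generate_code_pair(sob$plan, sob$kernels, pert)
  write_profile_csv(agg_to_profile(aggregate_runs(pair$code_a, "dose")),
                    out_a)
  write_profile_csv(agg_to_profile(aggregate_runs(pair$code_b, "dose")),
                    out_b)
  invisible(pair)
}
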