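#' Run configuration
#'
#' Central container for the tunable constants shared across the pipeline.
#' Defaults are the protocol values used throughout: contact cutoff 4.5 A
#' with strict >75% occupancy for network edges, reweighting bin size 5 (PC
#' units) with Maclaurin order 10, helical rise 27.5 A / twist -166.7 deg
#' per protomer, the azimuth x longitude scan in 2.5 deg x 2.5 A steps with
#' radial docking from 43 A to 39 A in 0.5 A steps, and 310 K.
#'
#' @param seed integer; root of all randomness in a run.
#' @param temperature_K simulation/analysis temperature (K).
#' @param contact_cutoff_A contact distance cutoff (A).
#' @param occupancy_min minimum contact occupancy (fraction; edges require
#'   strictly more than this).
#' @param reweight_bin_size histogram bin size in PC units.
#' @param maclaurin_order truncation order K of the reweighting series.
#' @param helical_rise_A axial rise per protomer (A).
#' @param helical_twist_deg azimuthal twist per protomer (degrees).
#' @param scan_az_step_deg,scan_z_step_A grid steps of the landscape scan.
#' @param scan_radius_start_A,scan_radius_end_A,scan_radius_step_A radial
#'   docking sweep (start > end; step applied inward).
#' @param dielectric_model `"4r"` (distance-dependent epsilon = 4r) or
#'   `"vacuum"` (epsilon = 1).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       temperature_K = 310,
                       contact_cutoff_A = 4.5,
                       occupancy_min = 0.75,
                       reweight_bin_size = 5,
                       maclaurin_order = 10L,
                       helical_rise_A = 27.5,
                       helical_twist_deg = -166.7,
                       scan_az_step_deg = 2.5,
                       scan_z_step_A = 2.5,
                       scan_radius_start_A = 43,
                       scan_radius_end_A = 39,
                       scan_radius_step_A = 0.5,
                       dielectric_model = "4r") {
  cfg <- list(seed = as.integer(seed),
              temperature_K = temperature_K,
              contact_cutoff_A = contact_cutoff_A,
              occupancy_min = occupancy_min,
              reweight_bin_size = reweight_bin_size,
              maclaurin_order = as.integer(maclaurin_order),
              helical_rise_A = helical_rise_A,
              helical_twist_deg = helical_twist_deg,
              scan_az_step_deg = scan_az_step_deg,
              scan_z_step_A = scan_z_step_A,
              scan_radius_start_A = scan_radius_start_A,
              scan_radius_end_A = scan_radius_end_A,
              scan_radius_step_A = scan_radius_step_A,
              dielectric_model = match.arg(dielectric_model, c("4r", "vacuum")))
  stopifnot(cfg$temperature_K > 0,
            cfg$contact_cutoff_A > 0,
            cfg$occupancy_min >= 0, cfg$occupancy_min <= 1,
            cfg$reweight_bin_size > 0,
            cfg$maclaurin_order >= 0,
            cfg$helical_rise_A > 0,
            cfg$scan_radius_start_A > cfg$scan_radius_end_A,
            cfg$scan_radius_step_A > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their [run_config()] defaults; unknown
#' keys raise an error.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("read_config: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Boltzmann constant in kcal mol^-1 K^-1
#' @keywords internal
KB_KCAL <- 0.0019872041

#' Inverse temperature beta = 1/(kB T) in mol kcal^-1
#' @param temperature_K temperature in kelvin
#' @export
beta_from_temperature <- function(temperature_K) 1 / (KB_KCAL * temperature_K)
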