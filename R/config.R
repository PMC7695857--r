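#' Default run configuration
#'
#' Nested configuration for the full pipeline. The damage and chemistry
#' defaults are the production parameter set: accumulation radius 0.35 nm,
#' ramp endpoints 5 and 37.5 eV, indirect break probability 0.405,
#' chemistry cut 5 ns, kill distance 9 nm, histone spheres of 2.5 nm.
#'
#' @param ... named overrides, either whole sections
#'   (`tracks = list(dose_gy = 2)`) or flat (`seed = 7`). Unknown keys are
#'   rejected.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    geometry = list(
      n_bp = 10000L,
      histone_spacing_bp = 200L,
      histone_scavenging = TRUE,
      bp_density_nm3 = 0.012,
      margin_nm = 10,
      rise_nm = 0.34,
      helix_radius_nm = 1.0,
      twist_deg = 34,
      histone_radius_nm = 2.5),
    tracks = list(
      dose_gy = 1,
      mean_linear_density = 20,
      energy_mean_ev = 45,
      energy_min_ev = 1,
      radial_sigma_nm = 2,
      g_oh_per_100ev = 2.5),
    chemistry = list(
      d_oh_nm2_ns = 2.8,
      dt_ns = 0.001,
      t_chem_ns = 5,
      reaction_radius_nm = 0.22,
      d_kill_nm = 9),
    scoring = list(
      r_dir_nm = 0.35,
      e_min_ev = 5,
      e_max_ev = 37.5,
      p_oh_break = 0.405),
    classification = list(
      d_dsb_bp = 10,
      cluster_gap_bp = 100,
      distant_gap_bp = 10000),
    repair = list(
      t_end_h = 25,
      dt_out_h = 0.1),
    verbose = FALSE)
  cfg <- structure(cfg, class = "run_config")
  overrides <- list(...)
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  validate_run_config(cfg)
}

merge_config <- function(cfg, overrides) {
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
    else cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

#' Validate a run configuration
#'
#' Rejects unknown keys at any level and checks the physical constraints
#' of each section.
#'
#' @param cfg a `run_config` (or plain nested list).
#' @return the validated config, classed `run_config`.
#' @export
validate_run_config <- function(cfg) {
  template <- unclass(default_run_config_template())
  check_keys <- function(x, tpl, path) {
    unknown <- setdiff(names(x), names(tpl))
    if (length(unknown))
      stop("unknown configuration key", if (length(unknown) > 1) "s", ": ",
           paste0(path, unknown, collapse = ", "), call. = FALSE)
    for (nm in names(x))
      if (is.list(tpl[[nm]]))
        check_keys(x[[nm]], tpl[[nm]], paste0(path, nm, "."))
  }
  check_keys(unclass(cfg), template, "")
  with(cfg$scoring, {
    stopifnot(e_min_ev > 0, e_max_ev > e_min_ev,
              p_oh_break >= 0, p_oh_break <= 1, r_dir_nm > 0)
  })
  stopifnot(cfg$geometry$n_bp >= 1, cfg$tracks$dose_gy >= 0,
            cfg$chemistry$t_chem_ns >= 0, cfg$chemistry$d_kill_nm > 0)
  structure(cfg, class = "run_config")
}

# the raw template (no validation recursion)
default_run_config_template <- function() {
  cfg <- list(seed = 1L,
              geometry = list(n_bp = 1L, histone_spacing_bp = 1L,
                              histone_scavenging = TRUE,
                              bp_density_nm3 = 1, margin_nm = 1,
                              rise_nm = 1, helix_radius_nm = 1,
                              twist_deg = 1, histone_radius_nm = 1),
              tracks = list(dose_gy = 1, mean_linear_density = 1,
                            energy_mean_ev = 1, energy_min_ev = 1,
                            radial_sigma_nm = 1, g_oh_per_100ev = 1),
              chemistry = list(d_oh_nm2_ns = 1, dt_ns = 1, t_chem_ns = 1,
                               reaction_radius_nm = 1, d_kill_nm = 1),
              scoring = list(r_dir_nm = 1, e_min_ev = 1, e_max_ev = 2,
                             p_oh_break = 0.5),
              classification = list(d_dsb_bp = 1, cluster_gap_bp = 1,
                                    distant_gap_bp = 1),
              repair = list(t_end_h = 1, dt_out_h = 1),
              verbose = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Starts from [default_run_config()] and overlays the file's keys;
#' unknown keys are rejected with the offending key name.
#'
#' @param path JSON config file.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(merge_config(default_run_config(), raw))
}

#' Stable hash of a configuration (provenance)
#' @param cfg any R object.
#' @return character hash.
#' @export
config_hash <- function(cfg) rlang::hash(unclass(cfg))
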