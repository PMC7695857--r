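#' Run the full damage pipeline
#'
#' Geometry build, surrogate irradiation, radical culling and diffusion,
#' direct/indirect break scoring, clustering and classification, in one
#' deterministic call. All randomness derives from `config$seed`.
#'
#' @param config a [default_run_config()] (or overrides via `...` passed
#'   to it when `config` is NULL).
#' @param keep_geometry keep the geometry object in the result (large).
#' @param ... overrides forwarded to [default_run_config()].
#' @return list of class `damage_run`: `breaks`, `clusters`, `summary`
#'   (a `yield_summary`), `counts` (per-stage event log), `config`,
#'   `config_hash`, and optionally `geometry`.
#' @export
simulate_damage <- function(config = NULL, keep_geometry = FALSE, ...) {
  if (is.null(config)) config <- default_run_config(...)
  config <- validate_run_config(config)
  gc_ <- config$geometry
  say <- function(...) if (isTRUE(config$verbose)) message(...)

  geo_cfg <- geometry_config(rise_nm = gc_$rise_nm,
                             helix_radius_nm = gc_$helix_radius_nm,
                             twist_deg = gc_$twist_deg,
                             histone_radius_nm = gc_$histone_radius_nm)
  seg <- build_helix_segment(gc_$n_bp, seed = config$seed, config = geo_cfg)
  if (isTRUE(gc_$histone_scavenging) || gc_$histone_spacing_bp > 0)
    seg <- place_histones(seg, gc_$histone_spacing_bp)
  container <- fibre_container(gc_$n_bp, gc_$bp_density_nm3, gc_$margin_nm,
                               geo_cfg)
  geom <- assemble_geometry(seg, container)
  say("geometry: ", nrow(geom$sites), " sites, ",
      nrow(geom$histones), " histones")

  irr <- irradiation_config(dose_gy = config$tracks$dose_gy,
                            mean_linear_density = config$tracks$mean_linear_density,
                            energy_mean_ev = config$tracks$energy_mean_ev,
                            energy_min_ev = config$tracks$energy_min_ev,
                            radial_sigma_nm = config$tracks$radial_sigma_nm,
                            g_oh_per_100ev = config$tracks$g_oh_per_100ev,
                            seed = config$seed)
  events <- generate_tracks(geom, irr)
  say("tracks: ", events$n_tracks, ", deposits: ", nrow(events$deposits),
      ", dose: ", signif(events$delivered_dose_gy, 4), " Gy")

  radicals <- cull_radicals_at_creation(events$radicals, geom,
                                        config$chemistry$d_kill_nm)
  n_killed <- sum(radicals$status == "killed")
  chem <- chem_config(d_oh_nm2_ns = config$chemistry$d_oh_nm2_ns,
                      dt_ns = config$chemistry$dt_ns,
                      t_chem_ns = config$chemistry$t_chem_ns,
                      reaction_radius_nm = config$chemistry$reaction_radius_nm)
  dif <- diffuse_radicals(radicals, geom, chem, seed = config$seed,
                          use_histones = isTRUE(gc_$histone_scavenging))
  say("radicals: ", nrow(radicals), " spawned, ", n_killed, " killed, ",
      sum(dif$radicals$status == "scavenged"), " scavenged, ",
      nrow(dif$encounters), " encounters")

  params <- scoring_params(r_dir_nm = config$scoring$r_dir_nm,
                           e_min_ev = config$scoring$e_min_ev,
                           e_max_ev = config$scoring$e_max_ev,
                           p_oh_break = config$scoring$p_oh_break)
  energy <- accumulate_direct_energy(events$deposits, geom, params)
  breaks <- withr_seed(config$seed + 1L, {
    direct <- score_direct_breaks(energy, params)
    indirect <- score_indirect_breaks(dif$encounters, params,
                                      seed = config$seed)
    combine_breaks(direct, indirect)
  })
  say("breaks: ", nrow(breaks), " (",
      sum(breaks$source == "direct"), " direct, ",
      sum(breaks$source == "indirect"), " indirect)")

  cls <- config$classification
  clusters <- segment_clusters(breaks, cls$cluster_gap_bp)
  genome_gbp <- gc_$n_bp / 1e9
  dose_for_norm <- if (events$delivered_dose_gy > 0)
    events$delivered_dose_gy else config$tracks$dose_gy
  summary <- if (config$tracks$dose_gy > 0)
    summarize_yields(clusters, dose_for_norm, genome_gbp,
                     cls$d_dsb_bp, cls$distant_gap_bp)
  else zero_summary(genome_gbp)

  counts <- list(
    n_sites = nrow(geom$sites), n_histones = nrow(geom$histones),
    n_tracks = events$n_tracks, n_deposits = nrow(events$deposits),
    delivered_dose_gy = events$delivered_dose_gy,
    n_radicals = nrow(events$radicals), n_killed = n_killed,
    n_scavenged = sum(dif$radicals$status == "scavenged"),
    n_reacted = sum(dif$radicals$status == "reacted"),
    n_timed_out = sum(dif$radicals$status == "timed_out"),
    n_encounters = nrow(dif$encounters),
    n_breaks_direct = sum(breaks$source == "direct"),
    n_breaks_indirect = sum(breaks$source == "indirect"),
    n_clusters = length(clusters))

  out <- list(breaks = breaks, clusters = clusters, summary = summary,
              counts = counts, config = config,
              config_hash = config_hash(config))
  if (keep_geometry) out$geometry <- geom
  structure(out, class = "damage_run")
}

# all-zero yield summary (dose-0 runs)
zero_summary <- function(genome_gbp) {
  structure(list(
    n_breaks = 0L, n_ssb = 0L, n_dsb_clusters = 0L, n_dsb_pairs = 0L,
    n_dsb = 0L, n_dsbp = 0L, n_dsbpp = 0L, n_cdsb = 0L, n_ncdsb = 0L,
    n_distant_dsb = 0L, n_dsbdir = 0L, n_dsbind = 0L, n_dsbhyb = 0L,
    n_dsbmix = 0L,
    ssb_per_gy_gbp = 0, dsb_per_gy_gbp = 0, distant_dsb_per_gy_gbp = 0,
    cdsb_per_gy_gbp = 0, dose_gy = 0, genome_gbp = genome_gbp,
    ssb_dsb_ratio = NA_real_, scavengeable_fraction = NA_real_),
    class = "yield_summary")
}

#' @export
print.yield_summary <- function(x, ...) {
  cat("DNA damage yield summary\n")
  cat(sprintf("  dose: %.4g Gy over %.4g Gbp\n", x$dose_gy, x$genome_gbp))
  cat(sprintf("  breaks: %d | SSB: %d | DSB clusters: %d (DSBp %d, DSBpp %d)\n",
              x$n_breaks, x$n_ssb, x$n_dsb, x$n_dsbp, x$n_dsbpp))
  cat(sprintf("  complex DSB (N_cDSB): %d | distant DSB: %d\n",
              x$n_cdsb, x$n_distant_dsb))
  cat(sprintf("  source classes: dir %d, ind %d, hyb %d, mix %d\n",
              x$n_dsbdir, x$n_dsbind, x$n_dsbhyb, x$n_dsbmix))
  cat(sprintf("  yields /Gy/Gbp: SSB %.4g, DSB %.4g, distant DSB %.4g\n",
              x$ssb_per_gy_gbp, x$dsb_per_gy_gbp, x$distant_dsb_per_gy_gbp))
  cat(sprintf("  SSB/DSB ratio: %s | scavengeable fraction: %s\n",
              format(x$ssb_dsb_ratio, digits = 4),
              format(x$scavengeable_fraction, digits = 4)))
  invisible(x)
}
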