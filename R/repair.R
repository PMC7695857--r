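# Mass-action DSB repair kinetics: NHEJ, HR, SSA, micro-SSA and Alt-NHEJ
# pathway chains, ATM signalling, and Michaelis-Menten gamma-H2AX output.
#
# N0 counts all unrepaired DSBs (free plus enzyme-bound). Complex formation
# draws on the free pool N0 - sum(complexes); only the terminal
# ligation/resolution step of each pathway removes a DSB from N0, so N0 is
# monotone non-increasing after irradiation.

# pathway chains: species names and the rate constants linking them.
# Each chain step i has a forward constant (pseudo-first-order, enzyme
# pools folded in, per hour) and a reverse constant; the final constant is
# the terminal repair step.
repair_pathways <- function() {
  list(
    nhej = list(
      species = c("nhej_ku", "nhej_dnapk", "nhej_syn", "nhej_proc",
                  "nhej_lig"),
      forward = c("k_nhej_ku_f", "k_nhej_dnapk_f", "k_nhej_syn_f",
                  "k_nhej_proc_f", "k_nhej_lig_f"),
      reverse = c("k_nhej_ku_r", "k_nhej_dnapk_r", "k_nhej_syn_r",
                  "k_nhej_proc_r", "k_nhej_lig_r"),
      final = "k_nhej_fin"),
    hr = list(
      species = c("hr_mrn", "hr_resect", "hr_rpa", "hr_rad51", "hr_dloop",
                  "hr_synth"),
      forward = c("k_hr_mrn_f", "k_hr_resect_f", "k_hr_rpa_f",
                  "k_hr_rad51_f", "k_hr_dloop_f", "k_hr_synth_f"),
      reverse = c("k_hr_mrn_r", "k_hr_resect_r", "k_hr_rpa_r",
                  "k_hr_rad51_r", "k_hr_dloop_r", "k_hr_synth_r"),
      final = "k_hr_fin"),
    ssa = list(
      species = c("ssa_resect", "ssa_rpa", "ssa_rad52", "ssa_flap"),
      forward = c("k_ssa_resect_f", "k_ssa_rpa_f", "k_ssa_rad52_f",
                  "k_ssa_flap_f"),
      reverse = c("k_ssa_resect_r", "k_ssa_rpa_r", "k_ssa_rad52_r",
                  "k_ssa_flap_r"),
      final = "k_ssa_fin"),
    micro_ssa = list(
      species = c("mssa_resect", "mssa_anneal"),
      forward = c("k_mssa_resect_f", "k_mssa_anneal_f"),
      reverse = c("k_mssa_resect_r", "k_mssa_anneal_r"),
      final = "k_mssa_fin"),
    alt_nhej = list(
      species = c("alt_parp", "alt_polq", "alt_lig3"),
      forward = c("k_alt_parp_f", "k_alt_polq_f", "k_alt_lig3_f"),
      reverse = c("k_alt_parp_r", "k_alt_polq_r", "k_alt_lig3_r"),
      final = "k_alt_fin"))
}

#' Names of the 53 repair-model rate constants
#'
#' Pathway attachment/disattachment and terminal constants for NHEJ (11),
#' HR (13), SSA (9), micro-SSA (5) and Alt-NHEJ (7), ATM
#' activation/deactivation/autoamplification (3), the Michaelis-Menten
#' gamma-H2AX parameters (2), the phosphorylation/dephosphorylation
#' relaxation pair (2) and the DSB induction slope alpha (1).
#'
#' @return character vector of length 53.
#' @export
repair_rate_names <- function() {
  p <- repair_pathways()
  c(unlist(lapply(p, function(x) c(x$forward, x$reverse, x$final)),
           use.names = FALSE),
    "k_atm_act", "k_atm_deact", "k_atm_auto",
    "k_h2ax_vmax", "k_h2ax_km",
    "k_h2ax_phos", "k_h2ax_deph",
    "alpha_dsb_per_gy")
}

#' Default repair rate table
#'
#' Pseudo-first-order rate constants (per hour; protein pools folded in)
#' giving fast-dominant NHEJ, slower HR, and minor SSA / micro-SSA /
#' Alt-NHEJ fluxes, a gamma-H2AX peak within the first hours and a late
#' plateau from irreparable damage. The values are the package's documented
#' defaults, intended to be replaced by a fitted table for quantitative
#' work; every entry can be overridden via a JSON rate file
#' ([read_rate_table()]).
#'
#' @return named numeric vector of length 53, class `repair_rate_table`.
#' @export
default_rate_table <- function() {
  v <- c(
    # NHEJ
    k_nhej_ku_f = 10, k_nhej_dnapk_f = 8, k_nhej_syn_f = 4,
    k_nhej_proc_f = 3, k_nhej_lig_f = 2.5,
    k_nhej_ku_r = 0.5, k_nhej_dnapk_r = 0.3, k_nhej_syn_r = 0.2,
    k_nhej_proc_r = 0.1, k_nhej_lig_r = 0.1,
    k_nhej_fin = 2,
    # HR
    k_hr_mrn_f = 1.5, k_hr_resect_f = 0.8, k_hr_rpa_f = 1,
    k_hr_rad51_f = 0.8, k_hr_dloop_f = 0.5, k_hr_synth_f = 0.4,
    k_hr_mrn_r = 0.2, k_hr_resect_r = 0.1, k_hr_rpa_r = 0.1,
    k_hr_rad51_r = 0.1, k_hr_dloop_r = 0.05, k_hr_synth_r = 0.05,
    k_hr_fin = 0.3,
    # SSA
    k_ssa_resect_f = 0.5, k_ssa_rpa_f = 0.6, k_ssa_rad52_f = 0.4,
    k_ssa_flap_f = 0.3,
    k_ssa_resect_r = 0.1, k_ssa_rpa_r = 0.1, k_ssa_rad52_r = 0.05,
    k_ssa_flap_r = 0.05,
    k_ssa_fin = 0.25,
    # micro-SSA
    k_mssa_resect_f = 0.3, k_mssa_anneal_f = 0.25,
    k_mssa_resect_r = 0.05, k_mssa_anneal_r = 0.05,
    k_mssa_fin = 0.2,
    # Alt-NHEJ
    k_alt_parp_f = 0.4, k_alt_polq_f = 0.3, k_alt_lig3_f = 0.25,
    k_alt_parp_r = 0.1, k_alt_polq_r = 0.05, k_alt_lig3_r = 0.05,
    k_alt_fin = 0.2,
    # ATM signalling
    k_atm_act = 5, k_atm_deact = 1.5, k_atm_auto = 0.01,
    # gamma-H2AX Michaelis-Menten + phospho relaxation
    k_h2ax_vmax = 1, k_h2ax_km = 15,
    k_h2ax_phos = 6, k_h2ax_deph = 0.8,
    # DSB induction slope (per Gy per cell)
    alpha_dsb_per_gy = 1)
  validate_rate_table(v)
}

#' Validate a repair rate table against the 53-name schema
#'
#' @param rates named numeric vector.
#' @return the table, classed `repair_rate_table`; errors on missing,
#'   unknown or negative entries.
#' @export
validate_rate_table <- function(rates) {
  need <- repair_rate_names()
  missing <- setdiff(need, names(rates))
  extra <- setdiff(names(rates), need)
  if (length(missing))
    stop("rate table is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(extra))
    stop("unknown rate constants: ", paste(extra, collapse = ", "),
         call. = FALSE)
  rates <- rates[need]
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  structure(rates, class = "repair_rate_table")
}

#' Repair model inputs
#'
#' @param n_ncdsb,n_cdsb non-complex and complex DSB counts per cell.
#' @param dose_gy absorbed dose, Gy.
#' @param irreparable_fraction fraction of DSBs never repaired; default
#'   `n_cdsb / (n_cdsb + n_ncdsb)` (0 when both counts are 0).
#' @return list of class `repair_inputs`.
#' @export
repair_inputs <- function(n_ncdsb, n_cdsb, dose_gy = 1,
                          irreparable_fraction = NULL) {
  stopifnot(n_ncdsb >= 0, n_cdsb >= 0)
  if (is.null(irreparable_fraction)) {
    tot <- n_ncdsb + n_cdsb
    irreparable_fraction <- if (tot > 0) n_cdsb / tot else 0
  }
  stopifnot(irreparable_fraction >= 0, irreparable_fraction <= 1)
  structure(list(n_ncdsb = n_ncdsb, n_cdsb = n_cdsb, dose_gy = dose_gy,
                 irreparable_fraction = irreparable_fraction),
            class = "repair_inputs")
}

repair_species <- function() {
  c("n0", unlist(lapply(repair_pathways(), `[[`, "species"),
                 use.names = FALSE), "atm_active")
}

repair_rhs <- function(t, state, parms) {
  rates <- parms$rates
  paths <- parms$paths
  d <- setNames(numeric(length(state)), names(state))
  complexed <- 0
  for (p in paths) complexed <- complexed + sum(state[p$species])
  n_free <- max(state[["n0"]] - complexed, 0)
  v_total <- 0
  for (p in paths) {
    sp <- p$species
    k <- length(sp)
    if (k == 0L) { # reduced pathway: direct first-order elimination
      v_total <- v_total + rates[[p$final]] * n_free
      next
    }
    x <- state[sp]
    # first complex forms from the free DSB pool
    d[sp[1L]] <- rates[[p$forward[1L]]] * n_free - rates[[p$reverse[1L]]] * x[1L]
    if (k > 1L) for (i in 2:k) {
      flux <- rates[[p$forward[i]]] * x[i - 1L] - rates[[p$reverse[i]]] * x[i]
      d[sp[i - 1L]] <- d[sp[i - 1L]] - flux
      d[sp[i]] <- flux
    }
    v <- rates[[p$final]] * x[k]
    d[sp[k]] <- d[sp[k]] - v
    v_total <- v_total + v
  }
  d[["n0"]] <- -v_total
  d[["atm_active"]] <- rates[["k_atm_act"]] * state[["n0"]] +
    rates[["k_atm_auto"]] * state[["atm_active"]] * state[["n0"]] -
    rates[["k_atm_deact"]] * state[["atm_active"]]
  list(d)
}

#' Simulate DSB repair kinetics
#'
#' Integrates the mass-action pathway network with the instantaneous
#' irradiation convention: the whole dose is delivered at t = 0, so the
#' induction term collapses to the initial condition
#' `N0(0) = n_ncdsb + n_cdsb` with all intermediate complexes zero. Uses a
#' stiff-capable solver (deSolve::lsoda).
#'
#' @param inputs a [repair_inputs()].
#' @param rates a [default_rate_table()] or validated replacement.
#' @param t_end_h end of the output grid, hours (default 25).
#' @param dt_out_h output step, hours (default 0.1).
#' @param atol,rtol solver tolerances.
#' @param pathways pathway network definition; the default is the full
#'   five-pathway chain network. A pathway with an empty `species` vector
#'   is treated as direct first-order elimination `V = k_final * N_free`
#'   (the reduced configuration used for closed-form checks).
#' @return data.frame of class `repair_trajectory`: time_h, n0, every
#'   intermediate complex, atm_active, and per-pathway elimination fluxes
#'   v_nhej, v_hr, v_ssa, v_micro_ssa, v_alt_nhej. The inputs are attached
#'   as attribute `inputs`.
#' @export
simulate_repair <- function(inputs, rates = default_rate_table(),
                            t_end_h = 25, dt_out_h = 0.1,
                            atol = 1e-9, rtol = 1e-8,
                            pathways = repair_pathways()) {
  stopifnot(inherits(inputs, "repair_inputs"), t_end_h > 0)
  rates <- validate_rate_table(rates)
  paths <- pathways
  species <- c("n0", unlist(lapply(paths, `[[`, "species"),
                            use.names = FALSE), "atm_active")
  state <- setNames(numeric(length(species)), species)
  state[["n0"]] <- inputs$n_ncdsb + inputs$n_cdsb
  times <- seq(0, t_end_h, by = dt_out_h)
  out <- deSolve::lsoda(state, times, repair_rhs,
                        parms = list(rates = rates, paths = paths),
                        atol = atol, rtol = rtol)
  if (attr(out, "istate")[1L] < 0)
    stop("repair ODE integration failed (istate = ",
         attr(out, "istate")[1L], ")", call. = FALSE)
  traj <- as.data.frame(out)
  names(traj)[1L] <- "time_h"
  for (nm in names(paths)) {
    sp <- paths[[nm]]$species
    driver <- if (length(sp)) traj[[tail(sp, 1L)]] else traj[["n0"]]
    traj[[paste0("v_", nm)]] <- rates[[paths[[nm]]$final]] * driver
  }
  attr(traj, "inputs") <- inputs
  attr(traj, "rates") <- rates
  class(traj) <- c("repair_trajectory", "data.frame")
  traj
}

default_foci_map <- function() {
  list(ku = c("nhej_ku", "nhej_dnapk", "nhej_syn", "nhej_proc", "nhej_lig"),
       dnapkcs = c("nhej_dnapk", "nhej_syn", "nhej_proc", "nhej_lig"),
       rpa = c("hr_rpa", "ssa_rpa"),
       rad51 = c("hr_rad51", "hr_dloop", "hr_synth"),
       atm = "atm_active")
}

# Michaelis-Menten kernel
mm_transform <- function(s, vmax, km) vmax * s / (km + s)

#' Foci time-curves including gamma-H2AX
#'
#' Pools the trajectory's active DNA-PKcs-bearing complexes and active ATM,
#' adds the irreparable component (a fraction of the initial DSBs that
#' permanently retains repair-protein foci), applies the Michaelis-Menten
#' induction kernel and a phosphorylation/dephosphorylation relaxation to
#' obtain the gamma-H2AX curve, plus Ku, DNA-PKcs, RPA and Rad51
#' accumulation curves. By default all curves are scaled to their maxima;
#' `scaled = FALSE` returns absolute levels.
#'
#' @param trajectory a `repair_trajectory`.
#' @param rates the rate table used for the simulation.
#' @param irreparable_fraction fraction of initial DSBs never repaired;
#'   defaults to the value recorded in the trajectory's inputs.
#' @param species_map names of trajectory columns pooled for each focus
#'   type; see `default_foci_map()` in the sources.
#' @param scaled normalise each curve to its maximum.
#' @return data.frame of class `foci_curve`: time_h, ku, dnapkcs, rpa,
#'   rad51, gh2ax.
#' @export
gamma_h2ax_curve <- function(trajectory, rates = attr(trajectory, "rates"),
                             irreparable_fraction = NULL,
                             species_map = default_foci_map(),
                             scaled = TRUE) {
  rates <- validate_rate_table(rates)
  inputs <- attr(trajectory, "inputs")
  if (is.null(irreparable_fraction))
    irreparable_fraction <- if (!is.null(inputs)) inputs$irreparable_fraction
      else 0
  miss <- setdiff(unlist(species_map), names(trajectory))
  if (length(miss))
    stop("species missing from trajectory: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pool <- function(cols) {
    m <- as.matrix(trajectory[, cols, drop = FALSE])
    rowSums(m)
  }
  n0_init <- trajectory$n0[1L]
  substrate <- pool(species_map$dnapkcs) + pool(species_map$atm) +
    irreparable_fraction * n0_init
  m <- mm_transform(substrate, rates[["k_h2ax_vmax"]], rates[["k_h2ax_km"]])
  # asymmetric first-order relaxation: fast phosphorylation toward the
  # induction level, slower dephosphorylation away from it
  g <- numeric(length(m))
  tt <- trajectory$time_h
  for (i in seq_along(m)[-1L]) {
    dt <- tt[i] - tt[i - 1L]
    k <- if (m[i] >= g[i - 1L]) rates[["k_h2ax_phos"]]
         else rates[["k_h2ax_deph"]]
    g[i] <- m[i] + (g[i - 1L] - m[i]) * exp(-k * dt)
  }
  out <- data.frame(time_h = tt,
                    ku = pool(species_map$ku),
                    dnapkcs = pool(species_map$dnapkcs),
                    rpa = pool(species_map$rpa),
                    rad51 = pool(species_map$rad51),
                    gh2ax = g)
  if (scaled) for (nm in c("ku", "dnapkcs", "rpa", "rad51", "gh2ax")) {
    mx <- max(out[[nm]])
    if (mx > 0) out[[nm]] <- out[[nm]] / mx
  }
  class(out) <- c("foci_curve", "data.frame")
  out
}

#' Degree of protection from paired survival fractions
#'
#' `DP = (ln SF0 - ln SFx) / ln SF0` for survival without (`SF0`) and with
#' (`SFx`) the scavenger.
#'
#' @param sf0 survival fraction without scavenger, in (0, 1).
#' @param sfx survival fraction with scavenger, in (0, 1].
#' @return degree of protection (vectorised).
#' @examples
#' degree_of_protection(0.1, 0.4) # ~0.602
#' @export
degree_of_protection <- function(sf0, sfx) {
  if (any(sf0 <= 0) || any(sf0 >= 1))
    stop("`sf0` must lie strictly between 0 and 1", call. = FALSE)
  if (any(sfx <= 0) || any(sfx > 1))
    stop("`sfx` must lie in (0, 1]", call. = FALSE)
  (log(sf0) - log(sfx)) / log(sf0)
}

#' Reciprocal fit for the maximum degree of protection
#'
#' Ordinary least squares of `1/DP` on `1/x` (`1/DP = k/x + y_inf`); the
#' intercept gives the maximum degree of protection at infinite scavenger
#' concentration, `max_dp = 1/y_inf`, the estimate of the scavengeable
#' damage fraction.
#'
#' @param concentrations scavenger concentrations x (> 0, at least two
#'   distinct values).
#' @param dp degrees of protection in (0, 1].
#' @return list: k, y_inf, max_dp, standard errors `se_k`, `se_y_inf`,
#'   `r_squared`, `status` ("ok" or "non_physical" when `y_inf <= 0`, with
#'   a warning), and the `fit` lm object.
#' @export
fit_max_protection <- function(concentrations, dp) {
  x <- as.numeric(concentrations)
  if (length(x) < 2 || length(unique(x)) < 2)
    stop("need at least two distinct concentrations", call. = FALSE)
  if (any(x <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (any(dp <= 0) || any(dp > 1))
    stop("DP values must lie in (0, 1]", call. = FALSE)
  inv_dp <- 1 / dp
  inv_x <- 1 / x
  fit <- lm(inv_dp ~ inv_x)
  k <- unname(coef(fit)[2L])
  y_inf <- unname(coef(fit)[1L])
  # suppressWarnings: lm warns on exact-line input ("essentially perfect fit")
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  status <- "ok"
  if (y_inf <= 0) {
    warning("fitted intercept y_inf <= 0 is non-physical; max_dp set to NA")
    status <- "non_physical"
  }
  list(k = k, y_inf = y_inf,
       max_dp = if (y_inf > 0) 1 / y_inf else NA_real_,
       se_k = unname(se[2L]), se_y_inf = unname(se[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       status = status, fit = fit)
}

#' Read a repair rate table from a JSON file
#' @param path JSON file of name: value pairs.
#' @return validated `repair_rate_table`.
#' @export
read_rate_table <- function(path) {
  v <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  validate_rate_table(v)
}

#' Write a repair rate table to JSON
#' @param rates a rate table.
#' @param path output file.
#' @export
write_rate_table <- function(rates, path) {
  rates <- validate_rate_table(rates)
  jsonlite::write_json(as.list(unclass(rates)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
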