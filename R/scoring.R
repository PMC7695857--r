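#' Damage-model parameters
#'
#' The direct model assigns each energy deposit to the closest backbone
#' molecule within `r_dir_nm` (3.5 Angstrom), accumulates energy per
#' sugar-phosphate scoring unit over the whole irradiation, and converts the
#' accumulated energy to a break probability with a linear ramp: 0 below
#' `e_min_ev` (5 eV), 1 above `e_max_ev` (37.5 eV). The indirect model
#' converts each hydroxyl-backbone encounter to a break with probability
#' `p_oh_break` (0.405).
#'
#' @param r_dir_nm direct-damage accumulation radius, nm (default 0.35).
#' @param e_min_ev,e_max_ev linear ramp endpoints, eV (defaults 5, 37.5).
#' @param p_oh_break indirect break probability per encounter (default
#'   0.405).
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(r_dir_nm = 0.35, e_min_ev = 5, e_max_ev = 37.5,
                           p_oh_break = 0.405) {
  stopifnot(r_dir_nm > 0, e_min_ev > 0, e_max_ev > e_min_ev,
            p_oh_break >= 0, p_oh_break <= 1)
  structure(list(r_dir_nm = r_dir_nm, e_min_ev = e_min_ev,
                 e_max_ev = e_max_ev, p_oh_break = p_oh_break),
            class = "scoring_params")
}

#' Accumulate direct energy per sugar-phosphate scoring unit
#'
#' Each deposit whose nearest backbone site lies within `r_dir_nm`
#' contributes its full energy to that site; deposits farther from all
#' backbone sites contribute nothing. The phosphate and deoxyribose of one
#' nucleotide form one scoring unit, so energies are pooled per
#' (segment, bp, strand).
#'
#' @param deposits deposit data.frame (x, y, z, energy).
#' @param geometry a `damage_geometry`.
#' @param params a [scoring_params()].
#' @return data.frame segment_id, bp_index, strand, energy (eV), one row
#'   per scoring unit that received energy.
#' @export
accumulate_direct_energy <- function(deposits, geometry,
                                     params = scoring_params()) {
  geom <- as_damage_geometry(geometry)
  empty <- data.frame(segment_id = integer(), bp_index = integer(),
                      strand = integer(), energy = numeric())
  if (!nrow(deposits)) return(empty)
  idx <- geom$index
  q <- cbind(deposits$x, deposits$y, deposits$z)
  res <- cpp_nearest_site(q, idx$bb_x, idx$bb_y, idx$bb_z, idx$bb_prio)
  keep <- res$distance <= params$r_dir_nm
  if (!any(keep)) return(empty)
  meta <- idx$bb_meta[res$index[keep], , drop = FALSE]
  df <- data.frame(meta[, c("segment_id", "bp_index", "strand")],
                   energy = deposits$energy[keep])
  out <- stats::aggregate(energy ~ segment_id + bp_index + strand, df, sum)
  out <- out[order(out$segment_id, out$bp_index, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Direct strand-break probability (linear energy ramp)
#'
#' 0 for accumulated energies at or below `e_min_ev`, 1 at or above
#' `e_max_ev`, linear in between.
#'
#' @param energy_ev accumulated energy per scoring unit, eV (vectorised).
#' @param params a [scoring_params()].
#' @return probability in `[0, 1]`.
#' @examples
#' direct_break_probability(4)     # 0
#' direct_break_probability(40)    # 1
#' direct_break_probability(21.25) # 0.5
#' @export
direct_break_probability <- function(energy_ev, params = scoring_params()) {
  if (any(energy_ev < 0)) stop("energy must be non-negative", call. = FALSE)
  p <- (energy_ev - params$e_min_ev) / (params$e_max_ev - params$e_min_ev)
  pmin(pmax(p, 0), 1)
}

empty_breaks <- function() {
  data.frame(segment_id = integer(), bp_index = integer(),
             strand = integer(), source = character(),
             stringsAsFactors = FALSE)
}

#' Score direct strand breaks
#'
#' One Bernoulli trial per scoring unit using the accumulated-energy ramp
#' probability. Draws from the current R random stream; seed with
#' `set.seed()` (the pipeline does this for you).
#'
#' @param energy_table output of [accumulate_direct_energy()].
#' @param params a [scoring_params()].
#' @return break data.frame (segment_id, bp_index, strand, source =
#'   "direct").
#' @export
score_direct_breaks <- function(energy_table, params = scoring_params()) {
  if (!nrow(energy_table)) return(empty_breaks())
  p <- direct_break_probability(energy_table$energy, params)
  hit <- runif(nrow(energy_table)) < p
  if (!any(hit)) return(empty_breaks())
  out <- energy_table[hit, c("segment_id", "bp_index", "strand")]
  out$source <- "direct"
  rownames(out) <- NULL
  out
}

#' Score indirect strand breaks
#'
#' Independent Bernoulli(`p_oh_break`) per hydroxyl-backbone encounter;
#' successes become indirect breaks at the hit nucleotide. Duplicate
#' successes at one (segment, bp, strand) collapse to a single break.
#'
#' Each trial's uniform is derived deterministically from
#' `(seed, radical_id)`, so a radical that encounters the backbone in two
#' paired simulation arms (for example histone scavenging on and off)
#' receives the same draw in both, and raising `p_oh_break` can only add
#' breaks at a fixed seed.
#'
#' @param encounters encounter table from [diffuse_radicals()] (needs a
#'   `radical_id` column).
#' @param params a [scoring_params()].
#' @param seed integer seed for the per-radical trial uniforms.
#' @return break data.frame (source = "indirect").
#' @export
score_indirect_breaks <- function(encounters, params = scoring_params(),
                                  seed = 1L) {
  if (!nrow(encounters)) return(empty_breaks())
  u <- cpp_hash_unif(as.integer(encounters$radical_id), as.double(seed))
  hit <- u < params$p_oh_break
  if (!any(hit)) return(empty_breaks())
  out <- unique(encounters[hit, c("segment_id", "bp_index", "strand")])
  out$source <- "indirect"
  out <- out[order(out$segment_id, out$bp_index, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Combine direct and indirect breaks
#'
#' A position hit both directly and indirectly yields one break whose
#' source is "direct" (direct damage is resolved first; the duplicate
#' indirect success is dropped).
#'
#' @param direct,indirect break data.frames.
#' @return merged break data.frame sorted by (segment, bp, strand).
#' @export
combine_breaks <- function(direct, indirect) {
  if (nrow(indirect) && nrow(direct)) {
    dk <- paste(direct$segment_id, direct$bp_index, direct$strand)
    ik <- paste(indirect$segment_id, indirect$bp_index, indirect$strand)
    indirect <- indirect[!(ik %in% dk), , drop = FALSE]
  }
  out <- rbind(direct, indirect)
  if (!nrow(out)) return(empty_breaks())
  out <- out[order(out$segment_id, out$bp_index, out$strand), ]
  rownames(out) <- NULL
  out
}
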