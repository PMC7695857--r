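#' Geometry construction parameters
#'
#' Dimensions of the simplified B-DNA double helix and histone spheres. The
#' 34 degree twist per base pair is the defining structural constant; rise
#' and helix radius are the B-DNA conventions, and base ellipsoids are
#' geometry-only (they never carry strand breaks).
#'
#' @param rise_nm helical rise per base pair, nm.
#' @param helix_radius_nm radial distance of backbone site centres from the
#'   fibre axis, nm.
#' @param twist_deg azimuthal rotation between consecutive base pairs,
#'   degrees.
#' @param r_phosphate_nm,r_deoxyribose_nm backbone sphere radii, nm.
#' @param base_half_axes_nm half-axes of the base ellipsoid, nm; the largest
#'   is stored as the site radius.
#' @param base_radial_offset_nm radial distance of base centres from the
#'   fibre axis, nm.
#' @param deoxyribose_offset_deg azimuthal offset of the deoxyribose from
#'   the phosphate of the same nucleotide, degrees.
#' @param histone_radius_nm histone sphere radius, nm (perfect scavenger).
#' @return list of class `geometry_config`.
#' @export
geometry_config <- function(rise_nm = 0.34,
                            helix_radius_nm = 1.0,
                            twist_deg = 34,
                            r_phosphate_nm = 0.228,
                            r_deoxyribose_nm = 0.263,
                            base_half_axes_nm = c(0.35, 0.35, 0.17),
                            base_radial_offset_nm = 0.3,
                            deoxyribose_offset_deg = 17,
                            histone_radius_nm = 2.5) {
  stopifnot(rise_nm > 0, helix_radius_nm > 0,
            r_phosphate_nm > 0, r_deoxyribose_nm > 0,
            all(base_half_axes_nm > 0), histone_radius_nm > 0)
  structure(list(rise_nm = rise_nm,
                 helix_radius_nm = helix_radius_nm,
                 twist_deg = twist_deg,
                 r_phosphate_nm = r_phosphate_nm,
                 r_deoxyribose_nm = r_deoxyribose_nm,
                 base_half_axes_nm = base_half_axes_nm,
                 base_radial_offset_nm = base_radial_offset_nm,
                 deoxyribose_offset_deg = deoxyribose_offset_deg,
                 histone_radius_nm = histone_radius_nm),
            class = "geometry_config")
}

#' Build a straight double-helix chromatin segment
#'
#' Places the six molecule sites of every base pair (two phosphates, two
#' deoxyriboses, two bases) on a straight fibre along the z axis, with a
#' 34 degree azimuthal rotation between consecutive base pairs and random
#' AT/CG base-pair labels.
#'
#' @param n_bp number of base pairs (>= 1).
#' @param seed integer seed for the base-sequence draw.
#' @param config a [geometry_config()].
#' @param segment_id integer id stored on every site.
#' @return list of class `chromatin_segment` with elements `sites`
#'   (data.frame: segment_id, bp_index, strand, kind, x, y, z, radius),
#'   `histones` (empty until [place_histones()]), `base_sequence`, `n_bp`.
#' @export
build_helix_segment <- function(n_bp, seed = 1L, config = geometry_config(),
                                segment_id = 1L) {
  if (!is.numeric(n_bp) || length(n_bp) != 1L || n_bp < 1)
    stop("`n_bp` must be a single integer >= 1", call. = FALSE)
  n_bp <- as.integer(n_bp)
  bp <- seq_len(n_bp) - 1L
  theta0 <- bp * config$twist_deg * pi / 180
  z <- bp * config$rise_nm
  off <- config$deoxyribose_offset_deg * pi / 180

  one_strand <- function(strand) {
    th <- theta0 + strand * pi
    rh <- config$helix_radius_nm
    rb <- config$base_radial_offset_nm
    data.frame(
      segment_id = segment_id,
      bp_index = rep(bp, 3L),
      strand = strand,
      kind = rep(c("phosphate", "deoxyribose", "base"), each = n_bp),
      x = c(rh * cos(th), rh * cos(th + off), rb * cos(th)),
      y = c(rh * sin(th), rh * sin(th + off), rb * sin(th)),
      z = rep(z, 3L),
      radius = rep(c(config$r_phosphate_nm, config$r_deoxyribose_nm,
                     max(config$base_half_axes_nm)), each = n_bp),
      stringsAsFactors = FALSE
    )
  }
  sites <- rbind(one_strand(0L), one_strand(1L))
  sites <- sites[order(sites$bp_index, sites$strand, sites$kind), ]
  rownames(sites) <- NULL

  base_sequence <- withr_seed(seed, sample(c("AT", "CG"), n_bp, replace = TRUE))

  structure(list(segment_id = segment_id, n_bp = n_bp, sites = sites,
                 histones = empty_histones(), base_sequence = base_sequence,
                 config = config),
            class = "chromatin_segment")
}

empty_histones <- function() {
  data.frame(segment_id = integer(), x = numeric(), y = numeric(),
             z = numeric(), radius = numeric())
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Place histone spheres along a segment
#'
#' Histones are 2.5 nm radius spheres centred on the fibre axis at a fixed
#' base-pair spacing (one per `spacing_bp` base pairs, at the interval
#' midpoint). They act as perfect scavengers in the chemistry stage.
#'
#' @param segment a `chromatin_segment`.
#' @param spacing_bp base pairs per histone (>= 1).
#' @return the segment with its `histones` table filled;
#'   `floor(n_bp / spacing_bp)` histones.
#' @export
place_histones <- function(segment, spacing_bp = 200L) {
  stopifnot(inherits(segment, "chromatin_segment"))
  if (!is.numeric(spacing_bp) || length(spacing_bp) != 1L || spacing_bp < 1)
    stop("`spacing_bp` must be a single integer >= 1", call. = FALSE)
  spacing_bp <- as.integer(spacing_bp)
  n_h <- segment$n_bp %/% spacing_bp
  if (n_h == 0L) {
    segment$histones <- empty_histones()
    return(segment)
  }
  k <- seq_len(n_h)
  z <- (k * spacing_bp - spacing_bp / 2) * segment$config$rise_nm
  segment$histones <- data.frame(
    segment_id = segment$segment_id, x = 0, y = 0, z = z,
    radius = segment$config$histone_radius_nm)
  segment
}

#' Nucleus and cytoplasm container model
#'
#' Concentric ellipsoids (full axis lengths in micrometres) holding the
#' genome; the nucleus volume defines the dose normalisation mass (unit
#' density water).
#'
#' @param nucleus_axes_um,cytoplasm_axes_um full axis lengths (a, b, c), um.
#'   Defaults are the human-fibroblast model: nucleus 14.2 x 14.2 x 5.0 um
#'   (~528 um^3) inside a 28.0 x 28.0 x 5.0 um cytoplasm (~2052 um^3).
#' @param total_bp base pairs contained (default 6.4e9).
#' @return list of class `container_model`.
#' @export
container_model <- function(nucleus_axes_um = c(14.2, 14.2, 5.0),
                            cytoplasm_axes_um = c(28.0, 28.0, 5.0),
                            total_bp = 6.4e9) {
  stopifnot(length(nucleus_axes_um) == 3L, length(cytoplasm_axes_um) == 3L)
  if (any(nucleus_axes_um <= 0) || any(cytoplasm_axes_um <= 0))
    stop("container axes must be positive", call. = FALSE)
  if (any(cytoplasm_axes_um < nucleus_axes_um))
    stop("cytoplasm ellipsoid must contain the nucleus ellipsoid",
         call. = FALSE)
  structure(list(nucleus_axes_um = as.numeric(nucleus_axes_um),
                 cytoplasm_axes_um = as.numeric(cytoplasm_axes_um),
                 total_bp = total_bp),
            class = "container_model")
}

#' Ellipsoid volume from full axis lengths
#'
#' @param a,b,c full axis lengths (diameters along each principal axis).
#' @return volume `(pi/6) * a * b * c`, in the cube of the input unit.
#' @examples
#' ellipsoid_volume(14.2, 14.2, 5.0) # ~528 um^3 nucleus
#' ellipsoid_volume(28.0, 28.0, 5.0) # ~2052 um^3 cytoplasm
#' @export
ellipsoid_volume <- function(a, b, c) {
  if (any(c(a, b, c) <= 0)) stop("axes must be positive", call. = FALSE)
  (pi / 6) * a * b * c
}

#' Base-pair density of a nucleus
#'
#' @param total_bp base-pair count.
#' @param volume_um3 nucleus volume in um^3.
#' @return density in bp/nm^3 (`total_bp / (volume_um3 * 1e9)`).
#' @examples
#' bp_density(6.4e9, 528)  # ~0.012 bp/nm^3 (human fibroblast)
#' bp_density(3.9e9, ellipsoid_volume(8, 8, 8))  # ~0.015 bp/nm^3 (V79)
#' @export
bp_density <- function(total_bp, volume_um3) {
  if (volume_um3 <= 0) stop("volume must be positive", call. = FALSE)
  total_bp / (volume_um3 * 1e9)
}

#' Assemble segments and a container into an indexed geometry
#'
#' Builds the z-sorted spatial index used by every downstream query
#' (nearest backbone site, radical culling, diffusion).
#'
#' @param segments a `chromatin_segment` or list of them.
#' @param container a [container_model()] (optional for pure geometry
#'   queries, required by the track source).
#' @return object of class `damage_geometry`.
#' @export
assemble_geometry <- function(segments, container = NULL) {
  if (inherits(segments, "chromatin_segment")) segments <- list(segments)
  sites <- do.call(rbind, lapply(segments, `[[`, "sites"))
  histones <- do.call(rbind, lapply(segments, `[[`, "histones"))
  geom <- structure(list(segments = segments, sites = sites,
                         histones = histones, container = container,
                         config = segments[[1L]]$config),
                    class = "damage_geometry")
  geom$index <- build_site_index(geom)
  geom
}

# z-sorted matrices + tie-break priority for the C++ queries
build_site_index <- function(geom) {
  s <- geom$sites
  ord_all <- order(s$z, s$segment_id, s$bp_index, s$strand)
  bb <- which(s$kind %in% c("phosphate", "deoxyribose"))
  sb <- s[bb, ]
  ord_bb <- order(sb$z, sb$segment_id, sb$bp_index, sb$strand)
  sbo <- sb[ord_bb, ]
  # tie rule: lowest strand, then lowest bp_index
  prio <- order(order(sbo$strand, sbo$bp_index, sbo$segment_id,
                      sbo$kind, method = "radix"))
  h <- geom$histones
  list(
    all_x = s$x[ord_all], all_y = s$y[ord_all], all_z = s$z[ord_all],
    bb_rows = bb[ord_bb],
    bb_x = sbo$x, bb_y = sbo$y, bb_z = sbo$z,
    bb_radius = sbo$radius, bb_prio = as.integer(prio),
    bb_meta = sbo[, c("segment_id", "bp_index", "strand", "kind")],
    hist_x = h$x[order(h$z)], hist_y = h$y[order(h$z)],
    hist_z = sort(h$z),
    hist_radius = if (nrow(h)) h$radius[[1L]] else 0
  )
}

as_damage_geometry <- function(x) {
  if (inherits(x, "damage_geometry")) return(x)
  if (inherits(x, "chromatin_segment")) return(assemble_geometry(x))
  stop("expected a chromatin_segment or damage_geometry", call. = FALSE)
}

#' Nearest backbone site to a point
#'
#' Only phosphate and deoxyribose sites are considered (energy deposits are
#' assigned to the closest strand molecule). Exact-distance ties go to the
#' lower strand, then the lower bp index.
#'
#' @param point numeric xyz, nm (or an n x 3 matrix of query points).
#' @param geometry a `chromatin_segment` or `damage_geometry`.
#' @return data.frame with segment_id, bp_index, strand, kind, distance_nm
#'   (one row per query point).
#' @export
nearest_backbone_site <- function(point, geometry) {
  geom <- as_damage_geometry(geometry)
  q <- if (is.matrix(point)) point else matrix(point, ncol = 3L)
  idx <- geom$index
  res <- cpp_nearest_site(q, idx$bb_x, idx$bb_y, idx$bb_z, idx$bb_prio)
  out <- idx$bb_meta[res$index, , drop = FALSE]
  out$distance_nm <- res$distance
  rownames(out) <- NULL
  out
}

#' Write geometry sites to CSV
#'
#' Columns: segment_id, bp_index, strand, kind, x, y, z, radius.
#'
#' @param geometry a `damage_geometry` or `chromatin_segment`.
#' @param path output file.
#' @export
write_geometry_csv <- function(geometry, path) {
  geom <- as_damage_geometry(geometry)
  write.csv(geom$sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
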