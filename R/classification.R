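#' Split breaks into damage clusters
#'
#' Consecutive breaks along a segment stay in one cluster while the run of
#' unbroken base pairs between them is at most 100; a strictly longer
#' unbroken stretch (> 100 bp) starts a new cluster. Clusters never span
#' segments.
#'
#' @param breaks break data.frame (segment_id, bp_index, strand, source).
#' @param cluster_gap_bp maximum unbroken run kept inside one cluster
#'   (default 100).
#' @return list of `damage_cluster` objects, each a list with `segment_id`
#'   and `breaks` (rows sorted by bp, strand).
#' @export
segment_clusters <- function(breaks, cluster_gap_bp = 100) {
  if (!nrow(breaks)) return(list())
  breaks <- breaks[order(breaks$segment_id, breaks$bp_index, breaks$strand), ]
  out <- list()
  for (seg in unique(breaks$segment_id)) {
    b <- breaks[breaks$segment_id == seg, , drop = FALSE]
    pos <- b$bp_index
    # unbroken bp between consecutive break positions = diff - 1
    new_cluster <- c(TRUE, diff(pos) - 1 > cluster_gap_bp)
    grp <- cumsum(new_cluster)
    for (g in unique(grp)) {
      cl <- b[grp == g, , drop = FALSE]
      rownames(cl) <- NULL
      out[[length(out) + 1L]] <- structure(
        list(segment_id = seg, breaks = cl), class = "damage_cluster")
    }
  }
  out
}

#' Pair opposite-strand breaks into DSBs
#'
#' Maximum-cardinality pairing of opposite-strand breaks separated by at
#' most `d_dsb_bp` base pairs, realised deterministically by the
#' two-pointer sweep over position-sorted breaks of each strand (optimal
#' for this interval-window matching structure). Each break joins at most
#' one pair.
#'
#' @param cluster a `damage_cluster` (or plain break data.frame).
#' @param d_dsb_bp maximum bp separation of a DSB (default 10).
#' @return data.frame of pairs: bp0, bp1 (break positions on strand 0/1),
#'   row0, row1 (row indices into the cluster's sorted break table),
#'   midpoint.
#' @export
pair_dsbs <- function(cluster, d_dsb_bp = 10) {
  b <- if (inherits(cluster, "damage_cluster")) cluster$breaks else cluster
  i0 <- which(b$strand == 0L)
  i1 <- which(b$strand == 1L)
  i0 <- i0[order(b$bp_index[i0])]
  i1 <- i1[order(b$bp_index[i1])]
  p0 <- integer(); p1 <- integer()
  i <- 1L; j <- 1L
  while (i <= length(i0) && j <= length(i1)) {
    d <- b$bp_index[i0[i]] - b$bp_index[i1[j]]
    if (abs(d) <= d_dsb_bp) {
      p0 <- c(p0, i0[i]); p1 <- c(p1, i1[j])
      i <- i + 1L; j <- j + 1L
    } else if (d > d_dsb_bp) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(bp0 = b$bp_index[p0], bp1 = b$bp_index[p1],
             row0 = p0, row1 = p1,
             midpoint = (b$bp_index[p0] + b$bp_index[p1]) / 2)
}

#' Complexity class of a damage cluster
#'
#' Most complex applicable label: `DSBpp` for at least two DSBs, `DSBp` for
#' one DSB plus at least one additional break within `d_dsb_bp` of either
#' paired break, `DSB` for a lone DSB, otherwise `SSB_cluster`.
#'
#' @param cluster a `damage_cluster`.
#' @param d_dsb_bp maximum bp separation (default 10).
#' @param pairs optional precomputed [pair_dsbs()] result.
#' @return one of "SSB_cluster", "DSB", "DSBp", "DSBpp".
#' @export
complexity_class <- function(cluster, d_dsb_bp = 10, pairs = NULL) {
  if (is.null(pairs)) pairs <- pair_dsbs(cluster, d_dsb_bp)
  n_dsb <- nrow(pairs)
  if (n_dsb >= 2L) return("DSBpp")
  if (n_dsb == 0L) return("SSB_cluster")
  b <- cluster$breaks
  extra <- setdiff(seq_len(nrow(b)), c(pairs$row0, pairs$row1))
  if (length(extra)) {
    near <- abs(b$bp_index[extra] - pairs$bp0[1]) <= d_dsb_bp |
      abs(b$bp_index[extra] - pairs$bp1[1]) <= d_dsb_bp
    if (any(near)) return("DSBp")
  }
  "DSB"
}

#' Source class of a DSB cluster
#'
#' `DSBdir` when every break in the cluster is direct, `DSBind` when every
#' break is indirect. For mixed clusters the indirect breaks are removed
#' and pairing is re-run: if no DSB survives the cluster is `DSBhyb` (the
#' DSB does not occur in the absence of indirect damage), otherwise
#' `DSBmix`.
#'
#' @inheritParams complexity_class
#' @return one of "DSBdir", "DSBind", "DSBhyb", "DSBmix".
#' @export
source_class <- function(cluster, d_dsb_bp = 10, pairs = NULL) {
  if (is.null(pairs)) pairs <- pair_dsbs(cluster, d_dsb_bp)
  if (!nrow(pairs))
    stop("source_class() requires a cluster containing a DSB", call. = FALSE)
  src <- cluster$breaks$source
  if (all(src == "direct")) return("DSBdir")
  if (all(src == "indirect")) return("DSBind")
  direct_only <- cluster$breaks[src == "direct", , drop = FALSE]
  if (nrow(pair_dsbs(direct_only, d_dsb_bp)) == 0L) "DSBhyb" else "DSBmix"
}

#' Count DSBs surviving the distant-DSB filter
#'
#' Left-to-right scan over sorted DSB midpoints of one segment: a DSB is
#' retained only if its midpoint lies at least `min_gap_bp` after the last
#' retained one (segment ends count as open boundaries). Emulates the loss
#' of small fragments in gel electrophoresis.
#'
#' @param midpoints numeric DSB midpoints (bp) of one segment.
#' @param min_gap_bp minimum gap (default 10000).
#' @return number of retained DSBs.
#' @export
distant_dsb_filter <- function(midpoints, min_gap_bp = 10000) {
  if (length(midpoints) <= 1L) return(length(midpoints))
  m <- sort(midpoints)
  kept <- 1L
  last <- m[1L]
  for (x in m[-1L]) {
    if (x - last >= min_gap_bp) {
      kept <- kept + 1L
      last <- x
    }
  }
  kept
}

#' Summarise damage yields
#'
#' Classifies every cluster, counts breaks and DSB classes, and normalises
#' to yields per Gy per Gbp. SSBs are counted as individual breaks not in
#' any DSB pair. `N_cDSB = N_DSBp + 2 * N_DSBpp`; clusters with three or
#' more DSBs still count as one DSBpp.
#'
#' @param clusters list from [segment_clusters()].
#' @param dose_gy absorbed dose, Gy (> 0).
#' @param genome_gbp genome size, Gbp (> 0).
#' @param d_dsb_bp DSB pairing distance (default 10).
#' @param distant_gap_bp distant-DSB filter gap (default 10000).
#' @return object of class `yield_summary`: counts (n_ssb, n_dsb_clusters,
#'   n_dsb_pairs, n_dsbp, n_dsbpp, n_cdsb, n_ncdsb, n_distant_dsb, source
#'   class counts), yields per Gy per Gbp, ssb_dsb_ratio (NA when no DSBs)
#'   and scavengeable_fraction.
#' @export
summarize_yields <- function(clusters, dose_gy, genome_gbp, d_dsb_bp = 10,
                             distant_gap_bp = 10000) {
  if (dose_gy <= 0) stop("`dose_gy` must be positive", call. = FALSE)
  if (genome_gbp <= 0) stop("`genome_gbp` must be positive", call. = FALSE)
  comp <- character(length(clusters))
  srcc <- rep(NA_character_, length(clusters))
  n_pairs <- integer(length(clusters))
  n_unpaired <- integer(length(clusters))
  mids <- list()
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    pairs <- pair_dsbs(cl, d_dsb_bp)
    comp[k] <- complexity_class(cl, d_dsb_bp, pairs)
    n_pairs[k] <- nrow(pairs)
    n_unpaired[k] <- nrow(cl$breaks) - 2L * nrow(pairs)
    if (nrow(pairs)) {
      srcc[k] <- source_class(cl, d_dsb_bp, pairs)
      mids[[length(mids) + 1L]] <-
        data.frame(segment_id = cl$segment_id, midpoint = pairs$midpoint)
    }
  }
  n_dsb_clusters <- sum(comp != "SSB_cluster")
  n_dsbp <- sum(comp == "DSBp")
  n_dsbpp <- sum(comp == "DSBpp")
  n_cdsb <- n_dsbp + 2L * n_dsbpp
  n_distant <- 0L
  if (length(mids)) {
    md <- do.call(rbind, mids)
    n_distant <- sum(vapply(split(md$midpoint, md$segment_id),
                            distant_dsb_filter, integer(1),
                            min_gap_bp = distant_gap_bp))
  }
  counts <- list(
    n_breaks = sum(vapply(clusters, function(cl) nrow(cl$breaks), integer(1))),
    n_ssb = sum(n_unpaired),
    n_dsb_clusters = n_dsb_clusters,
    n_dsb_pairs = sum(n_pairs),
    n_dsb = n_dsb_clusters,
    n_dsbp = n_dsbp,
    n_dsbpp = n_dsbpp,
    n_cdsb = n_cdsb,
    n_ncdsb = n_dsb_clusters - n_dsbp - n_dsbpp,
    n_distant_dsb = n_distant,
    n_dsbdir = sum(srcc == "DSBdir", na.rm = TRUE),
    n_dsbind = sum(srcc == "DSBind", na.rm = TRUE),
    n_dsbhyb = sum(srcc == "DSBhyb", na.rm = TRUE),
    n_dsbmix = sum(srcc == "DSBmix", na.rm = TRUE))
  norm <- dose_gy * genome_gbp
  yields <- list(ssb_per_gy_gbp = counts$n_ssb / norm,
                 dsb_per_gy_gbp = counts$n_dsb / norm,
                 distant_dsb_per_gy_gbp = counts$n_distant_dsb / norm,
                 cdsb_per_gy_gbp = counts$n_cdsb / norm)
  summary <- structure(
    c(counts, yields,
      list(dose_gy = dose_gy, genome_gbp = genome_gbp,
           ssb_dsb_ratio = if (counts$n_dsb > 0)
             counts$n_ssb / counts$n_dsb else NA_real_)),
    class = "yield_summary")
  summary$scavengeable_fraction <- scavengeable_fraction(summary)
  summary
}

#' Scavengeable DSB fraction
#'
#' `(N_DSBind + N_DSBhyb) / (N_DSBdir + N_DSBmix + N_DSBind + N_DSBhyb)`.
#' DSBmix counts as non-scavengeable because it cannot be cleanly assigned.
#' Returns NA when there are no DSB clusters.
#'
#' @param summary a `yield_summary` (or list with the four source counts).
#' @return fraction in `[0, 1]`, or NA.
#' @export
scavengeable_fraction <- function(summary) {
  denom <- summary$n_dsbdir + summary$n_dsbmix + summary$n_dsbind +
    summary$n_dsbhyb
  if (denom == 0) return(NA_real_)
  (summary$n_dsbind + summary$n_dsbhyb) / denom
}

#' Classify a break list end to end
#'
#' Convenience wrapper: clusters breaks, pairs DSBs, classifies and
#' summarises in one call (also the engine behind classification-only runs
#' on break files).
#'
#' @param breaks break data.frame.
#' @param dose_gy,genome_gbp normalisation (see [summarize_yields()]).
#' @param cluster_gap_bp,d_dsb_bp,distant_gap_bp classification parameters.
#' @return a `yield_summary`.
#' @export
classify_breaks <- function(breaks, dose_gy, genome_gbp,
                            cluster_gap_bp = 100, d_dsb_bp = 10,
                            distant_gap_bp = 10000) {
  clusters <- segment_clusters(breaks, cluster_gap_bp)
  summarize_yields(clusters, dose_gy, genome_gbp, d_dsb_bp, distant_gap_bp)
}

#' Per-cluster classification table
#'
#' @param clusters list from [segment_clusters()].
#' @param d_dsb_bp DSB pairing distance.
#' @return data.frame: segment_id, n_breaks, n_dsb_pairs, span_bp,
#'   complexity, source_class.
#' @export
cluster_table <- function(clusters, d_dsb_bp = 10) {
  rows <- lapply(clusters, function(cl) {
    pairs <- pair_dsbs(cl, d_dsb_bp)
    data.frame(
      segment_id = cl$segment_id,
      n_breaks = nrow(cl$breaks),
      n_dsb_pairs = nrow(pairs),
      span_bp = diff(range(cl$breaks$bp_index)),
      complexity = complexity_class(cl, d_dsb_bp, pairs),
      source_class = if (nrow(pairs)) source_class(cl, d_dsb_bp, pairs)
      else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(segment_id = integer(), n_breaks = integer(),
                      n_dsb_pairs = integer(), span_bp = numeric(),
                      complexity = character(), source_class = character())
  out
}
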