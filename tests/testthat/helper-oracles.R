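# Brute-force oracles and small fixture builders shared across tests.

# exhaustive nearest backbone site with the documented tie rule
# (lowest strand, then lowest bp index)
brute_nearest_backbone <- function(point, sites) {
  bb <- sites[sites$kind %in% c("phosphate", "deoxyribose"), ]
  d <- sqrt((bb$x - point[1])^2 + (bb$y - point[2])^2 + (bb$z - point[3])^2)
  best <- min(d)
  cand <- bb[d <= best + 1e-9, ]
  cand <- cand[order(cand$strand, cand$bp_index), ]
  list(site = cand[1L, ], distance = best)
}

# exhaustive maximum matching of opposite-strand breaks within d bp
brute_max_matching <- function(breaks, d_dsb = 10) {
  i0 <- which(breaks$strand == 0L)
  i1 <- which(breaks$strand == 1L)
  edges <- list()
  for (a in i0) for (b in i1)
    if (abs(breaks$bp_index[a] - breaks$bp_index[b]) <= d_dsb)
      edges[[length(edges) + 1L]] <- c(a, b)
  if (!length(edges)) return(0L)
  best <- 0L
  recurse <- function(k, used) {
    if (k > length(edges)) return(0L)
    skip <- recurse(k + 1L, used)
    e <- edges[[k]]
    take <- 0L
    if (!(e[1L] %in% used) && !(e[2L] %in% used))
      take <- 1L + recurse(k + 1L, c(used, e))
    max(skip, take)
  }
  recurse(1L, integer())
}

# random damage cluster of up to max_breaks breaks in a small bp window
random_cluster <- function(max_breaks = 8L, window = 40L) {
  n <- sample.int(max_breaks, 1L)
  b <- data.frame(segment_id = 1L,
                  bp_index = sample.int(window, n, replace = TRUE),
                  strand = sample(0:1, n, replace = TRUE),
                  source = sample(c("direct", "indirect"), n, replace = TRUE))
  b <- unique(b[, c("segment_id", "bp_index", "strand", "source")])
  b[order(b$bp_index, b$strand), ]
}

as_cluster <- function(breaks) {
  structure(list(segment_id = breaks$segment_id[1L], breaks = breaks),
            class = "damage_cluster")
}

# small indexed geometry with container, used across modules
make_test_geometry <- function(n_bp = 200L, histone_spacing = 50L,
                               bp_density = 0.012, seed = 1L) {
  seg <- build_helix_segment(n_bp, seed = seed)
  if (!is.null(histone_spacing)) seg <- place_histones(seg, histone_spacing)
  assemble_geometry(seg, fibre_container(n_bp, bp_density))
}

make_breaks <- function(bp, strand, source = "direct", segment = 1L) {
  data.frame(segment_id = rep_len(as.integer(segment), length(bp)),
             bp_index = as.integer(bp),
             strand = as.integer(strand),
             source = rep_len(source, length(bp)),
             stringsAsFactors = FALSE)
}
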