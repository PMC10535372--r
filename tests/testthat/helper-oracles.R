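# Independent oracle implementations used to cross-check the package's
# primitives and merge loop.  All are deliberately naive (per-pixel scans,
# exhaustive re-evaluation) and share no code with the implementations they
# check.

# Flood-fill connected-component labelling (8-connectivity) on a raster of
# categorical values: regions are maximal connected runs of equal value.
oracle_label <- function(raster) {
  h <- nrow(raster)
  w <- ncol(raster)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    val <- raster[start]
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      p <- queue[1]
      queue <- queue[-1]
      r <- (p - 1L) %% h + 1L
      cc <- (p - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr
        c2 <- cc + dc
        if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
        p2 <- (c2 - 1L) * h + r2
        if (lab[p2] == 0L && raster[p2] == val) {
          lab[p2] <- nxt
          queue <- c(queue, p2)
        }
      }
    }
  }
  lab
}

# Border flood fill of the background (4-connectivity): everything not
# reached from the border is a hole.
oracle_fill_holes <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  reached <- matrix(FALSE, h, w)
  queue <- integer()
  for (r in 1:h) for (cc in c(1, w)) {
    p <- (cc - 1L) * h + r
    if (!mask[p] && !reached[p]) { reached[p] <- TRUE; queue <- c(queue, p) }
  }
  for (cc in 1:w) for (r in c(1, h)) {
    p <- (cc - 1L) * h + r
    if (!mask[p] && !reached[p]) { reached[p] <- TRUE; queue <- c(queue, p) }
  }
  while (length(queue) > 0) {
    p <- queue[1]
    queue <- queue[-1]
    r <- (p - 1L) %% h + 1L
    cc <- (p - 1L) %/% h + 1L
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
      p2 <- (c2 - 1L) * h + r2
      if (!mask[p2] && !reached[p2]) { reached[p2] <- TRUE; queue <- c(queue, p2) }
    }
  }
  mask | !reached
}

# Per-pixel 4-neighbour scan edge detector (border counts as outside).
oracle_edge <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in 1:h) for (cc in 1:w) {
    if (!mask[r, cc]) next
    outside <- r == 1 || r == h || cc == 1 || cc == w ||
      !mask[r - 1, cc] || !mask[r + 1, cc] ||
      !mask[r, cc - 1] || !mask[r, cc + 1]
    out[r, cc] <- outside
  }
  out
}

# Brute-force region-puzzle merge: exhaustive re-evaluation each round, no
# incremental state.  `adm` and `w` are per-region-id vectors.
oracle_rpa <- function(region_labels, seed, adm, w) {
  k <- max(region_labels)
  merged <- seed
  T_mask <- oracle_fill_holes(region_labels == seed)
  repeat {
    # neighbours by per-pixel scan
    h <- nrow(T_mask); wd <- ncol(T_mask)
    nb_ids <- integer()
    for (r in 1:h) for (cc in 1:wd) {
      if (!T_mask[r, cc]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 < 1 || r2 > h || c2 < 1 || c2 > wd) next
        if (!T_mask[r2, c2]) nb_ids <- c(nb_ids, region_labels[r2, c2])
      }
    }
    cand <- setdiff(unique(nb_ids), merged)
    cand <- cand[adm[cand]]
    if (length(cand) == 0) break
    if (length(cand) == 1) {
      T_mask <- oracle_fill_holes(T_mask | region_labels == cand)
      merged <- c(merged, cand)
      next
    }
    C_set <- which(oracle_edge(T_mask))
    P <- length(C_set)
    pass <- integer()
    for (j in cand) {
      D_set <- which(oracle_edge(region_labels == j))
      val <- length(D_set) + P - 2 * length(intersect(D_set, C_set)) - w[j]
      if (val <= P) pass <- c(pass, j)
    }
    if (length(pass) == 0) break
    T_new <- T_mask
    for (j in pass) T_new <- T_new | region_labels == j
    T_new <- oracle_fill_holes(T_new)
    P_new <- sum(oracle_edge(T_new))
    if (P_new < P) {
      T_mask <- T_new
      merged <- c(merged, pass)
    } else {
      break
    }
  }
  T_mask
}

# Random 16x16 region map (discretized Voronoi cells, relabelled into
# connected regions) plus random admissibility and weights.
random_region_map <- function(seed, size = 16, max_seeds = 6) {
  set.seed(seed)
  k <- sample(2:max_seeds, 1)
  pts <- cbind(runif(k, 1, size), runif(k, 1, size))
  assign <- matrix(0L, size, size)
  for (r in 1:size) for (cc in 1:size) {
    d <- (pts[, 1] - r)^2 + (pts[, 2] - cc)^2
    assign[r, cc] <- which.min(d)
  }
  qimg <- structure(
    list(labels = assign,
         palette = matrix(as.integer(seq(20, 240, length.out = k)),
                          nrow = k, ncol = 3),
         q = k, width = size, height = size, frame_index = 1L),
    class = "quantized_image")
  rm <- label_regions(qimg)
  n_reg <- nrow(rm$regions)
  adm <- runif(n_reg) < 0.8
  if (!any(adm)) adm[1] <- TRUE
  ids <- which(adm)
  seed_id <- ids[sample.int(length(ids), 1)]
  w <- runif(n_reg, 0, 30)
  list(map = rm, adm = adm, w = w, seed = seed_id)
}

# Construct a region_map directly from a list of disjoint id masks (the
# last listed region absorbs all unassigned pixels).
make_region_fixture <- function(height, width, masks, colors) {
  lab <- matrix(length(masks) + 1L, height, width)
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  qimg <- structure(
    list(labels = lab, palette = do.call(rbind, colors),
         q = nrow(do.call(rbind, colors)), width = width, height = height,
         frame_index = 1L),
    class = "quantized_image")
  label_regions(qimg)
}

# Rectangular logical mask from 0-based inclusive pixel coordinates.
rect_mask <- function(height, width, y0, y1, x0, x1) {
  m <- matrix(FALSE, height, width)
  m[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- TRUE
  m
}

# Small phantom geometry used across tests (320 x 240 raster).
small_phantom <- function(n_frames = 10, noise_sd = 0, seed = 7,
                          baseline_area = 10000, breathing_amplitude = 1500,
                          ...) {
  phantom_config(width = 320, height = 240, n_frames = n_frames,
                 epiglottis_center = c(160, 190), epiglottis_axes = c(120, 45),
                 baseline_area = baseline_area,
                 breathing_amplitude = breathing_amplitude,
                 breathing_period = 12, noise_sd = noise_sd, seed = seed, ...)
}
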