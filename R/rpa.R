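# Region Puzzle Algorithm: seeded merging of colour regions into the
# epiglottis (EP) region and the airway field-of-view (AE) region.
#
# The puzzle value of a mask is the size of its boundary edge set
# (P_k = |C_k|).  A candidate region R_j is scored by the symmetric
# difference of its edge with the current edge minus a positional weight
# (P_j^{k+1} = |D_j xor C_k| - w_j) and accepted when P_j^{k+1} <= P_k; a
# sweep of accepted candidates is committed only when the merged mask's
# boundary actually shrank, mirroring a jigsaw whose outline smooths as
# pieces fall into place.

#' Positional weight of a candidate region
#'
#' For AE-region merging, regions vertically closer to the epiglottis top
#' edge `Y_e` weigh more: `w_j = ybar_j - Y_e/2` (the literal reading of the
#' printed formula), or `(ybar_j - Y_e)/2` under `mode = "halved"` — both are
#' strictly increasing in the centroid row and induce the same ordering.
#'
#' @param region one-row slice (or vectorized columns) of a `region_map`
#'   `regions` tibble; only `ybar` is used.
#' @param Y_e row of the epiglottis top-edge point (0-based, positive).
#' @param mode weight variant, `"literal"` (default) or `"halved"`.
#' @return numeric weight(s).
#' @export
region_weight <- function(region, Y_e, mode = c("literal", "halved")) {
  mode <- match.arg(mode)
  if (!is.numeric(Y_e) || length(Y_e) != 1 || Y_e <= 0) {
    abort("`Y_e` must be a single positive number.",
          class = "airway_invalid_parameter")
  }
  ybar <- if (is.list(region) || is.data.frame(region)) region$ybar else region
  switch(mode,
    literal = ybar - Y_e / 2,
    halved  = (ybar - Y_e) / 2
  )
}

# Normalize an edge-set argument to a canonical set of keys.
as_pixel_set <- function(p) {
  if (is.logical(p) && is.matrix(p)) return(which(p))
  if (is.matrix(p) && ncol(p) == 2) return(complex(real = p[, 1], imaginary = p[, 2]))
  if (is.numeric(p)) return(p)
  abort("Pixel sets must be logical matrices, 2-column coordinate matrices or index vectors.",
        class = "airway_invalid_parameter")
}

#' Puzzle-function value of a merge candidate
#'
#' `|D_j xor C_k| - w_j`, where `xor` is the symmetric set difference of
#' pixel coordinates.
#'
#' @param D_j candidate region's edge pixel set (logical matrix, 2-column
#'   coordinate matrix, or linear-index vector).
#' @param C_k current target edge pixel set (same representations).
#' @param w_j candidate weight.
#' @return numeric puzzle value.
#' @export
puzzle_candidate <- function(D_j, C_k, w_j = 0) {
  d <- unique(as_pixel_set(D_j))
  c_ <- unique(as_pixel_set(C_k))
  inter <- sum(d %in% c_)
  (length(d) + length(c_) - 2 * inter) - w_j
}

#' Select a seed region inside a window
#'
#' Among regions intersecting the `s x s` window centred at `center`
#' (clipped at raster borders), returns the id of the region whose palette
#' colour has the largest (`brightest`) or smallest (`darkest`) R+G+B sum.
#' Ties go to the larger area, then the lower region id.
#'
#' @param region_map a `region_map`.
#' @param center 0-based `(x, y)` window centre.
#' @param s window side in pixels.
#' @param polarity `"brightest"` or `"darkest"`.
#' @param admissible optional logical vector over region ids; inadmissible
#'   regions are never selected.
#' @return a region id.  Signals an error of class `airway_no_seed` when the
#'   window contains no eligible region pixels.
#' @export
seed_region <- function(region_map, center, s,
                        polarity = c("brightest", "darkest"),
                        admissible = NULL) {
  polarity <- match.arg(polarity)
  s <- check_count(s, "s", min = 1)
  win <- clip_window(center[1], center[2], s, region_map$width, region_map$height)
  if (is.null(win)) {
    abort("Seed window lies outside the raster.", class = "airway_no_seed")
  }
  ids <- unique(as.vector(region_map$region_labels[win$rows, win$cols]))
  if (!is.null(admissible)) ids <- ids[admissible[ids]]
  if (length(ids) == 0) {
    abort("No eligible region in the seed window.", class = "airway_no_seed")
  }
  reg <- region_map$regions[ids, ]
  key <- if (polarity == "brightest") -reg$color_sum else reg$color_sum
  ids[order(key, -reg$area, reg$id)][1]
}

# Per-region boundary-edge pixel indices: a pixel is on its region's edge if
# any 4-neighbour carries a different region id (raster border counts as
# different).  Returns a list indexed by region id.
region_edge_sets <- function(region_map) {
  rl <- region_map$region_labels
  h <- nrow(rl)
  w <- ncol(rl)
  pad <- -1L
  up    <- rbind(pad, rl[-h, , drop = FALSE])
  down  <- rbind(rl[-1, , drop = FALSE], pad)
  left  <- cbind(pad, rl[, -w, drop = FALSE])
  right <- cbind(rl[, -1, drop = FALSE], pad)
  edge <- rl != up | rl != down | rl != left | rl != right
  idx <- which(edge)
  out <- split(idx, rl[idx])
  # ensure every region id (1..K) is present
  k <- nrow(region_map$regions)
  full <- vector("list", k)
  full[as.integer(names(out))] <- out
  full
}

# Region ids 4-adjacent to mask `T`, with shared-border pixel counts.
mask_neighbors <- function(region_map, T_mask) {
  h <- nrow(T_mask)
  w <- ncol(T_mask)
  up    <- rbind(FALSE, T_mask[-h, , drop = FALSE])
  down  <- rbind(T_mask[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, T_mask[, -w, drop = FALSE])
  right <- cbind(T_mask[, -1, drop = FALSE], FALSE)
  ring <- (up | down | left | right) & !T_mask
  ring_ids <- region_map$region_labels[ring]
  counts <- tabulate(ring_ids, nbins = nrow(region_map$regions))
  list(ids = which(counts > 0), counts = counts)
}

#' Region-puzzle merge loop
#'
#' Grows a mask from a seed region.  Each iteration: (i) when exactly one
#' admissible region neighbours the current mask it is merged directly;
#' (ii) otherwise every admissible neighbour `R_j` is scored with
#' [puzzle_candidate()] against the current edge `C_k`, all candidates with
#' `P_j^{k+1} <= P_k` are merged in one sweep (holes filled afterwards), and
#' the sweep is committed only if the resulting boundary is strictly smaller
#' than `P_k`.  The loop stops when no candidate passes or a sweep fails to
#' shrink the boundary; a seed-only result is valid.
#'
#' @param region_map a `region_map`.
#' @param seed admissible seed region id.
#' @param admissible logical vector over region ids (`TRUE` = mergeable), or
#'   a function of the `regions` tibble returning one.
#' @param weight_fn `NULL` (weight 0 everywhere) or a function of the
#'   `regions` tibble returning per-region weights.
#' @return a list: `mask` (logical matrix), `merged_ids` (region ids in merge
#'   order, seed first), and `trace`, a tibble with one row per committed
#'   iteration (`iteration`, `type` = direct/sweep, `ids` list-column,
#'   `P_before`, `P_after`).
#' @export
rpa_merge <- function(region_map, seed, admissible = NULL, weight_fn = NULL) {
  k_regions <- nrow(region_map$regions)
  adm <- if (is.null(admissible)) {
    rep(TRUE, k_regions)
  } else if (is.function(admissible)) {
    admissible(region_map$regions)
  } else {
    admissible
  }
  if (!adm[seed]) {
    abort("Seed region must be admissible.", class = "airway_invalid_parameter")
  }
  w <- if (is.null(weight_fn)) rep(0, k_regions) else weight_fn(region_map$regions)
  d_sets <- region_edge_sets(region_map)
  d_size <- lengths(d_sets)
  rl <- region_map$region_labels

  T_mask <- fill_holes(rl == seed)
  merged <- seed
  trace <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > k_regions + 1L) break  # safety; merging is strictly monotone
    nb <- mask_neighbors(region_map, T_mask)
    cand <- setdiff(nb$ids[adm[nb$ids]], merged)
    if (length(cand) == 0) break

    if (length(cand) == 1L) {
      # surrounded by a single admissible region: merge directly
      T_mask <- fill_holes(T_mask | rl == cand)
      merged <- c(merged, cand)
      trace[[length(trace) + 1L]] <-
        list(iteration = iter, type = "direct", ids = list(cand),
             P_before = NA_real_, P_after = sum(boundary_edge(T_mask)))
      next
    }

    C_idx <- edge_which(T_mask)
    P <- length(C_idx)
    p_cand <- vapply(cand, function(j) {
      inter <- sum(d_sets[[j]] %in% C_idx)
      (d_size[j] + P - 2 * inter) - w[j]
    }, numeric(1))
    pass <- cand[p_cand <= P]
    if (length(pass) == 0) break
    pass <- pass[order(-nb$counts[pass], pass)]  # sweep order: shared border desc

    T_new <- fill_holes(T_mask | matrix(rl %in% pass, nrow(rl), ncol(rl)))
    P_new <- sum(boundary_edge(T_new))
    if (P_new < P) {
      T_mask <- T_new
      merged <- c(merged, pass)
      trace[[length(trace) + 1L]] <-
        list(iteration = iter, type = "sweep", ids = list(pass),
             P_before = P, P_after = P_new)
    } else {
      break
    }
  }

  trace_tbl <- if (length(trace) == 0) {
    tibble(iteration = integer(), type = character(), ids = list(),
           P_before = numeric(), P_after = numeric())
  } else {
    dplyr::bind_rows(lapply(trace, as_tibble))
  }
  list(mask = T_mask, merged_ids = merged, trace = trace_tbl)
}

#' Anchor points of an EP mask
#'
#' Finds the lowest EP pixel `rho = (x_rho, y_rho)` (maximum row; ties to the
#' smallest column), and the top edge point `tau = (x_rho, Y_e)` — the
#' minimum-row mask pixel in column `x_rho`.  The AE seed window is centred
#' at `(x_rho, round(Y_e/2))`.
#'
#' @param ep logical EP mask.
#' @return list with `x_rho`, `y_rho`, `Y_e` (0-based) and `ae_center`,
#'   the `(x, y)` AE seed-window centre.
#' @export
ep_anchor <- function(ep) {
  idx <- which(ep, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    abort("EP mask is empty.", class = "airway_invalid_parameter")
  }
  row0 <- idx[, 1] - 1L
  col0 <- idx[, 2] - 1L
  y_rho <- max(row0)
  x_rho <- min(col0[row0 == y_rho])
  y_e <- min(row0[col0 == x_rho])
  list(x_rho = x_rho, y_rho = y_rho, Y_e = y_e,
       ae_center = c(x_rho, as.integer(floor(y_e / 2 + 0.5))))
}

#' Merge the epiglottis (EP) region inside a bounding box
#'
#' Seeds at the brightest region in a `u x u` window at the box centre and
#' grows by [rpa_merge()] with weight 0; only regions wholly inside the box
#' are mergeable.  When the seed region itself overflows the box it is
#' returned unmerged as the EP region.
#'
#' @param region_map a `region_map`.
#' @param box bounding box: list or one-row data frame with `x`, `y`
#'   (0-based top-left), `width`, `height`.
#' @param u seed window side; defaults to `max(8, round(height/2))`.  When
#'   supplied explicitly it must lie within `[height/4, height/2]`.
#' @return an object of class `ep_region`: `mask`, `anchor` (see
#'   [ep_anchor()]), `overflowed`, `merged_ids`, `trace`.  Signals
#'   `airway_no_epiglottis` when the seed window contains no region pixels.
#' @export
merge_ep_region <- function(region_map, box, u = NULL) {
  bx <- as.integer(box$x); by <- as.integer(box$y)
  bw <- as.integer(box$width); bh <- as.integer(box$height)
  if (bw <= 0 || bh <= 0) {
    abort("Bounding box must have positive size.", class = "airway_invalid_parameter")
  }
  if (is.null(u)) {
    u <- max(8L, as.integer(round(bh / 2)))
  } else {
    u <- check_count(u, "u")
    if (u < floor(bh / 4) || u > ceiling(bh / 2)) {
      abort("`u` must lie between height/4 and height/2 of the bounding box.",
            class = "airway_invalid_parameter")
    }
  }
  center <- c(bx + as.integer(floor((bw - 1) / 2 + 0.5)),
              by + as.integer(floor((bh - 1) / 2 + 0.5)))
  seed <- tryCatch(
    seed_region(region_map, center, u, "brightest"),
    airway_no_seed = function(e) {
      abort("No epiglottis region found in the detector box.",
            class = "airway_no_epiglottis")
    }
  )
  reg <- region_map$regions
  inside <- reg$xmin >= bx & reg$xmax <= bx + bw - 1L &
            reg$ymin >= by & reg$ymax <= by + bh - 1L
  if (!inside[seed]) {
    mask <- region_map$region_labels == seed
    res <- list(mask = mask, merged_ids = seed,
                trace = tibble(iteration = integer(), type = character(),
                               ids = list(), P_before = numeric(),
                               P_after = numeric()))
    overflowed <- TRUE
  } else {
    res <- rpa_merge(region_map, seed, admissible = inside)
    overflowed <- FALSE
  }
  structure(
    list(mask = res$mask, anchor = ep_anchor(res$mask), overflowed = overflowed,
         merged_ids = res$merged_ids, trace = res$trace,
         box = list(x = bx, y = by, width = bw, height = bh)),
    class = "ep_region"
  )
}

#' Merge the airway FOV (AE) region above the epiglottis
#'
#' Seeds at the darkest admissible region in an `h x h` window centred at
#' `(x_rho, Y_e/2)` and grows by [rpa_merge()] with the positional weight
#' [region_weight()]; only regions lying entirely above the epiglottis top
#' edge (`ymax <= Y_e`) are mergeable.  A window with no sufficiently dark
#' admissible region yields an empty AE region — the complete-obstruction
#' outcome (`omega = 0`), not an error.
#'
#' @param region_map a `region_map`.
#' @param anchor anchor list from [ep_anchor()].
#' @param h seed window side; defaults to `max(4, round(Y_e/4))`.  When
#'   supplied explicitly it must lie within `[Y_e/4, Y_e/2]`.
#' @param seed_dark_max maximum palette R+G+B sum for a region to qualify as
#'   an airway seed (default 300); the darkness criterion that lets a fully
#'   obstructed airway report `omega = 0`.
#' @param weight_mode weight variant passed to [region_weight()].
#' @return an object of class `ae_region`: `mask`, `omega` (pixel area |A|),
#'   `complete` (no airway seed found), `merged_ids`, `trace`.
#' @export
merge_ae_region <- function(region_map, anchor, h = NULL, seed_dark_max = 300,
                            weight_mode = c("literal", "halved")) {
  weight_mode <- match.arg(weight_mode)
  y_e <- anchor$Y_e
  empty <- function() {
    structure(
      list(mask = matrix(FALSE, region_map$height, region_map$width),
           omega = 0L, complete = TRUE, merged_ids = integer(),
           trace = tibble(iteration = integer(), type = character(),
                          ids = list(), P_before = numeric(),
                          P_after = numeric())),
      class = "ae_region"
    )
  }
  if (y_e < 4) return(empty())
  if (is.null(h)) {
    h <- max(4L, as.integer(round(y_e / 4)))
  } else {
    h <- check_count(h, "h")
    if (h < floor(y_e / 4) || h > ceiling(y_e / 2)) {
      abort("`h` must lie between Y_e/4 and Y_e/2.",
            class = "airway_invalid_parameter")
    }
  }
  reg <- region_map$regions
  adm <- reg$ymax <= y_e
  seed_ok <- adm & reg$color_sum <= seed_dark_max
  seed <- tryCatch(
    seed_region(region_map, anchor$ae_center, h, "darkest", admissible = seed_ok),
    airway_no_seed = function(e) NULL
  )
  if (is.null(seed)) return(empty())
  res <- rpa_merge(region_map, seed, admissible = adm,
                   weight_fn = function(regions) {
                     region_weight(regions, y_e, mode = weight_mode)
                   })
  structure(
    list(mask = res$mask, omega = sum(res$mask), complete = FALSE,
         merged_ids = res$merged_ids, trace = res$trace),
    class = "ae_region"
  )
}
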