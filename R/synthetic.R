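# Phantom endoscopy sequences with exact ground truth: a bright convex
# epiglottis in the lower image half, a dark airway blob above its top edge
# whose pixel area follows a programmed schedule, a mid-tone pharyngeal-wall
# background, optional sensor noise, and scope-slip gaps.

#' Phantom sequence configuration
#'
#' @param width,height raster size in pixels (default 640 x 480).
#' @param n_frames number of frames.
#' @param epiglottis_center,epiglottis_axes 0-based `(x, y)` centre and
#'   `(a, b)` semi-axes of the bright epiglottis ellipse.
#' @param epiglottis_color,background,airway_color RGB triples.
#' @param baseline_area airway pixel-area baseline of the schedule.
#' @param breathing_amplitude,breathing_period sinusoidal modulation of the
#'   airway area (pixels; period in frames).
#' @param occlusions list of occlusion episodes `list(start, end, depth)`
#'   with `depth` in `[0, 1]` (1 = complete obstruction).
#' @param slips list of scope-slip intervals `c(start, end)`: the epiglottis
#'   leaves the frame and the scene shifts.
#' @param interference list of operator-marked interference intervals.
#' @param noise_sd Gaussian sensor-noise standard deviation in gray levels
#'   (default 4; 0 disables noise).
#' @param vignette radial illumination falloff strength in `[0, 1)` (default
#'   0 = flat illumination); positive values darken the frame towards the
#'   corners, emulating the endoscope light source.
#' @param airway_aspect vertical-to-horizontal semi-axis ratio of the airway
#'   ellipse.
#' @param seed RNG seed for the noise.
#' @return a `phantom_config` list, validated.
#' @export
phantom_config <- function(width = 640, height = 480, n_frames = 100,
                           epiglottis_center = c(320, 380),
                           epiglottis_axes = c(240, 90),
                           epiglottis_color = c(250, 210, 200),
                           background = c(140, 105, 100),
                           airway_color = c(15, 15, 20),
                           baseline_area = 40000,
                           breathing_amplitude = 6000,
                           breathing_period = 40,
                           occlusions = list(),
                           slips = list(),
                           interference = list(),
                           noise_sd = 4,
                           vignette = 0,
                           airway_aspect = 0.6,
                           seed = 1L) {
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    n_frames = check_count(n_frames, "n_frames"),
    epiglottis_center = epiglottis_center, epiglottis_axes = epiglottis_axes,
    epiglottis_color = epiglottis_color, background = background,
    airway_color = airway_color,
    baseline_area = baseline_area,
    breathing_amplitude = breathing_amplitude,
    breathing_period = breathing_period,
    occlusions = occlusions, slips = slips, interference = interference,
    noise_sd = noise_sd, vignette = vignette,
    airway_aspect = airway_aspect,
    seed = as.integer(seed)
  )
  cfg$epi_top <- epiglottis_center[2] - epiglottis_axes[2]
  cfg$airway_center <- c(epiglottis_center[1], round(cfg$epi_top / 2))

  a_max <- baseline_area + abs(breathing_amplitude)
  if (a_max < 0 || baseline_area < 0) {
    abort("Schedule areas must be non-negative.", class = "airway_config_error")
  }
  b_max <- sqrt(a_max * airway_aspect / pi)
  a_semi_max <- sqrt(a_max / (pi * airway_aspect))
  if (cfg$airway_center[2] + b_max > cfg$epi_top - 4 ||
      cfg$airway_center[2] - b_max < 0 ||
      cfg$airway_center[1] - a_semi_max < 0 ||
      cfg$airway_center[1] + a_semi_max > width - 1) {
    abort("Scheduled airway area does not fit above the epiglottis.",
          class = "airway_config_error")
  }
  all_int <- c(cfg$slips, cfg$occlusions, cfg$interference)
  for (iv in all_int) {
    s <- if (is.list(iv)) iv$start else iv[1]
    e <- if (is.list(iv)) iv$end else iv[2]
    if (s < 1 || e > n_frames || s > e) {
      abort("Intervals must lie within the frame range.",
            class = "airway_config_error")
    }
  }
  structure(cfg, class = "phantom_config")
}

# Programmed airway area for each frame.
phantom_schedule <- function(cfg) {
  n <- seq_len(cfg$n_frames)
  area <- cfg$baseline_area +
    cfg$breathing_amplitude * sin(2 * pi * (n - 1) / cfg$breathing_period)
  for (ep in cfg$occlusions) {
    sel <- n >= ep$start & n <= ep$end
    area[sel] <- area[sel] * (1 - ep$depth)
  }
  pmax(area, 0)
}

# Rasterize an ellipse of (approximately) `target` pixels, calibrating the
# semi-axes until the rendered area is within 0.5% of the target.
render_ellipse_area <- function(target, cx, cy, aspect, width, height) {
  if (target < 1) return(matrix(FALSE, height, width))
  x <- matrix(rep(0:(width - 1), each = height), height, width)
  y <- matrix(rep(0:(height - 1), times = width), height, width)
  a <- sqrt(target / (pi * aspect))
  for (i in 1:12) {
    b <- aspect * a
    mask <- ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
    cnt <- sum(mask)
    if (cnt > 0 && abs(cnt - target) / target <= 0.005) break
    a <- a * sqrt(target / max(cnt, 1))
  }
  mask
}

render_ellipse <- function(cx, cy, a, b, width, height) {
  x <- matrix(rep(0:(width - 1), each = height), height, width)
  y <- matrix(rep(0:(height - 1), times = width), height, width)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

#' Generate a phantom frame sequence with ground truth
#'
#' Deterministic for a fixed config (the config's `seed` drives the noise).
#' Each frame composes a mid-tone background, the bright epiglottis ellipse,
#' and a dark airway ellipse whose rendered pixel area matches the schedule
#' within ±2%; scope-slip frames omit the epiglottis and shift the scene.
#'
#' @param cfg a [phantom_config()].
#' @return a list: `frames` (list of [rgb_frame()]) and `truth`, a
#'   `ground_truth` object (per-frame tibble with status, true box, masks in
#'   run-length form, true area `a_star` and true ratio `o_star`; plus the
#'   true `periods`).
#' @export
generate_sequence <- function(cfg) {
  if (!inherits(cfg, "phantom_config")) {
    abort("`cfg` must be a phantom_config.", class = "airway_invalid_parameter")
  }
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(cfg$seed)

  w <- cfg$width; h <- cfg$height
  schedule <- phantom_schedule(cfg)
  as_matrix <- function(ivs) {
    if (length(ivs) == 0) return(matrix(integer(), ncol = 2))
    do.call(rbind, lapply(ivs, function(v) {
      if (is.list(v)) c(v$start, v$end) else c(v[1], v[2])
    }))
  }
  slip <- in_intervals(seq_len(cfg$n_frames), as_matrix(cfg$slips))
  interf <- in_intervals(seq_len(cfg$n_frames), as_matrix(cfg$interference))

  ep_mask0 <- render_ellipse(cfg$epiglottis_center[1], cfg$epiglottis_center[2],
                             cfg$epiglottis_axes[1], cfg$epiglottis_axes[2], w, h)
  ep_idx <- which(ep_mask0, arr.ind = TRUE)
  box <- list(
    x = max(0L, min(ep_idx[, 2]) - 1L - 5L),
    y = max(0L, min(ep_idx[, 1]) - 1L - 5L)
  )
  box$width  <- min(w - 1L, max(ep_idx[, 2]) - 1L + 5L) - box$x + 1L
  box$height <- min(h - 1L, max(ep_idx[, 1]) - 1L + 5L) - box$y + 1L

  frames <- vector("list", cfg$n_frames)
  rows <- vector("list", cfg$n_frames)
  slip_shift <- c(17L, 11L)

  for (n in seq_len(cfg$n_frames)) {
    target <- schedule[n]
    cx <- cfg$airway_center[1]
    cy <- cfg$airway_center[2]
    if (slip[n]) {
      ae_mask <- render_ellipse_area(target, cx + slip_shift[1],
                                     cy + slip_shift[2], cfg$airway_aspect, w, h)
      ep_mask <- matrix(FALSE, h, w)
    } else {
      ae_mask <- render_ellipse_area(target, cx, cy, cfg$airway_aspect, w, h)
      ep_mask <- ep_mask0
    }
    px <- array(0L, dim = c(h, w, 3))
    vig <- NULL
    if (cfg$vignette > 0) {
      xg <- matrix(rep(0:(w - 1), each = h), h, w)
      yg <- matrix(rep(0:(h - 1), times = w), h, w)
      r2 <- (((xg - (w - 1) / 2) / (w / 2))^2 +
               ((yg - (h - 1) / 2) / (h / 2))^2) / 2
      vig <- 1 - cfg$vignette * r2
    }
    for (ch in 1:3) {
      plane <- matrix(cfg$background[ch], h, w)
      plane[ae_mask] <- cfg$airway_color[ch]
      plane[ep_mask] <- cfg$epiglottis_color[ch]
      if (!is.null(vig)) plane <- plane * vig
      if (cfg$noise_sd > 0) {
        plane <- plane + rnorm(h * w, sd = cfg$noise_sd)
      }
      px[, , ch] <- as.integer(pmin(255, pmax(0, round(plane))))
    }
    frames[[n]] <- rgb_frame(px, index = n)

    status <- if (slip[n]) "slip" else if (target == 0) "occluded"
      else if (interf[n]) "interference" else "normal"
    rows[[n]] <- tibble(
      n = n, status = status,
      box_x = if (slip[n]) NA_integer_ else box$x,
      box_y = if (slip[n]) NA_integer_ else box$y,
      box_width = if (slip[n]) NA_integer_ else box$width,
      box_height = if (slip[n]) NA_integer_ else box$height,
      scheduled_area = target,
      a_star = if (slip[n]) NA_integer_ else sum(ae_mask),
      ep_rle = list(encode_mask_rle(ep_mask)),
      ae_rle = list(encode_mask_rle(ae_mask))
    )
  }

  ft <- dplyr::bind_rows(rows)
  periods <- segment_periods(!slip)
  ft$o_star <- NA_real_
  for (i in seq_len(nrow(periods))) {
    sel <- which(ft$n >= periods$start[i] & ft$n <= periods$end[i])
    mx <- max(ft$a_star[sel])
    if (mx > 0) ft$o_star[sel] <- 100 * (mx - ft$a_star[sel]) / mx
  }

  truth <- structure(list(frames = ft, periods = periods, config = cfg),
                     class = "ground_truth")
  list(frames = frames, truth = truth)
}

#' Run-length encode a binary mask
#'
#' Column-major runs; the companion of [decode_mask_rle()].
#'
#' @param mask logical matrix.
#' @return list with `dim`, `first` (value of the first run, 0/1) and
#'   `lengths`.
#' @export
encode_mask_rle <- function(mask) {
  r <- rle(as.integer(mask))
  list(dim = dim(mask), first = r$values[1], lengths = r$lengths)
}

#' Decode a run-length encoded mask
#'
#' @param rle_obj list produced by [encode_mask_rle()].
#' @return logical matrix.
#' @export
decode_mask_rle <- function(rle_obj) {
  k <- length(rle_obj$lengths)
  values <- rep(c(rle_obj$first, 1 - rle_obj$first), length.out = k)
  v <- inverse.rle(list(lengths = rle_obj$lengths, values = values))
  matrix(as.logical(v), rle_obj$dim[1], rle_obj$dim[2])
}

#' Write ground truth to JSON
#'
#' Lossless round trip with [read_ground_truth()]; masks stored run-length
#' encoded.
#'
#' @param truth a `ground_truth` object.
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  ft <- truth$frames
  frames <- lapply(seq_len(nrow(ft)), function(i) {
    list(
      n = ft$n[i], status = ft$status[i],
      box = if (is.na(ft$box_x[i])) NULL else
        list(x = ft$box_x[i], y = ft$box_y[i],
             width = ft$box_width[i], height = ft$box_height[i]),
      scheduled_area = ft$scheduled_area[i],
      a_star = ft$a_star[i], o_star = ft$o_star[i],
      ep_rle = ft$ep_rle[[i]], ae_rle = ft$ae_rle[[i]]
    )
  })
  payload <- list(
    frames = frames,
    periods = lapply(seq_len(nrow(truth$periods)), function(i)
      as.list(truth$periods[i, ]))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read ground truth from JSON
#'
#' @param path JSON file written by [write_ground_truth()].
#' @return a `ground_truth` object (without the generating config).
#' @export
read_ground_truth <- function(path) {
  js <- jsonlite::read_json(path)
  rows <- lapply(js$frames, function(f) {
    tibble(
      n = as.integer(f$n), status = f$status,
      box_x = if (is.null(f$box)) NA_integer_ else as.integer(f$box$x),
      box_y = if (is.null(f$box)) NA_integer_ else as.integer(f$box$y),
      box_width = if (is.null(f$box)) NA_integer_ else as.integer(f$box$width),
      box_height = if (is.null(f$box)) NA_integer_ else as.integer(f$box$height),
      scheduled_area = as.numeric(f$scheduled_area),
      a_star = if (is.null(f$a_star)) NA_integer_ else as.integer(f$a_star),
      ep_rle = list(list(dim = unlist(f$ep_rle$dim),
                         first = f$ep_rle$first,
                         lengths = unlist(f$ep_rle$lengths))),
      ae_rle = list(list(dim = unlist(f$ae_rle$dim),
                         first = f$ae_rle$first,
                         lengths = unlist(f$ae_rle$lengths))),
      o_star = if (is.null(f$o_star)) NA_real_ else as.numeric(f$o_star)
    )
  })
  ft <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(n = integer(), status = character())
  periods <- if (length(js$periods)) {
    dplyr::bind_rows(lapply(js$periods, as_tibble))
  } else {
    tibble(m = integer(), start = integer(), end = integer())
  }
  structure(list(frames = ft, periods = periods, config = NULL),
            class = "ground_truth")
}
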