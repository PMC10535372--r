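# Sequence-level orchestration: per-frame analysis, endoscope-stable
# periods, abnormal-frame filtering, and the obstruction-ratio series.

FRAME_STATUSES <- c("ok", "no_epiglottis", "complete_obstruction",
                    "abnormal", "interference_excluded")

#' Segment detection flags into endoscope-stable periods
#'
#' A period is a maximal run of consecutive frames in which the epiglottis
#' is detected; the first undetected frame ends the period (the endoscope is
#' assumed to have slipped) and the next detection opens period `m + 1`.
#'
#' @param detected logical vector, one flag per frame.
#' @return a tibble with columns `m`, `start`, `end` (1-based frame
#'   indices); zero rows when nothing was detected.
#' @export
segment_periods <- function(detected) {
  if (length(detected) == 0) {
    abort("`detected` must be non-empty.", class = "airway_invalid_parameter")
  }
  r <- rle(as.logical(detected))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(m = seq_len(sum(keep)), start = starts[keep], end = ends[keep])
}

#' Analyze one frame
#'
#' Runs the full single-frame chain: quantize, label regions, merge the EP
#' region inside the detector box, anchor it, and merge the AE region above
#' it.  A missing box — or a box whose seed window holds no region — yields
#' status `no_epiglottis`; an empty AE region yields `complete_obstruction`
#' with `omega = 0`.
#'
#' @param frame an [rgb_frame()].
#' @param box one-row box tibble (or `NULL` when undetected).
#' @param q colour quantization number (default 6).
#' @param u,h seed window sides for EP / AE merging (defaults derived from
#'   the box height and `Y_e`; see [merge_ep_region()], [merge_ae_region()]).
#' @param seed_dark_max,weight_mode passed to [merge_ae_region()].
#' @param keep_masks retain the EP/AE masks in the result (memory-heavy for
#'   long sequences).
#' @return a list: `n`, `detected`, `status`, `omega`, and (when
#'   `keep_masks`) `ep` and `ae` objects.
#' @export
analyze_frame <- function(frame, box, q = 6, u = NULL, h = NULL,
                          seed_dark_max = 300,
                          weight_mode = c("literal", "halved"),
                          keep_masks = FALSE) {
  weight_mode <- match.arg(weight_mode)
  n <- frame$index
  blank <- list(n = n, detected = FALSE, status = "no_epiglottis", omega = 0L)
  if (is.null(box)) return(blank)
  qimg <- median_cut_quantize(frame, q)
  rmap <- label_regions(qimg)
  ep <- tryCatch(merge_ep_region(rmap, box, u = u),
                 airway_no_epiglottis = function(e) NULL)
  if (is.null(ep)) return(blank)
  ae <- merge_ae_region(rmap, ep$anchor, h = h, seed_dark_max = seed_dark_max,
                        weight_mode = weight_mode)
  out <- list(
    n = n, detected = TRUE,
    status = if (ae$complete) "complete_obstruction" else "ok",
    omega = as.integer(ae$omega)
  )
  if (keep_masks) {
    out$ep <- ep
    out$ae <- ae
  }
  out
}

#' Neighbour-consistency abnormality rule
#'
#' A frame with a positive airway area is abnormal when both its neighbours
#' report no epiglottis or complete obstruction — the endoscope cannot
#' reveal an open airway for a single frame between two blocked views.
#' Sequence endpoints are judged by their single neighbour.
#'
#' @param status character vector of frame statuses.
#' @param omega integer vector of airway areas.
#' @return logical vector: `TRUE` where the frame is abnormal.
#' @export
flag_abnormal_neighbors <- function(status, omega) {
  n <- length(status)
  if (n < 1) abort("Empty sequence.", class = "airway_invalid_parameter")
  blocker <- status %in% c("no_epiglottis", "complete_obstruction")
  candidate <- status == "ok" & omega > 0
  if (n == 1) return(rep(FALSE, 1))
  left <- c(NA, blocker[-n])
  right <- c(blocker[-1], NA)
  left[1] <- right[1]      # endpoints: single neighbour counts twice
  right[n] <- left[n]
  candidate & left & right
}

#' Backward-difference spike abnormality rule
#'
#' Computes the backward difference `omega'_n = omega_n - omega_{n-1}` and
#' flags frame `n` when the flanking differences form a sign-alternating
#' spike (`+,-` or `-,+`) with both magnitudes above the threshold
#' `epsilon` — a one-frame excursion too fast for a physiological airway.
#' Monotone ramps and sub-threshold bumps are never flagged.
#'
#' @param omega numeric series of airway areas (consecutive frames).
#' @param epsilon spike threshold in pixels (default 30000).
#' @return logical vector the length of `omega`.
#' @export
flag_abnormal_diff <- function(omega, epsilon = 30000) {
  if (epsilon <= 0) {
    abort("`epsilon` must be positive.", class = "airway_invalid_parameter")
  }
  n <- length(omega)
  out <- rep(FALSE, n)
  if (n < 3) return(out)
  d <- diff(omega)  # d[i] = omega'_{i+1} = omega_{i+1} - omega_i
  for (i in 2:(n - 1)) {
    din <- d[i - 1]
    dout <- d[i]
    if (sign(din) * sign(dout) < 0 && abs(din) > epsilon && abs(dout) > epsilon) {
      out[i] <- TRUE
    }
  }
  out
}

#' Obstruction-ratio series
#'
#' Implements the per-period ratio: each period's largest AE area among
#' frames that are neither abnormal nor excluded is the unobstructed
#' reference, and every frame reports
#' `O = 100 * (max|A| - |A|) / max|A|`, rounded half-up to 0.1.
#' Complete-obstruction frames report 100.0; abnormal, excluded and
#' no-epiglottis frames carry no ratio.  A period whose maximum is zero
#' yields no ratios and a warning.
#'
#' @param results tibble with columns `n`, `status`, `omega` (one row per
#'   frame, `n` consecutive from 1).
#' @param periods tibble from [segment_periods()].
#' @return a list: `frames` (the input plus `period`, `max_area`, `ratio`)
#'   and `periods` (the input plus `max_area`, `n_frames`).
#' @export
obstruction_ratios <- function(results, periods) {
  n_frames <- nrow(results)
  lens <- periods$end - periods$start + 1L
  period_of <- rep(NA_integer_, n_frames)
  in_rows <- match(
    unlist(mapply(seq.int, periods$start, periods$end, SIMPLIFY = FALSE)),
    results$n)
  pid <- rep(periods$m, lens)
  keep <- !is.na(in_rows)
  period_of[in_rows[keep]] <- pid[keep]

  status <- results$status
  omega <- results$omega
  counted <- !is.na(period_of) & status %in% c("ok", "complete_obstruction")
  max_by_m <- rep(NA_real_, nrow(periods))
  if (any(counted)) {
    mx <- tapply(omega[counted], period_of[counted], max)
    max_by_m[match(as.integer(names(mx)), periods$m)] <- as.numeric(mx)
  }
  zero_max <- which(!is.na(max_by_m) & max_by_m <= 0)
  if (length(zero_max) > 0) {
    warn(sprintf("Period(s) %s have zero maximum AE area; no ratios reported.",
                 paste(periods$m[zero_max], collapse = ", ")))
  }

  max_of <- rep(NA_real_, n_frames)
  valid <- !is.na(period_of)
  max_of[valid] <- max_by_m[match(period_of[valid], periods$m)]
  max_of[!is.na(max_of) & max_of <= 0] <- NA_real_

  ratio <- rep(NA_real_, n_frames)
  ok <- status == "ok" & !is.na(max_of)
  ratio[ok] <- round_half_up(100 * (max_of[ok] - omega[ok]) / max_of[ok], 1)
  comp <- status == "complete_obstruction" & !is.na(max_of)
  ratio[comp] <- 100.0

  frames <- dplyr::mutate(results, period = period_of, max_area = max_of,
                          ratio = ratio)
  periods <- dplyr::mutate(periods, max_area = max_by_m, n_frames = lens)
  list(frames = frames, periods = periods)
}

#' Average obstruction ratio over a frame interval
#'
#' Arithmetic mean of the reported ratios over the frames of `interval` that
#' carry one, rounded half-up to 0.1.
#'
#' @param x an `airway_analysis` object or a frames tibble with `n` and
#'   `ratio` columns.
#' @param interval length-2 vector `c(first, last)` of 1-based frame indices.
#' @return the mean ratio (percent).  Signals `airway_undefined_average`
#'   when no frame in the interval carries a ratio.
#' @export
period_average <- function(x, interval) {
  frames <- if (inherits(x, "airway_analysis")) x$frames else x
  sel <- frames$n >= interval[1] & frames$n <= interval[2] & !is.na(frames$ratio)
  if (!any(sel)) {
    abort("No frames carrying a ratio in the interval.",
          class = "airway_undefined_average")
  }
  round_half_up(mean(frames$ratio[sel]), 1)
}

#' Analyze a frame sequence end to end
#'
#' Runs [analyze_frame()] over the sequence, segments periods, applies the
#' two abnormality rules (neighbour consistency first, then the
#' backward-difference spike rule, each before the period maxima are taken),
#' marks operator-declared interference intervals, and computes the
#' obstruction-ratio series.
#'
#' @param frames list of [rgb_frame()] objects, or a directory of PNG
#'   frames.
#' @param detections detections tibble (see [load_detections()]) or the path
#'   of a detection file in the `xywh` dialect.
#' @param q colour quantization number (default 6).
#' @param conf_min detector confidence floor (default 0.25).
#' @param epsilon spike threshold in pixels (default 30000).
#' @param exclude interference intervals: character `"a-b"` strings or a
#'   list of `c(a, b)` pairs; frames inside carry no ratio.
#' @param u,h,seed_dark_max,weight_mode per-frame parameters (see
#'   [analyze_frame()]).
#' @param keep_masks retain per-frame EP/AE masks (for validation work).
#' @param verbose log per-frame progress to stderr.
#' @return an object of class `airway_analysis`: `frames` tibble (`n`,
#'   `detected`, `status`, `omega`, `omega_diff`, `period`, `max_area`,
#'   `ratio`), `periods` tibble (`m`, `start`, `end`, `n_frames`,
#'   `max_area`), `params`, and optionally `masks`.
#' @export
analyze_frames <- function(frames, detections, q = 6, conf_min = 0.25,
                           epsilon = 30000, exclude = NULL, u = NULL,
                           h = NULL, seed_dark_max = 300,
                           weight_mode = c("literal", "halved"),
                           keep_masks = FALSE, verbose = FALSE) {
  weight_mode <- match.arg(weight_mode)
  if (is.character(frames)) frames <- read_frames(frames)
  if (is.character(detections)) detections <- load_detections(detections)
  excl <- parse_intervals(exclude)

  results <- vector("list", length(frames))
  masks <- if (keep_masks) vector("list", length(frames)) else NULL
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    box <- select_box(detections[detections$frame == fr$index, ], conf_min)
    t0 <- Sys.time()
    res <- analyze_frame(fr, box, q = q, u = u, h = h,
                         seed_dark_max = seed_dark_max,
                         weight_mode = weight_mode, keep_masks = keep_masks)
    if (verbose) {
      message(sprintf("frame %d: status=%s omega=%d (%.2fs)", fr$index,
                      res$status, res$omega,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
    if (keep_masks) {
      masks[[i]] <- res[c("ep", "ae")]
      res$ep <- NULL
      res$ae <- NULL
    }
    results[[i]] <- res
  }
  tbl <- dplyr::bind_rows(lapply(results, as_tibble))

  periods <- segment_periods(tbl$detected)

  # operator-declared interference intervals (never applied to undetected frames)
  excluded <- in_intervals(tbl$n, excl) & tbl$detected
  tbl$status[excluded] <- "interference_excluded"

  # rule 1: neighbour consistency
  abn1 <- flag_abnormal_neighbors(tbl$status, tbl$omega)
  tbl$status[abn1] <- "abnormal"

  # rule 2: backward-difference spikes, within each period over the frames
  # still eligible for the ratio series
  tbl$omega_diff <- NA_real_
  for (i in seq_len(nrow(periods))) {
    rows <- which(tbl$n >= periods$start[i] & tbl$n <= periods$end[i])
    elig <- rows[tbl$status[rows] %in% c("ok", "complete_obstruction")]
    if (length(elig) >= 2) {
      tbl$omega_diff[elig[-1]] <- diff(tbl$omega[elig])
    }
    abn2 <- flag_abnormal_diff(tbl$omega[elig], epsilon)
    tbl$status[elig[abn2]] <- "abnormal"
  }

  series <- obstruction_ratios(tbl[, c("n", "detected", "status", "omega",
                                       "omega_diff")], periods)

  structure(
    list(frames = series$frames, periods = series$periods,
         params = list(q = q, conf_min = conf_min, epsilon = epsilon,
                       exclude = exclude, u = u, h = h,
                       seed_dark_max = seed_dark_max,
                       weight_mode = weight_mode),
         masks = masks),
    class = "airway_analysis"
  )
}

#' @export
print.airway_analysis <- function(x, ...) {
  cat(sprintf("<airway_analysis: %d frames, %d periods>\n",
              nrow(x$frames), nrow(x$periods)))
  print(x$periods)
  invisible(x)
}

#' @rdname analyze_frames
#' @param x an `airway_analysis` object.
#' @param ... unused.
#' @export
tidy.airway_analysis <- function(x, ...) x$frames

#' @rdname analyze_frames
#' @export
glance.airway_analysis <- function(x, ...) {
  fr <- x$frames
  tibble(
    n_frames = nrow(fr),
    n_periods = nrow(x$periods),
    n_abnormal = sum(fr$status == "abnormal"),
    n_excluded = sum(fr$status == "interference_excluded"),
    n_complete_obstruction = sum(fr$status == "complete_obstruction"),
    mean_ratio = if (any(!is.na(fr$ratio))) {
      round_half_up(mean(fr$ratio, na.rm = TRUE), 1)
    } else {
      NA_real_
    }
  )
}

#' Plot airway area and obstruction ratio against frame index
#'
#' @param object an `airway_analysis` object.
#' @param ... unused.
#' @return a [ggplot2::ggplot] with the AE area (pixels, left scale drawn as
#'   points/line) and the obstruction ratio (percent) facetted beneath it.
#' @export
autoplot.airway_analysis <- function(object, ...) {
  fr <- object$frames
  long <- dplyr::bind_rows(
    tibble(n = fr$n, value = fr$omega, what = "AE area (px)"),
    tibble(n = fr$n, value = fr$ratio, what = "Obstruction ratio (%)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame index", y = NULL) +
    ggplot2::theme_minimal()
}
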