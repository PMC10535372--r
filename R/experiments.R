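# Desk-scale experiment drivers: the colour-quantization-number sensitivity
# sweep and the full continuous-sequence report bundle.

#' Clinical obstruction-degree band of a ratio
#'
#' Maps a ratio to the legacy three-band grading (0--49, 50--75, 76--100
#' percent collapse).  Reported as an annotation only — the continuous ratio
#' is the primary output.
#'
#' @param ratio numeric vector of obstruction ratios (percent).
#' @return factor with levels `"0-49%"`, `"50-75%"`, `"76-100%"`.
#' @export
obstruction_degree <- function(ratio) {
  cut(ratio, breaks = c(-Inf, 49.95, 75.95, Inf),
      labels = c("0-49%", "50-75%", "76-100%"))
}

#' Colour-quantization-number sensitivity sweep
#'
#' Re-analyzes the same frames at each `q` and collects the per-frame AE
#' area curves.  Low quantization numbers give few, coherent regions and
#' smooth curves; high numbers fragment the airway and make the curves
#' jumpy.  The dispersion statistic summarizes this: the mean pairwise mean
#' absolute distance between curves within the low group (q 4--8) versus
#' the high group (q 9--12).
#'
#' @param frames list of [rgb_frame()] objects (>= 2).
#' @param detections detections tibble or file path.
#' @param q_range integer vector of quantization numbers (default 3:12).
#' @param conf_min detector confidence floor.
#' @param ... further arguments passed to [analyze_frame()].
#' @return an object of class `q_sweep`: `curves`, a tibble with columns
#'   `q`, `n`, `omega`, `status`; and `dispersion`, a tibble with the
#'   within-group statistics.
#' @export
run_q_sweep <- function(frames, detections, q_range = 3:12,
                        conf_min = 0.25, ...) {
  if (length(frames) < 2) {
    abort("A q-sweep needs at least 2 frames.", class = "airway_invalid_parameter")
  }
  if (is.character(detections)) detections <- load_detections(detections)
  curves <- dplyr::bind_rows(lapply(q_range, function(q) {
    dplyr::bind_rows(lapply(frames, function(fr) {
      box <- select_box(detections[detections$frame == fr$index, ], conf_min)
      res <- analyze_frame(fr, box, q = q, ...)
      tibble(q = q, n = fr$index, omega = res$omega, status = res$status)
    }))
  }))

  group_dispersion <- function(qs) {
    qs <- intersect(qs, q_range)
    if (length(qs) < 2) return(NA_real_)
    prs <- utils::combn(qs, 2)
    mean(apply(prs, 2, function(p) {
      a <- curves$omega[curves$q == p[1]][order(curves$n[curves$q == p[1]])]
      b <- curves$omega[curves$q == p[2]][order(curves$n[curves$q == p[2]])]
      mean(abs(a - b))
    }))
  }
  dispersion <- tibble(
    group = c("low (q 4-8)", "high (q 9-12)"),
    mean_pairwise_distance = c(group_dispersion(4:8), group_dispersion(9:12))
  )
  structure(list(curves = curves, dispersion = dispersion),
            class = "q_sweep")
}

#' @export
print.q_sweep <- function(x, ...) {
  cat(sprintf("<q_sweep: %d q values x %d frames>\n",
              length(unique(x$curves$q)), length(unique(x$curves$n))))
  print(x$dispersion)
  invisible(x)
}

#' @rdname run_q_sweep
#' @param x a `q_sweep` object.
#' @export
tidy.q_sweep <- function(x, ...) x$curves

#' @rdname run_q_sweep
#' @param object a `q_sweep` object.
#' @export
autoplot.q_sweep <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$n, y = .data$omega,
                               colour = factor(.data$q))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame index", y = "AE area (px)",
                  colour = "q") +
    ggplot2::theme_minimal()
}

#' Full continuous-sequence report bundle
#'
#' Runs [analyze_frames()] and writes a per-frame CSV, a period-summary CSV,
#' a run-metadata JSON and (optionally) a PNG chart of the AE area and
#' obstruction ratio.  Reproducible bit-for-bit for fixed inputs and
#' parameters.
#'
#' @param frames,detections as in [analyze_frames()].
#' @param out_dir output directory (created if missing).
#' @param intervals optional named list of frame intervals (`c(first, last)`)
#'   for which period-average ratios are reported in the period summary.
#' @param chart write the PNG chart (default TRUE).
#' @param ... parameters forwarded to [analyze_frames()].
#' @return invisibly, a list with the `airway_analysis` object and the
#'   written file paths.
#' @export
run_sequence_report <- function(frames, detections, out_dir,
                                intervals = NULL, chart = TRUE, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ana <- analyze_frames(frames, detections, ...)

  fr <- dplyr::mutate(ana$frames,
                      degree = as.character(obstruction_degree(.data$ratio)))
  frames_csv <- file.path(out_dir, "frames.csv")
  utils::write.csv(fr, frames_csv, row.names = FALSE, na = "")

  per <- ana$periods
  if (!is.null(intervals)) {
    avg <- vapply(intervals, function(iv) {
      tryCatch(period_average(ana, iv), airway_undefined_average = function(e)
        NA_real_)
    }, numeric(1))
    iv_tbl <- tibble(
      interval = names(intervals),
      first = vapply(intervals, `[`, numeric(1), 1),
      last = vapply(intervals, `[`, numeric(1), 2),
      mean_ratio = avg,
      degree = as.character(obstruction_degree(avg))
    )
    intervals_csv <- file.path(out_dir, "interval_averages.csv")
    utils::write.csv(iv_tbl, intervals_csv, row.names = FALSE, na = "")
  } else {
    intervals_csv <- NULL
  }
  periods_csv <- file.path(out_dir, "periods.csv")
  utils::write.csv(per, periods_csv, row.names = FALSE, na = "")

  meta_json <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(
    list(package = "airwayrpa",
         version = as.character(utils::packageVersion("airwayrpa")),
         params = ana$params,
         n_frames = nrow(ana$frames), n_periods = nrow(ana$periods)),
    meta_json, auto_unbox = TRUE, null = "null", na = "null")

  chart_png <- NULL
  if (isTRUE(chart)) {
    chart_png <- file.path(out_dir, "series.png")
    ggplot2::ggsave(chart_png, autoplot(ana), width = 8, height = 5, dpi = 120)
  }

  invisible(list(analysis = ana,
                 paths = c(frames = frames_csv, periods = periods_csv,
                           intervals = intervals_csv, metadata = meta_json,
                           chart = chart_png)))
}
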