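# Pluggable detector interface: the pipeline consumes per-frame epiglottis
# bounding boxes from a plain-text detection file, so any detector (or the
# phantom generator's mock) can stand upstream.

#' Load a detection file
#'
#' Two dialects are accepted.  `"xywh"` (default): one line per box,
#' `frame_index x y width height confidence`, with 1-based frame indices and
#' 0-based integer pixel coordinates.  `"yolo"`: the common normalized
#' centre format `frame_index class cx cy w h [confidence]` with values in
#' `[0, 1]`, converted to pixels on load (requires `width` and `height`).
#'
#' @param path detection file.
#' @param format `"xywh"` or `"yolo"`.
#' @param width,height raster size in pixels, required for `format = "yolo"`.
#' @return a tibble with columns `frame`, `x`, `y`, `width`, `height`,
#'   `confidence` (one row per box; frames absent from the file simply have
#'   no rows — the epiglottis was not detected there).
#' @export
load_detections <- function(path, format = c("xywh", "yolo"),
                            width = NULL, height = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Detection file '%s' not found.", path), class = "airway_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(frame = integer(), x = integer(), y = integer(),
                  width = integer(), height = integer(), confidence = numeric()))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  n_expected <- if (format == "xywh") 6L else c(6L, 7L)
  parse_line <- function(i) {
    tk <- toks[[i]]
    if (!(length(tk) %in% n_expected)) {
      abort(sprintf("Malformed detection line %d: expected %s fields, got %d.",
                    i, paste(n_expected, collapse = " or "), length(tk)),
            class = "airway_parse_error")
    }
    v <- suppressWarnings(as.numeric(tk))
    if (any(is.na(v))) {
      abort(sprintf("Malformed detection line %d: non-numeric field.", i),
            class = "airway_parse_error")
    }
    v
  }
  vals <- lapply(seq_along(toks), parse_line)
  if (format == "xywh") {
    m <- do.call(rbind, vals)
    out <- tibble(frame = as.integer(m[, 1]),
                  x = as.integer(m[, 2]), y = as.integer(m[, 3]),
                  width = as.integer(m[, 4]), height = as.integer(m[, 5]),
                  confidence = m[, 6])
  } else {
    if (is.null(width) || is.null(height)) {
      abort("`width` and `height` are required for the 'yolo' dialect.",
            class = "airway_invalid_parameter")
    }
    m <- do.call(rbind, lapply(vals, function(v) {
      if (length(v) == 6) v <- c(v, 1.0)
      v
    }))
    w_px <- m[, 5] * width
    h_px <- m[, 6] * height
    out <- tibble(
      frame = as.integer(m[, 1]),
      x = as.integer(round(m[, 3] * width - w_px / 2)),
      y = as.integer(round(m[, 4] * height - h_px / 2)),
      width = pmax(1L, as.integer(round(w_px))),
      height = pmax(1L, as.integer(round(h_px))),
      confidence = m[, 7]
    )
  }
  if (any(out$confidence < 0 | out$confidence > 1)) {
    abort("Confidence values must lie in [0, 1].", class = "airway_parse_error")
  }
  dplyr::arrange(out, .data$frame)
}

#' Write detections in the plain `xywh` dialect
#'
#' Integer coordinates and confidences at 4 decimal places, so a
#' write-then-load round trip is lossless.
#'
#' @param detections tibble as returned by [load_detections()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_detections <- function(detections, path) {
  lines <- sprintf("%d %d %d %d %d %.4f",
                   detections$frame, detections$x, detections$y,
                   detections$width, detections$height, detections$confidence)
  writeLines(lines, path)
  invisible(path)
}

#' Select the working box for one frame
#'
#' The highest-confidence box at or above `conf_min`; ties go to the larger
#' area.  Returns `NULL` when no box qualifies (epiglottis undetected).
#'
#' @param record tibble of boxes for one frame (possibly 0 rows).
#' @param conf_min minimum confidence in `[0, 1]` (default 0.25).
#' @return a one-row tibble or `NULL`.
#' @export
select_box <- function(record, conf_min = 0.25) {
  if (conf_min < 0 || conf_min > 1) {
    abort("`conf_min` must lie in [0, 1].", class = "airway_invalid_parameter")
  }
  if (is.null(record) || nrow(record) == 0) return(NULL)
  ok <- record$confidence >= conf_min
  if (!any(ok)) return(NULL)
  rec <- record[ok, ]
  rec[order(-rec$confidence, -(rec$width * rec$height)), ][1, ]
}

#' Mock detector over phantom ground truth
#'
#' Emits each frame's true epiglottis box, optionally perturbed by integer
#' jitter drawn uniformly from `[-jitter, jitter]` on every coordinate;
#' scope-slip frames emit no box.  Deterministic for a fixed seed.
#'
#' @param truth a `ground_truth` object from [generate_sequence()].
#' @param jitter maximum absolute perturbation in pixels (default 0).
#' @param seed RNG seed for the jitter.
#' @param confidence confidence assigned to emitted boxes (default 0.9).
#' @return a detections tibble (see [load_detections()]).
#' @export
mock_detect <- function(truth, jitter = 0, seed = 1L, confidence = 0.9) {
  fr <- truth$frames
  keep <- fr$status != "slip" & !is.na(fr$box_x)
  fr <- fr[keep, ]
  n <- nrow(fr)
  if (n == 0) {
    return(tibble(frame = integer(), x = integer(), y = integer(),
                  width = integer(), height = integer(), confidence = numeric()))
  }
  jit <- matrix(0L, n, 4)
  if (jitter > 0) {
    old <- .Random.seed_exists()
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
    jit <- matrix(as.integer(sample(-jitter:jitter, 4 * n, replace = TRUE)), n, 4)
  }
  tibble(
    frame = fr$n,
    x = pmax(0L, fr$box_x + jit[, 1]),
    y = pmax(0L, fr$box_y + jit[, 2]),
    width = pmax(1L, fr$box_width + jit[, 3]),
    height = pmax(1L, fr$box_height + jit[, 4]),
    confidence = round(confidence, 4)
  )
}

# Save/restore the global RNG state so seeded helpers don't disturb callers.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
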