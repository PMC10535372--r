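#' Median-cut colour quantization
#'
#' Reduces a 24-bit RGB frame to at most `q` representative colours.  Boxes
#' are split iteratively: the box with the largest single-channel range is cut
#' at the median of that channel until `q` boxes exist (or no box contains
#' more than one distinct colour).  Each pixel maps to the arithmetic mean
#' colour of its box, rounded to the nearest integer.  Ties in box selection
#' are broken by larger pixel count, then earlier box creation, which makes
#' the result deterministic for a fixed frame and `q`.
#'
#' @param frame an [rgb_frame()].
#' @param q maximum number of palette colours (positive integer; the paper's
#'   operating range is 3--12, default pipeline value 6).
#' @return an object of class `quantized_image` with elements `labels`
#'   (`H x W` integer matrix of palette indices), `palette` (`<= q` by 3
#'   integer matrix of RGB rows) and `q`.
#' @export
median_cut_quantize <- function(frame, q) {
  q <- check_count(q, "q", min = 1)
  if (!inherits(frame, "rgb_frame")) frame <- rgb_frame(frame)
  px <- frame$pixels
  h <- frame$height
  w <- frame$width
  n <- h * w
  # n x 3 channel matrix, pixels in column-major raster order
  chan <- matrix(as.integer(px), nrow = n, ncol = 3)

  boxes <- list(list(idx = seq_len(n), created = 1L))
  next_id <- 2L
  box_stats <- function(b) {
    rng <- vapply(1:3, function(ch) {
      v <- chan[b$idx, ch]
      max(v) - min(v)
    }, numeric(1))
    list(score = max(rng), channel = which.max(rng), count = length(b$idx))
  }
  stats <- lapply(boxes, box_stats)

  while (length(boxes) < q) {
    score <- vapply(stats, `[[`, numeric(1), "score")
    count <- vapply(stats, `[[`, numeric(1), "count")
    created <- vapply(boxes, `[[`, integer(1), "created")
    splittable <- score > 0
    if (!any(splittable)) break
    ord <- order(-score, -count, created)
    sel <- ord[splittable[ord]][1]
    ch <- stats[[sel]]$channel
    v <- chan[boxes[[sel]]$idx, ch]
    m <- median(v)
    lo <- v <= m
    if (all(lo)) lo <- v < m
    b_lo <- list(idx = boxes[[sel]]$idx[lo], created = next_id)
    b_hi <- list(idx = boxes[[sel]]$idx[!lo], created = next_id + 1L)
    next_id <- next_id + 2L
    boxes[[sel]] <- b_lo
    boxes[[length(boxes) + 1L]] <- b_hi
    stats[[sel]] <- box_stats(b_lo)
    stats[[length(boxes)]] <- box_stats(b_hi)
  }

  # palette in box-creation order
  created <- vapply(boxes, `[[`, integer(1), "created")
  boxes <- boxes[order(created)]
  palette <- t(vapply(boxes, function(b) {
    as.integer(round(colMeans(chan[b$idx, , drop = FALSE])))
  }, integer(3)))
  labels <- integer(n)
  for (i in seq_along(boxes)) labels[boxes[[i]]$idx] <- i
  dim(labels) <- c(h, w)

  structure(
    list(labels = labels, palette = palette, q = q,
         width = w, height = h, frame_index = frame$index),
    class = "quantized_image"
  )
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image: %d x %d, %d/%d palette colours>\n",
              x$width, x$height, nrow(x$palette), x$q))
  invisible(x)
}

#' Label colour-homogeneous connected regions
#'
#' Partitions the raster into maximal 8-connected components of equal palette
#' index and computes per-region statistics.  4-connected components come
#' from [EBImage::bwlabel()]; components of the same palette colour touching
#' diagonally are then merged through an adjacency graph.
#'
#' @param qimg a `quantized_image`.
#' @return an object of class `region_map`: `region_labels` (`H x W` integer
#'   matrix of region ids, 1..K) and `regions`, a tibble with one row per
#'   region: `id`, `palette_index`, RGB colour, `color_sum`, `area`, centroid
#'   (`xbar`, `ybar`, 0-based), and 0-based bounding extent
#'   `xmin`/`xmax`/`ymin`/`ymax`.
#' @export
label_regions <- function(qimg) {
  if (!inherits(qimg, "quantized_image")) {
    abort("`qimg` must be a quantized_image.", class = "airway_invalid_parameter")
  }
  pal_raster <- qimg$labels
  h <- nrow(pal_raster)
  w <- ncol(pal_raster)

  lab4 <- matrix(0L, h, w)
  offset <- 0L
  for (p in seq_len(nrow(qimg$palette))) {
    bw <- EBImage::bwlabel(pal_raster == p)
    k <- max(bw)
    if (k > 0) {
      sel <- bw > 0
      lab4[sel] <- as.integer(bw[sel]) + offset
      offset <- offset + as.integer(k)
    }
  }

  # merge 4-conn components of equal palette index that touch diagonally
  if (h > 1 && w > 1) {
    dr_same <- pal_raster[-h, -w] == pal_raster[-1, -1]
    ur_same <- pal_raster[-1, -w] == pal_raster[-h, -1]
    pairs <- rbind(
      cbind(lab4[-h, -w][dr_same], lab4[-1, -1][dr_same]),
      cbind(lab4[-1, -w][ur_same], lab4[-h, -1][ur_same])
    )
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  } else {
    pairs <- matrix(integer(), ncol = 2)
  }
  if (nrow(pairs) > 0) {
    g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, offset - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    merged <- comp[lab4]
  } else {
    merged <- as.integer(lab4)
  }
  # renumber regions by first occurrence in raster scan order
  first <- !duplicated(merged)
  remap <- integer(max(merged))
  remap[merged[first]] <- seq_len(sum(first))
  region_labels <- matrix(remap[merged], h, w)

  ids <- region_labels[first]
  ids_order <- order(ids)
  k <- length(ids)
  area <- tabulate(region_labels, nbins = k)
  col0 <- rep(0:(w - 1L), each = h)
  row0 <- rep(0:(h - 1L), times = w)
  v <- as.vector(region_labels)
  xsum <- unname(rowsum(col0, v)[, 1])
  ysum <- unname(rowsum(row0, v)[, 1])
  idx_split <- split(seq_along(v), v)
  xmin <- vapply(idx_split, function(i) min(col0[i]), numeric(1))
  xmax <- vapply(idx_split, function(i) max(col0[i]), numeric(1))
  ymin <- vapply(idx_split, function(i) min(row0[i]), numeric(1))
  ymax <- vapply(idx_split, function(i) max(row0[i]), numeric(1))
  pal_idx <- pal_raster[first][ids_order]

  regions <- tibble(
    id = seq_len(k),
    palette_index = as.integer(pal_idx),
    color_r = qimg$palette[pal_idx, 1],
    color_g = qimg$palette[pal_idx, 2],
    color_b = qimg$palette[pal_idx, 3],
    color_sum = qimg$palette[pal_idx, 1] + qimg$palette[pal_idx, 2] +
      qimg$palette[pal_idx, 3],
    area = area,
    xbar = xsum / area,
    ybar = ysum / area,
    xmin = as.integer(xmin), xmax = as.integer(xmax),
    ymin = as.integer(ymin), ymax = as.integer(ymax)
  )

  structure(
    list(region_labels = region_labels, regions = regions,
         width = w, height = h),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map: %d x %d, %d regions>\n",
              x$width, x$height, nrow(x$regions)))
  invisible(x)
}

#' Fill enclosed holes in a binary mask
#'
#' Sets every background component that does not touch the raster border
#' (4-connected background, pairing the 8-connected foreground convention).
#' Idempotent; the output always contains the input.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same dimensions.
#' @export
fill_holes <- function(mask) {
  if (!any(mask)) return(mask)
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  out <- EBImage::fillHull(m) > 0
  dim(out) <- dim(mask)
  out
}

#' Boundary edge of a binary mask
#'
#' The edge set used by all puzzle functions: mask pixels having at least one
#' 4-neighbour outside the mask, where the raster border counts as outside.
#'
#' @param mask logical matrix.
#' @return logical matrix marking the edge pixels (empty for an empty mask).
#' @export
boundary_edge <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  up    <- rbind(FALSE, mask[-h, , drop = FALSE])
  down  <- rbind(mask[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, mask[, -w, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  mask & !(up & down & left & right)
}

# Edge pixel linear indices (column-major), the working representation in
# the merge loops.
edge_which <- function(mask) which(boundary_edge(mask))
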