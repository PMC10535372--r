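test_that("region_weight follows the centroid-row formula", {
  expect_equal(region_weight(list(ybar = 200), 224), 88)
  expect_equal(region_weight(list(ybar = 112), 224), 0)
  w <- region_weight(list(ybar = c(50, 80, 120)), 200)
  expect_true(all(diff(w) > 0))          # strictly increasing in ybar
  # the halved variant rescales but preserves the ordering
  w2 <- region_weight(list(ybar = c(50, 80, 120)), 200, mode = "halved")
  expect_true(all(diff(w2) > 0))
  expect_error(region_weight(list(ybar = 10), 0),
               class = "airway_invalid_parameter")
})

test_that("puzzle_candidate is the symmetric-difference count minus weight", {
  d <- cbind(c(0, 0), c(0, 1))
  expect_equal(puzzle_candidate(d, d, 0), 0)
  expect_equal(puzzle_candidate(d, d, 5), -5)
  d1 <- rbind(c(0, 0), c(0, 1))
  c1 <- rbind(c(0, 1), c(0, 2))
  expect_equal(puzzle_candidate(d1, c1, 0), 2)
  # random sets against the |D| + |C| - 2|D∩C| identity
  for (s in 1:20) {
    set.seed(400 + s)
    universe <- as.matrix(expand.grid(0:7, 0:7))
    d_set <- universe[sample(64, sample(1:20, 1)), , drop = FALSE]
    c_set <- universe[sample(64, sample(1:20, 1)), , drop = FALSE]
    key <- function(m) paste(m[, 1], m[, 2])
    inter <- length(intersect(key(d_set), key(c_set)))
    expect_equal(puzzle_candidate(d_set, c_set, 0),
                 nrow(d_set) + nrow(c_set) - 2 * inter)
  }
  # logical-matrix representation agrees
  m1 <- matrix(FALSE, 4, 4); m1[1, 1:2] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[1, 2:3] <- TRUE
  expect_equal(puzzle_candidate(m1, m2, 0), 2)
})

test_that("seed_region picks the colour-extreme region in the window", {
  bright <- rect_mask(10, 10, 2, 4, 2, 4)
  rm <- make_region_fixture(10, 10, list(bright),
                            list(c(250L, 250L, 250L), c(20L, 20L, 20L)))
  id_bright <- rm$region_labels[4, 4]
  id_dark <- rm$region_labels[1, 1]
  expect_equal(seed_region(rm, c(3, 3), 3, "brightest"), id_bright)
  expect_equal(seed_region(rm, c(3, 3), 9, "darkest"), id_dark)
  # window covering exactly one region
  expect_equal(seed_region(rm, c(3, 3), 1, "darkest"), id_bright)
  # all regions inadmissible -> no seed
  expect_error(seed_region(rm, c(3, 3), 3, "darkest",
                           admissible = rep(FALSE, nrow(rm$regions))),
               class = "airway_no_seed")
  expect_error(seed_region(rm, c(50, 50), 3, "darkest"),
               class = "airway_no_seed")
})

test_that("seed_region matches an exhaustive window-scan oracle", {
  for (s in 1:10) {
    rr <- random_region_map(500 + s)
    rm <- rr$map
    center <- c(sample(0:15, 1), sample(0:15, 1))
    side <- sample(c(3, 5, 7), 1)
    got <- seed_region(rm, center, side, "darkest")
    # oracle: enumerate ids in the clipped window, rank by colour sum
    x0 <- center[1] - floor(side / 2); y0 <- center[2] - floor(side / 2)
    cols <- max(x0, 0):min(x0 + side - 1, 15) + 1
    rows <- max(y0, 0):min(y0 + side - 1, 15) + 1
    ids <- unique(as.vector(rm$region_labels[rows, cols]))
    reg <- rm$regions[ids, ]
    want <- ids[order(reg$color_sum, -reg$area, reg$id)][1]
    expect_equal(got, want)
  }
})

test_that("a seed with no admissible neighbours returns its filled mask", {
  blob <- rect_mask(12, 12, 3, 8, 3, 8)
  blob[6, 6] <- FALSE                       # enclosed hole
  rm <- make_region_fixture(12, 12, list(blob),
                            list(c(10L, 10L, 10L), c(200L, 200L, 200L)))
  id_blob <- rm$region_labels[5, 5]
  adm <- rep(FALSE, nrow(rm$regions))
  adm[id_blob] <- TRUE
  res <- rpa_merge(rm, id_blob, admissible = adm)
  expect_identical(res$mask, fill_holes(rm$region_labels == id_blob))
  expect_equal(res$merged_ids, id_blob)
  expect_equal(nrow(res$trace), 0)
})

test_that("a sweep merges concavity-filling candidates and rejects the rest", {
  # 6x10 rectangle with a 2x4 notch in the top side (edge count 30, hand
  # enumerated); the notch block (|D| = 8, w = 10) passes and restores the
  # full rectangle (edge 28 < 30, committed); two protruding blocks below
  # (|D| = 8, w = 0) fail.
  seed_m <- rect_mask(20, 20, 5, 10, 5, 14) & !rect_mask(20, 20, 5, 6, 8, 11)
  notch <- rect_mask(20, 20, 5, 6, 8, 11)
  below1 <- rect_mask(20, 20, 11, 13, 5, 7)
  below2 <- rect_mask(20, 20, 11, 13, 12, 14)
  rm <- make_region_fixture(20, 20, list(seed_m, notch, below1, below2),
                            list(c(30L, 30L, 30L), c(90L, 90L, 90L),
                                 c(120L, 120L, 120L), c(150L, 150L, 150L),
                                 c(220L, 220L, 220L)))
  id_seed <- rm$region_labels[8, 8]
  id_notch <- rm$region_labels[6, 9]
  id_b1 <- rm$region_labels[13, 6]
  id_b2 <- rm$region_labels[13, 13]
  id_bg <- rm$region_labels[1, 1]
  adm <- rep(TRUE, nrow(rm$regions))
  adm[id_bg] <- FALSE
  w <- numeric(nrow(rm$regions))
  w[id_notch] <- 10
  res <- rpa_merge(rm, id_seed, admissible = adm,
                   weight_fn = function(reg) w[reg$id])
  expect_identical(res$mask, rect_mask(20, 20, 5, 10, 5, 14))
  expect_setequal(res$merged_ids, c(id_seed, id_notch))
  sweep_rows <- res$trace[res$trace$type == "sweep", ]
  expect_equal(nrow(sweep_rows), 1)
  expect_equal(sweep_rows$P_before, 30)
  expect_equal(sweep_rows$P_after, 28)
})

test_that("a merge that would grow the boundary is rejected", {
  # two adjacent 4x4 squares: merging doubles the width and raises the edge
  # count from 12 to 20, so the sweep is never committed, whatever the weight
  a_sq <- rect_mask(16, 16, 5, 8, 4, 7)
  b_sq <- rect_mask(16, 16, 5, 8, 8, 11)
  c_sq <- rect_mask(16, 16, 3, 4, 4, 7)    # second admissible neighbour
  rm <- make_region_fixture(16, 16, list(a_sq, b_sq, c_sq),
                            list(c(10L, 10L, 10L), c(60L, 60L, 60L),
                                 c(90L, 90L, 90L), c(220L, 220L, 220L)))
  id_a <- rm$region_labels[7, 6]
  id_b <- rm$region_labels[7, 10]
  id_c <- rm$region_labels[4, 6]
  id_bg <- rm$region_labels[1, 1]
  adm <- rep(TRUE, nrow(rm$regions)); adm[id_bg] <- FALSE
  for (wb in c(0, 12)) {
    w <- numeric(nrow(rm$regions)); w[id_b] <- wb
    res <- rpa_merge(rm, id_a, admissible = adm,
                     weight_fn = function(reg) w[reg$id])
    expect_identical(res$mask, a_sq)
    expect_equal(res$merged_ids, id_a)
  }
})

test_that("rpa_merge equals the exhaustive re-evaluation oracle", {
  for (s in 1:25) {
    rr <- random_region_map(700 + s)
    res <- rpa_merge(rr$map, rr$seed, admissible = rr$adm,
                     weight_fn = function(reg) rr$w[reg$id])
    ora <- oracle_rpa(rr$map$region_labels, rr$seed, rr$adm, rr$w)
    expect_identical(res$mask, ora)
    expect_true(all(res$mask[rr$map$region_labels == rr$seed]))
    sweeps <- res$trace[res$trace$type == "sweep", ]
    expect_true(all(sweeps$P_after < sweeps$P_before))
  }
})

test_that("ep_anchor reproduces the worked endoscopy geometry", {
  # EP mask whose column 418 spans rows 224..371 and is the lowest column
  mask <- matrix(FALSE, 480, 640)
  mask[(224:371) + 1, 418 + 1] <- TRUE
  mask[(250:300) + 1, (300:417) + 1] <- TRUE
  a <- ep_anchor(mask)
  expect_equal(a$x_rho, 418)
  expect_equal(a$y_rho, 371)
  expect_equal(a$Y_e, 224)
  expect_equal(a$ae_center, c(418, 112))
})

test_that("ep_anchor handles degenerate masks", {
  one <- matrix(FALSE, 30, 30); one[8, 13] <- TRUE   # 0-based (12, 7)
  a <- ep_anchor(one)
  expect_equal(a$x_rho, 12)
  expect_equal(a$y_rho, 7)
  expect_equal(a$Y_e, 7)
  rectm <- rect_mask(20, 20, 4, 9, 6, 12)
  a2 <- ep_anchor(rectm)
  expect_equal(a2$Y_e, 4)
  expect_equal(a2$y_rho, 9)
  expect_equal(a2$x_rho, 6)                # ties at max row -> smallest column
  expect_error(ep_anchor(matrix(FALSE, 3, 3)),
               class = "airway_invalid_parameter")
})

make_fig9_fixture <- function() {
  r0 <- rect_mask(40, 40, 16, 22, 16, 22)
  r1 <- rect_mask(40, 40, 12, 15, 14, 24)
  r2 <- rect_mask(40, 40, 23, 32, 16, 22)
  rm <- make_region_fixture(40, 40, list(r0, r1, r2),
                            list(c(250L, 250L, 250L), c(180L, 180L, 180L),
                                 c(140L, 140L, 140L), c(60L, 60L, 60L)))
  list(rm = rm, r0 = r0, r1 = r1, r2 = r2,
       id_r0 = rm$region_labels[18, 18], id_r1 = rm$region_labels[14, 16],
       id_r2 = rm$region_labels[26, 18])
}

test_that("EP merging keeps in-box neighbours and stops at the box edge", {
  fx <- make_fig9_fixture()
  box <- list(x = 8, y = 8, width = 22, height = 22)   # covers rows/cols 8..29
  ep <- merge_ep_region(fx$rm, box)
  expect_false(ep$overflowed)
  expect_identical(ep$mask, fx$r0 | fx$r1)             # R2 exceeds B: not merged
  expect_setequal(ep$merged_ids, c(fx$id_r0, fx$id_r1))
  expect_equal(ep$anchor$y_rho, 22)
  expect_equal(ep$anchor$Y_e, 12)
})

test_that("a seed overflowing the box is returned unmerged as the EP region", {
  big <- rect_mask(40, 40, 10, 35, 10, 35)
  rm <- make_region_fixture(40, 40, list(big),
                            list(c(240L, 240L, 240L), c(50L, 50L, 50L)))
  box <- list(x = 12, y = 12, width = 16, height = 16)
  ep <- merge_ep_region(rm, box)
  expect_true(ep$overflowed)
  expect_identical(ep$mask, big)
})

test_that("EP merging chains through nested rings inside the box", {
  r0 <- rect_mask(40, 40, 18, 21, 18, 21)
  ring1 <- rect_mask(40, 40, 16, 23, 16, 23) & !r0
  ring2 <- rect_mask(40, 40, 14, 25, 14, 25) & !rect_mask(40, 40, 16, 23, 16, 23)
  rm <- make_region_fixture(40, 40, list(r0, ring1, ring2),
                            list(c(250L, 250L, 250L), c(190L, 190L, 190L),
                                 c(150L, 150L, 150L), c(60L, 60L, 60L)))
  box <- list(x = 10, y = 10, width = 20, height = 20)
  ep <- merge_ep_region(rm, box)
  expect_identical(ep$mask, rect_mask(40, 40, 14, 25, 14, 25))
  expect_length(ep$merged_ids, 3)
})

test_that("EP merging validates the seed-window size", {
  fx <- make_fig9_fixture()
  box <- list(x = 8, y = 8, width = 22, height = 22)
  expect_error(merge_ep_region(fx$rm, box, u = 2),
               class = "airway_invalid_parameter")
  expect_error(merge_ep_region(fx$rm, box, u = 20),
               class = "airway_invalid_parameter")
  ep <- merge_ep_region(fx$rm, box, u = 8)             # within [H_B/4, H_B/2]
  expect_identical(ep$mask, fx$r0 | fx$r1)
})

make_fig12_fixture <- function() {
  h <- 220; w <- 100
  a0 <- rect_mask(h, w, 90, 169, 35, 64) &
    !rect_mask(h, w, 160, 169, 40, 49) & !rect_mask(h, w, 160, 169, 52, 59)
  r1 <- rect_mask(h, w, 160, 169, 40, 49)
  r2 <- rect_mask(h, w, 160, 169, 52, 59)
  r3 <- rect_mask(h, w, 80, 89, 35, 44)
  r4 <- rect_mask(h, w, 80, 89, 55, 64)
  rm <- make_region_fixture(h, w, list(a0, r1, r2, r3, r4),
                            list(c(20L, 20L, 20L), c(60L, 60L, 60L),
                                 c(65L, 65L, 65L), c(70L, 70L, 70L),
                                 c(80L, 80L, 80L), c(200L, 200L, 200L)))
  anchor <- list(x_rho = 50, y_rho = 205, Y_e = 200, ae_center = c(50, 100))
  list(rm = rm, anchor = anchor,
       id_a0 = rm$region_labels[100, 50], id_r1 = rm$region_labels[165, 45],
       id_r2 = rm$region_labels[165, 55], id_r3 = rm$region_labels[85, 40],
       id_r4 = rm$region_labels[85, 60])
}

test_that("AE merging accepts heavy near-epiglottis pieces and rejects light far ones", {
  fx <- make_fig12_fixture()
  ae <- merge_ae_region(fx$rm, fx$anchor)
  expect_false(ae$complete)
  expect_identical(ae$mask, rect_mask(220, 100, 90, 169, 35, 64))
  expect_equal(ae$omega, 80 * 30)
  expect_setequal(ae$merged_ids, c(fx$id_a0, fx$id_r1, fx$id_r2))
  expect_false(fx$id_r3 %in% ae$merged_ids)
  expect_false(fx$id_r4 %in% ae$merged_ids)
  # AE never crosses the epiglottis top edge
  rows0 <- which(ae$mask, arr.ind = TRUE)[, 1] - 1
  expect_lte(max(rows0), fx$anchor$Y_e)
})

test_that("no sufficiently dark region means complete obstruction", {
  fx <- make_fig12_fixture()
  ae <- merge_ae_region(fx$rm, fx$anchor, seed_dark_max = 10)
  expect_true(ae$complete)
  expect_equal(ae$omega, 0)
  expect_false(any(ae$mask))
  # an epiglottis whose top edge nearly touches the image top also reports 0
  ae2 <- merge_ae_region(fx$rm, list(x_rho = 50, y_rho = 10, Y_e = 2,
                                     ae_center = c(50, 1)))
  expect_true(ae2$complete)
})
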