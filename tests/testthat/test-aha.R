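annulus_mask <- function(g = 64, r1 = 12, r2 = 20) {
  ctr <- c(g, g) / 2 + 0.5
  xs <- matrix(seq_len(g), g, g)
  ys <- matrix(seq_len(g), g, g, byrow = TRUE)
  r <- sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2)
  r >= r1 & r <= r2
}

test_that("uniform annulus splits into six near-equal basal sectors", {
  mask <- annulus_mask()
  lab <- assign_segments(mask, rv_insertion_angle = 90, level = "basal")
  counts <- table(lab[lab > 0])
  expect_equal(sort(unique(lab[lab > 0])), 1:6)
  expect_equal(sum(counts), sum(mask))
  expect_true(all(abs(counts / sum(mask) - 1 / 6) < 0.02 / 6 + 0.01))
  ## apical level gives four sectors, ids 13-16
  lab_a <- assign_segments(mask, 90, level = "apical")
  expect_equal(sort(unique(lab_a[lab_a > 0])), 13:16)
})

test_that("boundary pixels take the counterclockwise-following segment", {
  mask <- matrix(FALSE, 21, 21)
  ## pixels exactly on the 0-degree and 60-degree rays about (11, 11)
  mask[16, 11] <- TRUE                      # angle 0 from +x ray
  mask[11, 16] <- TRUE                      # angle 90 degrees
  lab <- assign_segments(mask, rv_insertion_angle = 0, level = "basal",
                         centroid = c(11, 11))
  expect_equal(lab[16, 11], 1L)             # on the origin ray -> segment 1
  expect_equal(lab[11, 16], 2L)             # 90 deg inside [60, 120)
  ## exactly on the 60-degree boundary via rv rotation
  lab2 <- assign_segments(mask, rv_insertion_angle = 30, level = "basal",
                          centroid = c(11, 11))
  expect_equal(lab2[11, 16], 2L)            # 90 - 30 = 60 -> segment 2
})

test_that("rotating the RV insertion by 60 degrees permutes basal labels", {
  mask <- annulus_mask()
  l0 <- assign_segments(mask, 90, "basal")
  l60 <- assign_segments(mask, 150, "basal")
  m <- l0[mask]
  expect_equal(l60[mask], ((m - 2) %% 6) + 1L)
})

test_that("segment labels partition the mask exactly", {
  ph <- simulate_heart_phantom(phantom_spec(seed = 6))
  lab <- assign_segments_volume(ph$mask, ph$rv_insertion_angle)
  expect_equal(sum(lab > 0), sum(ph$mask))
  expect_true(all((lab > 0) == ph$mask))
  ## basal/mid get 1-12, apical 13-16
  expect_true(all(lab[, , 1][ph$mask[, , 1]] %in% 1:6))
  expect_true(all(lab[, , 2][ph$mask[, , 2]] %in% 7:12))
  expect_true(all(lab[, , 3][ph$mask[, , 3]] %in% 13:16))
})

test_that("degenerate geometry is rejected", {
  expect_error(assign_segments(matrix(FALSE, 5, 5), 0, "basal"), "empty")
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_error(assign_segments(one, 0, "basal"), "degenerate")
})

test_that("segment statistics reproduce construction ground truth", {
  ph <- simulate_heart_phantom(phantom_spec(base_t2 = 60, seed = 2))
  lab <- assign_segments_volume(ph$mask, ph$rv_insertion_angle)
  tab <- segment_statistics(ph$truth_t2, lab, min_pixels = 1)
  ## constant field: every segment (60, 0)
  expect_equal(tab$mean_t2_ms, rep(60, 16))
  expect_equal(tab$pixel_sd_ms, rep(0, 16))
  expect_equal(sum(tab$n_pixels), sum(ph$mask))
})

test_that("a single basal lesion elevates exactly one basal segment", {
  ## 60-degree lesion aligned with basal segment 2 (angles 60-120 from rv)
  les <- list(list(angle_deg = 60, extent_deg = 60, transmural = 1,
                   dt2 = 20, spread = 0))
  ph <- simulate_heart_phantom(
    phantom_spec(base_t2 = 55, lesions = les, rv_insertion_angle = 90,
                 seed = 3))
  lab <- assign_segments_volume(ph$mask, 90)
  tab <- segment_statistics(ph$truth_t2, lab, min_pixels = 1)
  basal <- tab[tab$level == "basal", ]
  elevated <- which(basal$mean_t2_ms > 60)
  expect_length(elevated, 1L)
  expect_equal(basal$mean_t2_ms[elevated], 75, tolerance = 1e-9)
  expect_equal(basal$pixel_sd_ms[elevated], 0, tolerance = 1e-9)
})

test_that("two-point segment SD follows the sample formula", {
  vals <- array(NA_real_, c(4, 4, 1))
  lab <- array(0L, c(4, 4, 1))
  vals[1, 1, 1] <- 58; vals[2, 1, 1] <- 62
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L
  tab <- suppressWarnings(segment_statistics(vals, lab, min_pixels = 1))
  expect_equal(tab$mean_t2_ms[1], 60)
  expect_equal(tab$pixel_sd_ms[1], sqrt(8), tolerance = 1e-12)  # 2.828...
})

test_that("segmental means aggregate exactly to the global mean", {
  les <- list(list(angle_deg = 15, extent_deg = 80, transmural = 0.7,
                   dt2 = 30, spread = 10))
  ph <- simulate_heart_phantom(phantom_spec(lesions = les, seed = 12))
  lab <- assign_segments_volume(ph$mask, ph$rv_insertion_angle)
  tab <- segment_statistics(ph$truth_t2, lab, min_pixels = 1)
  w <- tab$n_pixels
  expect_equal(sum(tab$mean_t2_ms * w) / sum(w),
               mean(ph$truth_t2[ph$mask]), tolerance = 1e-10)
})

test_that("statistics are invariant to whole-slice translation", {
  les <- list(list(angle_deg = 200, extent_deg = 50, transmural = 0.5,
                   dt2 = 20, spread = 0))
  ph <- simulate_heart_phantom(
    phantom_spec(grid_size = 80, center = c(40.5, 40.5), lesions = les,
                 seed = 5))
  lab1 <- assign_segments_volume(ph$mask, ph$rv_insertion_angle)
  tab1 <- segment_statistics(ph$truth_t2, lab1, min_pixels = 1)
  shift <- function(a, dx, dy) {
    out <- array(a[1] * NA, dim(a))
    out[(1 + dx):dim(a)[1], (1 + dy):dim(a)[2], ] <-
      a[1:(dim(a)[1] - dx), 1:(dim(a)[2] - dy), ]
    out
  }
  mask2 <- shift(ph$mask, 5, 7)
  mask2[is.na(mask2)] <- FALSE
  mask2 <- array(as.logical(mask2), dim(ph$mask))
  truth2 <- shift(ph$truth_t2, 5, 7)
  lab2 <- assign_segments_volume(mask2, ph$rv_insertion_angle)
  tab2 <- segment_statistics(truth2, lab2, min_pixels = 1)
  expect_equal(tab2$mean_t2_ms, tab1$mean_t2_ms, tolerance = 1e-10)
  expect_equal(tab2$n_pixels, tab1$n_pixels)
})

test_that("undersized segments are flagged", {
  vals <- array(60, c(6, 6, 1))
  lab <- array(0L, c(6, 6, 1)); lab[1:3, 1, 1] <- 1L
  expect_warning(tab <- segment_statistics(vals, lab, min_pixels = 10),
                 "flagged")
  expect_true(tab$flagged[1])
  expect_equal(tab$n_pixels[1], 3L)
})
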