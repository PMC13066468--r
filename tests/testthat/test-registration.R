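# Cross-camera identity registration: cost geometry, exhaustive search,
# thresholding, and recovery of ground-truth identities.

# Unscrambled single-frame detection table: det index == true fish in every
# view, so the identity assignment is the known-correct pairing.
make_frame <- function(truth, frame, cams = fx_cams, frame_out = 0L) {
  rows <- list()
  for (v in VIEWS) {
    for (f in 1:2) {
      r <- truth[truth$frame == frame & truth$fish == f, ]
      pts <- project_points(cams, v, rbind(
        as.numeric(r[, c("head_x", "head_y", "head_z")]),
        as.numeric(r[, c("pec_x", "pec_y", "pec_z")]),
        as.numeric(r[, c("tail_x", "tail_y", "tail_z")])
      ))
      rows[[paste(v, f)]] <- data.frame(
        frame = frame_out, view = v, det = f,
        head_u = pts[1, 1], head_v = pts[1, 2],
        pec_u = pts[2, 1], pec_v = pts[2, 2],
        tail_u = pts[3, 1], tail_v = pts[3, 2]
      )
    }
  }
  do.call(rbind, rows)
}

all_candidates <- function() {
  out <- list()
  for (yz in list(c(1L, 2L), c(2L, 1L))) {
    for (xz in list(c(1L, 2L), c(2L, 1L))) {
      out[[length(out) + 1L]] <- list(XY = c(1L, 2L), YZ = yz, XZ = xz)
    }
  }
  out
}

correct <- list(XY = c(1L, 2L), YZ = c(1L, 2L), XZ = c(1L, 2L))

test_that("the correct assignment of a consistent frame has (near-)zero cost", {
  b <- fx_bundle(n_frames = 50, seed = 21)
  fr <- make_frame(b$truth, 30, fx_cams)
  expect_lt(reprojection_cost(fr, correct, fx_model), 1e-3)
  # exactly-representable camera family: machine-precision round trip
  fr0 <- make_frame(b$truth, 30, fx_cams_affine)
  expect_lt(reprojection_cost(fr0, correct, fx_model_affine), 1e-6)
})

test_that("swapping identities in one view strictly increases the cost", {
  b <- fx_bundle(n_frames = 120, seed = 22)
  hh <- head_to_head_distance(b$truth)
  test_frames <- hh$frame[hh$dist_cm > 2][c(10, 40, 80)]
  for (f in test_frames) {
    fr <- make_frame(b$truth, f)
    c_ok <- reprojection_cost(fr, correct, fx_model)
    for (a in all_candidates()[-1]) {
      expect_gt(reprojection_cost(fr, a, fx_model), c_ok)
    }
  }
})

test_that("missing body points are excluded from the cost average", {
  b <- fx_bundle(n_frames = 50, seed = 23)
  fr <- make_frame(b$truth, 25, fx_cams_affine)
  fr[fr$view == "XZ" & fr$det == 1, c("tail_u", "tail_v")] <- NA
  expect_lt(reprojection_cost(fr, correct, fx_model_affine), 1e-6)
})

test_that("register_frame returns the brute-force argmin over all four candidates", {
  b <- fx_bundle(n_frames = 60, seed = 24)
  set.seed(99)
  for (f in c(10, 20, 30, 40, 50)) {
    fr <- make_frame(b$truth, f)
    jitter <- matrix(rnorm(nrow(fr) * 6, 0, 1), nrow(fr))
    fr[, 4:9] <- fr[, 4:9] + jitter
    costs <- vapply(all_candidates(), function(a) reprojection_cost(fr, a, fx_model),
                    numeric(1))
    res <- register_frame(fr, fx_model)
    expect_equal(res$n_candidates, 4L)
    expect_equal(res$cost, min(costs), tolerance = 1e-12)
    expect_identical(res$assignment, all_candidates()[[which.min(costs)]])
  }
})

test_that("frames are discarded exactly when the best cost exceeds the threshold", {
  b <- fx_bundle(n_frames = 30, seed = 25)
  fr <- make_frame(b$truth, 15)
  set.seed(7)
  crossed_low <- FALSE
  crossed_high <- FALSE
  for (sig in c(1, 3, 5, 8, 12, 20)) {
    frj <- fr
    frj[, 4:9] <- frj[, 4:9] + matrix(rnorm(nrow(fr) * 6, 0, sig), nrow(fr))
    res <- register_frame(frj, fx_model)
    expect_identical(res$discarded, res$cost > 10)
    if (!is.na(res$cost) && res$cost <= 10) crossed_low <- TRUE
    if (!is.na(res$cost) && res$cost > 10) crossed_high <- TRUE
  }
  expect_true(crossed_low && crossed_high)  # both sides of the boundary seen
})

test_that("cost of the correct pairing is invariant under relabeling the fish", {
  b <- fx_bundle(n_frames = 40, seed = 26)
  fr <- make_frame(b$truth, 20)
  swapped <- fr
  swapped$det <- 3L - swapped$det    # relabel detections in every view
  c1 <- reprojection_cost(fr, correct, fx_model)
  c2 <- reprojection_cost(swapped, correct, fx_model)
  expect_equal(c1, c2, tolerance = 1e-6)
})

test_that("degenerate frames enumerate fewer candidates", {
  b <- fx_bundle(n_frames = 40, seed = 27)
  fr <- make_frame(b$truth, 20)
  solo <- fr[fr$det == 1, ]          # one fish per view -> single candidate
  res <- register_frame(solo, fx_model)
  expect_equal(res$n_candidates, 1L)
  expect_false(res$discarded)
  no_view <- fr[fr$view != "YZ", ]   # a whole view missing: 2 candidates
  res2 <- register_frame(no_view, fx_model)
  expect_equal(res2$n_candidates, 2L)
  empty <- fr[0, ]
  res3 <- register_frame(empty, fx_model)
  expect_true(res3$empty)
  expect_equal(res3$n_candidates, 0L)
})

test_that("identities are recovered perfectly on separated noise-free dyads", {
  b <- fx_bundle(n_frames = 1000, seed = 28)
  reg <- register_frames(b$detections, fx_model)
  expect_equal(registration_accuracy(reg, b$log$det_map), 1)
  expect_true(all(reg$summary$n_candidates == 4))
  expect_false(any(reg$summary$discarded))
})

test_that("identity recovery survives pixel noise at the detector scale", {
  cfg <- sim_config(seed = 29, n_frames = 500, noise_sigma_px = 1,
                    dropout_rate = 0, part_confusion_rate = 0, swap_rate = 0)
  truth <- simulate_dyad(cfg)
  rend <- render_detections(truth, fx_cams, cfg)
  reg <- register_frames(rend$detections, fx_model)
  hh <- head_to_head_distance(truth)
  sep <- reg$summary$frame %in% hh$frame[hh$dist_cm >= 2]
  ok <- vapply(which(sep), function(i) {
    a <- reg$assignments[[i]]
    !is.null(a)
  }, logical(1))
  expect_true(all(ok))
  expect_equal(registration_accuracy(reg, rend$log$det_map), 1)
})
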