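# The synthetic-data generator: determinism, kinematic invariants, corruption
# bookkeeping, and the bead fixture.

test_that("generator outputs are bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 61, n_frames = 300)
  t1 <- simulate_dyad(cfg)
  t2 <- simulate_dyad(cfg)
  expect_identical(t1, t2)
  r1 <- render_detections(t1, fx_cams, cfg)
  r2 <- render_detections(t2, fx_cams, cfg)
  expect_identical(r1, r2)
  c1 <- corrupt_tracks(t1, dropout_rate = 0.05, swap_rate = 0.01, seed = 9)
  c2 <- corrupt_tracks(t1, dropout_rate = 0.05, swap_rate = 0.01, seed = 9)
  expect_identical(c1, c2)
})

test_that("trajectories stay inside the cage and keep rigid segment lengths", {
  cfg <- sim_config(seed = 62, n_frames = 10000)
  tr <- simulate_dyad(cfg)
  half <- cfg$cage_cm / 2
  expect_true(all(tr$pec_x >= -half[1] & tr$pec_x <= half[1]))
  expect_true(all(tr$pec_y >= -half[2] & tr$pec_y <= half[2]))
  expect_true(all(tr$pec_z >= 0 & tr$pec_z <= cfg$cage_cm[3]))
  hp <- sqrt((tr$head_x - tr$pec_x)^2 + (tr$head_y - tr$pec_y)^2 +
               (tr$head_z - tr$pec_z)^2)
  pt <- sqrt((tr$tail_x - tr$pec_x)^2 + (tr$tail_y - tr$pec_y)^2 +
               (tr$tail_z - tr$pec_z)^2)
  expect_lt(max(abs(hp - cfg$head_pec_cm)) / cfg$body_length_cm, 0.01)
  expect_lt(max(abs(pt - cfg$pec_tail_cm)) / cfg$body_length_cm, 0.01)
})

test_that("dropout rate is realized at the configured frequency", {
  cfg <- sim_config(seed = 63, n_frames = 2000, dropout_rate = 0.05,
                    part_confusion_rate = 0, swap_rate = 0)
  rend <- render_detections(simulate_dyad(cfg), fx_cams, cfg)
  n_cells <- cfg$n_frames * 3 * 2 * 3   # frames x views x fish x points
  n_drop <- sum(rend$log$events$kind == "dropout")
  expect_lt(abs(n_drop / n_cells - 0.05), 1.96 * sqrt(0.05 * 0.95 / n_cells))
  # the log matches the table: logged dropouts are absent from the detections
  ev <- rend$log$events[rend$log$events$kind == "dropout", ][1:50, ]
  dm <- rend$log$det_map
  for (i in seq_len(nrow(ev))) {
    d <- dm$det[dm$frame == ev$frame[i] & dm$view == ev$view[i] & dm$fish == ev$fish[i]]
    row <- rend$detections[rend$detections$frame == ev$frame[i] &
                             rend$detections$view == ev$view[i] &
                             rend$detections$det %in% d, ]
    if (nrow(row) == 1) {
      expect_true(is.na(row[[paste0(ev$part[i], "_u")]]))
    } # else: the whole skeleton vanished, which is also a valid realization
  }
})

test_that("every injected centroid swap appears in the log exactly once", {
  cfg <- sim_config(seed = 64, n_frames = 3000, noise_sigma_px = 0,
                    centroid_sigma_px = 0, dropout_rate = 0,
                    part_confusion_rate = 0, swap_rate = 0.01)
  truth <- simulate_dyad(cfg)
  rend <- render_detections(truth, fx_cams, cfg)
  ev <- rend$log$events[rend$log$events$kind == "centroid_swap", ]
  expect_false(anyDuplicated(ev$frame) > 0)
  # swapped frames really carry exchanged labels: identity 1's centroid sits
  # on fish 2's pec projection
  pec2 <- project_points(fx_cams, "XY",
                         as.matrix(truth[truth$fish == 2, c("pec_x", "pec_y", "pec_z")]))
  cen1 <- rend$centroids[rend$centroids$identity == 1, ]
  cen1 <- cen1[order(cen1$frame), ]
  swapped <- cen1$frame %in% ev$frame
  d <- sqrt(rowSums((cbind(cen1$u, cen1$v) - pec2)^2))
  expect_true(all(d[swapped] < 1e-9))
  expect_true(all(d[!swapped] > 1e-9 | pec2[!swapped, 1] == cen1$u[!swapped]))
  n_really_swapped <- sum(d < 1e-9 &
                            sqrt((cen1$u - pec2[, 1])^2) < 1e-9)
  expect_equal(sum(swapped), nrow(ev))
})

test_that("part confusions exchange head and tail in the logged view only", {
  cfg <- sim_config(seed = 65, n_frames = 500, noise_sigma_px = 0,
                    dropout_rate = 0, part_confusion_rate = 0.02, swap_rate = 0,
                    scramble = FALSE)
  truth <- simulate_dyad(cfg)
  rend <- render_detections(truth, fx_cams, cfg)
  ev <- rend$log$events[rend$log$events$kind == "part_confusion", ]
  expect_gt(nrow(ev), 0)
  i <- 1
  fr <- ev$frame[i]; v <- ev$view[i]; f <- ev$fish[i]
  tru <- truth[truth$frame == fr & truth$fish == f, ]
  true_head <- project_points(fx_cams, v, as.matrix(tru[, c("head_x", "head_y", "head_z")]))
  dm <- rend$log$det_map
  d <- dm$det[dm$frame == fr & dm$view == v & dm$fish == f]
  row <- rend$detections[rend$detections$frame == fr & rend$detections$view == v &
                           rend$detections$det == d, ]
  expect_equal(c(row$tail_u, row$tail_v), as.vector(true_head), tolerance = 1e-9)
})

test_that("the bead fixture has 49 beads per orientation and refits cleanly", {
  expect_equal(fx_beads$n_beads, 49 * 4)
  expect_equal(attr(fx_beads, "n_orientations"), 4)
  expect_equal(as.vector(table(attr(fx_beads, "orientation"))), rep(49L, 4))
  one <- make_bead_fixture(fx_cams, n_orientations = 1)
  expect_equal(one$n_beads, 49)
  # a single orientation already supports the full fit on these cameras
  m1 <- fit_calibration(one)
  expect_lt(m1$to_views$rms_residual, 1e-6)
  # pooling orientations leaves world-map accuracy unchanged (exact either way)
  expect_lt(fx_model$to_world$rms_residual, 1e-6)
  # model-mismatch cameras produce genuinely nonzero residuals
  mm <- fit_calibration(make_bead_fixture(synth_cameras(mismatch = 1)))
  expect_gt(mm$to_views$rms_residual, 1e-3)
})

test_that("an uncorrupted rendering reconstructs the truth end to end", {
  b <- fx_bundle(n_frames = 300, seed = 66)
  tracks <- reconstruct_tracks(b$detections, b$centroids, fx_model)
  expect_lt(track_error(tracks, b$truth), 1e-2)
  expect_false(anyNA(tracks[, COORD_COLS]))
})
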