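# QC filters: anatomy bounds, jump/swap detection, gap closing, smoothing,
# and coverage accounting.

test_that("anatomy filter nulls skeletons beyond the segment-length bounds", {
  base <- line_coords(4)
  m <- base
  m[2, 1:3] <- c(m[2, 4] + 1.5, 0, 10)   # head-pec 1.5 cm -> removed
  m[3, 1:3] <- c(m[3, 4] + 1.3, 0, 10)   # head-pec 1.3 cm -> kept
  m[4, 7:9] <- c(m[4, 4] - 2.6, 0, 10)   # pec-tail 2.6 cm -> removed
  tr <- make_tracks(4, list(`1` = m))
  out <- filter_anatomy(tr, qc_config())
  expect_true(is.na(out$head_x[2]))
  expect_match(out$flags[2], "HEAD_PEC_LEN")
  expect_false(is.na(out$head_x[3]))
  expect_equal(out$flags[3], "")
  expect_true(is.na(out$tail_x[4]))
  expect_match(out$flags[4], "PEC_TAIL_LEN")
  # pec-tail 2.4 cm is kept
  m2 <- base
  m2[1, 7:9] <- c(m2[1, 4] - 2.4, 0, 10)
  out2 <- filter_anatomy(make_tracks(4, list(`1` = m2)), qc_config())
  expect_false(is.na(out2$tail_x[1]))
})

test_that("anatomy filter is idempotent and ignores all-missing skeletons", {
  cfg <- sim_config(seed = 41, n_frames = 300)
  truth <- simulate_dyad(cfg)
  cor <- corrupt_tracks(truth, dropout_rate = 0.1, point_jump_rate = 0.05, seed = 2)
  once <- filter_anatomy(cor$tracks, qc_config())
  twice <- filter_anatomy(once, qc_config())
  expect_identical(once, twice)
  allna <- cor$tracks
  allna[1, COORD_COLS] <- NA
  out <- filter_anatomy(allna, qc_config())
  expect_true(all(is.na(out[1, COORD_COLS])))
  expect_equal(out$flags[1], "")
})

test_that("injected artifacts are flagged with the matching jump class", {
  cfg <- sim_config(seed = 42, n_frames = 400)
  truth <- simulate_dyad(cfg)
  qc <- qc_config()
  # identity swap: both fish exchanged for one frame
  sw <- corrupt_tracks(truth, swap_rate = 0.01, seed = 3)
  out <- detect_jumps(sw$tracks, qc)
  swap_frames <- sw$log$frame[sw$log$kind == "swap"]
  expect_gt(length(swap_frames), 0)
  for (fr in swap_frames) {
    expect_true(all(grepl("ID_SWAP", out$flags[out$frame == fr])))
    expect_true(all(is.na(out[out$frame == fr, COORD_COLS])))
  }
  # single-fish teleport
  fj <- corrupt_tracks(truth, fish_jump_rate = 0.01, seed = 4)
  outf <- detect_jumps(fj$tracks, qc)
  for (i in which(fj$log$kind == "fish_jump")) {
    fr <- fj$log$frame[i]
    f <- fj$log$fish[i]
    expect_match(outf$flags[outf$frame == fr & outf$fish == f], "FISH_JUMP")
    expect_false(grepl("JUMP|SWAP", outf$flags[outf$frame == fr & outf$fish != f]))
  }
  # single-point teleport
  pj <- corrupt_tracks(truth, point_jump_rate = 0.01, seed = 5)
  outp <- detect_jumps(pj$tracks, qc)
  for (i in which(pj$log$kind == "point_jump")) {
    fr <- pj$log$frame[i]
    f <- pj$log$fish[i]
    bp <- pj$log$part[i]
    row <- outp[outp$frame == fr & outp$fish == f, ]
    expect_match(row$flags, "POINT_JUMP")
    expect_true(all(is.na(row[, paste0(bp, c("_x", "_y", "_z"))])))
  }
  # clean smooth tracks produce no flags at all
  clean <- detect_jumps(truth, qc)
  expect_true(all(clean$flags == ""))
})

test_that("gaps up to seven frames are closed exactly on a ramp; longer gaps stay", {
  n <- 200
  tr <- make_tracks(n, list(`1` = line_coords(n)))
  gapped <- tr
  gap_starts <- seq(10, 154, by = 16)          # 10 gaps of lengths 1..8, 7, 8
  gap_lens <- c(1:8, 7, 8)
  for (k in seq_along(gap_starts)) {
    rows <- gap_starts[k]:(gap_starts[k] + gap_lens[k] - 1)
    gapped[rows, COORD_COLS] <- NA
  }
  out <- close_gaps_and_smooth(gapped, qc_config())
  for (k in seq_along(gap_starts)) {
    rows <- gap_starts[k]:(gap_starts[k] + gap_lens[k] - 1)
    if (gap_lens[k] <= 7) {
      expect_false(anyNA(out[rows, COORD_COLS]))
      expect_true(all(grepl("INTERPOLATED", out$flags[rows])))
      # linear signal: interpolation lands exactly on the ramp
      expect_equal(out$pec_x[rows], tr$pec_x[rows], tolerance = 1e-9)
    } else {
      expect_true(all(is.na(out[rows, "pec_x"])))
    }
  }
})

test_that("gaps at a sequence boundary are not interpolated", {
  n <- 50
  tr <- make_tracks(n, list(`1` = line_coords(n)))
  tr[1:3, COORD_COLS] <- NA
  tr[(n - 2):n, COORD_COLS] <- NA
  out <- close_gaps_and_smooth(tr, qc_config())
  expect_true(all(is.na(out$pec_x[c(1:3, (n - 2):n)])))
})

test_that("the smoother passes quadratic signals and has 9-frame impulse support", {
  n <- 101
  t <- seq_len(n) - 1
  q <- 0.3 + 0.01 * t + 2e-4 * t^2
  quad <- cbind(q, 0, 10, q - 0.9, 0, 10, q - 2.0, 0, 10)
  colnames(quad) <- NULL
  tr <- make_tracks(n, list(`1` = quad))
  out <- close_gaps_and_smooth(tr, qc_config())
  expect_equal(out$head_x, tr$head_x, tolerance = 1e-9)
  # impulse at the center: response support is exactly the window length
  imp <- matrix(0, n, 9)
  imp[51, 1] <- 1
  tri <- make_tracks(n, list(`1` = imp))
  outi <- close_gaps_and_smooth(tri, qc_config())
  nz <- which(abs(outi$head_x) > 1e-12)
  expect_equal(length(nz), 9)
  expect_equal(range(nz), c(51 - 4, 51 + 4))
})

test_that("coverage summary counts full and empty frames by definition", {
  n <- 20
  tr <- make_tracks(n, list(`1` = line_coords(n), `2` = line_coords(n, y = 5)))
  tr[tr$frame %in% 2:4 & tr$fish == 1, COORD_COLS] <- NA      # fish 1 absent
  tr[tr$frame %in% 7:8, COORD_COLS] <- NA                     # both absent
  tr[tr$frame == 11 & tr$fish == 2, paste0("tail", c("_x", "_y", "_z"))] <- NA
  cov <- coverage_summary(tr)
  expect_equal(cov$n_frames_total, n)
  expect_equal(cov$n_frames_empty, 2)
  expect_equal(cov$n_frames_full, n - 3 - 2 - 1)
  expect_lte(cov$n_frames_full + cov$n_frames_empty, cov$n_frames_total)
})

test_that("flagged fractions recover injected corruption rates", {
  cfg <- sim_config(seed = 44, n_frames = 5000)
  truth <- simulate_dyad(cfg)
  rates <- c(swap = 0.004, fish = 0.004, point = 0.006, dropout = 0.03)
  cor <- corrupt_tracks(truth, dropout_rate = rates["dropout"],
                        swap_rate = rates["swap"], fish_jump_rate = rates["fish"],
                        point_jump_rate = rates["point"], seed = 6)
  # dropout estimated from missingness before jump filtering
  miss <- mean(c(is.na(cor$tracks$head_x), is.na(cor$tracks$pec_x),
                 is.na(cor$tracks$tail_x)))
  ci <- function(p, n) 1.96 * sqrt(p * (1 - p) / n)
  expect_lt(abs(miss - rates["dropout"]), ci(rates["dropout"], 3 * nrow(cor$tracks)) + 0.002)
  out <- detect_jumps(cor$tracks, qc_config())
  n <- cfg$n_frames
  est_swap <- sum(tapply(grepl("ID_SWAP", out$flags), out$frame, any)) / n
  est_fish <- sum(grepl("FISH_JUMP", out$flags)) / n
  est_point <- sum(grepl("POINT_JUMP", out$flags)) / n
  expect_lt(abs(est_swap - rates["swap"]), ci(rates["swap"], n) + 1 / n)
  expect_lt(abs(est_fish - rates["fish"]), ci(rates["fish"], n) + 2 / n)
  expect_lt(abs(est_point - rates["point"]), ci(rates["point"], n) + 2 / n)
})

test_that("QC configuration validates and survives a file round trip", {
  expect_error(qc_config(sg_window = 8), "sg_window")
  expect_error(qc_config(head_pec_max_cm = -1))
  path <- withr::local_tempfile(fileext = ".cfg")
  cfg <- qc_config(jump_speed_max_cm = 3.5, max_gap_frames = 5)
  write_qc_config(cfg, path)
  cfg2 <- read_qc_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
})
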