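# Shared fixtures, built once per test run. The default camera family has
# quadratic distortion; the affine member (distortion = 0) makes all five
# calibration maps exactly representable and is used for machine-precision
# assertions.

fx_cams <- synth_cameras()
fx_beads <- make_bead_fixture(fx_cams)
fx_model <- fit_calibration(fx_beads, n_orientations = 4)

fx_cams_affine <- synth_cameras(distortion = 0)
fx_beads_affine <- make_bead_fixture(fx_cams_affine)
fx_model_affine <- fit_calibration(fx_beads_affine, n_orientations = 4)

COORD_COLS <- as.vector(t(outer(c("head", "pec", "tail"), c("_x", "_y", "_z"), paste0)))

# Clean (uncorrupted, noise-free) synthetic bundle: truth + detector tables.
fx_bundle <- function(n_frames = 200, seed = 11, cams = fx_cams, ...) {
  cfg <- sim_config(seed = seed, n_frames = n_frames,
                    noise_sigma_px = 0, centroid_sigma_px = 0,
                    dropout_rate = 0, part_confusion_rate = 0, swap_rate = 0,
                    ...)
  out <- render_detections(simulate_dyad(cfg), fx_cams, cfg)
  out$truth <- simulate_dyad(cfg)
  out$cfg <- cfg
  out
}

# Max absolute coordinate error between two track tables (frame/fish aligned).
track_error <- function(a, b) {
  m <- merge(as.data.frame(a), as.data.frame(b), by = c("frame", "fish"),
             suffixes = c("", ".ref"))
  max(abs(as.matrix(m[, COORD_COLS]) - as.matrix(m[, paste0(COORD_COLS, ".ref")])),
      na.rm = TRUE)
}

# Minimal hand-built track table (one or two fish) from coordinate matrices.
make_tracks <- function(n, coords = list()) {
  fish <- if (length(coords) == 0) 1:2 else as.integer(names(coords))
  rows <- lapply(fish, function(f) {
    df <- data.frame(frame = seq_len(n) - 1L, fish = f)
    m <- coords[[as.character(f)]]
    for (k in seq_along(COORD_COLS)) {
      df[[COORD_COLS[k]]] <- if (is.null(m)) 0 else m[, k]
    }
    df$flags <- ""
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$fish), ]
  track_table(out)
}

# Tracks in which fish 1 orients toward fish 2 in exactly n1 frames and
# fish 2 toward fish 1 in exactly n2 frames (orientation flips by moving the
# head to the opposite side of the pec).
oriented_tracks <- function(n, n1, n2) {
  h1x <- ifelse(seq_len(n) <= n1, 1, -1)      # +1: heading at the partner
  m1 <- cbind(h1x, 0, 10, 0, 0, 10, -1.6 * h1x, 0, 10)
  h2x <- ifelse(seq_len(n) <= n2, -1, 1)
  m2 <- cbind(10 + h2x, 0, 10, 10, 0, 10, 10 - 1.6 * h2x, 0, 10)
  make_tracks(n, list(`1` = m1, `2` = m2))
}

# Straight-line swimmer along +x at `speed` cm/frame (keeps anatomy valid).
line_coords <- function(n, speed = 0.05, y = 0, z = 10) {
  x <- seq_len(n) * speed
  cbind(x + 0.9, y, z,   # head
        x, y, z,         # pec
        x - 1.6, y, z)   # tail
}
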