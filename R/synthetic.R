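# Ground-truthed synthetic inputs for every pipeline stage: smooth 3D dyad
# kinematics, exact polynomial cameras, bead fixtures, detector-style
# corruption (pixel noise, dropouts, head/tail confusion, identity swaps),
# and an injection log that serves as the testing oracle.

#' Simulation configuration
#'
#' Defaults emulate the recording conditions of the tracking rig: a
#' 25 x 25 x 25 cm cage inside a larger tank, 140 Hz sampling, adult fish of
#' 2.5 cm body length imaged at roughly 36 px/cm (a fish spans about 90 px).
#'
#' @param seed RNG seed; every generator output is bit-reproducible given the
#'   same configuration.
#' @param n_frames Number of frames to simulate.
#' @param fs_hz Frame rate, Hz.
#' @param cage_cm Cage extents `(x, y, z)`, cm; x and y are centered on the
#'   tank axis, z starts at the floor.
#' @param body_length_cm Fish body length, cm.
#' @param head_pec_cm,pec_tail_cm Rigid skeleton segment lengths, cm (they sum
#'   to `body_length_cm`).
#' @param noise_sigma_px Gaussian pixel noise on rendered body points.
#' @param centroid_sigma_px Gaussian pixel noise on top-view identity
#'   centroids (centroid detection does not land exactly on the pec).
#' @param dropout_rate Per body point, per view, per frame probability of a
#'   missing detection.
#' @param part_confusion_rate Per skeleton, per view, per frame probability of
#'   a head/tail exchange (body-part misidentification).
#' @param swap_rate Per frame probability that the two top-view identity
#'   labels are exchanged for that frame.
#' @param scramble If `TRUE`, detection order within each view is randomized
#'   per frame (detector output order carries no identity information).
#' @param pursuit If `TRUE`, fish 1 steers toward fish 2 from
#'   `pursuit_switch_frame` onward (dominance-like one-sided orientation).
#' @param pursuit_switch_frame Frame at which pursuit starts.
#' @param speed_alpha,speed_sigma Velocity autocorrelation and innovation s.d.
#'   (cm/frame) of the correlated random walk.
#' @param pursuit_speed Pursuit swimming speed, cm/frame.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_frames = 1000L, fs_hz = 140,
                       cage_cm = c(25, 25, 25),
                       body_length_cm = 2.5,
                       head_pec_cm = 0.9, pec_tail_cm = 1.6,
                       noise_sigma_px = 0.5, centroid_sigma_px = 2,
                       dropout_rate = 0.02, part_confusion_rate = 0.005,
                       swap_rate = 0.001, scramble = TRUE,
                       pursuit = FALSE,
                       pursuit_switch_frame = floor(n_frames / 2),
                       speed_alpha = 0.96, speed_sigma = 0.012,
                       pursuit_speed = 0.08) {
  rates <- c(dropout_rate, part_confusion_rate, swap_rate)
  stopifnot(n_frames >= 2, fs_hz > 0, all(cage_cm > 0),
            head_pec_cm > 0, pec_tail_cm > 0,
            all(rates >= 0), all(rates <= 1))
  structure(
    list(
      seed = as.integer(seed), n_frames = as.integer(n_frames), fs_hz = fs_hz,
      cage_cm = cage_cm, body_length_cm = body_length_cm,
      head_pec_cm = head_pec_cm, pec_tail_cm = pec_tail_cm,
      noise_sigma_px = noise_sigma_px, centroid_sigma_px = centroid_sigma_px,
      dropout_rate = dropout_rate, part_confusion_rate = part_confusion_rate,
      swap_rate = swap_rate, scramble = scramble,
      pursuit = pursuit, pursuit_switch_frame = as.integer(pursuit_switch_frame),
      speed_alpha = speed_alpha, speed_sigma = speed_sigma,
      pursuit_speed = pursuit_speed
    ),
    class = "sim_config"
  )
}

# --- synthetic cameras -----------------------------------------------------

#' Synthetic polynomial cameras
#'
#' Each image coordinate is an exact polynomial in the single world coordinate
#' that the view images along that pixel axis:
#' `u = c0 + c1 t + c2 t^2 (+ c3 t^3)`. Quadratic coefficients differ between
#' the two views that share each world axis, which makes the world
#' coordinates exactly recoverable by the calibration model at the fitted
#' degrees. With `mismatch > 0` a cubic term is added, so a degree-2 fit has
#' genuinely nonzero residuals (model-mismatch mode).
#'
#' @param pixel_scale Pixels per cm (about 36: a 2.5 cm fish spans ~90 px).
#' @param image_size Image width and height, px.
#' @param distortion Scale factor on the quadratic coefficients.
#' @param mismatch Scale factor on the cubic (unmodeled) coefficients.
#' @return A `synth_cameras` object.
#' @export
synth_cameras <- function(pixel_scale = 36, image_size = c(1280, 1024),
                          distortion = 1, mismatch = 0) {
  s <- pixel_scale
  cu <- image_size[1] / 2
  # base quadratic distortions, px/cm^2; distinct for the two views per axis
  quad <- list(
    XY = c(u = 0.010, v = -0.012),
    YZ = c(u = 0.009, v = 0.011),
    XZ = c(u = -0.008, v = -0.010)
  )
  cams <- list()
  for (v in VIEWS) {
    # u images the first world axis of the view, v the second; v axis points
    # down in the image, and side views place the floor near the bottom.
    v_off <- if (v == "XY") image_size[2] / 2 else image_size[2] - 80
    cams[[v]] <- rbind(
      u = c(cu, s, distortion * quad[[v]]["u"], mismatch * 1e-4),
      v = c(v_off, -s, distortion * quad[[v]]["v"], mismatch * -1.3e-4)
    )
    colnames(cams[[v]]) <- c("c0", "c1", "c2", "c3")
  }
  structure(list(views = cams, pixel_scale = pixel_scale,
                 image_size = image_size, mismatch = mismatch),
            class = "synth_cameras")
}

#' Project world points through the synthetic cameras
#'
#' @param cams A [synth_cameras()] object.
#' @param view A view label from [VIEWS].
#' @param points3d Numeric (n x 3) world coordinates, cm.
#' @return Numeric (n x 2) pixel coordinates.
#' @export
project_points <- function(cams, view, points3d) {
  if (is.null(dim(points3d))) points3d <- matrix(points3d, ncol = 3)
  ax <- VIEW_AXES[[view]]
  co <- cams$views[[view]]
  pv <- function(cf, t) cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3
  cbind(pv(co["u", ], points3d[, ax[1]]), pv(co["v", ], points3d[, ax[2]]))
}

#' Generating coefficients of the world-to-views map
#'
#' Expresses the synthetic cameras as a coefficient matrix over the degree-2
#' monomial basis in `(x, y, z)` with the same row layout as
#' [fit_poly_map()], for parameter-recovery comparisons against a fitted
#' `to_views` map. Only defined for `mismatch = 0` cameras (otherwise the
#' cameras are not degree-2 representable).
#'
#' @param cams A [synth_cameras()] object with `mismatch = 0`.
#' @return Numeric (10 x 6) coefficient matrix, output columns ordered
#'   `XY_u, XY_v, YZ_u, YZ_v, XZ_u, XZ_v`.
#' @export
camera_to_views_coefficients <- function(cams) {
  if (cams$mismatch != 0) {
    stop("cameras with mismatch != 0 are not exactly degree-2 representable", call. = FALSE)
  }
  pw <- poly_powers(3, 2)
  row_of <- function(expo) which(apply(pw, 1, function(r) all(r == expo)))
  coef <- matrix(0, nrow(pw), 6)
  col <- 0
  for (v in VIEWS) {
    ax <- VIEW_AXES[[v]]
    for (coord in c("u", "v")) {
      col <- col + 1
      cf <- cams$views[[v]][coord, ]
      axis <- ax[if (coord == "u") 1 else 2]
      e0 <- c(0L, 0L, 0L)
      e1 <- e0; e1[axis] <- 1L
      e2 <- e0; e2[axis] <- 2L
      coef[row_of(e0), col] <- cf[1]
      coef[row_of(e1), col] <- cf[2]
      coef[row_of(e2), col] <- cf[3]
    }
  }
  coef
}

#' Synthetic calibration bead fixture
#'
#' Emits a 49-bead board (7 x 7 grid with deterministically varying bead
#' heights) photographed in `n_orientations` rotations about the vertical
#' axis, pooled into a single correspondence set.
#'
#' @param cams A [synth_cameras()] object.
#' @param n_orientations Number of board orientations pooled (default 4).
#' @param n_grid Beads per grid side.
#' @param pitch_cm Grid pitch, cm (default spans ~18 cm of the 25 cm cage).
#' @param z_base_cm,z_span_cm Bead height offset and range, cm.
#' @param noise_sigma_px Gaussian noise added to the image points.
#' @param seed RNG seed (used only when `noise_sigma_px > 0`).
#' @return A [bead_set()]; the orientation index of each bead row is stored in
#'   `attr(, "orientation")`.
#' @export
make_bead_fixture <- function(cams, n_orientations = 4, n_grid = 7, pitch_cm = 3,
                              z_base_cm = 2, z_span_cm = 20,
                              noise_sigma_px = 0, seed = 1L) {
  half <- (n_grid - 1) / 2
  ij <- expand.grid(i = seq_len(n_grid), j = seq_len(n_grid))
  phi <- (sqrt(5) - 1) / 2
  # golden-ratio height schedule: irrational spacing avoids accidental
  # low-degree algebraic relations between z and (x, y) on the grid
  z <- z_base_cm + z_span_cm * ((phi * (n_grid * (ij$i - 1) + ij$j)) %% 1)
  base <- cbind((ij$i - 1 - half) * pitch_cm, (ij$j - 1 - half) * pitch_cm, z)
  world <- NULL
  orient <- integer(0)
  for (k in seq_len(n_orientations)) {
    th <- (k - 1) * pi / max(1, n_orientations) * 0.9
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    world <- rbind(world, base %*% t(R))
    orient <- c(orient, rep(k, nrow(base)))
  }
  images <- lapply(VIEWS, function(v) project_points(cams, v, world))
  names(images) <- VIEWS
  if (noise_sigma_px > 0) {
    set.seed(seed)
    images <- lapply(images, function(m) m + matrix(stats::rnorm(length(m), 0, noise_sigma_px), nrow(m)))
  }
  beads <- bead_set(world, images)
  attr(beads, "orientation") <- orient
  attr(beads, "n_orientations") <- n_orientations
  beads
}

# --- dyad kinematics -------------------------------------------------------

#' Simulate ground-truth 3D dyad kinematics
#'
#' Two fish follow smoothed correlated random walks with reflective cage
#' boundaries. The skeleton is rigid: head and tail sit at fixed distances
#' from the pec along the (smoothly varying) heading. In pursuit mode, fish 1
#' steers toward fish 2's head from `pursuit_switch_frame` onward.
#'
#' @param cfg A [sim_config()].
#' @return A [track_table()] of ground-truth coordinates (cm), two rows per
#'   frame (fish 1 and 2), with the configuration attached as
#'   `attr(, "sim_config")`.
#' @export
simulate_dyad <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_frames
  lo <- c(-cfg$cage_cm[1] / 2, -cfg$cage_cm[2] / 2, 0) + 1
  hi <- c(cfg$cage_cm[1] / 2, cfg$cage_cm[2] / 2, cfg$cage_cm[3]) - 1
  pos <- array(NA_real_, c(n, 3, 2))
  hdg <- array(NA_real_, c(n, 3, 2))
  p <- rbind(c(-5, -5, 8), c(5, 5, 14))        # starting pecs, well separated
  vel <- matrix(stats::rnorm(6, 0, 0.03), 2, 3)
  h <- t(apply(vel, 1, function(v) v / sqrt(sum(v^2))))
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) c(1, 0, 0) else v / nv
  }
  for (t in seq_len(n)) {
    for (f in 1:2) {
      pursuing <- cfg$pursuit && f == 1 && t > cfg$pursuit_switch_frame
      v <- cfg$speed_alpha * vel[f, ] + stats::rnorm(3, 0, cfg$speed_sigma)
      if (pursuing) {
        # follow the partner at a standoff of a few cm: approach when far,
        # back off when too close, otherwise hover
        d <- p[2, ] - p[1, ]
        dist <- sqrt(sum(d^2))
        if (dist > 4) {
          v <- 0.25 * v + 0.75 * cfg$pursuit_speed * unit(d)
        } else if (dist < 2) {
          v <- 0.25 * v - 0.5 * cfg$pursuit_speed * unit(d)
        } else {
          v <- 0.3 * v
        }
      }
      pn <- p[f, ] + v
      for (k in 1:3) { # reflective walls
        if (pn[k] < lo[k]) { pn[k] <- 2 * lo[k] - pn[k]; v[k] <- -v[k] }
        if (pn[k] > hi[k]) { pn[k] <- 2 * hi[k] - pn[k]; v[k] <- -v[k] }
      }
      p[f, ] <- pn
      vel[f, ] <- v
      if (pursuing) {
        # orientation is decoupled from translation: the pursuer keeps its
        # body axis pointed at the partner's head (with small angular noise)
        target_head <- pos[max(t - 1, 1), , 2] + cfg$head_pec_cm * hdg[max(t - 1, 1), , 2]
        if (t == 1) target_head <- p[2, ]
        h[f, ] <- unit(unit(target_head - p[1, ]) + 0.06 * stats::rnorm(3))
      } else {
        sp <- sqrt(sum(v^2))
        # heading relaxes toward the swim direction: fish turn, they do not
        # flip instantaneously when the velocity passes through zero
        if (sp > 1e-6) h[f, ] <- unit(0.75 * h[f, ] + 0.25 * v / sp)
      }
      pos[t, , f] <- pn
      hdg[t, , f] <- h[f, ]
    }
  }
  rows <- vector("list", 2)
  for (f in 1:2) {
    head <- pos[, , f] + cfg$head_pec_cm * hdg[, , f]
    tail <- pos[, , f] - cfg$pec_tail_cm * hdg[, , f]
    rows[[f]] <- data.frame(
      frame = seq_len(n) - 1L, fish = f,
      head_x = head[, 1], head_y = head[, 2], head_z = head[, 3],
      pec_x = pos[, 1, f], pec_y = pos[, 2, f], pec_z = pos[, 3, f],
      tail_x = tail[, 1], tail_y = tail[, 2], tail_z = tail[, 3],
      flags = ""
    )
  }
  out <- rbind(rows[[1]], rows[[2]])
  out <- out[order(out$frame, out$fish), ]
  rownames(out) <- NULL
  out <- track_table(out)
  attr(out, "sim_config") <- cfg
  out
}

# --- detector emulation ----------------------------------------------------

track_point_matrix <- function(tracks, fish, part) {
  sub <- tracks[tracks$fish == fish, ]
  as.matrix(sub[order(sub$frame), paste0(part, c("_x", "_y", "_z"))])
}

#' Render synthetic detector output from ground-truth tracks
#'
#' Projects the true skeletons through the synthetic cameras and applies, per
#' the configuration: Gaussian pixel noise, per-point dropouts, head/tail
#' part confusions, per-frame scrambling of detection order, and top-view
#' centroid tables with occasional identity-label swaps. Every corruption is
#' recorded in the injection log.
#'
#' @param truth A ground-truth [track_table()] from [simulate_dyad()].
#' @param cams A [synth_cameras()] object.
#' @param cfg The [sim_config()] (rates, noise, scrambling).
#' @return A list:
#'   `detections` (data frame `frame, view, det, head_u, head_v, pec_u,
#'   pec_v, tail_u, tail_v`), `centroids` (data frame
#'   `frame, identity, u, v`), and `log` with `det_map` (true fish behind
#'   each detection) and `events` (every injected corruption).
#' @export
render_detections <- function(truth, cams, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1000L)
  frames <- sort(unique(truth$frame))
  n <- length(frames)
  events <- list()
  ev <- function(frame, kind, view = NA, fish = NA, part = NA) {
    events[[length(events) + 1L]] <<- data.frame(
      frame = frame, kind = kind, view = view, fish = fish, part = part
    )
  }
  # pixel coordinates per view/fish/part, with noise, dropout, confusion
  px <- list()
  for (v in VIEWS) {
    px[[v]] <- list()
    for (f in 1:2) {
      mats <- lapply(BODY_POINTS, function(bp) {
        m <- project_points(cams, v, track_point_matrix(truth, f, bp))
        m + matrix(stats::rnorm(length(m), 0, cfg$noise_sigma_px), nrow(m))
      })
      names(mats) <- BODY_POINTS
      if (cfg$dropout_rate > 0) {
        for (bp in BODY_POINTS) {
          drop <- stats::runif(n) < cfg$dropout_rate
          mats[[bp]][drop, ] <- NA_real_
          for (fr in frames[drop]) ev(fr, "dropout", v, f, bp)
        }
      }
      if (cfg$part_confusion_rate > 0) {
        conf <- stats::runif(n) < cfg$part_confusion_rate
        if (any(conf)) {
          tmp <- mats$head[conf, , drop = FALSE]
          mats$head[conf, ] <- mats$tail[conf, , drop = FALSE]
          mats$tail[conf, ] <- tmp
          for (fr in frames[conf]) ev(fr, "part_confusion", v, f, "head/tail")
        }
      }
      px[[v]][[f]] <- mats
    }
  }
  # assemble detection rows with per-frame scrambled det order
  det_rows <- list()
  map_rows <- list()
  for (v in VIEWS) {
    p1 <- rowSums(!is.na(cbind(px[[v]][[1]]$head[, 1], px[[v]][[1]]$pec[, 1], px[[v]][[1]]$tail[, 1]))) > 0
    p2 <- rowSums(!is.na(cbind(px[[v]][[2]]$head[, 1], px[[v]][[2]]$pec[, 1], px[[v]][[2]]$tail[, 1]))) > 0
    flip <- if (cfg$scramble) stats::runif(n) < 0.5 else rep(FALSE, n)
    det_f1 <- ifelse(!p1, NA_integer_, ifelse(p2 & flip, 2L, 1L))
    det_f2 <- ifelse(!p2, NA_integer_, ifelse(p1 & !flip, 2L, 1L))
    for (f in 1:2) {
      det <- if (f == 1) det_f1 else det_f2
      keep <- !is.na(det)
      if (!any(keep)) next
      m <- px[[v]][[f]]
      det_rows[[paste(v, f)]] <- data.frame(
        frame = frames[keep], view = v, det = det[keep],
        head_u = m$head[keep, 1], head_v = m$head[keep, 2],
        pec_u = m$pec[keep, 1], pec_v = m$pec[keep, 2],
        tail_u = m$tail[keep, 1], tail_v = m$tail[keep, 2]
      )
      map_rows[[paste(v, f)]] <- data.frame(
        frame = frames[keep], view = v, det = det[keep], fish = f
      )
    }
  }
  detections <- do.call(rbind, det_rows)
  detections <- detections[order(detections$frame, match(detections$view, VIEWS), detections$det), ]
  rownames(detections) <- NULL
  det_map <- do.call(rbind, map_rows)
  det_map <- det_map[order(det_map$frame, match(det_map$view, VIEWS), det_map$det), ]
  rownames(det_map) <- NULL
  # top-view identity centroids: noisy pec projections with persistent labels
  cen <- list()
  swap <- stats::runif(n) < cfg$swap_rate
  for (f in 1:2) {
    m <- project_points(cams, "XY", track_point_matrix(truth, f, "pec"))
    m <- m + matrix(stats::rnorm(length(m), 0, cfg$centroid_sigma_px), nrow(m))
    ident <- rep(f, n)
    ident[swap] <- 3L - f
    cen[[f]] <- data.frame(frame = frames, identity = ident, u = m[, 1], v = m[, 2])
  }
  for (fr in frames[swap]) ev(fr, "centroid_swap", "XY", NA, NA)
  centroids <- rbind(cen[[1]], cen[[2]])
  centroids <- centroids[order(centroids$frame, centroids$identity), ]
  rownames(centroids) <- NULL
  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(frame = integer(0), kind = character(0), view = character(0),
               fish = integer(0), part = character(0))
  list(detections = detections, centroids = centroids,
       log = list(det_map = det_map, events = events_df))
}

#' Inject track-level artifacts with a ground-truth log
#'
#' Applies, at randomly chosen isolated frames (never the first or last, at
#' most one event per frame): identity swaps (both fish's coordinates
#' exchanged for that frame), single-fish teleports (all three points of one
#' fish displaced), and single-point teleports; plus independent per-point
#' dropouts. This is the oracle-generating counterpart of the QC jump
#' filters.
#'
#' @param tracks A clean [track_table()].
#' @param dropout_rate Per fish-frame-point probability of a missing point.
#' @param swap_rate,fish_jump_rate,point_jump_rate Per-frame event
#'   probabilities (their sum must be < 1).
#' @param jump_size_cm Teleport displacement, cm. The default (8 cm) keeps
#'   injected teleports unambiguously above the jump-speed bound even when a
#'   short dropout gap divides the displacement over a few frames.
#' @param seed RNG seed.
#' @return A list: corrupted `tracks` and the injection `log` (data frame
#'   `frame, kind, fish, part`).
#' @export
corrupt_tracks <- function(tracks, dropout_rate = 0, swap_rate = 0,
                           fish_jump_rate = 0, point_jump_rate = 0,
                           jump_size_cm = 8, seed = 1L) {
  stopifnot(swap_rate + fish_jump_rate + point_jump_rate < 1)
  set.seed(seed)
  tracks <- tracks[order(tracks$frame, tracks$fish), ]
  rownames(tracks) <- NULL
  frames <- sort(unique(tracks$frame))
  inner <- frames[-c(1, length(frames))]
  u <- stats::runif(length(inner))
  kind <- rep(NA_character_, length(inner))
  kind[u < swap_rate] <- "swap"
  kind[u >= swap_rate & u < swap_rate + fish_jump_rate] <- "fish_jump"
  kind[u >= swap_rate + fish_jump_rate &
         u < swap_rate + fish_jump_rate + point_jump_rate] <- "point_jump"
  log <- list()
  coord_cols <- function(part) paste0(part, c("_x", "_y", "_z"))
  all_cols <- unlist(lapply(BODY_POINTS, coord_cols))
  ridx <- function(fr, f) which(tracks$frame == fr & tracks$fish == f)
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (i in which(!is.na(kind))) {
    fr <- inner[i]
    if (kind[i] == "swap") {
      r1 <- ridx(fr, 1); r2 <- ridx(fr, 2)
      tmp <- tracks[r1, all_cols]
      tracks[r1, all_cols] <- tracks[r2, all_cols]
      tracks[r2, all_cols] <- tmp
      log[[length(log) + 1L]] <- data.frame(frame = fr, kind = "swap", fish = NA, part = NA)
    } else if (kind[i] == "fish_jump") {
      f <- sample(1:2, 1)
      r <- ridx(fr, f)
      off <- jump_size_cm * rand_dir()
      for (bp in BODY_POINTS) {
        tracks[r, coord_cols(bp)] <- tracks[r, coord_cols(bp)] + as.list(off)
      }
      log[[length(log) + 1L]] <- data.frame(frame = fr, kind = "fish_jump", fish = f, part = NA)
    } else {
      f <- sample(1:2, 1)
      bp <- sample(BODY_POINTS, 1)
      r <- ridx(fr, f)
      tracks[r, coord_cols(bp)] <- tracks[r, coord_cols(bp)] + as.list(jump_size_cm * rand_dir())
      log[[length(log) + 1L]] <- data.frame(frame = fr, kind = "point_jump", fish = f, part = bp)
    }
  }
  if (dropout_rate > 0) {
    for (f in 1:2) {
      rows <- which(tracks$fish == f)
      for (bp in BODY_POINTS) {
        drop <- stats::runif(length(rows)) < dropout_rate
        tracks[rows[drop], coord_cols(bp)] <- NA_real_
        for (fr in tracks$frame[rows[drop]]) {
          log[[length(log) + 1L]] <- data.frame(frame = fr, kind = "dropout", fish = f, part = bp)
        }
      }
    }
  }
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(frame = integer(0), kind = character(0), fish = integer(0), part = character(0))
  list(tracks = track_table(tracks), log = log_df)
}
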