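# Dyadic gaze analysis: gaze angles, windowed gaze asymmetry, head-to-head
# distance, and 2D gaze histograms over 3D track tables.
#
# The gaze angle of a subject fish toward a target fish is the angle between
# the subject's heading (pec -> head) and the vector from the subject's head
# to the target's head, in degrees in [0, 180]. A fish is "oriented toward"
# its partner when this angle is within the cone half-width (default 20
# degrees).

#' Gaze angle of a subject toward a target
#'
#' @param subject_head,subject_pec Numeric (n x 3) matrices (or length-3
#'   vectors), cm.
#' @param target_head Numeric (n x 3) matrix or length-3 vector, cm.
#' @param mode `"3d"` (default) measures the angle in full 3D;
#'   `"horizontal"` projects both vectors onto the horizontal plane first.
#' @return Angles in degrees, `[0, 180]`; `NA` where a required point is
#'   missing or a vector has zero length.
#' @export
gaze_angle <- function(subject_head, subject_pec, target_head, mode = c("3d", "horizontal")) {
  mode <- match.arg(mode)
  as3 <- function(p) if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  sh <- as3(subject_head)
  sp <- as3(subject_pec)
  th <- as3(target_head)
  u <- sh - sp          # heading
  w <- th - sh          # subject head -> target head
  if (mode == "horizontal") {
    u[, 3] <- 0
    w[, 3] <- 0
  }
  nu <- sqrt(rowSums(u^2))
  nw <- sqrt(rowSums(w^2))
  cth <- rowSums(u * w) / (nu * nw)
  cth[nu < 1e-12 | nw < 1e-12] <- NA
  acos(pmin(1, pmax(-1, cth))) * 180 / pi
}

# Wide per-frame layout of a two-fish track table; errors if not a dyad.
dyad_wide <- function(tracks) {
  fish <- sort(unique(tracks$fish))
  if (length(fish) != 2) stop("gaze analysis requires exactly two fish", call. = FALSE)
  frames <- sort(unique(tracks$frame))
  get <- function(f, part) {
    sub <- tracks[tracks$fish == f, ]
    m <- as.matrix(sub[match(frames, sub$frame), coord_cols(part)])
    rownames(m) <- NULL
    m
  }
  list(frames = frames,
       head1 = get(fish[1], "head"), pec1 = get(fish[1], "pec"),
       head2 = get(fish[2], "head"), pec2 = get(fish[2], "pec"))
}

#' Per-frame gaze angles of both fish
#'
#' @param tracks A two-fish [track_table()] in cm.
#' @param mode Passed to [gaze_angle()].
#' @return Data frame `frame, theta_1to2, theta_2to1` (degrees).
#' @export
gaze_angles <- function(tracks, mode = c("3d", "horizontal")) {
  w <- dyad_wide(tracks)
  data.frame(
    frame = w$frames,
    theta_1to2 = gaze_angle(w$head1, w$pec1, w$head2, mode),
    theta_2to1 = gaze_angle(w$head2, w$pec2, w$head1, mode)
  )
}

#' Windowed gaze asymmetry
#'
#' Over each analysis window, counts the frames in which each fish is
#' oriented toward the other within the cone and computes
#' `A_gaze = |N_1to2 - N_2to1| / N_total`, where `N_total` is the number of
#' frames in the window with both gaze angles computable. `A_gaze` lies in
#' `[0, 1]`: near 0 for mutual (symmetric) engagement, near 1 when only one
#' fish orients toward the other.
#'
#' @param tracks A two-fish [track_table()] in cm.
#' @param window_frames Window length in frames (default 2 minutes at
#'   `fs_hz`).
#' @param cone_deg Cone half-width in degrees (default 20).
#' @param fs_hz Frame rate, used only for the default window length.
#' @param stride_frames Window stride (default non-overlapping).
#' @param mode Passed to [gaze_angle()].
#' @return Data frame per window: `window_start_frame, window_len_frames,
#'   n_1to2, n_2to1, n_total, a_gaze` (`a_gaze` is `NA` when `n_total` is 0).
#' @export
gaze_asymmetry <- function(tracks, window_frames = NULL, cone_deg = 20,
                           fs_hz = 140, stride_frames = NULL,
                           mode = c("3d", "horizontal")) {
  if (is.null(window_frames)) window_frames <- as.integer(2 * 60 * fs_hz)
  if (is.null(stride_frames)) stride_frames <- window_frames
  ga <- gaze_angles(tracks, mode)
  f0 <- min(ga$frame)
  fmax <- max(ga$frame)
  if (fmax - f0 + 1 < window_frames) {
    stop(sprintf("track (%d frames) is shorter than one analysis window (%d frames)",
                 fmax - f0 + 1, window_frames), call. = FALSE)
  }
  starts <- seq(f0, fmax - window_frames + 1, by = stride_frames)
  res <- lapply(starts, function(s) {
    in_w <- ga$frame >= s & ga$frame < s + window_frames
    ok <- in_w & !is.na(ga$theta_1to2) & !is.na(ga$theta_2to1)
    n1 <- sum(ok & ga$theta_1to2 <= cone_deg)
    n2 <- sum(ok & ga$theta_2to1 <= cone_deg)
    nt <- sum(ok)
    data.frame(window_start_frame = s, window_len_frames = window_frames,
               n_1to2 = n1, n_2to1 = n2, n_total = nt,
               a_gaze = if (nt > 0) abs(n1 - n2) / nt else NA_real_)
  })
  do.call(rbind, res)
}

#' Head-to-head distance
#'
#' @param tracks A two-fish [track_table()] in cm.
#' @return Data frame `frame, dist_cm` (3D Euclidean distance between the
#'   two heads; `NA` where either head is missing).
#' @export
head_to_head_distance <- function(tracks) {
  w <- dyad_wide(tracks)
  data.frame(frame = w$frames,
             dist_cm = sqrt(rowSums((w$head1 - w$head2)^2)))
}

#' Joint 2D histogram of the two gaze angles
#'
#' Normalized joint distribution of `(theta_1to2, theta_2to1)` over the
#' selected frames. Relabeling the two fish transposes the histogram.
#'
#' @param tracks A two-fish [track_table()] in cm.
#' @param frames Optional subset of frame indices (e.g. an early or late
#'   phase of the recording); default all.
#' @param n_bins Number of bins per axis over `[0, 180]` degrees.
#' @param mode Passed to [gaze_angle()].
#' @return A `gaze_histogram`: `counts` (n_bins x n_bins, sums to 1 over
#'   frames where both angles are computable; rows = theta_1to2 bins),
#'   `breaks` (bin edges, degrees), `n_frames`.
#' @export
gaze_histogram <- function(tracks, frames = NULL, n_bins = 36, mode = c("3d", "horizontal")) {
  ga <- gaze_angles(tracks, mode)
  if (!is.null(frames)) ga <- ga[ga$frame %in% frames, ]
  ok <- !is.na(ga$theta_1to2) & !is.na(ga$theta_2to1)
  breaks <- seq(0, 180, length.out = n_bins + 1)
  b1 <- cut(ga$theta_1to2[ok], breaks, include.lowest = TRUE, labels = FALSE)
  b2 <- cut(ga$theta_2to1[ok], breaks, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0, n_bins, n_bins)
  if (sum(ok) > 0) {
    tab <- table(factor(b1, levels = seq_len(n_bins)), factor(b2, levels = seq_len(n_bins)))
    counts <- unclass(tab) / sum(tab)
    dimnames(counts) <- NULL
  }
  structure(list(counts = counts, breaks = breaks, n_frames = sum(ok)),
            class = "gaze_histogram")
}

#' @export
print.gaze_histogram <- function(x, ...) {
  cat(sprintf("<gaze_histogram> %d x %d bins over [0, 180] deg, %d frames\n",
              nrow(x$counts), ncol(x$counts), x$n_frames))
  invisible(x)
}
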