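# Quality control of 3D track tables: anatomical length filters, identity
# swap / jump artifact removal, short-gap interpolation, Savitzky-Golay
# smoothing, and coverage diagnostics.
#
# Pipeline order is fixed: registration/fusion thresholds (upstream) ->
# anatomy filter -> jump detection -> gap closing -> smoothing. Jump
# detection must see the raw (unsmoothed) series: run_qc() enforces the
# order by construction.

#' Quality-control configuration
#'
#' Defaults are the pipeline's operating thresholds: registration discard at
#' 10 px, fusion discard at 15 px, anatomical bounds of 1.4 cm (head-pec) and
#' 2.5 cm (pec-tail), gap closing up to 7 frames, and a second-order
#' Savitzky-Golay filter with a 9-frame window at 140 Hz.
#'
#' @param reg_cost_max_px Cross-camera registration discard threshold, px.
#' @param fuse_cost_max_px Centroid-matching discard threshold, px.
#' @param head_pec_max_cm,pec_tail_max_cm Anatomical segment-length bounds, cm.
#' @param max_gap_frames Longest gap closed by linear interpolation, frames.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window
#'   (window must be odd and larger than the order).
#' @param jump_speed_max_cm Per-point displacement bound between consecutive
#'   valid frames, cm/frame. Default 2.5 cm/frame (one body length per frame,
#'   i.e. 350 cm/s at 140 Hz — several times burst-swim speed, far below
#'   typical identity-swap teleports).
#' @param fs_hz Frame rate, Hz.
#' @return A `qc_config` list.
#' @export
qc_config <- function(reg_cost_max_px = 10, fuse_cost_max_px = 15,
                      head_pec_max_cm = 1.4, pec_tail_max_cm = 2.5,
                      max_gap_frames = 7, sg_order = 2, sg_window = 9,
                      jump_speed_max_cm = 2.5, fs_hz = 140) {
  stopifnot(
    reg_cost_max_px > 0, fuse_cost_max_px > 0,
    head_pec_max_cm > 0, pec_tail_max_cm > 0,
    max_gap_frames >= 0, jump_speed_max_cm > 0, fs_hz > 0,
    sg_window %% 2 == 1, sg_window > sg_order
  )
  structure(
    list(reg_cost_max_px = reg_cost_max_px, fuse_cost_max_px = fuse_cost_max_px,
         head_pec_max_cm = head_pec_max_cm, pec_tail_max_cm = pec_tail_max_cm,
         max_gap_frames = as.integer(max_gap_frames),
         sg_order = as.integer(sg_order), sg_window = as.integer(sg_window),
         jump_speed_max_cm = jump_speed_max_cm, fs_hz = fs_hz),
    class = "qc_config"
  )
}

#' Read / write a QC configuration as key=value text
#'
#' @param path File path. Lines are `key = value`; `#` starts a comment.
#' @param cfg A [qc_config()].
#' @export
read_qc_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- stats::setNames(
    lapply(kv, function(x) as.numeric(x[2])),
    vapply(kv, `[`, character(1), 1)
  )
  known <- names(formals(qc_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop("unknown QC config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(qc_config, args)
}

#' @rdname read_qc_config
#' @export
write_qc_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(unclass(cfg)), unlist(cfg)), path)
  invisible(path)
}

#' @export
print.qc_config <- function(x, ...) {
  cat("<qc_config>\n")
  for (k in names(unclass(x))) cat(sprintf("  %s = %s\n", k, x[[k]]))
  invisible(x)
}

coord_cols <- function(part) paste0(part, c("_x", "_y", "_z"))

#' Remove anatomically implausible skeletons
#'
#' Skeletons whose head-pec or pec-tail distance exceeds the configured bound
#' are treated as erroneous detections: the distal point of the offending
#' segment (head, respectively tail) is set missing and the row flagged
#' `HEAD_PEC_LEN` / `PEC_TAIL_LEN`. Idempotent.
#'
#' @param tracks A [track_table()] in cm.
#' @param cfg A [qc_config()].
#' @return The filtered track table.
#' @export
filter_anatomy <- function(tracks, cfg = qc_config()) {
  hd <- as.matrix(tracks[, coord_cols("head")])
  pc <- as.matrix(tracks[, coord_cols("pec")])
  tl <- as.matrix(tracks[, coord_cols("tail")])
  hp <- sqrt(rowSums((hd - pc)^2))
  pt <- sqrt(rowSums((tl - pc)^2))
  bad_hp <- !is.na(hp) & hp > cfg$head_pec_max_cm
  bad_pt <- !is.na(pt) & pt > cfg$pec_tail_max_cm
  tracks[bad_hp, coord_cols("head")] <- NA_real_
  tracks[bad_pt, coord_cols("tail")] <- NA_real_
  tracks$flags[bad_hp] <- paste_flag(tracks$flags[bad_hp], "HEAD_PEC_LEN")
  tracks$flags[bad_pt] <- paste_flag(tracks$flags[bad_pt], "PEC_TAIL_LEN")
  tracks
}

#' Remove identity-swap and jump artifacts
#'
#' Per body point, the displacement from the last valid position divided by
#' the frame gap gives a speed in cm/frame. A fish "jumps" when at least two
#' of its scored points all exceed `jump_speed_max_cm`. Frames where both
#' fish jump simultaneously are identity swaps (`ID_SWAP`; both skeletons
#' nulled); a single jumping fish is a `FISH_JUMP` (that skeleton nulled);
#' isolated jumping points are `POINT_JUMP` (that point nulled). Reference
#' positions are never advanced onto removed data, so a one-frame teleport
#' yields exactly one flagged frame.
#'
#' @param tracks A time-ordered [track_table()] in cm.
#' @param cfg A [qc_config()].
#' @return The filtered track table.
#' @export
detect_jumps <- function(tracks, cfg = qc_config()) {
  tracks <- tracks[order(tracks$frame, tracks$fish), ]
  rownames(tracks) <- NULL
  fish <- sort(unique(tracks$fish))
  frames <- sort(unique(tracks$frame))
  n <- length(frames)
  rowix <- lapply(fish, function(f) {
    ix <- which(tracks$fish == f)
    ix[match(frames, tracks$frame[ix])]
  })
  X <- lapply(fish, function(f) {
    as.matrix(tracks[rowix[[match(f, fish)]],
                     unlist(lapply(BODY_POINTS, coord_cols))])
  })
  ref_val <- lapply(fish, function(f) matrix(NA_real_, 3, 3))   # point x coord
  ref_frm <- lapply(fish, function(f) rep(NA_real_, 3))
  flag_rows <- list(ID_SWAP = integer(0), FISH_JUMP = integer(0), POINT_JUMP = integer(0))
  for (i in seq_len(n)) {
    jump <- matrix(NA, length(fish), 3)   # fish x point: point jump status
    for (fi in seq_along(fish)) {
      for (bp in 1:3) {
        cur <- X[[fi]][i, (3 * bp - 2):(3 * bp)]
        if (anyNA(cur) || is.na(ref_frm[[fi]][bp])) next
        sp <- sqrt(sum((cur - ref_val[[fi]][bp, ])^2)) / (frames[i] - ref_frm[[fi]][bp])
        jump[fi, bp] <- sp > cfg$jump_speed_max_cm
      }
    }
    fish_jump <- vapply(seq_along(fish), function(fi) {
      sc <- jump[fi, ]
      sum(!is.na(sc)) >= 2 && all(sc[!is.na(sc)])
    }, logical(1))
    null_point <- matrix(FALSE, length(fish), 3)
    if (length(fish) == 2 && all(fish_jump)) {
      null_point[] <- TRUE
      flag_rows$ID_SWAP <- c(flag_rows$ID_SWAP, vapply(seq_along(fish), function(fi) rowix[[fi]][i], integer(1)))
    } else if (any(fish_jump)) {
      fi <- which(fish_jump)
      null_point[fi, ] <- TRUE
      flag_rows$FISH_JUMP <- c(flag_rows$FISH_JUMP, rowix[[fi]][i])
    }
    for (fi in seq_along(fish)) {
      if (fish_jump[fi] || (length(fish) == 2 && all(fish_jump))) next
      pj <- which(!is.na(jump[fi, ]) & jump[fi, ])
      if (length(pj)) {
        null_point[fi, pj] <- TRUE
        flag_rows$POINT_JUMP <- c(flag_rows$POINT_JUMP, rowix[[fi]][i])
      }
    }
    for (fi in seq_along(fish)) {
      for (bp in 1:3) {
        cur <- X[[fi]][i, (3 * bp - 2):(3 * bp)]
        if (null_point[fi, bp]) {
          X[[fi]][i, (3 * bp - 2):(3 * bp)] <- NA_real_
        } else if (!anyNA(cur)) {
          ref_val[[fi]][bp, ] <- cur
          ref_frm[[fi]][bp] <- frames[i]
        }
      }
    }
  }
  for (fi in seq_along(fish)) {
    tracks[rowix[[fi]], unlist(lapply(BODY_POINTS, coord_cols))] <- X[[fi]]
  }
  for (fl in names(flag_rows)) {
    r <- unique(flag_rows[[fl]])
    if (length(r)) tracks$flags[r] <- paste_flag(tracks$flags[r], fl)
  }
  tracks
}

#' Close short gaps and smooth tracks
#'
#' Per fish and per scalar coordinate: runs of missing values of length
#' `<= max_gap_frames` with valid values on both sides are filled by linear
#' interpolation (flagged `INTERPOLATED`); longer gaps and gaps touching a
#' sequence boundary are left missing. Each contiguous valid segment at
#' least `sg_window` frames long is then smoothed with a Savitzky-Golay
#' filter of order `sg_order` and window `sg_window` (shorter segments are
#' left as-is).
#'
#' @param tracks A [track_table()] in cm.
#' @param cfg A [qc_config()].
#' @return The gap-closed, smoothed track table.
#' @export
close_gaps_and_smooth <- function(tracks, cfg = qc_config()) {
  tracks <- tracks[order(tracks$frame, tracks$fish), ]
  rownames(tracks) <- NULL
  cols <- unlist(lapply(BODY_POINTS, coord_cols))
  for (f in sort(unique(tracks$fish))) {
    ix <- which(tracks$fish == f)
    ix <- ix[order(tracks$frame[ix])]
    filled_any <- rep(FALSE, length(ix))
    for (cl in cols) {
      x <- tracks[[cl]][ix]
      was_na <- is.na(x)
      if (cfg$max_gap_frames > 0 && any(was_na) && sum(!was_na) >= 2) {
        x <- zoo::na.approx(x, na.rm = FALSE, maxgap = cfg$max_gap_frames)
      }
      filled_any <- filled_any | (was_na & !is.na(x))
      # Savitzky-Golay on contiguous valid segments
      r <- rle(!is.na(x))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values & r$lengths >= cfg$sg_window)) {
        seg <- starts[k]:ends[k]
        x[seg] <- signal::sgolayfilt(x[seg], p = cfg$sg_order, n = cfg$sg_window)
      }
      tracks[[cl]][ix] <- x
    }
    tracks$flags[ix[filled_any]] <- paste_flag(tracks$flags[ix[filled_any]], "INTERPOLATED")
  }
  tracks
}

#' Frame-coverage summary
#'
#' Full frames have all three body points present in 3D for both fish; empty
#' frames have no detected body point for either fish.
#'
#' @param tracks A [track_table()].
#' @return A `coverage_summary`: `n_frames_total`, `n_frames_full`,
#'   `n_frames_empty`, and per-flag removal counts (`flag_counts`).
#' @export
coverage_summary <- function(tracks) {
  cols <- unlist(lapply(BODY_POINTS, coord_cols))
  frames <- sort(unique(tracks$frame))
  M <- as.matrix(tracks[, cols])
  n_present <- rowSums(!is.na(M[, c(1, 4, 7)]))  # points present per row (x coord)
  by_frame_full <- tapply(n_present == 3, tracks$frame, all)
  by_frame_empty <- tapply(n_present == 0, tracks$frame, all)
  two_rows <- tapply(tracks$fish, tracks$frame, function(x) length(unique(x)) == 2)
  tokens <- unlist(strsplit(tracks$flags[tracks$flags != ""], ";"))
  structure(
    list(
      n_frames_total = length(frames),
      n_frames_full = sum(by_frame_full & two_rows),
      n_frames_empty = sum(by_frame_empty),
      flag_counts = if (length(tokens)) table(tokens) else table(character(0))
    ),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> %d frames: %d full (%.1f%%), %d empty (%.1f%%)\n",
              x$n_frames_total, x$n_frames_full, 100 * x$n_frames_full / x$n_frames_total,
              x$n_frames_empty, 100 * x$n_frames_empty / x$n_frames_total))
  if (length(x$flag_counts)) {
    cat("  flags:", paste(sprintf("%s=%d", names(x$flag_counts), x$flag_counts), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the full QC pipeline
#'
#' Applies, in order: [filter_anatomy()], [detect_jumps()],
#' [close_gaps_and_smooth()]. The order is fixed — jump detection must see
#' unsmoothed displacements, and interpolation precedes smoothing. The
#' effective configuration and a [coverage_summary()] are attached as
#' attributes.
#'
#' @param tracks A [track_table()] in cm.
#' @param cfg A [qc_config()].
#' @return The QC'd track table with `attr(, "qc_config")` and
#'   `attr(, "coverage")`.
#' @export
run_qc <- function(tracks, cfg = qc_config()) {
  out <- filter_anatomy(tracks, cfg)
  out <- detect_jumps(out, cfg)
  out <- close_gaps_and_smooth(out, cfg)
  attr(out, "qc_config") <- cfg
  attr(out, "coverage") <- coverage_summary(out)
  out
}
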