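# Fusion of per-frame registered skeletons with whole-video top-view
# identity labels, and 3D skeleton reconstruction through the calibration
# model.

#' Match registered skeletons to top-view identity centroids
#'
#' Each registered skeleton's top-view pec point is matched to the nearest
#' identity centroid, greedily by ascending distance; a centroid claims at
#' most one skeleton, and matches farther than `fuse_cost_max` px are
#' rejected (the skeleton keeps no identity).
#'
#' @param pec_xy Numeric (n_slots x 2) matrix: each slot's pec point in the
#'   XY view, px (`NA` rows allowed).
#' @param centroids Data frame `identity, u, v` for one frame.
#' @param fuse_cost_max Rejection threshold, px (default 15).
#' @return A data frame per slot: `identity` (`NA` if unmatched) and
#'   `fuse_cost` (px distance, `NA` if no match attempted).
#' @export
fuse_identity <- function(pec_xy, centroids, fuse_cost_max = 15) {
  if (is.null(dim(pec_xy))) pec_xy <- matrix(pec_xy, ncol = 2)
  n_slots <- nrow(pec_xy)
  out <- data.frame(identity = rep(NA, n_slots), fuse_cost = rep(NA_real_, n_slots))
  if (is.null(centroids) || nrow(centroids) == 0) return(out)
  D <- matrix(NA_real_, n_slots, nrow(centroids))
  for (s in seq_len(n_slots)) {
    if (anyNA(pec_xy[s, ])) next
    D[s, ] <- sqrt((centroids$u - pec_xy[s, 1])^2 + (centroids$v - pec_xy[s, 2])^2)
  }
  repeat {
    if (all(is.na(D))) break
    m <- which(D == min(D, na.rm = TRUE), arr.ind = TRUE)[1, ]
    if (D[m[1], m[2]] > fuse_cost_max) break
    out$identity[m[1]] <- centroids$identity[m[2]]
    out$fuse_cost[m[1]] <- D[m[1], m[2]]
    D[m[1], ] <- NA
    D[, m[2]] <- NA
  }
  out
}

# 3D points for one slot: body point present in all three views -> world
# coordinates; otherwise missing. Optionally a point missing in exactly one
# view is first imputed from the other two through the view maps.
reconstruct_slot <- function(skel, assignment, slot, model, impute_missing_view = FALSE) {
  pts <- lapply(VIEWS, function(v) {
    d <- assignment[[v]][slot]
    if (is.na(d) || d > length(skel[[v]]) || is.null(skel[[v]][[d]])) {
      matrix(NA_real_, 3, 2)
    } else {
      skel[[v]][[d]]
    }
  })
  names(pts) <- VIEWS
  if (impute_missing_view) {
    for (bp in 1:3) {
      present <- vapply(VIEWS, function(v) !anyNA(pts[[v]][bp, ]), logical(1))
      if (sum(present) == 2) {
        target <- VIEWS[!present]
        src <- view_sources(target)
        pts[[target]][bp, ] <- map_views_pairwise(
          model, src[1], src[2],
          pts[[src[1]]][bp, , drop = FALSE], pts[[src[2]]][bp, , drop = FALSE]
        )
      }
    }
  }
  map_to_world(model, pts$XY, pts$YZ, pts$XZ)
}

#' Reconstruct the two 3D skeletons of one registered frame
#'
#' Applies the image-to-world calibration map to each body point that is
#' present in all three views under the accepted assignment; points missing
#' in any view are missing in 3D (unless `impute_missing_view`).
#'
#' @param frame Detection rows of a single frame.
#' @param assignment Accepted identity assignment ([register_frame()]).
#' @param model A `calibration_model`.
#' @param impute_missing_view If `TRUE`, a body point missing in exactly one
#'   view is imputed through the view-mapping functions before
#'   reconstruction (off by default).
#' @return A list of (3 x 3) matrices (rows head/pec/tail, columns x/y/z,
#'   cm), one per identity slot.
#' @export
reconstruct_skeleton3d <- function(frame, assignment, model, impute_missing_view = FALSE) {
  skel <- frame_skeletons(frame)
  lapply(seq_along(assignment[[1]]), function(s) {
    reconstruct_slot(skel, assignment, s, model, impute_missing_view)
  })
}

#' Run registration, fusion, and 3D reconstruction over a recording
#'
#' Per frame: register identities across views ([register_frames()]), match
#' the registered skeletons to the top-view identity centroids
#' ([fuse_identity()]), and reconstruct 3D skeletons. Frames discarded by the
#' registration threshold are flagged `REG_COST`; skeletons that cannot be
#' matched to a centroid within the fusion threshold are dropped and the
#' frame flagged `FUSE_COST` for that identity.
#'
#' @param detections Detection table (px).
#' @param centroids Top-view centroid table (`frame, identity, u, v`).
#' @param model A `calibration_model`.
#' @param reg_cost_max Registration discard threshold, px (default 10).
#' @param fuse_cost_max Fusion rejection threshold, px (default 15).
#' @param impute_missing_view Passed to the reconstruction step.
#' @return A [track_table()] in cm with one row per frame per identity; the
#'   registration summary is attached as `attr(, "registration")`.
#' @export
reconstruct_tracks <- function(detections, centroids, model,
                               reg_cost_max = 10, fuse_cost_max = 15,
                               impute_missing_view = FALSE) {
  reg <- register_frames(detections, model, reg_cost_max)
  frames <- reg$summary$frame
  ids <- sort(unique(centroids$identity))
  if (length(ids) == 0) ids <- 1:2
  if (length(ids) > 2) stop("more than two identities in centroid table", call. = FALSE)
  cen_idx <- split(seq_len(nrow(centroids)), factor(centroids$frame, levels = frames))
  det_idx <- split(seq_len(nrow(detections)), factor(detections$frame, levels = frames))
  n <- length(frames)
  coord <- matrix(NA_real_, n * length(ids), 9)
  flags <- rep("", n * length(ids))
  fuse_cost_out <- rep(NA_real_, n * length(ids))
  row_of <- function(i, id_pos) (i - 1L) * length(ids) + id_pos
  for (i in seq_len(n)) {
    disc <- reg$summary$discarded[i]
    a <- reg$assignments[[i]]
    if (disc && !reg$summary$empty[i]) {
      for (k in seq_along(ids)) flags[row_of(i, k)] <- "REG_COST"
      next
    }
    if (is.null(a)) next
    frame_rows <- detections[det_idx[[i]], , drop = FALSE]
    skel <- frame_skeletons(frame_rows)
    n_slots <- length(a[[1]])
    pec_xy <- t(vapply(seq_len(n_slots), function(s) {
      d <- a[["XY"]][s]
      if (is.na(d) || is.null(skel[["XY"]][[d]])) c(NA_real_, NA_real_) else skel[["XY"]][[d]][2, ]
    }, numeric(2)))
    cen <- centroids[cen_idx[[i]], , drop = FALSE]
    fused <- fuse_identity(pec_xy, cen, fuse_cost_max)
    for (s in seq_len(n_slots)) {
      id <- fused$identity[s]
      if (is.na(id)) {
        # unmatched skeleton: its data cannot be attributed to an identity
        next
      }
      k <- match(id, ids)
      p3 <- reconstruct_slot(skel, a, s, model, impute_missing_view)
      coord[row_of(i, k), ] <- as.vector(t(p3))
      fuse_cost_out[row_of(i, k)] <- fused$fuse_cost[s]
    }
    # identities with a pec present but no acceptable centroid match
    for (s in seq_len(n_slots)) {
      if (is.na(fused$identity[s]) && !anyNA(pec_xy[s, ]) && nrow(cen) > 0) {
        unmatched <- setdiff(ids, fused$identity[!is.na(fused$identity)])
        for (id in unmatched) {
          k <- match(id, ids)
          flags[row_of(i, k)] <- paste_flag(flags[row_of(i, k)], "FUSE_COST")
        }
      }
    }
  }
  out <- data.frame(
    frame = rep(frames, each = length(ids)),
    fish = rep(ids, times = n)
  )
  cn <- as.vector(t(outer(BODY_POINTS, c("_x", "_y", "_z"), paste0)))
  for (j in seq_along(cn)) out[[cn[j]]] <- coord[, j]
  out$flags <- flags
  out$fuse_cost_px <- fuse_cost_out
  out <- track_table(out)
  attr(out, "registration") <- reg$summary
  out
}

paste_flag <- function(flags, new) {
  ifelse(flags == "", new,
         ifelse(vapply(strsplit(flags, ";"), function(x) new %in% x, logical(1)),
                flags, paste(flags, new, sep = ";")))
}
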