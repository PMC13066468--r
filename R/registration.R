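# Per-frame cross-camera identity registration: exhaustive search over
# candidate pairings of the (up to two) detections per view, scored by the
# cross-camera reprojection cost.
#
# Candidates fix the detection order of the XY reference view and permute the
# two side views independently (2 x 2 = 4 candidates for a full two-fish
# frame). The cost of a candidate is averaged over the three source-pair
# configurations (each view takes the target role once); within each
# configuration both fish are projected from the two source views to the
# target and back to each source, and the pixel distances to the original
# body points are averaged over present points, fish, and the two sources.

# Convert one frame's detection rows to an internal skeleton list:
# skel[[view]] = list of 3x2 matrices (rows head/pec/tail), one per detection.
frame_skeletons <- function(frame_df) {
  skel <- stats::setNames(vector("list", 3), VIEWS)
  for (v in VIEWS) skel[[v]] <- list()
  if (nrow(frame_df) == 0) return(skel)
  coords <- as.matrix(frame_df[, c("head_u", "head_v", "pec_u", "pec_v", "tail_u", "tail_v")])
  for (i in seq_len(nrow(frame_df))) {
    v <- frame_df$view[i]
    skel[[v]][[frame_df$det[i]]] <- matrix(coords[i, ], ncol = 2, byrow = TRUE)
  }
  skel
}

# Stack a view's detections into a matrix with three rows per detection
# index, index 0 (missing) first; rows_of(d) addresses detection d.
view_matrix <- function(skel_view) {
  k <- length(skel_view)
  M <- matrix(NA_real_, 3 * (k + 1), 2)
  for (d in seq_len(k)) {
    if (!is.null(skel_view[[d]])) M[(3 * d + 1):(3 * d + 3), ] <- skel_view[[d]]
  }
  M
}

rows_of <- function(d) (3 * d + 1):(3 * d + 3)  # d = 0 addresses the NA block

# Candidate slot assignments for every view. Returns a list of candidates,
# each a named list view -> integer vector (det index per slot, NA = none).
enumerate_assignments <- function(skel) {
  ndet <- vapply(VIEWS, function(v) length(skel[[v]]), integer(1))
  n_slots <- max(ndet)
  if (n_slots == 0) return(list())
  n_slots <- min(n_slots, 2L)
  ref <- VIEWS[which(ndet > 0)[1]]
  opts <- list()
  for (v in VIEWS) {
    k <- ndet[[v]]
    if (v == ref) {
      opts[[v]] <- list(c(seq_len(k), rep(NA_integer_, n_slots - k))[seq_len(n_slots)])
    } else if (k >= 2) {
      opts[[v]] <- list(c(1L, 2L), c(2L, 1L))
    } else if (k == 1) {
      opts[[v]] <- if (n_slots == 2) list(c(1L, NA_integer_), c(NA_integer_, 1L)) else list(1L)
    } else {
      opts[[v]] <- list(rep(NA_integer_, n_slots))
    }
  }
  grid <- expand.grid(lapply(VIEWS, function(v) seq_along(opts[[v]])))
  names(grid) <- VIEWS
  lapply(seq_len(nrow(grid)), function(i) {
    stats::setNames(lapply(VIEWS, function(v) opts[[v]][[grid[i, v]]]), VIEWS)
  })
}

# Costs of a set of candidates for one frame (hot path). Projections depend
# only on which detections of the two source views are paired, so each
# source-pair configuration is evaluated once per distinct detection combo
# and candidate costs are assembled by lookup.
frame_costs <- function(skel, cands, model) {
  Vmat <- lapply(VIEWS, function(v) view_matrix(skel[[v]]))
  names(Vmat) <- VIEWS
  ndet <- vapply(VIEWS, function(v) length(skel[[v]]), integer(1))
  n_slots <- length(cands[[1]][[1]])
  costs <- rep(NA_real_, length(cands))
  # per config: per-combo mean point distance back to each source
  per_config <- vector("list", 3)
  for (ci in seq_along(VIEWS)) {
    target <- VIEWS[ci]
    src <- view_sources(target)
    n1 <- ndet[[src[1]]]
    n2 <- ndet[[src[2]]]
    ci_ <- rep(0:n1, times = n2 + 1L)
    cj_ <- rep(0:n2, each = n1 + 1L)
    nc <- length(ci_)
    ridx1 <- unlist(lapply(ci_, rows_of))
    ridx2 <- unlist(lapply(cj_, rows_of))
    A1 <- Vmat[[src[1]]][ridx1, , drop = FALSE]
    A2 <- Vmat[[src[2]]][ridx2, , drop = FALSE]
    tstar <- poly_eval(model$view_maps[[target]], cbind(A1, A2))
    cc <- matrix(NA_real_, nc, 2)  # combo x source
    for (si in 1:2) {
      s <- src[si]
      obs <- if (si == 1) A1 else A2
      back_src <- view_sources(s)  # canonical input order for the map to s
      inp <- lapply(back_src, function(bv) {
        if (bv == target) tstar else if (bv == src[1]) A1 else A2
      })
      sstar <- poly_eval(model$view_maps[[s]], cbind(inp[[1]], inp[[2]]))
      d <- sqrt(rowSums((sstar - obs)^2))
      dm <- matrix(d, nrow = 3)  # points x combos
      cnt <- colSums(!is.na(dm))
      cc[, si] <- ifelse(cnt > 0, colSums(dm, na.rm = TRUE) / cnt, NA_real_)
    }
    per_config[[ci]] <- list(src = src, n1 = n1, cc = cc)
  }
  for (k in seq_along(cands)) {
    a <- cands[[k]]
    config_costs <- rep(NA_real_, 3)
    for (ci in seq_along(VIEWS)) {
      pc <- per_config[[ci]]
      i <- a[[pc$src[1]]]
      j <- a[[pc$src[2]]]
      i[is.na(i)] <- 0L
      j[is.na(j)] <- 0L
      combo <- j * (pc$n1 + 1L) + i + 1L
      src_costs <- rep(NA_real_, 2)
      for (si in 1:2) {
        per_fish <- pc$cc[combo, si]
        if (!all(is.na(per_fish))) src_costs[si] <- mean(per_fish, na.rm = TRUE)
      }
      if (!all(is.na(src_costs))) config_costs[ci] <- mean(src_costs, na.rm = TRUE)
    }
    if (!all(is.na(config_costs))) costs[k] <- mean(config_costs, na.rm = TRUE)
  }
  costs
}

assignment_cost <- function(skel, assignment, model) {
  frame_costs(skel, list(assignment), model)[1]
}

#' Cross-camera reprojection cost of an identity assignment
#'
#' For each source-pair configuration, both fish are projected from the two
#' source views into the remaining view and back to each source through the
#' view-mapping functions; the cost is the pixel distance of the reprojected
#' body points to the originals, averaged over present body points, the two
#' fish, the two source cameras, and the configurations. Missing body points
#' are excluded from the average; if nothing can be scored the cost is `NA`.
#'
#' @param frame Detection rows of a single frame (schema of
#'   [read_detections_csv()]).
#' @param assignment Named list (by view) of integer vectors giving, per
#'   identity slot, the detection index assigned to it (`NA` = none).
#' @param model A `calibration_model`.
#' @return Scalar cost in px, or `NA` if unscorable.
#' @export
reprojection_cost <- function(frame, assignment, model) {
  assignment_cost(frame_skeletons(frame), assignment, model)
}

register_one <- function(skel, model, reg_cost_max, prev = NULL) {
  cands <- enumerate_assignments(skel)
  if (length(cands) == 0) {
    return(list(assignment = NULL, cost = NA_real_, n_candidates = 0L,
                discarded = TRUE, empty = TRUE))
  }
  costs <- frame_costs(skel, cands, model)
  if (all(is.na(costs))) {
    return(list(assignment = NULL, cost = NA_real_, n_candidates = length(cands),
                discarded = TRUE, empty = TRUE))
  }
  best <- min(costs, na.rm = TRUE)
  tied <- which(!is.na(costs) & costs <= best + 1e-12)
  pick <- tied[1]
  if (length(tied) > 1 && !is.null(prev)) {
    # temporal coherence tie-break: prefer the previous accepted assignment
    same <- vapply(tied, function(i) identical(cands[[i]], prev), logical(1))
    if (any(same)) pick <- tied[same][1]
  }
  list(assignment = cands[[pick]], cost = costs[pick],
       n_candidates = length(cands),
       discarded = costs[pick] > reg_cost_max, empty = FALSE)
}

#' Register fish identities across views for one frame
#'
#' Enumerates all candidate pairings (4 when the two permutable views each
#' hold two skeletons, fewer with missing detections), scores each with
#' [reprojection_cost()], and returns the minimizer. Frames whose best cost
#' exceeds `reg_cost_max` are marked discarded. Cost ties are broken in favor
#' of the previous frame's accepted assignment, then lexicographically.
#'
#' @param frame Detection rows of a single frame.
#' @param model A `calibration_model`.
#' @param reg_cost_max Discard threshold, px (default 10).
#' @param prev Previous frame's accepted assignment (tie-breaking), or `NULL`.
#' @return List with `assignment`, `cost`, `n_candidates`, `discarded`,
#'   `empty`.
#' @export
register_frame <- function(frame, model, reg_cost_max = 10, prev = NULL) {
  register_one(frame_skeletons(frame), model, reg_cost_max, prev)
}

#' Register fish identities for a whole detection table
#'
#' @param detections Detection table (schema of [read_detections_csv()]).
#' @param model A `calibration_model`.
#' @param reg_cost_max Discard threshold, px (default 10; the per-frame best
#'   cost must not exceed it).
#' @return A `registration` object: `summary` data frame (`frame, cost,
#'   n_candidates, discarded, empty`) and `assignments` (list keyed by frame
#'   position).
#' @export
register_frames <- function(detections, model, reg_cost_max = 10) {
  frames <- sort(unique(detections$frame))
  idx <- split(seq_len(nrow(detections)), factor(detections$frame, levels = frames))
  coords <- as.matrix(detections[, c("head_u", "head_v", "pec_u", "pec_v", "tail_u", "tail_v")])
  view <- detections$view
  det <- detections$det
  assignments <- vector("list", length(frames))
  cost <- numeric(length(frames))
  ncand <- integer(length(frames))
  disc <- logical(length(frames))
  empt <- logical(length(frames))
  prev <- NULL
  for (i in seq_along(frames)) {
    rows <- idx[[i]]
    skel <- stats::setNames(vector("list", 3), VIEWS)
    for (v in VIEWS) skel[[v]] <- list()
    for (r in rows) skel[[view[r]]][[det[r]]] <- matrix(coords[r, ], ncol = 2, byrow = TRUE)
    res <- register_one(skel, model, reg_cost_max, prev)
    assignments[[i]] <- res$assignment
    cost[i] <- res$cost
    ncand[i] <- res$n_candidates
    disc[i] <- res$discarded
    empt[i] <- res$empty
    if (!res$discarded) prev <- res$assignment
  }
  structure(
    list(
      summary = data.frame(frame = frames, cost = cost, n_candidates = ncand,
                           discarded = disc, empty = empt),
      assignments = stats::setNames(assignments, frames),
      reg_cost_max = reg_cost_max
    ),
    class = "registration"
  )
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("<registration> %d frames, %d discarded (cost > %g px), median cost %.3g px\n",
              nrow(x$summary), sum(x$summary$discarded), x$reg_cost_max,
              stats::median(x$summary$cost, na.rm = TRUE)))
  invisible(x)
}

#' Identity-recovery accuracy against a generator's detection map
#'
#' A frame is counted correct when the accepted assignment groups detections
#' of the same true fish into the same slot in every view (and distinct fish
#' into distinct slots).
#'
#' @param reg A `registration` from [register_frames()].
#' @param det_map The `log$det_map` from [render_detections()]:
#'   `frame, view, det, fish`.
#' @return Fraction of non-empty frames with a fully consistent assignment.
#' @export
registration_accuracy <- function(reg, det_map) {
  key <- paste(det_map$frame, det_map$view, det_map$det)
  fish_of <- stats::setNames(det_map$fish, key)
  frames <- reg$summary$frame
  ok <- 0L
  n <- 0L
  for (i in seq_along(frames)) {
    a <- reg$assignments[[i]]
    if (is.null(a)) next
    n <- n + 1L
    n_slots <- length(a[[1]])
    slot_fish <- matrix(NA_integer_, 3, n_slots)
    for (vi in seq_along(VIEWS)) {
      for (s in seq_len(n_slots)) {
        d <- a[[VIEWS[vi]]][s]
        if (!is.na(d)) slot_fish[vi, s] <- fish_of[[paste(frames[i], VIEWS[vi], d)]]
      }
    }
    consistent <- all(apply(slot_fish, 2, function(col) {
      u <- unique(col[!is.na(col)])
      length(u) <= 1
    }))
    distinct <- {
      reps <- apply(slot_fish, 2, function(col) {
        u <- unique(col[!is.na(col)])
        if (length(u) == 1) u else NA_integer_
      })
      reps <- reps[!is.na(reps)]
      !anyDuplicated(reps)
    }
    if (consistent && distinct) ok <- ok + 1L
  }
  if (n == 0) return(NA_real_)
  ok / n
}
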