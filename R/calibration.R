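# Polynomial multi-view calibration: five least-squares maps between the
# three orthogonal camera views (XY top, YZ and XZ side) and world
# coordinates, fitted from bead-board correspondences.
#
# Conventions: world origin at the tank floor center, right-handed axes,
# units cm; pixel origin top-left, units px. View XY images world (x, y),
# view YZ images (y, z), view XZ images (x, z).

#' The three camera views
#'
#' `XY` is the top camera; `YZ` and `XZ` are the side cameras.
#' @export
VIEWS <- c("XY", "YZ", "XZ")

# Which world axes each view images.
VIEW_AXES <- list(XY = c(1L, 2L), YZ = c(2L, 3L), XZ = c(1L, 3L))

BODY_POINTS <- c("head", "pec", "tail")

#' Construct a bead correspondence set
#'
#' @param world Numeric matrix (n x 3) of known bead world coordinates, cm.
#' @param images Named list with one (n x 2) pixel-coordinate matrix per view
#'   (`XY`, `YZ`, `XZ`), rows aligned with `world`.
#' @return A `bead_set`.
#' @export
bead_set <- function(world, images) {
  world <- as.matrix(world)
  stopifnot(ncol(world) == 3, all(VIEWS %in% names(images)))
  images <- lapply(images[VIEWS], as.matrix)
  for (v in VIEWS) {
    if (nrow(images[[v]]) != nrow(world) || ncol(images[[v]]) != 2) {
      stop(sprintf("image points for view %s must be %d x 2", v, nrow(world)), call. = FALSE)
    }
  }
  structure(list(world = world, images = images, n_beads = nrow(world)),
            class = "bead_set")
}

#' @export
print.bead_set <- function(x, ...) {
  cat(sprintf("<bead_set> %d bead correspondences in 3 views\n", x$n_beads))
  invisible(x)
}

# Source views (in canonical VIEWS order) for a given target view.
view_sources <- function(target) VIEWS[VIEWS != target]

#' Fit the five-map calibration model
#'
#' Fits, by ordinary least squares over the full monomial basis:
#' two 3D-mapping functions — all six image coordinates to world `(x, y, z)`
#' and back — of degree `degree_world` (default 2), and three view-mapping
#' functions — the four coordinates of two source views to the two
#' coordinates of the remaining view — of degree `degree_view` (default 3).
#' The six-coordinate image triplet is always ordered `XY, YZ, XZ`
#' (u then v per view); view-map inputs take the two source views in that
#' same canonical order.
#'
#' @param beads A [bead_set()], typically pooling several orientations of the
#'   bead board.
#' @param degree_world Polynomial degree of the two 3D-mapping functions.
#' @param degree_view Polynomial degree of the three view-mapping functions.
#' @param n_orientations Number of board orientations pooled in `beads`
#'   (recorded as provenance; the fit itself is pooled either way).
#' @return A `calibration_model` with elements `to_world`, `to_views`,
#'   `view_maps` (named by *target* view) and `fitted_on`.
#' @details Errors are raised for underdetermined fits (too few beads for the
#'   requested degree) and for degenerate bead geometry (world points coplanar
#'   or a view's image points collinear). Image-domain design matrices are
#'   rank-deficient by construction (consistent triplets lie on a 3-dimensional
#'   variety), so those maps are fitted minimum-norm; their predictions on
#'   consistent inputs are unaffected.
#' @export
fit_calibration <- function(beads, degree_world = 2, degree_view = 3,
                            n_orientations = NA_integer_) {
  stopifnot(inherits(beads, "bead_set"))
  stopifnot(degree_world %in% 2:3, degree_view %in% 2:3)
  world <- beads$world
  if (qr(cbind(1, world))$rank < 4) {
    stop("degenerate bead geometry: world points are coplanar (no 3D extent in some direction)",
         call. = FALSE)
  }
  for (v in VIEWS) {
    if (qr(cbind(1, beads$images[[v]]))$rank < 3) {
      stop(sprintf("degenerate bead geometry: image points in view %s are collinear", v),
           call. = FALSE)
    }
  }
  img6 <- do.call(cbind, beads$images)  # XY.u XY.v YZ.u YZ.v XZ.u XZ.v
  to_world <- fit_poly_map(img6, world, degree_world, normalize = TRUE, name = "to_world")
  to_views <- fit_poly_map(world, img6, degree_world, normalize = FALSE, name = "to_views")
  view_maps <- list()
  for (target in VIEWS) {
    src <- view_sources(target)
    Xv <- cbind(beads$images[[src[1]]], beads$images[[src[2]]])
    view_maps[[target]] <- fit_poly_map(
      Xv, beads$images[[target]], degree_view, normalize = TRUE,
      name = sprintf("view_map %s+%s -> %s", src[1], src[2], target)
    )
  }
  structure(
    list(
      to_world = to_world, to_views = to_views, view_maps = view_maps,
      fitted_on = list(n_points = beads$n_beads, n_orientations = n_orientations)
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> five polynomial maps\n")
  cat(sprintf("  to_world  (deg %d): rms %.3g cm\n", x$to_world$degree, x$to_world$rms_residual))
  cat(sprintf("  to_views  (deg %d): rms %.3g px\n", x$to_views$degree, x$to_views$rms_residual))
  for (t in VIEWS) {
    cat(sprintf("  %s+%s -> %s (deg %d): rms %.3g px\n",
                view_sources(t)[1], view_sources(t)[2], t,
                x$view_maps[[t]]$degree, x$view_maps[[t]]$rms_residual))
  }
  invisible(x)
}

#' Map image triplets to world coordinates
#'
#' @param model A `calibration_model`.
#' @param xy,yz,xz Numeric (n x 2) pixel coordinates in each view.
#' @return Numeric (n x 3) world coordinates in cm. Rows with any missing
#'   input coordinate are missing in the output.
#' @export
map_to_world <- function(model, xy, yz, xz) {
  as2 <- function(p) if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  X <- cbind(as2(xy), as2(yz), as2(xz))
  poly_eval(model$to_world, X)
}

#' Map world points to the three views
#'
#' @param model A `calibration_model`.
#' @param points3d Numeric (n x 3) world coordinates, cm.
#' @return Named list of (n x 2) pixel matrices, one per view. Rows with a
#'   missing world coordinate are missing in every view.
#' @export
map_to_views <- function(model, points3d) {
  if (is.null(dim(points3d))) points3d <- matrix(points3d, ncol = 3)
  Y <- poly_eval(model$to_views, as.matrix(points3d))
  list(XY = Y[, 1:2, drop = FALSE],
       YZ = Y[, 3:4, drop = FALSE],
       XZ = Y[, 5:6, drop = FALSE])
}

#' Map two views' coordinates into the third view
#'
#' Evaluates the view-mapping function whose target is the view not named by
#' `source_a`/`source_b`. Sources may be given in either order.
#'
#' @param model A `calibration_model`.
#' @param source_a,source_b Distinct view labels from [VIEWS].
#' @param points_a,points_b Numeric (n x 2) pixel coordinates in the two
#'   source views.
#' @return Numeric (n x 2) pixel coordinates in the remaining view; rows with
#'   a missing source coordinate are missing.
#' @export
map_views_pairwise <- function(model, source_a, source_b, points_a, points_b) {
  stopifnot(source_a %in% VIEWS, source_b %in% VIEWS)
  if (source_a == source_b) stop("source views must be distinct", call. = FALSE)
  target <- VIEWS[!(VIEWS %in% c(source_a, source_b))]
  src <- view_sources(target)
  as2 <- function(p) if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  pts <- list()
  pts[[source_a]] <- as2(points_a)
  pts[[source_b]] <- as2(points_b)
  X <- cbind(pts[[src[1]]], pts[[src[2]]])
  poly_eval(model$view_maps[[target]], X)
}

# --- serialization ---------------------------------------------------------

poly_map_to_list <- function(pm) {
  list(
    input_dim = pm$input_dim, output_dim = pm$output_dim, degree = pm$degree,
    powers = pm$powers, coefficients = pm$coefficients,
    center = pm$center, scale = pm$scale, rank = pm$rank,
    n_obs = pm$n_obs, rms_residual = pm$rms_residual
  )
}

poly_map_from_list <- function(l) {
  pm <- list(
    input_dim = as.integer(l$input_dim), output_dim = as.integer(l$output_dim),
    degree = as.integer(l$degree),
    powers = matrix(as.integer(unlist(l$powers)), nrow = length(l$powers), byrow = TRUE),
    coefficients = matrix(as.numeric(unlist(l$coefficients)), nrow = length(l$coefficients), byrow = TRUE),
    center = as.numeric(l$center), scale = as.numeric(l$scale),
    rank = as.integer(l$rank), n_obs = as.integer(l$n_obs),
    rms_residual = as.numeric(l$rms_residual)
  )
  class(pm) <- "poly_map"
  pm
}

#' Write / read a calibration model as JSON
#'
#' The full model (degrees, exponent layouts, coefficient matrices, input
#' normalizations, residual diagnostics) is stored in one JSON document;
#' reading it back reproduces predictions exactly to double precision.
#'
#' @param model A `calibration_model`.
#' @param path File path.
#' @return `write_calibration_json` returns `path` invisibly;
#'   `read_calibration_json` returns a `calibration_model`.
#' @export
write_calibration_json <- function(model, path) {
  doc <- list(
    format = "fintrack3d/calibration",
    to_world = poly_map_to_list(model$to_world),
    to_views = poly_map_to_list(model$to_views),
    view_maps = lapply(model$view_maps, poly_map_to_list),
    fitted_on = model$fitted_on
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (is.null(doc$format) || doc$format != "fintrack3d/calibration") {
    stop("not a fintrack3d calibration JSON document", call. = FALSE)
  }
  structure(
    list(
      to_world = poly_map_from_list(doc$to_world),
      to_views = poly_map_from_list(doc$to_views),
      view_maps = lapply(doc$view_maps[VIEWS], poly_map_from_list),
      fitted_on = doc$fitted_on
    ),
    class = "calibration_model"
  )
}

#' Write / read bead correspondences as CSV
#'
#' Columns: `bead_id, X, Y, Z`, then `u, v` pixel columns per view
#' (`XY_u, XY_v, YZ_u, YZ_v, XZ_u, XZ_v`).
#'
#' @param beads A [bead_set()].
#' @param path File path.
#' @export
write_beads_csv <- function(beads, path) {
  df <- data.frame(
    bead_id = seq_len(beads$n_beads),
    X = beads$world[, 1], Y = beads$world[, 2], Z = beads$world[, 3]
  )
  for (v in VIEWS) {
    df[[paste0(v, "_u")]] <- beads$images[[v]][, 1]
    df[[paste0(v, "_v")]] <- beads$images[[v]][, 2]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_beads_csv
#' @export
read_beads_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("X", "Y", "Z", as.vector(t(outer(VIEWS, c("_u", "_v"), paste0))))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("bead CSV missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  images <- lapply(VIEWS, function(v) as.matrix(df[, paste0(v, c("_u", "_v"))]))
  names(images) <- VIEWS
  bead_set(as.matrix(df[, c("X", "Y", "Z")]), images)
}
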