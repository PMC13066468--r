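# Multivariate polynomial least-squares maps. These are the primitive behind
# all five calibration functions, so they are implemented here rather than
# delegated: the fits must be minimum-norm (consistent multi-view image
# coordinates lie on a 3-dimensional variety, so image-domain design matrices
# are structurally rank-deficient) and the monomial layout must be stable so
# that coefficient matrices can be serialized and compared.

#' Exponent matrix of the full monomial basis
#'
#' All monomials of total degree `<= degree` in `input_dim` variables,
#' including the constant and all cross terms, in a stable order (by total
#' degree, then lexicographically by exponent vector).
#'
#' @param input_dim Number of input variables.
#' @param degree Maximum total degree.
#' @return Integer matrix with one row per monomial and `input_dim` columns of
#'   exponents.
#' @examples
#' nrow(poly_powers(3, 2))  # choose(5, 2) = 10 monomials
#' @export
poly_powers <- function(input_dim, degree) {
  stopifnot(input_dim >= 1, degree >= 0)
  g <- as.matrix(do.call(expand.grid, rep(list(0:degree), input_dim)))
  g <- g[rowSums(g) <= degree, , drop = FALSE]
  ord <- do.call(order, c(list(rowSums(g)), lapply(seq_len(ncol(g)), function(k) g[, k])))
  g <- g[ord, , drop = FALSE]
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

# Design matrix of monomials for points X (n x p) under an exponent matrix.
poly_design <- function(X, powers) {
  n <- nrow(X)
  m <- nrow(powers)
  D <- matrix(1, n, m)
  maxd <- max(powers)
  for (k in seq_len(ncol(X))) {
    pw <- matrix(1, n, maxd + 1L)
    if (maxd > 0) for (d in seq_len(maxd)) pw[, d + 1L] <- pw[, d] * X[, k]
    D <- D * pw[, powers[, k] + 1L, drop = FALSE]
  }
  D
}

#' Fit a polynomial map by least squares
#'
#' Fits `output_dim` polynomials of total degree `degree` over the full
#' monomial basis in the columns of `X`, by minimum-norm ordinary least
#' squares (SVD pseudoinverse). Rows containing missing values are dropped
#' before fitting.
#'
#' @param X Numeric matrix of inputs (n x input_dim).
#' @param Y Numeric matrix of outputs (n x output_dim).
#' @param degree Polynomial total degree (2 or 3 in the calibration model).
#' @param normalize If `TRUE`, inputs are affinely standardized (stored in the
#'   map and re-applied at prediction time). Used for pixel-domain inputs,
#'   whose monomials span several orders of magnitude.
#' @param name Label used in error messages.
#' @return A `poly_map` object: exponent matrix, coefficient matrix
#'   (monomials x outputs), input normalization, numerical rank, and
#'   `rms_residual` (root-mean-square training residual in output units).
#' @seealso [predict.poly_map()]
#' @export
fit_poly_map <- function(X, Y, degree, normalize = FALSE, name = "poly_map") {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  Xf <- X[ok, , drop = FALSE]
  Yf <- Y[ok, , drop = FALSE]
  p <- ncol(X)
  q <- ncol(Y)
  powers <- poly_powers(p, degree)
  m <- nrow(powers)
  if (nrow(Xf) < m) {
    stop(sprintf(
      "underdetermined fit for '%s': %d usable observations for %d monomial coefficients (degree %d in %d inputs)",
      name, nrow(Xf), m, degree, p
    ), call. = FALSE)
  }
  if (normalize) {
    ctr <- colMeans(Xf)
    scl <- apply(Xf, 2, stats::sd)
    scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  } else {
    ctr <- rep(0, p)
    scl <- rep(1, p)
  }
  Xs <- sweep(sweep(Xf, 2, ctr, "-"), 2, scl, "/")
  D <- poly_design(Xs, powers)
  # column equilibration before the SVD keeps the pseudoinverse accurate
  # when monomial columns differ in magnitude
  cnorm <- sqrt(colSums(D^2))
  cnorm[cnorm < .Machine$double.eps] <- 1
  sv <- svd(sweep(D, 2, cnorm, "/"))
  tol <- max(dim(D)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  rank <- sum(keep)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  coef <- (sv$v %*% (dinv * (t(sv$u) %*% Yf))) / cnorm
  rms <- sqrt(mean((D %*% coef - Yf)^2))
  structure(
    list(
      input_dim = p, output_dim = q, degree = degree,
      powers = powers, coefficients = coef,
      center = ctr, scale = scl,
      rank = rank, n_obs = nrow(Xf), rms_residual = rms
    ),
    class = "poly_map"
  )
}

#' Evaluate a fitted polynomial map
#'
#' Rows of `newdata` containing any missing coordinate produce a fully missing
#' output row (missingness propagates; it is never an error).
#'
#' @param object A `poly_map`.
#' @param newdata Numeric matrix (n x input_dim), or a vector of length
#'   `input_dim`.
#' @param ... Unused.
#' @return Numeric matrix (n x output_dim).
#' @export
predict.poly_map <- function(object, newdata, ...) {
  X <- newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != object$input_dim) {
    stop(sprintf("expected %d input columns, got %d", object$input_dim, ncol(X)), call. = FALSE)
  }
  poly_eval(object, X)
}

# Internal fast path: no input checking, used in per-frame loops.
poly_eval <- function(pm, X) {
  out <- matrix(NA_real_, nrow(X), pm$output_dim)
  ok <- rowSums(is.na(X)) == 0L
  if (any(ok)) {
    Xs <- X[ok, , drop = FALSE]
    for (k in seq_len(ncol(Xs))) Xs[, k] <- (Xs[, k] - pm$center[k]) / pm$scale[k]
    out[ok, ] <- poly_design(Xs, pm$powers) %*% pm$coefficients
  }
  out
}

#' @export
print.poly_map <- function(x, ...) {
  cat(sprintf(
    "<poly_map> degree %d: R^%d -> R^%d (%d monomials, rank %d, fit on %d points, rms residual %.3g)\n",
    x$degree, x$input_dim, x$output_dim, nrow(x$powers), x$rank, x$n_obs, x$rms_residual
  ))
  invisible(x)
}
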