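#' Kernel specification
#'
#' Bundles a covariance-function family with its hyperparameters.  The
#' families follow the conventions used throughout this package:
#' \describe{
#'   \item{rbf}{\eqn{\sigma^2 \exp(-\|x_i - x_j\|^2 / \ell^2)}: a single
#'     lengthscale for the (squared Euclidean) distance.  Note the
#'     denominator is \eqn{\ell^2} with no factor 1/2.}
#'   \item{ard_rbf}{\eqn{\sigma^2 \exp(-\sum_k (x_{i,k}-x_{j,k})^2/\ell_k^2)}:
#'     one lengthscale per input dimension (automatic relevance
#'     determination); a large \eqn{\ell_k} prunes covariate k.}
#'   \item{matern32}{\eqn{\sigma^2 (1+\sqrt3 r)\exp(-\sqrt3 r)} with
#'     \eqn{r = \|x_i - x_j\|/\ell}.}
#'   \item{linear}{\eqn{\sum_k \sigma_k^2 x_{i,k} x_{j,k}}.}
#' }
#' The nugget \eqn{\sigma^2_{nugget}} is independent Gaussian observation
#' noise: it is added once per observation on the diagonal of the training
#' covariance matrix.
#'
#' @param family one of \code{"rbf"}, \code{"ard_rbf"}, \code{"matern32"},
#'   \code{"linear"}.
#' @param variance signal variance \eqn{\sigma^2} (ignored by
#'   \code{linear}).
#' @param lengthscales positive lengthscale(s); scalar for \code{rbf} /
#'   \code{matern32}, one per input dimension for \code{ard_rbf}.
#' @param nugget observation-noise variance, \eqn{\ge 0}.
#' @param linear_variances per-dimension weights \eqn{\sigma_k^2} for the
#'   \code{linear} family.
#' @return object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(family = c("rbf", "ard_rbf", "matern32", "linear"),
                        variance = 1, lengthscales = 1, nugget = 0,
                        linear_variances = NULL) {
  family <- match.arg(family)
  if (family != "linear") {
    if (any(!is.finite(variance)) || variance <= 0)
      stop("variance must be strictly positive", call. = FALSE)
    if (any(!is.finite(lengthscales)) || any(lengthscales <= 0))
      stop("lengthscales must be strictly positive", call. = FALSE)
  } else {
    if (is.null(linear_variances)) linear_variances <- 1
    if (any(linear_variances <= 0))
      stop("linear variances must be strictly positive", call. = FALSE)
  }
  if (nugget < 0) stop("nugget must be non-negative", call. = FALSE)
  structure(list(family = family, variance = variance,
                 lengthscales = as.numeric(lengthscales), nugget = nugget,
                 linear_variances = linear_variances),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel_spec: %s\n", x$family))
  if (x$family == "linear") {
    cat("  weights:", paste(signif(x$linear_variances, 4), collapse = ", "), "\n")
  } else {
    cat(sprintf("  variance: %.4g\n", x$variance))
    cat("  lengthscales:", paste(signif(x$lengthscales, 4), collapse = ", "), "\n")
  }
  cat(sprintf("  nugget: %.4g\n", x$nugget))
  invisible(x)
}

as_row <- function(x) if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)

check_pair <- function(xi, xj) {
  xi <- as.numeric(xi); xj <- as.numeric(xj)
  if (length(xi) != length(xj))
    stop("input dimensions do not match", call. = FALSE)
  list(xi = xi, xj = xj)
}

#' Evaluate the RBF kernel for one input pair
#'
#' \eqn{\sigma^2 \exp(-\|x_i-x_j\|^2/\ell^2) + \sigma^2_{nugget}
#' \delta_{x_i = x_j}}; the nugget indicator fires on exact input equality.
#'
#' @param xi,xj numeric input vectors of equal length.
#' @param spec a \code{kernel_spec} with \code{family = "rbf"}.
#' @return scalar covariance.
#' @export
rbf_kernel <- function(xi, xj, spec) {
  stopifnot(spec$family == "rbf")
  p <- check_pair(xi, xj)
  d2 <- sum((p$xi - p$xj)^2)
  spec$variance * exp(-d2 / spec$lengthscales[1]^2) +
    spec$nugget * as.numeric(identical(p$xi, p$xj))
}

#' Evaluate the Matern-3/2 kernel for one input pair
#'
#' \eqn{\sigma^2 (1 + \sqrt3 r) \exp(-\sqrt3 r)} with the scaled distance
#' \eqn{r = \|x_i - x_j\|/\ell}.
#' @inheritParams rbf_kernel
#' @export
matern32_kernel <- function(xi, xj, spec) {
  stopifnot(spec$family == "matern32")
  p <- check_pair(xi, xj)
  r <- sqrt(sum((p$xi - p$xj)^2)) / spec$lengthscales[1]
  spec$variance * (1 + sqrt(3) * r) * exp(-sqrt(3) * r) +
    spec$nugget * as.numeric(identical(p$xi, p$xj))
}

#' Evaluate the linear kernel for one input pair
#'
#' \eqn{\sum_k \sigma_k^2 x_{i,k} x_{j,k}}.
#' @inheritParams rbf_kernel
#' @export
linear_kernel <- function(xi, xj, spec) {
  stopifnot(spec$family == "linear")
  p <- check_pair(xi, xj)
  w <- rep_len(spec$linear_variances, length(p$xi))
  sum(w * p$xi * p$xj) + spec$nugget * as.numeric(identical(p$xi, p$xj))
}

#' Evaluate the ARD squared-exponential kernel for one input pair
#'
#' \eqn{\sigma^2 \exp(-\sum_k (x_{i,k}-x_{j,k})^2/\ell_k^2)}; reduces to
#' \code{\link{rbf_kernel}} for one-dimensional input.
#' @inheritParams rbf_kernel
#' @export
ard_rbf_kernel <- function(xi, xj, spec) {
  stopifnot(spec$family == "ard_rbf")
  p <- check_pair(xi, xj)
  l <- spec$lengthscales
  if (length(l) != length(p$xi))
    stop(sprintf("ard_rbf needs one lengthscale per dimension (%d != %d)",
                 length(l), length(p$xi)), call. = FALSE)
  spec$variance * exp(-sum((p$xi - p$xj)^2 / l^2)) +
    spec$nugget * as.numeric(identical(p$xi, p$xj))
}

# Cross-covariance matrix k(X1, X2) without nugget.  X1, X2: n x D matrices.
kernel_cross <- function(spec, X1, X2) {
  X1 <- as_row(X1); X2 <- as_row(X2)
  D <- ncol(X1)
  switch(spec$family,
    rbf = {
      d2 <- sqdist(X1, X2)
      spec$variance * exp(-d2 / spec$lengthscales[1]^2)
    },
    ard_rbf = {
      l <- rep_len(spec$lengthscales, D)
      d2 <- sqdist(sweep(X1, 2, l, "/"), sweep(X2, 2, l, "/"))
      spec$variance * exp(-d2)
    },
    matern32 = {
      r <- sqrt(pmax(sqdist(X1, X2), 0)) / spec$lengthscales[1]
      spec$variance * (1 + sqrt(3) * r) * exp(-sqrt(3) * r)
    },
    linear = {
      w <- rep_len(spec$linear_variances, D)
      (X1 * rep(w, each = nrow(X1))) %*% t(X2)
    })
}

# Pairwise squared Euclidean distances.
sqdist <- function(X1, X2) {
  n1 <- rowSums(X1^2); n2 <- rowSums(X2^2)
  d2 <- outer(n1, n2, "+") - 2 * tcrossprod(X1, X2)
  pmax(d2, 0)
}

#' Build a kernel covariance matrix
#'
#' @param spec a \code{kernel_spec}.
#' @param X input matrix (rows = inputs).
#' @param X2 optional second input matrix for a cross-covariance; when
#'   omitted the square matrix \eqn{K(X,X)} is returned with the nugget
#'   added to the diagonal (one noise term per observation).
#' @param nugget add the nugget to the diagonal (square case only).
#' @return covariance matrix.
#' @export
kernel_matrix <- function(spec, X, X2 = NULL, nugget = TRUE) {
  if (is.null(X2)) {
    K <- kernel_cross(spec, X, X)
    K <- (K + t(K)) / 2
    if (nugget && spec$nugget > 0) K <- K + diag(spec$nugget, nrow(as_row(X)))
    K
  } else {
    kernel_cross(spec, X, X2)
  }
}

# Number of free hyperparameters of a family at D input dimensions
# (signal variance + lengthscales + nugget).
n_hyperparameters <- function(spec, D) {
  switch(spec$family,
    rbf = 3L, matern32 = 3L,
    ard_rbf = as.integer(D + 2L),
    linear = as.integer(D + 1L))
}
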