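#' Describe a base kernel
#'
#' A kernel specification names one of the three kernel families used
#' throughout the package and carries its parameters. Parameters irrelevant
#' to the chosen family are stored but ignored.
#'
#' The radial basis kernel is parameterized as
#' `exp(-||x_i - x_j||^2 / (2 * rbf_bandwidth))`, so the default
#' `rbf_bandwidth = 1` gives a denominator of 2.
#'
#' @param family one of `"linear"`, `"rbf"`, `"polynomial"`.
#' @param rbf_bandwidth positive scale in the RBF denominator `2 * bandwidth`.
#' @param poly_degree positive integer degree of the polynomial kernel.
#' @param poly_offset additive offset `c` of the polynomial kernel
#'   `(<x_i, x_j> + c)^degree`.
#'
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("rbf", rbf_bandwidth = 2)
#' @export
kernel_spec <- function(family = c("linear", "rbf", "polynomial"),
                        rbf_bandwidth = 1, poly_degree = 2L, poly_offset = 1) {
  family <- match.arg(family)
  if (family == "rbf" && (!is.numeric(rbf_bandwidth) || rbf_bandwidth <= 0)) {
    stop("`rbf_bandwidth` must be a positive real for the rbf family", call. = FALSE)
  }
  if (family == "polynomial" && (poly_degree < 1 || poly_degree != round(poly_degree))) {
    stop("`poly_degree` must be a positive integer for the polynomial family", call. = FALSE)
  }
  structure(list(family = family,
                 rbf_bandwidth = rbf_bandwidth,
                 poly_degree = as.integer(poly_degree),
                 poly_offset = poly_offset),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.kernel_spec <- function(x, ...) {
  switch(x$family,
         linear = "<kernel: linear>",
         rbf = sprintf("<kernel: rbf, denominator 2*%g>", x$rbf_bandwidth),
         polynomial = sprintf("<kernel: polynomial, (<x,x'> + %g)^%d>",
                              x$poly_offset, x$poly_degree))
}

#' The default bank of three base kernels
#'
#' Linear, RBF with denominator 2 (`rbf_bandwidth = 1`), and inhomogeneous
#' polynomial `(<x_i, x_j> + 1)^2`. This is the kernel combination used by
#' default in both selection stages.
#'
#' @return A list of three [kernel_spec()] objects.
#' @examples
#' default_kernel_bank()
#' @export
default_kernel_bank <- function() {
  list(kernel_spec("linear"),
       kernel_spec("rbf", rbf_bandwidth = 1),
       kernel_spec("polynomial", poly_degree = 2L, poly_offset = 1))
}

kernel_from_inner_sq <- function(ip, sq, spec) {
  switch(spec$family,
         linear = ip,
         rbf = exp(-sq / (2 * spec$rbf_bandwidth)),
         polynomial = (ip + spec$poly_offset)^spec$poly_degree)
}

#' Compute a Gram matrix on a feature subset
#'
#' Evaluates the kernel described by `spec` between every pair of rows of
#' `X_sub` (samples as rows, the chosen features as columns).
#'
#' @param X_sub numeric sample-by-feature matrix without missing values.
#' @param spec a [kernel_spec()].
#' @param feature_subset optional character vector of feature identifiers the
#'   columns correspond to (stored for provenance checks).
#'
#' @return A `gram_matrix`: a numeric n x n matrix with the spec and feature
#'   subset attached as attributes.
#' @examples
#' X <- matrix(rnorm(12), 6, 2)
#' compute_gram(X, kernel_spec("rbf"))
#' @export
compute_gram <- function(X_sub, spec, feature_subset = colnames(X_sub)) {
  X_sub <- as.matrix(X_sub)
  if (nrow(X_sub) < 1L || ncol(X_sub) < 1L) {
    stop("`X_sub` needs at least one sample and one feature", call. = FALSE)
  }
  if (anyNA(X_sub)) {
    bad <- which(colSums(is.na(X_sub)) > 0)
    nm <- if (!is.null(colnames(X_sub))) colnames(X_sub)[bad[1]] else as.character(bad[1])
    stop("missing values in feature ", nm, "; impute before kernel computation",
         call. = FALSE)
  }
  if (!all(is.finite(X_sub))) stop("non-finite values in `X_sub`", call. = FALSE)
  ip <- tcrossprod(X_sub)
  sq <- if (spec$family == "rbf") {
    sn <- diag(ip)
    pmax(outer(sn, sn, "+") - 2 * ip, 0)
  } else NULL
  K <- kernel_from_inner_sq(ip, sq, spec)
  K <- (K + t(K)) / 2
  new_gram(K, spec, feature_subset)
}

new_gram <- function(K, spec, feature_subset = NULL, scale = 1) {
  structure(K, spec = spec, feature_subset = feature_subset,
            gram_scale = scale, class = c("gram_matrix", class(K)))
}

#' Cross-kernel block between training and new samples
#'
#' Evaluates `spec` between every training sample (rows of `X_train`) and
#' every new sample (rows of `X_new`) on the same feature subset. Any trace
#' normalization factor learned on the training Gram must be re-applied via
#' `scale`.
#'
#' @param X_train,X_new sample-by-feature matrices over identical features.
#' @param spec a [kernel_spec()].
#' @param scale multiplicative factor carried over from the (possibly
#'   trace-normalized) training Gram.
#' @return A train-by-new numeric matrix.
#' @export
compute_cross_gram <- function(X_train, X_new, spec, scale = 1) {
  X_train <- as.matrix(X_train); X_new <- as.matrix(X_new)
  if (ncol(X_train) != ncol(X_new)) {
    stop("training and new samples must share the feature subset", call. = FALSE)
  }
  ip <- tcrossprod(X_train, X_new)
  sq <- if (spec$family == "rbf") {
    pmax(outer(rowSums(X_train^2), rowSums(X_new^2), "+") - 2 * ip, 0)
  } else NULL
  kernel_from_inner_sq(ip, sq, spec) * scale
}

#' Rescale a Gram matrix to unit average diagonal
#'
#' Divides the matrix by `trace / n` so the trace equals the number of
#' samples. Base kernels of different families then enter the convex
#' combination on a common scale. Symmetry and positive semidefiniteness are
#' preserved.
#'
#' @param g a `gram_matrix`.
#' @return The rescaled `gram_matrix`; the applied factor accumulates in the
#'   `gram_scale` attribute so cross-kernel blocks can be scaled consistently.
#' @export
normalize_gram <- function(g) {
  n <- nrow(g)
  tr <- sum(diag(g))
  if (tr <= 0) stop("Gram matrix has non-positive trace; cannot normalize", call. = FALSE)
  f <- n / tr
  new_gram(unclass(g) * f, attr(g, "spec"), attr(g, "feature_subset"),
           scale = attr(g, "gram_scale") %||% 1 * f)
}

#' Stack base kernels computed on one feature subset
#'
#' @param mats list of `gram_matrix` objects over identical samples and an
#'   identical feature subset.
#' @return A `gram_stack` with elements `mats`, `M`, `specs`, `scales`.
#' @export
gram_stack <- function(mats) {
  if (length(mats) < 1L) stop("a gram_stack needs at least one kernel", call. = FALSE)
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, function(m) nrow(m) == n && ncol(m) == n, logical(1)))) {
    stop("all Gram matrices in a stack must share their dimension", call. = FALSE)
  }
  fs <- attr(mats[[1]], "feature_subset")
  same <- vapply(mats, function(m) identical(attr(m, "feature_subset"), fs), logical(1))
  if (!all(same)) stop("all Gram matrices in a stack must share the feature subset", call. = FALSE)
  structure(list(mats = mats,
                 M = length(mats),
                 specs = lapply(mats, attr, "spec"),
                 scales = vapply(mats, function(m) attr(m, "gram_scale") %||% 1, numeric(1)),
                 feature_subset = fs),
            class = "gram_stack")
}

#' Build the Gram stack of a kernel bank on a feature subset
#'
#' @param X_sub sample-by-feature matrix.
#' @param bank list of [kernel_spec()]s (default [default_kernel_bank()]).
#' @param normalize trace-normalize each base kernel to trace `n` (default
#'   `TRUE`; disable for exact-formula work).
#' @param feature_subset optional feature identifiers.
#' @return A `gram_stack`.
#' @export
build_gram_stack <- function(X_sub, bank = default_kernel_bank(),
                             normalize = TRUE, feature_subset = colnames(X_sub)) {
  mats <- lapply(bank, function(sp) {
    g <- compute_gram(X_sub, sp, feature_subset = feature_subset)
    if (normalize) normalize_gram(g) else g
  })
  gram_stack(mats)
}

#' Validate simplex weights for a kernel stack
#'
#' @param d nonnegative weights summing to one.
#' @return `d`, validated.
#' @export
kernel_weights <- function(d) {
  if (any(d < -1e-12)) stop("kernel weights must be nonnegative", call. = FALSE)
  if (abs(sum(d) - 1) > 1e-8) stop("kernel weights must sum to one", call. = FALSE)
  pmax(d, 0)
}

#' Convex combination of the base kernels in a stack
#'
#' Computes `sum_m d_m K_m` elementwise. A convex combination of positive
#' semidefinite matrices is positive semidefinite.
#'
#' @param stack a `gram_stack`.
#' @param d weights on the probability simplex, one per base kernel.
#' @return A `gram_matrix` (spec attribute lists the member specs and weights).
#' @export
combine_grams <- function(stack, d) {
  if (length(d) != stack$M) {
    stop("need exactly one weight per base kernel (", stack$M, ")", call. = FALSE)
  }
  d <- kernel_weights(d)
  K <- matrix(0, nrow(stack$mats[[1]]), ncol(stack$mats[[1]]))
  for (m in seq_len(stack$M)) K <- K + d[m] * unclass(stack$mats[[m]])
  new_gram(K, list(combined = stack$specs, weights = d), stack$feature_subset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
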