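#' Solver settings for the SVM/MKL optimizer
#'
#' @param C positive box constraint on the dual variables (soft-margin cost).
#' @param dual_gap_tol relative change in the objective `J` between outer
#'   iterations below which the weight descent stops.
#' @param max_outer_iter maximum outer (weight-update) iterations.
#' @param qp_tol accuracy demanded of the inner quadratic program (KKT /
#'   duality-gap scale).
#' @param seed integer seed governing any randomness in harnesses built
#'   around the solver (the solver itself is deterministic).
#' @return A `solver_settings` list.
#' @examples
#' solver_settings(C = 10)
#' @export
solver_settings <- function(C = 1, dual_gap_tol = 1e-3, max_outer_iter = 200L,
                            qp_tol = 1e-8, seed = 1L) {
  stopifnot(C > 0, dual_gap_tol > 0, max_outer_iter >= 1, qp_tol > 0)
  structure(list(C = C, dual_gap_tol = dual_gap_tol,
                 max_outer_iter = as.integer(max_outer_iter),
                 qp_tol = qp_tol, seed = as.integer(seed)),
            class = "solver_settings")
}

check_two_classes <- function(y) {
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
}

#' Solve the soft-margin SVM dual for one fixed kernel
#'
#' Maximizes `sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K_ij`
#' subject to `sum(alpha * y) = 0` and `0 <= alpha <= C`, then computes the
#' bias from the class-wise extreme raw scores (see [compute_bias()]).
#'
#' @param K n x n kernel (Gram) matrix.
#' @param y labels in `{-1, +1}`, both classes present.
#' @param settings a [solver_settings()].
#' @return A `dual_solution`: list with `alpha`, `bias`, `dual_objective`,
#'   `support_indices`, `converged`.
#' @examples
#' K <- tcrossprod(c(-1, 1))
#' solve_svm_dual(K, c(-1, 1), solver_settings(C = 10))
#' @export
solve_svm_dual <- function(K, y, settings = solver_settings()) {
  K <- unclass(as.matrix(K))
  n <- length(y)
  if (nrow(K) != n || ncol(K) != n) stop("K must be n x n for n labels", call. = FALSE)
  check_two_classes(y)
  check_psd(K)
  H <- (tcrossprod(y)) * K
  qp <- solve_box_qp(H, y, settings$C, tol = min(settings$qp_tol, 1e-10))
  alpha <- qp$alpha
  structure(list(alpha = alpha,
                 bias = compute_bias(alpha, K, y),
                 dual_objective = qp$obj,
                 support_indices = which(alpha > 1e-8 * settings$C),
                 converged = qp$converged,
                 qp_iters = qp$iters),
            class = "dual_solution")
}

check_psd <- function(K, tol = 1e-8) {
  n <- nrow(K)
  # cheap certificate: attempt Cholesky with a tolerance-scaled shift
  shift <- tol * max(sum(diag(K)) / n, 1)
  ok <- tryCatch({ chol(K + diag(2 * shift, n)); TRUE }, error = function(e) FALSE)
  if (!ok) {
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -tol * max(sum(diag(K)), 1)) {
      stop("kernel matrix is not positive semidefinite (min eigenvalue ",
           signif(ev, 3), ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Bias of the SVM decision function
#'
#' `b = -1/2 * (max over negative-class samples of the raw score + min over
#' positive-class samples of the raw score)`, where the raw score of sample
#' `i` is `sum_j alpha_j y_j K(x_i, x_j)`.
#'
#' @param alpha dual variables.
#' @param K n x n kernel matrix.
#' @param y labels in `{-1, +1}`, both classes present.
#' @return The scalar bias.
#' @export
compute_bias <- function(alpha, K, y) {
  check_two_classes(y)
  s <- as.numeric(unclass(as.matrix(K)) %*% (alpha * y))
  -0.5 * (max(s[y == -1]) + min(s[y == 1]))
}

#' Gradient of the MKL objective in the kernel weights
#'
#' At the inner-QP maximizer `alpha`, the partial derivative of the dual
#' objective with respect to weight `d_m` is
#' `-1/2 * alpha' (y y' * K_m) alpha` (an envelope-theorem consequence: the
#' maximizing `alpha` may be held fixed).
#'
#' @param alpha dual variables from a converged inner solve.
#' @param y labels.
#' @param stack a `gram_stack`.
#' @return Numeric vector of length `stack$M`.
#' @export
mkl_gradient <- function(alpha, y, stack) {
  if (length(alpha) != length(y) || length(y) != nrow(stack$mats[[1]])) {
    stop("alpha, y, and the stack disagree on the sample count", call. = FALSE)
  }
  ay <- alpha * y
  vapply(stack$mats, function(K) -0.5 * sum(ay * (unclass(K) %*% ay)), numeric(1))
}

inner_solve <- function(Hs, d, y, C, tol) {
  H <- Hs[[1]] * d[1]
  if (length(Hs) > 1) for (m in 2:length(Hs)) H <- H + d[m] * Hs[[m]]
  solve_box_qp(H, y, C, tol = tol)
}

#' Solve the SimpleMKL saddle-point problem
#'
#' Alternates (a) the SVM dual QP at fixed kernel weights with (b) a
#' reduced-gradient descent step on the weights constrained to the
#' probability simplex, with a backtracking line search, until the relative
#' change in the objective `J = min_d max_alpha W(alpha, d)` falls below
#' `dual_gap_tol` or `max_outer_iter` is reached. `J` is non-increasing
#' across outer iterations by construction (only improving steps are taken).
#'
#' @param stack a `gram_stack` of `M >= 1` base kernels.
#' @param y labels in `{-1, +1}`, both classes present.
#' @param settings a [solver_settings()].
#' @return An `mkl_model`: list with `weights` (simplex vector `d`), `dual`
#'   (a `dual_solution` at the final weights), `J`, `J_path`,
#'   `n_outer_iter`, `converged`, plus the stack's specs and scales for
#'   prediction.
#' @export
solve_simplemkl <- function(stack, y, settings = solver_settings()) {
  check_two_classes(y)
  M <- stack$M
  C <- settings$C
  qp_tol <- min(settings$qp_tol, 1e-10)
  yy <- tcrossprod(y)
  Hs <- lapply(stack$mats, function(K) yy * unclass(K))
  d <- rep(1 / M, M)
  qp <- inner_solve(Hs, d, y, C, qp_tol)
  J <- qp$obj
  J_path <- J
  converged <- M == 1L
  n_outer <- 0L
  if (M > 1L) {
    for (outer in seq_len(settings$max_outer_iter)) {
      n_outer <- outer
      g <- vapply(Hs, function(H) -0.5 * sum(qp$alpha * (H %*% qp$alpha)), numeric(1))
      mu <- which.max(d)                       # reference coordinate
      red <- g - g[mu]                         # reduced gradient
      D <- -red
      D[d <= 1e-12 & red > 0] <- 0             # never leave the simplex face
      D[mu] <- -sum(D[-mu])
      if (max(abs(D)) < 1e-12) { converged <- TRUE; break }
      neg <- which(D < 0)
      gamma <- min(-d[neg] / D[neg])           # step to the nearest face
      accepted <- FALSE
      for (half in 0:20) {
        d_try <- pmax(d + gamma * D, 0)
        d_try <- d_try / sum(d_try)
        qp_try <- inner_solve(Hs, d_try, y, C, qp_tol)
        if (qp_try$obj < J - 1e-12 * max(1, abs(J))) {
          d <- d_try; qp <- qp_try; accepted <- TRUE
          break
        }
        gamma <- gamma / 2
      }
      if (!accepted) { converged <- TRUE; break }
      J_new <- qp$obj
      J_path <- c(J_path, J_new)
      if (abs(J - J_new) <= settings$dual_gap_tol * max(abs(J), 1e-12)) {
        J <- J_new; converged <- TRUE; break
      }
      J <- J_new
    }
  }
  Kd <- matrix(0, length(y), length(y))
  for (m in seq_len(M)) Kd <- Kd + d[m] * unclass(stack$mats[[m]])
  dual <- structure(list(alpha = qp$alpha,
                         bias = compute_bias(qp$alpha, Kd, y),
                         dual_objective = qp$obj,
                         support_indices = which(qp$alpha > 1e-8 * C),
                         converged = qp$converged),
                    class = "dual_solution")
  structure(list(weights = d, dual = dual, J = J, J_path = J_path,
                 n_outer_iter = n_outer, converged = converged,
                 y = y, specs = stack$specs, scales = stack$scales,
                 feature_subset = stack$feature_subset, settings = settings),
            class = "mkl_model")
}

#' @export
print.mkl_model <- function(x, ...) {
  cat(sprintf("<mkl_model: J = %.6g, d = (%s), %d support vectors, %s in %d outer iterations>\n",
              x$J, paste(signif(x$weights, 4), collapse = ", "),
              length(x$dual$support_indices),
              if (x$converged) "converged" else "NOT converged", x$n_outer_iter))
  invisible(x)
}

#' Predict labels for new samples with a fitted MKL model
#'
#' Computes `sign(sum_i alpha_i y_i sum_m d_m K_m(x_i, z) + b)` for each new
#' sample `z`; a raw score of exactly zero maps to +1.
#'
#' @param object an `mkl_model` from [solve_simplemkl()].
#' @param cross list of `M` train-by-new kernel blocks computed with the same
#'   specs (and trace-normalization scales) as the training stack, e.g. via
#'   [compute_cross_gram()].
#' @param ... unused.
#' @return Numeric vector of predicted labels in `{-1, +1}` with the raw
#'   decision values in attribute `"decision"`.
#' @export
predict.mkl_model <- function(object, cross, ...) {
  if (length(cross) != length(object$weights)) {
    stop("need one cross-kernel block per base kernel", call. = FALSE)
  }
  n_new <- ncol(cross[[1]])
  Kd <- matrix(0, length(object$y), n_new)
  for (m in seq_along(cross)) {
    if (nrow(cross[[m]]) != length(object$y) || ncol(cross[[m]]) != n_new) {
      stop("cross-kernel block ", m, " has mismatched dimensions", call. = FALSE)
    }
    Kd <- Kd + object$weights[m] * cross[[m]]
  }
  f <- as.numeric(crossprod(Kd, object$dual$alpha * object$y)) + object$dual$bias
  out <- ifelse(f >= 0, 1, -1)
  attr(out, "decision") <- f
  out
}

#' Train an MKL classifier on raw feature data and predict new samples
#'
#' Convenience wrapper used by the evaluation harness: standardizes features
#' on the training samples, builds the Gram stack, fits [solve_simplemkl()],
#' and predicts the held-out samples with consistently scaled cross-kernels.
#'
#' @param X_train,X_new feature-by-sample matrices over identical features.
#' @param y_train training labels.
#' @param bank kernel bank (default [default_kernel_bank()]).
#' @param settings a [solver_settings()].
#' @param standardize z-score features on training statistics.
#' @param normalize trace-normalize base kernels.
#' @return Predicted labels for the columns of `X_new`.
#' @importFrom stats predict
#' @export
mkl_train_predict <- function(X_train, X_new, y_train,
                              bank = default_kernel_bank(),
                              settings = solver_settings(),
                              standardize = TRUE, normalize = TRUE) {
  if (standardize) {
    zs <- zscore_features(X_train)
    X_train <- zs$X
    X_new <- (X_new - zs$center) / zs$scale
  }
  stack <- build_gram_stack(t(X_train), bank, normalize = normalize,
                            feature_subset = rownames(X_train))
  fit <- solve_simplemkl(stack, y_train, settings)
  cross <- lapply(seq_along(bank), function(m) {
    compute_cross_gram(t(X_train), t(X_new), bank[[m]], scale = stack$scales[m])
  })
  predict(fit, cross)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the kernel weights of a fitted MKL model
#'
#' @param x an `mkl_model`.
#' @param ... unused.
#' @return A tibble with one row per base kernel: `kernel`, `weight`,
#'   `gradient` is omitted (not stored); plus the model objective.
#' @export
tidy.mkl_model <- function(x, ...) {
  tibble::tibble(
    kernel = vapply(x$specs, function(s) {
      if (is.list(s) && !is.null(s$family)) s$family else "combined"
    }, character(1)),
    weight = x$weights
  )
}

#' One-row summary of a fitted MKL model
#'
#' @param x an `mkl_model`.
#' @param ... unused.
#' @return A one-row tibble: `J`, `n_kernels`, `n_support`, `n_outer_iter`,
#'   `converged`.
#' @export
glance.mkl_model <- function(x, ...) {
  tibble::tibble(J = x$J,
                 n_kernels = length(x$weights),
                 n_support = length(x$dual$support_indices),
                 n_outer_iter = x$n_outer_iter,
                 converged = x$converged)
}
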