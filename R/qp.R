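#' Solve the soft-margin SVM dual quadratic program
#'
#' Minimizes `0.5 * a' H a - sum(a)` subject to `sum(y * a) = 0` and
#' `0 <= a <= C`, i.e. the (negated) soft-margin SVM dual for Hessian
#' `H = (y y') * K`. A primal-dual interior-point method with a Mehrotra
#' predictor-corrector step is used; the box-plus-single-equality structure
#' makes every Newton step a single Cholesky solve of `H + D` with `D`
#' diagonal and strictly positive, so rank-deficient `H` needs no explicit
#' regularization.
#'
#' @param H symmetric n x n Hessian (positive semidefinite up to tolerance).
#' @param y numeric vector of labels in `{-1, +1}`, length n.
#' @param C positive box constraint.
#' @param tol relative duality-gap tolerance for termination.
#' @param maxit maximum interior-point iterations.
#'
#' @return A list with `alpha` (clamped to the box), `nu` (equality
#'   multiplier), `obj` (the maximized dual value `sum(a) - 0.5 a'Ha`),
#'   `iters`, `converged`, and the final residuals `gap`, `rd`, `rp`.
#' @keywords internal
solve_box_qp <- function(H, y, C, tol = 1e-10, maxit = 100) {
  n <- length(y)
  stopifnot(is.matrix(H), nrow(H) == n, ncol(H) == n, C > 0)
  a <- rep(C / 2, n)
  nu <- 0
  z <- rep(max(1, C / 10), n)
  w <- z
  e <- rep(1, n)
  converged <- FALSE
  gap <- rd_max <- rp_abs <- NA_real_
  it <- 0L
  for (it in seq_len(maxit)) {
    s <- C - a
    Ha <- as.numeric(H %*% a)
    rd <- Ha - e + nu * y - z + w
    rp <- sum(y * a)
    gap <- sum(a * z) + sum(s * w)
    obj <- sum(a) - 0.5 * sum(a * Ha)
    scale <- max(1, abs(obj), C)
    rd_max <- max(abs(rd))
    rp_abs <- abs(rp)
    if (gap < tol * scale &&
        rd_max < sqrt(tol) * scale / 10 &&
        rp_abs < sqrt(tol) * scale / 10) {
      converged <- TRUE
      break
    }
    mu <- gap / (2 * n)
    d <- z / a + w / s
    M <- H + diag(d, n)
    R <- tryCatch(chol(M),
                  error = function(err) chol(M + diag(1e-12 * max(diag(M)), n)))
    solve_M <- function(b) backsolve(R, forwardsolve(t(R), b))
    My <- solve_M(y)
    yMy <- sum(y * My)
    newton <- function(tgt, cxz = 0, csw = 0) {
      r1 <- -rd + (tgt - a * z - cxz) / a - (tgt - s * w - csw) / s
      Mr <- solve_M(r1)
      dnu <- (sum(y * Mr) + rp) / yMy
      da <- Mr - dnu * My
      list(da = da,
           dz = (tgt - a * z - cxz - z * da) / a,
           dw = (tgt - s * w - csw + w * da) / s,
           dnu = dnu)
    }
    step_len <- function(st, frac) {
      da <- st$da; dz <- st$dz; dw <- st$dw
      min(1, frac * min(c(Inf,
                          -a[da < 0] / da[da < 0],
                          s[da > 0] / da[da > 0],
                          -z[dz < 0] / dz[dz < 0],
                          -w[dw < 0] / dw[dw < 0])))
    }
    aff <- newton(0)
    st_aff <- step_len(aff, 1)
    mu_aff <- (sum((a + st_aff * aff$da) * (z + st_aff * aff$dz)) +
               sum((s - st_aff * aff$da) * (w + st_aff * aff$dw))) / (2 * n)
    sigma <- min(1, (mu_aff / mu)^3)
    cc <- newton(sigma * mu, cxz = aff$da * aff$dz, csw = -aff$da * aff$dw)
    st <- step_len(cc, max(0.99, 1 - mu))
    a <- a + st * cc$da
    z <- z + st * cc$dz
    w <- w + st * cc$dw
    nu <- nu + st * cc$dnu
  }
  a <- pmin(pmax(a, 0), C)
  list(alpha = as.numeric(a),
       nu = nu,
       obj = sum(a) - 0.5 * sum(a * as.numeric(H %*% a)),
       iters = it,
       converged = converged,
       gap = gap, rd = rd_max, rp = rp_abs)
}
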