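# Shared fixture builders; everything is generated in code under fixed seeds.

# Small labeled dataset with one cleanly separating feature and noise.
toy_dataset <- function(n_per_class = 10, p_noise = 4, sep = 3, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(-1, 1), each = n_per_class)
  X <- matrix(rnorm(p_noise * n), p_noise, n)
  informative <- y * sep / 2 + rnorm(n, sd = 0.3)
  X <- rbind(informative, X)
  rownames(X) <- c("sep1", paste0("noise", seq_len(p_noise)))
  colnames(X) <- paste0("s", seq_len(n))
  expression_dataset(X, y)
}

# Random PD Gram over n well-spread samples (RBF on Gaussian points): the
# SVM dual then has a unique maximizer, so alpha comparison is meaningful.
random_pd_instance <- function(n = 20, seed = 1, C = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rep_len(c(-1, 1), n)[sample(n)]
  K <- exp(-as.matrix(dist(X))^2 / 2)
  list(K = K, y = y, C = C, X = X)
}

# Independent QP route: kernlab's interior-point solver on the same dual;
# when its internal linear solve goes singular (an ipop fragility on some
# instances) the equally independent SMO route (ksvm at tight tolerance)
# takes over. Both are independent of the package's own solver.
ipop_dual_oracle <- function(K, y, C) {
  n <- length(y)
  H <- tcrossprod(y) * K
  alpha <- tryCatch({
    fit <- kernlab::ipop(c = rep(-1, n), H = H, A = t(y), b = 0,
                         l = rep(0, n), u = rep(C, n), r = 0,
                         sigf = 9, maxiter = 300)
    kernlab::primal(fit)
  }, error = function(e) {
    fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                         C = C, scaled = FALSE, tol = 1e-9)
    a <- rep(0, n)
    a[kernlab::SVindex(fit)] <- abs(unlist(kernlab::coef(fit)))
    a
  })
  alpha <- pmin(pmax(alpha, 0), C)
  list(alpha = alpha,
       obj = sum(alpha) - 0.5 * sum(alpha * (H %*% alpha)))
}

# Exhaustive greedy oracle for the forward search: at every round, evaluate
# every remaining candidate with a full from-scratch subset solve.
greedy_oracle <- function(ds, candidates, r_max, settings = solver_settings()) {
  Z <- character(0)
  J_prev <- Inf
  J_seq <- numeric(0)
  remaining <- candidates
  reason <- "candidates_exhausted"
  while (length(remaining) > 0) {
    J_cand <- vapply(remaining, function(f) {
      subset_objective(ds, c(Z, f), settings = settings)
    }, numeric(1))
    best <- which.min(J_cand)
    if (J_prev - J_cand[best] <= 0) { reason <- "delta_nonpositive"; break }
    Z <- c(Z, remaining[best])
    J_seq <- c(J_seq, unname(J_cand[best]))
    J_prev <- J_cand[best]
    remaining <- remaining[-best]
    if (length(Z) >= r_max) { reason <- "max_size"; break }
  }
  list(Z = Z, J_seq = J_seq, stop_reason = reason)
}
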