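test_that("the two-point instance has the hand-derived saddle point", {
  K <- tcrossprod(c(-1, 1))           # linear kernel on x = (-1, +1)
  y <- c(-1, 1)
  sol <- solve_svm_dual(K, y, solver_settings(C = 10))
  expect_equal(sol$alpha, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sol$bias, 0, tolerance = 1e-6)
  expect_equal(sol$dual_objective, 0.5, tolerance = 1e-6)
})

test_that("the dual solution matches an independent interior-point QP", {
  for (seed in 1:10) {
    inst <- random_pd_instance(n = 20, seed = seed, C = c(0.5, 1, 10)[seed %% 3 + 1])
    mine <- solve_svm_dual(inst$K, inst$y, solver_settings(C = inst$C))
    ref <- ipop_dual_oracle(inst$K, inst$y, inst$C)
    expect_equal(mine$alpha, ref$alpha, tolerance = 1e-4)
    expect_equal(mine$dual_objective, ref$obj, tolerance = 1e-6)
  }
})

test_that("the box constraint collapses the dual as C tends to zero", {
  inst <- random_pd_instance(n = 12, seed = 3)
  sol <- solve_svm_dual(inst$K, inst$y, solver_settings(C = 1e-8))
  expect_lt(max(sol$alpha), 2e-8)
  expect_lt(abs(sol$dual_objective), 1e-6)
})

test_that("degenerate label vectors and bad kernels are rejected", {
  K <- diag(4)
  expect_error(solve_svm_dual(K, rep(1, 4), solver_settings()), "both classes")
  expect_error(solve_svm_dual(-diag(4), c(-1, 1, -1, 1), solver_settings()),
               "positive semidefinite")
  expect_error(compute_bias(rep(0, 4), K, rep(-1, 4)), "both classes")
})

test_that("the bias follows the class-extreme raw-score formula", {
  # symmetric instance mirrored about the origin: bias is exactly zero
  x <- c(-2, -1, 1, 2); y <- c(-1, -1, 1, 1)
  K <- tcrossprod(x)
  sol <- solve_svm_dual(K, y, solver_settings(C = 5))
  expect_equal(sol$bias, 0, tolerance = 1e-8)
  # direct recomputation from the definition
  s <- as.numeric(K %*% (sol$alpha * y))
  expect_equal(sol$bias, -0.5 * (max(s[y == -1]) + min(s[y == 1])))
  # shifting every raw score by +delta shifts the bias by -delta
  delta <- 0.7
  ay <- sol$alpha * y
  K_shift <- K + delta * outer(rep(1, 4), ay) / sum(ay^2)  # adds +delta to every score
  expect_equal(as.numeric(K_shift %*% ay), s + delta)
  expect_equal(compute_bias(sol$alpha, K_shift, y), sol$bias - delta,
               tolerance = 1e-10)
})

test_that("prediction applies the sign rule with ties mapping to +1", {
  K <- tcrossprod(c(-1, 1)); y <- c(-1, 1)
  stack <- gram_stack(list(new_gram(K, kernel_spec("linear"))))
  model <- solve_simplemkl(stack, y, solver_settings(C = 10))
  cross <- list(compute_cross_gram(cbind(c(-1, 1)), cbind(2), kernel_spec("linear")))
  p <- predict(model, cross)
  expect_equal(as.numeric(p), 1)
  expect_equal(attr(p, "decision"), 2, tolerance = 1e-6)
  # a test point at a support vector of the negative class predicts -1
  cross_neg <- list(compute_cross_gram(cbind(c(-1, 1)), cbind(-1), kernel_spec("linear")))
  expect_equal(as.numeric(predict(model, cross_neg)), -1)
  # a zero decision value maps to +1
  cross_zero <- list(compute_cross_gram(cbind(c(-1, 1)), cbind(0), kernel_spec("linear")))
  expect_equal(as.numeric(predict(model, cross_zero)), 1)
})

test_that("the analytic weight gradient matches central finite differences", {
  set.seed(21)
  inst <- random_pd_instance(n = 16, seed = 21)
  X <- inst$X
  stack <- build_gram_stack(X, normalize = FALSE)
  st <- solver_settings(C = 1)
  d0 <- c(0.5, 0.3, 0.2)
  yy <- tcrossprod(inst$y)
  inner_obj <- function(d) {
    K <- Reduce(`+`, Map(function(m, w) w * unclass(m), stack$mats, d))
    solve_svm_dual(K, inst$y, st)$dual_objective
  }
  K0 <- Reduce(`+`, Map(function(m, w) w * unclass(m), stack$mats, d0))
  alpha <- solve_svm_dual(K0, inst$y, st)$alpha
  g <- mkl_gradient(alpha, inst$y, stack)
  h <- 1e-5
  for (m in 1:3) {
    dp <- d0; dp[m] <- dp[m] + h
    dm <- d0; dm[m] <- dm[m] - h
    fd <- (inner_obj(dp) - inner_obj(dm)) / (2 * h)
    expect_equal(g[m], fd, tolerance = 1e-4 * max(1, abs(fd)))
  }
  # trivial cases
  expect_equal(mkl_gradient(rep(0, 16), inst$y, stack), rep(0, 3))
  st_same <- gram_stack(list(stack$mats[[1]], stack$mats[[1]]))
  g_same <- mkl_gradient(alpha, inst$y, st_same)
  expect_equal(g_same[1], g_same[2])
})

test_that("SimpleMKL with one kernel reduces exactly to the single-kernel dual", {
  for (seed in 1:10) {
    inst <- random_pd_instance(n = 14, seed = 100 + seed)
    single <- solve_svm_dual(inst$K, inst$y, solver_settings(C = 1))
    stack <- gram_stack(list(new_gram(inst$K, kernel_spec("rbf"))))
    model <- solve_simplemkl(stack, inst$y, solver_settings(C = 1))
    expect_equal(model$weights, 1)
    expect_equal(model$J, single$dual_objective, tolerance = 1e-8)
  }
})

test_that("SimpleMKL keeps J non-increasing and the weights on the simplex", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 30
    X <- matrix(rnorm(n * 4), n, 4)
    y <- rep_len(c(-1, 1), n)
    stack <- build_gram_stack(X)
    model <- solve_simplemkl(stack, y, solver_settings(C = 1))
    expect_true(all(diff(model$J_path) <= 1e-8))
    expect_equal(sum(model$weights), 1, tolerance = 1e-8)
    expect_true(all(model$weights >= -1e-12))
    al <- model$dual$alpha
    expect_true(all(al >= -1e-9) && all(al <= 1 + 1e-6))
    expect_lt(abs(sum(al * y)), 1e-6 * 1 * n)
    expect_equal(model$J, model$dual$dual_objective, tolerance = 1e-8)
  }
})

test_that("two identical kernels give the single-kernel objective", {
  inst <- random_pd_instance(n = 18, seed = 7)
  single <- solve_svm_dual(inst$K, inst$y, solver_settings(C = 1))
  g <- new_gram(inst$K, kernel_spec("rbf"))
  model <- solve_simplemkl(gram_stack(list(g, g)), inst$y, solver_settings(C = 1))
  expect_equal(model$J, single$dual_objective, tolerance = 1e-8)
})

test_that("a separating kernel is favoured over a noise kernel", {
  set.seed(9)
  n <- 30
  y <- rep(c(-1, 1), each = n / 2)
  x_sep <- y * 1.5 + rnorm(n, sd = 0.2)
  K_sep <- normalize_gram(compute_gram(cbind(x_sep), kernel_spec("linear"),
                                       feature_subset = NULL))
  x_noise <- rnorm(n)
  K_noise <- normalize_gram(compute_gram(cbind(x_noise), kernel_spec("linear"),
                                         feature_subset = NULL))
  st <- solver_settings(C = 1)
  J_noise_alone <- solve_svm_dual(K_noise, y, st)$dual_objective
  model <- solve_simplemkl(gram_stack(list(K_sep, K_noise)), y, st)
  expect_gt(model$weights[1], model$weights[2])
  expect_lt(model$J, J_noise_alone)
})

test_that("J is invariant to a simultaneous permutation of samples", {
  set.seed(12)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rep_len(c(-1, 1), n)
  st <- solver_settings(C = 1)
  J1 <- solve_simplemkl(build_gram_stack(X), y, st)$J
  perm <- sample(n)
  J2 <- solve_simplemkl(build_gram_stack(X[perm, ]), y[perm], st)$J
  expect_equal(J1, J2, tolerance = 1e-7)
})

test_that("flipping labels of a separable instance tends not to decrease J", {
  n <- 40
  worse <- 0
  for (seed in 1:20) {
    set.seed(300 + seed)
    y <- rep(c(-1, 1), each = n / 2)
    X <- cbind(y * 2 + rnorm(n, sd = 0.3), rnorm(n))
    st <- solver_settings(C = 1)
    J_clean <- solve_simplemkl(build_gram_stack(X), y, st)$J
    y_noisy <- y
    flip <- sample(n, n / 5)
    y_noisy[flip] <- -y_noisy[flip]
    if (length(unique(y_noisy)) < 2) next
    J_noisy <- solve_simplemkl(build_gram_stack(X), y_noisy, st)$J
    if (J_noisy < J_clean) worse <- worse + 1
  }
  expect_lt(worse, 10)  # majority direction: label noise does not decrease J
})

test_that("tidy and glance summarise a fitted model", {
  inst <- random_pd_instance(n = 12, seed = 5)
  model <- solve_simplemkl(build_gram_stack(inst$X), inst$y, solver_settings(C = 1))
  td <- tidy(model)
  expect_equal(td$kernel, c("linear", "rbf", "polynomial"))
  expect_equal(sum(td$weight), 1, tolerance = 1e-8)
  gl <- glance(model)
  expect_equal(gl$J, model$J)
  expect_true(gl$converged)
})
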