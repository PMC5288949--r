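test_that("an informative feature scores lower J than noise, duplicates tie, constants flag", {
  ds <- toy_dataset(n_per_class = 20, p_noise = 3, seed = 8)
  # add a duplicate of the separating feature and a constant feature
  X <- rbind(ds$X, dup = ds$X["sep1", ], const = rep(2, ncol(ds$X)))
  ds2 <- expression_dataset(X, ds$y)
  sc <- score_features(ds2)
  J <- setNames(sc$J, sc$feature_id)
  expect_lt(J["sep1"], min(J[paste0("noise", 1:3)]))
  expect_equal(unname(J["sep1"]), unname(J["dup"]), tolerance = 1e-8)
  expect_true(is.infinite(J["const"]))
  expect_equal(sc$feature_id[nrow(sc)], "const")   # constants rank last
  expect_true(sc$constant[nrow(sc)])
})

test_that("select_relevant keeps the ascending-J head with the stated tie rule", {
  sc <- tibble::tibble(feature_id = c("f3", "f1", "f2"),
                       J = c(0.1, 0.5, 0.9), rank = 1:3, constant = FALSE)
  class(sc) <- c("smkl_scores", class(sc))
  expect_equal(select_relevant(sc, 2), c("f3", "f1"))
  expect_equal(select_relevant(sc, 10), c("f3", "f1", "f2"))
  expect_error(select_relevant(sc, 0), "at least 1")
})

test_that("stage-1 ranking puts ties in input order", {
  set.seed(5)
  n <- 20
  y <- rep(c(-1, 1), n / 2)
  x <- rnorm(n)
  X <- rbind(a = x, b = x + 10, c = rnorm(n))  # a and b identical after z-scoring
  ds <- expression_dataset(X, y)
  sc <- score_features(ds)
  expect_lt(which(sc$feature_id == "a"), which(sc$feature_id == "b"))
})

test_that("the subset objective matches the single-feature score and is order-invariant", {
  ds <- toy_dataset(n_per_class = 8, p_noise = 2, seed = 3)
  sc <- score_features(ds)
  st <- solver_settings()
  for (f in ds$feature_ids) {
    expect_equal(subset_objective(ds, f, settings = st),
                 sc$J[sc$feature_id == f], tolerance = 1e-8)
  }
  Z <- c("sep1", "noise2")
  expect_equal(subset_objective(ds, Z, settings = st),
               subset_objective(ds, rev(Z), settings = st), tolerance = 1e-8)
})

test_that("incremental stage-2 Grams equal full recomputation", {
  # forward_select builds candidate Grams from additive accumulators; the
  # brute-force oracle recomputes every subset from scratch
  ds <- toy_dataset(n_per_class = 8, p_noise = 5, seed = 13)
  st <- solver_settings()
  tr <- forward_select(ds, ds$feature_ids, r_max = 4, settings = st)
  for (k in seq_along(tr$Z)) {
    expect_equal(tr$J_seq[k],
                 subset_objective(ds, tr$Z[seq_len(k)], settings = st),
                 tolerance = 1e-8)
  }
})

test_that("forward selection reproduces the exhaustive greedy oracle", {
  ds <- toy_dataset(n_per_class = 10, p_noise = 5, seed = 17)
  st <- solver_settings()
  sc <- score_features(ds)
  candidates <- select_relevant(sc, 6)
  tr <- forward_select(ds, candidates, r_max = 3, settings = st)
  oracle <- greedy_oracle(ds, candidates, r_max = 3, settings = st)
  expect_equal(tr$Z, oracle$Z)
  expect_equal(tr$J_seq, oracle$J_seq, tolerance = 1e-8)
  expect_equal(tr$stop_reason, oracle$stop_reason)
  expect_true(all(tr$deltaJ_seq > 0))
  expect_true(all(diff(tr$J_seq) < 0))
})

test_that("the first accepted feature is the argmin of the single-feature J", {
  ds <- toy_dataset(n_per_class = 10, p_noise = 4, seed = 19)
  sc <- score_features(ds)
  tr <- forward_select(ds, ds$feature_ids, r_max = 1)
  expect_equal(tr$Z[1], sc$feature_id[1])
  expect_equal(tr$Z[1], "sep1")
  expect_equal(tr$stop_reason, "max_size")
  expect_true(is.infinite(tr$deltaJ_seq[1]))  # J_0 starts at +Inf
})

test_that("forward selection is invariant to candidate input order given fixed tie ranks", {
  ds <- toy_dataset(n_per_class = 8, p_noise = 4, seed = 23)
  sc <- score_features(ds)
  candidates <- select_relevant(sc, 5)
  tr_ref <- forward_select(ds, candidates, r_max = 3)
  # shuffling the *dataset's* feature order must not change the trace as long
  # as the candidate list (the tie order) is the same
  set.seed(1)
  perm <- sample(nrow(ds$X))
  ds_shuf <- expression_dataset(ds$X[perm, ], ds$y)
  tr_shuf <- forward_select(ds_shuf, candidates, r_max = 3)
  expect_equal(tr_shuf$Z, tr_ref$Z)
  expect_equal(tr_shuf$J_seq, tr_ref$J_seq, tolerance = 1e-10)
})

test_that("stage-1 ranking is invariant to sample order and feature-wise affine maps", {
  ds <- toy_dataset(n_per_class = 8, p_noise = 3, seed = 29)
  sc <- score_features(ds)
  set.seed(2)
  perm <- sample(ncol(ds$X))
  ds_perm <- expression_dataset(ds$X[, perm], ds$y[perm],
                                sample_ids = ds$sample_ids[perm])
  expect_equal(score_features(ds_perm)$feature_id, sc$feature_id)
  a <- runif(nrow(ds$X), 0.5, 3); b <- rnorm(nrow(ds$X))
  ds_aff <- expression_dataset(ds$X * a + b, ds$y)
  sc_aff <- score_features(ds_aff)
  expect_equal(sc_aff$feature_id, sc$feature_id)
  expect_equal(sc_aff$J, sc$J, tolerance = 1e-6)
})

test_that("smkl_fs composes the stages and skip_stage1 searches all features", {
  ds <- toy_dataset(n_per_class = 8, p_noise = 9, seed = 31)
  fit <- smkl_fs(ds, n_star = 5, r_max = 3)
  expect_s3_class(fit$scores, "smkl_scores")
  expect_length(fit$relevant, 5)
  expect_true(all(fit$trace$Z %in% fit$relevant))
  # n_star = 1: the trace holds exactly the top-ranked feature
  fit1 <- smkl_fs(ds, n_star = 1, r_max = 3)
  expect_equal(fit1$trace$Z, fit1$scores$feature_id[1])
  # skip_stage1 on a small problem equals forward_select over all features
  fit_skip <- smkl_fs(ds, r_max = 3, skip_stage1 = TRUE)
  expect_null(fit_skip$scores)
  tr_all <- forward_select(ds, ds$feature_ids, r_max = 3)
  expect_equal(fit_skip$trace$Z, tr_all$Z)
  expect_equal(fit_skip$trace$J_seq, tr_all$J_seq)
})

test_that("stage 1 recovers planted informative features", {
  ds <- simulate_expression(synthetic_spec(n_pairs = 20, p = 60,
                                           k_informative = 5, k_redundant = 0,
                                           effect = 2, seed = 11))
  roles <- attr(ds, "roles")
  sc <- score_features(ds)
  top10 <- utils::head(sc$feature_id, 10)
  planted <- roles$feature_id[roles$role == "informative"]
  expect_gte(sum(top10 %in% planted), 4)
})
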