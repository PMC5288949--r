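#' Rank features by their single-feature MKL objective
#'
#' Stage one of the two-stage selection: for every feature, the bank of base
#' kernels is computed on that feature alone and the SimpleMKL saddle-point
#' objective `J` is solved. Smaller `J` means the single feature supports a
#' wider-margin separation, i.e. greater relevance; the returned table is
#' sorted ascending in `J`, with ties broken by input feature order.
#' Zero-variance features are assigned `J = Inf` and flagged rather than
#' raising an error.
#'
#' @param ds an [expression_dataset()] with both classes present.
#' @param bank list of [kernel_spec()]s (default [default_kernel_bank()]).
#' @param settings a [solver_settings()].
#' @param standardize z-score each feature before kernel computation.
#' @param normalize trace-normalize each base kernel.
#' @return A tibble of class `smkl_scores` with columns `feature_id`, `J`,
#'   `rank` (1 = most relevant), `constant` (zero-variance flag), sorted
#'   ascending by `J`.
#' @export
score_features <- function(ds, bank = default_kernel_bank(),
                           settings = solver_settings(),
                           standardize = TRUE, normalize = TRUE) {
  check_two_classes(ds$y)
  X <- ds$X
  if (anyNA(X)) stop("dataset contains missing values; preprocess first", call. = FALSE)
  sds <- apply(X, 1, stats::sd)
  if (standardize) X <- zscore_features(X)$X
  J <- rep(Inf, nrow(X))
  for (i in seq_len(nrow(X))) {
    if (!is.finite(sds[i]) || sds[i] == 0) next
    stack <- build_gram_stack(cbind(X[i, ]), bank, normalize = normalize,
                              feature_subset = ds$feature_ids[i])
    J[i] <- solve_simplemkl(stack, ds$y, settings)$J
  }
  ord <- order(J, seq_along(J))   # ascending J, ties by input order
  out <- tibble::tibble(feature_id = ds$feature_ids[ord],
                        J = J[ord],
                        rank = seq_along(ord),
                        constant = !is.finite(J[ord]) & (sds[ord] == 0 | !is.finite(sds[ord])))
  class(out) <- c("smkl_scores", class(out))
  out
}

#' Keep the top-ranked relevant features
#'
#' @param scores an `smkl_scores` tibble from [score_features()].
#' @param n_star number of features to keep (default 100).
#' @return A character vector of the `min(n_star, nrow(scores))` top-ranked
#'   feature identifiers, in rank order.
#' @export
select_relevant <- function(scores, n_star = 100L) {
  if (n_star < 1) stop("`n_star` must be at least 1", call. = FALSE)
  utils::head(scores$feature_id, n_star)
}

#' MKL objective of a feature subset
#'
#' `J_Z`: the SimpleMKL saddle-point value where every base kernel is
#' computed on the samples restricted to the features in `Z`. With a single
#' feature this reproduces the stage-one score.
#'
#' @param ds an [expression_dataset()].
#' @param Z nonempty vector of feature identifiers.
#' @inheritParams score_features
#' @return The scalar objective `J_Z`.
#' @export
subset_objective <- function(ds, Z, bank = default_kernel_bank(),
                             settings = solver_settings(),
                             standardize = TRUE, normalize = TRUE) {
  if (length(Z) < 1) stop("`Z` must be nonempty", call. = FALSE)
  sub <- subset_dataset(ds, features = Z)
  X <- if (standardize) zscore_features(sub$X)$X else sub$X
  stack <- build_gram_stack(t(X), bank, normalize = normalize,
                            feature_subset = sub$feature_ids)
  solve_simplemkl(stack, sub$y, settings)$J
}

# Incremental Gram machinery for the forward search: per-subset inner-product
# and squared-distance accumulators are additive over features, so the Grams
# of Z + {f} come from rank-style updates instead of full recomputation.
stack_from_accumulators <- function(ip, sq, bank, normalize, feature_subset) {
  n <- nrow(ip)
  mats <- lapply(bank, function(sp) {
    K <- kernel_from_inner_sq(ip, sq, sp)
    g <- new_gram((K + t(K)) / 2, sp, feature_subset)
    if (normalize) normalize_gram(g) else g
  })
  gram_stack(mats)
}

#' Greedy forward selection by objective reduction
#'
#' Stage two: starting from the empty set with `J_0 = +Inf`, each round
#' evaluates `J` on `Z + {f}` for every remaining candidate `f` and accepts
#' the candidate with the largest reduction `deltaJ = J_prev - J_new` (ties
#' broken by candidate order, i.e. lowest stage-one rank). The search stops
#' when no candidate reduces the objective (`deltaJ <= 0`), when `r_max`
#' features are selected, or when the candidates are exhausted.
#'
#' @param ds an [expression_dataset()].
#' @param candidates character vector of candidate feature identifiers in
#'   stage-one rank order.
#' @param r_max maximum subset size (default 10).
#' @inheritParams score_features
#' @return An object of class `smkl_trace`: list with `Z` (selected
#'   identifiers in acceptance order), `J_seq`, `deltaJ_seq`, `stop_reason`
#'   (one of `"delta_nonpositive"`, `"max_size"`, `"candidates_exhausted"`).
#' @export
forward_select <- function(ds, candidates, r_max = 10L,
                           bank = default_kernel_bank(),
                           settings = solver_settings(),
                           standardize = TRUE, normalize = TRUE) {
  if (length(candidates) < 1) stop("`candidates` must be nonempty", call. = FALSE)
  if (r_max < 1) stop("`r_max` must be at least 1", call. = FALSE)
  sub <- subset_dataset(ds, features = candidates)
  X <- if (standardize) zscore_features(sub$X)$X else sub$X
  n <- ncol(X)
  need_sq <- any(vapply(bank, function(s) s$family == "rbf", logical(1)))
  ip_feat <- lapply(seq_len(nrow(X)), function(i) tcrossprod(X[i, ]))
  sq_feat <- if (need_sq) lapply(seq_len(nrow(X)), function(i) outer(X[i, ], X[i, ], "-")^2)
             else NULL
  remaining <- seq_along(candidates)
  ip_Z <- matrix(0, n, n)
  sq_Z <- if (need_sq) matrix(0, n, n) else NULL
  Z <- character(0)
  J_seq <- numeric(0)
  deltaJ_seq <- numeric(0)
  J_prev <- Inf
  stop_reason <- "candidates_exhausted"
  while (length(remaining) > 0) {
    J_cand <- vapply(remaining, function(i) {
      stack <- stack_from_accumulators(ip_Z + ip_feat[[i]],
                                       if (need_sq) sq_Z + sq_feat[[i]] else NULL,
                                       bank, normalize,
                                       candidates[c(match(Z, candidates), i)])
      solve_simplemkl(stack, sub$y, settings)$J
    }, numeric(1))
    # maximizing deltaJ = J_prev - J_cand is minimizing J_cand; which.min
    # returns the first minimum, i.e. ties break by lowest stage-1 rank
    best <- which.min(J_cand)
    dJ <- J_prev - J_cand[best]
    if (dJ <= 0) { stop_reason <- "delta_nonpositive"; break }
    i <- remaining[best]
    Z <- c(Z, candidates[i])
    J_seq <- c(J_seq, J_cand[best])
    deltaJ_seq <- c(deltaJ_seq, dJ)
    J_prev <- J_cand[best]
    ip_Z <- ip_Z + ip_feat[[i]]
    if (need_sq) sq_Z <- sq_Z + sq_feat[[i]]
    remaining <- remaining[-best]
    if (length(Z) >= r_max) { stop_reason <- "max_size"; break }
  }
  structure(list(Z = Z, J_seq = J_seq, deltaJ_seq = deltaJ_seq,
                 stop_reason = stop_reason),
            class = "smkl_trace")
}

#' @export
print.smkl_trace <- function(x, ...) {
  cat(sprintf("<smkl_trace: %d features selected (%s)>\n",
              length(x$Z), x$stop_reason))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a forward-selection trace
#'
#' @param x an `smkl_trace`.
#' @param ... unused.
#' @return A tibble with one row per accepted feature: `step`, `feature_id`,
#'   `J` (objective after acceptance), `delta_J` (reduction that earned the
#'   acceptance; `Inf` for the first feature since the search starts at
#'   `J_0 = +Inf`).
#' @export
tidy.smkl_trace <- function(x, ...) {
  tibble::tibble(step = seq_along(x$Z),
                 feature_id = x$Z,
                 J = x$J_seq,
                 delta_J = x$deltaJ_seq)
}

#' One-row summary of a forward-selection trace
#'
#' @param x an `smkl_trace`.
#' @param ... unused.
#' @return A one-row tibble: `n_selected`, `J_final`, `stop_reason`.
#' @export
glance.smkl_trace <- function(x, ...) {
  tibble::tibble(n_selected = length(x$Z),
                 J_final = if (length(x$J_seq)) x$J_seq[length(x$J_seq)] else Inf,
                 stop_reason = x$stop_reason)
}

#' Two-stage MKL feature selection
#'
#' Runs stage one ([score_features()]), keeps the top `n_star` features
#' ([select_relevant()]), and runs the greedy forward search
#' ([forward_select()]) over them. With `skip_stage1 = TRUE` the forward
#' search runs over all features in input-matrix order (ties in round one
#' then break by that order) and the stage-one table is not computed.
#'
#' @param ds an [expression_dataset()] (preprocessed: no missing values).
#' @param n_star size of the stage-one relevant set (default 100).
#' @param r_max maximum stage-two subset size (default 10).
#' @param skip_stage1 run the forward search on all features directly.
#' @inheritParams score_features
#' @return A list of class `smkl_fit` with `scores` (`smkl_scores` tibble or
#'   `NULL` when stage one is skipped), `relevant` (candidate identifiers),
#'   and `trace` (`smkl_trace`).
#' @examples
#' ds <- simulate_expression(synthetic_spec(n_pairs = 10, p = 12,
#'                                          k_informative = 2, k_redundant = 0,
#'                                          seed = 1))
#' fit <- smkl_fs(ds, n_star = 6, r_max = 3)
#' tidy(fit$trace)
#' @export
smkl_fs <- function(ds, n_star = 100L, r_max = 10L, skip_stage1 = FALSE,
                    bank = default_kernel_bank(), settings = solver_settings(),
                    standardize = TRUE, normalize = TRUE) {
  if (skip_stage1) {
    scores <- NULL
    relevant <- ds$feature_ids
  } else {
    scores <- score_features(ds, bank, settings, standardize, normalize)
    relevant <- select_relevant(scores, n_star)
  }
  trace <- forward_select(ds, relevant, r_max = r_max, bank = bank,
                          settings = settings, standardize = standardize,
                          normalize = normalize)
  structure(list(scores = scores, relevant = relevant, trace = trace),
            class = "smkl_fit")
}

#' @export
print.smkl_fit <- function(x, ...) {
  cat("Two-stage MKL feature selection\n")
  if (!is.null(x$scores)) {
    cat(sprintf("  stage 1: %d features scored, %d kept\n",
                nrow(x$scores), length(x$relevant)))
  } else {
    cat("  stage 1: skipped\n")
  }
  cat(sprintf("  stage 2: %d features selected (%s)\n",
              length(x$trace$Z), x$trace$stop_reason))
  invisible(x)
}
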