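#' Classification accuracy and error from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)` and
#' `error = (FN + FP) / (TP + TN + FP + FN)`; they sum to one.
#'
#' @param TP,TN,FP,FN nonnegative integer confusion counts, totalling > 0.
#' @return A named numeric vector `c(accuracy, error)`.
#' @examples
#' accuracy_and_error(TP = 9, TN = 8, FP = 1, FN = 2)
#' @export
accuracy_and_error <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("confusion counts sum to zero", call. = FALSE)
  c(accuracy = (TP + TN) / total, error = (FN + FP) / total)
}

#' Union stability of a list of selected feature sets
#'
#' The size of the global intersection over the size of the global union of
#' the `k` sets selected on `k` resamples; 1 iff all sets are identical.
#'
#' @param sets list of `k >= 2` nonempty character vectors.
#' @return A number in `[0, 1]`.
#' @examples
#' union_stability(list(c("a", "b", "c"), c("b", "c", "d")))
#' @export
union_stability <- function(sets) {
  if (length(sets) < 2) stop("need at least two feature sets", call. = FALSE)
  U <- Reduce(union, sets)
  if (length(U) == 0) stop("the union of the feature sets is empty", call. = FALSE)
  length(Reduce(intersect, sets)) / length(U)
}

#' Independent (pairwise Jaccard) stability
#'
#' The mean over all unordered pairs of sets of
#' `|S_i intersect S_j| / |S_i union S_j|`. A pair with an empty union
#' contributes 0 with a warning (impossible for fixed-size nonempty lists).
#'
#' @param sets list of `k >= 2` character vectors.
#' @return A number in `[0, 1]`.
#' @examples
#' independent_stability(list(c("a", "b"), c("b", "c"), c("a", "c")))
#' @export
independent_stability <- function(sets) {
  k <- length(sets)
  if (k < 2) stop("need at least two feature sets", call. = FALSE)
  pairs <- utils::combn(k, 2)
  vals <- apply(pairs, 2, function(ij) {
    u <- union(sets[[ij[1]]], sets[[ij[2]]])
    if (length(u) == 0) {
      warning("pair with empty union contributes 0", call. = FALSE)
      return(0)
    }
    length(intersect(sets[[ij[1]]], sets[[ij[2]]])) / length(u)
  })
  mean(vals)
}

#' Mean intersection size with other methods' feature sets
#'
#' For a target set and the sets selected by other methods on the same data,
#' the similarity is the average intersection *size* (not Jaccard) between
#' the target and each other set.
#'
#' @param target character vector of the method's selected features.
#' @param others list of `k - 1 >= 1` character vectors from other methods.
#' @return A nonnegative number (at most `length(target)`).
#' @examples
#' similarity_mean(c("a", "b", "c"), list(c("a", "b", "x"), c("b", "y", "z")))
#' @export
similarity_mean <- function(target, others) {
  if (length(others) < 1) stop("need at least one other feature set", call. = FALSE)
  mean(vapply(others, function(s) length(intersect(target, s)), numeric(1)))
}

#' Draw repeated training subsamples, keeping pairs together
#'
#' Draws `k` independent subsamples of the dataset, each a uniform
#' without-replacement draw of `ceiling(fraction * n)` samples. When the
#' dataset is paired, whole pairs are drawn (`ceiling(fraction * n_pairs)`
#' of them), so a tumour sample and its matched normal stay together.
#'
#' @param ds an [expression_dataset()].
#' @param k number of subsamples (>= 2).
#' @param fraction fraction of samples (or pairs) per subsample, in (0, 1).
#' @param seed integer seed; the plan is a deterministic function of it.
#' @return An object of class `resample_plan`: list with `subsamples` (list
#'   of `k` integer index vectors into the samples), `fraction`, `seed`,
#'   `paired`.
#' @export
make_resamples <- function(ds, k = 10L, fraction = 0.9, seed = 1L) {
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1)", call. = FALSE)
  n <- length(ds$y)
  paired <- !is.null(ds$pair_ids)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  subsamples <- lapply(seq_len(k), function(i) {
    if (paired) {
      keys <- unique(ds$pair_ids)
      take <- sample(keys, ceiling(fraction * length(keys)))
      idx <- which(ds$pair_ids %in% take)
    } else {
      idx <- sort(sample(n, ceiling(fraction * n)))
    }
    if (sum(ds$y[idx] > 0) < 2 || sum(ds$y[idx] < 0) < 2) {
      stop("subsample has fewer than two samples in a class; increase `fraction`",
           call. = FALSE)
    }
    idx
  })
  structure(list(subsamples = subsamples, k = k, fraction = fraction,
                 seed = as.integer(seed), paired = paired),
            class = "resample_plan")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Stratified cross-validation folds that keep pairs together
#'
#' @param y labels in `{-1, +1}`.
#' @param folds number of folds.
#' @param pair_ids optional pair keys; both members of a pair land in the
#'   same fold.
#' @param seed integer seed.
#' @return Integer vector of fold assignments, one per sample.
#' @export
make_folds <- function(y, folds = 10L, pair_ids = NULL, seed = 1L) {
  n <- length(y)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fold <- integer(n)
  if (!is.null(pair_ids)) {
    keys <- unique(pair_ids)
    if (folds > length(keys)) stop("more folds than pairs", call. = FALSE)
    assign_keys <- rep(seq_len(folds), length.out = length(keys))[sample(length(keys))]
    fold <- assign_keys[match(pair_ids, keys)]
  } else {
    for (cls in c(-1, 1)) {
      idx <- which(y == cls)
      if (folds > length(idx)) stop("a fold would miss a class", call. = FALSE)
      fold[idx] <- rep(seq_len(folds), length.out = length(idx))[sample(length(idx))]
    }
  }
  fold
}

#' Cross-validated accuracy of a feature subset
#'
#' Trains a classifier on the given features and measures stratified,
#' pair-respecting `folds`-fold cross-validation accuracy. The classifier is
#' either the MKL predictor over the default kernel bank (`"mkl"`) or a
#' plain linear-kernel SVM (`"linear"`, faster).
#'
#' @param ds an [expression_dataset()].
#' @param features character vector of feature identifiers to train on.
#' @param folds number of CV folds (default 10).
#' @param settings a [solver_settings()].
#' @param classifier `"mkl"` or `"linear"`.
#' @param seed seed for the fold assignment.
#' @return The mean accuracy over folds.
#' @export
cv_accuracy <- function(ds, features, folds = 10L,
                        settings = solver_settings(),
                        classifier = c("mkl", "linear"), seed = 1L) {
  classifier <- match.arg(classifier)
  bank <- if (classifier == "mkl") default_kernel_bank() else list(kernel_spec("linear"))
  sub <- subset_dataset(ds, features = features)
  fold <- make_folds(sub$y, folds, sub$pair_ids, seed)
  accs <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    te <- !tr
    pred <- mkl_train_predict(sub$X[, tr, drop = FALSE],
                              sub$X[, te, drop = FALSE],
                              sub$y[tr], bank = bank, settings = settings)
    mean(pred == sub$y[te])
  }, numeric(1))
  mean(accs)
}

#' Mean and max effectiveness of a nested feature chain
#'
#' For a nested chain `S_1 < S_2 < ... < S_n` of selected feature sets, the
#' per-k effectiveness is the cross-validated accuracy of a classifier
#' trained on `S_k`; mean effectiveness averages over `k` and max
#' effectiveness takes the best `k`.
#'
#' @param ds an [expression_dataset()].
#' @param chain list of nested feature-identifier vectors (e.g. the
#'   stage-two trace prefixes, or top-k prefixes of a ranking).
#' @inheritParams cv_accuracy
#' @return A tibble of class `smkl_effectiveness` with columns `k`,
#'   `n_features`, `accuracy`; `mean_effectiveness` and `max_effectiveness`
#'   are attached as attributes and reported by [glance.smkl_effectiveness()].
#' @export
effectiveness <- function(ds, chain, folds = 10L,
                          settings = solver_settings(),
                          classifier = c("mkl", "linear"), seed = 1L) {
  classifier <- match.arg(classifier)
  if (length(chain) < 1) stop("`chain` must be nonempty", call. = FALSE)
  sizes <- lengths(chain)
  if (any(diff(sizes) <= 0) ||
      !all(vapply(seq_along(chain)[-1],
                  function(i) all(chain[[i - 1]] %in% chain[[i]]), logical(1)))) {
    stop("`chain` must be strictly nested", call. = FALSE)
  }
  acc <- vapply(chain, function(S) {
    cv_accuracy(ds, S, folds, settings, classifier, seed)
  }, numeric(1))
  out <- tibble::tibble(k = seq_along(chain), n_features = sizes, accuracy = acc)
  attr(out, "mean_effectiveness") <- mean(acc)
  attr(out, "max_effectiveness") <- max(acc)
  class(out) <- c("smkl_effectiveness", class(out))
  out
}

#' @rdname effectiveness
#' @param x an `smkl_effectiveness` tibble.
#' @param ... unused.
#' @export
glance.smkl_effectiveness <- function(x, ...) {
  tibble::tibble(mean_effectiveness = attr(x, "mean_effectiveness"),
                 max_effectiveness = attr(x, "max_effectiveness"),
                 n_sets = nrow(x))
}

#' Build the nested chain of top-k prefixes from an ordered feature vector
#'
#' @param ordered_features character vector in selection order.
#' @param n chain length (default: all prefixes).
#' @return List of nested prefix sets `S_1 < ... < S_n`.
#' @export
prefix_chain <- function(ordered_features, n = length(ordered_features)) {
  n <- min(n, length(ordered_features))
  lapply(seq_len(n), function(k) ordered_features[seq_len(k)])
}

#' Stability of the selector under resampling
#'
#' Runs stage-one selection on each subsample of a [make_resamples()] plan,
#' collects the top-`n_features` sets, and reports both stability measures.
#'
#' @param ds an [expression_dataset()].
#' @param plan a `resample_plan`.
#' @param n_features size of the selected list per subsample (default 100).
#' @param bank,settings,standardize,normalize passed to [score_features()].
#' @return A list of class `smkl_stability` with `sets`, `union_stability`,
#'   `independent_stability`, and the `plan`.
#' @export
selection_stability <- function(ds, plan, n_features = 100L,
                                bank = default_kernel_bank(),
                                settings = solver_settings(),
                                standardize = TRUE, normalize = TRUE) {
  sets <- lapply(plan$subsamples, function(idx) {
    sub <- subset_dataset(ds, samples = idx)
    scores <- score_features(sub, bank, settings, standardize, normalize)
    select_relevant(scores, n_features)
  })
  structure(list(sets = sets,
                 union_stability = union_stability(sets),
                 independent_stability = independent_stability(sets),
                 n_features = n_features,
                 plan = plan),
            class = "smkl_stability")
}

#' @export
print.smkl_stability <- function(x, ...) {
  cat(sprintf("<smkl_stability over %d resamples of size fraction %.2f>\n",
              x$plan$k, x$plan$fraction))
  cat(sprintf("  union stability:       %.4f\n", x$union_stability))
  cat(sprintf("  independent stability: %.4f\n", x$independent_stability))
  invisible(x)
}
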