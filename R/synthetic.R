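#' Specification of a synthetic expression dataset with planted structure
#'
#' The generator emulates the feature taxonomy of two-class expression
#' studies: a small set of class-informative features with an additive mean
#' shift, correlated redundant copies of them, and many irrelevant noise
#' features, measured on paired tumour/normal samples.
#'
#' @param n_pairs number of sample pairs (one +1 and one -1 sample each).
#' @param p total number of features.
#' @param k_informative number of informative features (class means
#'   `+effect/2` and `-effect/2` in standardized units).
#' @param k_redundant number of redundant features, each correlated with an
#'   informative parent at `redundancy_rho`.
#' @param effect standardized between-class mean shift on informative
#'   features.
#' @param redundancy_rho correlation of a redundant copy with its parent.
#' @param noise_sd within-class standard deviation of every feature.
#' @param missing_rate fraction of cells masked missing at random in `[0, 1)`.
#' @param pair_sd standard deviation of a per-pair random intercept shared
#'   by both samples of a pair (0 disables it).
#' @param log_scale exponentiate the values to mimic the positivity of raw
#'   expression measurements.
#' @param seed integer seed; the dataset is a deterministic function of the
#'   spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pairs = 30L, p = 200L, k_informative = 10L,
                           k_redundant = 10L, effect = 2, redundancy_rho = 0.9,
                           noise_sd = 1, missing_rate = 0, pair_sd = 0,
                           log_scale = FALSE, seed = 1L) {
  stopifnot(n_pairs >= 1, p >= 1, k_informative >= 0, k_redundant >= 0,
            k_informative + k_redundant <= p, effect >= 0,
            redundancy_rho >= 0, redundancy_rho <= 1,
            noise_sd > 0, missing_rate >= 0, missing_rate < 1, pair_sd >= 0)
  if (k_redundant > 0 && k_informative == 0) {
    stop("redundant features need at least one informative parent", call. = FALSE)
  }
  structure(list(n_pairs = as.integer(n_pairs), p = as.integer(p),
                 k_informative = as.integer(k_informative),
                 k_redundant = as.integer(k_redundant),
                 effect = effect, redundancy_rho = redundancy_rho,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 pair_sd = pair_sd, log_scale = log_scale,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset
#'
#' @param spec a [synthetic_spec()].
#' @return An [expression_dataset()] of `spec$p` features by
#'   `2 * spec$n_pairs` samples. The tibble in attribute `"roles"` records
#'   each feature's planted role (`informative`, `redundant`, `irrelevant`)
#'   and, for redundant features, the parent feature.
#' @examples
#' ds <- simulate_expression(synthetic_spec(n_pairs = 5, p = 20, seed = 3))
#' table(attr(ds, "roles")$role)
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- 2L * spec$n_pairs
  p <- spec$p
  ki <- spec$k_informative
  kr <- spec$k_redundant
  y <- rep(c(1, -1), spec$n_pairs)
  pair_ids <- rep(sprintf("pair%03d", seq_len(spec$n_pairs)), each = 2L)
  feature_ids <- sprintf("f%04d", seq_len(p))
  X <- matrix(stats::rnorm(p * n, sd = spec$noise_sd), p, n)
  role <- rep("irrelevant", p)
  parent <- rep(NA_character_, p)
  if (ki > 0) {
    shift <- spec$effect * spec$noise_sd / 2
    X[seq_len(ki), ] <- X[seq_len(ki), ] +
      matrix(rep(y * shift, each = ki), ki, n)
    role[seq_len(ki)] <- "informative"
  }
  if (kr > 0) {
    rho <- spec$redundancy_rho
    parents <- rep(seq_len(ki), length.out = kr)
    idx <- ki + seq_len(kr)
    # the parent is standardized to unit population variance (noise plus the
    # +/- effect/2 class shift) before mixing, so the redundant copy has
    # population correlation exactly rho with its parent
    parent_sd <- spec$noise_sd * sqrt(1 + (spec$effect / 2)^2)
    X[idx, ] <- spec$noise_sd *
      (rho * X[parents, , drop = FALSE] / parent_sd +
       sqrt(1 - rho^2) * matrix(stats::rnorm(kr * n), kr, n))
    role[idx] <- "redundant"
    parent[idx] <- feature_ids[parents]
  }
  if (spec$pair_sd > 0) {
    intercepts <- stats::rnorm(spec$n_pairs, sd = spec$pair_sd)
    X <- X + matrix(rep(rep(intercepts, each = 2L), each = p), p, n)
  }
  if (spec$log_scale) X <- exp(X)
  if (spec$missing_rate > 0) {
    mask <- stats::runif(p * n) < spec$missing_rate
    X[matrix(mask, p, n)] <- NA_real_
  }
  sample_ids <- paste0(pair_ids, ifelse(y > 0, "_t", "_n"))
  ds <- expression_dataset(X, y, feature_ids = feature_ids,
                           sample_ids = sample_ids, pair_ids = pair_ids)
  attr(ds, "roles") <- tibble::tibble(feature_id = feature_ids,
                                      role = role, parent = parent)
  attr(ds, "spec") <- spec
  ds
}

#' Generate a small probe-level fixture with known structure
#'
#' A 12-probe, 8-feature, 6-sample probe matrix with 3 masked cells,
#' multi-probe features, and an exactly linearly dependent probe pair, built
#' for exercising the preprocessing chain. Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param missing include the 3 masked cells (default `TRUE`).
#' @return A [probe_matrix()].
#' @export
simulate_probe_matrix <- function(seed = 1L, missing = TRUE) {
  set.seed(seed)
  n_probes <- 12L
  n_samples <- 6L
  V <- matrix(round(stats::rnorm(n_probes * n_samples, mean = 8, sd = 2), 3),
              n_probes, n_samples)
  V[2, ] <- 2 * V[1, ]                    # exact linear dependence
  V[11, ] <- 7.5                          # constant probe
  map <- c("gA", "gA", "gB", "gB", "gB", "gC", "gD", "gE", "gF", "gG", "gH", "gH")
  if (missing) {
    V[2, 3] <- NA
    V[6, 1] <- NA
    V[11, 5] <- NA
  }
  probe_matrix(V, map,
               probe_ids = sprintf("p%02d", seq_len(n_probes)),
               sample_ids = sprintf("s%d", seq_len(n_samples)))
}
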