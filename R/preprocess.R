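#' Construct a probe-level matrix with an explicit missing mask
#'
#' Probe-level expression as measured on an array: several probes may map to
#' one feature (gene or miRNA). Missing entries are encoded as `NA`.
#'
#' @param values numeric probe-by-sample matrix (`NA` = missing).
#' @param probe_ids unique probe identifiers (default rownames).
#' @param probe_to_feature character vector mapping each probe to exactly one
#'   feature identifier.
#' @param sample_ids unique sample identifiers (default colnames).
#' @return An object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, probe_to_feature, probe_ids = rownames(values),
                         sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(probe_ids)) probe_ids <- paste0("p", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(probe_ids)) stop("duplicate probe identifiers", call. = FALSE)
  if (length(probe_to_feature) != nrow(values)) {
    stop("need exactly one feature per probe", call. = FALSE)
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values, probe_ids = probe_ids,
                 probe_to_feature = stats::setNames(as.character(probe_to_feature), probe_ids),
                 sample_ids = sample_ids),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("<probe_matrix: %d probes -> %d features x %d samples, %d missing cells>\n",
              nrow(x$values), length(unique(x$probe_to_feature)),
              ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Missingness and imputation policy
#'
#' @param max_missing_fraction probes with a missing fraction at or above
#'   this threshold are dropped (strict reading of "less than 20 percent":
#'   `fraction < 0.20` is kept). Default 0.20.
#' @param neighbor_count number of most-correlated complete probes used by
#'   local least squares imputation. Default 10.
#' @return A `missing_policy` list.
#' @export
missing_policy <- function(max_missing_fraction = 0.20, neighbor_count = 10L) {
  stopifnot(max_missing_fraction > 0, max_missing_fraction < 1, neighbor_count >= 1)
  structure(list(max_missing_fraction = max_missing_fraction,
                 neighbor_count = as.integer(neighbor_count)),
            class = "missing_policy")
}

#' Drop probes with too many missing values
#'
#' Probes whose missing fraction is greater than or equal to
#' `max_missing_fraction` are removed; the rest are retained for imputation.
#'
#' @param pm a [probe_matrix()].
#' @param policy a [missing_policy()].
#' @return The filtered [probe_matrix()].
#' @export
filter_missing <- function(pm, policy = missing_policy()) {
  frac <- rowMeans(is.na(pm$values))
  keep <- frac < policy$max_missing_fraction
  if (!any(keep)) stop("all probes exceed the missingness threshold", call. = FALSE)
  probe_matrix(pm$values[keep, , drop = FALSE],
               pm$probe_to_feature[keep],
               probe_ids = pm$probe_ids[keep],
               sample_ids = pm$sample_ids)
}

#' Local least squares imputation of missing probe values
#'
#' Each missing entry is predicted by regressing the target probe on its
#' `neighbor_count` most-correlated complete probes (absolute Pearson
#' correlation over the target's observed samples), by least squares, and
#' evaluating the fit at the missing sample. Constant targets are filled
#' with their constant. If fewer complete probes exist than
#' `neighbor_count`, the affected probes fall back to a row-median fill with
#' a warning.
#'
#' @param pm a [probe_matrix()] whose probes all pass [filter_missing()].
#' @param policy a [missing_policy()].
#' @return The completed [probe_matrix()] (no `NA` left).
#' @export
impute_lls <- function(pm, policy = missing_policy()) {
  V <- pm$values
  has_na <- which(rowSums(is.na(V)) > 0)
  if (length(has_na) == 0) return(pm)
  complete <- which(rowSums(is.na(V)) == 0)
  for (i in has_na) {
    obs <- !is.na(V[i, ])
    target <- V[i, obs]
    if (length(unique(target)) == 1L) {          # constant probe
      V[i, !obs] <- target[1]
      next
    }
    if (length(complete) < policy$neighbor_count) {
      warning("fewer complete probes than neighbor_count; row-median fill for probe ",
              pm$probe_ids[i], call. = FALSE)
      V[i, !obs] <- stats::median(target)
      next
    }
    cors <- abs(apply(V[complete, obs, drop = FALSE], 1, function(r) {
      if (stats::sd(r) == 0) 0 else stats::cor(r, target)
    }))
    nb <- complete[order(-cors)[seq_len(policy$neighbor_count)]]
    A <- t(V[nb, obs, drop = FALSE])             # observed samples x neighbors
    fit <- stats::lm.fit(cbind(1, A), target)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    V[i, !obs] <- as.numeric(cbind(1, t(V[nb, !obs, drop = FALSE])) %*% co)
  }
  probe_matrix(V, pm$probe_to_feature, probe_ids = pm$probe_ids,
               sample_ids = pm$sample_ids)
}

#' Merge probes of the same feature by their per-sample maximum
#'
#' @param pm a completed [probe_matrix()] (no missing entries).
#' @return A feature-by-sample numeric matrix; features appear in order of
#'   first occurrence in the probe map.
#' @export
merge_probes <- function(pm) {
  if (anyNA(pm$values)) stop("impute missing values before merging", call. = FALSE)
  feats <- unique(pm$probe_to_feature)
  out <- matrix(NA_real_, length(feats), ncol(pm$values),
                dimnames = list(feats, pm$sample_ids))
  for (f in feats) {
    rows <- which(pm$probe_to_feature == f)
    out[f, ] <- apply(pm$values[rows, , drop = FALSE], 2, max)
  }
  out
}

#' Per-sample median absolute deviation normalization
#'
#' For every sample (column): subtract the column median and divide by the
#' raw median absolute deviation (no Gaussian consistency constant), giving
#' all samples a comparable background. A per-feature mode is available.
#'
#' @param X numeric matrix without missing values (features x samples).
#' @param margin `"sample"` (columns, the default) or `"feature"` (rows).
#' @return The normalized matrix.
#' @examples
#' mad_normalize(cbind(c(1, 2, 3, 4, 100)))
#' @export
mad_normalize <- function(X, margin = c("sample", "feature")) {
  margin <- match.arg(margin)
  if (anyNA(X)) stop("missing values present; impute before normalization", call. = FALSE)
  if (margin == "feature") return(t(mad_normalize(t(X), "sample")))
  med <- apply(X, 2, stats::median)
  ctr <- sweep(X, 2, med)
  md <- apply(abs(ctr), 2, stats::median)
  if (any(md == 0)) {
    bad <- colnames(X)[md == 0] %||% as.character(which(md == 0))
    stop("zero median absolute deviation in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(ctr, 2, md, "/")
}

#' Run the full preprocessing chain
#'
#' Filter probes by missingness, impute the remainder by local least
#' squares, merge probes of a feature by their per-sample maximum, and
#' normalize every sample by its median absolute deviation — in that fixed
#' order.
#'
#' @param pm a [probe_matrix()].
#' @param policy a [missing_policy()].
#' @param normalize_margin passed to [mad_normalize()].
#' @return A feature-by-sample matrix ready for [expression_dataset()].
#' @export
preprocess_expression <- function(pm, policy = missing_policy(),
                                  normalize_margin = "sample") {
  pm <- filter_missing(pm, policy)
  pm <- impute_lls(pm, policy)
  X <- merge_probes(pm)
  mad_normalize(X, normalize_margin)
}
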