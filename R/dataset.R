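#' Construct a labeled expression dataset
#'
#' The central container: a feature-by-sample numeric matrix with class
#' labels in `{+1, -1}` (by convention tumour = +1, adjacent normal = -1)
#' and optional pair keys tying a tumour sample to its matched normal.
#'
#' @param X numeric feature-by-sample matrix.
#' @param y labels, one per sample, coercible to `{+1, -1}` (the strings
#'   `"tumor"`/`"tumour"` and `"normal"` are also accepted).
#' @param feature_ids unique feature identifiers (default: rownames of `X`).
#' @param sample_ids unique sample identifiers (default: colnames of `X`).
#' @param pair_ids optional per-sample pair keys; each key must appear
#'   exactly twice, once per class.
#'
#' @return An object of class `expression_dataset` with elements `X`, `y`,
#'   `feature_ids`, `sample_ids`, `pair_ids`.
#' @examples
#' X <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' expression_dataset(X, c(1, -1, 1, -1, 1))
#' @export
expression_dataset <- function(X, y, feature_ids = rownames(X),
                               sample_ids = colnames(X), pair_ids = NULL) {
  X <- as.matrix(X)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(X)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(X)))
  if (anyDuplicated(feature_ids)) stop("duplicate feature identifiers", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers", call. = FALSE)
  if (length(feature_ids) != nrow(X)) stop("feature_ids do not match rows of X", call. = FALSE)
  if (length(sample_ids) != ncol(X)) stop("sample_ids do not match columns of X", call. = FALSE)
  y <- coerce_labels(y)
  if (length(y) != ncol(X)) stop("need one label per sample", call. = FALSE)
  if (!is.null(pair_ids)) {
    if (length(pair_ids) != ncol(X)) stop("need one pair key per sample", call. = FALSE)
    tab <- table(pair_ids)
    if (any(tab != 2L)) {
      stop("each pair key must appear exactly twice; offending: ",
           paste(names(tab)[tab != 2L], collapse = ", "), call. = FALSE)
    }
    sums <- tapply(y, pair_ids, sum)
    if (any(sums != 0)) {
      stop("each pair must hold one sample of each class; offending: ",
           paste(names(sums)[sums != 0], collapse = ", "), call. = FALSE)
    }
  }
  dimnames(X) <- list(feature_ids, sample_ids)
  structure(list(X = X, y = y, feature_ids = feature_ids,
                 sample_ids = sample_ids, pair_ids = pair_ids),
            class = "expression_dataset")
}

coerce_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    low <- tolower(y)
    out <- ifelse(low %in% c("tumor", "tumour", "1", "+1", "case"), 1,
                  ifelse(low %in% c("normal", "-1", "control"), -1, NA))
    if (anyNA(out)) {
      stop("unrecognized labels: ", paste(unique(y[is.na(out)]), collapse = ", "),
           call. = FALSE)
    }
    return(as.numeric(out))
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1 (or tumor/normal)", call. = FALSE)
  y
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset: %d features x %d samples (%d positive, %d negative%s)>\n",
              nrow(x$X), ncol(x$X), sum(x$y > 0), sum(x$y < 0),
              if (is.null(x$pair_ids)) "" else sprintf(", %d pairs", length(unique(x$pair_ids)))))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$X)

#' Subset an expression dataset by features and/or samples
#'
#' @param ds an [expression_dataset()].
#' @param features feature identifiers (or indices) to keep, in order.
#' @param samples sample indices or identifiers to keep.
#' @return The subsetted [expression_dataset()].
#' @export
subset_dataset <- function(ds, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(ds$X)) else features
  si <- if (is.null(samples)) seq_len(ncol(ds$X)) else samples
  if (is.character(si)) si <- match(si, ds$sample_ids)
  if (is.character(fi)) {
    miss <- setdiff(fi, ds$feature_ids)
    if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "), call. = FALSE)
    fi <- match(fi, ds$feature_ids)
  }
  expression_dataset(ds$X[fi, si, drop = FALSE], ds$y[si],
                     feature_ids = ds$feature_ids[fi],
                     sample_ids = ds$sample_ids[si],
                     pair_ids = if (is.null(ds$pair_ids)) NULL else {
                       pid <- ds$pair_ids[si]
                       if (all(table(pid) == 2L)) pid else NULL
                     })
}

#' Read an expression matrix and its labels from delimited text
#'
#' Expects features as rows: the first column holds feature identifiers, the
#' header row holds sample identifiers. The labels file is two-column
#' delimited text (`sample_id`, label) with labels in `{tumor, normal}` or
#' `{+1, -1}`. Tumour maps to +1.
#'
#' @param path path to the expression matrix.
#' @param labels_path path to the label table.
#' @param sep field separator (default tab).
#' @param orientation `"features"` if features are rows (default),
#'   `"samples"` if the matrix is transposed.
#' @param pairs_path optional two-column table (`sample_id`, `pair_id`).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, labels_path, sep = "\t",
                            orientation = c("features", "samples"),
                            pairs_path = NULL) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           row.names = 1, colClasses = "character")
  X <- as.matrix(raw)
  suppressWarnings(storage.mode(X) <- "double")
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 rownames(X)[idx[1]], colnames(X)[idx[2]], path), call. = FALSE)
  }
  if (orientation == "samples") X <- t(X)
  lab <- utils::read.table(labels_path, header = FALSE, sep = sep,
                           colClasses = "character")
  if (ncol(lab) < 2) stop("labels file needs two columns: sample_id, label", call. = FALSE)
  missing_samples <- setdiff(colnames(X), lab[[1]])
  if (length(missing_samples)) {
    stop("labels file is missing samples: ", paste(missing_samples, collapse = ", "),
         call. = FALSE)
  }
  y <- coerce_labels(lab[[2]][match(colnames(X), lab[[1]])])
  pair_ids <- NULL
  if (!is.null(pairs_path)) {
    pr <- utils::read.table(pairs_path, header = FALSE, sep = sep,
                            colClasses = "character")
    pair_ids <- pr[[2]][match(colnames(X), pr[[1]])]
  }
  expression_dataset(X, y, pair_ids = pair_ids)
}

#' Write an expression dataset to delimited text
#'
#' Writes the matrix (features as rows, `feature_id` as first column), the
#' label table, and, when pairs are present, the pair table.
#'
#' @param ds an [expression_dataset()].
#' @param path output path for the matrix.
#' @param labels_path optional output path for the label table.
#' @param pairs_path optional output path for the pair table.
#' @param sep field separator.
#' @param digits significant digits to print.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path, labels_path = NULL, pairs_path = NULL,
                             sep = "\t", digits = 10) {
  df <- data.frame(feature_id = ds$feature_ids,
                   signif(ds$X, digits), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(data.frame(ds$sample_ids, ifelse(ds$y > 0, "tumor", "normal")),
                       labels_path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(pairs_path) && !is.null(ds$pair_ids)) {
    utils::write.table(data.frame(ds$sample_ids, ds$pair_ids),
                       pairs_path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a plain-text feature list (one identifier per line)
#'
#' Used to feed externally produced rankings into the similarity metric.
#'
#' @param path file with one feature identifier per line.
#' @param n optional truncation to the first `n` entries.
#' @return Character vector of feature identifiers.
#' @export
read_feature_list <- function(path, n = NULL) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (!is.null(n)) x <- utils::head(x, n)
  x
}

#' Standardize features to mean zero and unit variance
#'
#' Per-feature z-scoring with statistics fit on the given (training) samples.
#' Zero-variance features are left centered at zero rather than divided by
#' zero.
#'
#' @param X feature-by-sample matrix.
#' @param center,scale optional precomputed per-feature statistics (used to
#'   apply training statistics to held-out samples).
#' @return A list with the standardized matrix `X` and the `center` and
#'   `scale` vectors used.
#' @export
zscore_features <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- rowMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 1, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  list(X = (X - center) / scale, center = center, scale = scale)
}
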