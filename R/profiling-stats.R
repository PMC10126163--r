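#' Z-score the feature columns of a feature table
#'
#' Per-feature standardisation over all cells, as used before profile
#' heatmaps and linear classifiers. Rows containing non-finite feature
#' values are dropped, and zero-variance features are removed (both with a
#' warning naming what was dropped).
#'
#' @param data A data frame of cells by features.
#' @param feature_cols Tidy-select of feature columns; defaults to every
#'   numeric column except `cell_id`, `label`, `source`.
#' @return A tibble with the selected columns standardised (mean 0, SD 1).
#' @export
zscore_features <- function(data, feature_cols = NULL) {
  data <- tibble::as_tibble(data)
  cols <- resolve_feature_cols(data, rlang::enquo(feature_cols))
  vals <- as.matrix(data[cols])
  ok <- complete.cases(vals) & apply(is.finite(vals), 1, all)
  if (!all(ok)) {
    warn(paste0("dropped ", sum(!ok), " row(s) with non-finite feature values"))
    data <- data[ok, , drop = FALSE]
    vals <- vals[ok, , drop = FALSE]
  }
  sds <- apply(vals, 2, sd)
  dead <- cols[is.na(sds) | sds == 0]
  if (length(dead)) {
    warn(paste0("dropped zero-variance feature(s): ",
                paste(dead, collapse = ", ")))
    data <- data[setdiff(names(data), dead)]
    cols <- setdiff(cols, dead)
  }
  dplyr::mutate(data, dplyr::across(dplyr::all_of(cols),
                                    ~ (.x - mean(.x)) / sd(.x)))
}

resolve_feature_cols <- function(data, quo) {
  if (rlang::quo_is_null(quo)) {
    num <- vapply(data, is.numeric, logical(1))
    setdiff(names(data)[num], c("cell_id", "label", "source"))
  } else {
    names(tidyselect::eval_select(quo, data))
  }
}

#' Cliff's delta effect size
#'
#' The nonparametric, sample-size-independent effect size
#' d = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y), ties contributing
#' zero. Computed by midranks in O((n_x + n_y) log n), identical to pair
#' enumeration. Related to the rank AUROC by d = 2 * AUROC - 1.
#'
#' @param x,y Nonempty numeric sample vectors.
#' @return A scalar in \[-1, 1\]; positive when `x` tends to exceed `y`.
#' @export
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y)) {
    abort("both samples must be nonempty", class = "fractometry_parameter_error")
  }
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  auc <- (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
  2 * auc - 1
}

#' ROC curve and AUROC of a score against binary labels
#'
#' Rank-based (Mann-Whitney) AUROC with ties counted one half, plus the
#' ROC curve from a full threshold sweep (tied scores collapsed onto one
#' curve vertex, so the trapezoidal area equals the rank statistic).
#'
#' @param scores Numeric score vector.
#' @param labels Logical (or coercible) vector: TRUE = positive class.
#' @return A list of class `roc_result` with `thresholds`, `tpr`, `fpr`
#'   (nondecreasing from 0 to 1) and `auroc`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(labels) || !any(labels) || all(labels)) {
    abort("both classes must be present", class = "fractometry_parameter_error")
  }
  np <- sum(labels); nn <- sum(!labels)
  r <- rank(scores)
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  structure(list(
    thresholds = c(Inf, s[last]),
    tpr = c(0, tp[last] / np),
    fpr = c(0, fp[last] / nn),
    auroc = auc
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUROC = ", signif(x$auroc, 4), " (",
      length(x$thresholds) - 1, " thresholds)\n", sep = "")
  invisible(x)
}

#' Linear regression one-versus-all classifier
#'
#' Least-squares fit of a +/-1 class indicator on the (z-scored) features,
#' with an intercept and the minimum-norm solution for rank-deficient
#' designs — so duplicated features change nothing. Scores are the fitted
#' values; discrimination is summarised by the one-versus-all ROC.
#'
#' @param data A data frame of cells by features with a label column.
#' @param positive The class treated as +1.
#' @param label_col Name of the label column (default `"label"`).
#' @param feature_cols Tidy-select of feature columns; default as in
#'   [zscore_features()].
#' @return A list of class `ova_classifier` with `weights` (named, incl.
#'   `(Intercept)`), `scores`, `labels`, `positive`, `roc`.
#' @export
linear_ova_classifier <- function(data, positive, label_col = "label",
                                  feature_cols = NULL) {
  data <- tibble::as_tibble(data)
  labels <- data[[label_col]]
  if (length(unique(labels)) < 2) {
    abort("need at least two classes", class = "fractometry_parameter_error")
  }
  if (!positive %in% labels) {
    abort("`positive` is not a label level", class = "fractometry_parameter_error")
  }
  if (sum(labels == positive) < 2 || sum(labels != positive) < 2) {
    abort("need at least 2 cells per class", class = "fractometry_parameter_error")
  }
  cols <- resolve_feature_cols(data, rlang::enquo(feature_cols))
  x <- cbind(`(Intercept)` = 1, as.matrix(data[cols]))
  y <- ifelse(labels == positive, 1, -1)
  w <- MASS::ginv(x) %*% y
  scores <- as.numeric(x %*% w)
  structure(list(
    weights = setNames(as.numeric(w), colnames(x)),
    scores = scores, labels = labels, positive = positive,
    roc = auroc(scores, labels == positive)
  ), class = "ova_classifier")
}

#' @export
print.ova_classifier <- function(x, ...) {
  cat("<ova_classifier> '", x$positive, "' vs rest, training AUROC = ",
      signif(x$roc$auroc, 4), ", ", length(x$weights) - 1, " features\n",
      sep = "")
  invisible(x)
}

#' Spearman correlation matrix of a feature table
#'
#' Rank correlation (average ranks for ties) between all feature pairs.
#'
#' @inheritParams zscore_features
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(data, feature_cols = NULL) {
  data <- tibble::as_tibble(data)
  cols <- resolve_feature_cols(data, rlang::enquo(feature_cols))
  if (nrow(data) < 3) {
    abort("need at least 3 cells", class = "fractometry_insufficient_data_error")
  }
  cor(as.matrix(data[cols]), method = "spearman")
}

#' Strongly correlated feature pairs
#'
#' The edge list behind circular correlation plots: all feature pairs with
#' |rho| above the threshold.
#'
#' @param mat A correlation matrix (e.g. from [spearman_matrix()]).
#' @param threshold Absolute-correlation cutoff (default 0.6).
#' @return A tibble with `feature_a`, `feature_b`, `rho`, ordered by
#'   decreasing |rho|.
#' @export
correlation_edges <- function(mat, threshold = 0.6) {
  idx <- which(upper.tri(mat) & abs(mat) > threshold, arr.ind = TRUE)
  out <- tibble::tibble(
    feature_a = rownames(mat)[idx[, 1]],
    feature_b = colnames(mat)[idx[, 2]],
    rho = mat[idx]
  )
  dplyr::arrange(out, dplyr::desc(abs(rho)))
}

#' Rank features by mean one-versus-all AUROC
#'
#' Screens each feature as a raw score for every class-versus-rest
#' problem, orienting the AUROC as max(a, 1 - a), and ranks features by
#' the mean over classes (descending; ties keep the input feature order).
#'
#' @inheritParams linear_ova_classifier
#' @return A tibble with `feature`, one `auroc_<class>` column per class,
#'   and `mean_auroc`, sorted by decreasing `mean_auroc`.
#' @export
rank_features <- function(data, label_col = "label", feature_cols = NULL) {
  data <- tibble::as_tibble(data)
  labels <- data[[label_col]]
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    abort("need at least two classes", class = "fractometry_parameter_error")
  }
  cols <- resolve_feature_cols(data, rlang::enquo(feature_cols))
  per_class <- vapply(classes, function(cl) {
    vapply(cols, function(f) {
      a <- auroc(data[[f]], labels == cl)$auroc
      max(a, 1 - a)
    }, numeric(1))
  }, numeric(length(cols)))
  per_class <- matrix(per_class, nrow = length(cols),
                      dimnames = list(cols, paste0("auroc_", classes)))
  out <- tibble::as_tibble(per_class)
  out$feature <- cols
  out$mean_auroc <- unname(rowMeans(per_class))
  out <- out[c("feature", colnames(per_class), "mean_auroc")]
  out[order(-out$mean_auroc), ]
}
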