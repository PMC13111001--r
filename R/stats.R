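# Confusion-matrix metrics (one-vs-rest, macro-averaged), rank-statistic
# AUC, per-fold aggregation, and the Friedman / Nemenyi / critical-
# difference model-comparison harness.

#' Confusion matrix from labels
#'
#' @param y_true,y_pred integer class labels in `[0, n_classes)`.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(y_true, y_pred, n_classes = 3L) {
  if (length(y_true) != length(y_pred))
    hmc_stop("y_true and y_pred differ in length", "hmcnet_input_error")
  if (any(c(y_true, y_pred) < 0) || any(c(y_true, y_pred) >= n_classes))
    hmc_stop("labels out of range", "hmcnet_input_error")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1),
                               pred = 0:(n_classes - 1)))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Classification metrics from a confusion matrix
#'
#' Per class (one-vs-rest): accuracy `(TP+TN)/total`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, and
#' `F1 = 2*precision*sensitivity/(precision+sensitivity)`. Macro values are
#' unweighted means over classes; `overall_accuracy` is the trace over the
#' grand total. Zero-denominator cases return 0 and are flagged in the
#' `zero_denominator` attribute.
#'
#' @param cm confusion matrix from [confusion()].
#' @return list with `per_class` (data frame), `macro` (named vector) and
#'   `overall_accuracy`.
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) hmc_stop("all-zero confusion matrix", "hmcnet_input_error")
  K <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  prec <- safe_div(tp, tp + fp)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  acc <- (tp + tn) / total
  f1 <- safe_div(2 * prec * sens, prec + sens)
  per_class <- data.frame(class = 0:(K - 1), tp = tp, fp = fp, fn = fn,
                          tn = tn, accuracy = acc, sensitivity = sens,
                          specificity = spec, precision = prec, f1 = f1)
  macro <- c(accuracy = mean(acc), sensitivity = mean(sens),
             specificity = mean(spec), precision = mean(prec),
             f1 = mean(f1))
  out <- list(per_class = per_class, macro = macro,
              overall_accuracy = sum(tp) / total)
  attr(out, "zero_denominator") <-
    any((tp + fp) == 0 | (tp + fn) == 0 | (tn + fp) == 0)
  out
}

auc_binary <- function(pos_scores, neg_scores) {
  # Mann-Whitney rank statistic
  r <- rank(c(pos_scores, neg_scores))
  np <- length(pos_scores); nn <- length(neg_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Macro one-vs-rest AUC
#'
#' Per-class area under the ROC curve via the Mann-Whitney rank statistic
#' on the class's probability column, macro-averaged. Classes absent from
#' `y_true` (or covering all of it) are skipped and flagged in the
#' `skipped_classes` attribute.
#'
#' @param y_true integer labels `0..(K-1)`.
#' @param probabilities `n x K` matrix; rows sum to 1.
#' @return AUC in `[0, 1]`.
#' @export
auc_macro <- function(y_true, probabilities) {
  K <- ncol(probabilities)
  aucs <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    pos <- y_true == (k - 1)
    if (!any(pos) || all(pos)) next
    aucs[k] <- auc_binary(probabilities[pos, k], probabilities[!pos, k])
  }
  out <- mean(aucs, na.rm = TRUE)
  attr(out, "skipped_classes") <- which(is.na(aucs)) - 1L
  out
}

#' Aggregate per-fold metrics into mean +- sd
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) per
#' metric column; the `formatted` column rounds to 2 decimals in the
#' `"mean ± sd"` style used in cross-validation reports.
#'
#' @param table data frame of per-fold rows; a `fold` column is ignored,
#'   every other numeric column is a metric.
#' @return data frame with `metric`, `mean`, `sd`, `formatted`.
#' @export
aggregate_folds <- function(table) {
  cols <- setdiff(names(table), "fold")
  if (nrow(table) < 2)
    hmc_stop("need at least 2 folds to aggregate", "hmcnet_input_error")
  if (anyNA(table[cols]))
    hmc_stop("missing fold values", "hmcnet_input_error")
  mu <- vapply(table[cols], mean, 0)
  sd_ <- vapply(table[cols], stats::sd, 0)
  data.frame(metric = cols, mean = mu, sd = sd_,
             formatted = sprintf("%.2f ± %.2f", round(mu, 2),
                                 round(sd_, 2)),
             row.names = NULL)
}

rank_matrix <- function(scores) {
  # per-fold ranks, rank 1 = best (highest score); ties -> average ranks
  t(apply(scores, 1, function(row) rank(-row)))
}

#' Friedman rank test over folds
#'
#' Ranks the `k` models within each of the `N` folds (rank 1 = best; ties
#' average) and computes
#' `chi2_F = 12 N / (k (k+1)) * sum_j Rbar_j^2 - 3 N (k+1)` with the
#' p-value from the chi-squared distribution on `k - 1` degrees of freedom.
#'
#' @param scores `N x k` matrix: rows = folds, columns = models.
#' @param p_method `"chisq"` for the chi-squared approximation (default;
#'   matches the usual reporting style) or `"permutation"` for a Monte
#'   Carlo permutation p-value (within-fold rank permutations), preferable
#'   when `N * k` is small.
#' @param n_perm number of Monte Carlo permutations.
#' @param perm_seed seed for the permutation draw.
#' @return list with `statistic`, `p_value`, `avg_ranks`, `N`, `k`.
#' @export
friedman_rank <- function(scores, p_method = c("chisq", "permutation"),
                          n_perm = 5000L, perm_seed = 1L) {
  p_method <- match.arg(p_method)
  check_finite(scores, "score matrix")
  N <- nrow(scores); k <- ncol(scores)
  if (N < 2 || k < 2)
    hmc_stop("need at least 2 folds and 2 models", "hmcnet_input_error")
  R <- rank_matrix(scores)
  Rbar <- colMeans(R)
  stat_from_ranks <- function(R)
    12 * N / (k * (k + 1)) * sum(colMeans(R)^2) - 3 * N * (k + 1)
  stat <- stat_from_ranks(R)
  p <- if (p_method == "chisq") {
    stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  } else {
    set.seed(perm_seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      Rp <- t(apply(R, 1, sample))
      if (stat_from_ranks(Rp) >= stat - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  }
  list(statistic = stat, p_value = p, avg_ranks = Rbar, N = N, k = k)
}

#' Nemenyi post-hoc pairwise p-values
#'
#' For each model pair, `z = (Rbar_i - Rbar_j) / sqrt(k (k+1) / (6 N))`;
#' the p-value is the upper tail of the studentized-range distribution
#' (`k` groups, infinite degrees of freedom) at `|z| * sqrt(2)`.
#'
#' @inheritParams friedman_rank
#' @return `k x k` symmetric matrix with unit diagonal.
#' @export
nemenyi_pairwise <- function(scores) {
  fr <- friedman_rank(scores)
  k <- fr$k; N <- fr$N
  se <- sqrt(k * (k + 1) / (6 * N))
  P <- matrix(1, k, k)
  nms <- colnames(scores)
  if (!is.null(nms)) dimnames(P) <- list(nms, nms)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    z <- abs(fr$avg_ranks[i] - fr$avg_ranks[j]) / se
    p <- stats::ptukey(z * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
    P[i, j] <- p; P[j, i] <- p
  }
  P
}

#' Nemenyi critical difference
#'
#' `CD = q_alpha * sqrt(k (k+1) / (6 N))`: the minimum average-rank gap at
#' which two of `k` models compared over `N` folds differ significantly.
#' `q_nemenyi_05[["4"]]` holds the standard two-tailed alpha = 0.05 critical
#' value for four models.
#'
#' @param k number of models (>= 2).
#' @param N number of folds (>= 1).
#' @param q_alpha Nemenyi critical value.
#' @return the critical difference (>= 0).
#' @export
critical_difference <- function(k, N, q_alpha) {
  if (k < 2 || N < 1)
    hmc_stop("need k >= 2 models and N >= 1 folds", "hmcnet_input_error")
  if (q_alpha < 0) hmc_stop("q_alpha must be >= 0", "hmcnet_input_error")
  q_alpha * sqrt(k * (k + 1) / (6 * N))
}

#' Standard Nemenyi q values at alpha = 0.05 (infinite df), k = 2..10
#' @format named numeric vector; names are the model counts.
#' @export
q_nemenyi_05 <- stats::setNames(
  stats::qtukey(0.95, nmeans = 2:10, df = Inf) / sqrt(2),
  as.character(2:10))

#' Critical-difference diagram structure
#'
#' Sorts models by average rank (ascending = better) and joins pairs whose
#' rank difference is strictly below `CD` into connectivity groups (a pair
#' at exactly `CD` is *not* connected); unconnected pairs are the
#' significant ones.
#'
#' @param avg_ranks named numeric vector of average ranks.
#' @param CD critical difference from [critical_difference()].
#' @return list with `order` (data frame `model`, `rank`), `groups` (list of
#'   model-name vectors, maximal non-significant cliques) and
#'   `significant_pairs` (data frame `model_i`, `model_j`, `diff`).
#' @export
cd_diagram <- function(avg_ranks, CD) {
  if (is.null(names(avg_ranks)))
    names(avg_ranks) <- paste0("model", seq_along(avg_ranks))
  ord <- sort(avg_ranks)
  k <- length(ord)
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && ord[j + 1] - ord[i] < CD) j <- j + 1
    groups[[length(groups) + 1]] <- names(ord)[i:j]
  }
  keep <- !vapply(seq_along(groups), function(i)
    any(vapply(seq_along(groups), function(j)
      i != j && all(groups[[i]] %in% groups[[j]]), TRUE)), TRUE)
  groups <- groups[keep]
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    dd <- ord[j] - ord[i]
    if (dd >= CD)
      pairs[[length(pairs) + 1]] <- data.frame(
        model_i = names(ord)[i], model_j = names(ord)[j], diff = unname(dd))
  }
  sig <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(model_i = character(0), model_j = character(0),
               diff = numeric(0))
  list(order = data.frame(model = names(ord), rank = unname(ord)),
       groups = groups, significant_pairs = sig)
}
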