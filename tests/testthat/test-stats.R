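# Confusion metrics, AUC, fold aggregation, Friedman/Nemenyi/CD harness.

test_that("confusion matrices count correctly and add over folds", {
  cm <- confusion(c(0, 0, 1, 2), c(0, 1, 1, 2), 3)
  expect_equal(cm["0", "1"], 1L)
  expect_equal(sum(diag(cm)), 3L)
  expect_equal(sum(cm), 4L)
  # perfect prediction -> diagonal with row sums = class counts
  y <- c(0, 0, 1, 2, 2, 2)
  cmp <- confusion(y, y, 3)
  expect_equal(diag(cmp), c(`0` = 2L, `1` = 1L, `2` = 3L))
  expect_equal(sum(cmp) - sum(diag(cmp)), 0L)
  # fold additivity: metrics on summed matrices == metrics on pooled labels
  y1 <- c(0, 1, 2, 0); p1 <- c(0, 1, 1, 0)
  y2 <- c(2, 2, 1, 0); p2 <- c(2, 0, 1, 0)
  expect_equal(confusion(y1, p1, 3) + confusion(y2, p2, 3),
               confusion(c(y1, y2), c(p1, p2), 3))
  expect_error(confusion(0:1, 0L, 2), class = "hmcnet_input_error")
})

test_that("classification metrics follow the one-vs-rest definitions", {
  # binary example: TP=2, FP=1, FN=1, TN=6
  cm <- matrix(c(2L, 1L, 1L, 6L), 2, 2, byrow = TRUE)
  met <- classification_metrics(cm)
  cls <- met$per_class[1, ]
  expect_equal(cls$precision, 2 / 3)
  expect_equal(cls$sensitivity, 2 / 3)
  expect_equal(cls$specificity, 6 / 7)
  expect_equal(cls$accuracy, 0.8)
  expect_equal(cls$f1, 2 / 3)
  # perfect diagonal -> all metrics 1
  met <- classification_metrics(diag(c(5L, 3L, 2L)))
  expect_equal(unname(met$macro), rep(1, 5))
  expect_equal(met$overall_accuracy, 1)
  # the near-perfect 322-case matrix: one benign case called malignant
  cm <- matrix(0L, 3, 3)
  diag(cm) <- c(207L, 63L, 51L)
  cm[2, 3] <- 1L
  met <- classification_metrics(cm)
  expect_equal(met$overall_accuracy, 321 / 322, tolerance = 1e-12)
  expect_equal(round(100 * met$overall_accuracy, 2), 99.69)
  expect_error(classification_metrics(matrix(0L, 2, 2)),
               class = "hmcnet_input_error")
})

test_that("macro AUC equals exhaustive pair counting and handles edge cases", {
  # brute-force pair-counting oracle on a 6-sample binary problem
  y <- c(0, 1, 0, 1, 1, 0)
  s <- c(0.1, 0.8, 0.4, 0.35, 0.9, 0.2)
  pos <- s[y == 1]; neg <- s[y == 0]
  wins <- 0
  for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
  oracle <- wins / (length(pos) * length(neg))
  probs <- cbind(1 - s, s)
  expect_equal(as.numeric(auc_macro(y, probs)),
               (oracle + oracle) / 2)  # class-0 AUC mirrors class-1
  # cross-check against an established implementation
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(oracle, ref)
  # perfect separation and constant scores
  yp <- c(0, 0, 1, 1)
  expect_equal(as.numeric(auc_macro(yp, cbind(c(.9, .8, .1, .2),
                                              c(.1, .2, .9, .8)))), 1)
  expect_equal(as.numeric(auc_macro(yp, matrix(0.5, 4, 2))), 0.5)
  # absent class skipped with a flag
  out <- auc_macro(c(0, 0, 1, 1), cbind(c(.9, .8, .1, .2),
                                        c(.1, .2, .9, .8), c(0, 0, 0, 0)))
  expect_equal(attr(out, "skipped_classes"), 2L)
})

test_that("fold aggregation reproduces mean +- sample sd", {
  tbl <- data.frame(fold = 1:5,
                    accuracy = c(99.68, 99.75, 99.70, 99.80, 99.67),
                    sensitivity = c(98.72, 99.21, 98.93, 99.15, 98.94))
  agg <- aggregate_folds(tbl)
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(round(acc$mean, 2), 99.72)
  expect_equal(round(acc$sd, 2), 0.05)
  expect_equal(acc$formatted, "99.72 ± 0.05")
  expect_equal(round(agg[agg$metric == "sensitivity", "mean"], 2), 98.99)
  # identical folds -> sd 0; translation/scale equivariance of the mean
  same <- data.frame(fold = 1:3, m = c(7, 7, 7))
  expect_equal(aggregate_folds(same)$sd, 0)
  shifted <- data.frame(fold = 1:5, m = 2 * tbl$accuracy + 10)
  expect_equal(aggregate_folds(shifted)$mean,
               2 * acc$mean + 10, tolerance = 1e-12)
  expect_error(aggregate_folds(data.frame(fold = 1, m = 1)),
               class = "hmcnet_input_error")
  expect_error(aggregate_folds(data.frame(fold = 1:2, m = c(1, NA))),
               class = "hmcnet_input_error")
})

test_that("Friedman statistic matches formula arithmetic and friedman.test", {
  # strict ordering in every fold: ranks 1..4 -> statistic 15
  ordered <- matrix(rep(c(4, 3, 2, 1), 5), 5, 4, byrow = TRUE)
  fr <- friedman_rank(ordered)
  expect_equal(fr$statistic, 15)
  expect_equal(sum(fr$avg_ranks), 4 * 5 / 2)
  # all models identical -> statistic 0
  expect_equal(friedman_rank(matrix(1, 5, 4))$statistic, 0)
  # random matrix: agree exactly with the independent base-R implementation
  set.seed(50)
  for (rep in 1:5) {
    sc <- matrix(rnorm(5 * 4), 5, 4)
    fr <- friedman_rank(sc)
    ref <- stats::friedman.test(sc)
    expect_equal(fr$statistic, unname(ref$statistic))
    expect_equal(fr$p_value, unname(ref$p.value))
    # rank-based: invariant under strictly monotone transforms per fold
    sc2 <- t(apply(sc, 1, function(r) exp(3 * r) + 1))
    expect_equal(friedman_rank(sc2)$statistic, fr$statistic)
    expect_equal(sum(fr$avg_ranks), 4 * 5 / 2)
  }
  # Monte Carlo permutation p agrees with the asymptotic p in direction
  set.seed(52)
  sc <- matrix(rnorm(5 * 4), 5, 4)
  p_perm <- friedman_rank(sc, p_method = "permutation",
                          n_perm = 2000)$p_value
  expect_true(p_perm > 0 && p_perm <= 1)
  tied_p <- friedman_rank(matrix(1, 5, 4), p_method = "permutation",
                          n_perm = 200)$p_value
  expect_equal(tied_p, 1)
  expect_error(friedman_rank(matrix(1, 1, 4)), class = "hmcnet_input_error")
  expect_error(friedman_rank(matrix(c(1, NA, 1, 1), 2, 2)),
               class = "hmcnet_numeric_error")
})

test_that("Nemenyi p-values are symmetric with unit diagonal", {
  set.seed(51)
  sc <- matrix(rnorm(5 * 4), 5, 4)
  P <- nemenyi_pairwise(sc)
  expect_equal(diag(P), rep(1, 4))
  expect_equal(P, t(P))
  expect_true(all(P >= 0 & P <= 1))
  # equal average ranks -> p = 1
  tied <- matrix(rep(c(1, 1, 2, 3), 4), 4, 4, byrow = TRUE)
  P <- nemenyi_pairwise(tied)
  expect_equal(P[1, 2], 1)
  # sanity: p agrees with the studentized-range tail formula
  fr <- friedman_rank(sc)
  z <- abs(fr$avg_ranks[1] - fr$avg_ranks[2]) / sqrt(4 * 5 / 30)
  expect_equal(nemenyi_pairwise(sc)[1, 2],
               stats::ptukey(z * sqrt(2), 4, Inf, lower.tail = FALSE))
})

test_that("critical difference follows q * sqrt(k(k+1)/(6N))", {
  expect_equal(critical_difference(3, 10, 2.343), 2.343 * sqrt(0.2),
               tolerance = 1e-12)
  expect_equal(critical_difference(4, 5, 0), 0)
  expect_error(critical_difference(1, 5, 2), class = "hmcnet_input_error")
  # the shipped standard table value for k = 4 is about 2.569
  expect_equal(unname(q_nemenyi_05[["4"]]), 2.569, tolerance = 1e-3)
})

test_that("CD diagram groups by strict rank-gap rule", {
  ranks <- c(a = 1, b = 1.5, c = 3.1)
  cd <- cd_diagram(ranks, CD = 2)
  expect_equal(cd$order$model, c("a", "b", "c"))
  expect_equal(nrow(cd$significant_pairs), 1L)
  expect_equal(cd$significant_pairs$model_i, "a")
  expect_equal(cd$significant_pairs$model_j, "c")
  # all equal -> one group with every model
  cd <- cd_diagram(c(x = 2, y = 2, z = 2), CD = 1)
  expect_length(cd$groups, 1L)
  expect_setequal(cd$groups[[1]], c("x", "y", "z"))
  # boundary: gap exactly CD is significant (not connected)
  cd <- cd_diagram(c(p = 1, q = 3), CD = 2)
  expect_equal(nrow(cd$significant_pairs), 1L)
})
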