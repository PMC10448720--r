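make_labels <- function(n_pos, n_neg) {
  data.frame(chem_id = sprintf("C%03d", seq_len(n_pos + n_neg)),
             hepatotoxic = rep(c(1, 0), c(n_pos, n_neg)),
             hepatocellular = NA, hepatobiliary = NA)
}

test_that("undersampling balances classes deterministically", {
  keep <- undersample_balance(make_labels(80, 20), seed = 1)
  expect_length(keep, 40)
  labs <- make_labels(80, 20)
  kept <- labs[labs$chem_id %in% keep, ]
  expect_equal(sum(kept$hepatotoxic == 1), 20)
  expect_equal(sum(kept$hepatotoxic == 0), 20)

  bal <- make_labels(53, 53)
  expect_equal(undersample_balance(bal, seed = 7), sort(bal$chem_id))

  expect_identical(undersample_balance(labs, 5),
                   undersample_balance(labs, 5))
  expect_false(identical(undersample_balance(labs, 5),
                         undersample_balance(labs, 6)))
  expect_error(undersample_balance(make_labels(10, 0), 1),
               "both classes")
})

test_that("ridge logistic fits separable, constant and null features sanely", {
  set.seed(31)
  y <- rep(c(0, 1), each = 10)
  x <- cbind(sig = y, noise = rnorm(20))
  fit <- fit_logistic(x, y)
  expect_equal(as.integer(predict(fit, x) > 0.5), y)  # training acc 1

  # constant feature: coefficient 0, intercept = base-rate log-odds
  y2 <- rep(c(0, 1), c(6, 14))
  x2 <- cbind(flat = rep(3, 20))
  fit2 <- fit_logistic(x2, y2)
  expect_equal(unname(fit2$coefficients["flat"]), 0)
  expect_equal(fit2$intercept, qlogis(0.7), tolerance = 1e-6)

  # label-independent features: training accuracy near the base rate
  set.seed(32)
  y3 <- rbinom(200, 1, 0.5)
  x3 <- matrix(rnorm(200 * 10), 200)
  colnames(x3) <- paste0("f", 1:10)
  fit3 <- fit_logistic(x3, y3)
  acc3 <- mean(as.integer(predict(fit3, x3) > 0.5) == y3)
  expect_lt(acc3, 0.72)
})

test_that("LOO CV isolates folds and reports exact confusion metrics", {
  set.seed(41)
  n <- 24
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(sig = y + rnorm(n, sd = 0.1), n1 = rnorm(n))
  rownames(x) <- sprintf("C%02d", 1:n)
  res <- loo_cv(x, y, model_id = 1L)
  expect_equal(res$accuracy, 1)
  expect_equal(res$recall, 1)

  # metrics are exact rational functions of the confusion counts
  x2 <- cbind(noise = rnorm(n))
  rownames(x2) <- rownames(x)
  res2 <- loo_cv(x2, y)
  expect_equal(res2$accuracy, (res2$TP + res2$TN) / n)
  expect_equal(res2$recall, res2$TP / (res2$TP + res2$FN))
  expect_equal(res2$TP + res2$FP + res2$TN + res2$FN, n)

  expect_error(loo_cv(x[1:3, ], y[1:3]), "n >= 4")
  expect_error(loo_cv(x, rep(1, n)), "both classes")
})

test_that("leakage canary: the held-out label never reaches its own fold", {
  set.seed(43)
  n <- 16
  y <- rep(c(0, 1), n / 2)
  x <- matrix(rnorm(n * 3), n, dimnames = list(sprintf("C%02d", 1:n),
                                               c("a", "b", "c")))
  base <- loo_cv(x, y)
  for (i in c(1, 7, n)) {
    y_flip <- y
    y_flip[i] <- 1 - y_flip[i]
    flipped <- loo_cv(x, y_flip)
    expect_equal(flipped$probability[i], base$probability[i],
                 tolerance = 1e-12)
  }
})

test_that("per-feature Welch t tests match the textbook formula", {
  y <- rep(c(1, 0), each = 3)
  x <- cbind(f1 = c(1, 2, 3, 2, 4, 6),   # hand Welch: t = -2/sqrt(5/3)
             same = rep(2, 6),
             sep = c(1, 1, 1, 0, 0, 0))
  res <- feature_group_test(x, y)
  expect_equal(res$t[res$feature == "f1"], -2 / sqrt(5 / 3),
               tolerance = 1e-12)
  expect_equal(res$t[res$feature == "same"], 0)
  expect_equal(res$p_value[res$feature == "same"], 1)
  expect_equal(res$t[res$feature == "sep"], Inf)
  expect_equal(res$p_value[res$feature == "sep"], 0)
  expect_equal(res$feature[1], "sep")    # ranked by |t|
})

test_that("compare_models reports deltas and corrected chemicals", {
  mk <- function(pred, actual) {
    n <- length(pred)
    tp <- sum(pred == 1 & actual == 1); fp <- sum(pred == 1 & actual == 0)
    tn <- sum(pred == 0 & actual == 0); fn <- sum(pred == 0 & actual == 1)
    structure(list(model_id = 1, n = n,
                   chem_id = sprintf("C%d", seq_len(n)),
                   probability = pred, predicted = pred, actual = actual,
                   TP = tp, FP = fp, TN = tn, FN = fn,
                   accuracy = (tp + tn) / n, recall = tp / (tp + fn)),
              class = "aop_model_result")
  }
  actual <- c(1, 1, 1, 0, 0, 0, 1, 0)
  m1 <- mk(c(0, 0, 1, 1, 1, 0, 0, 0), actual)  # wrong on C1,C2,C4,C5,C7
  m2 <- mk(c(1, 1, 1, 1, 1, 0, 1, 0), actual)  # fixes C1,C2,C7
  cmp <- compare_models(m1, m2)
  expect_equal(cmp$corrected, c("C1", "C2", "C7"))
  expect_equal(cmp$delta_accuracy, 3 / 8)
  same <- compare_models(m1, m1)
  expect_equal(same$delta_accuracy, 0)
  expect_length(same$corrected, 0)
})

test_that("assemble_features joins scores, labels, Css and descriptors", {
  scores <- data.frame(chem_id = rep(c("C1", "C2", "C3"), 2),
                       ke_id = rep(c("K1", "K2"), each = 3),
                       raw_auc = 0.2, scaled_score = runif(6))
  labs <- data.frame(chem_id = c("C1", "C2", "C3"),
                     hepatotoxic = c(1, 0, NA),
                     hepatocellular = NA, hepatobiliary = NA)
  f1 <- assemble_features(scores, labs)
  expect_equal(rownames(f1$x), c("C1", "C2"))    # unlabeled dropped
  expect_equal(colnames(f1$x), c("KE_K1", "KE_K2"))

  css <- data.frame(chem_id = c("C1", "C2"), css95 = c(100, 0.01))
  desc <- data.frame(chem_id = c("C1", "C2"), mw = c(300, 150),
                     logp = c(2, -1))
  f2 <- assemble_features(scores, labs, css, desc)
  expect_equal(colnames(f2$x),
               c("KE_K1", "KE_K2", "log10_css", "mw", "logp"))
  expect_equal(unname(f2$x[, "log10_css"]), c(2, -2))
  expect_false(anyNA(f2$x))
})
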