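#' @title Logistic models of in vivo hepatotoxicity
#' @description Two leave-one-out-validated logistic models: Model 1
#'   uses scaled KE scores only; Model 2 adds bioavailability features
#'   (log10 Css and Lipinski descriptors). The class-imbalanced label
#'   set is balanced once, before validation, by random undersampling
#'   of the majority class. Chemicals with probability > 0.5 are
#'   classified as hepatotoxicants.
#' @name aop_model
NULL

#' Balance classes by undersampling the majority class
#'
#' Keeps every minority-class chemical and a uniform random subset of
#' the majority class of equal size. Deterministic given the seed.
#'
#' @param labels Label table (see [read_labels()]); rows with missing
#'   `hepatotoxic` are dropped.
#' @param seed Integer seed for the majority-class draw.
#' @return Character vector of retained chem_ids (sorted).
#' @export
undersample_balance <- function(labels, seed) {
  lab <- labels[!is.na(labels$hepatotoxic), ]
  pos <- lab$chem_id[lab$hepatotoxic == 1]
  neg <- lab$chem_id[lab$hepatotoxic == 0]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present to balance")
  if (length(pos) == length(neg)) return(sort(c(pos, neg)))
  maj <- if (length(pos) > length(neg)) pos else neg
  mino <- if (length(pos) > length(neg)) neg else pos
  # local RNG so the draw never perturbs the caller's stream
  old <- .Random.seed_exists()
  set.seed(seed)
  sel <- sample(sort(maj), length(mino))
  .restore_seed(old)
  sort(c(mino, sel))
}

# RNG bookkeeping helpers: snapshot/restore .Random.seed so seeded
# draws inside the package are invisible to the caller's stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Assemble the model feature table
#'
#' Model 1 features are the scaled KE scores (one column per KE).
#' Model 2 adds `log10_css` (Css spans several orders of magnitude, so
#' it enters as log10 uM) and the Lipinski descriptors. Only chemicals
#' with a label -- and, for Model 2, Css and descriptors -- are kept;
#' the assembled table has no missing values.
#'
#' @param score_table Output of [ke_score_table()].
#' @param labels Label table.
#' @param css Optional Css table (Model 2).
#' @param descriptors Optional [lipinski_descriptors()] table (Model 2).
#' @return List with `x` (numeric feature matrix, rownames chem_id),
#'   `y` (0/1 labels), `chem_id`.
#' @export
assemble_features <- function(score_table, labels, css = NULL,
                              descriptors = NULL) {
  wide <- stats::reshape(
    score_table[, c("chem_id", "ke_id", "scaled_score")],
    idvar = "chem_id", timevar = "ke_id", direction = "wide")
  names(wide) <- sub("^scaled_score\\.", "KE_", names(wide))
  df <- merge(wide, labels[!is.na(labels$hepatotoxic),
                           c("chem_id", "hepatotoxic")], by = "chem_id")
  if (!is.null(css)) {
    css <- css[, c("chem_id", "css95")]
    css$log10_css <- log10(css$css95)
    df <- merge(df, css[, c("chem_id", "log10_css")], by = "chem_id")
  }
  if (!is.null(descriptors))
    df <- merge(df, descriptors, by = "chem_id")
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df <- df[order(df$chem_id), ]
  y <- df$hepatotoxic
  x <- as.matrix(df[, setdiff(names(df), c("chem_id", "hepatotoxic")),
                    drop = FALSE])
  rownames(x) <- df$chem_id
  list(x = x, y = y, chem_id = df$chem_id)
}

#' Ridge-penalized logistic regression
#'
#' Maximizes the log-likelihood minus (lambda/2)*||beta||^2 by
#' Newton-Raphson (IRLS), with features standardized to zero mean and
#' unit variance internally and the intercept left unpenalized. The
#' weak default penalty guarantees a finite, unique optimum even under
#' complete separation while leaving well-conditioned fits essentially
#' unpenalized. Coefficients are reported on the original feature
#' scale.
#'
#' @param x Numeric feature matrix.
#' @param y 0/1 response.
#' @param lambda L2 penalty weight on standardized coefficients
#'   (default 1e-4 per observation; 0 turns the penalty off).
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `ridge_logit` with `intercept`,
#'   `coefficients`, and the standardization used.
#' @export
fit_logistic <- function(x, y, lambda = 1e-4 * nrow(x),
                         max_iter = 100L, tol = 1e-10) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1   # constant feature: leave centered at 0
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  z1 <- cbind(1, z)
  p_ <- ncol(z1)
  pen <- diag(c(0, rep(lambda, p_ - 1)))   # intercept unpenalized
  beta <- numeric(p_)
  beta[1] <- stats::qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6))
  for (it in seq_len(max_iter)) {
    eta <- drop(z1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(z1, y - mu)) - drop(pen %*% beta)
    hess <- crossprod(z1 * w, z1) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  coef_std <- beta[-1]
  coef_raw <- coef_std / scl
  intercept <- unname(beta[1] - sum(coef_std * ctr / scl))
  structure(list(intercept = intercept,
                 coefficients = stats::setNames(coef_raw, colnames(x)),
                 lambda = lambda, center = ctr, scale = scl,
                 iterations = it),
            class = "ridge_logit")
}

#' @describeIn fit_logistic Predicted hepatotoxicity probabilities.
#' @param object A `ridge_logit` fit.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @export
predict.ridge_logit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stats::plogis(object$intercept +
                  drop(newdata %*% object$coefficients))
}

#' Leave-one-out cross-validation of a logistic model
#'
#' Fits n models, each leaving one chemical out and predicting its
#' hepatotoxicity probability; the held-out chemical's label is never
#' visible to the fold that scores it. Metrics use the 0.5 threshold.
#'
#' @param x Feature matrix (rownames chem_id).
#' @param y 0/1 labels.
#' @param model_id Identifier carried on the result (1 or 2).
#' @param lambda Ridge penalty (see [fit_logistic()]).
#' @return Object of class `aop_model_result`: `model_id`, per-chemical
#'   `probability` and `predicted`, `actual`, confusion counts
#'   `TP,FP,TN,FN`, `accuracy`, `recall`, `n`, and the full-data
#'   coefficient table.
#' @export
loo_cv <- function(x, y, model_id = 1L, lambda = 1e-4 * nrow(x)) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need n >= 4 for leave-one-out validation")
  if (length(unique(y)) < 2) stop("both classes must be present")
  prob <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_logistic(x[-i, , drop = FALSE], y[-i], lambda = lambda)
    prob[i] <- predict(fit, x[i, , drop = FALSE])
  }
  pred <- as.integer(prob > 0.5)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  full <- fit_logistic(x, y, lambda = lambda)
  structure(list(
    model_id = model_id, n = n,
    chem_id = rownames(x), probability = prob, predicted = pred,
    actual = y,
    TP = tp, FP = fp, TN = tn, FN = fn,
    accuracy = (tp + tn) / n,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fit = full), class = "aop_model_result")
}

#' @export
print.aop_model_result <- function(x, ...) {
  cat(sprintf(
    "<aop_model_result> Model %s: n=%d  acc=%.3f  recall=%.3f  (TP %d, FP %d, TN %d, FN %d)\n",
    x$model_id, x$n, x$accuracy, x$recall, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Welch t-test of each feature between toxicity classes
#'
#' For every predictor, compares its distribution in hepatotoxic vs
#' nonhepatotoxic chemicals (Welch two-sample t). Zero-variance
#' degenerate splits give t = +/-Inf with p = 0 when means differ, and
#' t = 0, p = 1 when they do not.
#'
#' @param x Feature matrix.
#' @param y 0/1 labels.
#' @return data.frame `feature,t,p_value`, ranked by |t| descending.
#' @export
feature_group_test <- function(x, y) {
  x <- as.matrix(x)
  res <- lapply(colnames(x), function(f) {
    a <- x[y == 1, f]; b <- x[y == 0, f]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
      p <- if (t == 0) 1 else 0
    } else {
      tt <- stats::t.test(a, b)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(feature = f, t = t, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-abs(out$t), out$feature), ]
}

#' Compare two LOO model results
#'
#' @param result1,result2 `aop_model_result` objects over the same
#'   chemicals.
#' @return List with `delta_accuracy`, `delta_recall`, and `corrected`
#'   (chem_ids wrong under result1 but right under result2).
#' @export
compare_models <- function(result1, result2) {
  if (!identical(result1$chem_id, result2$chem_id))
    stop("results cover different chemical sets")
  wrong1 <- result1$predicted != result1$actual
  right2 <- result2$predicted == result2$actual
  list(delta_accuracy = result2$accuracy - result1$accuracy,
       delta_recall = result2$recall - result1$recall,
       corrected = result1$chem_id[wrong1 & right2])
}
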