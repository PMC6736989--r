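# Cross-validated classification of pSS vs HC on variance-stabilized
# expression, with backward feature elimination and a prediction-confidence
# rule that stratifies the intermediate (nSS) group. The classifier is
# ridge-regularized logistic regression (probability outputs, stable under
# perfect separation).

# ~1/n for the cohort sizes this pipeline sees; strong enough for stable
# coefficients with p ~ 100 features, mild enough that confident samples
# reach class probabilities well above the 0.75 stratification threshold
ridge_lambda_default <- 0.05

fit_ridge <- function(x, y, lambda = ridge_lambda_default) {
  # y: factor with levels c(negative, positive)
  glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                 standardize = TRUE)
}

predict_ridge <- function(fit, x) {
  as.numeric(stats::predict(fit, newx = x, type = "response"))
}

# stratified fold assignment, deterministic under seed
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  f <- integer(length(y))
  for (lev in unique(y)) {
    idx <- sample(which(y == lev))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Out-of-fold cross-validated prediction
#'
#' Stratified k-fold cross-validation of a ridge-logistic classifier of
#' `pSS` (positive) vs `HC`: each sample's class probability comes from the
#' model trained without its fold. Sensitivity is recall on `pSS`,
#' specificity recall on `HC`, both at probability 0.5.
#'
#' @param vsd expression matrix, genes x samples.
#' @param labels character/factor per sample, values `"pSS"` or `"HC"`.
#' @param features gene ids used as predictors.
#' @param folds number of folds (default 10; capped at the smaller class).
#' @param seed integer seed for the fold assignment.
#' @param lambda ridge penalty.
#' @return list: `probability` (named per-sample P(pSS)), `predicted`,
#'   `sensitivity`, `specificity`, `accuracy`, `folds`.
#' @export
fit_predict_cv <- function(vsd, labels, features, folds = 10, seed = 1L,
                           lambda = ridge_lambda_default) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("pSS", "HC")), length(labels) == ncol(vsd))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  missing <- setdiff(features, rownames(vsd))
  if (length(missing) > 0)
    stop("features absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  folds <- max(2, min(folds, min(table(labels))))
  x <- t(vsd[features, , drop = FALSE])
  if (length(features) == 1) {        # glmnet needs >= 2 columns
    x <- cbind(x, `.const` = 0)
  }
  y <- factor(labels, levels = c("HC", "pSS"))
  fid <- stratified_folds(labels, folds, seed)
  prob <- rep(NA_real_, length(labels))
  for (k in seq_len(folds)) {
    tr <- fid != k
    if (length(unique(labels[tr])) < 2) stop("fold without both classes")
    fit <- fit_ridge(x[tr, , drop = FALSE], y[tr], lambda)
    prob[!tr] <- predict_ridge(fit, x[!tr, , drop = FALSE])
  }
  names(prob) <- colnames(vsd)
  pred <- ifelse(prob > 0.5, "pSS", "HC")
  sens <- mean(pred[labels == "pSS"] == "pSS")
  spec <- mean(pred[labels == "HC"] == "HC")
  list(probability = prob, predicted = pred, sensitivity = sens,
       specificity = spec, accuracy = mean(pred == labels), folds = folds)
}

#' Backward feature elimination under cross-validation
#'
#' Starting from the candidate genes, repeatedly drops the feature with the
#' smallest importance (absolute standardized ridge coefficient on the full
#' data) as long as the cross-validated accuracy does not drop below the
#' best accuracy seen so far minus `tolerance`. With many candidates the
#' bottom `drop_fraction` of features is dropped per round for speed until
#' 20 features remain, then one at a time. Deterministic under `seed`.
#'
#' @inheritParams fit_predict_cv
#' @param candidate_genes starting feature set.
#' @param tolerance allowed CV-accuracy slack when removing (default 0.01).
#' @param drop_fraction fraction dropped per round while > 20 features.
#' @return list: `features` (selected set), `cv_accuracy`, `trace`
#'   (data.frame of size vs accuracy).
#' @export
select_features <- function(vsd, labels, candidate_genes, folds = 10,
                            seed = 1L, lambda = ridge_lambda_default,
                            tolerance = 0.01, drop_fraction = 0.2) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (length(candidate_genes) <= 1)
    return(list(features = candidate_genes, cv_accuracy = NA_real_,
                trace = NULL))
  current <- candidate_genes
  acc <- fit_predict_cv(vsd, labels, current, folds, seed, lambda)$accuracy
  best <- acc
  trace <- list(data.frame(n_features = length(current), cv_accuracy = acc))
  y <- factor(labels, levels = c("HC", "pSS"))
  repeat {
    if (length(current) <= 1) break
    x <- t(vsd[current, , drop = FALSE])
    fit <- fit_ridge(x, y, lambda)
    co <- abs(as.numeric(stats::coef(fit))[-1]) * apply(x, 2, stats::sd)
    n_drop <- if (length(current) > 20)
      max(1L, floor(drop_fraction * length(current))) else 1L
    drop_idx <- order(co)[seq_len(n_drop)]
    candidate <- current[-drop_idx]
    if (length(candidate) == 0) break
    acc_new <- fit_predict_cv(vsd, labels, candidate, folds, seed,
                              lambda)$accuracy
    if (acc_new >= best - tolerance) {
      current <- candidate
      best <- max(best, acc_new)
      trace[[length(trace) + 1]] <-
        data.frame(n_features = length(current), cv_accuracy = acc_new)
    } else if (n_drop > 1L) {
      # chunked drop failed: retry one-at-a-time before giving up
      candidate <- current[-drop_idx[1]]
      acc_new <- fit_predict_cv(vsd, labels, candidate, folds, seed,
                                lambda)$accuracy
      if (acc_new >= best - tolerance) {
        current <- candidate
        best <- max(best, acc_new)
        trace[[length(trace) + 1]] <-
          data.frame(n_features = length(current), cv_accuracy = acc_new)
      } else break
    } else break
  }
  list(features = current,
       cv_accuracy = fit_predict_cv(vsd, labels, current, folds, seed,
                                    lambda)$accuracy,
       trace = do.call(rbind, trace))
}

#' Stratify intermediate-group samples by prediction confidence
#'
#' Trains the ridge-logistic classifier on all `pSS` vs `HC` samples with the
#' selected features, predicts P(pSS) for the held-out intermediate samples,
#' and labels those with probability STRICTLY above `threshold` as
#' `"pSS-like"`; the rest are `"reference"`.
#'
#' @param vsd expression matrix, genes x samples (training and intermediate
#'   samples as columns).
#' @param labels per training sample, `"pSS"`/`"HC"` (names = sample ids).
#' @param intermediate_samples sample ids to stratify (e.g. the nSS group).
#' @param features selected gene panel.
#' @param threshold confidence cutoff (default 0.75), strict `>`.
#' @param lambda ridge penalty.
#' @return list: `label` (named, `"pSS-like"`/`"reference"`), `probability`
#'   (named P(pSS)), `threshold`.
#' @export
classify_intermediate <- function(vsd, labels, intermediate_samples, features,
                                  threshold = 0.75,
                                  lambda = ridge_lambda_default) {
  stopifnot(threshold > 0.5, threshold < 1)
  missing <- setdiff(features, rownames(vsd))
  if (length(missing) > 0)
    stop("features absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  tr_samples <- names(labels)
  stopifnot(!is.null(tr_samples), all(tr_samples %in% colnames(vsd)),
            all(intermediate_samples %in% colnames(vsd)))
  xtr <- t(vsd[features, tr_samples, drop = FALSE])
  xte <- t(vsd[features, intermediate_samples, drop = FALSE])
  if (length(features) == 1) {
    xtr <- cbind(xtr, `.const` = 0)
    xte <- cbind(xte, `.const` = 0)
  }
  y <- factor(as.character(labels), levels = c("HC", "pSS"))
  fit <- fit_ridge(xtr, y, lambda)
  prob <- stats::setNames(predict_ridge(fit, xte), intermediate_samples)
  list(label = confidence_label(prob, threshold),
       probability = prob, threshold = threshold)
}

# strict >: a sample AT the threshold stays in the reference stratum
confidence_label <- function(prob, threshold) {
  stats::setNames(ifelse(prob > threshold, "pSS-like", "reference"),
                  names(prob))
}
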