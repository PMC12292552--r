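#' Train a baseline classifier on utterance feature vectors
#'
#' Two baselines over hand-crafted acoustic features (MFCC or eGeMAPS):
#' `"MLP"` uses the identical architecture as the model's classification
#' head (input to 64 units, ReLU, dropout 0.2, linear to 2 logits) trained
#' with AdamW on standardized features; `"GBT"` delegates to gradient
#' boosted trees (xgboost) with a small grid search over depth, learning
#' rate and boosting rounds selected by cross-validated log-loss. Both
#' return calibrated class scores in `[0, 1]` that sum to 1.
#'
#' @param features Numeric matrix (`n x d`), one row per utterance.
#' @param labels Class labels (`"HC"`/`"PD"`), both classes required.
#' @param model_kind `"MLP"` or `"GBT"`.
#' @param config Optional list: for MLP `epochs` (default 200),
#'   `batch_size` (32), `lr` (1e-3); for GBT `depth_grid` (3, 5, 7),
#'   `eta_grid` (0.05, 0.1), `nrounds_grid` (100, 300), `cv_folds` (3).
#' @param seed Integer seed; MLP fits are bit-reproducible.
#' @return An object of class `baseline_model` with a
#'   [predict.baseline_model()] method.
#' @export
train_baseline <- function(features, labels, model_kind = c("MLP", "GBT"),
                           config = list(), seed = 1) {
  model_kind <- match.arg(model_kind)
  features <- as.matrix(features)
  if (any(!is.finite(features))) stopf("features must be finite")
  if (nrow(features) != length(labels)) stopf("features/labels length mismatch")
  if (length(unique(labels)) < 2L) stopf("need both classes in the labels")
  y <- label_ids(labels)
  if (model_kind == "MLP") {
    mu <- colMeans(features)
    sd_ <- apply(features, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    xs <- sweep(sweep(features, 2, mu, "-"), 2, sd_, "/")
    epochs <- config$epochs %||% 200
    bsz <- config$batch_size %||% 32
    lr <- config$lr %||% 1e-3
    clf <- with_seed(combine_seed(seed, "mlp-init"),
                     init_classifier(ncol(xs), 64))
    st <- adamw_state(clf)
    for (epoch in seq_len(epochs)) {
      idx <- with_seed(combine_seed(seed, "mlp-epoch", epoch),
                       sample(nrow(xs)))
      for (step in seq_len(ceiling(length(idx) / bsz))) {
        bi <- idx[(((step - 1L) * bsz) + 1L):min(step * bsz, length(idx))]
        if (length(bi) < 2L) next
        fwd <- with_seed(combine_seed(seed, "mlp-drop", epoch, step),
                         classifier_fwd_cached(clf, xs[bi, , drop = FALSE],
                                               0.2, TRUE))
        ce <- softmax_ce(fwd$out, y[bi])
        bwd <- classifier_bwd(clf, fwd, ce$dlogits)
        upd <- adamw_step(clf, bwd$grads, st,
                          cosine_lr(lr, epoch, epochs))
        clf <- upd$params
        st <- upd$state
      }
    }
    structure(list(kind = "MLP", clf = clf, mu = mu, sd = sd_),
              class = "baseline_model")
  } else {
    grid <- expand.grid(depth = config$depth_grid %||% c(3, 5, 7),
                        eta = config$eta_grid %||% c(0.05, 0.1),
                        nrounds = config$nrounds_grid %||% c(100, 300))
    cv_folds <- config$cv_folds %||% 3
    dtrain <- xgboost::xgb.DMatrix(features, label = y - 1)
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      params <- list(objective = "binary:logistic",
                     eval_metric = "logloss",
                     max_depth = grid$depth[g], eta = grid$eta[g],
                     nthread = 1, seed = seed)
      cv <- xgboost::xgb.cv(params = params, data = dtrain,
                            nrounds = grid$nrounds[g], nfold = cv_folds,
                            verbose = 0)
      score <- min(cv$evaluation_log$test_logloss_mean)
      if (is.null(best) || score < best$score)
        best <- list(score = score, params = params,
                     nrounds = grid$nrounds[g])
    }
    fit <- xgboost::xgb.train(params = best$params, data = dtrain,
                              nrounds = best$nrounds)
    structure(list(kind = "GBT", fit = fit, grid_score = best$score),
              class = "baseline_model")
  }
}

#' Predict class scores from a baseline model
#'
#' @param object A `baseline_model` from [train_baseline()].
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return `n x 2` matrix of class scores (columns `HC`, `PD`), rows
#'   summing to 1.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kind == "MLP") {
    xs <- sweep(sweep(newdata, 2, object$mu, "-"), 2, object$sd, "/")
    logits <- classifier_fwd_cached(object$clf, xs, 0, FALSE)$out
    probs <- softmax_rows(logits)
  } else {
    p_pd <- stats::predict(object$fit, xgboost::xgb.DMatrix(newdata))
    probs <- cbind(1 - p_pd, p_pd)
  }
  colnames(probs) <- c("HC", "PD")
  probs
}
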