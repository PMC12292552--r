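#' Training configuration
#'
#' Hyperparameters of the single-phase joint training loop: AdamW
#' (`beta1 = 0.9`, `beta2 = 0.999`, `weight_decay = 0.01`), batch size 32,
#' initial learning rate 2e-5 with cosine annealing over the epoch budget,
#' dropout 0.2, and early stopping on validation F1 with patience 15.
#'
#' @param epochs Maximum epochs (default 100).
#' @param batch_size Batch size (default 32).
#' @param initial_lr Initial learning rate (default 2e-5; desk-scale runs
#'   with the randomly initialized tiny encoder typically need a larger
#'   value such as 1e-3).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param dropout Classifier dropout rate (default 0.2).
#' @param patience Early-stop patience in epochs without improvement of
#'   the monitored validation metric (default 15).
#' @param monitor Validation metric driving early stopping and best-epoch
#'   selection: `"auc"` (default; smoother on few-speaker validation
#'   folds) or `"f1"`.
#' @param seed Integer seed controlling shuffling, dropout and fold
#'   assignment.
#' @param mode `"SUPCON"` (dual pathway with gradient blocking) or
#'   `"CE_ONLY"` (plain fine-tuning).
#' @param fine_tune_encoder Logical; if FALSE the encoder is frozen and its
#'   parameters are bit-identical before and after training.
#' @param encoder_lr_scale Multiplier on the learning rate for encoder
#'   updates (default 0.1): fine-tuning of the representation is gentler
#'   than the training of the freshly initialized heads, the usual
#'   discriminative-learning-rate arrangement.
#' @param supcon A [supcon_config()].
#' @param augment Optional [preprocess_config()]; when supplied, low-pass
#'   augmentation is applied to training batches (never to validation or
#'   test data - this is the only call site of the augmentation operator in
#'   the training pipeline).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 32, initial_lr = 2e-5,
                         weight_decay = 0.01, dropout = 0.2, patience = 15,
                         seed = 1, mode = c("SUPCON", "CE_ONLY"),
                         fine_tune_encoder = TRUE, supcon = supcon_config(),
                         augment = NULL, encoder_lr_scale = 0.1,
                         monitor = c("auc", "f1")) {
  mode <- match.arg(mode)
  monitor <- match.arg(monitor)
  if (epochs < 0 || batch_size < 1 || initial_lr <= 0)
    stopf("epochs >= 0, batch_size >= 1, initial_lr > 0 required")
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, weight_decay = weight_decay,
                 dropout = dropout, patience = as.integer(patience),
                 seed = as.integer(seed), mode = mode,
                 fine_tune_encoder = isTRUE(fine_tune_encoder),
                 supcon = supcon, augment = augment,
                 encoder_lr_scale = encoder_lr_scale, monitor = monitor),
            class = "train_config")
}

# Stack equal-length standardized clips into a B x L matrix with metadata.
clips_to_waves <- function(clips) {
  lens <- vapply(clips, function(c) length(c$samples), integer(1))
  if (length(unique(lens)) != 1L)
    stopf("clips must be standardized to equal length before batching")
  waves <- do.call(rbind, lapply(clips, `[[`, "samples"))
  list(waves = waves, labels = clip_labels(clips),
       speakers = clip_speakers(clips),
       sentences = vapply(clips, `[[`, character(1), "sentence_id"))
}

label_ids <- function(labels) match(labels, c("HC", "PD"))

#' PD scores for a batch of standardized clips
#'
#' Deterministic evaluation-mode forward pass; returns the softmax
#' probability of the PD class per clip.
#'
#' @param model A [supcon_model()].
#' @param clips List of standardized [audio_clip()] (or a `B x L` matrix).
#' @return Numeric vector of PD probabilities in `[0, 1]`.
#' @export
predict_scores <- function(model, clips) {
  waves <- if (is.matrix(clips)) clips else clips_to_waves(clips)$waves
  fwd <- dual_forward(model, waves, mode = "CE_ONLY", train_mode = FALSE)
  softmax_rows(fwd$logits)[, 2]
}

#' Stratified speaker-level fold assignment
#'
#' Assigns speakers (never clips) to `k` folds: within each class the
#' speakers are shuffled by `seed` and dealt round-robin, so per-class fold
#' counts differ by at most one speaker. All clips of a speaker share its
#' fold.
#'
#' @param clips List of [audio_clip()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Named integer vector mapping `speaker_id` to fold in `1..k`.
#' @export
make_folds <- function(clips, k = 5, seed = 1) {
  spk <- clip_speakers(clips)
  lab <- clip_labels(clips)
  spk_lab <- tapply(lab, spk, function(v) v[1])
  fold <- integer(0)
  for (cls in sort(unique(spk_lab))) {
    ids <- sort(names(spk_lab)[spk_lab == cls])
    if (length(ids) < k)
      stopf("need at least k=%d speakers per class (class %s has %d)",
            k, cls, length(ids))
    perm <- with_seed(combine_seed(seed, cls, "folds"), sample(ids))
    f <- ((seq_along(perm) - 1L) %% k) + 1L
    fold[perm] <- f
  }
  fold
}

assert_speaker_disjoint <- function(a, b, what) {
  ov <- intersect(unique(a), unique(b))
  if (length(ov) > 0)
    stopf("speaker leakage between %s: %s", what,
          paste(utils::head(ov, 5), collapse = ", "))
  invisible(TRUE)
}

apply_train_augmentation <- function(clips, config, epoch_seed) {
  lapply(seq_along(clips), function(i)
    augment_lowpass(clips[[i]], config, seed = combine_seed(epoch_seed, i)))
}

#' Train the dual-head model
#'
#' Single-phase joint loop: in `SUPCON` mode each step backpropagates the
#' hard-negative-scaled supervised contrastive loss through the projection
#' head into the encoder and the cross-entropy loss into the (gradient
#' detached) classification head; in `CE_ONLY` mode the cross-entropy loss
#' fine-tunes the whole stack. AdamW with cosine-annealed learning rate;
#' after every epoch the validation F1 is computed and the best epoch's
#' parameters are retained; training stops early after `patience` epochs
#' without improvement. Deterministic given `config$seed`.
#'
#' @param model A [supcon_model()].
#' @param train_clips,val_clips Speaker-disjoint lists of standardized
#'   [audio_clip()] (overlap raises an error).
#' @param config A [train_config()].
#' @return List with `model` (best-epoch parameters), `history`
#'   (per-epoch data.frame), and `best_epoch`.
#' @export
train_model <- function(model, train_clips, val_clips, config) {
  stopifnot(inherits(config, "train_config"))
  assert_speaker_disjoint(clip_speakers(train_clips), clip_speakers(val_clips),
                          "train and validation sets")
  model$dropout <- config$dropout
  val <- clips_to_waves(val_clips)
  opt_state <- list(encoder = adamw_state(model$encoder$params),
                    classifier = adamw_state(model$classifier),
                    projector = adamw_state(model$projector))
  best <- list(f1 = -Inf, epoch = 0L,
               params = list(encoder = model$encoder$params,
                             classifier = model$classifier,
                             projector = model$projector))
  history <- list()
  stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_lr(config$initial_lr, epoch, config$epochs)
    ep_seed <- combine_seed(config$seed, "epoch", epoch)
    ep_clips <- if (!is.null(config$augment))
      apply_train_augmentation(train_clips, config$augment, ep_seed)
    else train_clips
    tr <- clips_to_waves(ep_clips)
    idx <- with_seed(ep_seed, sample(length(ep_clips)))
    n_batches <- ceiling(length(idx) / config$batch_size)
    ep_loss <- c(total = 0, supcon = 0, ce = 0)
    for (step in seq_len(n_batches)) {
      bi <- idx[(((step - 1L) * config$batch_size) + 1L):
                  min(step * config$batch_size, length(idx))]
      if (length(bi) < 2L) next
      waves <- tr$waves[bi, , drop = FALSE]
      labels <- tr$labels[bi]
      fwd <- dual_forward(model, waves, mode = config$mode, train_mode = TRUE,
                          seed = combine_seed(ep_seed, "step", step))
      ce <- softmax_ce(fwd$logits, label_ids(labels))
      if (config$mode == "SUPCON") {
        sc <- hard_negative_adjust(fwd$z, labels, config$supcon,
                                   want_grad = TRUE)
        grads <- dual_backward(model, fwd, dlogits = ce$dlogits,
                               dz = attr(sc, "dz"),
                               fine_tune_encoder = config$fine_tune_encoder)
        ep_loss <- ep_loss + c(as.numeric(sc) + ce$loss, as.numeric(sc),
                               ce$loss)
      } else {
        grads <- dual_backward(model, fwd, dlogits = ce$dlogits,
                               fine_tune_encoder = config$fine_tune_encoder)
        ep_loss <- ep_loss + c(ce$loss, 0, ce$loss)
      }
      # skip components with no gradient signal (blocked/frozen pathways)
      for (comp in c("encoder", "classifier", "projector")) {
        g <- grads[[comp]]
        if (tree_all_zero(g)) next
        pars <- if (comp == "encoder") model$encoder$params else model[[comp]]
        comp_lr <- if (comp == "encoder")
          lr * (config$encoder_lr_scale %||% 1) else lr
        upd <- adamw_step(pars, g, opt_state[[comp]], comp_lr,
                          weight_decay = config$weight_decay)
        opt_state[[comp]] <- upd$state
        if (comp == "encoder") model$encoder$params <- upd$params
        else model[[comp]] <- upd$params
      }
    }
    val_scores <- predict_scores(model, val$waves)
    val_pred <- ifelse(val_scores >= 0.5, "PD", "HC")
    val_f1 <- suppressWarnings(
      compute_metrics(tally_confusion(val$labels, val_pred))$f1)
    val_auc <- if (length(unique(val$labels)) == 2L)
      roc_curve_auc(val_scores, val$labels)$auc else val_f1
    val_mon <- if ((config$monitor %||% "f1") == "auc") val_auc else val_f1
    history[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                   train_total = ep_loss[1] / n_batches,
                                   train_supcon = ep_loss[2] / n_batches,
                                   train_ce = ep_loss[3] / n_batches,
                                   val_f1 = val_f1, val_auc = val_auc)
    if (val_mon > best$f1) {
      best <- list(f1 = val_mon, epoch = epoch,
                   params = list(encoder = model$encoder$params,
                                 classifier = model$classifier,
                                 projector = model$projector))
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$encoder$params <- best$params$encoder
  model$classifier <- best$params$classifier
  model$projector <- best$params$projector
  list(model = model, history = do.call(rbind, history),
       best_epoch = best$epoch)
}

#' Evaluate a trained model on a clip set
#'
#' @param model A [supcon_model()].
#' @param clips List of standardized [audio_clip()].
#' @return List with `scores`, `predicted`, `counts`
#'   ([confusion_counts()]), `metrics` and `auc`.
#' @export
evaluate_model <- function(model, clips) {
  dat <- clips_to_waves(clips)
  scores <- predict_scores(model, dat$waves)
  predicted <- ifelse(scores >= 0.5, "PD", "HC")
  counts <- tally_confusion(dat$labels, predicted)
  metrics <- suppressWarnings(compute_metrics(counts))
  auc <- if (length(unique(dat$labels)) == 2L)
    roc_curve_auc(scores, dat$labels)$auc else NA_real_
  list(scores = scores, labels = dat$labels, sentences = dat$sentences,
       predicted = predicted, counts = counts, metrics = metrics, auc = auc)
}

#' Speaker-independent stratified k-fold cross-validation experiment
#'
#' Implements the evaluation protocol: speakers of the training partition
#' are assigned to `k` stratified folds; for each fold a fresh model is
#' trained on the other `k - 1` folds with the fold itself as the
#' early-stopping validation set, and the best model is evaluated on the
#' common held-out test partition. Reports per-fold metrics with mean and
#' sample (n-1) standard deviation, the cumulative confusion matrix over
#' the `k` test-set evaluations, a pooled ROC over all folds' test scores,
#' and pooled per-sentence-type accuracy. Leakage guards are unconditional.
#'
#' @param train_clips,test_clips Speaker-disjoint standardized clip lists
#'   (e.g. from [split_train_test()]).
#' @param model_factory Function `(seed) -> supcon_model()`; called once
#'   per fold.
#' @param config A [train_config()].
#' @param k Number of folds (default 5).
#' @return An object of class `cv_result`.
#' @export
run_cv_experiment <- function(train_clips, test_clips, model_factory, config,
                              k = 5) {
  assert_speaker_disjoint(clip_speakers(train_clips),
                          clip_speakers(test_clips),
                          "training partition and held-out test set")
  folds <- make_folds(train_clips, k = k, seed = config$seed)
  spk <- clip_speakers(train_clips)
  fold_models <- vector("list", k)
  fold_rows <- vector("list", k)
  fold_counts <- vector("list", k)
  pooled_scores <- numeric(0)
  pooled_labels <- character(0)
  pooled_pred <- character(0)
  pooled_sent <- character(0)
  for (f in seq_len(k)) {
    val_idx <- folds[spk] == f
    fit_clips <- train_clips[!val_idx]
    val_clips <- train_clips[val_idx]
    assert_speaker_disjoint(clip_speakers(val_clips),
                            clip_speakers(test_clips),
                            "validation fold and test set")
    fold_cfg <- config
    fold_cfg$seed <- combine_seed(config$seed, "fold", f)
    model <- model_factory(fold_cfg$seed)
    fit <- train_model(model, fit_clips, val_clips, fold_cfg)
    ev <- evaluate_model(fit$model, test_clips)
    fold_models[[f]] <- fit$model
    fold_counts[[f]] <- ev$counts
    fold_rows[[f]] <- data.frame(fold = f, best_epoch = fit$best_epoch,
                                 ac = ev$metrics$ac, f1 = ev$metrics$f1,
                                 sn = ev$metrics$sn, sp = ev$metrics$sp,
                                 p = ev$metrics$p, auc = ev$auc)
    pooled_scores <- c(pooled_scores, ev$scores)
    pooled_labels <- c(pooled_labels, ev$labels)
    pooled_pred <- c(pooled_pred, ev$predicted)
    pooled_sent <- c(pooled_sent, ev$sentences)
  }
  per_fold <- do.call(rbind, fold_rows)
  agg <- lapply(c(ac = "ac", f1 = "f1", sn = "sn", sp = "sp", p = "p",
                  auc = "auc"),
                function(m) c(mean = mean(per_fold[[m]]),
                              sd = stats::sd(per_fold[[m]])))
  structure(list(
    fold_models = fold_models, per_fold = per_fold, summary = agg,
    cumulative_confusion = cumulative_confusion(fold_counts),
    pooled_roc = roc_curve_auc(pooled_scores, pooled_labels),
    per_sentence = per_sentence_accuracy(pooled_labels, pooled_pred,
                                         pooled_sent),
    folds = folds, mode = config$mode), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_result> mode=%s folds=%d\n", x$mode, nrow(x$per_fold)))
  for (m in names(s))
    cat(sprintf("  %-4s %.4f +/- %.4f\n", toupper(m), s[[m]]["mean"],
                s[[m]]["sd"]))
  cat(sprintf("  pooled AUC %.4f\n", x$pooled_roc$auc))
  invisible(x)
}
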