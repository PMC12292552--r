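test_that("compute_metrics reproduces direct formula arithmetic", {
  m <- compute_metrics(confusion_counts(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_equal(m$ac, 0.7)
  expect_equal(m$sn, 0.6)
  expect_equal(m$sp, 0.8)
  expect_equal(m$p, 0.75)
  expect_equal(m$f1, 2 * 0.6 * 0.75 / 1.35, tolerance = 1e-12)

  perfect <- compute_metrics(confusion_counts(tp = 5, tn = 7, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(ac = 1, sn = 1, sp = 1, p = 1, f1 = 1))

  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
  expect_warning(compute_metrics(confusion_counts(0, 5, 0, 0)), "zero")
})

test_that("metrics agree with resimulation from label/prediction lists", {
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(4:60, 1)
    labels <- sample(c("HC", "PD"), n, replace = TRUE)
    predicted <- sample(c("HC", "PD"), n, replace = TRUE)
    counts <- tally_confusion(labels, predicted)
    expect_equal(counts$tp + counts$tn + counts$fp + counts$fn, n)
    m <- suppressWarnings(compute_metrics(counts))
    # independent re-derivation from the raw lists
    expect_equal(m$ac, mean(labels == predicted), tolerance = 1e-12)
    if (any(labels == "PD"))
      expect_equal(m$sn, mean(predicted[labels == "PD"] == "PD"),
                   tolerance = 1e-12)
    if (any(labels == "HC"))
      expect_equal(m$sp, mean(predicted[labels == "HC"] == "HC"),
                   tolerance = 1e-12)
  }
})

test_that("cumulative confusion is the elementwise fold sum", {
  one <- confusion_counts(3, 4, 1, 2)
  five <- cumulative_confusion(rep(list(one), 5))
  expect_equal(unlist(five), c(tp = 15, tn = 20, fp = 5, fn = 10))
  set.seed(2)
  folds <- lapply(1:7, function(i)
    confusion_counts(sample(0:9, 1), sample(0:9, 1), sample(0:9, 1),
                     sample(0:9, 1)))
  total <- cumulative_confusion(folds)
  expect_equal(total$tp, Reduce(`+`, lapply(folds, `[[`, "tp")))
  expect_equal(total$tp + total$tn + total$fp + total$fn,
               sum(vapply(folds, function(f) f$tp + f$tn + f$fp + f$fn,
                          numeric(1))))
  expect_error(cumulative_confusion(list()), "at least one")
})

test_that("AUC equals brute-force pairwise concordance", {
  expect_equal(roc_curve_auc(c(0.9, 0.4, 0.6, 0.2),
                             c("PD", "PD", "HC", "HC"))$auc, 0.75)
  expect_equal(roc_curve_auc(c(0.9, 0.8, 0.2, 0.1),
                             c("PD", "PD", "HC", "HC"))$auc, 1)
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    labels <- c("PD", "HC", sample(c("HC", "PD"), n - 2, replace = TRUE))
    scores <- round(runif(n), 2)   # rounding forces occasional ties
    expect_equal(roc_curve_auc(scores, labels)$auc,
                 pairwise_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_curve_auc(runif(4), rep("PD", 4)), "both classes")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(6)
  labels <- sample(c("HC", "PD"), 2000, replace = TRUE)
  auc <- roc_curve_auc(runif(2000), labels)$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  labels <- sample(c("HC", "PD"), 60, replace = TRUE)
  scores <- runif(60)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("HC", "PD"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_curve_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("per-sentence accuracy matches independent group-by recomputation", {
  labels <- c("PD", "PD", "HC", "PD", "HC", "HC")
  predicted <- c("PD", "HC", "HC", "PD", "HC", "HC")
  sentences <- c("S1", "S1", "S1", "S2", "S2", "S2")
  tbl <- per_sentence_accuracy(labels, predicted, sentences)
  expect_equal(tbl$accuracy[tbl$sentence_id == "S1"], 2 / 3, tolerance = 1e-12)
  expect_equal(tbl$accuracy[tbl$sentence_id == "S2"], 1)
  expect_equal(tbl$sentence_id[1], "S2")  # sorted by accuracy descending

  all_right <- per_sentence_accuracy(labels, labels, sentences)
  expect_true(all(all_right$accuracy == 1))

  set.seed(4)
  n <- 200
  lab <- sample(c("HC", "PD"), n, replace = TRUE)
  pred <- sample(c("HC", "PD"), n, replace = TRUE)
  sid <- sample(sprintf("S%02d", 1:16), n, replace = TRUE)
  tbl2 <- per_sentence_accuracy(lab, pred, sid)
  for (s in unique(sid))
    expect_equal(tbl2$accuracy[tbl2$sentence_id == s],
                 sum(lab == pred & sid == s) / sum(sid == s),
                 tolerance = 1e-12)
})

test_that("make_folds balances speakers per class and partitions cleanly", {
  coh <- desk_cohort(n_per_class = 10, effect_size = 0, seed = 5)
  folds <- make_folds(coh, k = 5, seed = 1)
  spk_lab <- tapply(vapply(coh, `[[`, character(1), "label"),
                    vapply(coh, `[[`, character(1), "speaker_id"),
                    function(v) v[1])
  for (cls in c("HC", "PD")) {
    per_fold <- table(folds[names(spk_lab)[spk_lab == cls]])
    expect_true(all(per_fold == 2))  # 10 speakers over 5 folds
  }
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 20)
  # every speaker in exactly one fold is implied by the named-vector shape
  expect_equal(anyDuplicated(names(folds)), 0)
})

test_that("make_folds stays within one speaker of perfect stratification", {
  # unbalanced cohort: 11 HC + 12 PD speakers
  clips <- c(
    lapply(1:11, function(i) audio_clip(0.1, 100, sprintf("HC%02d", i),
                                        "HC", "S01")),
    lapply(1:12, function(i) audio_clip(0.1, 100, sprintf("PD%02d", i),
                                        "PD", "S01")))
  for (seed in 1:10) {
    folds <- make_folds(clips, k = 5, seed = seed)
    lab <- substr(names(folds), 1, 2)
    for (cls in c("HC", "PD")) {
      per_fold <- tabulate(folds[lab == cls], 5)
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }
  expect_error(make_folds(clips[c(1:3, 12:14)], k = 5), "at least k")
})

test_that("train_model guards leakage, honours epochs = 0 and the frozen flag", {
  clips <- desk_cohort(n_per_class = 10, effect_size = 0, seed = 5)[1:64]
  spk <- vapply(clips, `[[`, character(1), "speaker_id")
  train <- clips[spk %in% unique(spk)[1:2]]
  val <- clips[spk %in% unique(spk)[3]]
  enc <- make_tiny_encoder(16, 1, seed = 1)
  model <- supcon_model(enc, p = 8, seed = 1)

  expect_error(train_model(model, clips, clips[1], train_config()),
               "leakage")

  fit0 <- train_model(model, train, val, train_config(epochs = 0, seed = 2))
  expect_true(supconvoice:::tree_identical(fit0$model$encoder$params,
                                           model$encoder$params))
  expect_true(supconvoice:::tree_identical(fit0$model$classifier,
                                           model$classifier))

  frozen_cfg <- train_config(epochs = 2, initial_lr = 1e-2, seed = 3,
                             mode = "SUPCON", fine_tune_encoder = FALSE,
                             batch_size = 8)
  fitf <- train_model(model, train, val, frozen_cfg)
  expect_true(supconvoice:::tree_identical(fitf$model$encoder$params,
                                           model$encoder$params))
  expect_false(supconvoice:::tree_identical(fitf$model$classifier,
                                            model$classifier))
})

test_that("training is bit-reproducible from its seed", {
  clips <- desk_cohort(n_per_class = 10, effect_size = 2, seed = 11)[1:48]
  spk <- vapply(clips, `[[`, character(1), "speaker_id")
  train <- clips[spk != unique(spk)[1]]
  val <- clips[spk == unique(spk)[1]]
  run_once <- function() {
    model <- supcon_model(make_tiny_encoder(16, 1, seed = 4), p = 8, seed = 4)
    fit <- train_model(model, train, val,
                       train_config(epochs = 2, initial_lr = 1e-3, seed = 9,
                                    batch_size = 8, mode = "SUPCON"))
    predict_scores(fit$model, val)
  }
  expect_identical(run_once(), run_once())
})

test_that("training loss decreases on separable data", {
  clips <- desk_cohort(n_per_class = 10, effect_size = 2, seed = 11)
  spk <- vapply(clips, `[[`, character(1), "speaker_id")
  uniq <- unique(spk)
  train <- clips[spk %in% uniq[c(1:6, 11:16)]]
  val <- clips[spk %in% uniq[c(7, 17)]]
  model <- supcon_model(make_tiny_encoder(32, 1, seed = 2), seed = 2)
  fit <- train_model(model, train, val,
                     train_config(epochs = 6, initial_lr = 1e-3, seed = 5,
                                  patience = 6, mode = "SUPCON"))
  h <- fit$history
  expect_lt(h$train_total[6], h$train_total[1])
})
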