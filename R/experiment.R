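#' Build a standardized desk-scale cohort
#'
#' Convenience wrapper bundling the full input pipeline at the package's
#' desk-scale study conditions: synthesize a cohort, trim edge silence, and
#' standardize every clip. Defaults (16 kHz, 1.5-3 s utterances
#' standardized to 1.5 s) keep a full cross-validated training experiment
#' tractable on one CPU while retaining the high-band aspiration-noise cue;
#' see the methods vignette for the rationale.
#'
#' @param n_per_class Speakers per class (default 10).
#' @param effect_size Class-shift scale of [cohort_config()] (default 2).
#' @param seed Integer seed.
#' @param sample_rate Hz (default 16000).
#' @param duration_range Utterance duration bounds in seconds.
#' @param target_seconds Standardized length in seconds (default 1.5).
#' @param sentences_per_speaker Number of sentence types (default 16).
#' @return List of standardized [audio_clip()].
#' @export
build_desk_cohort <- function(n_per_class = 10, effect_size = 2, seed = 1,
                              sample_rate = 16000,
                              duration_range = c(1.5, 3),
                              target_seconds = 1.5,
                              sentences_per_speaker = 16) {
  coh <- make_cohort(cohort_config(
    n_speakers_per_class = n_per_class,
    sentences_per_speaker = sentences_per_speaker,
    duration_range = duration_range, effect_size = effect_size,
    sample_rate = sample_rate, seed = seed))
  pp <- preprocess_config(target_rate = sample_rate,
                          target_seconds = target_seconds,
                          lowpass_cutoff_range = c(0.125 * sample_rate,
                                                   0.4375 * sample_rate))
  lapply(coh$clips, function(cl) standardize(trim_silence(cl, pp), pp))
}

#' Run one desk-scale cross-validated training experiment
#'
#' Speaker-disjoint 80/20 split of the supplied standardized clips followed
#' by [run_cv_experiment()] with the tiny encoder. The training
#' hyperparameters default to the package's desk-scale settings (18 epochs,
#' learning rate 1e-3, patience 7); the protocol itself (stratified
#' speaker-independent k-fold, early stopping on a validation metric,
#' common held-out test set) is the full evaluation protocol.
#'
#' @param clips Standardized clips, e.g. from [build_desk_cohort()].
#' @param mode `"SUPCON"` or `"CE_ONLY"`.
#' @param seed Integer seed for split, folds, initialization and training.
#' @param epochs,initial_lr,patience Training-loop settings.
#' @param d,n_layers Tiny-encoder size (defaults 64 and 2).
#' @param k Folds (default 5).
#' @param test_fraction Held-out speaker fraction (default 0.2).
#' @return A `cv_result` (see [run_cv_experiment()]).
#' @export
run_desk_experiment <- function(clips, mode = c("SUPCON", "CE_ONLY"),
                                seed = 1, epochs = 18, initial_lr = 1e-3,
                                patience = 7, d = 64, n_layers = 2, k = 5,
                                test_fraction = 0.2) {
  mode <- match.arg(mode)
  parts <- split_train_test(clips, test_fraction, seed = seed)
  cfg <- train_config(epochs = epochs, initial_lr = initial_lr,
                      seed = seed, patience = patience, mode = mode)
  sr <- clips[[1]]$sample_rate
  factory <- function(s)
    supcon_model(make_tiny_encoder(d, n_layers, seed = s, sample_rate = sr),
                 seed = s)
  run_cv_experiment(parts$train, parts$test, factory, cfg, k = k)
}
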