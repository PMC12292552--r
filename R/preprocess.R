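#' Preprocessing configuration
#'
#' Parameters for standardizing raw recordings to the fixed model input:
#' target sampling rate and duration, the energy threshold for edge silence
#' trimming, and the train-only low-pass augmentation settings.
#'
#' @param target_rate Target sampling rate in Hz (default 16000).
#' @param target_seconds Standardized clip length in seconds (default 5).
#' @param trim_threshold_db Frames whose RMS lies more than this many dB
#'   below the clip's maximum frame RMS count as silence (default 40).
#' @param augment_probability Probability of applying the low-pass
#'   augmentation to a training clip (default 0.5).
#' @param lowpass_cutoff_range Cutoff bounds in Hz for the augmentation
#'   filter, drawn uniformly (default `c(2000, 7000)`).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 16000, target_seconds = 5,
                              trim_threshold_db = 40,
                              augment_probability = 0.5,
                              lowpass_cutoff_range = c(2000, 7000)) {
  if (target_rate <= 0 || target_seconds <= 0)
    stopf("target_rate and target_seconds must be positive")
  if (augment_probability < 0 || augment_probability > 1)
    stopf("augment_probability must lie in [0, 1]")
  if (any(lowpass_cutoff_range <= 0) ||
      any(lowpass_cutoff_range >= target_rate / 2))
    stopf("lowpass_cutoff_range must lie within (0, target_rate/2)")
  structure(list(target_rate = target_rate, target_seconds = target_seconds,
                 trim_threshold_db = trim_threshold_db,
                 augment_probability = augment_probability,
                 lowpass_cutoff_range = as.numeric(lowpass_cutoff_range)),
            class = "preprocess_config")
}

# Frame RMS over 25 ms windows with a 10 ms hop.
frame_rms <- function(x, fs, frame_s = 0.025, hop_s = 0.010) {
  flen <- max(1L, round(frame_s * fs))
  hop <- max(1L, round(hop_s * fs))
  starts <- seq(1L, max(1L, length(x) - flen + 1L), by = hop)
  rms <- vapply(starts, function(s)
    sqrt(mean(x[s:min(s + flen - 1L, length(x))]^2)), numeric(1))
  list(starts = starts, flen = flen, rms = rms)
}

#' Trim leading and trailing silence
#'
#' Removes leading and trailing frames whose RMS falls more than
#' `trim_threshold_db` below the clip's maximum frame RMS. Interior silent
#' gaps are preserved; metadata is carried through.
#'
#' @param clip An [audio_clip()].
#' @param config A [preprocess_config()].
#' @return The trimmed [audio_clip()].
#' @export
trim_silence <- function(clip, config = preprocess_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  fr <- frame_rms(clip$samples, clip$sample_rate)
  thr <- max(fr$rms) * 10^(-config$trim_threshold_db / 20)
  keep <- which(fr$rms >= thr)
  if (length(keep) == 0L || max(fr$rms) == 0)
    stopf("clip is entirely below the trim threshold (empty after trim)")
  i0 <- fr$starts[min(keep)]
  i1 <- min(fr$starts[max(keep)] + fr$flen - 1L, length(clip$samples))
  audio_clip(clip$samples[i0:i1], clip$sample_rate, clip$speaker_id,
             clip$label, clip$sentence_id)
}

#' Standardize a clip to the fixed model input
#'
#' Resamples to `target_rate` (polyphase, via [signal::resample()]), then
#' zero-pads at the end or truncates to the first `target_seconds` so the
#' output has exactly `target_rate * target_seconds` samples.
#'
#' @inheritParams trim_silence
#' @return The standardized [audio_clip()].
#' @export
standardize <- function(clip, config = preprocess_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  if (clip$sample_rate != config$target_rate) {
    p <- as.integer(config$target_rate); q <- as.integer(clip$sample_rate)
    g <- gcd2(p, q)
    x <- as.numeric(signal::resample(x, p / g, q / g))
  }
  n_target <- round(config$target_rate * config$target_seconds)
  if (length(x) >= n_target) x <- x[seq_len(n_target)]
  else x <- c(x, numeric(n_target - length(x)))
  audio_clip(pmin(pmax(x, -1), 1), config$target_rate, clip$speaker_id,
             clip$label, clip$sentence_id)
}

#' Train-only low-pass augmentation
#'
#' With probability `augment_probability`, applies a 4th-order Butterworth
#' low-pass filter (zero-phase, [signal::filtfilt()]) with a cutoff drawn
#' uniformly from `lowpass_cutoff_range`; otherwise returns the clip
#' unchanged. Output length always equals input length. Intended only for
#' training data; the training loader is the sole call site in the pipeline.
#'
#' @inheritParams trim_silence
#' @param seed Integer seed controlling both the coin flip and the cutoff.
#' @return An [audio_clip()] of identical length.
#' @export
augment_lowpass <- function(clip, config = preprocess_config(), seed = 1) {
  stopifnot(inherits(clip, "audio_clip"))
  with_seed(combine_seed(seed, clip$speaker_id, clip$sentence_id, "aug"), {
    if (stats::runif(1) >= config$augment_probability) return(clip)
    cutoff <- stats::runif(1, config$lowpass_cutoff_range[1],
                           config$lowpass_cutoff_range[2])
    bf <- signal::butter(4, cutoff / (clip$sample_rate / 2), type = "low")
    y <- as.numeric(signal::filtfilt(bf, clip$samples))
    audio_clip(pmin(pmax(y, -1), 1), clip$sample_rate, clip$speaker_id,
               clip$label, clip$sentence_id)
  })
}

clip_speakers <- function(clips) vapply(clips, `[[`, character(1), "speaker_id")
clip_labels <- function(clips) vapply(clips, `[[`, character(1), "label")

#' Speaker-disjoint train/test split
#'
#' Splits at the speaker level, stratified by class: within each class the
#' speakers are shuffled deterministically by `seed` and the closest integer
#' number to `test_fraction` of them (at least one) is held out. No speaker
#' ever appears on both sides.
#'
#' @param clips List of [audio_clip()].
#' @param test_fraction Fraction of speakers per class to hold out
#'   (default 0.2).
#' @param seed Integer seed.
#' @return A list with `train` and `test` clip lists plus the speaker sets
#'   `train_speakers` / `test_speakers`.
#' @export
split_train_test <- function(clips, test_fraction = 0.2, seed = 1) {
  spk <- clip_speakers(clips)
  lab <- clip_labels(clips)
  spk_lab <- tapply(lab, spk, function(v) v[1])
  test_spk <- character(0)
  for (cls in unique(spk_lab)) {
    ids <- sort(names(spk_lab)[spk_lab == cls])
    if (length(ids) < 2L)
      stopf("need >= 2 speakers per class for a speaker-disjoint split")
    n_test <- max(1L, min(length(ids) - 1L, round(test_fraction * length(ids))))
    perm <- with_seed(combine_seed(seed, cls, "split"), sample(ids))
    test_spk <- c(test_spk, perm[seq_len(n_test)])
  }
  in_test <- spk %in% test_spk
  list(train = clips[!in_test], test = clips[in_test],
       train_speakers = sort(unique(spk[!in_test])),
       test_speakers = sort(test_spk))
}
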