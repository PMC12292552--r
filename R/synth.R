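#' Cohort configuration for the synthetic voice generator
#'
#' Defines a two-class (healthy control vs Parkinson's disease) synthetic
#' cohort: number of speakers per class, a fixed set of repeated sentence
#' types shared by all speakers, a duration range, and a single nonnegative
#' `effect_size` knob that scales every class-discriminative acoustic shift
#' (jitter, shimmer, aspiration noise up; F0 range, intensity, speech rate
#' down for the PD class). At `effect_size = 0` the two classes are drawn
#' from identical distributions.
#'
#' @param n_speakers_per_class Speakers per class (>= 1).
#' @param sentences_per_speaker Number of repeated sentence types (default 16).
#' @param duration_range Length-2 numeric, utterance duration bounds in
#'   seconds (default `c(2, 8)`).
#' @param effect_size Nonnegative scalar scaling the PD acoustic shifts.
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   this configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_speakers_per_class = 56, sentences_per_speaker = 16,
                          duration_range = c(2, 8), effect_size = 1,
                          sample_rate = 16000, seed = 1) {
  if (n_speakers_per_class < 1 || sentences_per_speaker < 1)
    stopf("counts must be >= 1")
  if (length(duration_range) != 2L || duration_range[1] >= duration_range[2])
    stopf("duration_range must be an increasing pair")
  if (sample_rate <= 0) stopf("sample_rate must be positive")
  if (effect_size < 0) stopf("effect_size must be nonnegative")
  structure(list(n_speakers_per_class = as.integer(n_speakers_per_class),
                 sentences_per_speaker = as.integer(sentences_per_speaker),
                 duration_range = as.numeric(duration_range),
                 effect_size = as.numeric(effect_size),
                 sample_rate = as.numeric(sample_rate),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Class-conditional priors for speaker-level phonatory/prosodic parameters.
# Healthy-control centers sit at values typical for sustained speech
# (jitter ~0.6%, shimmer ~4%); effect_size e shifts the PD log-means.
# At e = 0 both classes share one distribution.
sample_speaker_profile <- function(speaker_id, class_label, effect_size,
                                   sample_rate) {
  e <- if (class_label == "PD") effect_size else 0
  profile <- list(
    speaker_id = speaker_id,
    class_label = class_label,
    sample_rate = sample_rate,
    base_f0 = exp(stats::rnorm(1, log(140), 0.22)),
    f0_range = max(0.5, stats::rnorm(1, 4 - 1.0 * e, 1)),
    base_jitter = min(0.5, exp(stats::rnorm(1, log(0.006), 0.35) + 0.4 * e)),
    base_shimmer = min(0.6, exp(stats::rnorm(1, log(0.04), 0.30) + 0.35 * e)),
    breath_noise_level = min(0.8, exp(stats::rnorm(1, log(0.02), 0.40) + 0.5 * e)),
    intensity = min(0.95, 0.75 * exp(stats::rnorm(1, 0, 0.10) - 0.15 * e)),
    speech_rate = max(1.5, stats::rnorm(1, 3.5, 0.4) - 0.25 * e))
  class(profile) <- "speaker_profile"
  profile
}

validate_profile <- function(p) {
  stopifnot(p$base_f0 > 0, p$base_jitter >= 0, p$base_jitter < 1,
            p$base_shimmer >= 0, p$base_shimmer < 1, p$speech_rate > 0,
            p$sample_rate > 0)
  invisible(p)
}

# Second-order resonator cascade (source-filter vocal tract model).
formant_filter <- function(x, formants, bandwidths, fs) {
  for (k in seq_along(formants)) {
    f <- min(formants[k], 0.45 * fs)
    r <- exp(-pi * bandwidths[k] / fs)
    theta <- 2 * pi * f / fs
    a <- c(1, -2 * r * cos(theta), r^2)
    x <- as.numeric(signal::filter(1 - r, a, x))
  }
  x
}

# One voiced segment: glottal pulse train at a perturbed F0 through a
# formant cascade, plus aspiration noise. Pulses are placed with
# fractional-sample linear interpolation so cycle-length perturbation is
# not dominated by sample quantization.
synth_voiced_segment <- function(n, profile, formants, f0_contour) {
  fs <- profile$sample_rate
  exc <- numeric(n)
  t_pos <- 1
  while (t_pos < n) {
    f0_here <- f0_contour(t_pos / fs)
    period <- (fs / f0_here) * (1 + profile$base_jitter * stats::rnorm(1))
    period <- max(fs / 600, min(fs / 50, period))
    amp <- max(0.05, 1 + profile$base_shimmer * stats::rnorm(1))
    i0 <- floor(t_pos); frac <- t_pos - i0
    if (i0 >= 1 && i0 <= n) exc[i0] <- exc[i0] + amp * (1 - frac)
    if (i0 + 1 <= n) exc[i0 + 1] <- exc[i0 + 1] + amp * frac
    t_pos <- t_pos + period
  }
  y <- formant_filter(exc, formants, rep(90, length(formants)), fs)
  peak <- max(abs(y))
  if (peak > 0) y <- y / peak
  y <- y + stats::rnorm(n) * profile$breath_noise_level
  # 10 ms raised-cosine onset/offset ramps
  nr <- min(n %/% 2, round(0.01 * fs))
  if (nr > 1) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    y[seq_len(nr)] <- y[seq_len(nr)] * ramp
    y[(n - nr + 1):n] <- y[(n - nr + 1):n] * rev(ramp)
  }
  y
}

# Vowel-like formant targets (Hz); each synthetic "sentence" is a fixed
# vowel sequence derived from the sentence id, shared across speakers.
.vowel_formants <- list(
  c(730, 1090, 2440),  # /a/
  c(270, 2290, 3010),  # /i/
  c(300,  870, 2240),  # /u/
  c(530, 1840, 2480),  # /e/
  c(570,  840, 2410))  # /o/

#' Synthesize one utterance for a speaker profile
#'
#' Source-filter synthesis: a glottal pulse train at the speaker's perturbed
#' fundamental frequency (cycle-to-cycle jitter on period, shimmer on
#' amplitude) is passed through a cascade of vowel-formant resonators, with
#' aspiration noise added, in syllable-length voiced segments alternating
#' with short pauses at the speaker's speech rate. The waveform is a
#' deterministic function of `(profile, sentence_id, duration, seed)`.
#'
#' @param profile A speaker profile from [make_cohort()]'s sampler (or built
#'   manually with the same fields).
#' @param sentence_id Sentence/utterance type identifier; fixes the vowel
#'   sequence and intonation phase so all speakers share sentence structure.
#' @param duration Utterance duration in seconds (> 0).
#' @param seed Integer seed.
#' @return An [audio_clip()] with amplitude in `[-1, 1]` and exactly
#'   `round(duration * sample_rate)` samples.
#' @export
synth_utterance <- function(profile, sentence_id, duration, seed = 1) {
  if (!is.numeric(duration) || duration <= 0)
    stopf("duration must be positive (got %s)", format(duration))
  validate_profile(profile)
  fs <- profile$sample_rate
  n_total <- round(duration * fs)
  rng <- combine_seed(seed, profile$speaker_id, sentence_id,
                      round(duration * 1000))
  with_seed(rng, {
    n_syl <- max(1L, round(duration * profile$speech_rate * 0.85))
    sent_h <- str_hash31(sentence_id)
    # fixed 64-syllable vowel pattern per sentence, shared by all speakers
    vowels <- rep_len(with_seed(sent_h, sample.int(length(.vowel_formants),
                                                   64L, replace = TRUE)),
                      n_syl)
    intoning <- with_seed(sent_h + 1L, stats::runif(2, c(0.4, 0), c(1.2, 2 * pi)))
    f0_contour <- local({
      base <- profile$base_f0; range_st <- profile$f0_range
      rate_hz <- intoning[1]; phase <- intoning[2]
      function(t) base * 2^((range_st / 2) * sin(2 * pi * rate_hz * t + phase) / 12)
    })
    syl_len <- round(fs / profile$speech_rate)
    v_len <- round(0.75 * syl_len)
    p_len <- syl_len - v_len
    out <- numeric(0)
    for (s in seq_len(n_syl)) {
      seg <- synth_voiced_segment(v_len, profile,
                                  .vowel_formants[[vowels[s]]], f0_contour)
      out <- c(out, seg, numeric(p_len))
    }
    if (length(out) < n_total) out <- c(out, numeric(n_total - length(out)))
    out <- out[seq_len(n_total)]
    # level calibration: vocal intensity is an energy (SPL-like) quantity,
    # so scale to a target RMS of 0.2 * intensity, with a clipping guard
    rms <- sqrt(mean(out^2))
    if (rms > 0) out <- out * (0.2 * profile$intensity / rms)
    peak <- max(abs(out))
    if (peak > 0.98) out <- out * (0.98 / peak)
    audio_clip(out, fs, speaker_id = profile$speaker_id,
               label = profile$class_label, sentence_id = sentence_id)
  })
}

#' Generate a labeled synthetic voice cohort
#'
#' Draws speaker-level acoustic parameters from class-conditional priors
#' (shifted for the PD class by `effect_size`), then synthesizes every
#' speaker reading the same set of sentence types with durations sampled
#' uniformly from `duration_range`. The result is bit-reproducible from the
#' configuration alone.
#'
#' @param config A [cohort_config()].
#' @return A list with class `voice_cohort`: `clips` (list of
#'   [audio_clip()]), `metadata` (data.frame with columns `speaker_id`,
#'   `label`, `sentence_id`, `duration_s`), `profiles`, and `config`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_speakers_per_class
  sentences <- sprintf("S%02d", seq_len(config$sentences_per_speaker))
  profiles <- with_seed(combine_seed(config$seed, "profiles"), {
    p <- list()
    for (cls in c("HC", "PD")) {
      for (i in seq_len(n)) {
        id <- sprintf("%s%03d", cls, i)
        p[[id]] <- sample_speaker_profile(id, cls, config$effect_size,
                                          config$sample_rate)
      }
    }
    p
  })
  durations <- with_seed(combine_seed(config$seed, "durations"),
    stats::runif(2L * n * length(sentences),
                 config$duration_range[1], config$duration_range[2]))
  clips <- vector("list", length(durations))
  meta <- vector("list", length(durations))
  k <- 0L
  for (id in names(profiles)) {
    for (s in sentences) {
      k <- k + 1L
      clips[[k]] <- synth_utterance(profiles[[id]], s, durations[k],
                                    seed = config$seed)
      meta[[k]] <- data.frame(speaker_id = id,
                              label = profiles[[id]]$class_label,
                              sentence_id = s, duration_s = durations[k],
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(clips = clips, metadata = do.call(rbind, meta),
                 profiles = profiles, config = config),
            class = "voice_cohort")
}

#' @export
print.voice_cohort <- function(x, ...) {
  cat(sprintf("<voice_cohort> %d clips | %d speakers | %d sentence types | effect_size=%g\n",
              length(x$clips), length(x$profiles),
              x$config$sentences_per_speaker, x$config$effect_size))
  invisible(x)
}

#' Write a cohort to disk as WAV files plus a metadata CSV
#'
#' @param cohort A `voice_cohort` from [make_cohort()].
#' @param dir Output directory (created if absent).
#' @return The metadata data.frame (with a `path` column), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "voice_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$metadata
  meta$path <- sprintf("%s_%s.wav", meta$speaker_id, meta$sentence_id)
  for (i in seq_along(cohort$clips)) {
    clip <- cohort$clips[[i]]
    write_wav(clip$samples, clip$sample_rate, file.path(dir, meta$path[i]))
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `metadata.csv` and the WAV files.
#' @return A list of [audio_clip()] with metadata attached.
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i)
    read_wav(file.path(dir, meta$path[i]), speaker_id = meta$speaker_id[i],
             label = meta$label[i], sentence_id = meta$sentence_id[i]))
}
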