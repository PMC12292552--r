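# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (no vectorization, no stabilization) so they can
# serve as brute-force references.

# Naive double-loop supervised contrastive loss, with optional explicit
# top-k hard-negative scaling of the denominator.
naive_supcon <- function(z, labels, tau, hard_scale = 1, hard_k = 0) {
  n <- nrow(z)
  total <- 0
  for (i in seq_len(n)) {
    P <- setdiff(which(labels == labels[i]), i)
    A <- setdiff(seq_len(n), i)
    if (length(P) == 0) next
    w <- rep(1, n)
    negs <- setdiff(A, P)
    if (hard_scale > 1 && hard_k > 0 && length(negs) > 0) {
      sims <- vapply(negs, function(a) sum(z[i, ] * z[a, ]), numeric(1))
      ord <- negs[order(-sims, negs)]
      w[ord[seq_len(min(hard_k, length(ord)))]] <- hard_scale
    }
    den <- 0
    for (a in A) den <- den + w[a] * exp(sum(z[i, ] * z[a, ]) / tau)
    for (p in P)
      total <- total - (1 / length(P)) *
        log(exp(sum(z[i, ] * z[p, ]) / tau) / den)
  }
  total
}

random_projection_batch <- function(n, p, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p)
  z <- z / sqrt(rowSums(z^2))
  list(z = z, labels = sample(c("HC", "PD"), n, replace = TRUE))
}

# Brute-force AUC as the Mann-Whitney pairwise concordance statistic.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == "PD"]
  neg <- scores[labels == "HC"]
  conc <- 0
  for (a in pos) for (b in neg)
    conc <- conc + if (a > b) 1 else if (a == b) 0.5 else 0
  conc / (length(pos) * length(neg))
}

# Autocorrelation-based pitch tracker, independent of the synthesis model:
# frame-wise F0 from the lag of the autocorrelation peak, then
# cycle-to-cycle relative period perturbation as the jitter estimate.
measure_jitter <- function(x, fs, f0_lo = 60, f0_hi = 400,
                           frame_s = 0.04, hop_s = 0.02) {
  flen <- round(frame_s * fs)
  hop <- round(hop_s * fs)
  lag_lo <- floor(fs / f0_hi)
  lag_hi <- ceiling(fs / f0_lo)
  periods <- c()
  starts <- seq(1, length(x) - flen, by = hop)
  for (s in starts) {
    seg <- x[s:(s + flen - 1)]
    if (sqrt(mean(seg^2)) < 0.02) next
    seg <- seg - mean(seg)
    ac <- stats::acf(seg, lag.max = lag_hi, plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    window <- ac[(lag_lo + 1):(lag_hi + 1)]
    if (max(window) < 0.3 * ac[1]) next
    periods <- c(periods, lag_lo + which.max(window) - 1)
  }
  if (length(periods) < 3) return(NA_real_)
  # drop octave-jump artifacts before differencing
  med <- stats::median(periods)
  periods <- periods[abs(periods - med) < 0.3 * med]
  if (length(periods) < 3) return(NA_real_)
  mean(abs(diff(periods))) / mean(periods)
}

# Small standardized synthetic cohort shared by training-protocol tests;
# built once per test run.
desk_cohort <- local({
  cache <- new.env()
  function(n_per_class = 10, effect_size = 2, seed = 11, fs = 4000,
           target_seconds = 2) {
    key <- paste(n_per_class, effect_size, seed, fs, target_seconds,
                 sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    coh <- make_cohort(cohort_config(
      n_speakers_per_class = n_per_class, sentences_per_speaker = 16,
      duration_range = c(1.5, 3), effect_size = effect_size,
      sample_rate = fs, seed = seed))
    pp <- preprocess_config(target_rate = fs, target_seconds = target_seconds,
                            lowpass_cutoff_range = c(0.125 * fs, 0.4375 * fs))
    std <- lapply(coh$clips, function(cl) standardize(trim_silence(cl, pp), pp))
    cache[[key]] <- std
    std
  }
})
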