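# Mel filterbank matrix: n_mels triangular filters on the power spectrum.
mel_filterbank <- function(n_mels, nfft, fs) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(fs / 2), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bins <- floor((nfft + 1) * hz_pts / fs) + 1
  fb <- matrix(0, n_mels, nfft %/% 2 + 1)
  for (m in seq_len(n_mels)) {
    lo <- bins[m]; mid <- bins[m + 1]; hi <- bins[m + 2]
    if (mid > lo) fb[m, lo:mid] <- (seq(lo, mid) - lo) / (mid - lo)
    if (hi > mid) fb[m, mid:hi] <- (hi - seq(mid, hi)) / (hi - mid)
  }
  fb
}

# Orthonormal DCT-II basis (n_out x n_in).
dct_basis <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  n <- seq_len(n_in) - 1
  basis <- sqrt(2 / n_in) * cos(outer(k, n, function(k, n)
    pi * (n + 0.5) * k / n_in))
  basis[1, ] <- basis[1, ] / sqrt(2)
  basis
}

# Delta (regression) coefficients over a +/- width frame window,
# edge frames replicated.
delta_features <- function(c_mat, width = 2) {
  n <- nrow(c_mat)
  den <- 2 * sum((seq_len(width))^2)
  idx <- function(i) pmin(pmax(i, 1), n)
  d <- matrix(0, n, ncol(c_mat))
  for (w in seq_len(width))
    d <- d + w * (c_mat[idx(seq_len(n) + w), , drop = FALSE] -
                    c_mat[idx(seq_len(n) - w), , drop = FALSE])
  d / den
}

mfcc_frames <- function(x, fs, frame_s = 0.025, hop_s = 0.005, n_ceps = 13,
                        n_mels = 26, energy_floor = 1e-10) {
  flen <- round(frame_s * fs)
  hop <- round(hop_s * fs)
  if (length(x) < flen) stopf("clip shorter than one MFCC frame")
  starts <- seq(1L, length(x) - flen + 1L, by = hop)
  nfft <- 2^ceiling(log2(flen))
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))
  fb <- mel_filterbank(n_mels, nfft, fs)
  dct <- dct_basis(n_ceps, n_mels)
  frames <- matrix(0, length(starts), n_ceps)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + flen - 1L)] * win
    spec <- abs(stats::fft(c(seg, numeric(nfft - flen))))^2
    melE <- pmax(fb %*% spec[seq_len(nfft %/% 2 + 1)], energy_floor)
    frames[i, ] <- as.numeric(dct %*% log(melE))
  }
  frames
}

#' Utterance-level 39-dimensional MFCC vector
#'
#' Mel-frequency cepstral coefficients over Hamming-windowed 25 ms frames
#' with a 5 ms shift: 13 cepstral coefficients (including the 0th) plus
#' first and second temporal derivatives per frame, averaged over frames to
#' a single order-invariant 39-dimensional utterance vector. A log-energy
#' floor of 1e-10 keeps silent (zero-padded) frames finite.
#'
#' @param clip A standardized [audio_clip()].
#' @return Numeric vector of length 39 with attribute
#'   `feature_set = "MFCC"`.
#' @export
mfcc_utterance_vector <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  c0 <- mfcc_frames(clip$samples, clip$sample_rate)
  d1 <- delta_features(c0)
  d2 <- delta_features(d1)
  out <- c(colMeans(c0), colMeans(d1), colMeans(d2))
  attr(out, "feature_set") <- "MFCC"
  attr(out, "n_frames") <- nrow(c0)
  out
}

#' Ingest a precomputed eGeMAPS feature table
#'
#' The 88-functional extended Geneva minimalistic acoustic parameter set is
#' produced by an external extractor (openSMILE eGeMAPSv02); this operation
#' validates and joins it rather than recomputing the feature math. The
#' table must contain an id column plus exactly 88 numeric feature columns;
#' any other count is a schema error and non-finite entries are a data
#' error naming the offending rows.
#'
#' @param table data.frame with the clip id column and 88 feature columns.
#' @param id_col Name of the id column (default `"id"`; falls back to the
#'   first non-numeric column).
#' @return Numeric matrix (`n x 88`) with row names from the id column and
#'   attribute `feature_set = "eGeMAPS"`.
#' @export
ingest_egemaps <- function(table, id_col = "id") {
  stopifnot(is.data.frame(table))
  if (!id_col %in% names(table)) {
    nonnum <- names(table)[!vapply(table, is.numeric, logical(1))]
    if (length(nonnum) == 0L) stopf("no id column found in eGeMAPS table")
    id_col <- nonnum[1]
  }
  feat_cols <- setdiff(names(table), id_col)
  if (length(feat_cols) != 88L)
    stopf("eGeMAPS schema error: expected exactly 88 feature columns, got %d",
          length(feat_cols))
  if (!all(vapply(table[feat_cols], is.numeric, logical(1))))
    stopf("eGeMAPS schema error: all 88 feature columns must be numeric")
  m <- as.matrix(table[feat_cols])
  bad <- which(!apply(m, 1, function(r) all(is.finite(r))))
  if (length(bad) > 0)
    stopf("eGeMAPS data error: non-finite values in rows %s",
          paste(utils::head(bad, 10), collapse = ", "))
  rownames(m) <- as.character(table[[id_col]])
  attr(m, "feature_set") <- "eGeMAPS"
  m
}
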