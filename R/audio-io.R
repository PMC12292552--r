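#' Construct an audio clip
#'
#' The unit of all processing: a mono waveform in `[-1, 1]` with its sample
#' rate and the study metadata (speaker, class label, sentence id).
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param speaker_id Speaker identifier (string).
#' @param label Class label, one of `"HC"` or `"PD"`.
#' @param sentence_id Utterance/sentence identifier (string).
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, speaker_id = NA_character_,
                       label = NA_character_, sentence_id = NA_character_) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stopf("samples must be a non-empty numeric vector")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stopf("sample_rate must be positive")
  if (!is.na(label) && !label %in% c("HC", "PD"))
    stopf("label must be 'HC' or 'PD' (got '%s')", label)
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         speaker_id = as.character(speaker_id), label = as.character(label),
         sentence_id = as.character(sentence_id)),
    class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.2f s @ %g Hz | speaker=%s label=%s sentence=%s\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              x$speaker_id, x$label, x$sentence_id))
  invisible(x)
}

clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' Write a mono/stereo PCM16 WAV file
#'
#' Minimal RIFF/WAVE writer for 16-bit PCM. Samples are clipped to `[-1, 1]`
#' before quantization.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  x <- as.matrix(samples)
  n_chan <- ncol(x)
  x <- pmin(pmax(x, -1), 1)
  pcm <- as.integer(round(x * 32767))
  # interleave channels
  pcm <- as.vector(t(matrix(pcm, ncol = n_chan)))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(n_chan, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * n_chan * 2L, con, size = 4, endian = "little")
  writeBin(n_chan * 2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Reads 16- or 24-bit PCM RIFF/WAVE. Stereo input is downmixed to mono by
#' channel averaging.
#'
#' @param path WAV file path.
#' @param ... Metadata fields passed to [audio_clip()] (`speaker_id`, `label`,
#'   `sentence_id`).
#' @return An [audio_clip()].
#' @export
read_wav <- function(path, ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stopf("%s: not a RIFF file", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stopf("%s: not a WAVE file", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_chan = sum(as.integer(raw[3:4]) * c(1, 256)),
        rate = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stopf("%s: missing fmt/data chunk", path)
  if (fmt$audio_format != 1L) stopf("%s: only PCM WAV supported", path)
  if (fmt$bits == 16L) {
    x <- readBin(dat, "integer", length(dat) / 2L, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(dat), nrow = 3L)
    v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else stopf("%s: unsupported bit depth %d", path, fmt$bits)
  if (fmt$n_chan > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$n_chan))
  }
  audio_clip(x, fmt$rate, ...)
}
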