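# Audio containers and WAV (RIFF) input/output.
#
# Clips are full-scale normalized: samples live in [-1, 1] regardless of the
# on-disk encoding, so every downstream index sees the same amplitude
# convention. Integer PCM is rescaled by the type's maximum magnitude
# (2^15 for 16-bit, 2^23 for 24-bit).

#' Construct an audio clip
#'
#' An `audio_clip` is a uniformly sampled, full-scale-normalized waveform:
#' a numeric vector (mono) or an n-by-C matrix (one column per channel)
#' together with its sample rate. All samples must be finite and have
#' magnitude at most 1.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param sample_rate Sampling rate in Hz (positive).
#' @return An object of class `audio_clip` with fields `samples`,
#'   `sample_rate` and `duration_s`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 440 * seq(0, 1, length.out = 8000)), 8000)
#' clip$duration_s
#' @export
audio_clip <- function(samples, sample_rate) {
  if (is.matrix(samples) && ncol(samples) == 1L) samples <- drop(samples)
  if (!is.numeric(samples) || NROW(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector or matrix")
  if (!all(is.finite(samples)))
    stop("audio samples must all be finite")
  if (max(abs(samples)) > 1 + 1e-9)
    stop("audio samples exceed full scale; normalize to [-1, 1] first")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  structure(
    list(samples = samples, sample_rate = sample_rate,
         duration_s = NROW(samples) / sample_rate),
    class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d channel(s), %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), n_samples(x), x$sample_rate, x$duration_s))
  invisible(x)
}

#' Number of sample frames in a clip
#' @param clip An [audio_clip()].
#' @return Integer number of frames (per channel).
#' @export
n_samples <- function(clip) NROW(clip$samples)

#' Number of channels in a clip
#' @param clip An [audio_clip()].
#' @return Integer channel count.
#' @export
n_channels <- function(clip) NCOL(clip$samples)

read_chunk_id <- function(con) {
  b <- readBin(con, "raw", n = 4L)
  if (length(b) < 4L) return(NULL)
  rawToChar(b)
}

#' Read a WAV file
#'
#' Parses a RIFF/WAVE file with 16-bit PCM, 24-bit PCM or 32-bit IEEE float
#' encoding, mono or stereo, and returns a canonical [audio_clip()] with
#' samples rescaled to \[-1, 1\]. Any other encoding (including WAVE_FORMAT_
#' EXTENSIBLE) raises an unsupported-format error.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_clip()]; stereo files give an n-by-2 sample matrix.
#' @seealso [write_wav()], [to_mono()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    stop("cannot read WAV file (no such file): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(read_chunk_id(con), "RIFF"))
    stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!identical(read_chunk_id(con), "WAVE"))
    stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- read_chunk_id(con)
    if (is.null(id)) break
    sz <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(sz) < 1L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", n = sz)
      if (length(body) < 16L) stop("truncated WAV fmt chunk: ", path)
      u16 <- function(i) sum(as.integer(body[i + 0:1]) * c(1L, 256L))
      u32 <- function(i) sum(as.numeric(body[i + 0:3]) * 256^(0:3))
      fmt <- list(audio_format = u16(1L), n_channels = u16(3L),
                  sample_rate = u32(5L), bits = u16(15L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", n = sz)
      if (length(data_raw) < sz)
        stop("truncated WAV data chunk in ", path,
             " (expected ", sz, " bytes, got ", length(data_raw), ")")
    } else {
      seek(con, sz, origin = "current")
    }
    if (sz %% 2L == 1L) seek(con, 1L, origin = "current")  # word alignment
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw)) stop("WAV file has no data chunk: ", path)

  x <- decode_pcm(data_raw, fmt, path)
  if (length(x) %% fmt$n_channels != 0L)
    stop("WAV sample count is not a multiple of the channel count: ", path)
  if (fmt$n_channels > 1L)
    x <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  audio_clip(x, fmt$sample_rate)
}

decode_pcm <- function(data_raw, fmt, path) {
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    v <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                 size = 2L, signed = TRUE, endian = "little")
    v / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n = length(data_raw) %/% 4L, size = 4L,
            endian = "little")
  } else {
    stop("unsupported WAV encoding in ", path, " (format tag ",
         fmt$audio_format, ", ", fmt$bits,
         " bits); supported: PCM16, PCM24, float32")
  }
}

#' Write a clip to a WAV file
#'
#' Encodes an [audio_clip()] as RIFF/WAVE. Integer encodings quantize with
#' rounding, so a write/read round trip reproduces samples within one least
#' significant bit of the chosen depth; `"float32"` round-trips within
#' single-precision rounding.
#'
#' @param clip An [audio_clip()].
#' @param path Output path.
#' @param format One of `"pcm16"`, `"pcm24"`, `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, format = c("pcm16", "pcm24", "float32")) {
  format <- match.arg(format)
  x <- clip$samples
  if (is.matrix(x)) x <- as.vector(t(x))  # interleave channels
  nch <- n_channels(clip)
  sr <- round(clip$sample_rate)

  enc <- switch(format,
    pcm16 = list(tag = 1L, bits = 16L,
                 bytes = writeBin_int(pmin(pmax(round(x * 32768), -32768), 32767), 2L)),
    pcm24 = list(tag = 1L, bits = 24L,
                 bytes = int24_bytes(pmin(pmax(round(x * 2^23), -2^23), 2^23 - 1))),
    float32 = list(tag = 3L, bits = 32L, bytes = float32_bytes(x)))

  data_len <- length(enc$bytes)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w16(enc$tag); w16(nch); w32(sr)
  w32(sr * nch * enc$bits %/% 8L)          # byte rate
  w16(nch * enc$bits %/% 8L); w16(enc$bits)
  writeChar("data", con, eos = NULL)
  w32(data_len)
  writeBin(enc$bytes, con)
  invisible(path)
}

writeBin_int <- function(v, size) {
  rc <- rawConnection(raw(0L), "wb")
  on.exit(close(rc))
  writeBin(as.integer(v), rc, size = size, endian = "little")
  rawConnectionValue(rc)
}

int24_bytes <- function(v) {
  v <- ifelse(v < 0, v + 2^24, v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256))
}

float32_bytes <- function(x) {
  rc <- rawConnection(raw(0L), "wb")
  on.exit(close(rc))
  writeBin(x, rc, size = 4L, endian = "little")
  rawConnectionValue(rc)
}

#' Mix a clip down to mono
#'
#' Channels are averaged per frame (arithmetic mean), the deterministic
#' emulation of a single-microphone field protocol. Mono input is returned
#' unchanged; duration and sample rate are always preserved exactly.
#'
#' @param clip An [audio_clip()].
#' @return A mono [audio_clip()].
#' @export
to_mono <- function(clip) {
  if (!is.matrix(clip$samples)) return(clip)
  audio_clip(rowMeans(clip$samples), clip$sample_rate)
}

#' Band-limited resampling
#'
#' Resamples a clip to a new rate with `signal::resample` (polyphase
#' band-limited interpolation). Total duration is preserved to within one
#' sample period; equal rates are a no-op. Both rates must be integers so the
#' conversion ratio is exact.
#'
#' @param clip An [audio_clip()] (any channel count).
#' @param target_rate Target sampling rate in Hz (positive integer).
#' @return The resampled [audio_clip()].
#' @export
resample_clip <- function(clip, target_rate) {
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("`target_rate` must be a single positive number")
  sr <- clip$sample_rate
  if (sr != round(sr) || target_rate != round(target_rate))
    stop("resampling requires integer sample rates")
  if (target_rate == sr) return(clip)
  g <- gcd_int(as.integer(target_rate), as.integer(sr))
  p <- target_rate %/% g
  q <- sr %/% g
  res <- function(v) {
    y <- signal::resample(v, p, q)
    pmin(pmax(y, -1), 1)  # interpolation overshoot can graze full scale
  }
  x <- clip$samples
  y <- if (is.matrix(x)) apply(x, 2L, res) else res(x)
  audio_clip(y, target_rate)
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

# Minimum acceptable recorder rate: below this the 2-8 kHz biophony band is
# truncated by Nyquist and NDSI/ACI comparisons become meaningless.
MIN_SAMPLE_RATE <- 16000

#' Condition a clip for index extraction
#'
#' Mixes to mono and resamples to the shared analysis rate. Clips sampled
#' below 16 kHz are rejected: their Nyquist frequency truncates the 2-8 kHz
#' biophony band on which NDSI and the survey indices depend.
#'
#' @param clip An [audio_clip()].
#' @param analysis_rate Target rate in Hz (default 22050, Nyquist 11.025 kHz).
#' @return A mono [audio_clip()] at `analysis_rate`.
#' @export
condition_clip <- function(clip, analysis_rate = 22050) {
  if (clip$sample_rate < MIN_SAMPLE_RATE)
    stop("sample rate ", clip$sample_rate, " Hz is below the ", MIN_SAMPLE_RATE,
         " Hz minimum: the 2-8 kHz biophony band would be truncated")
  resample_clip(to_mono(clip), analysis_rate)
}

#' Truncate clips to a common duration
#'
#' Index totals (ACI in particular) scale with frame count, so all clips in
#' one survey must have identical length before extraction. Every clip is
#' truncated to the shortest duration present.
#'
#' @param clips A list of mono [audio_clip()]s sharing one sample rate.
#' @return A list of clips of equal sample count.
#' @export
truncate_common <- function(clips) {
  sr <- unique(vapply(clips, function(c) c$sample_rate, numeric(1)))
  if (length(sr) != 1L)
    stop("clips must share one sample rate before truncation; got: ",
         paste(sr, collapse = ", "))
  n <- min(vapply(clips, n_samples, integer(1)))
  lapply(clips, function(c) audio_clip(c$samples[seq_len(n)], c$sample_rate))
}
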