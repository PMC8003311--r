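# Short-time Fourier magnitude spectrograms and band-energy summaries.
#
# Conventions that every index in this package relies on:
#   * frames are left-aligned and the final partial window is dropped;
#   * magnitudes (not power, not dB) are stored; band_power() squares them;
#   * tapers use the periodic ("DFT-even") form, w[n] = f(2*pi*n/N). For a
#     sinusoid at an exact bin frequency this confines leakage to the two
#     neighbouring bins, which keeps band partitions clean;
#   * frequency bands are half-open intervals [f_lo, f_hi), so a partition
#     of [0, Nyquist) is non-overlapping and exhaustive.

taper_window <- function(name, n) {
  k <- 2 * pi * (seq_len(n) - 1) / n
  switch(name,
    hamming = 0.54 - 0.46 * cos(k),
    hann = 0.5 - 0.5 * cos(k),
    rectangular = rep(1, n),
    stop("unknown taper: ", name))
}

#' Magnitude spectrogram of a mono clip
#'
#' Computes the short-time Fourier magnitude spectrogram. Frames of
#' `window_len` samples are taken every `hop` samples starting at the first
#' sample; a final partial window is dropped, never padded. At least two
#' complete frames are required, since the complexity index differentiates
#' over time.
#'
#' @param clip A mono [audio_clip()].
#' @param window_len Analysis window length in samples (default 512).
#' @param hop Frame step in samples; defaults to `window_len`
#'   (non-overlapping frames, the convention of the classic ecoacoustics
#'   toolchain).
#' @param window Taper: `"hamming"` (default), `"hann"` or `"rectangular"`,
#'   applied in periodic (DFT-even) form.
#' @return A `spectrogram` object: `values` (T-by-F matrix of non-negative
#'   magnitudes, one row per frame), `frame_times_s`, `bin_freqs_hz`
#'   (0 .. Nyquist), `frame_step_s`, `window_len`, `sample_rate`, `window`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 4000 * (0:22049) / 22050), 22050)
#' sp <- spectrogram(clip)
#' sp$bin_freqs_hz[which.max(sp$values[1, ])]  # ~4 kHz
#' @export
spectrogram <- function(clip, window_len = 512L, hop = window_len,
                        window = c("hamming", "hann", "rectangular")) {
  window <- match.arg(window)
  if (n_channels(clip) != 1L)
    stop("spectrogram() needs a mono clip; use to_mono() first")
  x <- clip$samples
  n <- length(x)
  if (window_len < 2L || window_len > n)
    stop("clip shorter than one analysis window (", window_len, " samples)")
  if (hop < 1L) stop("`hop` must be at least 1 sample")
  starts <- seq.int(1L, n - window_len + 1L, by = hop)
  if (length(starts) < 2L)
    stop("fewer than two complete frames; use a longer clip or smaller hop")
  w <- taper_window(window, window_len)
  frames <- matrix(x[outer(0:(window_len - 1L), starts, "+")],
                   nrow = window_len)
  X <- stats::mvfft(frames * w)
  nb <- window_len %/% 2L + 1L
  sr <- clip$sample_rate
  structure(
    list(values = t(Mod(X[seq_len(nb), , drop = FALSE])),
         frame_times_s = (starts - 1 + window_len / 2) / sr,
         bin_freqs_hz = (seq_len(nb) - 1) * sr / window_len,
         frame_step_s = hop / sr,
         window_len = as.integer(window_len),
         sample_rate = sr,
         window = window),
    class = "spectrogram")
}

#' Construct a spectrogram from a precomputed matrix
#'
#' Low-level constructor for analyses (and tests) that start from a
#' time-frequency matrix rather than audio, e.g. brute-force cross-checks of
#' the complexity index on small random matrices.
#'
#' @param values T-by-F matrix of non-negative finite magnitudes
#'   (rows = frames).
#' @param bin_freqs_hz Strictly increasing bin centre frequencies (length F).
#' @param frame_step_s Frame step in seconds.
#' @param sample_rate Nominal sample rate in Hz; defaults to twice the top
#'   bin frequency so that the top bin is Nyquist.
#' @return A `spectrogram` object.
#' @export
new_spectrogram <- function(values, bin_freqs_hz, frame_step_s,
                            sample_rate = 2 * max(bin_freqs_hz)) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("a spectrogram needs at least 2 frames")
  if (!all(is.finite(values)) || any(values < 0))
    stop("spectrogram magnitudes must be finite and non-negative")
  if (length(bin_freqs_hz) != ncol(values))
    stop("length(bin_freqs_hz) must match ncol(values)")
  if (any(diff(bin_freqs_hz) <= 0))
    stop("bin_freqs_hz must be strictly increasing")
  structure(
    list(values = values,
         frame_times_s = (seq_len(nrow(values)) - 0.5) * frame_step_s,
         bin_freqs_hz = bin_freqs_hz,
         frame_step_s = frame_step_s,
         window_len = NA_integer_,
         sample_rate = sample_rate,
         window = "none"),
    class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d frames x %d bins, 0-%g Hz, step %.4g s (%s taper)\n",
    nrow(x$values), ncol(x$values), max(x$bin_freqs_hz), x$frame_step_s,
    x$window))
  invisible(x)
}

nyquist <- function(spec) spec$sample_rate / 2

#' Total spectral energy in a frequency band
#'
#' Sums squared magnitudes over all frames and all bins whose centre
#' frequency falls in the half-open interval `[f_lo, f_hi)`. Half-open bands
#' make any partition of `[0, Nyquist)` additive: the band powers of the
#' parts sum exactly to the power of the whole.
#'
#' @param spec A [spectrogram()].
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi <= Nyquist`.
#' @return A non-negative scalar.
#' @export
band_power <- function(spec, f_lo, f_hi) {
  if (f_lo < 0 || f_hi <= f_lo)
    stop("band edges must satisfy 0 <= f_lo < f_hi")
  if (f_hi > nyquist(spec) + 1e-9)
    stop("band [", f_lo, ", ", f_hi, ") extends beyond Nyquist (",
         nyquist(spec), " Hz)")
  sel <- spec$bin_freqs_hz >= f_lo & spec$bin_freqs_hz < f_hi
  if (!any(sel))
    stop("no spectrogram bins fall inside the band [", f_lo, ", ", f_hi, ") Hz")
  sum(spec$values[, sel, drop = FALSE]^2)
}

#' Dump a spectrogram to CSV
#'
#' Debug helper: writes the frame-by-bin magnitude matrix with a header row
#' of bin centre frequencies.
#'
#' @param spec A [spectrogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrogram_csv <- function(spec, path) {
  m <- as.data.frame(spec$values)
  names(m) <- sprintf("%.3f", spec$bin_freqs_hz)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
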