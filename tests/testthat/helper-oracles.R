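# Independent brute-force oracles and small fixture builders.

# ACI by explicit triple loop over clusters, bins and frames -- kept
# deliberately naive and separate from the vectorized implementation.
aci_brute <- function(values, frames_per_cluster, silence_floor = 1e-9) {
  m <- frames_per_cluster
  n_clusters <- nrow(values) %/% m
  den_floor <- silence_floor * max(values) * m
  total <- 0
  for (j in seq_len(n_clusters)) {
    for (k in seq_len(ncol(values))) {
      num <- 0
      den <- 0
      for (t in seq_len(m - 1)) {
        a <- values[(j - 1) * m + t, k]
        b <- values[(j - 1) * m + t + 1, k]
        num <- num + abs(b - a)
      }
      for (t in seq_len(m)) den <- den + values[(j - 1) * m + t, k]
      if (den > den_floor) total <- total + num / den
    }
  }
  total
}

# Gini by the pairwise mean-absolute-difference definition.
gini_brute <- function(x) {
  n <- length(x)
  if (mean(x) <= 0) return(0)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Spectrogram whose ACI clusters are easy to reason about: frame step of
# exactly 1 s, so cluster_s = m selects m frames per cluster.
spec_from_matrix <- function(values, freqs = NULL) {
  if (is.null(freqs)) freqs <- seq_len(ncol(values)) * 100
  new_spectrogram(values, freqs, frame_step_s = 1)
}

# Ten-band occupancy fixture: bin i (centre (i - 0.5) kHz) is the only bin
# of ADI/AEI band i; `active` gives, per band, the fraction of its frames
# set to full level (the rest sit 120 dB down, far below any threshold).
occupancy_spec <- function(active, n_frames = 8) {
  stopifnot(length(active) == 10)
  v <- matrix(1e-6, nrow = n_frames, ncol = 10)
  for (i in seq_len(10)) {
    k <- round(active[i] * n_frames)
    if (k > 0) v[seq_len(k), i] <- 1
  }
  new_spectrogram(v, seq(500, 9500, by = 1000), frame_step_s = 0.02,
                  sample_rate = 22050)
}

# A valid nine-point survey from explicit ACI / NDSI vectors (edge1..8, core).
survey_from_values <- function(aci_vals, ndsi_vals, area = "test_area") {
  area_survey(area, data.frame(role = survey_roles(),
                               clip_ref = survey_roles(),
                               aci = aci_vals, ndsi = ndsi_vals,
                               stringsAsFactors = FALSE))
}

sine_clip <- function(freq, sr, dur_s, amp = 0.5) {
  audio_clip(amp * sin(2 * pi * freq * (0:(round(sr * dur_s) - 1)) / sr), sr)
}

dominant_freq <- function(clip) {
  n <- n_samples(clip)
  mag <- Mod(stats::fft(clip$samples))[seq_len(n %/% 2)]
  (which.max(mag) - 1) * clip$sample_rate / n
}
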