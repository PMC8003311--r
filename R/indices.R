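# Per-recording scalar ecoacoustic indices: ACI, NDSI, ADI, AEI, relative Leq.
#
# Every index returns an index_result carrying the full parameter set used,
# because two index values are comparable only when their parameters match.

#' Shared analysis parameter set
#'
#' Bundles every tunable the index layer uses, so that one object can be
#' attached to all nine recordings of a survey and serialized into outputs.
#'
#' Defaults follow the operative conventions of this protocol: NDSI bands of
#' 1-2 kHz (anthropophony) versus 2-8 kHz (biophony); ACI cluster length 5 s;
#' 512-sample non-overlapping Hamming frames; ADI/AEI over ten 1-kHz bands
#' with a -50 dB occupancy threshold relative to the spectrogram maximum.
#'
#' @param analysis_rate Common sample rate (Hz) clips are conditioned to.
#' @param window_len,hop,window Spectrogram settings, see [spectrogram()].
#' @param cluster_s ACI temporal cluster length in seconds.
#' @param anthro_band,bio_band NDSI bands, Hz, half-open `[lo, hi)`.
#' @param adi_n_bands,adi_band_width,adi_db_threshold ADI/AEI occupancy
#'   settings: number of contiguous bands from 0 Hz, their width in Hz, and
#'   the dB-below-maximum occupancy threshold.
#' @param calibration_offset_db Offset added to relative Leq; 0 gives dBFS,
#'   a measured calibration constant maps to absolute dB SPL.
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(analysis_rate = 22050,
                            window_len = 512L, hop = window_len,
                            window = "hamming",
                            cluster_s = 5,
                            anthro_band = c(1000, 2000),
                            bio_band = c(2000, 8000),
                            adi_n_bands = 10L, adi_band_width = 1000,
                            adi_db_threshold = -50,
                            calibration_offset_db = 0) {
  p <- list(analysis_rate = analysis_rate, window_len = as.integer(window_len),
            hop = as.integer(hop), window = window, cluster_s = cluster_s,
            anthro_band = anthro_band, bio_band = bio_band,
            adi_n_bands = as.integer(adi_n_bands),
            adi_band_width = adi_band_width,
            adi_db_threshold = adi_db_threshold,
            calibration_offset_db = calibration_offset_db)
  stopifnot(p$analysis_rate >= MIN_SAMPLE_RATE, p$window_len >= 2L,
            p$hop >= 1L, p$cluster_s > 0,
            length(p$anthro_band) == 2L, length(p$bio_band) == 2L,
            p$adi_n_bands >= 2L, p$adi_band_width > 0)
  class(p) <- "analysis_params"
  p
}

index_result <- function(name, value, params, flags = character()) {
  structure(list(name = name, value = value, params = params, flags = flags),
            class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("<index_result> %s = %s%s\n", x$name, format(x$value),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Acoustic complexity index (ACI)
#'
#' ACI quantifies frame-to-frame intensity variability: biotic sounds such as
#' birdsong fluctuate in intensity while anthropogenic drones are nearly
#' constant, so complex biophony scores high and stationary noise scores near
#' zero. Frames are partitioned into consecutive temporal clusters of
#' `floor(cluster_s / frame_step_s)` frames (a final partial cluster is
#' dropped). For cluster j and frequency bin k,
#' \deqn{d_{jk} = \sum_t |I_{t+1,k} - I_{t,k}| / \sum_t I_{t,k},}
#' with `d = 0` where the denominator is zero (a silent bin must not poison
#' the total), and ACI is the sum of `d` over all clusters and bins. The
#' total is invariant to global amplitude scaling but grows with frame
#' count, so recordings are only comparable at equal duration and identical
#' spectrogram parameters.
#'
#' Denominators below `silence_floor` times the spectrogram's maximum cell
#' (times the cluster length) are treated as silent: without this floor,
#' FFT round-off noise of order 1e-16 in otherwise empty bins fluctuates
#' randomly and would register as complexity.
#'
#' @param spec A [spectrogram()].
#' @param cluster_s Cluster length in seconds; must cover at least two
#'   frames.
#' @param silence_floor Relative magnitude below which a bin-cluster counts
#'   as silent (default 1e-9; well below any real signal, well above
#'   double-precision FFT round-off).
#' @return An `index_result` named `"ACI"` (value >= 0).
#' @export
aci <- function(spec, cluster_s = 5, silence_floor = 1e-9) {
  step <- spec$frame_step_s
  if (cluster_s < 2 * step)
    stop("`cluster_s` must span at least two frames (>= ", 2 * step, " s)")
  m <- as.integer(floor(cluster_s / step))
  v <- spec$values
  n_clusters <- nrow(v) %/% m
  if (n_clusters < 1L)
    stop("no complete ACI cluster fits in ", nrow(v), " frames of ",
         step, " s")
  den_floor <- silence_floor * max(v) * m
  total <- 0
  for (j in seq_len(n_clusters)) {
    I <- v[((j - 1L) * m + 1L):(j * m), , drop = FALSE]
    num <- colSums(abs(I[-1L, , drop = FALSE] - I[-m, , drop = FALSE]))
    den <- colSums(I)
    total <- total + sum(ifelse(den > den_floor, num / den, 0))
  }
  index_result("ACI", total,
               list(cluster_s = cluster_s, frames_per_cluster = m,
                    n_clusters = n_clusters, silence_floor = silence_floor,
                    window_len = spec$window_len, frame_step_s = step,
                    window = spec$window))
}

#' Normalized difference soundscape index (NDSI)
#'
#' The ratio of biological to human-generated sound energy: with
#' \eqn{\alpha} the anthropophony band power (1-2 kHz by default, where
#' traffic and machinery concentrate) and \eqn{\beta} the biophony band
#' power (2-8 kHz, where most birdsong lives),
#' \deqn{NDSI = (\beta - \alpha) / (\beta + \alpha) \in [-1, +1],}
#' +1 meaning a purely biological signal and -1 a purely anthropogenic one.
#' Total silence (\eqn{\alpha = \beta = 0}) is defined as 0 (neutral) and
#' flagged, which keeps the survey-level disturbance sign well defined.
#'
#' @param spec A [spectrogram()].
#' @param anthro_band,bio_band Two-element band edges in Hz; the half-open
#'   bands must not overlap.
#' @return An `index_result` named `"NDSI"` with value in \[-1, 1\].
#' @export
ndsi <- function(spec, anthro_band = c(1000, 2000), bio_band = c(2000, 8000)) {
  if (!(anthro_band[2] <= bio_band[1] || bio_band[2] <= anthro_band[1]))
    stop("anthropophony and biophony bands overlap")
  alpha <- band_power(spec, anthro_band[1], anthro_band[2])
  beta <- band_power(spec, bio_band[1], bio_band[2])
  params <- list(anthro_band = anthro_band, bio_band = bio_band,
                 window_len = spec$window_len, window = spec$window)
  if (alpha == 0 && beta == 0)
    return(index_result("NDSI", 0, params, flags = "silent_clip"))
  index_result("NDSI", (beta - alpha) / (beta + alpha), params)
}

band_occupancy <- function(spec, n_bands, band_width, db_threshold) {
  if (n_bands * band_width > nyquist(spec) + 1e-9)
    stop("ADI/AEI bands extend beyond Nyquist: ", n_bands, " x ", band_width,
         " Hz > ", nyquist(spec), " Hz")
  mx <- max(spec$values)
  vapply(seq_len(n_bands), function(i) {
    sel <- spec$bin_freqs_hz >= (i - 1) * band_width &
      spec$bin_freqs_hz < i * band_width
    cells <- spec$values[, sel, drop = FALSE]
    if (mx == 0) return(0)
    mean(20 * log10(cells / mx) > db_threshold)
  }, numeric(1))
}

#' Acoustic diversity index (ADI)
#'
#' Shannon diversity of spectral occupancy. The spectrum up to
#' `n_bands * band_width` Hz is split into `n_bands` contiguous bands from
#' 0 Hz; each band's occupancy is the fraction of its spectrogram cells
#' whose level exceeds `db_threshold` dB relative to the spectrogram
#' maximum. Occupancies are normalized to proportions `q` and
#' \eqn{ADI = -\sum q_i \log q_i}, ranging from 0 (one active band, or
#' silence) to `log(n_bands)` (all bands equally active).
#'
#' @param spec A [spectrogram()].
#' @param n_bands Number of bands (>= 2).
#' @param band_width Band width in Hz.
#' @param db_threshold Occupancy threshold, dB relative to the spectrogram
#'   maximum (amplitude dB, `20 log10`).
#' @return An `index_result` named `"ADI"`.
#' @export
adi <- function(spec, n_bands = 10L, band_width = 1000, db_threshold = -50) {
  p <- band_occupancy(spec, n_bands, band_width, db_threshold)
  params <- list(n_bands = n_bands, band_width = band_width,
                 db_threshold = db_threshold)
  if (sum(p) == 0)
    return(index_result("ADI", 0, params, flags = "silent_clip"))
  q <- p / sum(p)
  q <- q[q > 0]
  index_result("ADI", -sum(q * log(q)), params)
}

#' Acoustic evenness index (AEI)
#'
#' Gini coefficient of the raw band occupancies used by [adi()]: 0 when all
#' bands are equally occupied, approaching 1 when activity concentrates in a
#' single band. By construction AEI moves opposite to ADI.
#'
#' @inheritParams adi
#' @return An `index_result` named `"AEI"` with value in \[0, 1\].
#' @export
aei <- function(spec, n_bands = 10L, band_width = 1000, db_threshold = -50) {
  p <- band_occupancy(spec, n_bands, band_width, db_threshold)
  params <- list(n_bands = n_bands, band_width = band_width,
                 db_threshold = db_threshold)
  if (sum(p) == 0)
    return(index_result("AEI", 0, params, flags = "silent_clip"))
  index_result("AEI", gini(p), params)
}

# Sample Gini coefficient, the standard relative-mean-difference form.
gini <- function(x) {
  n <- length(x)
  s <- sum(x)
  if (s <= 0) return(0)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n * s)
}

#' Equivalent continuous level relative to full scale (Leq)
#'
#' The constant level carrying the same energy as the clip over its whole
#' duration: `10 log10(mean(sample^2)) + offset`. With a zero offset this is
#' dB relative to digital full scale (dBFS); supplying a measured
#' calibration constant maps it to absolute dB SPL. A digitally silent clip
#' has no finite level and is returned as `NA` with a `"silent_clip"` flag
#' rather than as negative infinity.
#'
#' @param clip An [audio_clip()] (mono or multichannel; all samples enter
#'   the mean square).
#' @param calibration_offset_db Calibration offset in dB (default 0).
#' @return An `index_result` named `"LEQ_REL"`.
#' @export
leq_rel <- function(clip, calibration_offset_db = 0) {
  params <- list(calibration_offset_db = calibration_offset_db)
  msq <- mean(clip$samples^2)
  if (msq == 0)
    return(index_result("LEQ_REL", NA_real_, params, flags = "silent_clip"))
  index_result("LEQ_REL", 10 * log10(msq) + calibration_offset_db, params)
}

#' All five indices for one conditioned clip
#'
#' Convenience wrapper: computes the spectrogram once and returns ACI, NDSI,
#' ADI, AEI and relative Leq under one shared [analysis_params()] set.
#'
#' @param clip A mono [audio_clip()] already at `params$analysis_rate`
#'   (see [condition_clip()]).
#' @param params An [analysis_params()] object.
#' @return Named list of `index_result`s (`ACI`, `NDSI`, `ADI`, `AEI`,
#'   `LEQ_REL`).
#' @export
compute_indices <- function(clip, params = analysis_params()) {
  sp <- spectrogram(clip, params$window_len, params$hop, params$window)
  list(
    ACI = aci(sp, params$cluster_s),
    NDSI = ndsi(sp, params$anthro_band, params$bio_band),
    ADI = adi(sp, params$adi_n_bands, params$adi_band_width,
              params$adi_db_threshold),
    AEI = aei(sp, params$adi_n_bands, params$adi_band_width,
              params$adi_db_threshold),
    LEQ_REL = leq_rel(clip, params$calibration_offset_db))
}

#' Batch index extraction over WAV files
#'
#' Reads, conditions and analyses each file, returning one row per
#' recording. Files that fail to read or analyse are reported in the
#' `error` column and leave their index columns `NA`; the run continues.
#'
#' @param paths Character vector of WAV paths.
#' @param params An [analysis_params()] object shared by all files.
#' @return A data frame with columns `path`, `ACI`, `NDSI`, `ADI`, `AEI`,
#'   `LEQ_REL`, `error` and `params_json` (the full parameter set, so each
#'   row is self-describing).
#' @export
batch_indices <- function(paths, params = analysis_params()) {
  pj <- as.character(jsonlite::toJSON(unclass(params), auto_unbox = TRUE,
                                      digits = NA))
  rows <- lapply(paths, function(p) {
    res <- tryCatch({
      ix <- compute_indices(condition_clip(read_wav(p), params$analysis_rate),
                            params)
      data.frame(path = p, ACI = ix$ACI$value, NDSI = ix$NDSI$value,
                 ADI = ix$ADI$value, AEI = ix$AEI$value,
                 LEQ_REL = ix$LEQ_REL$value, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(path = p, ACI = NA_real_, NDSI = NA_real_, ADI = NA_real_,
                 AEI = NA_real_, LEQ_REL = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), ACI = numeric(), NDSI = numeric(),
               ADI = numeric(), AEI = numeric(), LEQ_REL = numeric(),
               error = character(), stringsAsFactors = FALSE)
  out$params_json <- rep(pj, nrow(out))
  out
}
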