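# Seeded synthetic-soundscape generator.
#
# Three source classes are emulated:
#   * biophony    — intensity-varying tonal chirps in 2-8 kHz (birdsong-like);
#   * anthropophony — a constant-envelope tonal drone in 1-2 kHz (traffic-like);
#   * geophony    — stationary broadband background noise.
#
# Synthesis is aligned to the analysis frame grid: event frequencies are
# quantized to the spectrogram's bin centres and envelopes are stepped per
# analysis frame. Under the package's default non-overlapping periodic-
# Hamming spectrogram, a bin-centred tone leaks into exactly its two
# neighbouring bins and nowhere else, so biophony and anthropophony are
# band-separated *exactly* in the analysed domain — which is what makes the
# NDSI endpoint values of +1 and -1 attainable rather than approximate.

#' Synthetic soundscape scenario
#'
#' The full specification of one synthetic acoustic condition. Defaults
#' describe a lively urban green space: an active songbird community
#' (2 chirp events per second at -20 dBFS peak), a moderate perimeter
#' traffic drone (-35 dBFS, 6 dB louder at the edge points than at the
#' core), and a faint broadband ambient floor (-55 dBFS). Levels are dB
#' relative to digital full scale; `-Inf` disables a source.
#'
#' @param duration_s Clip duration in seconds (default 60; long enough for
#'   twelve 5-s ACI clusters).
#' @param sample_rate Sample rate in Hz (default 22050).
#' @param bio_event_rate Poisson rate of biophony chirp events, events/s.
#' @param bio_band Frequency band of biophony, Hz (default 2-8 kHz).
#' @param bio_event_dur_s Range (min, max) of chirp durations, seconds.
#' @param bio_level_db Peak level of the loudest chirps, dBFS.
#' @param anthro_band Frequency band of anthropophony, Hz (default 1-2 kHz).
#' @param anthro_level_db RMS level of the anthropophony drone, dBFS.
#' @param anthro_n_tones Number of drone partials (spaced >= 3 bins so the
#'   summed frame energy is exactly constant).
#' @param geo_level_db RMS level of the broadband background, dBFS.
#' @param edge_anthro_boost_db Extra anthropophony level at edge points
#'   relative to the core, dB (perimeter traffic plus edge-to-core
#'   attenuation collapsed into one scalar).
#' @param seed Base RNG seed; identical (scenario, seed) pairs give
#'   bit-identical output.
#' @param frame_len Analysis frame length the synthesis grid is aligned to,
#'   samples (default 512, matching [analysis_params()]).
#' @return A list of class `scenario`.
#' @export
scenario <- function(duration_s = 60, sample_rate = 22050,
                     bio_event_rate = 2, bio_band = c(2000, 8000),
                     bio_event_dur_s = c(0.1, 0.5), bio_level_db = -20,
                     anthro_band = c(1000, 2000), anthro_level_db = -35,
                     anthro_n_tones = 7L, geo_level_db = -55,
                     edge_anthro_boost_db = 6, seed = 1L,
                     frame_len = 512L) {
  s <- list(duration_s = duration_s, sample_rate = sample_rate,
            bio_event_rate = bio_event_rate, bio_band = bio_band,
            bio_event_dur_s = bio_event_dur_s, bio_level_db = bio_level_db,
            anthro_band = anthro_band, anthro_level_db = anthro_level_db,
            anthro_n_tones = as.integer(anthro_n_tones),
            geo_level_db = geo_level_db,
            edge_anthro_boost_db = edge_anthro_boost_db,
            seed = as.integer(seed), frame_len = as.integer(frame_len))
  stopifnot(s$duration_s > 0, s$sample_rate > 0, s$bio_event_rate >= 0,
            length(s$bio_band) == 2L, s$bio_band[1] < s$bio_band[2],
            length(s$bio_event_dur_s) == 2L, s$bio_event_dur_s[1] > 0,
            s$bio_event_dur_s[1] <= s$bio_event_dur_s[2],
            s$anthro_n_tones >= 1L, s$frame_len >= 16L)
  if (s$bio_band[2] > s$sample_rate / 2)
    stop("biophony band extends beyond Nyquist (", s$sample_rate / 2, " Hz)")
  if (s$anthro_band[2] > s$sample_rate / 2)
    stop("anthropophony band extends beyond Nyquist")
  n_frames <- floor(s$duration_s * s$sample_rate / s$frame_len)
  if (n_frames < 2L)
    stop("scenario too short: fewer than two analysis frames")
  s$n_frames <- n_frames
  s$n_samples <- n_frames * s$frame_len
  class(s) <- "scenario"
  s
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(paste0(
    "<scenario> %gs @ %g Hz | bio %.3g ev/s %g dBFS in %g-%g Hz | ",
    "anthro %g dBFS (+%g dB at edges) | geo %g dBFS | seed %d\n"),
    x$duration_s, x$sample_rate, x$bio_event_rate, x$bio_level_db,
    x$bio_band[1], x$bio_band[2], x$anthro_level_db,
    x$edge_anthro_boost_db, x$geo_level_db, x$seed))
  invisible(x)
}

# Bins whose tone (plus its one-bin leakage skirt) stays inside [lo, hi):
# bin m has centre m*sr/L; require (m-1)*sr/L >= lo and (m+1)*sr/L < hi.
grid_bins <- function(lo, hi, sample_rate, frame_len) {
  m_min <- ceiling(lo * frame_len / sample_rate + 1 - 1e-9)
  m_max <- ceiling(hi * frame_len / sample_rate - 1 - 1e-9) - 1
  if (m_max < m_min)
    stop("band [", lo, ", ", hi, ") Hz is too narrow for the ",
         frame_len, "-sample analysis grid")
  seq.int(m_min, m_max)
}

db_amp <- function(db) 10^(db / 20)

# One frame of a bin-centred cosine; frames all start at multiples of
# frame_len, so the local sample index is all that matters.
frame_tone <- function(bin, frame_len, phase) {
  cos(2 * pi * bin * (0:(frame_len - 1)) / frame_len + phase)
}

#' Generate a biophony clip
#'
#' Amplitude-enveloped chirps emulating birdsong: event onsets are Poisson
#' with rate `bio_event_rate`, durations uniform in `bio_event_dur_s`,
#' frequencies sweep linearly between two random points of `bio_band`, and a
#' raised-cosine envelope gives each event the frame-to-frame intensity
#' variability that the complexity index rewards. Frequencies are quantized
#' to the analysis grid and envelopes stepped per frame (see the scenario
#' documentation), so all spectral energy falls strictly inside `bio_band`
#' under the default spectrogram. The output is peak-normalized to at most
#' full scale.
#'
#' @param scn A [scenario()].
#' @param seed RNG seed (defaults to the scenario's).
#' @return A mono [audio_clip()].
#' @export
generate_biophony <- function(scn, seed = scn$seed) {
  set.seed(seed)
  x <- numeric(scn$n_samples)
  if (scn$bio_event_rate > 0 && is.finite(scn$bio_level_db)) {
    n_ev <- stats::rpois(1L, scn$bio_event_rate * scn$duration_s)
    bins <- grid_bins(scn$bio_band[1], scn$bio_band[2], scn$sample_rate,
                      scn$frame_len)
    frame_dur <- scn$frame_len / scn$sample_rate
    peak <- db_amp(scn$bio_level_db)
    L <- scn$frame_len
    for (e in seq_len(n_ev)) {
      dur_s <- stats::runif(1L, scn$bio_event_dur_s[1], scn$bio_event_dur_s[2])
      df <- max(2L, min(scn$n_frames, round(dur_s / frame_dur)))
      onset <- sample.int(scn$n_frames - df + 1L, 1L)
      b0 <- sample(bins, 1L)
      b1 <- sample(bins, 1L)
      amp <- peak * stats::runif(1L, 0.5, 1)
      env <- amp * 0.5 * (1 - cos(2 * pi * (seq_len(df) - 0.5) / df))
      sweep <- round(b0 + (b1 - b0) * (seq_len(df) - 1) / (df - 1))
      phases <- stats::runif(df, 0, 2 * pi)
      for (t in seq_len(df)) {
        g <- onset + t - 1L
        idx <- ((g - 1L) * L + 1L):(g * L)
        x[idx] <- x[idx] + env[t] * frame_tone(sweep[t], L, phases[t])
      }
    }
  }
  pk <- max(abs(x))
  if (pk > 1) x <- x / pk
  audio_clip(x, scn$sample_rate)
}

#' Generate an anthropophony clip
#'
#' A stationary tonal drone emulating road/machinery noise: a fixed comb of
#' `anthro_n_tones` bin-centred partials inside `anthro_band` with constant
#' amplitudes and random phases, scaled to `anthro_level_db` RMS. Because
#' the partials are bin-centred and at least three bins apart, the energy
#' of every analysis frame is identical — the envelope is constant in
#' exactly the sense the complexity index is blind to (its ACI is 0).
#' A level of `-Inf` yields silence.
#'
#' @param scn A [scenario()].
#' @param seed RNG seed (defaults to the scenario's).
#' @param level_db Override for the drone level in dBFS (defaults to the
#'   scenario's `anthro_level_db`); the tone draw itself does not depend on
#'   the level, so ladders of increasing loudness share their structure.
#' @return A mono [audio_clip()].
#' @export
generate_anthropophony <- function(scn, seed = scn$seed,
                                   level_db = scn$anthro_level_db) {
  if (!is.finite(level_db) || level_db == -Inf)
    return(audio_clip(numeric(scn$n_samples), scn$sample_rate))
  set.seed(seed)
  bins <- grid_bins(scn$anthro_band[1], scn$anthro_band[2], scn$sample_rate,
                    scn$frame_len)
  comb <- bins[seq.int(1L, length(bins), by = 3L)]
  k <- min(scn$anthro_n_tones, length(comb))
  tones <- sort(sample(comb, k))
  phases <- stats::runif(k, 0, 2 * pi)
  amp <- db_amp(level_db) * sqrt(2 / k)  # per-tone amplitude for target RMS
  n <- 0:(scn$n_samples - 1)
  x <- numeric(scn$n_samples)
  for (i in seq_len(k))
    x <- x + amp * cos(2 * pi * tones[i] * n / scn$frame_len + phases[i])
  pk <- max(abs(x))
  if (pk > 1) x <- x / pk
  audio_clip(x, scn$sample_rate)
}

#' Generate a geophony clip
#'
#' Stationary broadband background noise (white Gaussian) at `geo_level_db`
#' RMS — the flat ambient floor that real recorders always capture. `-Inf`
#' yields silence.
#'
#' @param scn A [scenario()].
#' @param seed RNG seed (defaults to the scenario's).
#' @return A mono [audio_clip()].
#' @export
generate_geophony <- function(scn, seed = scn$seed) {
  if (!is.finite(scn$geo_level_db))
    return(audio_clip(numeric(scn$n_samples), scn$sample_rate))
  set.seed(seed)
  x <- stats::rnorm(scn$n_samples) * db_amp(scn$geo_level_db)
  pk <- max(abs(x))
  if (pk > 1) x <- x / pk
  audio_clip(x, scn$sample_rate)
}

# Deterministic per-(point, source) seed derivation, kept under 2^31.
derive_seed <- function(base, point_idx, source_idx) {
  as.integer((as.numeric(base) + 7919 * point_idx + 104729 * source_idx) %%
               2147483647)
}

#' Synthesize the clip heard at one sampling point
#'
#' Mixes one biophony draw (independent per point, common event rate), the
#' shared anthropophony drone (boosted by `edge_anthro_boost_db` at edge
#' points) and an independent geophony floor. If the mix exceeds full scale
#' it is peak-normalized (all indices used downstream are scale-invariant
#' or relative, so this is harmless).
#'
#' @param scn A [scenario()].
#' @param role One of [survey_roles()].
#' @return A mono [audio_clip()].
#' @export
simulate_point <- function(scn, role) {
  roles <- survey_roles()
  idx <- match(role, roles)
  if (is.na(idx)) stop("unknown sampling role: ", role)
  is_edge <- role != "core"
  bio <- generate_biophony(scn, derive_seed(scn$seed, idx, 1L))
  lvl <- scn$anthro_level_db + if (is_edge) scn$edge_anthro_boost_db else 0
  anth <- generate_anthropophony(scn, derive_seed(scn$seed, 0L, 2L),
                                 level_db = lvl)
  geo <- generate_geophony(scn, derive_seed(scn$seed, idx, 3L))
  x <- bio$samples + anth$samples + geo$samples
  pk <- max(abs(x))
  if (pk > 1) x <- x / pk
  audio_clip(x, scn$sample_rate)
}

#' Simulate a full nine-point survey in memory
#'
#' @param scn A [scenario()].
#' @param area_name Area label.
#' @return A list with `area_name`, `scenario` and `clips` (named list of
#'   nine mono [audio_clip()]s, one per role).
#' @export
simulate_survey <- function(scn, area_name = "synthetic_area") {
  clips <- lapply(survey_roles(), function(r) simulate_point(scn, r))
  names(clips) <- survey_roles()
  list(area_name = area_name, scenario = scn, clips = clips)
}

#' Render a survey to WAV files and a manifest
#'
#' Writes the nine point recordings as float32 WAVs (exact round trip of the
#' synthesized samples) plus a manifest CSV compatible with
#' [surveys_from_manifest()], and returns the manifest path.
#'
#' @param scn A [scenario()].
#' @param area_name Area label (also the file-name stem).
#' @param out_dir Output directory (created if needed).
#' @param format WAV sample format, see [write_wav()].
#' @return Invisibly, a list with `manifest` (path) and `wavs` (paths).
#' @export
render_survey <- function(scn, area_name, out_dir, format = "float32") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  sim <- simulate_survey(scn, area_name)
  wavs <- vapply(survey_roles(), function(r) {
    p <- file.path(out_dir, paste0(area_name, "_", r, ".wav"))
    write_wav(sim$clips[[r]], p, format = format)
    p
  }, character(1))
  manifest <- file.path(out_dir, paste0(area_name, "_manifest.csv"))
  utils::write.csv(
    data.frame(area_name = area_name, role = survey_roles(),
               wav_path = basename(wavs), stringsAsFactors = FALSE),
    manifest, row.names = FALSE)
  invisible(list(manifest = manifest, wavs = wavs))
}

#' Scenario ladder of increasing anthropogenic pressure
#'
#' Builds a sequence of scenarios sharing one seed (hence one biophony and
#' background realization — common random numbers) in which the
#' anthropophony level rises and, optionally, the biophony event rate falls.
#' Rung 1 is the planted "quietest" condition. Used for monotonicity and
#' parameter-recovery checks of the composite index.
#'
#' Because the seed and the event rate are shared, every rung hears the
#' *same* chirp pattern and background realization; only the source levels
#' move. Along such a ladder the anthropophony band power is strictly
#' increasing and the biophony band power strictly decreasing, so the mean
#' NDSI is strictly decreasing and its sign flips exactly once.
#'
#' @param base A [scenario()] providing all other fields.
#' @param anthro_levels_db Increasing vector of drone levels, dBFS.
#' @param bio_levels_db Optional vector (same length) of decreasing chirp
#'   peak levels, dBFS.
#' @param bio_event_rates Optional vector (same length) of decreasing chirp
#'   rates (note: changing the rate changes the event draw, so monotonicity
#'   is then only statistical).
#' @return A list of [scenario()]s.
#' @export
scenario_ladder <- function(base, anthro_levels_db, bio_levels_db = NULL,
                            bio_event_rates = NULL) {
  chk <- function(v, nm) {
    if (!is.null(v) && length(v) != length(anthro_levels_db))
      stop(nm, " must match anthro_levels_db in length")
  }
  chk(bio_levels_db, "bio_levels_db")
  chk(bio_event_rates, "bio_event_rates")
  lapply(seq_along(anthro_levels_db), function(i) {
    s <- unclass(base)
    s$anthro_level_db <- anthro_levels_db[i]
    if (!is.null(bio_levels_db)) s$bio_level_db <- bio_levels_db[i]
    if (!is.null(bio_event_rates)) s$bio_event_rate <- bio_event_rates[i]
    s$n_frames <- NULL; s$n_samples <- NULL
    do.call(scenario, s)
  })
}
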