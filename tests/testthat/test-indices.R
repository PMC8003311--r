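# The five per-recording indices.

test_that("ACI is zero for a time-constant spectrogram", {
  v <- matrix(rep(c(1, 2, 5, 0.3), each = 12), nrow = 12)
  expect_identical(aci(spec_from_matrix(v), cluster_s = 4)$value, 0)
})

test_that("ACI matches the worked two-bin example", {
  v <- cbind(c(1, 3, 1, 3), c(2, 2, 2, 2))
  r <- aci(spec_from_matrix(v), cluster_s = 4)
  expect_equal(r$value, 0.75, tolerance = 1e-15)  # (2+2+2)/8 + 0
  expect_identical(r$params$frames_per_cluster, 4L)
})

test_that("ACI drops a final partial cluster and records cluster geometry", {
  set.seed(31)
  v <- matrix(runif(10 * 3, 0.1, 1), nrow = 10)
  r <- aci(spec_from_matrix(v), cluster_s = 4)
  expect_identical(r$params$n_clusters, 2L)
  expect_equal(r$value, aci_brute(v[1:8, , drop = FALSE], 4),
               tolerance = 1e-12)
})

test_that("ACI is invariant to global amplitude scaling", {
  set.seed(32)
  v <- matrix(runif(40 * 8, 0, 2), nrow = 40)
  a1 <- aci(spec_from_matrix(v), cluster_s = 5)$value
  a2 <- aci(spec_from_matrix(v * 7.3), cluster_s = 5)$value
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("ACI rejects degenerate cluster settings", {
  v <- matrix(runif(6, 0, 1), nrow = 3)
  expect_error(aci(spec_from_matrix(v), cluster_s = 1), "at least two frames")
  expect_error(aci(spec_from_matrix(v), cluster_s = 5), "no complete ACI cluster")
})

test_that("NDSI reproduces constructed band powers and symmetry points", {
  # alpha = 3 in 1-2 kHz, beta = 5 in 2-8 kHz, two frames
  v <- cbind(rep(sqrt(1.5), 2), rep(sqrt(2.5), 2))
  sp <- new_spectrogram(v, c(1500, 4000), 0.02, sample_rate = 22050)
  expect_equal(ndsi(sp)$value, 0.25, tolerance = 1e-12)

  eq <- new_spectrogram(cbind(c(1, 1), c(1, 1)), c(1500, 4000), 0.02,
                        sample_rate = 22050)
  expect_identical(ndsi(eq)$value, 0)  # alpha == beta > 0

  bio_only <- new_spectrogram(cbind(c(0, 0), c(2, 1)), c(1500, 4000), 0.02,
                              sample_rate = 22050)
  expect_identical(ndsi(bio_only)$value, 1)
  anthro_only <- new_spectrogram(cbind(c(2, 1), c(0, 0)), c(1500, 4000), 0.02,
                                 sample_rate = 22050)
  expect_identical(ndsi(anthro_only)$value, -1)
})

test_that("NDSI of silence is a flagged neutral zero", {
  r <- ndsi(spectrogram(audio_clip(numeric(2048), 22050)))
  expect_identical(r$value, 0)
  expect_identical(r$flags, "silent_clip")
})

test_that("NDSI rejects overlapping bands and out-of-range bands", {
  sp <- spectrogram(audio_clip(runif(2048, -1, 1), 22050))
  expect_error(ndsi(sp, c(1000, 3000), c(2000, 8000)), "overlap")
  expect_error(ndsi(sp, c(1000, 2000), c(2000, 12000)), "beyond Nyquist")
})

test_that("ADI hits its closed-form Shannon landmarks", {
  expect_equal(adi(occupancy_spec(rep(1, 10)))$value, log(10),
               tolerance = 1e-12)
  expect_identical(adi(occupancy_spec(c(1, rep(0, 9))))$value, 0)
  expect_equal(adi(occupancy_spec(c(0.5, 0.5, rep(0, 8))))$value, log(2),
               tolerance = 1e-12)
  silent <- adi(spectrogram(audio_clip(numeric(2048), 22050)))
  expect_identical(silent$value, 0)
  expect_identical(silent$flags, "silent_clip")
})

test_that("AEI hits its closed-form Gini landmarks and matches brute force", {
  expect_identical(aei(occupancy_spec(rep(1, 10)))$value, 0)
  expect_equal(aei(occupancy_spec(c(1, rep(0, 9))))$value, 0.9,
               tolerance = 1e-12)
  set.seed(33)
  for (i in 1:20) {
    occ <- round(runif(10), 1)
    if (sum(occ) == 0) occ[1] <- 0.5
    expect_equal(aei(occupancy_spec(occ, n_frames = 10))$value,
                 gini_brute(round(occ * 10) / 10), tolerance = 1e-12)
  }
})

test_that("ADI/AEI respect the Nyquist precondition", {
  sp <- spectrogram(audio_clip(runif(2048, -1, 1), 16000))
  expect_error(adi(sp, n_bands = 10L, band_width = 1000), "beyond Nyquist")
})

test_that("relative Leq matches closed-form levels", {
  sr <- 22050
  square <- audio_clip(rep(c(1, -1), sr / 2), sr)
  expect_identical(leq_rel(square)$value, 0)

  sine <- sine_clip(1000, sr, 1, amp = 1)  # integer cycles: mean square 1/2
  expect_equal(leq_rel(sine)$value, 10 * log10(0.5), tolerance = 1e-9)

  half <- audio_clip(sine$samples / 2, sr)
  expect_equal(leq_rel(sine)$value - leq_rel(half)$value, 20 * log10(2),
               tolerance = 1e-9)

  expect_equal(leq_rel(sine, calibration_offset_db = 94)$value,
               10 * log10(0.5) + 94, tolerance = 1e-9)
})

test_that("a digitally silent clip is flagged rather than -Inf", {
  r <- leq_rel(audio_clip(numeric(100), 22050))
  expect_true(is.na(r$value))
  expect_identical(r$flags, "silent_clip")
})

test_that("compute_indices returns all five results under one parameter set", {
  scn <- scenario(duration_s = 6, seed = 9)
  ix <- compute_indices(simulate_point(scn, "core"))
  expect_named(ix, c("ACI", "NDSI", "ADI", "AEI", "LEQ_REL"))
  expect_gte(ix$ACI$value, 0)
  expect_true(abs(ix$NDSI$value) <= 1)
  expect_true(ix$ADI$value >= 0 && ix$ADI$value <= log(10) + 1e-12)
  expect_true(ix$AEI$value >= 0 && ix$AEI$value <= 1)
  expect_lt(ix$LEQ_REL$value, 0)
})

test_that("batch extraction survives a corrupt file and reports it", {
  dir <- withr::local_tempdir()
  good <- file.path(dir, "good.wav")
  write_wav(generate_biophony(scenario(duration_s = 6, seed = 5)), good)
  bad <- file.path(dir, "bad.wav")
  writeLines("not audio", bad)
  tab <- batch_indices(c(good, bad))
  expect_identical(nrow(tab), 2L)
  expect_true(is.na(tab$error[1]) && !is.na(tab$NDSI[1]))
  expect_true(!is.na(tab$error[2]) && is.na(tab$ACI[2]))
  empty <- batch_indices(character())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("path", "ACI", "NDSI", "error") %in% names(empty)))
})
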