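test_that("WAV round-trip preserves samples, rate and mono averaging", {
  sr <- 8000
  x <- 0.5 * sin(2 * pi * 440 * seq_len(sr) / sr)
  rec <- recording(x, sr, species_id = "sp1", recording_id = "r1")
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, path)
  back <- read_wav(path, species_id = "sp1")
  expect_equal(length(back$samples), sr)
  expect_equal(back$sample_rate, sr)
  expect_lt(max(abs(back$samples - x)), 1 / 32767)

  # stereo with identical channels averages to either channel
  con <- file(path, "rb"); hdr <- readBin(con, "raw", 1e7); close(con)
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  stereo <- withr::local_tempfile(fileext = ".wav")
  con <- file(stereo, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 4 * sr), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 2)), con, size = 2, endian = "little")
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 4), con, size = 4, endian = "little")
  writeBin(as.integer(c(4, 16)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(4 * sr), con, size = 4, endian = "little")
  writeBin(as.integer(rbind(pcm, pcm)), con, size = 2, endian = "little")
  close(con)
  st <- read_wav(stereo)
  expect_lt(max(abs(st$samples - back$samples)), 1e-12)
})

test_that("unreadable or empty WAV input fails loudly", {
  bad <- withr::local_tempfile(fileext = ".wav")
  writeLines("not a wav", bad)
  expect_error(read_wav(bad), "RIFF")
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), "exist")
})

test_that("frame decomposition matches the frame-count formula and RMS", {
  sr <- 44100
  rec <- recording(rep(0.5, sr), sr)
  fs <- compute_frames(rec, 40, 20)
  expect_equal(length(fs$frame_rms), (sr - 1764) %/% 882 + 1)  # 49
  expect_equal(unname(fs$frame_rms), rep(0.5, 49), tolerance = 1e-12)
  # unit sine over full cycles: RMS ~ 1/sqrt(2)
  rec2 <- recording(sin(2 * pi * 1000 * seq_len(sr) / sr), sr)
  fs2 <- compute_frames(rec2)
  expect_equal(mean(fs2$frame_rms), 1 / sqrt(2), tolerance = 1e-3)
  expect_error(compute_frames(recording(rep(1, 100), sr)), "shorter")
})

test_that("CVA matches constant, gain-invariance and AM-envelope oracles", {
  tone <- synth_call(f0 = 500, am_depth = 0, noise_snr = Inf, duration = 1,
                     sample_rate = 8000, seed = 1)
  expect_lt(cva(compute_frames(tone)), 0.02)
  # gain invariance
  fs1 <- compute_frames(tone)
  tone10 <- recording(tone$samples * 10, tone$sample_rate)
  expect_equal(cva(compute_frames(tone10)), cva(fs1), tolerance = 1e-12)
  # slow sinusoidal AM of depth m: CVA -> m / sqrt(2)
  am <- synth_call(f0 = 1000, am_rate = 2, am_depth = 0.5, noise_snr = Inf,
                   duration = 25, sample_rate = 8000, seed = 1)
  expect_equal(cva(compute_frames(am)), 0.5 / sqrt(2), tolerance = 0.02)
  expect_error(cva(compute_frames(recording(rep(0, 8000), 8000))), "zero")
})

test_that("dominant frequency finds the strongest partial", {
  sr <- 44100; t <- seq_len(sr) / sr
  fs <- compute_frames(recording(sin(2 * pi * 1000 * t), sr))
  expect_lt(abs(dominant_frequency(fs) - 1000), sr / 1764 + 1e-9)  # one bin
  two <- recording(sin(2 * pi * 500 * t) + 0.5 * sin(2 * pi * 2000 * t), sr)
  expect_lt(abs(dominant_frequency(compute_frames(two)) - 500), 26)
  # harmonic stack with rolloff: fundamental dominates
  stack <- synth_call(f0 = 800, n_harmonics = 6, rolloff_db = 6,
                      am_depth = 0, noise_snr = Inf, sample_rate = 44100,
                      seed = 3)
  expect_lt(abs(dominant_frequency(compute_frames(stack)) - 800), 26)
})

test_that("spectral flux separates stationary from modulated signals", {
  sr <- 8820  # 40 ms window = 352.8 -> rounds to 353 samples
  t <- seq_len(sr) / sr
  stat_tone <- compute_frames(recording(sin(2 * pi * 441 * t), sr))
  expect_error(spectral_flux(
    compute_frames(recording(sin(2 * pi * 441 * seq_len(360) / sr), sr))),
    "2 frames")
  am_tone <- compute_frames(recording(
    (1 + 0.8 * sin(2 * pi * 7 * t)) * sin(2 * pi * 441 * t), sr))
  expect_gt(spectral_flux(am_tone), spectral_flux(stat_tone))
  # SF is the only gain-sensitive descriptor: scales linearly
  g <- compute_frames(recording(2 * sin(2 * pi * 441 * t), sr))
  expect_equal(spectral_flux(g), 2 * spectral_flux(stat_tone),
               tolerance = 1e-10)
  # tone frame followed by a silent frame (non-overlapping): flux equals
  # the tone-spectrum norm exactly
  win <- round(0.04 * sr)
  x <- c(sin(2 * pi * 441 * seq_len(win) / sr), rep(0, win))
  fs <- compute_frames(recording(x, sr), window_ms = 40, hop_ms = 40)
  expect_equal(spectral_flux(fs), sqrt(sum(fs$frame_spectra[, 1]^2)),
               tolerance = 1e-12)
})

test_that("spectral irregularity follows the adjoining-partial formula", {
  sr <- 44100; t <- seq_len(2 * sr) / sr
  # single partial scores 1 under the normalized convention
  one <- compute_frames(recording(sin(2 * pi * 1000 * t), sr))
  expect_equal(spectral_irregularity(one), 1, tolerance = 0.05)
  # equal-amplitude comb of many partials tends to 0
  comb <- Reduce(`+`, lapply(1:10, function(h) sin(2 * pi * 400 * h * t)))
  si_comb <- spectral_irregularity(compute_frames(recording(comb, sr)))
  expect_lt(si_comb, 0.3)
  # alternating amplitudes are more irregular than the flat comb
  alt <- Reduce(`+`, lapply(1:10, function(h)
    c(1, 0.2)[1 + h %% 2] * sin(2 * pi * 400 * h * t)))
  expect_gt(spectral_irregularity(compute_frames(recording(alt, sr))), si_comb)
  # gain invariance of the normalized form
  expect_equal(spectral_irregularity(compute_frames(recording(3 * comb, sr))),
               si_comb, tolerance = 1e-10)
})

test_that("tonality separates tones from noise and rises with noise level", {
  tone <- synth_call(f0 = 1000, am_depth = 0, noise_snr = Inf,
                     sample_rate = 22050, seed = 1)
  noise <- synth_call(f0 = 1000, noise_snr = -Inf, sample_rate = 22050,
                      seed = 2)
  ton_tone <- tonality(compute_frames(tone))
  ton_noise <- tonality(compute_frames(noise))
  expect_lt(ton_tone, 0.05)
  expect_gt(ton_noise, 0.5)
  # monotone in added noise on a fixed tone
  tons <- vapply(c(40, 20, 5, -10), function(snr)
    tonality(compute_frames(synth_call(f0 = 1000, noise_snr = snr,
                                       sample_rate = 22050, seed = 4))),
    numeric(1))
  expect_true(all(diff(tons) > 0))
  expect_true(all(tons > 0 & tons <= 1))
})

test_that("species trait table averages on the linear scale then logs", {
  recs <- data.frame(species_id = c("a", "a", "b"),
                     cva = c(0.2, 0.4, 0.5), df = c(800, 1200, 2000),
                     sf = c(1, 3, 2), si = c(0.5, 0.7, 0.3),
                     ton = c(0.1, 0.3, 0.2))
  md <- data.frame(species_id = c("a", "b"), clade = c("c1", "c2"),
                   svl_mm = c(50, 80))
  tab <- species_trait_table(recs, md)
  expect_equal(tab$logdf[tab$species_id == "a"], log10(1000))
  expect_equal(tab$cva[tab$species_id == "a"], 0.3)
  expect_equal(tab$logsvl, log10(c(50, 80)))
  expect_equal(tab$logsf[tab$species_id == "b"], log10(2))
  # validation errors name the offending species
  expect_error(species_trait_table(recs, rbind(md,
    data.frame(species_id = "c", clade = "c1", svl_mm = 60))), "c")
  md_bad <- md; md_bad$svl_mm[2] <- NA
  expect_error(species_trait_table(recs, md_bad), "b")
})

test_that("feature extraction is deterministic and end-to-end consistent", {
  r <- synth_call(f0 = 1500, n_harmonics = 3, am_depth = 0.4, noise_snr = 20,
                  sample_rate = 22050, seed = 7)
  f1 <- extract_features(r); f2 <- extract_features(r)
  expect_identical(f1, f2)
  truth <- attr(r, "truth")
  expect_lt(abs(f1[["df"]] - truth$df), 22050 / round(0.04 * 22050) + 1)
})
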