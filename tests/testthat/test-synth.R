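# Synthetic voice generator: determinism, phonatory control parameters
# measured by independent acoustic oracles, corpus layout invariants.

test_that("vowel synthesis is bit-identical under a fixed seed", {
  prof <- speaker_profiles(1, "HC", "domA", seed = 3)
  eff <- class_effects()[1, ]
  dom <- domain_specs()[1, ]
  r1 <- synth_vowel(prof, eff, dom, 1, seed = 7)
  r2 <- synth_vowel(prof, eff, dom, 1, seed = 7)
  expect_identical(r1$samples, r2$samples)
  r3 <- synth_ddk(prof, eff, dom, 2, seed = 7)
  r4 <- synth_ddk(prof, eff, dom, 2, seed = 7)
  expect_identical(r3$samples, r4$samples)
  expect_lte(max(abs(r1$samples)), 1)
  expect_error(synth_vowel(prof, eff, dom, 0.3, seed = 1), "0.49")
})

test_that("a jitter-free source has under 0.5% measured f0 variation", {
  prof <- oracle_plain_speaker(seed = 3)
  eff0 <- tibble::tibble(class_label = "HC", jitter_pct = 0,
                         shimmer_pct = 0, breath_noise_db = -Inf,
                         ddk_rate_hz = 6, ddk_rate_cv = 0)
  r <- synth_vowel(prof, eff0, oracle_flat_domain(), 1, seed = 5)
  cv <- oracle_f0_cv(r$samples, r$sample_rate)
  expect_lt(cv, 0.005)
  f0 <- oracle_track_f0(r$samples, r$sample_rate)
  expect_lt(abs(mean(f0) - prof$f0_base) / prof$f0_base, 0.02)
})

test_that("measured f0 variation is monotone in the jitter preset", {
  effs <- class_effects()
  dom <- oracle_flat_domain()
  for (s in 1:3) {
    prof <- oracle_plain_speaker(seed = s)
    cv_hc <- oracle_f0_cv(synth_vowel(prof, effs[1, ], dom, 1,
                                      seed = s * 10)$samples, 44100)
    cv_pd <- oracle_f0_cv(synth_vowel(prof, effs[2, ], dom, 1,
                                      seed = s * 10)$samples, 44100)
    expect_gt(cv_pd, cv_hc)
  }
})

test_that("class presets separate on oracle-measured f0 variation", {
  dom <- oracle_flat_domain()
  effs <- class_effects()
  cvs <- list(HC = c(), PD = c())
  for (cl in 1:2) {
    profs <- speaker_profiles(10, effs$class_label[cl], "flat", seed = 90 + cl)
    for (s in 1:10) {
      r <- synth_vowel(profs[s, ], effs[cl, ], dom, 1, seed = 1000 + s)
      cvs[[cl]] <- c(cvs[[cl]], oracle_f0_cv(r$samples, 44100))
    }
  }
  # accuracy of the best single threshold
  all_cv <- c(cvs$HC, cvs$PD)
  truth <- rep(c(0, 1), each = 10)
  acc <- max(vapply(all_cv, function(th) {
    mean((all_cv > th) == truth)
  }, numeric(1)))
  expect_gte(acc, 0.9)
})

test_that("DDK burst count and onset regularity follow the presets", {
  prof <- oracle_plain_speaker(seed = 2)
  dom <- oracle_flat_domain()
  eff <- tibble::tibble(class_label = "HC", jitter_pct = 0.5,
                        shimmer_pct = 2, breath_noise_db = -40,
                        ddk_rate_hz = 5, ddk_rate_cv = 0)
  r <- synth_ddk(prof, eff, dom, 2, seed = 5)
  onsets <- oracle_burst_onsets(r$samples, r$sample_rate)
  expect_equal(length(onsets), 10)
  # inter-onset intervals: sd strictly larger with rate_cv 0.3
  eff_j <- eff
  eff_j$ddk_rate_cv <- 0.3
  sds <- vapply(1:3, function(s) {
    on0 <- oracle_burst_onsets(synth_ddk(prof, eff, dom, 2,
                                         seed = s)$samples, 44100)
    on1 <- oracle_burst_onsets(synth_ddk(prof, eff_j, dom, 2,
                                         seed = s)$samples, 44100)
    sd(diff(on1)) - sd(diff(on0))
  }, numeric(1))
  expect_true(all(sds > 0))
})

test_that("generated corpora have the configured layout", {
  dir <- withr::local_tempdir()
  cfg <- corpus_config(dir, speakers_per_cell = 3, tasks = "vowel")
  manifest <- generate_corpus(cfg, seed = 9)
  expect_equal(nrow(manifest), 4 * 2 * 3)
  # no speaker under two domains
  per_speaker <- table(manifest$speaker_id,
                       manifest$domain_label) > 0
  expect_true(all(rowSums(per_speaker) == 1))
  # the 48 kHz domain carries its rate into the manifest and the files
  d48 <- manifest[manifest$domain_label == "domD", ]
  expect_true(all(d48$sample_rate == 48000))
  wav <- read_wav(d48$file_path[1])
  expect_equal(wav$sample_rate, 48000)
  # determinism of the whole corpus
  dir2 <- withr::local_tempdir()
  m2 <- generate_corpus(corpus_config(dir2, speakers_per_cell = 3,
                                      tasks = "vowel"), seed = 9)
  expect_identical(read_wav(manifest$file_path[5])$samples,
                   read_wav(m2$file_path[5])$samples)
  # balanced classes
  expect_true(all(table(manifest$class_label) == 12))
  expect_error(corpus_config(dir, speakers_per_cell = 0), "zero speakers")
})

test_that("domains differ in long-term average spectrum by construction", {
  doms <- domain_specs()
  eff <- class_effects()[1, ]
  spectra <- lapply(1:3, function(d) {
    prof <- oracle_plain_speaker(seed = 4, domain = doms$name[d])
    r <- synth_vowel(prof, eff, doms[d, ], 1, seed = 11)
    p <- Mod(stats::fft(r$samples))^2
    p <- p[1:8000]
    p / sum(p)
  })
  d12 <- sum(abs(spectra[[1]] - spectra[[2]]))
  d13 <- sum(abs(spectra[[1]] - spectra[[3]]))
  expect_gt(d12, 0.05)
  expect_gt(d13, 0.05)
})

test_that("WAV files round-trip through the codec", {
  x <- sin(2 * pi * 440 * (0:999) / 8000) * 0.8
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, path, 8000)
  w <- read_wav(path)
  expect_equal(w$sample_rate, 8000)
  expect_lt(max(abs(w$samples - x)), 1 / 32000)
})

test_that("the pretraining corpus has two classes in one domain", {
  dir <- withr::local_tempdir()
  m <- generate_pretrain_corpus(dir, speakers_per_class = 2, seed = 3)
  expect_setequal(unique(m$class_label), c("healthy", "disordered"))
  expect_equal(length(unique(m$domain_label)), 1)
  expect_equal(nrow(m), 4)
})
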