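# Independent oracles used across the suite. These deliberately avoid the
# package's own signal path: the f0 tracker is a plain autocorrelation
# tracker, the burst detector a moving-average envelope peak picker, and the
# gradient oracle is central finite differences.

# Two-pass autocorrelation f0 tracker: a global period estimate first, then
# frame-wise peaks restricted to +-25% of it (octave-error protection).
oracle_track_f0 <- function(x, sr, fmin = 70, fmax = 350,
                            frame_s = 0.04, hop_s = 0.01) {
  fl <- round(frame_s * sr)
  hp <- round(hop_s * sr)
  starts <- seq(1, length(x) - fl, by = hp)
  est <- function(fr, lags) {
    fr <- fr - mean(fr)
    ac <- vapply(lags, function(L) {
      sum(fr[1:(length(fr) - L)] * fr[(L + 1):length(fr)])
    }, numeric(1))
    lags[which.max(ac)]
  }
  lags_all <- floor(sr / fmax):ceiling(sr / fmin)
  glob <- est(x[1:min(length(x), 4 * fl)], lags_all)
  lags <- max(floor(sr / fmax), floor(glob * 0.8)):
    min(ceiling(sr / fmin), ceiling(glob * 1.25))
  sr / vapply(starts, function(s) est(x[s:(s + fl - 1)], lags), numeric(1))
}

oracle_f0_cv <- function(x, sr) {
  f0 <- oracle_track_f0(x, sr)
  stats::sd(f0) / mean(f0)
}

# Envelope peak picking: 20 ms moving-average of |x|, onsets where the
# envelope crosses 30% of its maximum upward.
oracle_burst_onsets <- function(x, sr) {
  k <- round(0.02 * sr)
  env <- stats::filter(abs(x), rep(1 / k, k), sides = 2)
  env[is.na(env)] <- 0
  above <- env > 0.3 * max(env)
  which(diff(c(FALSE, above)) == 1) / sr
}

# A flat, essentially noiseless domain for source-level measurements.
oracle_flat_domain <- function(sample_rate = 44100) {
  tibble::tibble(name = "flat", sample_rate = sample_rate,
                 channel_ir = list(c(1)), snr_db = 90, formant_shift = 1)
}

# Speaker with unit random effects so class presets act exactly as given.
oracle_plain_speaker <- function(seed = 1, domain = "flat") {
  p <- speaker_profiles(1, "X", domain, seed = seed)
  p$re_jitter <- 1
  p$re_shimmer <- 1
  p$re_rate <- 1
  p
}

# Central finite-difference gradient of f at x (vectorised over elements).
oracle_fd_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_len(length(x))) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# Layer-stack gradient check against finite differences on a random linear
# functional of the output. Returns max relative error over input and all
# parameters.
oracle_check_net <- function(layers, x, train = FALSE, eps = 1e-5,
                             skip_params = FALSE) {
  fw <- voiceda:::net_forward(layers, x, train)
  r <- array(rnorm(length(fw$out)), dim(fw$out) %||% length(fw$out))
  bw <- voiceda:::net_backward(fw$layers, fw$caches, r)
  loss <- function(lys, xx) sum(voiceda:::net_forward(lys, xx, train)$out * r)
  err <- max_rel_err(bw$dx, oracle_fd_grad(function(xx) loss(layers, xx), x,
                                           eps))
  if (!skip_params) {
    for (li in seq_along(layers)) {
      for (p in names(layers[[li]]$params)) {
        th <- layers[[li]]$params[[p]]
        fd <- oracle_fd_grad(function(v) {
          lp <- layers
          pp <- th
          pp[] <- v
          lp[[li]]$params[[p]] <- pp
          loss(lp, x)
        }, th, eps)
        err <- max(err, max_rel_err(bw$grads[[li]][[p]], fd))
      }
    }
  }
  err
}

# Tiny shared corpus, generated once per test session.
tiny_corpus_env <- new.env()
tiny_corpus <- function() {
  if (is.null(tiny_corpus_env$manifest)) {
    dir <- file.path(tempdir(), "voiceda-tiny-corpus")
    cfg <- corpus_config(dir, speakers_per_cell = 2, tasks = "vowel",
                         vowel_duration_s = 1.0)
    tiny_corpus_env$manifest <- generate_corpus(cfg, seed = 42L)
    tiny_corpus_env$data <- preprocess_corpus(tiny_corpus_env$manifest)
  }
  tiny_corpus_env
}

# Small spectrogram-level dataset with a strong class-linked pattern,
# bypassing audio synthesis entirely; used for optimisation tests.
rigged_segment_data <- function(n_speakers_per_class = 6, segs_per_speaker = 3,
                                shape = c(65, 41), strength = 2, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (cl in c("HC", "PD")) {
      for (s in seq_len(n_speakers_per_class)) {
        sp <- sprintf("%s_S%02d", cl, s)
        for (g in seq_len(segs_per_speaker)) {
          m <- matrix(rnorm(prod(shape)), shape[1], shape[2])
          if (cl == "PD") m[seq(1, shape[1], by = 2), ] <-
              m[seq(1, shape[1], by = 2), ] + strength
          m <- (m - mean(m)) / sqrt(mean((m - mean(m))^2))
          rows[[length(rows) + 1]] <- tibble::tibble(
            segment_id = paste0(sp, "#", g), recording = sp,
            speaker_id = sp, class_label = cl,
            domain_label = if (s %% 2 == 0) "domA" else "domB",
            task = "vowel", start_s = (g - 1) * 0.2, spec = list(m))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
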