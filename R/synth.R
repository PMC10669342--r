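# Seedable multi-domain synthetic voice generator.
#
# Two diagnostic classes differ in phonatory stability (cycle-to-cycle jitter
# and shimmer, aspiration noise, diadochokinetic rate and its regularity);
# recording domains differ in channel colouration, noise floor, sampling rate
# and a multiplicative formant offset standing in for language. Speaker-level
# random effects are drawn once per speaker so all material from one speaker
# is correlated — the property that makes speaker-independent validation
# meaningful.

#' A single synthetic voice recording
#'
#' @param samples Numeric waveform in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @param speaker_id,class_label,domain_label,task Provenance labels.
#' @return An object of class `voice_recording`.
#' @export
voice_recording <- function(samples, sample_rate, speaker_id = NA_character_,
                            class_label = NA_character_,
                            domain_label = NA_character_,
                            task = NA_character_) {
  stop_if_not(all(is.finite(samples)), "waveform contains non-finite samples")
  stop_if_not(sample_rate > 0, "sample_rate must be positive")
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         speaker_id = speaker_id, class_label = class_label,
         domain_label = domain_label, task = task),
    class = "voice_recording"
  )
}

#' @export
print.voice_recording <- function(x, ...) {
  cat(sprintf("<voice_recording> %s | %s | %s | %s | %.3f s @ %d Hz\n",
              x$speaker_id, x$class_label, x$domain_label, x$task,
              length(x$samples) / x$sample_rate, as.integer(x$sample_rate)))
  invisible(x)
}

#' Default recording-domain specifications
#'
#' Four domains emulating distinct recording corpora: three at 44.1 kHz and
#' one at 48 kHz, each with its own short FIR channel colouration (spectral
#' tilt), additive noise floor, and multiplicative formant offset acting as a
#' language proxy.
#'
#' @return A tibble with columns `name`, `sample_rate`, `channel_ir`
#'   (list-column of FIR taps), `snr_db`, `formant_shift`.
#' @export
domain_specs <- function() {
  tibble::tibble(
    name = c("domA", "domB", "domC", "domD"),
    sample_rate = c(44100, 44100, 44100, 48000),
    channel_ir = list(c(1), c(1, 0.65), c(1, -0.45), c(0.75, 0.35, 0.15)),
    snr_db = c(32, 24, 20, 26),
    formant_shift = c(1.00, 0.94, 1.06, 0.90)
  )
}

#' Class-level phonatory presets
#'
#' HC and PD presets are separable but noisy: PD has strictly larger jitter,
#' shimmer, breath noise and DDK-rate variability, and a slower DDK rate.
#'
#' @return A tibble with one row per class.
#' @export
class_effects <- function() {
  tibble::tibble(
    class_label = c("HC", "PD"),
    jitter_pct = c(0.5, 2.5),
    shimmer_pct = c(2.0, 8.0),
    breath_noise_db = c(-40, -25),
    ddk_rate_hz = c(6.0, 4.0),
    ddk_rate_cv = c(0.05, 0.25)
  )
}

# Pretraining presets: healthy vs generic voice disorder, a cruder and larger
# contrast than HC/PD, mirroring a pathological-voice reference corpus.
pretrain_effects <- function() {
  tibble::tibble(
    class_label = c("healthy", "disordered"),
    jitter_pct = c(0.4, 3.5),
    shimmer_pct = c(1.5, 12.0),
    breath_noise_db = c(-42, -20),
    ddk_rate_hz = c(6.0, 4.0),
    ddk_rate_cv = c(0.05, 0.3)
  )
}

#' Draw speaker profiles for one (domain, class) cell
#'
#' Per-speaker base f0 (females around 190 Hz, males around 115 Hz), formant
#' centre frequencies for /a/ with per-speaker scatter, and multiplicative
#' random effects on the class presets, drawn once per speaker.
#'
#' @param n Number of speakers.
#' @param class_label,domain_label Labels attached to every speaker.
#' @param seed Integer seed.
#' @param id_prefix Prefix for speaker ids.
#' @return A tibble with one row per speaker; `formants` is a list-column of
#'   three strictly increasing centre frequencies (Hz).
#' @export
speaker_profiles <- function(n, class_label, domain_label, seed,
                             id_prefix = paste0(domain_label, "_", class_label)) {
  stop_if_not(n >= 1, "need at least one speaker")
  with_seed(seed, {
    sex <- rep(c("F", "M"), length.out = n)
    f0 <- ifelse(sex == "F", rnorm(n, 190, 20), rnorm(n, 115, 15))
    f0 <- pmax(f0, 70)
    base_formants <- c(730, 1090, 2440)  # canonical /a/
    formants <- lapply(seq_len(n), function(i) {
      f <- base_formants * exp(rnorm(3, 0, 0.04))
      sort(f)
    })
    tibble::tibble(
      speaker_id = sprintf("%s_S%02d", id_prefix, seq_len(n)),
      sex = sex,
      f0_base = f0,
      formants = formants,
      class_label = class_label,
      domain_label = domain_label,
      # speaker random effects: scale the class presets once per speaker
      re_jitter = exp(rnorm(n, 0, 0.15)),
      re_shimmer = exp(rnorm(n, 0, 0.15)),
      re_rate = exp(rnorm(n, 0, 0.05))
    )
  })
}

# Apply a speaker's random effects to a class preset row.
speaker_effect <- function(profile, effect) {
  effect$jitter_pct <- effect$jitter_pct * (profile$re_jitter %||% 1)
  effect$shimmer_pct <- effect$shimmer_pct * (profile$re_shimmer %||% 1)
  effect$ddk_rate_hz <- effect$ddk_rate_hz * (profile$re_rate %||% 1)
  effect
}

# Voiced source: impulse train with per-cycle period jitter and amplitude
# shimmer; pulse energy split over adjacent samples to avoid grid quantisation
# masquerading as jitter.
glottal_source <- function(n, sr, f0, jitter_pct, shimmer_pct) {
  t0 <- 1 / f0
  n_cycles <- ceiling(n / sr / t0) + 4L
  periods <- t0 * (1 + jitter_pct / 100 * rnorm(n_cycles))
  periods <- pmax(periods, 0.2 * t0)
  amps <- pmax(1 + shimmer_pct / 100 * rnorm(n_cycles), 0.05)
  times <- cumsum(periods)
  keep <- times * sr < (n - 2)
  times <- times[keep]
  amps <- amps[keep]
  src <- numeric(n)
  pos <- times * sr
  idx <- floor(pos) + 1L
  frac <- pos - (idx - 1L)
  src[idx] <- src[idx] + amps * (1 - frac)
  src[idx + 1L] <- src[idx + 1L] + amps * frac
  src
}

# Cascade of three second-order resonators (Klatt-style formant filter).
formant_filter <- function(x, formants, sr, bandwidths = c(80, 110, 150)) {
  for (i in seq_along(formants)) {
    r <- exp(-pi * bandwidths[i] / sr)
    theta <- 2 * pi * formants[i] / sr
    x <- stats::filter(x, c(2 * r * cos(theta), -r^2), method = "recursive")
  }
  as.numeric(x)
}

# Channel chain shared by both tasks: FIR colouration then noise at snr_db.
apply_channel <- function(x, domain) {
  ir <- domain$channel_ir[[1]] %||% domain$channel_ir
  ir <- unlist(ir)
  stop_if_not(length(ir) >= 1, "channel_ir must be non-empty")
  y <- as.numeric(signal::filter(ir, 1, x))
  stop_if_not(is.finite(domain$snr_db), "snr_db must be finite")
  noise_sd <- rms(y) / 10^(domain$snr_db / 20)
  y <- y + rnorm(length(y), 0, noise_sd)
  y / max(abs(y)) * 0.95
}

as_row <- function(x) if (is.data.frame(x)) as.list(x[1, ]) else x

#' Synthesise a sustained vowel /a/
#'
#' Source-filter synthesis: an impulse-train source with per-cycle f0 jitter
#' and amplitude shimmer, plus aspiration noise, shaped by three formant
#' resonators (shifted by the domain's formant offset), then passed through
#' the domain channel (FIR colouration + noise at the domain SNR).
#'
#' @param profile One speaker row from [speaker_profiles()] (or a list with
#'   `f0_base`, `formants`, labels).
#' @param effect One class row from [class_effects()].
#' @param domain One domain row from [domain_specs()].
#' @param duration_s Duration in seconds; at least 0.49.
#' @param seed Integer seed; fixed seed gives a bit-identical waveform.
#' @return A [voice_recording()].
#' @export
synth_vowel <- function(profile, effect, domain, duration_s = 1, seed = 1L) {
  stop_if_not(duration_s >= 0.49,
              "duration_s must be at least 0.49 s, got ", duration_s)
  profile <- as_row(profile); effect <- as_row(effect); domain <- as_row(domain)
  effect <- speaker_effect(profile, effect)
  sr <- domain$sample_rate
  n <- round(duration_s * sr)
  with_seed(seed, {
    src <- glottal_source(n, sr, profile$f0_base,
                          effect$jitter_pct, effect$shimmer_pct)
    breath_gain <- 10^(effect$breath_noise_db / 20)
    if (breath_gain > 0) {
      src <- src + rnorm(n, 0, breath_gain * max(rms(src), 1e-12) * 8)
    }
    formants <- unlist(profile$formants) * (domain$formant_shift %||% 1)
    voiced <- formant_filter(src, formants, sr)
    out <- apply_channel(voiced, domain)
    voice_recording(out, sr, profile$speaker_id %||% NA_character_,
                    profile$class_label %||% NA_character_,
                    domain$name %||% NA_character_, "vowel")
  })
}

#' Synthesise a diadochokinetic /pa-ta-ka/-like burst train
#'
#' A train of syllable bursts — amplitude-modulated voiced pulses with
#' stop-gap silences and a short noise transient at each onset — at
#' `ddk_rate_hz` syllables per second with inter-onset jitter governed by
#' `ddk_rate_cv`, passed through the same domain channel chain as the vowels.
#'
#' @inheritParams synth_vowel
#' @return A [voice_recording()].
#' @export
synth_ddk <- function(profile, effect, domain, duration_s = 2, seed = 1L) {
  stop_if_not(duration_s >= 0.49,
              "duration_s must be at least 0.49 s, got ", duration_s)
  profile <- as_row(profile); effect <- as_row(effect); domain <- as_row(domain)
  effect <- speaker_effect(profile, effect)
  sr <- domain$sample_rate
  n <- round(duration_s * sr)
  rate <- effect$ddk_rate_hz
  cv <- effect$ddk_rate_cv
  with_seed(seed, {
    # onset times: first at half a nominal period, then jittered intervals
    onsets <- numeric(0)
    t <- 0.5 / rate
    repeat {
      if (t >= duration_s - 0.4 / rate) break
      onsets <- c(onsets, t)
      t <- t + pmax((1 / rate) * (1 + cv * rnorm(1)), 0.3 / rate)
    }
    stop_if_not(length(onsets) >= 1, "duration too short for one syllable")
    # continuous voiced source, gated by a per-syllable raised-cosine envelope
    src <- glottal_source(n, sr, profile$f0_base,
                          effect$jitter_pct, effect$shimmer_pct)
    breath_gain <- 10^(effect$breath_noise_db / 20)
    if (breath_gain > 0) {
      src <- src + rnorm(n, 0, breath_gain * max(rms(src), 1e-12) * 8)
    }
    formants <- unlist(profile$formants) * (domain$formant_shift %||% 1)
    voiced <- formant_filter(src, formants, sr)
    env <- numeric(n)
    syl_len <- round(0.45 / rate * sr)
    win <- 0.5 - 0.5 * cos(2 * pi * seq_len(syl_len) / (syl_len + 1))
    for (on in onsets) {
      i0 <- round(on * sr) + 1L
      i1 <- min(i0 + syl_len - 1L, n)
      env[i0:i1] <- pmax(env[i0:i1], win[seq_len(i1 - i0 + 1L)])
    }
    out <- voiced * env
    # consonant burst: 8 ms noise transient at each onset
    burst_len <- round(0.008 * sr)
    decay <- exp(-seq_len(burst_len) / (burst_len / 4))
    for (on in onsets) {
      i0 <- round(on * sr) + 1L
      i1 <- min(i0 + burst_len - 1L, n)
      k <- i1 - i0 + 1L
      out[i0:i1] <- out[i0:i1] +
        rnorm(k, 0, 0.4 * max(abs(voiced))) * decay[seq_len(k)]
    }
    out <- apply_channel(out, domain)
    voice_recording(out, sr, profile$speaker_id %||% NA_character_,
                    profile$class_label %||% NA_character_,
                    domain$name %||% NA_character_, "ddk")
  })
}

#' Corpus generation configuration
#'
#' @param out_dir Directory for WAV files and the manifest.
#' @param domains Tibble of domain specifications ([domain_specs()]).
#' @param effects Tibble of class presets ([class_effects()]).
#' @param speakers_per_cell Speakers per (domain, class) cell.
#' @param tasks Character subset of `c("vowel", "ddk")`.
#' @param vowel_duration_s,ddk_duration_s Recording durations (seconds).
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(out_dir, domains = domain_specs(),
                          effects = class_effects(), speakers_per_cell = 3,
                          tasks = "vowel", vowel_duration_s = 1.0,
                          ddk_duration_s = 2.0) {
  stop_if_not(all(tasks %in% c("vowel", "ddk")), "unknown task")
  stop_if_not(speakers_per_cell >= 1,
              "zero speakers requested in a (domain, class) cell")
  structure(list(out_dir = out_dir, domains = domains, effects = effects,
                 speakers_per_cell = speakers_per_cell, tasks = tasks,
                 vowel_duration_s = vowel_duration_s,
                 ddk_duration_s = ddk_duration_s),
            class = "corpus_config")
}

#' Generate a multi-domain corpus on disk
#'
#' Writes one 16-bit mono PCM WAV per (speaker, task) and a comma-separated
#' manifest. Speakers are never shared across domains; classes are balanced
#' per the configuration. Identical `(config, seed)` reproduce the corpus
#' bit for bit.
#'
#' @param config A [corpus_config()].
#' @param seed Integer master seed.
#' @return The manifest as a tibble with columns `file_path`, `speaker_id`,
#'   `class_label`, `domain_label`, `task`, `duration_s`, `sample_rate`;
#'   also written to `file.path(out_dir, "manifest.csv")`.
#' @export
generate_corpus <- function(config, seed = 1L) {
  stop_if_not(inherits(config, "corpus_config"), "need a corpus_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (d in seq_len(nrow(config$domains))) {
    domain <- config$domains[d, ]
    dir.create(file.path(config$out_dir, domain$name), showWarnings = FALSE)
    for (cl in seq_len(nrow(config$effects))) {
      effect <- config$effects[cl, ]
      profiles <- speaker_profiles(
        config$speakers_per_cell, effect$class_label, domain$name,
        seed = child_seed(seed, "profiles", domain$name, effect$class_label)
      )
      for (s in seq_len(nrow(profiles))) {
        prof <- profiles[s, ]
        for (task in config$tasks) {
          dur <- if (task == "vowel") config$vowel_duration_s else
            config$ddk_duration_s
          rec_seed <- child_seed(seed, "rec", prof$speaker_id, task)
          rec <- if (task == "vowel") {
            synth_vowel(prof, effect, domain, dur, rec_seed)
          } else {
            synth_ddk(prof, effect, domain, dur, rec_seed)
          }
          path <- file.path(config$out_dir, domain$name,
                            paste0(prof$speaker_id, "_", task, ".wav"))
          write_wav(rec$samples, path, rec$sample_rate)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            file_path = path, speaker_id = prof$speaker_id,
            class_label = effect$class_label, domain_label = domain$name,
            task = task, duration_s = length(rec$samples) / rec$sample_rate,
            sample_rate = rec$sample_rate
          )
        }
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(config$out_dir, "manifest.csv"))
  manifest
}

#' Generate the pretraining corpus (healthy vs voice disorder)
#'
#' A single-domain sustained-vowel corpus with a healthy/disordered contrast,
#' used for transfer-learning pretraining of the extractor and task head.
#'
#' @param out_dir Output directory.
#' @param speakers_per_class Speakers per class.
#' @param seed Integer seed.
#' @return The manifest tibble (see [generate_corpus()]).
#' @export
generate_pretrain_corpus <- function(out_dir, speakers_per_class = 8,
                                     seed = 1L) {
  cfg <- corpus_config(
    out_dir,
    domains = tibble::tibble(name = "pretrain", sample_rate = 44100,
                             channel_ir = list(c(1)), snr_db = 30,
                             formant_shift = 1),
    effects = pretrain_effects(),
    speakers_per_cell = speakers_per_class,
    tasks = "vowel"
  )
  generate_corpus(cfg, seed)
}
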