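# Raw recordings -> fixed-size normalised Mel-spectrogram tensors.
#
# Contract: every 400 ms segment at 44.1 kHz becomes a 65 x 41 image under
# either the 40 ms (sustained vowel) or 15 ms (DDK) analysis window, because
# the frame count is hop-determined (10 ms hop, centred framing).

#' Preprocessing configuration
#'
#' @param target_rate Common sampling rate every recording is resampled to
#'   (Hz).
#' @param segment_ms Segment length (ms).
#' @param overlap Fractional overlap between consecutive segments, in (0, 1).
#' @param window_ms Analysis window length (ms): 40 for sustained vowels,
#'   15 for DDK material.
#' @param hop_ms Hop between analysis frames (ms).
#' @param n_mels Number of Mel bands.
#' @param db_floor Lower clip for the dB-scaled spectrogram, relative to the
#'   per-segment maximum.
#' @param zscore_scope `"segment"` (per-spectrogram standardisation, the
#'   default) or `"global"` (statistics pooled over a whole batch).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_rate = 44100, segment_ms = 400,
                              overlap = 0.5, window_ms = 40, hop_ms = 10,
                              n_mels = 65, db_floor = -80,
                              zscore_scope = c("segment", "global")) {
  stop_if_not(overlap > 0 && overlap < 1, "overlap must be in (0, 1)")
  stop_if_not(window_ms < segment_ms, "window must be shorter than a segment")
  stop_if_not(n_mels >= 1, "need at least one Mel band")
  structure(list(target_rate = target_rate, segment_ms = segment_ms,
                 overlap = overlap, window_ms = window_ms, hop_ms = hop_ms,
                 n_mels = n_mels, db_floor = db_floor,
                 zscore_scope = match.arg(zscore_scope)),
            class = "preprocess_config")
}

#' Band-limited resampling of a recording
#'
#' Polyphase resampling to `target_rate`; the output length is
#' `round(n * target_rate / sample_rate)` (enforced to within the codec's
#' one-sample tolerance by edge padding/trimming). Matching rates return the
#' recording unchanged.
#'
#' @param rec A [voice_recording()].
#' @param target_rate Target sampling rate (Hz).
#' @return A [voice_recording()] at `target_rate` with labels preserved.
#' @export
resample_audio <- function(rec, target_rate = 44100) {
  stop_if_not(target_rate > 0, "target_rate must be positive")
  if (rec$sample_rate == target_rate) return(rec)
  p <- as.integer(round(target_rate))
  q <- as.integer(round(rec$sample_rate))
  g <- gcd_int(p, q)
  y <- signal::resample(rec$samples, p %/% g, q %/% g)
  n_out <- round(length(rec$samples) * target_rate / rec$sample_rate)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  out <- rec
  out$samples <- as.numeric(y)
  out$sample_rate <- target_rate
  out
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Peak-normalise a recording
#'
#' Scales the waveform so its maximum absolute amplitude is exactly 1.
#'
#' @param rec A [voice_recording()].
#' @return The scaled recording.
#' @export
peak_normalize <- function(rec) {
  peak <- max(abs(rec$samples))
  stop_if_not(peak > 0, "degenerate recording: all samples are zero")
  rec$samples <- rec$samples / peak
  rec
}

#' Cut a recording into fixed-length overlapping segments
#'
#' Segments of `segment_ms` start at multiples of
#' `segment_ms * (1 - overlap)`; a trailing remainder shorter than one
#' segment is dropped. Recordings shorter than one segment are rejected
#' rather than padded.
#'
#' @param rec A [voice_recording()] (already at the target rate).
#' @param config A [preprocess_config()].
#' @return A tibble with columns `segment` (list-column of sample vectors of
#'   length `round(segment_ms/1000 * rate)`), `start_s`, and the recording's
#'   labels.
#' @export
segment_audio <- function(rec, config = preprocess_config()) {
  sr <- rec$sample_rate
  seg_len <- round(config$segment_ms / 1000 * sr)
  hop <- round(seg_len * (1 - config$overlap))
  n <- length(rec$samples)
  if (n < seg_len) {
    stop("recording ", rec$speaker_id %||% "?", " is shorter (",
         round(n / sr * 1000), " ms) than one segment (",
         config$segment_ms, " ms)", call. = FALSE)
  }
  starts <- seq(0L, n - seg_len, by = hop)
  tibble::tibble(
    segment = lapply(starts, function(s) rec$samples[(s + 1L):(s + seg_len)]),
    start_s = starts / sr,
    speaker_id = rec$speaker_id, class_label = rec$class_label,
    domain_label = rec$domain_label, task = rec$task
  )
}

# Triangular Mel filterbank (HTK mel scale), rows = bands, cols = FFT bins.
mel_filterbank <- function(n_mels, n_fft, sr, fmin = 0, fmax = sr / 2) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freq <- (0:(n_fft %/% 2)) * sr / n_fft
  fb <- matrix(0, n_mels, length(bin_freq))
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_freq - lo) / (ce - lo)
    down <- (hi - bin_freq) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel spectrogram of one fixed-length segment
#'
#' Centred short-time analysis (reflect padding) with a Hann window of
#' `window_ms` and hop `hop_ms`, so a 400 ms segment at 44.1 kHz yields
#' `1 + floor(17640/441) = 41` frames; 65 triangular Mel bands; power mapped
#' to dB relative to the segment maximum and clipped at `db_floor`.
#'
#' @param segment Numeric vector of exactly
#'   `round(segment_ms/1000 * target_rate)` samples.
#' @param config A [preprocess_config()]; `window_ms` selects the vowel
#'   (40 ms) or DDK (15 ms) analysis.
#' @return A `n_mels` x `n_frames` numeric matrix in dB (not yet z-scored).
#' @export
mel_spectrogram <- function(segment, config = preprocess_config()) {
  sr <- config$target_rate
  seg_len <- round(config$segment_ms / 1000 * sr)
  stop_if_not(length(segment) == seg_len,
              "segment has ", length(segment), " samples, expected ", seg_len)
  win_len <- round(config$window_ms / 1000 * sr)
  hop <- round(config$hop_ms / 1000 * sr)
  n_frames <- 1L + floor(seg_len / hop)
  n_fft <- 2^ceiling(log2(win_len))
  segment <- segment - mean(segment)  # DC removal
  half <- ceiling(win_len / 2)
  padded <- c(rev(segment[2:(half + 1)]), segment,
              rev(segment[(seg_len - half):(seg_len - 1)]))
  centers <- (0:(n_frames - 1L)) * hop + half + 1L  # in padded coordinates
  idx <- outer(seq_len(win_len) - (win_len %/% 2L) - 1L, centers, "+")
  frames <- matrix(padded[idx], nrow = win_len)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win_len - 1)) / (win_len - 1))
  frames <- frames * hann
  frames <- rbind(frames, matrix(0, n_fft - win_len, n_frames))
  spec <- stats::mvfft(frames)[1:(n_fft %/% 2 + 1), , drop = FALSE]
  power <- Mod(spec)^2
  fb <- mel_filterbank(config$n_mels, n_fft, sr)
  mel <- fb %*% power
  ref <- max(mel)
  if (ref <= .Machine$double.eps) {
    return(matrix(config$db_floor, config$n_mels, n_frames))
  }
  db <- 10 * log10(pmax(mel / ref, 10^(config$db_floor / 10)))
  db
}

#' Z-score a spectrogram
#'
#' Standardises to mean 0 and standard deviation 1 (population convention,
#' i.e. dividing by `n`, not `n - 1`).
#'
#' @param spec Numeric matrix with finite entries and nonzero variance.
#' @return The standardised matrix.
#' @export
zscore_spec <- function(spec) {
  stop_if_not(all(is.finite(spec)), "spectrogram has non-finite entries")
  mu <- mean(spec)
  s <- sqrt(mean((spec - mu)^2))
  stop_if_not(s > 0, "degenerate segment: zero-variance spectrogram")
  (spec - mu) / s
}

#' Preprocess a corpus manifest into spectrogram tensors
#'
#' Reads each WAV, resamples to the target rate, peak-normalises, segments,
#' and computes z-scored Mel spectrograms. The analysis window follows the
#' task: `window_ms` for vowels and `ddk_window_ms` for DDK recordings.
#'
#' @param manifest Manifest tibble from [generate_corpus()] (or user corpora
#'   in the same layout).
#' @param config A [preprocess_config()]; its `window_ms` is used for vowels.
#' @param ddk_window_ms Analysis window for DDK recordings (ms).
#' @return A tibble with one row per segment: `segment_id`, `recording`,
#'   `speaker_id`, `class_label`, `domain_label`, `task`, `start_s`, and
#'   `spec` (list-column of z-scored `n_mels` x 41 matrices).
#' @export
preprocess_corpus <- function(manifest, config = preprocess_config(),
                              ddk_window_ms = 15) {
  rows <- purrr::pmap(manifest, function(file_path, speaker_id, class_label,
                                         domain_label, task, ...) {
    wav <- read_wav(file_path)
    rec <- voice_recording(wav$samples, wav$sample_rate, speaker_id,
                           class_label, domain_label, task)
    rec <- resample_audio(rec, config$target_rate)
    rec <- peak_normalize(rec)
    segs <- segment_audio(rec, config)
    cfg <- config
    if (task == "ddk") cfg$window_ms <- ddk_window_ms
    segs$spec <- lapply(segs$segment, function(s) mel_spectrogram(s, cfg))
    segs$segment <- NULL
    segs$recording <- file_path
    segs$segment_id <- paste0(basename(file_path), "#",
                              sprintf("%03d", seq_len(nrow(segs)) - 1L))
    segs
  })
  out <- dplyr::bind_rows(rows)
  if (config$zscore_scope == "global") {
    all_vals <- unlist(out$spec)
    mu <- mean(all_vals)
    s <- sqrt(mean((all_vals - mu)^2))
    stop_if_not(s > 0, "degenerate corpus: zero global variance")
    out$spec <- lapply(out$spec, function(m) (m - mu) / s)
  } else {
    out$spec <- lapply(out$spec, zscore_spec)
  }
  dplyr::select(out, "segment_id", "recording", "speaker_id", "class_label",
                "domain_label", "task", "start_s", "spec")
}
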