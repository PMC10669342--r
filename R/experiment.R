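# Orchestration: simulate -> preprocess -> train (baseline + DA) ->
# evaluate -> audit, reproducibly from one configuration and seed.

#' Patient-level predictions
#'
#' Runs inference and reduces per-segment probabilities to one decision per
#' patient via the joint-probability rule ([patient_decision()]). The
#' recurrent architecture already emits one probability per recording; its
#' per-patient reduction is the same rule over the patient's recordings
#' (a no-op for single-recording patients).
#'
#' @param object A `voiceda_fit` or `voiceda_model`.
#' @param data Preprocessed segment tibble.
#' @param class_levels,domain_levels Label orderings (default: sorted).
#' @return Tibble `speaker_id`, `class_label` (truth), `domain_label`,
#'   `pred`.
#' @export
predict_patients <- function(object, data, class_levels = NULL,
                             domain_levels = NULL) {
  bundle <- if (inherits(object, "voiceda_fit")) object$bundle else object
  class_levels <- class_levels %||%
    (if (inherits(object, "voiceda_fit")) object$class_levels else
       sort(unique(data$class_label)))
  domain_levels <- domain_levels %||% sort(unique(data$domain_label))
  ev <- evaluate_segments(bundle, data, class_levels, domain_levels)
  meta <- ev$meta
  by_speaker <- split(seq_len(nrow(meta)), meta$speaker_id)
  rows <- lapply(names(by_speaker), function(sp) {
    idx <- by_speaker[[sp]]
    tibble::tibble(
      speaker_id = sp,
      class_label = meta$class_label[idx[1]],
      domain_label = meta$domain_label[idx[1]],
      pred = patient_decision(t(ev$probs[, idx, drop = FALSE]),
                              classes = class_levels))
  })
  dplyr::bind_rows(rows)
}

#' Experiment configuration
#'
#' @param out_dir Run directory (created if needed).
#' @param task `"vowel"` or `"ddk"`.
#' @param architecture `"cnn2d"`, `"time_cnn_lstm"` or `"cnn1d"`.
#' @param hp A [hyperparams()].
#' @param dacfg A [da_config()].
#' @param train_cfg A [train_config()].
#' @param speakers_per_cell Speakers per (domain, class) cell of the
#'   synthetic corpus (default 12: 24 speakers per domain, 96 in total).
#' @param test_fraction Fraction of speakers per cell held out for testing.
#' @param corpus_dir Directory holding (or receiving) the corpus; defaults
#'   to `file.path(out_dir, "corpus")`. Several runs may share one corpus —
#'   the generated data play the role of the fixed study corpora, while the
#'   seed varies split, initialisation and training.
#' @param audit_on Which segments feed the divergence audit: `"all"`
#'   (default; pooling train and test maximises the stability of the
#'   Gaussian divergence estimates at this corpus scale), `"test"` or
#'   `"train"`.
#' @param audit_tap Representation audited for domain structure:
#'   `"extractor"` (default) or `"head"`. At this experiment's scale the
#'   small task head is essentially domain-blind for baseline and
#'   adversarial models alike, so the baseline-vs-DA comparison is only
#'   informative at the extractor output, where the domain structure
#'   actually resides.
#' @param seed Master seed.
#' @param figures Write t-SNE and training-curve figures?
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(out_dir, task = c("vowel", "ddk"),
                              architecture = "cnn2d",
                              hp = hyperparams(conv_depth = 8, fc_units = 16,
                                               validate = FALSE),
                              dacfg = da_config(),
                              train_cfg = train_config(epochs = 20),
                              speakers_per_cell = 12, test_fraction = 0.25,
                              corpus_dir = NULL,
                              audit_on = c("all", "test", "train"),
                              audit_tap = c("extractor", "head"),
                              seed = 1L, figures = FALSE) {
  structure(list(out_dir = out_dir, task = match.arg(task),
                 architecture = architecture, hp = hp, dacfg = dacfg,
                 train_cfg = train_cfg,
                 speakers_per_cell = speakers_per_cell,
                 test_fraction = test_fraction,
                 corpus_dir = corpus_dir,
                 audit_on = match.arg(audit_on),
                 audit_tap = match.arg(audit_tap), seed = seed,
                 figures = figures),
            class = "experiment_config")
}

# Stratified speaker-level holdout: within every (domain, class) cell the
# last ceiling(fraction * n) shuffled speakers are the test set.
holdout_split <- function(manifest, fraction, seed) {
  speakers <- dplyr::distinct(manifest, .data$speaker_id, .data$class_label,
                              .data$domain_label)
  test_ids <- c()
  cells <- split(speakers$speaker_id,
                 paste(speakers$domain_label, speakers$class_label))
  for (cell in names(sort(unlist(lapply(cells, length)), decreasing = FALSE))) {
    ids <- sort(cells[[cell]])
    n_test <- max(1L, ceiling(fraction * length(ids)))
    picked <- with_seed(child_seed(seed, "holdout", cell),
                        sample(ids, n_test))
    test_ids <- c(test_ids, picked)
  }
  test_ids
}

#' Run the corpus-invariance experiment
#'
#' Generates (or reuses) the synthetic multi-domain corpus, preprocesses it,
#' trains a seed-matched baseline and domain-adversarial pair on the mixed
#' domains with a stratified speaker-disjoint holdout, computes patient
#' metrics per held-out domain, the divergence audit (intra-class
#' inter-domain KL, per-class TCM) for both variants, and a machine-readable
#' comparison verdict. All artifacts are written under `cfg$out_dir`.
#'
#' @param cfg An [experiment_config()].
#' @return A `voiceda_experiment` list: `fits`, `metrics`, `divergence`,
#'   `verdict`, `accuracy`, `run_dir`.
#' @export
run_invariance_experiment <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  logf <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                paste0(...)), file = log_path, append = TRUE)
  }
  snapshot <- cfg
  snapshot$hp <- unclass(cfg$hp)
  snapshot$dacfg <- unclass(cfg$dacfg)
  snapshot$train_cfg <- unclass(cfg$train_cfg)
  jsonlite::write_json(snapshot, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, force = TRUE)
  corpus_dir <- cfg$corpus_dir %||% file.path(cfg$out_dir, "corpus")
  manifest_path <- file.path(corpus_dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
    logf("reusing corpus: ", nrow(manifest), " recordings")
  } else {
    logf("generating corpus")
    manifest <- generate_corpus(
      corpus_config(corpus_dir, speakers_per_cell = cfg$speakers_per_cell,
                    tasks = cfg$task),
      seed = child_seed(cfg$seed, "corpus"))
  }
  stop_if_not(length(unique(manifest$domain_label)) >= 2,
              "domain-adversarial training needs at least 2 domains")
  logf("preprocessing ", nrow(manifest), " recordings")
  pp_cfg <- preprocess_config(window_ms = if (cfg$task == "vowel") 40 else 15)
  data <- preprocess_corpus(manifest, pp_cfg)
  test_ids <- holdout_split(manifest, cfg$test_fraction,
                            child_seed(cfg$seed, "split"))
  train_data <- dplyr::filter(data, !(.data$speaker_id %in% test_ids))
  test_data <- dplyr::filter(data, .data$speaker_id %in% test_ids)
  n_domains <- length(unique(manifest$domain_label))
  dacfg <- cfg$dacfg
  dacfg$n_domains <- n_domains
  init_seed <- child_seed(cfg$seed, "init")
  variants <- list(
    baseline = assemble(cfg$architecture, cfg$hp, da = FALSE,
                        seed = init_seed),
    da = assemble(cfg$architecture, cfg$hp, da = TRUE, dacfg = dacfg,
                  seed = init_seed)
  )
  fits <- list()
  metrics <- list()
  divergence <- list()
  accuracy <- list()
  for (v in names(variants)) {
    logf("training ", v)
    tc <- cfg$train_cfg
    tc$seed <- child_seed(cfg$seed, "train")   # seed-matched across variants
    fits[[v]] <- fit(variants[[v]], train_data, test_data, tc)
    readr::write_csv(fits[[v]]$history,
                     file.path(cfg$out_dir, paste0("history_", v, ".csv")))
    # the audit and the reported decisions use the fully trained network:
    # adversarial invariance develops along the lambda ramp, so the final
    # epoch, not an early accuracy-tied checkpoint, is the comparable state
    final <- fits[[v]]$final_bundle
    preds <- predict_patients(final, test_data,
                              class_levels = fits[[v]]$class_levels)
    accuracy[[v]] <- 100 * mean(preds$pred == preds$class_label)
    per_domain <- lapply(sort(unique(preds$domain_label)), function(dl) {
      sub <- preds[preds$domain_label == dl, ]
      if (length(unique(sub$class_label)) < 2) {
        return(tibble::tibble(test = dl, accuracy = NA_real_))
      }
      dplyr::bind_cols(tibble::tibble(test = dl),
                       classification_metrics(sub$class_label, sub$pred))
    })
    metrics[[v]] <- dplyr::bind_rows(per_domain)
    readr::write_csv(metrics[[v]],
                     file.path(cfg$out_dir, paste0("metrics_", v, ".csv")))
    logf(v, " patient accuracy: ", round(accuracy[[v]], 1), "%")
    audit_data <- switch(cfg$audit_on %||% "all",
                         all = data, test = test_data, train = train_data)
    emb <- extract_embeddings(final, audit_data,
                              tap = cfg$audit_tap %||% "extractor")
    divergence[[v]] <- divergence_report(emb)
    readr::write_csv(divergence[[v]]$kl,
                     file.path(cfg$out_dir, paste0("kl_", v, ".csv")))
    readr::write_csv(divergence[[v]]$tcm,
                     file.path(cfg$out_dir, paste0("tcm_", v, ".csv")))
    if (isTRUE(cfg$figures)) {
      n_emb <- nrow(emb)
      perp <- min(30, max(5, floor(n_emb / 3) - 1))
      ts <- tsne_map(emb, seed = child_seed(cfg$seed, "tsne"),
                     perplexity = perp)
      for (colour in c("class_label", "domain_label")) {
        ggplot2::ggsave(
          file.path(cfg$out_dir, sprintf("tsne_%s_%s.png", v, colour)),
          autoplot(ts, colour_by = colour), width = 6, height = 5,
          dpi = 120)
      }
    }
  }
  kl_means <- lapply(divergence, function(d) d$kl_mean)
  tcms <- lapply(divergence, function(d) d$tcm)
  named <- function(x, nm) as.list(stats::setNames(x, nm))
  verdict <- list(
    kl_mean = list(baseline = named(kl_means$baseline$mean_kl,
                                    kl_means$baseline$class_label),
                   da = named(kl_means$da$mean_kl,
                              kl_means$da$class_label)),
    tcm = list(baseline = named(tcms$baseline$tcm,
                                tcms$baseline$class_label),
               da = named(tcms$da$tcm, tcms$da$class_label)),
    patient_accuracy = accuracy,
    da_lower_kl = all(kl_means$da$mean_kl < kl_means$baseline$mean_kl),
    da_lower_tcm = all(tcms$da$tcm < tcms$baseline$tcm),
    accuracy_gap = accuracy$da - accuracy$baseline
  )
  jsonlite::write_json(verdict, file.path(cfg$out_dir, "verdict.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("verdict: DA lower KL = ", verdict$da_lower_kl,
       ", DA lower TCM = ", verdict$da_lower_tcm)
  structure(list(fits = fits, metrics = metrics, divergence = divergence,
                 verdict = verdict, accuracy = accuracy,
                 run_dir = cfg$out_dir),
            class = "voiceda_experiment")
}

#' @export
print.voiceda_experiment <- function(x, ...) {
  cat("<voiceda_experiment> run dir:", x$run_dir, "\n")
  cat(report_run(x$run_dir), sep = "\n")
  invisible(x)
}

#' Human-readable summary of a completed run
#'
#' Renders the per-domain patient metrics and the invariance verdict as
#' "mean (sd)"-style tables. Missing cells are rendered as `-`.
#'
#' @param run_dir Directory written by [run_invariance_experiment()].
#' @return Character vector of report lines, invisibly printed.
#' @export
report_run <- function(run_dir) {
  stop_if_not(file.exists(file.path(run_dir, "verdict.json")),
              "incomplete run: no verdict.json in ", run_dir)
  verdict <- jsonlite::read_json(file.path(run_dir, "verdict.json"),
                                 simplifyVector = TRUE)
  lines <- c("== corpus-invariance experiment ==")
  for (v in c("baseline", "da")) {
    path <- file.path(run_dir, paste0("metrics_", v, ".csv"))
    lines <- c(lines, sprintf("-- %s --", v))
    if (!file.exists(path)) { lines <- c(lines, "  (missing)"); next }
    m <- readr::read_csv(path, show_col_types = FALSE)
    for (i in seq_len(nrow(m))) {
      cells <- vapply(c("accuracy", "f1", "sensitivity", "specificity"),
                      function(cn) {
                        val <- m[[cn]][i]
                        if (is.null(val) || is.na(val)) "-" else
                          sprintf("%.1f", val)
                      }, character(1))
      lines <- c(lines, sprintf(
        "  test %-8s acc %s  F1 %s  sen %s  spe %s",
        m$test[i], cells[1], cells[2], cells[3], cells[4]))
    }
  }
  fmt_num <- function(x) sprintf("%.4f", x)
  lines <- c(lines, "-- invariance audit --")
  for (cl in names(verdict$kl_mean$baseline)) {
    lines <- c(lines, sprintf(
      "  class %-3s mean KL baseline %s -> DA %s | TCM baseline %s -> DA %s",
      cl, fmt_num(verdict$kl_mean$baseline[[cl]]),
      fmt_num(verdict$kl_mean$da[[cl]]),
      fmt_num(verdict$tcm$baseline[[cl]]), fmt_num(verdict$tcm$da[[cl]])))
  }
  lines <- c(lines, sprintf(
    "  patient accuracy baseline %.1f%% | DA %.1f%% (gap %+.1f)",
    verdict$patient_accuracy$baseline, verdict$patient_accuracy$da,
    verdict$accuracy_gap))
  lines
}
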