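# Patient-level decisions, classification metrics, and the corpus-invariance
# audit: embedding extraction, intra-class inter-domain Gaussian KL
# divergence, trace of covariance (TCM), and t-SNE maps.

#' Patient decision from segment probabilities
#'
#' Assigns the patient to the class with the highest joint probability over
#' all of the patient's segments (product of per-segment probabilities,
#' computed as a log sum). Ties go to the first class (HC).
#'
#' @param segment_probs Matrix with one row per segment and one column per
#'   class (rows sum to 1), or a list of probability vectors.
#' @param classes Class names, first = the tie-break class.
#' @return A single class label.
#' @export
patient_decision <- function(segment_probs, classes = c("HC", "PD")) {
  if (is.list(segment_probs)) {
    segment_probs <- do.call(rbind, segment_probs)
  }
  segment_probs <- as.matrix(segment_probs)
  stop_if_not(nrow(segment_probs) >= 1, "no segments for this patient")
  score <- colSums(log(pmax(segment_probs, 1e-300)))
  classes[which.max(score)]  # which.max takes the first maximum: tie -> HC
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, F1 of the positive class, sensitivity (recall of the positive
#' class) and specificity, as percentages.
#'
#' @param y_true,y_pred Label vectors of equal length; `y_true` must contain
#'   both classes.
#' @param positive The positive (disease) class.
#' @return A one-row tibble with `accuracy`, `f1`, `sensitivity`,
#'   `specificity` (percent) and the confusion counts.
#' @export
classification_metrics <- function(y_true, y_pred, positive = "PD") {
  stop_if_not(length(y_true) == length(y_pred),
              "y_true and y_pred differ in length")
  stop_if_not(length(unique(y_true)) >= 2,
              "y_true contains a single class")
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  tibble::tibble(accuracy = 100 * (tp + tn) / length(y_true),
                 f1 = 100 * f1, sensitivity = 100 * sens,
                 specificity = 100 * spec,
                 tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Format fold-level metrics as "mean (sd)" strings
#'
#' @param metrics Tibble of per-fold metric rows (percent scale).
#' @param cols Metric columns to summarise.
#' @return One-row tibble of `"72.4 (10.6)"`-style strings.
#' @export
format_mean_sd <- function(metrics,
                           cols = c("accuracy", "f1", "sensitivity",
                                    "specificity")) {
  out <- lapply(cols, function(cn) {
    v <- metrics[[cn]]
    if (is.null(v) || all(is.na(v))) return("-")
    sprintf("%.1f (%.1f)", mean(v, na.rm = TRUE),
            if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0)
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

#' Extract embeddings at the registered tap point
#'
#' Runs the model in inference mode and taps either the representation
#' entering the task head's softmax layer (`"head"`, the default: the
#' head's hidden layer of width `fc_units`) or the extractor output
#' (`"extractor"`).
#'
#' @param object A `voiceda_fit` or `voiceda_model`.
#' @param data Preprocessed segment tibble.
#' @param tap `"head"` or `"extractor"`.
#' @return A tibble with the alignment labels (`speaker_id`, `class_label`,
#'   `domain_label`, ...) and an `embedding` list-column of numeric vectors.
#' @export
extract_embeddings <- function(object, data, tap = c("head", "extractor")) {
  tap <- match.arg(tap)
  bundle <- if (inherits(object, "voiceda_fit")) object$bundle else object
  stop_if_not(inherits(bundle, "voiceda_model"), "need a voiceda model")
  units <- batch_units(bundle, data)
  class_levels <- sort(unique(data$class_label))
  domain_levels <- sort(unique(data$domain_label))
  rows <- list()
  for (b0 in seq(1, length(units), by = 256L)) {
    take <- seq(b0, min(b0 + 255L, length(units)))
    idx <- unlist(units[take])
    bt <- assemble_batch(bundle, data, idx, class_levels, domain_levels)
    fw <- model_forward(bundle, bt$x, train = FALSE)
    emb <- if (tap == "head") fw$pd$hidden else fw$emb
    meta <- bt$meta
    meta$embedding <- lapply(seq_len(ncol(emb)), function(j) emb[, j])
    rows[[length(rows) + 1]] <- meta
  }
  dplyr::bind_rows(rows)
}

#' Stack an embedding list-column into a matrix
#'
#' @param emb Tibble with an `embedding` list-column.
#' @return Numeric matrix, one row per embedding.
#' @export
embedding_matrix <- function(emb) {
  do.call(rbind, emb$embedding)
}

# Ledoit-Wolf shrinkage of the ML covariance toward a scaled identity.
shrunk_covariance <- function(x) {
  n <- nrow(x)
  d <- ncol(x)
  xc <- sweep(x, 2, colMeans(x), "-")
  s <- crossprod(xc) / n
  mu <- sum(diag(s)) / d
  delta2 <- sum((s - mu * diag(d))^2) / d
  if (delta2 < 1e-300) return(s + 1e-8 * diag(d))
  q <- rowSums(xc^2)
  # sum_k ||x_k x_k' - S||_F^2 = sum(q^2) - 2 sum_k x_k' S x_k + n ||S||^2
  cross <- sum(xc * (xc %*% s))
  beta2 <- (sum(q^2) - 2 * cross + n * sum(s^2)) / (n^2 * d)
  beta2 <- min(beta2, delta2)
  rho <- beta2 / delta2
  # small ridge keeps the estimate invertible when dimensions collapse
  rho * mu * diag(d) + (1 - rho) * s + max(mu, 1e-12) * 1e-6 * diag(d)
}

#' Symmetrised Gaussian Kullback-Leibler divergence between two groups
#'
#' Fits a multivariate Gaussian (mean + shrinkage-regularised covariance)
#' to each group and returns `0.5 * (KL(P||Q) + KL(Q||P))` via the closed
#' Gaussian form.
#'
#' @param x,y Numeric matrices (rows = samples) or vectors.
#' @param shrinkage `"ledoit-wolf"` (default) or `"none"`.
#' @param ridge Nonnegative scalar added to the diagonal of both fitted
#'   covariances. With few samples per group in many dimensions the fitted
#'   Gaussians can collapse and the divergence diverges; callers comparing
#'   many small groups pass a ridge on the scale of the pooled variance
#'   (see [intraclass_domain_kl()]). Default 0 (no floor).
#' @return Nonnegative scalar, invariant to swapping `x` and `y`.
#' @export
gaussian_kl_symmetric <- function(x, y,
                                  shrinkage = c("ledoit-wolf", "none"),
                                  ridge = 0) {
  shrinkage <- match.arg(shrinkage)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  stop_if_not(nrow(x) >= 2 && nrow(y) >= 2,
              "each group needs at least 2 samples")
  covf <- if (shrinkage == "ledoit-wolf") shrunk_covariance else {
    function(m) {
      mc <- sweep(m, 2, colMeans(m), "-")
      s0 <- crossprod(mc) / nrow(m)
      s0 + max(mean(diag(s0)), 1e-12) * 1e-6 * diag(ncol(m))
    }
  }
  mu_p <- colMeans(x); mu_q <- colMeans(y)
  sp <- covf(x) + ridge * diag(ncol(x))
  sq <- covf(y) + ridge * diag(ncol(y))
  d <- ncol(x)
  kl_dir <- function(mu0, s0, mu1, s1) {
    ch <- chol(s1)
    inv1 <- chol2inv(ch)
    dm <- mu1 - mu0
    0.5 * (sum(inv1 * s0) + sum(dm * (inv1 %*% dm)) - d +
             2 * sum(log(diag(ch))) - determinant_log(s0))
  }
  0.5 * (kl_dir(mu_p, sp, mu_q, sq) + kl_dir(mu_q, sq, mu_p, sp))
}

determinant_log <- function(s) {
  2 * sum(log(diag(chol(s))))
}

#' Intra-class inter-domain KL divergences
#'
#' For each diagnostic class, the symmetrised Gaussian KL divergence between
#' the embedding distributions of every unordered pair of domains (4 domains
#' give 6 pairs per class). Low values indicate corpus-invariant features.
#'
#' @param emb Embedding tibble from [extract_embeddings()].
#' @param shrinkage Covariance regularisation, see [gaussian_kl_symmetric()].
#' @param ridge_frac Per-class covariance floor as a fraction of the pooled
#'   intra-class per-dimension variance; stabilises the divergence when a
#'   (class, domain) cluster collapses. 0 disables.
#' @return A tibble `class_label`, `domain_a`, `domain_b`, `kl`.
#' @export
intraclass_domain_kl <- function(emb, shrinkage = "ledoit-wolf",
                                 ridge_frac = 0.01) {
  classes <- sort(unique(emb$class_label))
  domains <- sort(unique(emb$domain_label))
  stop_if_not(length(domains) >= 2, "need at least 2 domains")
  rows <- list()
  for (cl in classes) {
    sub <- emb[emb$class_label == cl, ]
    pooled <- embedding_matrix(sub)
    ridge <- ridge_frac * mean(apply(pooled, 2, stats::var))
    for (dom in domains) {
      stop_if_not(sum(sub$domain_label == dom) >= 2,
                  "empty or singleton (class, domain) cell: ", cl, "/", dom)
    }
    for (i in seq_len(length(domains) - 1)) {
      for (j in seq(i + 1, length(domains))) {
        xi <- embedding_matrix(sub[sub$domain_label == domains[i], ])
        xj <- embedding_matrix(sub[sub$domain_label == domains[j], ])
        rows[[length(rows) + 1]] <- tibble::tibble(
          class_label = cl, domain_a = domains[i], domain_b = domains[j],
          kl = gaussian_kl_symmetric(xi, xj, shrinkage, ridge = ridge))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Trace of the covariance matrix of a class's embeddings
#'
#' Trace of the unbiased (`n - 1` denominator) sample covariance of all
#' embeddings of one class, domains pooled: a scalar spread measure.
#'
#' @param emb Embedding tibble from [extract_embeddings()].
#' @param class Class label to restrict to (default: use all rows).
#' @return Nonnegative scalar.
#' @export
tcm <- function(emb, class = NULL) {
  if (!is.null(class)) emb <- emb[emb$class_label == class, ]
  x <- embedding_matrix(emb)
  stop_if_not(nrow(x) >= 2, "need at least 2 samples")
  sum(apply(x, 2, var))
}

#' Divergence report: KL pairs and per-class TCM
#'
#' @param emb Embedding tibble from [extract_embeddings()].
#' @return A list with `kl` (pairwise tibble from
#'   [intraclass_domain_kl()]), `kl_mean` (per class), `tcm` (per class).
#' @export
divergence_report <- function(emb) {
  kl <- intraclass_domain_kl(emb)
  kl_mean <- dplyr::summarise(dplyr::group_by(kl, .data$class_label),
                              mean_kl = mean(.data$kl), .groups = "drop")
  classes <- sort(unique(emb$class_label))
  tcm_tbl <- tibble::tibble(
    class_label = classes,
    tcm = vapply(classes, function(cl) tcm(emb, cl), numeric(1)))
  structure(list(kl = kl, kl_mean = kl_mean, tcm = tcm_tbl),
            class = "voiceda_divergence")
}

#' @export
print.voiceda_divergence <- function(x, ...) {
  cat("<voiceda_divergence>\n mean intra-class inter-domain KL:\n")
  print(x$kl_mean)
  cat(" per-class TCM:\n")
  print(x$tcm)
  invisible(x)
}
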