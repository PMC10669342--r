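# Optimisation: transfer-learning pretraining, first-layer freezing,
# baseline and domain-adversarial SGD with weighted cross-entropy, stratified
# speaker-independent k-fold cross-validation, and hyperparameter search.

#' Stratified speaker-independent fold assignment
#'
#' Speakers (never segments) are assigned to folds, stratified by class, so
#' no speaker's material can appear on both sides of any train/validation
#' split. Per-fold class counts differ from perfect balance by at most one
#' speaker.
#'
#' @param speakers Character vector of speaker ids (one entry per speaker).
#' @param class_labels Class label per speaker.
#' @param k Number of folds; at most the per-class speaker count.
#' @param seed Integer seed.
#' @return A tibble `speaker_id`, `class_label`, `fold` (1-based).
#' @export
make_folds <- function(speakers, class_labels, k = 10, seed = 1L) {
  stop_if_not(length(speakers) == length(class_labels),
              "speakers and class_labels differ in length")
  stop_if_not(!anyDuplicated(speakers), "duplicated speaker ids")
  counts <- table(class_labels)
  if (any(counts < k)) {
    stop("k = ", k, " exceeds the number of speakers in class ",
         names(counts)[which.min(counts)], " (", min(counts), ")",
         call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(split(seq_along(speakers), class_labels), function(idx) {
      idx <- sample(idx)
      tibble::tibble(speaker_id = speakers[idx],
                     class_label = class_labels[idx],
                     fold = ((seq_along(idx) - 1L) %% k) + 1L)
    })
    dplyr::arrange(dplyr::bind_rows(out), .data$speaker_id)
  })
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * N_c)` for `K` classes; balanced data gives unit weights.
#'
#' @param labels Vector of class labels.
#' @return Named numeric vector of weights, one per observed class.
#' @export
class_weights <- function(labels) {
  counts <- table(labels)
  stop_if_not(all(counts > 0), "empty class")
  n <- length(labels)
  k <- length(counts)
  w <- as.numeric(n / (k * counts))
  names(w) <- names(counts)
  w
}

#' Weighted cross-entropy loss
#'
#' Mean over samples of `-w_y * log(p_y)`; reduces to plain cross-entropy
#' when every weight is 1. Probabilities are clipped at `1e-12` (with a
#' warning) before taking logs.
#'
#' @param probs Matrix of predicted probabilities, one row per sample, rows
#'   summing to 1.
#' @param labels Integer (1-based column index) or factor/character labels
#'   matching `colnames(probs)` or the weight names.
#' @param weights Positive per-class weight vector (recycled order = column
#'   order of `probs`).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels, weights = NULL) {
  probs <- as.matrix(probs)
  k <- ncol(probs)
  if (is.null(weights)) weights <- rep(1, k)
  stop_if_not(all(weights > 0), "weights must be positive")
  if (!is.numeric(labels)) {
    lev <- colnames(probs) %||% names(weights)
    stop_if_not(!is.null(lev), "need column names to match labels")
    labels <- match(as.character(labels), lev)
  }
  stop_if_not(length(labels) == nrow(probs),
              "labels and probs differ in length")
  p <- probs[cbind(seq_len(nrow(probs)), labels)]
  if (any(p < 1e-12)) {
    warning("probabilities at the true label clipped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  mean(-weights[labels] * log(p))
}

#' Training configuration
#'
#' @param lr_init Initial learning rate for SGD.
#' @param momentum SGD momentum (0 disables).
#' @param epochs Epoch cap.
#' @param lr_factor,lr_patience,min_lr Learning-rate schedule: multiply the
#'   rate by `lr_factor` when the validation loss has not improved for
#'   `lr_patience` epochs, never below `min_lr`.
#' @param clip_norm Global gradient-norm clip (`Inf` disables); guards the
#'   high initial learning rate against loss blow-ups.
#' @param class_weighting Weight the task (and domain) cross-entropy by
#'   inverse class frequency?
#' @param early_stop_patience Stop when validation accuracy has not improved
#'   for this many epochs (`Inf` disables).
#' @param seed Integer seed governing shuffling and dropout.
#' @return A `voiceda_trainconfig` list.
#' @export
train_config <- function(lr_init = 0.1, momentum = 0.9, epochs = 20,
                         lr_factor = 0.1, lr_patience = 5, min_lr = 1e-3,
                         clip_norm = 0.5, class_weighting = TRUE,
                         early_stop_patience = Inf, seed = 1L) {
  stop_if_not(lr_init > 0, "lr_init must be positive")
  stop_if_not(epochs >= 1, "need at least one epoch")
  structure(list(lr_init = lr_init, momentum = momentum, epochs = epochs,
                 lr_factor = lr_factor,
                 lr_patience = lr_patience, min_lr = min_lr,
                 clip_norm = clip_norm,
                 class_weighting = class_weighting,
                 early_stop_patience = early_stop_patience, seed = seed),
            class = "voiceda_trainconfig")
}

# ---- internal: batches and single steps ------------------------------------

# Forward the full bundle on one batch container. The domain head draws its
# dropout masks from a dedicated RNG stream (dom_seed) so that attaching it
# never perturbs the shared extractor/task-head randomness: a seed-matched
# baseline and DA run consume identical draws on the shared path.
model_forward <- function(bundle, batch, train = FALSE, dom_seed = NULL) {
  ef <- extractor_forward(bundle$extractor, batch, train)
  bundle$extractor <- ef$ext
  pd <- head_forward(bundle$pd_head, ef$emb, train)
  bundle$pd_head <- pd$head
  dom <- NULL
  if (!is.null(bundle$domain_head)) {
    dom <- if (train && !is.null(dom_seed)) {
      with_seed(dom_seed, head_forward(bundle$domain_head, grl(ef$emb, 0),
                                       train))
    } else {
      head_forward(bundle$domain_head, grl(ef$emb, 0), train)
    }
    bundle$domain_head <- dom$head
  }
  list(bundle = bundle, emb = ef$emb, ext_cache = ef$cache, pd = pd,
       dom = dom)
}

# Gradient of mean weighted CE w.r.t. logits, columns = samples.
ce_dlogits <- function(probs, y, w) {
  n <- ncol(probs)
  d <- probs
  d[cbind(y, seq_len(n))] <- d[cbind(y, seq_len(n))] - 1
  sweep(d, 2, w[y] / n, "*")
}

ce_loss <- function(probs, y, w) {
  p <- pmax(probs[cbind(y, seq_len(ncol(probs)))], 1e-12)
  mean(-w[y] * log(p))
}

# One SGD step; y_task/y_domain are 1-based integer labels per column.
grad_sq_sum <- function(g) {
  if (is.null(g)) return(0)
  sum(vapply(g, function(e) {
    if (is.list(e)) grad_sq_sum(e) else sum(e^2)
  }, numeric(1)))
}

scale_grads <- function(g, f) {
  if (is.null(g)) return(g)
  lapply(g, function(e) if (is.list(e)) scale_grads(e, f) else e * f)
}

train_step <- function(bundle, batch, y_task, w_task, lr, lambda = 0,
                       y_domain = NULL, w_domain = NULL, momentum = 0,
                       clip_norm = Inf, dom_seed = NULL) {
  fw <- model_forward(bundle, batch, train = TRUE, dom_seed = dom_seed)
  bundle <- fw$bundle
  loss_task <- ce_loss(fw$pd$probs, y_task, w_task)
  dl_task <- ce_dlogits(fw$pd$probs, y_task, w_task)
  bp <- head_backward(bundle$pd_head, fw$pd$caches, dl_task)
  demb <- bp$demb
  loss_dom <- NA_real_
  dom_grads <- NULL
  if (!is.null(bundle$domain_head) && !is.null(y_domain)) {
    loss_dom <- ce_loss(fw$dom$probs, y_domain, w_domain)
    dl_dom <- ce_dlogits(fw$dom$probs, y_domain, w_domain)
    bd <- head_backward(bundle$domain_head, fw$dom$caches, dl_dom)
    demb <- demb + grl_backward(bd$demb, lambda)
    dom_grads <- bd$grads
  }
  eb <- extractor_backward(bundle$extractor, fw$ext_cache, demb)
  if (is.finite(clip_norm)) {
    gnorm <- sqrt(grad_sq_sum(eb$grads) + grad_sq_sum(bp$grads) +
                    grad_sq_sum(dom_grads))
    if (gnorm > clip_norm) {
      f <- clip_norm / gnorm
      eb$grads <- scale_grads(eb$grads, f)
      bp$grads <- scale_grads(bp$grads, f)
      dom_grads <- scale_grads(dom_grads, f)
    }
  }
  if (!all(is.finite(c(loss_task, if (!is.na(loss_dom)) loss_dom)))) {
    stop("non-finite loss; aborting (task = ", loss_task,
         ", domain = ", loss_dom, ")", call. = FALSE)
  }
  bundle$extractor <- apply_extractor_grads(bundle$extractor, eb$grads, lr,
                                            momentum)
  bundle$pd_head$layers <- sgd_update_layers(bundle$pd_head$layers,
                                             bp$grads, lr, momentum)
  if (!is.null(dom_grads)) {
    bundle$domain_head$layers <- sgd_update_layers(bundle$domain_head$layers,
                                                   dom_grads, lr, momentum)
  }
  list(bundle = bundle, loss_task = loss_task, loss_domain = loss_dom)
}

# Build the batch container + integer labels for a row subset of `data`.
assemble_batch <- function(bundle, data, idx, class_levels, domain_levels) {
  if (bundle$architecture == "time_cnn_lstm") {
    seqs <- make_sequences(data[idx, ], bundle$hp$n_frames)
    list(x = list(slots = seqs$slots, mask = seqs$mask),
         y_task = match(seqs$meta$class_label, class_levels),
         y_domain = match(seqs$meta$domain_label, domain_levels),
         meta = seqs$meta)
  } else {
    list(x = make_batch(bundle$architecture, data$spec[idx]),
         y_task = match(data$class_label[idx], class_levels),
         y_domain = match(data$domain_label[idx], domain_levels),
         meta = data[idx, ])
  }
}

# Units over which batches are formed: segments for the convolutional
# architectures, whole recordings for the recurrent one.
batch_units <- function(bundle, data) {
  if (bundle$architecture == "time_cnn_lstm") {
    split(seq_len(nrow(data)), data$recording)
  } else {
    as.list(seq_len(nrow(data)))
  }
}

#' Fit a model, baseline or domain-adversarial
#'
#' SGD with (optionally class-weighted) cross-entropy. The baseline
#' minimises the task loss; with a domain head attached, the domain
#' detector is trained on its own (domain-weighted) cross-entropy while the
#' shared extractor receives that gradient reversed and scaled by the
#' schedule of [lambda_schedule()]. The learning rate starts at
#' `cfg$lr_init` and decays on validation-loss plateau; the epoch with the
#' best validation task accuracy is kept as the checkpoint.
#'
#' @param bundle A [assemble()]d model.
#' @param train_data,val_data Preprocessed segment tibbles
#'   ([preprocess_corpus()]); speaker-disjoint.
#' @param cfg A [train_config()].
#' @param class_levels,domain_levels Label orderings (defaults: sorted
#'   unique labels of `train_data`).
#' @return A `voiceda_fit`: `bundle` (best checkpoint), `history` (per-epoch
#'   tibble), `class_levels`, `domain_levels`.
#' @export
fit <- function(bundle, train_data, val_data, cfg = train_config(),
                class_levels = NULL, domain_levels = NULL) {
  shared <- intersect(unique(train_data$speaker_id),
                      unique(val_data$speaker_id))
  stop_if_not(length(shared) == 0,
              "speakers appear in both train and validation: ",
              paste(head(shared, 3), collapse = ", "))
  class_levels <- class_levels %||% sort(unique(train_data$class_label))
  domain_levels <- domain_levels %||% sort(unique(train_data$domain_label))
  stop_if_not(length(class_levels) >= 2, "training data has a single class")
  da <- !is.null(bundle$domain_head)
  if (da) {
    stop_if_not(bundle$domain_head$n_out == length(domain_levels),
                "domain head expects ", bundle$domain_head$n_out,
                " domains, data has ", length(domain_levels))
  }
  w_task <- if (cfg$class_weighting) {
    class_weights(factor(train_data$class_label, class_levels))
  } else rep(1, length(class_levels))
  w_dom <- if (da) {
    if (cfg$class_weighting) {
      class_weights(factor(train_data$domain_label, domain_levels))
    } else rep(1, length(domain_levels))
  }
  units <- batch_units(bundle, train_data)
  bs <- bundle$hp$batch_size
  lr <- cfg$lr_init
  best <- list(acc = -Inf, bundle = bundle, epoch = 0L)
  best_val_loss <- Inf
  plateau <- 0L
  stall <- 0L
  history <- list()
  for (epoch in seq_len(cfg$epochs)) {
    progress <- if (cfg$epochs > 1) (epoch - 1) / (cfg$epochs - 1) else 1
    lambda <- if (da) lambda_schedule(progress, bundle$dacfg) else 0
    order_units <- with_seed(child_seed(cfg$seed, "shuffle", epoch),
                             sample(length(units)))
    n_units <- length(order_units)
    task_losses <- c()
    dom_losses <- c()
    with_seed(child_seed(cfg$seed, "dropout", epoch), {
      for (b0 in seq(1, n_units, by = bs)) {
        take <- order_units[b0:min(b0 + bs - 1, n_units)]
        idx <- unlist(units[take])
        bt <- assemble_batch(bundle, train_data, idx, class_levels,
                             domain_levels)
        st <- train_step(bundle, bt$x, bt$y_task, w_task, lr, lambda,
                         if (da) bt$y_domain, w_dom,
                         momentum = cfg$momentum %||% 0,
                         clip_norm = cfg$clip_norm %||% Inf,
                         dom_seed = child_seed(cfg$seed, "domdrop", epoch,
                                               b0))
        bundle <- st$bundle
        task_losses <- c(task_losses, st$loss_task)
        dom_losses <- c(dom_losses, st$loss_domain)
      }
    })
    ev <- evaluate_segments(bundle, val_data, class_levels, domain_levels)
    if (!is.finite(ev$loss)) {
      stop("non-finite validation loss at epoch ", epoch, call. = FALSE)
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, lambda = lambda,
      train_task_loss = mean(task_losses),
      train_domain_loss = mean(dom_losses),
      val_loss = ev$loss, val_accuracy = ev$accuracy,
      val_domain_accuracy = ev$domain_accuracy
    )
    if (ev$accuracy > best$acc) {
      best <- list(acc = ev$accuracy, bundle = bundle, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (ev$loss < best_val_loss - 1e-8) {
      best_val_loss <- ev$loss
      plateau <- 0L
    } else {
      plateau <- plateau + 1L
      if (plateau >= cfg$lr_patience) {
        lr <- max(lr * cfg$lr_factor, cfg$min_lr %||% 0)
        plateau <- 0L
      }
    }
    if (stall >= cfg$early_stop_patience) break
  }
  structure(list(bundle = best$bundle, final_bundle = bundle,
                 best_epoch = best$epoch,
                 history = dplyr::bind_rows(history),
                 class_levels = class_levels, domain_levels = domain_levels,
                 config = cfg),
            class = "voiceda_fit")
}

# Inference over a preprocessed table: per-segment (or per-sequence)
# probabilities, task loss and accuracies.
evaluate_segments <- function(bundle, data, class_levels, domain_levels,
                              chunk = 64L) {
  units <- batch_units(bundle, data)
  probs <- NULL
  dprobs <- NULL
  y <- c()
  yd <- c()
  meta <- list()
  for (b0 in seq(1, length(units), by = chunk)) {
    take <- seq(b0, min(b0 + chunk - 1, length(units)))
    idx <- unlist(units[take])
    bt <- assemble_batch(bundle, data, idx, class_levels, domain_levels)
    fw <- model_forward(bundle, bt$x, train = FALSE)
    probs <- cbind(probs, fw$pd$probs)
    if (!is.null(fw$dom)) dprobs <- cbind(dprobs, fw$dom$probs)
    y <- c(y, bt$y_task)
    yd <- c(yd, bt$y_domain)
    meta[[length(meta) + 1]] <- bt$meta
  }
  pred <- apply(probs, 2, which.max)
  list(loss = ce_loss(probs, y, rep(1, length(class_levels))),
       accuracy = mean(pred == y),
       domain_accuracy = if (!is.null(dprobs)) {
         mean(apply(dprobs, 2, which.max) == yd)
       } else NA_real_,
       probs = probs, y = y, meta = dplyr::bind_rows(meta))
}

#' @export
print.voiceda_fit <- function(x, ...) {
  cat(sprintf(
    "<voiceda_fit> %s%s | %d epochs | best val accuracy %.3f (epoch %d)\n",
    x$bundle$architecture,
    if (!is.null(x$bundle$domain_head)) " +DA" else "",
    nrow(x$history), max(x$history$val_accuracy), x$best_epoch))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted model
#'
#' @param x A `voiceda_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: losses, learning rate, reversal
#'   strength and validation metrics.
#' @method tidy voiceda_fit
#' @export
tidy.voiceda_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x A `voiceda_fit`.
#' @param ... Unused.
#' @return Tibble with architecture, adversarial flag, epochs run, best
#'   epoch and best validation accuracy.
#' @method glance voiceda_fit
#' @export
glance.voiceda_fit <- function(x, ...) {
  tibble::tibble(architecture = x$bundle$architecture,
                 domain_adversarial = !is.null(x$bundle$domain_head),
                 epochs = nrow(x$history),
                 best_epoch = x$best_epoch,
                 val_accuracy = max(x$history$val_accuracy))
}

# ---- transfer learning -----------------------------------------------------

#' Pretrain extractor and task head on a pathological-voice corpus
#'
#' Trains the baseline (extractor + binary task head) on a
#' healthy-vs-voice-disorder sustained-vowel corpus, the transfer source for
#' the Parkinson's task.
#'
#' @param bundle A non-adversarial [assemble()]d model.
#' @param data Preprocessed segment tibble with two class labels.
#' @param cfg A [train_config()].
#' @param val_fraction Fraction of speakers held out for the schedule.
#' @return A `voiceda_fit` whose `bundle` carries `pretrained = TRUE`.
#' @export
pretrain <- function(bundle, data, cfg = train_config(), val_fraction = 0.25) {
  stop_if_not(length(unique(data$class_label)) >= 2,
              "pretraining data has a single class")
  speakers <- dplyr::distinct(data, .data$speaker_id, .data$class_label)
  folds <- make_folds(speakers$speaker_id, speakers$class_label,
                      k = max(2L, round(1 / val_fraction)),
                      seed = child_seed(cfg$seed, "pretrain-split"))
  val_sp <- folds$speaker_id[folds$fold == 1]
  ft <- fit(bundle, dplyr::filter(data, !(.data$speaker_id %in% val_sp)),
            dplyr::filter(data, .data$speaker_id %in% val_sp), cfg)
  ft$bundle$pretrained <- TRUE
  ft
}

#' Initialise a model from pretrained weights
#'
#' Copies extractor (and task head) parameters from a pretrained bundle of
#' the same architecture into `bundle`.
#'
#' @param bundle Target model.
#' @param pretrained Source bundle (from [pretrain()]).
#' @param copy_head Also copy the task head parameters?
#' @return `bundle` with transferred weights and `pretrained = TRUE`.
#' @export
init_from_pretrained <- function(bundle, pretrained, copy_head = TRUE) {
  src <- if (inherits(pretrained, "voiceda_fit")) pretrained$bundle else
    pretrained
  stop_if_not(identical(bundle$architecture, src$architecture),
              "architecture mismatch")
  for (i in seq_along(src$extractor$layers)) {
    bundle$extractor$layers[[i]]$params <- src$extractor$layers[[i]]$params
    if (!is.null(src$extractor$layers[[i]]$buffers)) {
      bundle$extractor$layers[[i]]$buffers <- src$extractor$layers[[i]]$buffers
    }
  }
  if (bundle$architecture == "time_cnn_lstm") {
    bundle$extractor$lstm_f$params <- src$extractor$lstm_f$params
    bundle$extractor$lstm_b$params <- src$extractor$lstm_b$params
  }
  if (copy_head) bundle$pd_head$layers <- src$pd_head$layers
  bundle$pretrained <- TRUE
  bundle
}

#' Freeze the first extractor layer
#'
#' Excludes the first convolutional layer and its batch-normalisation
#' parameters and running statistics from further updates — the
#' transfer-learning protocol after pretraining.
#'
#' @param bundle A bundle whose weights were pretrained
#'   ([init_from_pretrained()] or [pretrain()]).
#' @return The bundle with the initial layer frozen.
#' @export
freeze_initial_layer <- function(bundle) {
  stop_if_not(isTRUE(bundle$pretrained),
              "freeze_initial_layer() called before pretrained weights ",
              "were loaded")
  bundle$extractor$layers[[1]]$frozen <- TRUE
  if (bundle$extractor$layers[[2]]$type %in% c("batchnorm", "batchnorm1d")) {
    bundle$extractor$layers[[2]]$frozen <- TRUE
  }
  bundle$frozen_layer_ids <- c(1L, 2L)
  bundle
}

# ---- hyperparameter search -------------------------------------------------

#' Search the hyperparameter grid
#'
#' Evaluates candidates from `space` (exhaustively, or a seeded random
#' subset of at most `budget`) with a scoring function and returns the best
#' candidate. The default scorer fits the requested architecture on a
#' speaker-disjoint split of `data` and scores validation accuracy; any
#' function `f(hp)` returning a scalar score can be substituted.
#'
#' @param space Named list of candidate values per hyperparameter
#'   ([hyperparameter_space()] or a subset).
#' @param data Preprocessed segment tibble (used by the default scorer).
#' @param architecture Architecture for the default scorer.
#' @param budget Maximum number of candidates evaluated.
#' @param seed Integer seed.
#' @param cfg A [train_config()] for the default scorer.
#' @param scorer Optional `function(hp) -> numeric` replacing the default.
#' @return A list: `best` (a [hyperparams()], `validate = FALSE`),
#'   `evaluations` (tibble of candidates and scores).
#' @export
grid_search <- function(space, data = NULL, architecture = "cnn2d",
                        budget = 10, seed = 1L, cfg = train_config(),
                        scorer = NULL) {
  stop_if_not(length(space) > 0 && all(lengths(space) > 0),
              "empty search space")
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) > budget) {
    keep <- with_seed(child_seed(seed, "grid"),
                      sample(nrow(grid), budget))
    grid <- grid[keep, , drop = FALSE]
  }
  if (is.null(scorer)) {
    stop_if_not(!is.null(data), "default scorer needs data")
    speakers <- dplyr::distinct(data, .data$speaker_id, .data$class_label)
    folds <- make_folds(speakers$speaker_id, speakers$class_label, k = 4,
                        seed = child_seed(seed, "search-split"))
    val_sp <- folds$speaker_id[folds$fold == 1]
    tr <- dplyr::filter(data, !(.data$speaker_id %in% val_sp))
    va <- dplyr::filter(data, .data$speaker_id %in% val_sp)
    scorer <- function(hp) {
      bundle <- assemble(architecture, hp, da = FALSE,
                         input_shape = dim(data$spec[[1]]),
                         seed = child_seed(seed, "search-init"))
      ft <- fit(bundle, tr, va, cfg)
      max(ft$history$val_accuracy)
    }
  }
  defaults <- hyperparams(validate = FALSE)
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- defaults
    for (f in names(grid)) hp[[f]] <- grid[[f]][i]
    scores[i] <- scorer(hp)
  }
  best_row <- which.max(scores)
  best <- defaults
  for (f in names(grid)) best[[f]] <- grid[[f]][best_row]
  list(best = best,
       evaluations = tibble::as_tibble(cbind(grid, score = scores)))
}
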