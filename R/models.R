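# Model zoo: three feature extractors (2D-CNN, time-distributed CNN +
# bidirectional LSTM with masking, 1D-CNN with attention pooling), the
# two-layer softmax detector heads, and the gradient reversal layer that
# couples the corpus detector adversarially to the shared extractor.

#' Hyperparameter set for the detector architectures
#'
#' Fields follow the tuning grid the architectures are searched over:
#' batch size, dropout rate, convolutional depth (shared across conv
#' blocks), fully connected units (shared by both detector heads), the two
#' 2-D kernel sizes, LSTM units, and the sequence length `n_frames` of the
#' recurrent architecture.
#'
#' @param batch_size One of 16, 32, 64.
#' @param dropout One of 0.2, 0.5.
#' @param conv_depth One of 32, 64, 128 (filters per conv block).
#' @param fc_units One of 16, 32, 64.
#' @param kernel1 One of 4, 6, 8 (first 2-D conv block).
#' @param kernel2 One of 5, 7, 9 (second 2-D conv block).
#' @param lstm_units One of 16, 32, 64.
#' @param n_frames One of 3, 5, 7, 9 (spectrogram slots per sequence).
#' @param validate If `FALSE`, values outside the grid are allowed (used for
#'   reduced-scale experiments).
#' @return A `voiceda_hyperparams` list.
#' @export
hyperparams <- function(batch_size = 16, dropout = 0.2, conv_depth = 32,
                        fc_units = 16, kernel1 = 4, kernel2 = 5,
                        lstm_units = 16, n_frames = 5, validate = TRUE) {
  hp <- list(batch_size = batch_size, dropout = dropout,
             conv_depth = conv_depth, fc_units = fc_units,
             kernel1 = kernel1, kernel2 = kernel2,
             lstm_units = lstm_units, n_frames = n_frames)
  if (validate) {
    grid <- hyperparameter_space()
    for (f in names(grid)) {
      stop_if_not(hp[[f]] %in% grid[[f]],
                  f, " = ", hp[[f]], " is outside the search grid {",
                  paste(grid[[f]], collapse = ", "), "}")
    }
  }
  stop_if_not(hp$conv_depth %% 2 == 0,
              "conv_depth must be even (attention pooling splits filters)")
  structure(hp, class = "voiceda_hyperparams")
}

#' The hyperparameter search grid
#'
#' @return Named list of admissible values per hyperparameter.
#' @export
hyperparameter_space <- function() {
  list(batch_size = c(16, 32, 64), dropout = c(0.2, 0.5),
       conv_depth = c(32, 64, 128), fc_units = c(16, 32, 64),
       kernel1 = c(4, 6, 8), kernel2 = c(5, 7, 9),
       lstm_units = c(16, 32, 64), n_frames = c(3, 5, 7, 9))
}

#' Domain-adversarial configuration
#'
#' @param lambda_mode `"ramp"` (default) scales the reversal strength along
#'   training progress as `2/(1 + exp(-ramp_gamma * p)) - 1`; `"fixed"` uses
#'   `lambda_value` throughout.
#' @param lambda_value Nonnegative reversal strength for fixed mode.
#' @param ramp_gamma Ramp steepness.
#' @param n_domains Number of recording domains (corpora).
#' @return A `voiceda_daconfig` list.
#' @export
da_config <- function(lambda_mode = c("ramp", "fixed"), lambda_value = 1,
                      ramp_gamma = 10, n_domains = 4) {
  stop_if_not(lambda_value >= 0, "lambda_value must be nonnegative")
  structure(list(lambda_mode = match.arg(lambda_mode),
                 lambda_value = lambda_value, ramp_gamma = ramp_gamma,
                 n_domains = n_domains),
            class = "voiceda_daconfig")
}

#' Gradient reversal layer, forward pass
#'
#' The forward pass is the identity; during backpropagation the gradient is
#' multiplied by `-lam` (see [grl_backward()]), so that the domain
#' detector's learning signal pushes the shared extractor *away* from
#' domain-discriminative features.
#'
#' @param x Numeric tensor.
#' @param lam Nonnegative reversal strength.
#' @return `x`, unchanged.
#' @export
grl <- function(x, lam) {
  stop_if_not(lam >= 0, "GRL strength lam must be nonnegative")
  x
}

#' Gradient reversal layer, backward pass
#'
#' @param dout Upstream gradient.
#' @param lam Nonnegative reversal strength.
#' @return `-lam * dout`.
#' @export
grl_backward <- function(dout, lam) {
  stop_if_not(lam >= 0, "GRL strength lam must be nonnegative")
  -lam * dout
}

#' Reversal-strength schedule
#'
#' @param progress Training progress in \[0, 1\].
#' @param dacfg A [da_config()].
#' @return The reversal strength at `progress`: `lambda_value` in fixed
#'   mode, `2/(1 + exp(-ramp_gamma * progress)) - 1` in ramp mode.
#' @export
lambda_schedule <- function(progress, dacfg = da_config()) {
  stop_if_not(all(progress >= 0 & progress <= 1),
              "progress must lie in [0, 1]")
  if (dacfg$lambda_mode == "fixed") {
    rep(dacfg$lambda_value, length(progress))
  } else {
    2 / (1 + exp(-dacfg$ramp_gamma * progress)) - 1
  }
}

# ---- extractors ------------------------------------------------------------

conv_block_2d <- function(h, w, in_c, k, depth, dropout) {
  list(layer_conv2d(h, w, in_c, k, k, depth),
       layer_batchnorm(depth),
       layer_relu(),
       layer_maxpool2d(3L),
       layer_dropout(dropout))
}

#' Build the 2-D CNN feature extractor
#'
#' Two convolutional blocks (conv, batch norm, ReLU, 3x3 max pooling,
#' dropout) followed by a flatten; consumes one spectrogram image per
#' sample.
#'
#' @param hp A [hyperparams()].
#' @param input_shape Spectrogram shape, `c(n_mels, n_frames)`.
#' @return A `voiceda_extractor`.
#' @export
build_extractor_2dcnn <- function(hp, input_shape = c(65, 41)) {
  h <- input_shape[1]; w <- input_shape[2]
  b1 <- conv_block_2d(h, w, 1L, hp$kernel1, hp$conv_depth, hp$dropout)
  h2 <- h %/% 3L; w2 <- w %/% 3L
  b2 <- conv_block_2d(h2, w2, hp$conv_depth, hp$kernel2, hp$conv_depth,
                      hp$dropout)
  h3 <- h2 %/% 3L; w3 <- w2 %/% 3L
  layers <- c(b1, b2, list(layer_flatten()))
  structure(list(arch = "cnn2d", layers = layers,
                 embedding_dim = h3 * w3 * hp$conv_depth,
                 input_shape = input_shape, hp = hp),
            class = "voiceda_extractor")
}

#' Build the time-distributed CNN + bidirectional LSTM extractor
#'
#' The same two conv blocks are applied to each of up to `n_frames`
#' spectrogram slots of a recording (zero-padded slots are masked out of
#' both the convolutional stage and the recurrence); per-slot features feed
#' a bidirectional LSTM whose final hidden states, concatenated, form the
#' embedding of dimension `2 * lstm_units`.
#'
#' @inheritParams build_extractor_2dcnn
#' @return A `voiceda_extractor`.
#' @export
build_extractor_time_cnn_lstm <- function(hp, input_shape = c(65, 41)) {
  base <- build_extractor_2dcnn(hp, input_shape)
  lstm_f <- layer_lstm(base$embedding_dim, hp$lstm_units)
  lstm_b <- layer_lstm(base$embedding_dim, hp$lstm_units)
  structure(list(arch = "time_cnn_lstm", layers = base$layers,
                 lstm_f = lstm_f, lstm_b = lstm_b,
                 n_frames = hp$n_frames,
                 slot_dim = base$embedding_dim,
                 embedding_dim = 2L * hp$lstm_units,
                 input_shape = input_shape, hp = hp),
            class = "voiceda_extractor")
}

#' Build the 1-D CNN extractor with attention pooling
#'
#' The spectrogram is flattened frequency-major into a 1-D sequence, passed
#' through three conv blocks with kernel sizes 5, 11 and 21 (max pooling of
#' size 6 between blocks); in the last block half of the filters undergo a
#' time-wise softmax and act as attention weights for the other half, whose
#' attention-weighted time sum is the embedding.
#'
#' @inheritParams build_extractor_2dcnn
#' @return A `voiceda_extractor`.
#' @export
build_extractor_1dcnn <- function(hp, input_shape = c(65, 41)) {
  l0 <- prod(input_shape)
  depth <- hp$conv_depth
  l1 <- l0 %/% 6L
  l2 <- l1 %/% 6L
  layers <- list(
    layer_conv1d(l0, 1L, 5L, depth),
    layer_batchnorm_1d(depth),
    layer_relu(),
    layer_dropout(hp$dropout),
    layer_maxpool1d(6L),
    layer_conv1d(l1, depth, 11L, depth),
    layer_batchnorm_1d(depth),
    layer_relu(),
    layer_dropout(hp$dropout),
    layer_maxpool1d(6L),
    layer_conv1d(l2, depth, 21L, depth),
    layer_batchnorm_1d(depth),
    layer_relu(),
    layer_dropout(hp$dropout),
    layer_attention_pool()
  )
  structure(list(arch = "cnn1d", layers = layers,
                 embedding_dim = depth %/% 2L,
                 input_shape = input_shape, hp = hp),
            class = "voiceda_extractor")
}

layer_batchnorm_1d <- function(n_c) {
  ly <- layer_batchnorm(n_c)
  ly$type <- "batchnorm1d"
  ly
}

#' Build a detector head
#'
#' Fully connected layer (`fc_units`, ReLU), dropout, then a fully connected
#' softmax output layer; rows of the output sum to 1.
#'
#' @param embedding_dim Input embedding dimension.
#' @param hp A [hyperparams()].
#' @param n_out Number of output classes (2 for the task head, `n_domains`
#'   for the domain head).
#' @return A `voiceda_head`.
#' @export
build_head <- function(embedding_dim, hp, n_out = 2) {
  stop_if_not(n_out >= 2, "a detector head needs at least 2 outputs")
  structure(list(layers = list(layer_dense(embedding_dim, hp$fc_units),
                               layer_relu(),
                               layer_dropout(hp$dropout),
                               layer_dense(hp$fc_units, n_out)),
                 n_out = n_out, fc_units = hp$fc_units),
            class = "voiceda_head")
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Head forward: returns probabilities, the pre-softmax hidden representation
# (the embedding tap used by the invariance audit) and caches.
head_forward <- function(head, emb, train = FALSE) {
  r <- net_forward(head$layers, emb, train)
  list(probs = softmax_cols(r$out), logits = r$out,
       hidden = r$caches[[4]]$x, caches = r$caches,
       head = { head$layers <- r$layers; head })
}

# dlogits: gradient w.r.t. the pre-softmax logits.
head_backward <- function(head, caches, dlogits) {
  r <- net_backward(head$layers, caches, dlogits)
  list(demb = r$dx, grads = r$grads)
}

#' Assemble a baseline or domain-adversarial model
#'
#' A baseline model is extractor + task head; the domain-adversarial (DA)
#' variant adds a domain head connected to the same embedding through the
#' gradient reversal layer. The embedding tap point (input to the task
#' head's softmax layer) is registered for the invariance audit.
#'
#' @param architecture `"cnn2d"`, `"time_cnn_lstm"` or `"cnn1d"`.
#' @param hp A [hyperparams()].
#' @param da Add the adversarial domain head?
#' @param dacfg A [da_config()] (required when `da = TRUE`).
#' @param input_shape Spectrogram shape.
#' @param seed Seed for weight initialisation.
#' @return A `voiceda_model` bundle.
#' @export
assemble <- function(architecture = c("cnn2d", "time_cnn_lstm", "cnn1d"),
                     hp = hyperparams(), da = FALSE, dacfg = da_config(),
                     input_shape = c(65, 41), seed = 1L) {
  architecture <- match.arg(architecture)
  with_seed(seed, {
    extractor <- switch(architecture,
      cnn2d = build_extractor_2dcnn(hp, input_shape),
      time_cnn_lstm = build_extractor_time_cnn_lstm(hp, input_shape),
      cnn1d = build_extractor_1dcnn(hp, input_shape))
    pd_head <- build_head(extractor$embedding_dim, hp, n_out = 2)
    domain_head <- if (da) {
      build_head(extractor$embedding_dim, hp, n_out = dacfg$n_domains)
    }
    structure(list(architecture = architecture, hp = hp,
                   extractor = extractor, pd_head = pd_head,
                   domain_head = domain_head,
                   dacfg = if (da) dacfg,
                   embedding_dim = extractor$embedding_dim,
                   seed = seed),
              class = "voiceda_model")
  })
}

#' @export
print.voiceda_model <- function(x, ...) {
  cat(sprintf("<voiceda_model> %s%s | embedding %d | %d parameters\n",
              x$architecture, if (!is.null(x$domain_head)) " +DA" else "",
              x$embedding_dim, model_param_count(x)))
  invisible(x)
}

model_param_count <- function(bundle) {
  n <- net_param_count(bundle$extractor$layers) +
    net_param_count(bundle$pd_head$layers)
  if (bundle$extractor$arch == "time_cnn_lstm") {
    n <- n + net_param_count(list(bundle$extractor$lstm_f,
                                  bundle$extractor$lstm_b))
  }
  if (!is.null(bundle$domain_head)) {
    n <- n + net_param_count(bundle$domain_head$layers)
  }
  n
}

# ---- extractor forward/backward --------------------------------------------

# x containers: cnn2d (65,41,1,N); cnn1d (L,1,N); time_cnn_lstm a list with
# $slots (list of (65,41,1,N) arrays, one per sequence position) and $mask
# (n_frames x N matrix; 1 = real slot).
extractor_forward <- function(ext, x, train = FALSE) {
  if (ext$arch != "time_cnn_lstm") {
    r <- net_forward(ext$layers, x, train)
    ext$layers <- r$layers
    return(list(emb = r$out, cache = list(conv = r$caches), ext = ext))
  }
  n_seq <- ncol(x$mask)
  xs <- vector("list", length(x$slots))
  slot_caches <- vector("list", length(x$slots))
  for (t in seq_along(x$slots)) {
    live <- which(x$mask[t, ] == 1)
    feat <- matrix(0, ext$slot_dim, n_seq)
    if (length(live) > 0) {
      r <- net_forward(ext$layers, x$slots[[t]][, , , live, drop = FALSE],
                       train)
      ext$layers <- r$layers
      feat[, live] <- r$out
      slot_caches[[t]] <- list(live = live, caches = r$caches)
    }
    xs[[t]] <- feat
  }
  fwd <- lstm_forward(ext$lstm_f, xs, x$mask)
  rev_idx <- rev(seq_along(xs))
  bwd <- lstm_forward(ext$lstm_b, xs[rev_idx],
                      x$mask[rev_idx, , drop = FALSE])
  emb <- rbind(fwd$h, bwd$h)
  list(emb = emb,
       cache = list(slot_caches = slot_caches, fwd = fwd, bwd = bwd,
                    n_slots = length(xs)),
       ext = ext)
}

extractor_backward <- function(ext, cache, demb) {
  if (ext$arch != "time_cnn_lstm") {
    r <- net_backward(ext$layers, cache$conv, demb)
    return(list(grads = list(conv = r$grads)))
  }
  nu <- ext$hp$lstm_units
  dh_f <- demb[seq_len(nu), , drop = FALSE]
  dh_b <- demb[nu + seq_len(nu), , drop = FALSE]
  bf <- lstm_backward(ext$lstm_f, cache$fwd$caches, dh_f)
  bb <- lstm_backward(ext$lstm_b, cache$bwd$caches, dh_b)
  rev_idx <- rev(seq_len(cache$n_slots))
  conv_grads <- NULL
  for (t in seq_len(cache$n_slots)) {
    sc <- cache$slot_caches[[t]]
    if (is.null(sc)) next
    dfeat <- bf$dxs[[t]] + bb$dxs[[rev_idx[t]]]
    r <- net_backward(ext$layers, sc$caches,
                      dfeat[, sc$live, drop = FALSE])
    conv_grads <- if (is.null(conv_grads)) r$grads else {
      add_grads(conv_grads, r$grads)
    }
  }
  list(grads = list(conv = conv_grads, lstm_f = bf$grads, lstm_b = bb$grads))
}

add_grads <- function(a, b) {
  for (i in seq_along(b)) {
    if (length(b[[i]]) == 0) next
    for (p in names(b[[i]])) {
      a[[i]][[p]] <- if (is.null(a[[i]][[p]])) b[[i]][[p]] else
        a[[i]][[p]] + b[[i]][[p]]
    }
  }
  a
}

apply_extractor_grads <- function(ext, grads, lr, momentum = 0) {
  ext$layers <- sgd_update_layers(ext$layers, grads$conv, lr, momentum)
  if (ext$arch == "time_cnn_lstm") {
    for (side in c("lstm_f", "lstm_b")) {
      g <- grads[[side]]
      if (isTRUE(ext[[side]]$frozen) || is.null(g)) next
      for (p in names(ext[[side]]$params)) {
        if (momentum > 0) {
          v <- ext[[side]]$vel[[p]]
          if (is.null(v)) v <- g[[p]] * 0
          v <- momentum * v - lr * g[[p]]
          ext[[side]]$vel[[p]] <- v
          ext[[side]]$params[[p]] <- ext[[side]]$params[[p]] + v
        } else {
          ext[[side]]$params[[p]] <- ext[[side]]$params[[p]] - lr * g[[p]]
        }
      }
    }
  }
  ext
}

# ---- batch containers ------------------------------------------------------

#' Stack spectrograms into an architecture-specific batch container
#'
#' @param arch `"cnn2d"` or `"cnn1d"` (sequences for the recurrent
#'   architecture are built by [make_sequences()]).
#' @param specs List of `n_mels x n_frames` matrices.
#' @return A batch array: `(H, W, 1, N)` for `"cnn2d"`, `(H*W, 1, N)` with
#'   frequency-major flattening for `"cnn1d"`.
#' @export
make_batch <- function(arch, specs) {
  n <- length(specs)
  d <- dim(specs[[1]])
  flat <- unlist(specs)
  switch(arch,
    cnn2d = array(flat, c(d[1], d[2], 1L, n)),
    cnn1d = array(flat, c(d[1] * d[2], 1L, n)),
    stop("make_batch supports cnn2d and cnn1d; use make_sequences for ",
         "time_cnn_lstm"))
}

#' Group a preprocessed segment table into per-recording sequences
#'
#' One sequence per recording: the first `n_frames` segments in temporal
#' order, zero-padded (and masked) when a recording has fewer.
#'
#' @param data Preprocessed segment tibble (see [preprocess_corpus()]).
#' @param n_frames Sequence length cap.
#' @return A list with `$slots` (list of `(H, W, 1, N)` arrays), `$mask`
#'   (`n_frames x N`), and `$meta` (one tibble row per recording).
#' @export
make_sequences <- function(data, n_frames) {
  data <- dplyr::arrange(data, .data$recording, .data$start_s)
  recs <- split(seq_len(nrow(data)), data$recording)
  recs <- recs[unique(data$recording)]
  n <- length(recs)
  d <- dim(data$spec[[1]])
  slots <- lapply(seq_len(n_frames), function(t) array(0, c(d[1], d[2], 1L, n)))
  mask <- matrix(0, n_frames, n)
  for (j in seq_along(recs)) {
    idx <- recs[[j]]
    use <- head(idx, n_frames)
    for (t in seq_along(use)) {
      slots[[t]][, , 1L, j] <- data$spec[[use[t]]]
      mask[t, j] <- 1
    }
  }
  meta <- data[vapply(recs, function(i) i[1], integer(1)),
               c("recording", "speaker_id",
                                            "class_label", "domain_label",
                                            "task")]
  list(slots = slots, mask = mask, meta = meta)
}
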