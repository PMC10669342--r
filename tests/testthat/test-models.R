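# Architectures, heads and the gradient reversal layer.

test_that("gradient reversal is the identity forward and -lambda backward", {
  x <- c(1.2, -0.3)
  expect_identical(grl(x, 1), x)
  expect_equal(grl_backward(c(2, -1), 0.5), c(-1, 0.5))
  expect_equal(grl_backward(c(2, -1), 0), c(0, 0))
  expect_error(grl(x, -1), "nonnegative")
})

test_that("GRL backward equals -lambda times the finite-difference gradient", {
  withr::local_seed(7)
  for (case in 1:20) {
    a <- rnorm(10)
    lam <- runif(1, 0, 2)
    loss <- function(x) sum(sin(x) * a) + 0.5 * sum(x^2)
    x <- rnorm(10)
    analytic <- grl_backward(cos(x) * a + x, lam)   # closed-form upstream
    oracle <- -lam * oracle_fd_grad(loss, x)        # FD through the loss
    expect_lt(max_rel_err(analytic, oracle), 1e-4)
  }
})

test_that("the reversal-strength schedule follows its closed form", {
  expect_equal(lambda_schedule(0, da_config("ramp")), 0)
  expect_equal(lambda_schedule(1, da_config("ramp", ramp_gamma = 10)),
               2 / (1 + exp(-10)) - 1, tolerance = 1e-12)
  expect_lt(abs(lambda_schedule(1, da_config("ramp", ramp_gamma = 10)) -
                  0.9999), 1e-4)
  expect_equal(lambda_schedule(c(0, 0.5, 1), da_config("fixed",
                                                       lambda_value = 1)),
               c(1, 1, 1))
  expect_error(lambda_schedule(1.5, da_config()), "0, 1")
})

tiny_hp <- function(...) {
  args <- utils::modifyList(
    list(conv_depth = 4, fc_units = 8, lstm_units = 6, n_frames = 3,
         validate = FALSE), list(...))
  do.call(hyperparams, args)
}

test_that("the 2D-CNN maps a batch to embeddings of the declared width", {
  hp <- tiny_hp()
  ext <- voiceda:::with_seed(1, build_extractor_2dcnn(hp))
  x <- array(rnorm(65 * 41 * 5), c(65, 41, 1, 5))
  r <- voiceda:::extractor_forward(ext, x)
  expect_equal(dim(r$emb), c(ext$embedding_dim, 5))
  # inference is deterministic (dropout disabled)
  r2 <- voiceda:::extractor_forward(ext, x)
  expect_identical(r$emb, r2$emb)
})

test_that("parameter count grows with convolutional depth", {
  n32 <- voiceda:::net_param_count(
    voiceda:::with_seed(1, build_extractor_2dcnn(hyperparams(
      conv_depth = 32)))$layers)
  n64 <- voiceda:::net_param_count(
    voiceda:::with_seed(1, build_extractor_2dcnn(hyperparams(
      conv_depth = 64)))$layers)
  expect_gt(n64, n32)
})

test_that("recurrent extractor masks padding and is order sensitive", {
  hp <- tiny_hp(n_frames = 5)
  ext <- voiceda:::with_seed(11, build_extractor_time_cnn_lstm(hp))
  slots3 <- lapply(1:3, function(t) array(rnorm(65 * 41 * 2),
                                          c(65, 41, 1, 2)))
  x3 <- list(slots = slots3, mask = matrix(1, 3, 2))
  x5 <- list(slots = c(slots3, lapply(1:2, function(t) {
    array(0, c(65, 41, 1, 2))
  })), mask = rbind(matrix(1, 3, 2), matrix(0, 2, 2)))
  e3 <- voiceda:::extractor_forward(ext, x3)$emb
  e5 <- voiceda:::extractor_forward(ext, x5)$emb
  expect_identical(e3, e5)                       # bit-stable under padding
  expect_equal(nrow(e3), 2 * hp$lstm_units)      # bidirectional concat
  xp <- list(slots = slots3[c(2, 1, 3)], mask = matrix(1, 3, 2))
  ep <- voiceda:::extractor_forward(ext, xp)$emb
  expect_false(isTRUE(all.equal(e3, ep)))        # order sensitivity
})

test_that("attention pooling normalises and degenerates as expected", {
  withr::local_seed(5)
  x <- array(rnorm(7 * 6 * 2), c(7, 6, 2))
  fw <- voiceda:::attention_pool_forward(voiceda:::layer_attention_pool(), x)
  w <- fw$cache$w
  expect_equal(apply(w, c(2, 3), sum), matrix(1, 3, 2), tolerance = 1e-6)
  # constant attention logits -> embedding equals the time-mean of A
  xc <- x
  xc[, 4:6, ] <- 0
  fwc <- voiceda:::attention_pool_forward(voiceda:::layer_attention_pool(),
                                          xc)
  expect_equal(fwc$out, apply(xc[, 1:3, , drop = FALSE], c(2, 3), mean),
               tolerance = 1e-12)
  # one-hot attention at time t -> embedding equals A at time t
  xh <- x
  xh[, 4:6, ] <- -1e4
  xh[3, 4:6, ] <- 1e4
  fwh <- voiceda:::attention_pool_forward(voiceda:::layer_attention_pool(),
                                          xh)
  expect_equal(fwh$out, xh[3, 1:3, ], tolerance = 1e-8)
  expect_error(voiceda:::attention_pool_forward(
    voiceda:::layer_attention_pool(), array(rnorm(21), c(7, 3, 1))), "even")
})

test_that("detector heads emit probability rows and symmetric defaults", {
  hp <- tiny_hp()
  head2 <- voiceda:::with_seed(2, build_head(10, hp, n_out = 2))
  head4 <- voiceda:::with_seed(2, build_head(10, hp, n_out = 4))
  emb <- matrix(rnorm(10 * 6), 10, 6)
  p2 <- voiceda:::head_forward(head2, emb)$probs
  p4 <- voiceda:::head_forward(head4, emb)$probs
  expect_equal(colSums(p2), rep(1, 6), tolerance = 1e-6)
  expect_equal(dim(p4), c(4, 6))
  expect_equal(colSums(p4), rep(1, 6), tolerance = 1e-6)
  expect_error(build_head(10, hp, n_out = 1), "at least 2")
  # zero input with zero biases -> uniform probabilities
  head0 <- head2
  head0$layers[[1]]$params$b[] <- 0
  head0$layers[[4]]$params$b[] <- 0
  p0 <- voiceda:::head_forward(head0, matrix(0, 10, 3))$probs
  expect_equal(p0, matrix(0.5, 2, 3), tolerance = 1e-12)
})

test_that("assembled bundles respect the adversarial wiring", {
  hp <- tiny_hp()
  base <- assemble("cnn2d", hp, da = FALSE, seed = 3)
  expect_null(base$domain_head)
  dab <- assemble("cnn2d", hp, da = TRUE, dacfg = da_config(n_domains = 4),
                  seed = 3)
  expect_equal(dab$domain_head$n_out, 4)
  expect_equal(dab$pd_head$n_out, 2)
  expect_error(assemble("transformer", hp), "arg")
})

test_that("domain gradients reach the extractor with reversed sign", {
  withr::local_seed(9)
  hp <- tiny_hp()
  dab <- assemble("cnn2d", hp, da = TRUE, dacfg = da_config(n_domains = 2),
                  seed = 3)
  x <- array(rnorm(65 * 41 * 4), c(65, 41, 1, 4))
  yd <- c(1, 2, 1, 2)
  fw <- voiceda:::model_forward(dab, x, train = FALSE)
  dl <- voiceda:::ce_dlogits(fw$dom$probs, yd, c(1, 1))
  bd <- voiceda:::head_backward(dab$domain_head, fw$dom$caches, dl)
  plain <- voiceda:::extractor_backward(dab$extractor, fw$ext_cache,
                                        bd$demb)$grads$conv
  revd <- voiceda:::extractor_backward(dab$extractor, fw$ext_cache,
                                       grl_backward(bd$demb, 1))$grads$conv
  w_plain <- plain[[1]]$W
  w_rev <- revd[[1]]$W
  expect_equal(w_rev, -w_plain, tolerance = 1e-12)
})

test_that("all three architectures accept a preprocessed batch", {
  hp <- tiny_hp()
  specs <- lapply(1:4, function(i) matrix(rnorm(65 * 41), 65, 41))
  for (arch in c("cnn2d", "cnn1d")) {
    b <- assemble(arch, hp, seed = 4)
    fw <- voiceda:::model_forward(b, make_batch(arch, specs))
    expect_equal(dim(fw$pd$probs), c(2, 4))
  }
  data <- rigged_segment_data(n_speakers_per_class = 2,
                              segs_per_speaker = 2)
  seqs <- make_sequences(data, hp$n_frames)
  b <- assemble("time_cnn_lstm", hp, seed = 4)
  fw <- voiceda:::model_forward(b, list(slots = seqs$slots,
                                        mask = seqs$mask))
  expect_equal(dim(fw$pd$probs), c(2, nrow(seqs$meta)))
})

test_that("hyperparameters outside the search grid are rejected", {
  expect_error(hyperparams(batch_size = 20), "outside the search grid")
  expect_silent(hyperparams(batch_size = 32, conv_depth = 64))
  expect_setequal(names(hyperparameter_space()),
                  c("batch_size", "dropout", "conv_depth", "fc_units",
                    "kernel1", "kernel2", "lstm_units", "n_frames"))
})
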