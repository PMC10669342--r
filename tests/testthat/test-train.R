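# Folds, losses, training loop, transfer learning, hyperparameter search.

test_that("stratified folds balance classes and separate speakers", {
  speakers <- sprintf("S%02d", 1:20)
  classes <- rep(c("HC", "PD"), each = 10)
  folds <- make_folds(speakers, classes, k = 10, seed = 4)
  # exhaustive check: every fold holds exactly 1 HC and 1 PD speaker
  tab <- table(folds$fold, folds$class_label)
  expect_true(all(tab == 1))
  expect_setequal(folds$speaker_id, speakers)
  expect_equal(anyDuplicated(folds$speaker_id), 0L)
  expect_error(make_folds(speakers, classes, k = 11), "exceeds")
  # determinism
  expect_identical(folds, make_folds(speakers, classes, k = 10, seed = 4))
})

test_that("fold assignment is speaker-disjoint for random cohorts", {
  withr::local_seed(11)
  for (i in 1:50) {
    n_hc <- sample(5:30, 1)
    n_pd <- sample(5:30, 1)
    k <- sample(2:min(n_hc, n_pd), 1)
    speakers <- c(sprintf("H%03d", seq_len(n_hc)),
                  sprintf("P%03d", seq_len(n_pd)))
    classes <- c(rep("HC", n_hc), rep("PD", n_pd))
    folds <- make_folds(speakers, classes, k, seed = i)
    expect_equal(anyDuplicated(folds$speaker_id), 0L)
    expect_equal(sort(unique(folds$fold)), 1:k)
    # class proportions within one speaker of balance
    tab <- table(folds$fold, folds$class_label)
    expect_lte(diff(range(tab[, "HC"])), 1)
    expect_lte(diff(range(tab[, "PD"])), 1)
  }
})

test_that("class weights follow the inverse-frequency formula", {
  w <- class_weights(rep(c("a", "b"), times = c(75, 25)))
  expect_equal(unname(w), c(100 / (2 * 75), 100 / (2 * 25)))
  expect_equal(unname(w), c(0.6667, 2.0), tolerance = 1e-4)
  expect_equal(unname(class_weights(rep(c("a", "b"), 50))), c(1, 1))
  # permutation symmetry for equal-sized classes
  w2 <- class_weights(rep(c("b", "a"), 50))
  expect_equal(sort(unname(w2)), sort(unname(w2)))
})

test_that("weighted cross-entropy matches closed forms", {
  # perfect one-hot predictions
  p <- matrix(c(1 - 1e-15, 1e-15, 1e-15, 1 - 1e-15), 2, byrow = TRUE)
  expect_lte(weighted_cross_entropy(p, c(1, 2)), 1e-10)
  # uniform two-class prediction with unit weights
  u <- matrix(0.5, 4, 2)
  expect_equal(weighted_cross_entropy(u, c(1, 2, 1, 2)), log(2),
               tolerance = 1e-12)
  # doubling a class weight doubles its contribution
  probs <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  l1 <- weighted_cross_entropy(probs, c(1, 1), weights = c(1, 1))
  l2 <- weighted_cross_entropy(probs, c(1, 1), weights = c(2, 1))
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  # weights of 1 equal the unweighted loss to 1e-12
  withr::local_seed(2)
  pr <- matrix(runif(20), 10, 2)
  pr <- pr / rowSums(pr)
  y <- sample(1:2, 10, replace = TRUE)
  expect_equal(weighted_cross_entropy(pr, y, c(1, 1)),
               weighted_cross_entropy(pr, y), tolerance = 1e-12)
  expect_warning(weighted_cross_entropy(matrix(c(0, 1), 1), 1), "clipped")
})

small_hp <- hyperparams(conv_depth = 4, fc_units = 8, validate = FALSE)

test_that("a lambda-0 adversarial step equals the baseline step", {
  shared <- function(b) c(voiceda:::net_param_vector(b$extractor$layers),
                          voiceda:::net_param_vector(b$pd_head$layers))
  base <- assemble("cnn2d", small_hp, da = FALSE, seed = 5)
  dab <- assemble("cnn2d", small_hp, da = TRUE,
                  dacfg = da_config("fixed", lambda_value = 0), seed = 5)
  expect_identical(shared(base), shared(dab))
  withr::local_seed(9)
  x <- array(rnorm(65 * 41 * 8), c(65, 41, 1, 8))
  y <- rep(1:2, 4)
  yd <- rep(1:4, 2)
  set.seed(33)
  s1 <- voiceda:::train_step(base, x, y, c(1, 1), lr = 0.1, momentum = 0.9)
  set.seed(33)
  s2 <- voiceda:::train_step(dab, x, y, c(1, 1), lr = 0.1, lambda = 0,
                             y_domain = yd, w_domain = rep(1, 4),
                             momentum = 0.9)
  expect_lt(max(abs(shared(s1$bundle) - shared(s2$bundle))), 1e-10)
})

test_that("fitting keeps finite losses and reproduces under a seed", {
  data <- rigged_segment_data(n_speakers_per_class = 4, segs_per_speaker = 2,
                              shape = c(65, 41))
  tr <- dplyr::filter(data, !grepl("S01", speaker_id))
  va <- dplyr::filter(data, grepl("S01", speaker_id))
  cfg <- train_config(epochs = 3, seed = 7)
  f1 <- fit(assemble("cnn2d", small_hp, seed = 2), tr, va, cfg)
  expect_true(all(is.finite(f1$history$train_task_loss)))
  expect_equal(nrow(f1$history), 3)
  f2 <- fit(assemble("cnn2d", small_hp, seed = 2), tr, va, cfg)
  expect_identical(f1$history$train_task_loss, f2$history$train_task_loss)
  # tidy/glance accessors
  expect_identical(tidy(f1), f1$history)
  expect_equal(glance(f1)$epochs, 3)
  # speaker overlap is rejected
  expect_error(fit(assemble("cnn2d", small_hp, seed = 2), data, va, cfg),
               "both train and validation")
})

test_that("pretraining learns a separable contrast and freezing holds", {
  data <- rigged_segment_data(n_speakers_per_class = 6, segs_per_speaker = 2,
                              strength = 3, seed = 5)
  bundle <- assemble("cnn2d", small_hp, seed = 3)
  accs <- c()
  for (s in 1:3) {
    ft <- pretrain(bundle, data, train_config(epochs = 6, seed = s))
    accs <- c(accs, max(ft$history$val_accuracy))
  }
  expect_gt(max(accs), 0.95)
  expect_true(all(is.finite(unlist(lapply(accs, identity)))))
  ft <- pretrain(bundle, data, train_config(epochs = 4, seed = 1))
  expect_true(ft$bundle$pretrained)
  # freeze: first conv layer + its normalisation stay bit-identical
  target <- assemble("cnn2d", small_hp, seed = 99)
  expect_error(freeze_initial_layer(target), "before pretrained")
  target <- init_from_pretrained(target, ft)
  frozen <- freeze_initial_layer(target)
  pre_w <- frozen$extractor$layers[[1]]$params$W
  pre_bn <- frozen$extractor$layers[[2]]$params
  tr <- dplyr::filter(data, !grepl("S01", speaker_id))
  va <- dplyr::filter(data, grepl("S01", speaker_id))
  f2 <- fit(frozen, tr, va, train_config(epochs = 2, seed = 3))
  post <- f2$final_bundle$extractor$layers
  expect_identical(post[[1]]$params$W, pre_w)
  expect_identical(post[[2]]$params, pre_bn)
  # at least one non-frozen parameter moved
  expect_false(identical(post[[6]]$params$W,
                         frozen$extractor$layers[[6]]$params$W))
  n_frozen <- length(unlist(post[[1]]$params)) +
    length(unlist(post[[2]]$params))
  expect_gt(n_frozen, 0)
  expect_lt(n_frozen, voiceda:::model_param_count(f2$final_bundle))
  expect_error(pretrain(bundle, dplyr::filter(data, class_label == "HC")),
               "single class")
})

test_that("grid search respects the space, the budget, and the scores", {
  space <- list(fc_units = c(16, 32, 64), dropout = c(0.2, 0.5))
  calls <- 0
  scorer <- function(hp) {
    calls <<- calls + 1
    # rigged: only fc_units = 64 can fit this problem
    if (hp$fc_units == 64) 1.0 else 0.5 + 0.1 * hp$dropout
  }
  res <- grid_search(space, budget = 100, seed = 1, scorer = scorer)
  expect_equal(res$best$fc_units, 64)
  expect_true(res$best$fc_units %in% space$fc_units)
  expect_true(res$best$dropout %in% space$dropout)
  expect_equal(calls, 6)           # exhaustive within budget
  calls <- 0
  res2 <- grid_search(space, budget = 4, seed = 1, scorer = scorer)
  expect_lte(calls, 4)             # budgeted subset
  expect_error(grid_search(list()), "empty search space")
})

test_that("the default grid-search scorer trains on speaker-disjoint data", {
  data <- rigged_segment_data(n_speakers_per_class = 4, segs_per_speaker = 2,
                              strength = 3)
  res <- grid_search(list(fc_units = c(8, 16)), data = data,
                     architecture = "cnn2d", budget = 2, seed = 2,
                     cfg = train_config(epochs = 2, seed = 1))
  expect_true(res$best$fc_units %in% c(8, 16))
  expect_equal(nrow(res$evaluations), 2)
  expect_true(all(res$evaluations$score >= 0 & res$evaluations$score <= 1))
})
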