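# Patient decisions, metrics, and the divergence audit.

test_that("patient decisions follow the joint-probability rule", {
  expect_equal(patient_decision(list(c(0.6, 0.4), c(0.7, 0.3))), "HC")
  expect_equal(patient_decision(list(c(0.4, 0.6), c(0.3, 0.7))), "PD")
  expect_equal(patient_decision(list(c(0.5, 0.5))), "HC")    # tie -> HC
  expect_equal(patient_decision(list(c(0.2, 0.8))), "PD")    # n = 1 argmax
  expect_error(patient_decision(matrix(numeric(0), 0, 2)), "no segments")
})

test_that("log-sum decisions equal brute-force products", {
  withr::local_seed(8)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    p <- matrix(runif(2 * n, min = 1e-12), n, 2)
    p <- p / rowSums(p)
    brute <- c("HC", "PD")[which.max(apply(p, 2, prod))]
    expect_equal(patient_decision(p), brute)
  }
})

test_that("classification metrics match confusion-matrix arithmetic", {
  y_true <- c(rep("PD", 10), rep("HC", 10))
  y_pred <- c(rep("PD", 8), rep("HC", 2), rep("HC", 6), rep("PD", 4))
  m <- classification_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 70)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 60)
  expect_equal(m$f1, 72.73, tolerance = 1e-3)
  perfect <- classification_metrics(y_true, y_true)
  expect_equal(unlist(perfect[c("accuracy", "f1", "sensitivity",
                                "specificity")]),
               c(accuracy = 100, f1 = 100, sensitivity = 100,
                 specificity = 100))
  # swapping the positive class swaps sensitivity and specificity
  sw <- classification_metrics(y_true, y_pred, positive = "HC")
  expect_equal(sw$sensitivity, m$specificity)
  expect_equal(sw$specificity, m$sensitivity)
  expect_error(classification_metrics(y_true, y_pred[1:5]), "length")
  expect_error(classification_metrics(rep("PD", 4), rep("PD", 4)),
               "single class")
})

test_that("mean (sd) formatting matches the reporting convention", {
  m <- tibble::tibble(accuracy = c(62, 70, 85.2), f1 = c(60, 70, 80),
                      sensitivity = c(50, 60, 70),
                      specificity = c(80, 80, 80))
  f <- format_mean_sd(m)
  expect_equal(f$accuracy, sprintf("%.1f (%.1f)", mean(m$accuracy),
                                   sd(m$accuracy)))
  expect_equal(f$specificity, "80.0 (0.0)")
})

test_that("symmetrised Gaussian KL matches closed forms", {
  withr::local_seed(3)
  x <- matrix(rnorm(500), ncol = 2)
  expect_lt(gaussian_kl_symmetric(x, x), 1e-8)
  # swap invariance
  y <- matrix(rnorm(500, 1), ncol = 2)
  expect_equal(gaussian_kl_symmetric(x, y), gaussian_kl_symmetric(y, x),
               tolerance = 1e-12)
  # unit-variance mean shift: symmetrised KL = (delta mu)^2 / 2
  a <- rnorm(1e5, 0, 1)
  b <- rnorm(1e5, 1, 1)
  expect_equal(gaussian_kl_symmetric(a, b), 0.5, tolerance = 0.02)
  expect_error(gaussian_kl_symmetric(matrix(1, 1, 2), x), "2 samples")
})

test_that("the KL estimate converges to the closed form with n", {
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    set.seed(100 + n)
    abs(gaussian_kl_symmetric(rnorm(n, 0, 1), rnorm(n, 1, 1)) - 0.5)
  }, numeric(1))
  expect_lt(errs[2], 0.05)
  expect_lt(errs[3], 0.02)
  expect_lt(errs[3], errs[1] + 1e-3)
})

make_emb_tbl <- function(by_domain, class_label = "HC") {
  rows <- lapply(names(by_domain), function(dn) {
    m <- by_domain[[dn]]
    tibble::tibble(class_label = class_label, domain_label = dn,
                   speaker_id = paste0(dn, "_s"),
                   embedding = lapply(seq_len(nrow(m)), function(i) m[i, ]))
  })
  dplyr::bind_rows(rows)
}

test_that("intra-class inter-domain KL enumerates unordered pairs", {
  withr::local_seed(5)
  doms4 <- setNames(lapply(1:4, function(i) matrix(rnorm(60), ncol = 2)),
                    paste0("d", 1:4))
  kl4 <- intraclass_domain_kl(make_emb_tbl(doms4))
  expect_equal(nrow(kl4), 6)
  doms2 <- doms4[1:2]
  expect_equal(nrow(intraclass_domain_kl(make_emb_tbl(doms2))), 1)
  expect_true(all(kl4$kl >= 0))
  # same-generator domains diverge less than a shifted control
  shifted <- doms4
  shifted$d4 <- shifted$d4 + 5
  kl_shift <- intraclass_domain_kl(make_emb_tbl(shifted))
  base_mean <- mean(kl4$kl)
  shift_pairs <- kl_shift$kl[kl_shift$domain_a == "d4" |
                               kl_shift$domain_b == "d4"]
  expect_gt(min(shift_pairs), base_mean)
  expect_error(intraclass_domain_kl(make_emb_tbl(doms4[1])), "2 domains")
})

test_that("trace of covariance follows its definitional identities", {
  two_pt <- make_emb_tbl(list(d1 = rbind(c(0, 0), c(2, 0))))
  expect_equal(tcm(two_pt), 2.0)
  same <- make_emb_tbl(list(d1 = rbind(c(1, 1), c(1, 1), c(1, 1))))
  expect_equal(tcm(same), 0)
  withr::local_seed(6)
  x <- matrix(rnorm(200), ncol = 4)
  tb <- make_emb_tbl(list(d1 = x))
  expect_equal(tcm(tb), sum(apply(x, 2, var)), tolerance = 1e-12)
  tb_scaled <- make_emb_tbl(list(d1 = 3 * x))
  expect_equal(tcm(tb_scaled), 9 * tcm(tb), tolerance = 1e-10)
})

test_that("embeddings align with labels and the declared tap point", {
  data <- rigged_segment_data(n_speakers_per_class = 2, segs_per_speaker = 2)
  hp <- hyperparams(conv_depth = 4, fc_units = 8, validate = FALSE)
  bundle <- assemble("cnn2d", hp, seed = 2)
  emb <- extract_embeddings(bundle, data)
  expect_equal(nrow(emb), nrow(data))
  expect_true(all(lengths(emb$embedding) == hp$fc_units))
  emb2 <- extract_embeddings(bundle, data)
  expect_identical(embedding_matrix(emb), embedding_matrix(emb2))
  ext <- extract_embeddings(bundle, data, tap = "extractor")
  expect_true(all(lengths(ext$embedding) == bundle$embedding_dim))
  rep_d <- divergence_report(emb)
  expect_setequal(rep_d$tcm$class_label, c("HC", "PD"))
  expect_equal(nrow(rep_d$kl), 2)   # 2 domains -> 1 pair per class
})
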