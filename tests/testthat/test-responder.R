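test_that("the responder rule handles its boundary cases as printed", {
  expect_equal(label_responder(20, 13), "responder")      # 35% and 7 points
  expect_equal(label_responder(20, 15), "non-responder")  # 25%, exactly 5 pts
  expect_equal(label_responder(10, 7), "responder")       # exactly 30%
  expect_equal(label_responder(40, 34), "responder")      # 15% but 6 points
  expect_true(is.na(label_responder(20, NA)))
  expect_error(label_responder(0, 0), class = "tmsreact_undefined_ratio")
})

test_that("the responder rule agrees with a brute-force restatement on a full grid", {
  for (t0 in 5:60) {
    lab <- vapply(0:t0, function(t10) label_responder(t0, t10), "")
    ref <- vapply(0:t0, function(t10) oracle_responder(t0, t10), "")
    expect_identical(lab, ref)
  }
})

test_that("fold z-scoring uses training statistics only", {
  set.seed(10)
  tr <- matrix(rnorm(40, mean = 3, sd = 2), 20, 2)
  te <- matrix(rnorm(10, mean = 3, sd = 2), 5, 2)
  z <- fold_zscore(tr, te)
  expect_equal(unname(colMeans(z$train)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z$train, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(unname(colMeans(z$test)), c(0, 0))))
  tr[, 2] <- 5
  expect_warning(z2 <- fold_zscore(tr, te), "constant")
  expect_true(all(z2$train[, 2] == 0))
})

test_that("ROC/AUC match hand and brute-force values, and pROC agrees", {
  expect_equal(roc_report(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_report(rep(0.3, 6), rep(c(FALSE, TRUE), 3))$auc, 0.5)
  r <- roc_report(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, oracle_auc(c(0.1, 0.4, 0.35, 0.8),
                                 c(FALSE, FALSE, TRUE, TRUE)))
  set.seed(12)
  sc <- rnorm(60)
  lab <- rbinom(60, 1, 0.5) == 1
  expect_equal(roc_report(sc, lab)$auc, oracle_auc(sc, lab))
  if (requireNamespace("pROC", quietly = TRUE)) {
    pr <- pROC::roc(lab, sc, quiet = TRUE, direction = "<")
    expect_equal(roc_report(sc, lab)$auc, as.numeric(pROC::auc(pr)))
  }
  expect_error(roc_report(sc, rep(TRUE, 60)), "both classes")
  # perfectly anti-ordered scores: Youden point has sens = spec = 1 at AUC 1
  r2 <- roc_report(c(5, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 1)
})

test_that("nested CV separates a separable cohort and is seed-reproducible", {
  set.seed(1)
  n <- 15
  x <- rbind(matrix(rnorm(2 * n, mean = 0), n, 2),
             matrix(rnorm(2 * n, mean = 4), n, 2))
  y <- rep(c("non-responder", "responder"), each = n)
  fit <- nested_cv_classify(x, y, repetitions = 3, seed = 42)
  expect_gte(fit$balanced_accuracy, 0.95)
  expect_gte(fit$auc, 0.98)
  # the first repetition is unchanged when more repetitions are requested
  fit2 <- nested_cv_classify(x, y, repetitions = 1, seed = 42)
  expect_equal(fit2$per_rep$auc[1], fit$per_rep$auc[1])
  expect_equal(fit2$per_rep$balanced_accuracy[1],
               fit$per_rep$balanced_accuracy[1])
  # tidy/glance accessors
  expect_equal(nrow(tidy(fit)), 3)
  expect_equal(glance(fit)$auc, fit$auc)
})

test_that("permuted labels keep the classifier at chance (no leakage)", {
  set.seed(2)
  n <- 15
  x <- rbind(matrix(rnorm(2 * n, mean = 0), n, 2),
             matrix(rnorm(2 * n, mean = 4), n, 2))
  y <- sample(rep(c("non-responder", "responder"), each = n))
  fit <- nested_cv_classify(x, y, repetitions = 10, seed = 3)
  expect_gte(fit$auc, 0.30)
  expect_lte(fit$auc, 0.70)
})

test_that("mean AUC is non-decreasing as class separation grows", {
  set.seed(5)
  n <- 30
  base <- matrix(rnorm(2 * 2 * n), 2 * n, 2)
  y <- rep(c("non-responder", "responder"), each = n)
  aucs <- vapply(c(0, 1, 2, 3, 4), function(gap) {
    x <- base
    x[y == "responder", ] <- x[y == "responder", ] + gap
    nested_cv_classify(x, y, repetitions = 5, seed = 11)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("group feature comparisons gate on normality and adjust by BH", {
  set.seed(8)
  d <- tibble::tibble(
    responder = rep(c("responder", "non-responder"), each = 15),
    f1 = c(rnorm(15, 0.35, 0.1), rnorm(15, 0.45, 0.1)),
    f2 = rep(1, 30),
    f3 = rnorm(30)
  )
  out <- group_difference_tests(d, features = c("f1", "f2", "f3"))
  expect_equal(out$note[out$feature == "f2"],
               "zero variance in both groups; test skipped")
  expect_true(out$test[out$feature == "f1"] %in% c("t", "mann-whitney"))
  ok <- !is.na(out$p)
  expect_equal(out$p_adj[ok], stats::p.adjust(out$p[ok], "BH"))
  # identical groups: p approximately 1
  same <- tibble::tibble(responder = rep(c("responder", "non-responder"),
                                         each = 6),
                         f1 = rep(c(1, 2, 3, 4, 5, 6), 2))
  out2 <- group_difference_tests(same, features = "f1")
  expect_gte(out2$p, 0.95)
})

test_that("feature extraction returns the frontal-delta / F2-F7 pair", {
  mont <- default_montage()
  spec <- resting_sim_spec(duration = 8, seed = 3,
                           band_fractions = c(delta = 0.4, alpha = 0.4))
  rec <- simulate_resting_eeg(spec, mont)
  s <- resting_spectral(rec)
  pli <- connectivity_matrix(rec, "delta")
  f <- extract_features(s, pli)
  expect_named(f, c("frontal_delta_relpow", "f2f7_delta_pli"))
  expect_equal(f$frontal_delta_relpow,
               region_average(s, "frontal", band = "delta"))
  expect_equal(f$f2f7_delta_pli, pair_pli(pli, "F2", "F7"))
  expect_true(all(unlist(f) >= 0 & unlist(f) <= 1))
})
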