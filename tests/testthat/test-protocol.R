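# Cross-validation protocol, AUC, model selection, ensembling and the
# per-epoch Wilcoxon comparison machinery.

test_that("the CV plan has k x repeats splits that partition each repeat", {
  co <- tiny_cohort(n_per_cell = 10L)
  plan <- make_cv_plan(co, k = 5, repeats = 2, seed = 3)
  expect_s3_class(plan, "cv_plan")
  expect_length(plan$splits, 10)
  n <- length(co$findings)
  for (r in 1:2) {
    vals <- lapply(Filter(function(s) s$repeat_idx == r, plan$splits),
                   `[[`, "validation")
    expect_setequal(unlist(vals), seq_len(n))          # union = cohort
    expect_equal(sum(lengths(vals)), n)                # disjoint
  }
  for (s in plan$splits) {
    expect_length(intersect(s$train, s$validation), 0)
    expect_setequal(c(s$train, s$validation), seq_len(n))
  }
})

test_that("CV splitting is by patient and deterministic under the seed", {
  co <- tiny_cohort(n_per_cell = 10L)
  patients <- vapply(co$findings, `[[`, character(1), "patient_id")
  plan <- make_cv_plan(co, seed = 11)
  for (s in plan$splits)
    expect_length(intersect(patients[s$train], patients[s$validation]), 0)
  expect_identical(make_cv_plan(co, seed = 11), plan)
  expect_false(identical(make_cv_plan(co, seed = 12), plan))
  expect_error(make_cv_plan(co$findings[1:3], k = 5), "fewer patients")
})

test_that("AUC matches the brute-force pairwise oracle, ties included", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  set.seed(71)
  for (i in 1:60) {
    n <- sample(10:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    sc <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)  # ties
    expect_equal(auc_score(y, sc), oracle_auc(y, sc))
    expect_equal(auc_score(y, -sc), 1 - auc_score(y, sc))  # reversal
  }
  expect_error(auc_score(rep(1, 5), rnorm(5)), "both classes")
})

test_that("AUC agrees with pROC and is ~0.5 for uninformative scores", {
  skip_if_not_installed("pROC")
  set.seed(72)
  y <- rbinom(200, 1, 0.4); sc <- rnorm(200)
  expect_equal(auc_score(y, sc),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  big_y <- rbinom(4000, 1, 0.5); big_s <- rnorm(4000)
  expect_lt(abs(auc_score(big_y, big_s) - 0.5), 0.05)
})

test_that("best-checkpoint selection breaks ties toward the earliest epoch", {
  rising <- data.frame(epoch = 1:5, val_auc = c(0.5, 0.6, 0.7, 0.8, 0.9))
  expect_equal(select_best(rising), 5)
  peak <- data.frame(epoch = 1:10, val_auc = c(0.5, 0.6, 0.65, 0.6, 0.62,
                                               0.6, 0.9, 0.7, 0.6, 0.5))
  expect_equal(select_best(peak), 7)
  plateau <- data.frame(epoch = 1:6, val_auc = c(0.5, 0.8, 0.8, 0.8, 0.7, 0.6))
  expect_equal(select_best(plateau), 2)
})

test_that("per-epoch Wilcoxon comparison flags only genuine differences", {
  set.seed(73)
  A <- matrix(runif(10 * 6, 0.5, 0.9), 10, 6)
  same <- compare_curves(A, A)
  expect_equal(nrow(same), 6)
  expect_false(any(same$significant))

  # consistent improvement across all 10 paired runs (jittered so the
  # absolute differences are untied and the exact distribution applies)
  D <- matrix(runif(60, 0.1, 0.3), 10, 6)
  rep2 <- compare_curves(A, A + D)
  expect_true(all(rep2$significant))
  # all-positive signs at n = 10: the minimal attainable two-sided p
  expect_equal(rep2$p_value, rep(2 / 2^10, 6), tolerance = 1e-12)
  expect_equal(rep2$mean_diff, colMeans(D), tolerance = 1e-12)
  expect_error(compare_curves(A, A[1:5, ]), "equal run counts")
})

test_that("the Wilcoxon p-values match exact sign-pattern enumeration", {
  set.seed(74)
  for (i in 1:100) {
    d <- rnorm(10)
    x <- runif(10); y <- x + d
    wt <- suppressWarnings(wilcox.test(y, x, paired = TRUE,
                                       alternative = "two.sided"))
    expect_equal(wt$p.value, oracle_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("first_epoch_at finds the first threshold crossing", {
  curve <- data.frame(epoch = 1:6, val_auc = c(0.5, 0.82, 0.6, 0.85, 0.9, 0.9))
  expect_equal(first_epoch_at(curve, 0.8), 2)
  expect_equal(first_epoch_at(curve, 0.89), 5)
  expect_true(is.na(first_epoch_at(curve, 0.99)))
})

test_that("a short training run fits, records curves and predicts", {
  samples <- tiny_samples(n_per_cell = 8L)
  labels <- vapply(samples, `[[`, integer(1), "label")
  set.seed(75)
  val <- c(sample(which(labels == 1), 4), sample(which(labels == 0), 4))
  tr <- setdiff(seq_along(samples), val)
  tc <- train_config(epochs = 2L, batch_size = 8L, stop_epochs = 2L)
  fit <- train_model("M2", samples, tr, val, config = tc,
                     augment = augment_config(), c = 2L, seed = 9L)
  expect_s3_class(fit, "mpcnn_fit")
  expect_equal(nrow(fit$curve), 2)
  expect_true(all(fit$curve$val_auc >= 0 & fit$curve$val_auc <= 1))
  expect_true("2" %in% names(fit$checkpoints))
  expect_equal(fit$best_epoch, select_best(fit$curve))
  p <- predict(fit, samples[val])
  expect_length(p, 8)
  expect_true(all(p > 0 & p < 1))
  # deterministic validation pipeline: repeated prediction is identical
  expect_identical(p, predict(fit, samples[val]))
  # same seed reproduces the whole fit
  fit2 <- train_model("M2", samples, tr, val, config = tc,
                      augment = augment_config(), c = 2L, seed = 9L)
  expect_equal(fit2$curve, fit$curve)
})

test_that("ensembling takes the arithmetic mean of model probabilities", {
  samples <- tiny_samples(n_per_cell = 8L)
  labels <- vapply(samples, `[[`, integer(1), "label")
  set.seed(76)
  val <- c(sample(which(labels == 1), 3), sample(which(labels == 0), 3))
  tr <- setdiff(seq_along(samples), val)
  tc <- train_config(epochs = 1L, batch_size = 8L, stop_epochs = 1L)
  fits <- lapply(c(21L, 22L), function(sd)
    train_model("M1", samples, tr, val, config = tc, augment = NULL,
                c = 2L, seed = sd))
  expect_equal(ensemble_predict(fits[1], samples[val]),
               predict(fits[[1]], samples[val]))
  expect_equal(ensemble_predict(fits, samples[val]),
               (predict(fits[[1]], samples[val]) +
                  predict(fits[[2]], samples[val])) / 2)
  expect_error(ensemble_predict(list(), samples[val]), "empty")
})
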