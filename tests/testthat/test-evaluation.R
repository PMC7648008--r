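test_that("fold plans partition subjects with balanced sizes", {
  subs <- 1:38
  loso <- make_fold_plan(subs, "loso")
  expect_length(loso$folds, 38)
  expect_identical(sort(unlist(lapply(loso$folds, `[[`, "test"))), subs)

  kf <- make_fold_plan(subs, "kfold", k = 10, seed = 2)
  sizes <- sort(vapply(kf$folds, function(f) length(f$test), integer(1)))
  expect_identical(sizes, c(3L, 3L, rep(4L, 8)))
  tests <- unlist(lapply(kf$folds, `[[`, "test"))
  expect_identical(sort(tests), subs)           # disjoint cover
  # inner plans never touch the outer test subjects
  for (f in kf$folds) {
    inner_subj <- unlist(lapply(f$inner$folds, `[[`, "test"))
    expect_length(intersect(inner_subj, f$test), 0)
    expect_setequal(inner_subj, f$train)
  }
  expect_error(make_fold_plan(1:5, "kfold", k = 10), "at least k")
  expect_error(make_fold_plan(1:2, "loso"), "at least 3")
})

test_that("folds keep both images of a subject on the same side", {
  ds <- tiny_dataset(tiny_atlas(), n_subjects = 12, seed = 1)
  sel <- class_samples(ds)
  plan <- make_fold_plan(sel$subjects, "kfold", k = 4, seed = 3)
  for (f in plan$folds) {
    te_rows <- sel$subjects %in% f$test
    # each test subject contributes exactly its two condition images
    expect_true(all(table(sel$subjects[te_rows]) == 2))
  }
})

test_that("pooled classification metrics reproduce printed arithmetic", {
  # class accuracies 24/38 = 63.16% and 31/38 = 81.58% average to 72.37%
  truth <- c(rep(1, 38), rep(-1, 38))
  dec <- c(rep(1, 24), rep(-1, 14), rep(-1, 31), rep(1, 7))
  m <- classification_metrics(dec, truth)
  expect_equal(round(100 * m$acc_class1, 2), 63.16)
  expect_equal(round(100 * m$acc_class2, 2), 81.58)
  expect_equal(round(100 * m$balanced_accuracy, 2), 72.37)
  expect_equal(m$balanced_accuracy, (m$acc_class1 + m$acc_class2) / 2)

  # 18/38 correct in each class: per-class and balanced all 47.37%
  dec2 <- c(rep(1, 18), rep(-1, 20), rep(-1, 18), rep(1, 20))
  m2 <- classification_metrics(dec2, truth)
  expect_equal(round(100 * m2$balanced_accuracy, 2), 47.37)
  expect_equal(m2$acc_class1, m2$acc_class2)
})

test_that("AUC hits its limits and matches an independent implementation", {
  truth <- c(rep(1, 19), rep(-1, 19))
  dec <- c(rnorm(19, 5), rnorm(19, -5))
  expect_equal(auc_score(dec, truth), 1)
  expect_equal(auc_score(-dec, truth), 0)
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:5) {
    sc <- rnorm(38)
    expect_equal(auc_score(sc, truth),
                 as.numeric(pROC::auc(pROC::roc(
                   response = truth, predictor = sc, quiet = TRUE,
                   direction = "<", levels = c(-1, 1)))))
  }
})

test_that("ROC curve endpoints and monotonicity", {
  truth <- rep(c(1, -1), 10)
  set.seed(2)
  roc <- roc_curve(rnorm(20), truth)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("regression metrics follow the R2 = r2 convention", {
  x <- c(1, 2, 3, 4, 5)
  m <- regression_metrics(x, x)
  expect_equal(m$r, 1)
  expect_equal(m$r2, 1)
  expect_equal(m$mse, 0)
  m2 <- regression_metrics(x + 3, x)
  expect_equal(m2$mse, 9)
  expect_equal(m2$r, 1)
  set.seed(4)
  a <- rnorm(30); b <- a + rnorm(30)
  m3 <- regression_metrics(a, b)
  expect_equal(m3$r2, cor(a, b)^2)
  expect_true(is.na(regression_metrics(rep(1, 5), x)$r))
  expect_equal(regression_metrics(rep(1, 5), x)$mse, mean((1 - x)^2))
})

test_that("permutation p-values follow the add-one counting convention", {
  # observed metric beats all 100 permutations -> p = 1/101 = 0.01 (2 dp)
  scores <- c(rnorm(10, 3), rnorm(10, -3))
  pipeline <- function(y) c(metric = cor(scores, y))
  y0 <- c(rep(1, 10), rep(-1, 10)) * 3 + scores   # near-perfectly aligned
  rep <- permutation_test(pipeline, y0, permuter_across_subjects(),
                          n_perm = 100, seed = 5)
  expect_true(all(abs(rep$perm[, "metric"]) < abs(rep$observed["metric"])))
  expect_equal(unname(rep$p["metric"]), 1 / 101)
  expect_equal(round(unname(rep$p["metric"]), 2), 0.01)

  # observed equal to every permutation -> p = 1
  rep2 <- permutation_test(function(y) c(m = 1), y0,
                           permuter_across_subjects(), n_perm = 50,
                           seed = 6)
  expect_equal(unname(rep2$p["m"]), 1)

  # MSE direction reversed: smaller permuted values count against
  rep3 <- permutation_test(function(y) c(mse = mean((y - scores)^2)),
                           y0, permuter_across_subjects(),
                           n_perm = 100, seed = 7,
                           lower_is_better = "mse")
  expect_equal(unname(rep3$p["mse"]), 1 / 101)
  expect_error(permutation_test(pipeline, y0, permuter_across_subjects(),
                                n_perm = 0), "at least 1")
})

test_that("within-subject permutation preserves the paired design", {
  subjects <- rep(1:10, each = 2)
  y <- rep(c(1, -1), 10)
  perm <- permuter_within_subject(subjects)
  for (i in 1:20) {
    yp <- regionmkl:::with_seed(i, perm(y))
    # every subject still holds one label of each class
    for (s in 1:10) expect_setequal(yp[subjects == s], c(-1, 1))
  }
  # flips actually happen
  expect_false(identical(regionmkl:::with_seed(1, perm(y)), y))
})

test_that("nested CV recovers signal, stays honest on null data", {
  atl <- tiny_atlas(c(10, 10, 10), 4, seed = 2)
  # separable data -> pooled balanced accuracy 1
  ds <- make_contrast_dataset(
    study_design(n_subjects = 10), atl,
    effect_spec(informative_region_ids = 1, delta = 3, gamma = 0,
                noise_sd = 0.2), seed = 21)
  sel <- class_samples(ds)
  kb <- kernels_for(ds, sel$rows)
  plan <- make_fold_plan(sel$subjects, "kfold", k = 5, seed = 4)
  cv <- run_nested_cv(kb$kset, sel$y, sel$subjects, "classification",
                      plan, C_grid = c(0.1, 1))
  expect_equal(cv$metrics$balanced_accuracy, 1.0)
  # one prediction per subject per class, metrics recomputable
  expect_equal(nrow(cv$predictions), length(sel$y))
  m_re <- classification_metrics(cv$predictions$decision,
                                 cv$predictions$truth)
  expect_identical(m_re$balanced_accuracy,
                   cv$metrics$balanced_accuracy)

  # regression on targets that are a noiseless function of one region
  dsr <- make_contrast_dataset(
    study_design(n_subjects = 14), atl,
    effect_spec(informative_region_ids = 1, delta = 0, gamma = 2,
                noise_sd = 0.05, subject_offset_sd = 0), seed = 22)
  rows <- which(dsr$info$condition == "threat_towards")
  kbr <- kernels_for(dsr, rows)
  yr <- dsr$info$index[rows]
  planr <- make_fold_plan(dsr$info$subject_id[rows], "kfold", k = 7,
                          seed = 5)
  cvr <- run_nested_cv(kbr$kset, yr, dsr$info$subject_id[rows],
                       "regression", planr, C_grid = c(1, 10))
  expect_gte(cvr$metrics$r, 0.95)
})

test_that("LOSO accuracies are integer multiples of 1/n_subjects", {
  atl <- tiny_atlas(c(8, 8, 8), 3, seed = 6)
  ds <- tiny_dataset(atl, n_subjects = 8, delta = 0.8, noise_sd = 0.8,
                     seed = 30)
  sel <- class_samples(ds)
  kb <- kernels_for(ds, sel$rows)
  plan <- make_fold_plan(sel$subjects, "loso")
  cv <- run_nested_cv(kb$kset, sel$y, sel$subjects, "classification",
                      plan, C_grid = 1)
  n <- length(unique(sel$subjects))
  for (acc in c(cv$metrics$acc_class1, cv$metrics$acc_class2))
    expect_equal(acc * n, round(acc * n), tolerance = 1e-9)
})

test_that("outer-test targets never leak into model selection", {
  atl <- tiny_atlas(c(8, 8, 8), 3, seed = 6)
  ds <- tiny_dataset(atl, n_subjects = 10, seed = 31)
  sel <- class_samples(ds)
  kb <- kernels_for(ds, sel$rows)
  plan <- make_fold_plan(sel$subjects, "kfold", k = 5, seed = 8)
  cv1 <- run_nested_cv(kb$kset, sel$y, sel$subjects, "classification",
                       plan, C_grid = c(0.1, 1, 10))
  # corrupt the labels of fold 1's test subjects only
  y2 <- sel$y
  te <- sel$subjects %in% plan$folds[[1]]$test
  y2[te] <- -y2[te]
  cv2 <- run_nested_cv(kb$kset, y2, sel$subjects, "classification",
                       plan, C_grid = c(0.1, 1, 10))
  expect_identical(cv1$chosen_C[1], cv2$chosen_C[1])
  expect_identical(cv1$fold_weights[1, ], cv2$fold_weights[1, ])
  expect_equal(cv1$predictions$decision[cv1$predictions$fold == 1],
               cv2$predictions$decision[cv2$predictions$fold == 1],
               tolerance = 1e-12)
})
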