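#' Build a (nested) cross-validation fold plan over subjects
#'
#' Folds are defined on subjects, never on samples, so both condition
#' images of a subject always stay on the same side of every split. LOSO
#' yields one fold per subject; k-fold shuffles subjects by the seed and
#' splits them into k groups whose sizes differ by at most one (38
#' subjects, k = 10: eight folds of 4 and two of 3). Each outer fold
#' carries an inner plan of the same scheme over its training subjects,
#' for hyperparameter selection; inner plans never touch the outer test
#' subjects.
#'
#' @param subject_ids vector of subject identifiers.
#' @param scheme `"loso"` or `"kfold"`.
#' @param k number of folds for `"kfold"`.
#' @param seed integer seed controlling the k-fold shuffle.
#' @param nested attach inner plans.
#' @return object of class `fold_plan`: `scheme`, `k`, and `folds`, a list
#'   of `list(train, test, inner)`.
#' @export
make_fold_plan <- function(subject_ids, scheme = c("loso", "kfold"),
                           k = 10L, seed = 1L, nested = TRUE) {
  scheme <- match.arg(scheme)
  subjects <- sort(unique(subject_ids))
  n <- length(subjects)
  if (scheme == "loso" && n < 3L)
    stop("LOSO needs at least 3 subjects", call. = FALSE)
  if (scheme == "kfold" && n < k)
    stop(sprintf("k-fold needs at least k = %d subjects", k),
         call. = FALSE)

  test_sets <- if (scheme == "loso") {
    lapply(subjects, function(s) s)
  } else {
    perm <- with_seed(derive_seed(seed, 31L), sample(subjects))
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    split(perm, rep(seq_len(k), times = sizes))
  }

  folds <- lapply(seq_along(test_sets), function(i) {
    test <- test_sets[[i]]
    train <- setdiff(subjects, test)
    inner <- if (nested) {
      k_in <- min(k, length(train))
      make_fold_plan(train, scheme = scheme, k = k_in,
                     seed = derive_seed(seed, 500L + i), nested = FALSE)
    } else NULL
    list(train = train, test = test, inner = inner)
  })
  structure(list(scheme = scheme,
                 k = if (scheme == "kfold") k else n,
                 subjects = subjects, folds = folds, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %s, %d folds over %d subjects\n",
              x$scheme, length(x$folds), length(x$subjects)))
  invisible(x)
}

#' Pooled classification metrics
#'
#' Per-class accuracy is the pooled fraction correct per class over all
#' outer-fold test predictions; balanced accuracy is the arithmetic mean
#' of the two class accuracies. The AUC integrates the pooled ROC curve
#' by trapezoids, with midrank handling of tied decision values.
#'
#' @param decision numeric decision values (positive predicts class +1).
#' @param truth true labels in `{-1, +1}`.
#' @return list with `acc_class1`, `acc_class2`, `balanced_accuracy`
#'   (proportions in 0-1), `auc`, and `roc` (data frame of FPR/TPR).
#' @export
classification_metrics <- function(decision, truth) {
  truth <- as.numeric(truth)
  if (!all(truth %in% c(-1, 1)) || length(unique(truth)) < 2L)
    stop("truth must contain both classes coded -1/+1", call. = FALSE)
  pred <- ifelse(decision >= 0, 1, -1)
  pos <- truth == 1
  acc1 <- mean(pred[pos] == 1)
  acc2 <- mean(pred[!pos] == -1)
  list(acc_class1 = acc1, acc_class2 = acc2,
       balanced_accuracy = (acc1 + acc2) / 2,
       auc = auc_score(decision, truth),
       roc = roc_curve(decision, truth))
}

#' Area under the ROC curve (midrank tie handling)
#'
#' @param decision numeric scores.
#' @param truth labels in `{-1, +1}`.
#' @return AUC in 0-1; 0.5 is chance, 1 is perfect ranking.
#' @export
auc_score <- function(decision, truth) {
  pos <- truth == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("one class absent", call. = FALSE)
  r <- rank(decision, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pooled ROC curve
#'
#' True/false positive rates as the decision threshold sweeps the
#' observed scores.
#'
#' @inheritParams auc_score
#' @return data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(decision, truth) {
  pos <- truth == 1
  th <- c(Inf, sort(unique(decision), decreasing = TRUE))
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(decision[!pos] >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(decision[pos] >= t), numeric(1)))
}

#' Pooled regression metrics
#'
#' Pearson's r between pooled predicted and true targets, the coefficient
#' of determination taken as `R^2 = r^2`, and the mean squared error.
#'
#' @param predicted,truth pooled predictions and true targets.
#' @return list with `r`, `r2`, `mse`; `r`/`r2` are `NA` when either
#'   vector has zero variance.
#' @export
regression_metrics <- function(predicted, truth) {
  if (length(truth) < 3L)
    stop("need at least 3 pooled predictions", call. = FALSE)
  mse <- mean((predicted - truth)^2)
  r <- if (stats::sd(predicted) > 0 && stats::sd(truth) > 0)
    stats::cor(predicted, truth) else NA_real_
  list(r = r, r2 = r^2, mse = mse)
}

# inner-loop hyperparameter score for one C over the inner folds, pooled;
# tol here is the (looser) selection-loop duality gap
inner_cv_score <- function(kset_raw, y, subjects, inner_plan, task, C,
                           epsilon, tol, rows) {
  pred <- numeric(0)
  truth <- numeric(0)
  for (f in inner_plan$folds) {
    itr <- rows[subjects[rows] %in% f$train]
    ite <- rows[subjects[rows] %in% f$test]
    if (task == "classification" && length(unique(y[itr])) < 2L) {
      warning("inner fold skipped: single class in training", call. = FALSE)
      next
    }
    prep <- prepare_kernels_rows(kset_raw, c(itr, ite), seq_along(itr))
    if (is.null(prep)) next
    model <- train_mkl(prep, y[c(itr, ite)], task = task, C = C,
                       epsilon = epsilon, tol = tol, check_psd = FALSE)
    cross <- lapply(prep$kernels, function(K)
      K[length(itr) + seq_along(ite), seq_along(itr), drop = FALSE])
    pred <- c(pred, predict(model, cross))
    truth <- c(truth, y[ite])
  }
  if (length(pred) == 0) return(NA_real_)
  if (task == "classification") {
    if (length(unique(truth)) < 2L) return(NA_real_)
    classification_metrics(pred, truth)$balanced_accuracy
  } else {
    -mean((pred - truth)^2)   # higher is better
  }
}

# restrict a raw kernel set to `rows`, then center+normalise with the
# first `n_tr` of those rows as training statistics; returns NULL if all
# regions degenerate
prepare_kernels_rows <- function(kset_raw, rows, tr_pos) {
  sub <- kset_raw
  sub$kernels <- lapply(kset_raw$kernels, function(K)
    K[rows, rows, drop = FALSE])
  tryCatch(prepare_kernels(sub, tr_pos, warn = FALSE),
           error = function(e) NULL)
}

#' Nested cross-validation of the MKL decoder
#'
#' For every outer fold, an inner cross-validation over the training
#' subjects (same scheme) selects the soft-margin constant C —
#' classification by maximal pooled inner balanced accuracy, regression by
#' minimal pooled inner MSE, ties resolved towards the smallest C — after
#' which the model is refit on the full outer-training set and the test
#' subjects are predicted. Kernel centering/normalisation statistics and
#' the regression target mean are always computed from the respective
#' training rows only. Predictions are pooled over outer folds before
#' metrics are computed.
#'
#' @param kset a raw (uncentered) `kernel_set` over all samples.
#' @param y targets per sample (`-1/+1` for classification).
#' @param subjects subject id per sample.
#' @param task `"classification"` or `"regression"`.
#' @param plan a nested [make_fold_plan()] over the subjects.
#' @param C_grid candidate C values; a single value skips the inner loop.
#' @param epsilon regression tube half-width (default 0.1 sd of training
#'   targets, per fold).
#' @param tol MKL duality-gap tolerance for the outer-fold refits.
#' @param selection_tol looser duality-gap tolerance used only while
#'   scoring the C grid in the inner loop (ranking candidate C values
#'   does not need the final optimisation precision).
#' @return object of class `cv_report`: `predictions` (pooled data frame),
#'   `metrics`, `chosen_C`, `fold_weights` (folds x regions matrix of
#'   kernel weights), `task`, `plan`.
#' @export
run_nested_cv <- function(kset, y, subjects, task, plan,
                          C_grid = c(0.01, 0.1, 1, 10, 100),
                          epsilon = NULL, tol = 1e-4,
                          selection_tol = 1e-3) {
  stopifnot(inherits(kset, "kernel_set"), !kset$centered)
  n <- nrow(kset$kernels[[1]])
  stopifnot(length(y) == n, length(subjects) == n)
  C_grid <- sort(C_grid)

  all_rows <- seq_len(n)
  preds <- list()
  chosen <- numeric(0)
  fold_w <- matrix(0, length(plan$folds), length(kset$region_ids),
                   dimnames = list(NULL, as.character(kset$region_ids)))

  for (i in seq_along(plan$folds)) {
    fold <- plan$folds[[i]]
    tr <- all_rows[subjects %in% fold$train]
    te <- all_rows[subjects %in% fold$test]

    C_best <- C_grid[1]
    if (length(C_grid) > 1L) {
      scores <- vapply(C_grid, function(C)
        inner_cv_score(kset, y, subjects, fold$inner, task, C, epsilon,
                       selection_tol, tr), numeric(1))
      ok <- which(is.finite(scores))
      if (length(ok) > 0)
        C_best <- C_grid[ok][which.max(scores[ok])]  # ties -> smallest C
    }

    prep <- prepare_kernels_rows(kset, c(tr, te), seq_along(tr))
    if (is.null(prep))
      stop(sprintf("all regions degenerate in outer fold %d", i),
           call. = FALSE)
    model <- train_mkl(prep, y[c(tr, te)], task = task, C = C_best,
                       epsilon = epsilon, tol = tol, check_psd = FALSE)
    cross <- lapply(prep$kernels, function(K)
      K[length(tr) + seq_along(te), seq_along(tr), drop = FALSE])
    f_te <- predict(model, cross)

    fold_w[i, names(model$d)] <- model$d
    chosen[i] <- C_best
    preds[[i]] <- data.frame(
      fold = i, subject_id = subjects[te], sample = te,
      decision = f_te, truth = y[te])
  }

  predictions <- do.call(rbind, preds)
  metrics <- if (task == "classification") {
    classification_metrics(predictions$decision, predictions$truth)
  } else {
    regression_metrics(predictions$decision, predictions$truth)
  }
  structure(list(predictions = predictions, metrics = metrics,
                 chosen_C = chosen, fold_weights = fold_w,
                 task = task, plan = plan),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%s, %s, %d folds)\n", x$task, x$plan$scheme,
              length(x$plan$folds)))
  m <- x$metrics
  if (x$task == "classification")
    cat(sprintf("  balanced accuracy %.2f%% (class1 %.2f%%, class2 %.2f%%), AUC %.2f\n",
                100 * m$balanced_accuracy, 100 * m$acc_class1,
                100 * m$acc_class2, m$auc))
  else
    cat(sprintf("  r %.3f, R2 %.3f, MSE %.3f\n", m$r, m$r2, m$mse))
  invisible(x)
}

#' Label permuters for permutation inference
#'
#' `permuter_within_subject` flips, independently per subject with
#' probability one half, the two condition labels of that subject's image
#' pair — the permutation scheme matching the paired design of the
#' classification task. `permuter_across_subjects` freely permutes
#' targets across subjects (used for regression, and available as the
#' unpaired classification alternative).
#'
#' @param subjects subject id per sample.
#' @return a function `(y) -> permuted y` drawing from the current RNG
#'   stream.
#' @export
permuter_within_subject <- function(subjects) {
  force(subjects)
  function(y) {
    out <- y
    for (s in unique(subjects)) {
      if (stats::runif(1) < 0.5) {
        rows <- which(subjects == s)
        out[rows] <- -y[rows]
      }
    }
    out
  }
}

#' @rdname permuter_within_subject
#' @export
permuter_across_subjects <- function(subjects = NULL) {
  function(y) sample(y)
}

#' Permutation test of pipeline performance metrics
#'
#' Re-runs a deterministic pipeline closure `n_perm` times with permuted
#' targets (fold plans and hyperparameter grids inside the closure are
#' held fixed) and counts, per metric, how often the permuted value
#' matches or beats the observed one: `|metric_perm| >= |metric_obs|`,
#' reversed (`<=`) for error-type metrics such as MSE. The p-value uses
#' the add-one convention `p = (1 + count) / (n_perm + 1)`, whose floor
#' with 100 permutations is 1/101 = 0.01 at two decimals.
#'
#' @param pipeline function mapping a target vector to a named numeric
#'   vector of metrics; must be deterministic given the targets.
#' @param y the observed targets.
#' @param permute a permuter, e.g. [permuter_within_subject()].
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed for the permutation stream.
#' @param lower_is_better names of metrics where smaller is better.
#' @return object of class `permutation_report`: `observed`, `perm`
#'   (matrix `n_perm x metrics`), `p`, `n_perm`, `seed`.
#' @export
permutation_test <- function(pipeline, y, permute, n_perm = 100L,
                             seed = 1L, lower_is_better = "mse") {
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  observed <- unlist(pipeline(y))
  perm <- matrix(NA_real_, n_perm, length(observed),
                 dimnames = list(NULL, names(observed)))
  for (b in seq_len(n_perm)) {
    yb <- with_seed(derive_seed(seed, 7000L + b), permute(y))
    perm[b, ] <- unlist(pipeline(yb))
  }
  p <- vapply(names(observed), function(mn) {
    cnt <- if (mn %in% lower_is_better)
      sum(perm[, mn] <= observed[mn], na.rm = TRUE)
    else
      sum(abs(perm[, mn]) >= abs(observed[mn]), na.rm = TRUE)
    (1 + cnt) / (n_perm + 1)
  }, numeric(1))
  structure(list(observed = observed, perm = perm, p = p,
                 n_perm = n_perm, seed = seed),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("permutation_report (%d permutations)\n", x$n_perm))
  for (mn in names(x$observed))
    cat(sprintf("  %s = %.4g (p = %.2f)\n", mn, x$observed[mn], x$p[mn]))
  invisible(x)
}
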