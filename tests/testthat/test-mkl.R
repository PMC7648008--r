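# grid-search oracle: minimise the inner objective over d1 on {0,.01,..,1}
grid_oracle <- function(kernels, y, task, C, epsilon = NULL) {
  grid <- seq(0, 1, by = 0.01)
  vapply(grid, function(g) {
    K <- g * kernels[[1]] + (1 - g) * kernels[[2]]
    if (task == "classification")
      regionmkl:::solve_svc(K, y, C)$J
    else
      regionmkl:::solve_svr(K, y - mean(y), C, epsilon)$J
  }, numeric(1))
}

test_that("single-kernel MKL collapses to the plain kernel machine", {
  tk <- toy_two_kernels(n = 20, seed = 3)
  K <- tk$kernels[[1]]
  m <- train_mkl(list(K), tk$y, "classification", C = 1)
  expect_equal(unname(m$d), 1)
  plain <- regionmkl:::solve_svc(K, tk$y, C = 1)
  expect_equal(m$coef, plain$coef, tolerance = 1e-6)
  expect_equal(m$b, plain$b, tolerance = 1e-6)
  f_mkl <- predict(m, list(K))
  f_plain <- drop(K %*% plain$coef) + plain$b
  expect_lt(max(abs(f_mkl - f_plain)), 1e-6)
})

test_that("the inner classifier dual matches an independent solver", {
  skip_if_not_installed("kernlab")
  tk <- toy_two_kernels(n = 30, seed = 12)
  K <- 0.4 * tk$kernels[[1]] + 0.6 * tk$kernels[[2]]
  for (C in c(0.1, 1, 10)) {
    mine <- regionmkl:::solve_svc(K, tk$y, C)
    ks <- kernlab::ksvm(kernlab::as.kernelMatrix(K), factor(tk$y),
                        type = "C-svc", C = C, scaled = FALSE)
    expect_equal(mine$J, -kernlab::obj(ks), tolerance = 1e-4)
  }
})

test_that("two-kernel problems match the brute-force simplex grid", {
  for (seed in c(3, 21)) {
    tk <- toy_two_kernels(n = 20, seed = seed)
    for (C in c(0.1, 1, 10)) {
      m <- train_mkl(tk$kernels, tk$y, "classification", C = C,
                     tol = 1e-5)
      Jg <- grid_oracle(tk$kernels, tk$y, "classification", C)
      expect_lt(abs(m$objective - min(Jg)),
                1e-3 * max(1, abs(min(Jg))))
    }
    # regression against the same oracle
    yr <- regionmkl:::with_seed(seed + 100,
      tk$feats$A[, 1] + 0.1 * rnorm(20))
    eps <- 0.1 * sd(yr)
    mr <- train_mkl(tk$kernels, yr, "regression", C = 10,
                    epsilon = eps, tol = 1e-5)
    Jgr <- grid_oracle(tk$kernels, yr, "regression", 10, eps)
    expect_lt(abs(mr$objective - min(Jgr)),
              1e-3 * max(1, abs(min(Jgr))))
  }
})

test_that("duplicating a kernel changes neither objective nor predictions", {
  tk <- toy_two_kernels(n = 20, seed = 5)
  A <- tk$kernels[[1]]
  m1 <- train_mkl(list(A), tk$y, "classification", C = 1)
  m2 <- train_mkl(list(A, A), tk$y, "classification", C = 1)
  expect_equal(m2$objective, m1$objective, tolerance = 1e-6)
  f1 <- predict(m1, list(A))
  f2 <- predict(m2, list(A, A))
  expect_equal(f2, f1, tolerance = 1e-6)
})

test_that("simplex, sparsity and KKT invariants hold on varied problems", {
  for (seed in 1:5) {
    tk <- toy_two_kernels(n = 16, seed = seed)
    extra <- regionmkl:::with_seed(seed + 50, {
      X <- matrix(rnorm(16 * 3), 16, 3)
      normalize_kernel(center_kernel(tcrossprod(X)))$K
    })
    m <- train_mkl(c(tk$kernels, list(extra)), tk$y, "classification",
                   C = 1)
    expect_true(all(m$d >= 0))
    expect_equal(sum(m$d), 1, tolerance = 1e-8)
    expect_true(all(m$d == 0 | m$d >= 1e-6))   # tiny weights exactly zero
    expect_lte(m$duality_gap, 1e-4 + 1e-12)
    # box constraint on signed duals: 0 <= alpha_i y_i <= C
    expect_true(all(m$coef * tk$y >= -1e-10 &
                      m$coef * tk$y <= 1 + 1e-10))
    # objective trace non-increasing
    expect_true(all(diff(m$objective_trace) <= 1e-9))
  }
})

test_that("separable data are fit perfectly and constructed targets recovered", {
  tk <- toy_two_kernels(n = 20, seed = 4, signal = 5)
  m <- train_mkl(tk$kernels, tk$y, "classification", C = 100)
  f <- predict(m, lapply(tk$kernels, identity))
  expect_equal(classification_metrics(f, tk$y)$balanced_accuracy, 1.0)

  # regression targets generated exactly by one kernel's features
  Xc <- sweep(tk$feats$A, 2, colMeans(tk$feats$A))
  yr <- drop(Xc %*% c(1, 0.5, -0.3, 0.2))
  mr <- train_mkl(tk$kernels, yr, "regression", C = 1000, epsilon = 0.01)
  pr <- predict(mr, lapply(tk$kernels, identity))
  expect_lte(mean((pr - yr)^2), 0.01^2 + 1e-8)
  expect_gt(mr$d[["A"]], 0.9)

  # constant targets: no support vectors, constant prediction
  mc <- train_mkl(tk$kernels, rep(5, 20), "regression", C = 1,
                  epsilon = 0.1)
  expect_lt(max(abs(mc$coef)), 1e-10)
  expect_equal(unname(predict(mc, lapply(tk$kernels, identity))),
               rep(5, 20), tolerance = 1e-8)
})

test_that("degenerate inputs raise the documented errors", {
  K <- diag(4)
  expect_error(train_mkl(list(K), rep(1, 4), "classification"),
               "both classes")
  expect_error(train_mkl(list(K), c(1, -1, 1), "classification"),
               "sample count")
  notpsd <- diag(c(1, 1, 1, -5))
  expect_error(train_mkl(list(notpsd), c(1, 1, -1, -1), "classification",
                         check_psd = TRUE), "PSD")
})

test_that("the informative region dominates the learned kernel weights", {
  atl <- tiny_atlas(c(10, 10, 10), 8, seed = 2)
  wins <- 0L
  for (s in 1:10) {
    ds <- make_contrast_dataset(
      study_design(n_subjects = 38), atl,
      effect_spec(informative_region_ids = 2, delta = 1, gamma = 0,
                  noise_sd = 0.5), seed = 400 + s)
    sel <- class_samples(ds)
    kb <- kernels_for(ds, sel$rows)
    prep <- prepare_kernels(kb$kset, seq_along(sel$y))
    m <- train_mkl(prep, sel$y, "classification", C = 1)
    if (names(which.max(m$d)) == "2") wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("weight maps reproduce the kernel decision function", {
  atl <- tiny_atlas(c(10, 10, 10), 4, seed = 2)
  ds <- tiny_dataset(atl, n_subjects = 10, seed = 6)
  sel <- class_samples(ds)
  kb <- kernels_for(ds, sel$rows)
  tr <- 1:14
  te <- 15:20
  prep <- prepare_kernels(kb$kset, tr)
  m <- train_mkl(prep, sel$y, "classification", C = 1)
  wm <- extract_weights(m, kb$blocks)

  expect_equal(sum(wm$region_pct), 100, tolerance = 1e-6)
  # voxel weights vanish exactly where d = 0
  for (i in seq_along(m$d)) {
    vox <- kb$blocks[[names(m$d)[i]]]$voxel_index
    if (m$d[i] == 0) expect_true(all(wm$voxel_weights[vox] == 0))
  }
  # f(x) from voxel weights == kernel-space prediction, on held-out rows
  f_kernel <- predict(m, prep, test_rows = te)
  f_weights <- vapply(te, function(row) {
    acc <- m$b
    for (rid in names(m$d)) {
      blk <- kb$blocks[[rid]]
      mu <- colMeans(blk$X[tr, , drop = FALSE])
      w <- wm$voxel_weights[blk$voxel_index]
      acc <- acc + sum(w * (blk$X[row, ] - mu))
    }
    acc
  }, numeric(1))
  expect_equal(f_weights, f_kernel, tolerance = 1e-8)
})
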