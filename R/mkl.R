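# Inner kernel-machine solvers ------------------------------------------
#
# Both duals are solved by the compiled SMO routine. `J` is the optimal
# dual objective of the inner machine at the current kernel mixture; the
# SimpleMKL outer loop minimises J(d) over the probability simplex.

# soft-margin classification dual on kernel K; y in {-1, +1}
solve_svc <- function(K, y, C, tol = 1e-8, max_iter = 2000000L,
                      alpha0 = NULL) {
  n <- length(y)
  Q <- K * tcrossprod(y)
  fit <- smo_solve(Q, rep(-1, n), as.integer(y), rep(C, n), tol, max_iter,
                   alpha0)
  coef <- fit$alpha * y
  list(coef = coef, alpha = fit$alpha, b = -fit$rho, J = -fit$obj,
       converged = fit$converged, inner_iterations = fit$iterations)
}

# epsilon-insensitive regression dual (doubled form); y numeric
solve_svr <- function(K, y, C, epsilon, tol = 1e-8, max_iter = 2000000L,
                      alpha0 = NULL) {
  n <- length(y)
  yhat <- c(rep(1L, n), rep(-1L, n))
  idx <- c(seq_len(n), seq_len(n))
  Q <- K[idx, idx] * tcrossprod(yhat)
  p <- c(epsilon - y, epsilon + y)
  fit <- smo_solve(Q, p, yhat, rep(C, 2L * n), tol, max_iter, alpha0)
  coef <- fit$alpha[seq_len(n)] - fit$alpha[n + seq_len(n)]
  list(coef = coef, alpha = fit$alpha, b = -fit$rho, J = -fit$obj,
       converged = fit$converged, inner_iterations = fit$iterations)
}

solve_inner <- function(K, y, task, C, epsilon, inner_tol, alpha0 = NULL) {
  if (task == "classification")
    solve_svc(K, y, C, tol = inner_tol, alpha0 = alpha0)
  else solve_svr(K, y, C, epsilon, tol = inner_tol, alpha0 = alpha0)
}

combine_kernels <- function(kernels, d) {
  K <- kernels[[1]] * d[1]
  for (m in seq_along(kernels)[-1])
    if (d[m] != 0) K <- K + kernels[[m]] * d[m]
  K
}

# n^2 x R stack of vectorised kernels: one BLAS call evaluates both the
# mixture kernel and the per-kernel quadratic forms of the gradient
stack_kernels <- function(kernels) {
  n <- nrow(kernels[[1]])
  vapply(kernels, as.vector, numeric(n * n))
}

#' Train a sparse multiple kernel learning model
#'
#' SimpleMKL: alternates an exact inner kernel-machine fit (soft-margin
#' hinge classifier or epsilon-insensitive regressor, solved by sequential
#' minimal optimisation) on the mixture kernel `K(d) = sum_m d_m K_m` with
#' reduced-gradient descent of the optimal-value objective `J(d)` over the
#' probability simplex `d >= 0, sum d = 1`. The gradient follows from the
#' stationary dual: `dJ/dd_m = -0.5 coef' K_m coef`. The L1 simplex
#' constraint induces sparsity: regions that do not help the predictive
#' task receive weight exactly zero.
#'
#' Initialisation is the uniform mixture `d = 1/R`; the line search is
#' Armijo backtracking along the reduced gradient, so the outer objective
#' is non-increasing and the fit is deterministic (no RNG). Termination:
#' relative duality gap `<= tol`, a vanishing direction, or `max_iter`.
#'
#' @param kernels a prepared `kernel_set` (see [prepare_kernels()]) whose
#'   kernels are restricted to the training rows, or a plain list of
#'   centered/normalised `n x n` training kernels.
#' @param y targets: for classification a vector in `{-1, +1}` or a
#'   two-level factor (first level = positive class); for regression a
#'   numeric vector (mean-centered internally, the mean is restored at
#'   prediction).
#' @param task `"classification"` or `"regression"`.
#' @param C soft-margin / regularisation constant.
#' @param epsilon regression tube half-width; default `0.1 * sd(y)`.
#' @param tol relative duality-gap tolerance of the outer loop.
#' @param max_iter maximum outer iterations.
#' @param check_psd verify each kernel is PSD up to `-1e-8 * trace`.
#' @param inner_tol KKT tolerance of the inner SMO solver.
#' @return an object of class `mkl_model`: kernel weights `d` (named by
#'   region), signed dual coefficients `coef`, bias `b`, hyperparameters,
#'   and convergence diagnostics (`iterations`, `duality_gap`,
#'   `objective`, `objective_trace`, `converged`).
#' @references Rakotomamonjy, Bach, Canu and Grandvalet, SimpleMKL,
#'   Journal of Machine Learning Research 9 (2008).
#' @export
train_mkl <- function(kernels, y, task = c("classification", "regression"),
                      C = 1, epsilon = NULL, tol = 1e-4, max_iter = 500L,
                      check_psd = FALSE, inner_tol = 1e-8) {
  task <- match.arg(task)
  kset <- NULL
  training_rows <- NULL
  if (inherits(kernels, "kernel_set")) {
    kset <- kernels
    kernels <- kernels$kernels
    n_full <- nrow(kernels[[1]])
    if (!is.null(kset$training_rows) &&
        length(kset$training_rows) < n_full) {
      training_rows <- kset$training_rows
      kernels <- lapply(kernels, function(K)
        K[training_rows, training_rows, drop = FALSE])
      if (length(y) == n_full) y <- y[training_rows]
    }
  }
  R <- length(kernels)
  stopifnot(R >= 1L)
  n <- nrow(kernels[[1]])
  if (length(y) != n)
    stop("targets must match the kernel sample count", call. = FALSE)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)

  y_mean <- 0
  if (task == "classification") {
    if (is.factor(y) || is.character(y)) {
      lev <- if (is.factor(y)) levels(y) else sort(unique(y))
      if (length(lev) != 2L)
        stop("classification needs exactly two classes", call. = FALSE)
      y <- ifelse(as.character(y) == lev[1], 1, -1)
    }
    if (!all(y %in% c(-1, 1)))
      stop("labels must be coded -1/+1 (or a two-level factor)",
           call. = FALSE)
    if (length(unique(y)) < 2L)
      stop("both classes must be present in training data", call. = FALSE)
  } else {
    y <- as.numeric(y)
    y_mean <- mean(y)
    y <- y - y_mean
    if (is.null(epsilon)) epsilon <- 0.1 * stats::sd(y)
    if (!is.finite(epsilon)) epsilon <- 0
  }

  if (check_psd) {
    for (m in seq_len(R)) {
      ev <- min(eigen(kernels[[m]], symmetric = TRUE,
                      only.values = TRUE)$values)
      trc <- sum(diag(kernels[[m]]))
      if (ev < -1e-8 * max(trc, 1))
        stop(sprintf("kernel %d is not PSD within tolerance", m),
             call. = FALSE)
    }
  }

  Kmat <- stack_kernels(kernels)
  alpha_warm <- NULL
  eval_J <- function(d) {
    K <- matrix(Kmat %*% d, n, n)
    fit <- solve_inner(K, y, task, C, epsilon, inner_tol,
                       alpha0 = alpha_warm)
    alpha_warm <<- fit$alpha
    fit$S <- 0.5 * drop(crossprod(Kmat, as.vector(tcrossprod(fit$coef))))
    fit
  }

  d <- rep(1 / R, R)
  fit <- eval_J(d)
  trace_J <- fit$J
  gap <- Inf
  iter <- 0L
  converged <- FALSE

  if (R == 1L) {
    gap <- 0
    converged <- TRUE
  } else {
    while (iter < max_iter) {
      iter <- iter + 1L
      S <- fit$S                       # S_m = 0.5 coef' K_m coef >= 0
      gap <- (max(S) - sum(d * S)) / max(abs(fit$J), .Machine$double.eps)
      if (gap <= tol) { converged <- TRUE; break }

      g <- -S                          # dJ/dd_m
      mu <- which.max(d)
      red <- g - g[mu]
      D <- -red
      D[d <= 0 & red > 0] <- 0
      D[mu] <- -(sum(D) - D[mu])
      if (max(abs(D)) < 1e-12) { converged <- gap <= tol; break }

      neg <- which(D < -1e-15)
      step_max <- if (length(neg)) min(-d[neg] / D[neg]) else 1
      if (!is.finite(step_max) || step_max <= 0) break
      gD <- sum(g * D)                 # directional derivative (< 0)

      step <- step_max
      accepted <- FALSE
      for (ls in 1:30) {
        d_new <- d + step * D
        d_new[d_new < 0] <- 0
        d_new <- d_new / sum(d_new)
        fit_new <- eval_J(d_new)
        if (fit_new$J <= fit$J + 1e-4 * step * gD) {
          d <- d_new
          fit <- fit_new
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      trace_J <- c(trace_J, fit$J)
      if (!accepted) {
        # no admissible decrease: treat as converged at current gap
        break
      }
    }
    if (!converged && gap <= tol) converged <- TRUE
  }

  # sparsity contract: tiny weights are exactly zero
  d[d < 1e-6] <- 0
  d <- d / sum(d)
  fit <- eval_J(d)
  S <- fit$S
  gap <- if (R == 1L) 0 else
    (max(S) - sum(d * S)) / max(abs(fit$J), .Machine$double.eps)

  region_ids <- if (!is.null(kset)) kset$region_ids else
    (if (!is.null(names(kernels))) names(kernels) else seq_len(R))
  names(d) <- as.character(region_ids)

  structure(list(
    d = d, coef = fit$coef, b = fit$b, task = task, C = C,
    epsilon = if (task == "regression") epsilon else NULL,
    y_mean = y_mean, region_ids = region_ids, n_train = n,
    training_rows = training_rows %||% seq_len(n),
    iterations = iter, duality_gap = gap,
    converged = converged || gap <= tol,
    objective = fit$J, objective_trace = trace_J,
    scales = if (!is.null(kset)) kset$scales else NULL,
    sample_hash = if (!is.null(kset)) kset$sample_hash else NULL),
    class = "mkl_model")
}

#' @export
print.mkl_model <- function(x, ...) {
  cat(sprintf("mkl_model (%s): %d kernels, %d nonzero weights, C = %g\n",
              x$task, length(x$d), sum(x$d > 0), x$C))
  cat(sprintf("  objective %.6g, duality gap %.3g, %d outer iterations%s\n",
              x$objective, x$duality_gap, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Predict from a multiple kernel learning model
#'
#' `f(x) = sum_i coef_i sum_m d_m K_m(x_i, x) + b`; classification labels
#' are `sign(f)`, regression predictions add back the training-target
#' mean. Test kernels must be centered/normalised with the model's
#' training statistics (slice the output of [prepare_kernels()] as
#' `K[test, train]`).
#'
#' @param object an `mkl_model`.
#' @param kernels list of `n_test x n_train` cross-kernel matrices in the
#'   model's region order, or a prepared `kernel_set` plus `test_rows`.
#' @param test_rows when `kernels` is a `kernel_set`: row indices of the
#'   test samples (training rows are taken from the set).
#' @param type `"decision"` (decision values / predicted targets) or
#'   `"label"` (classification only; -1/+1).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mkl_model <- function(object, kernels, test_rows = NULL,
                              type = c("decision", "label"), ...) {
  type <- match.arg(type)
  if (inherits(kernels, "kernel_set")) {
    kset <- kernels
    if (!is.null(object$sample_hash) &&
        !identical(object$sample_hash, kset$sample_hash))
      stop("sample-order mismatch between model and kernel set",
           call. = FALSE)
    if (is.null(test_rows)) stop("test_rows required with a kernel_set",
                                 call. = FALSE)
    if (!identical(as.integer(kset$region_ids),
                   as.integer(object$region_ids)))
      stop("kernel set regions do not match the model", call. = FALSE)
    tr <- kset$training_rows
    kernels <- lapply(kset$kernels, function(K)
      K[test_rows, tr, drop = FALSE])
  }
  stopifnot(length(kernels) == length(object$d))
  f <- rep(object$b, nrow(kernels[[1]]))
  for (m in seq_along(kernels))
    if (object$d[m] != 0)
      f <- f + object$d[m] * drop(kernels[[m]] %*% object$coef)
  if (object$task == "regression") return(f + object$y_mean)
  if (type == "label") ifelse(f >= 0, 1, -1) else f
}

#' Back-project model weights to regions and voxels
#'
#' Region weight percentages are `100 * d_m`. Voxel weights are the primal
#' linear weights in the original voxel space: for region m,
#' `w_m = d_m * s_m * Xc_m' coef`, where `Xc_m` is the region's training
#' feature block centered by its training-column means and `s_m` the
#' trace-normalisation factor, so `f(x) = sum_m w_m'(x_m - mu_m) + b`
#' reproduces the kernel decision function. Regions with zero kernel
#' weight have exactly zero voxel weights.
#'
#' @param model an `mkl_model` trained on kernels prepared from `blocks`.
#' @param blocks the full region blocks from [parcellate()] (all samples).
#' @param training_rows rows used for training (defaults to the rows
#'   recorded when the model was trained on a `kernel_set`).
#' @return object of class `weight_map`: `region_pct` (named percentages,
#'   summing to 100 over retained regions), `voxel_weights` (3-D array on
#'   the atlas grid), `region_ids`, `d`.
#' @export
extract_weights <- function(model, blocks, training_rows = NULL) {
  grid_dim <- attr(blocks, "grid_dim")
  if (is.null(grid_dim)) stop("blocks must carry a grid_dim attribute",
                              call. = FALSE)
  if (is.null(training_rows)) training_rows <- model$training_rows
  vol <- array(0, grid_dim)
  ids <- as.character(model$region_ids)
  for (m in seq_along(ids)) {
    blk <- blocks[[ids[m]]]
    if (is.null(blk)) stop("blocks do not match the model's regions",
                           call. = FALSE)
    if (model$d[m] == 0) next
    Xtr <- blk$X[training_rows, , drop = FALSE]
    Xc <- sweep(Xtr, 2, colMeans(Xtr))
    s <- if (!is.null(model$scales)) model$scales[[ids[m]]] else 1
    w <- model$d[m] * s * drop(crossprod(Xc, model$coef))
    vol[blk$voxel_index] <- w
  }
  pct <- 100 * model$d
  structure(list(region_pct = pct, voxel_weights = vol,
                 region_ids = model$region_ids, d = model$d,
                 note = paste("voxel weights are primal linear weights of",
                              "the train-centered, trace-normalised",
                              "features, scaled by the region's kernel",
                              "weight")),
            class = "weight_map")
}
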