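#' Assemble and validate a run configuration
#'
#' A run is configured either from a synthetic scenario (design + effect +
#' atlas spec + seed) or from files on disk (a directory written by
#' [write_contrast_images()]); exactly one input mode must be set.
#'
#' @param task `"classify"` or `"regress"`.
#' @param synthetic list with `design`, `effect`, `atlas_spec` (or a
#'   scenario YAML path).
#' @param files input directory with contrast images and atlas.
#' @param condition_pair for classification: the two condition labels
#'   (positive class first).
#' @param target_condition for regression: the condition whose images are
#'   used.
#' @param scheme,k cross-validation scheme (`"loso"` / `"kfold"`) and k.
#' @param C_grid hyperparameter grid.
#' @param n_permutations permutations for inference (0 disables).
#' @param permute_fixed_C re-run permutations at the modal selected C
#'   instead of re-optimising (fast mode).
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir where results are written.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(task = c("classify", "regress"),
                       synthetic = NULL, files = NULL,
                       condition_pair = c("threat_towards",
                                          "neutral_towards"),
                       target_condition = "threat_towards",
                       scheme = "kfold", k = 10L,
                       C_grid = c(0.01, 0.1, 1, 10, 100),
                       n_permutations = 0L, permute_fixed_C = TRUE,
                       seed = 1L, output_dir = tempfile("regionmkl_run")) {
  task <- match.arg(task)
  if (is.null(synthetic) == is.null(files))
    stop("exactly one input mode (synthetic or files) must be set",
         call. = FALSE)
  if (scheme == "kfold" && k < 2L) stop("k must be >= 2", call. = FALSE)
  if (is.character(synthetic)) synthetic <- read_scenario(synthetic)
  structure(list(task = task, synthetic = synthetic, files = files,
                 condition_pair = condition_pair,
                 target_condition = target_condition,
                 scheme = scheme, k = as.integer(k), C_grid = C_grid,
                 n_permutations = as.integer(n_permutations),
                 permute_fixed_C = isTRUE(permute_fixed_C),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full decoding experiment
#'
#' Executes generate/load, common-mask construction, region-kernel
#' building, nested cross-validation, optional permutation inference and
#' reporting, writing all results plus a provenance manifest to the
#' configured output directory. Identical config and seed give identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return list with `cv` (`cv_report`), `ranking`, `lobe_summary`,
#'   `permutation` (or `NULL`), `paths`; invisibly.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  dataset <- stage("input", {
    if (!is.null(config$synthetic)) {
      sc <- config$synthetic
      atlas <- make_synthetic_atlas(sc$atlas_spec$grid_shape,
                                    sc$atlas_spec$n_regions,
                                    seed = derive_seed(config$seed, 1L))
      make_contrast_dataset(sc$design, atlas, sc$effect,
                            seed = derive_seed(config$seed, 2L))
    } else read_contrast_images(config$files)
  })

  mask <- stage("mask",
    build_common_mask(dataset$images) & atlas_mask(dataset$atlas))

  # task-specific sample selection
  sel <- stage("samples", {
    info <- dataset$info
    if (config$task == "classify") {
      keep <- info$condition %in% config$condition_pair
      y <- ifelse(info$condition[keep] == config$condition_pair[1], 1, -1)
      list(rows = which(keep), y = y,
           subjects = info$subject_id[keep])
    } else {
      keep <- info$condition == config$target_condition
      list(rows = which(keep), y = info$index[keep],
           subjects = info$subject_id[keep])
    }
  })

  kset <- stage("kernels", {
    imgs <- dataset$images[, , , sel$rows, drop = FALSE]
    blocks <- parcellate(imgs, dataset$atlas, mask)
    build_kernel_set(blocks, sample_info = dataset$info[sel$rows, ])
  })
  blocks <- parcellate(dataset$images[, , , sel$rows, drop = FALSE],
                       dataset$atlas, mask)

  plan <- stage("folds",
    make_fold_plan(sel$subjects, scheme = config$scheme, k = config$k,
                   seed = derive_seed(config$seed, 3L)))

  task <- if (config$task == "classify") "classification" else "regression"
  cv <- stage("nested_cv",
    run_nested_cv(kset, sel$y, sel$subjects, task, plan,
                  C_grid = config$C_grid))

  perm <- NULL
  if (config$n_permutations > 0L) {
    perm <- stage("permutation", {
      C_perm <- if (config$permute_fixed_C) {
        tc <- table(cv$chosen_C)
        as.numeric(names(tc))[which.max(tc)]
      } else NULL
      pipeline <- function(yb) {
        rep <- run_nested_cv(kset, yb, sel$subjects, task, plan,
                             C_grid = C_perm %||% config$C_grid)
        m <- rep$metrics
        if (task == "classification")
          c(balanced_accuracy = m$balanced_accuracy, auc = m$auc)
        else c(r = m$r, mse = m$mse)
      }
      permuter <- if (task == "classification")
        permuter_within_subject(sel$subjects)
      else permuter_across_subjects()
      permutation_test(pipeline, sel$y, permuter,
                       n_perm = config$n_permutations,
                       seed = derive_seed(config$seed, 4L))
    })
  }

  rep_out <- stage("reporting", {
    ranking <- rank_regions(cv$fold_weights)
    lobe <- summarize_by_lobe(ranking, dataset$atlas$region_table)
    # final model on all samples at the modal selected C, for weight maps
    tc <- table(cv$chosen_C)
    C_fin <- as.numeric(names(tc))[which.max(tc)]
    prep <- prepare_kernels(kset, seq_along(sel$y), warn = FALSE)
    model <- train_mkl(prep, sel$y, task = task, C = C_fin)
    wm <- extract_weights(model, blocks)
    paths <- export_weight_maps(wm, dataset$atlas, out, ranking = ranking)
    list(ranking = ranking, lobe = lobe, paths = paths)
  })

  stage("outputs", {
    utils::write.csv(cv$predictions, file.path(out, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(rep_out$lobe, file.path(out, "lobe_summary.csv"),
                     row.names = FALSE)
    metr <- cv$metrics[setdiff(names(cv$metrics), "roc")]
    if (!is.null(perm)) {
      utils::write.csv(as.data.frame(perm$perm),
                       file.path(out, "permutation_metrics.csv"),
                       row.names = FALSE)
      metr$p_values <- as.list(perm$p)
    }
    jsonlite::write_json(metr, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package_version = as.character(utils::packageVersion("regionmkl")),
      seed = config$seed, task = config$task, scheme = config$scheme,
      k = config$k, C_grid = config$C_grid,
      n_permutations = config$n_permutations,
      sample_hash = kset$sample_hash,
      chosen_C = cv$chosen_C)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(cv = cv, ranking = rep_out$ranking,
                 lobe_summary = rep_out$lobe, permutation = perm,
                 paths = rep_out$paths, output_dir = out))
}
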