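`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Counter-based derivation so that pipeline stages, folds and permutations
#' each get an independent, reproducible stream while the user supplies a
#' single integer. Stays below 2^31.
#'
#' @param seed master integer seed.
#' @param offset nonnegative integer counter.
#' @return an integer-valued seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer(((as.numeric(seed) %% 2147483629) * 7919 +
                as.numeric(offset) * 104729) %% 2147483629)
}

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards so generators do not disturb user-level RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# md5 of an arbitrary object, used as a provenance / sample-order hash.
obj_hash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

stop_mismatch <- function(what) {
  stop(sprintf("grid mismatch: %s must share one voxel grid", what),
       call. = FALSE)
}

# all 3-D arrays in `vols` share dim
check_same_grid <- function(vols, what = "volumes") {
  dims <- lapply(vols, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
    stop_mismatch(what)
  invisible(dims[[1]])
}
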