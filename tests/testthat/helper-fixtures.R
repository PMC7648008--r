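# Shared small fixtures, built in code at test time.

tiny_atlas <- function(shape = c(10, 10, 10), n_regions = 4L, seed = 1L)
  make_synthetic_atlas(shape, n_regions, seed = seed)

# small dataset wired for classification of towards-context conditions
tiny_dataset <- function(atlas = tiny_atlas(), n_subjects = 12L,
                         delta = 1, gamma = 0, noise_sd = 0.5,
                         seed = 1L, ...) {
  design <- study_design(n_subjects = n_subjects)
  effect <- effect_spec(informative_region_ids = 1L, delta = delta,
                        gamma = gamma, noise_sd = noise_sd, ...)
  make_contrast_dataset(design, atlas, effect, seed = seed)
}

# classification samples (towards context) from a contrast dataset
class_samples <- function(ds) {
  keep <- ds$info$condition %in% c("threat_towards", "neutral_towards")
  list(rows = which(keep),
       y = ifelse(ds$info$condition[keep] == "threat_towards", 1, -1),
       subjects = ds$info$subject_id[keep])
}

# raw kernel set + blocks for given sample rows
kernels_for <- function(ds, rows) {
  mask <- build_common_mask(ds$images) & ds$atlas$label_volume > 0
  blocks <- parcellate(ds$images[, , , rows, drop = FALSE], ds$atlas, mask)
  list(blocks = blocks, kset = build_kernel_set(blocks))
}

# deterministic PSD toy kernels for solver tests: one label-aligned
# signal kernel, one pure-noise kernel, centered + normalised
toy_two_kernels <- function(n = 20L, seed = 3L, signal = 2) {
  stopifnot(n %% 2 == 0)
  y <- rep(c(1, -1), each = n / 2)
  feats <- regionmkl:::with_seed(seed, {
    A <- matrix(rnorm(n * 4), n, 4)
    A[, 1] <- A[, 1] + signal * y
    B <- matrix(rnorm(n * 4), n, 4)
    list(A = A, B = B)
  })
  ks <- lapply(feats, function(X)
    normalize_kernel(center_kernel(tcrossprod(X)))$K)
  list(kernels = ks, y = y, feats = feats)
}
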