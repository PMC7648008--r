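test_that("synthetic atlas construction honours its contract", {
  atl <- make_synthetic_atlas(c(16, 16, 16), n_regions = 8, seed = 1)
  counts <- table(atl$label_volume[atl$label_volume > 0])
  expect_identical(sort(as.integer(names(counts))), 1:8)
  expect_true(all(counts >= 1))
  expect_identical(atl$region_table$region_id, 1:8)
  expect_gte(length(unique(atl$region_table$lobe_group)), 4L)

  atl2 <- make_synthetic_atlas(c(16, 16, 16), n_regions = 8, seed = 1)
  expect_identical(atl$label_volume, atl2$label_volume)

  atl3 <- make_synthetic_atlas(c(16, 16, 16), n_regions = 8, seed = 2)
  expect_false(identical(atl$label_volume, atl3$label_volume))

  expect_error(make_synthetic_atlas(c(2, 2, 2), n_regions = 100),
               "too small")
  expect_error(make_synthetic_atlas(c(16, 16, 16), n_regions = 1),
               ">= 2")
})

test_that("atlas regions are spatially contiguous", {
  atl <- make_synthetic_atlas(c(12, 12, 12), n_regions = 6, seed = 4)
  # flood fill from one voxel of each region must reach all of it
  dm <- dim(atl$label_volume)
  for (rid in atl$region_table$region_id) {
    vox <- which(atl$label_volume == rid)
    co <- arrayInd(vox, dm)
    seen <- rep(FALSE, length(vox))
    key <- paste(co[, 1], co[, 2], co[, 3])
    lookup <- seq_along(vox)
    names(lookup) <- key
    queue <- 1L
    seen[1] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        nb <- co[i, ]; nb[ax] <- nb[ax] + dd
        j <- lookup[paste(nb[1], nb[2], nb[3])]
        if (!is.na(j) && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    expect_true(all(seen), label = sprintf("region %d contiguous", rid))
  }
})

test_that("ratings stay on scale and the index is their exact sum", {
  r <- sample_ratings(200, seed = 5)
  ratings <- as.matrix(r[, 2:5])
  expect_true(all(ratings >= 1 & ratings <= 9))
  expect_identical(r$threat_perception_index,
                   as.integer(unname(rowSums(ratings))))
  expect_true(all(r$threat_perception_index >= 4 &
                    r$threat_perception_index <= 36))
  # distribution centered near the published towards-context mean
  expect_gt(mean(r$threat_perception_index), 10)
  expect_lt(mean(r$threat_perception_index), 15)
})

test_that("contrast dataset places the class effect where specified", {
  atl <- tiny_atlas(c(12, 12, 12), 4, seed = 2)
  design <- study_design(n_subjects = 38)
  eff <- effect_spec(informative_region_ids = 1, delta = 1, gamma = 0,
                     noise_sd = 0.1, subject_offset_sd = 0)
  ds <- make_contrast_dataset(design, atl, eff, seed = 11)
  inf <- atl$label_volume == 1
  thr <- ds$info$is_threat
  m_thr <- mean(apply(ds$images[, , , thr, drop = FALSE], 4,
                      function(v) mean(v[inf])))
  m_neu <- mean(apply(ds$images[, , , !thr, drop = FALSE], 4,
                      function(v) mean(v[inf])))
  sem <- 0.1 / sqrt(sum(inf) * sum(thr))
  expect_lt(abs((m_thr - m_neu) - 1), max(3 * sem, 0.01))

  # determinism
  ds2 <- make_contrast_dataset(design, atl, eff, seed = 11)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$ratings, ds2$ratings)
})

test_that("null effect generates no threat/neutral difference", {
  atl <- tiny_atlas(c(10, 10, 10), 4, seed = 3)
  design <- study_design(n_subjects = 38)
  eff <- effect_spec(informative_region_ids = 1, delta = 0, gamma = 0,
                     noise_sd = 1)
  inf <- atl$label_volume == 1
  crit <- qt(0.9995, df = 2 * 38 - 2)
  hits <- 0L
  n_seeds <- 200L
  for (s in seq_len(n_seeds)) {
    ds <- make_contrast_dataset(design, atl, eff, seed = 5000 + s)
    vals <- apply(ds$images, 4, function(v) mean(v[inf]))
    tt <- t.test(vals[ds$info$is_threat], vals[!ds$info$is_threat],
                 var.equal = TRUE)
    if (abs(tt$statistic) < crit) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("NaN injection hits only border voxels and is off by default", {
  atl <- tiny_atlas(c(12, 12, 12), 4, seed = 2)
  ds0 <- tiny_dataset(atl, n_subjects = 6, seed = 3)
  expect_true(all(is.finite(ds0$images)))

  eff <- effect_spec(informative_region_ids = 1, nan_injection = TRUE)
  ds1 <- make_contrast_dataset(study_design(n_subjects = 6), atl, eff,
                               seed = 3)
  nan_any <- which(apply(ds1$images, 1:3, function(v) any(is.nan(v))))
  if (length(nan_any) > 0) {
    bord <- which(regionmkl:::border_voxels(atl$label_volume > 0))
    expect_true(all(nan_any %in% bord))
  }
  # the common mask rule then removes those voxels for everyone
  mask <- build_common_mask(ds1$images)
  expect_true(all(is.finite(ds1$images[mask])))
})

test_that("session event tables realise the block design", {
  ev <- make_event_table(study_design(), seed = 9)
  expect_equal(nrow(ev), 56)
  expect_true(all(table(ev$condition) == 14))
  expect_true(all(ev$duration_s == 15))
  expect_identical(sort(unique(ev$run)), 1:4)
  # every condition appears in every run
  expect_true(all(table(ev$run, ev$condition) >= 1))
  # blocks fit inside each run and are separated by the 12-s baseline
  for (r in 1:4) {
    ons <- sort(ev$onset_s[ev$run == r])
    expect_true(all(diff(ons) == 27))
    expect_lte(max(ons) + 15, 198 * 2)
  }
})

test_that("a silent session is constant and amplitudes drive the signal", {
  atl <- tiny_atlas(c(8, 8, 8), 3, seed = 5)
  eff <- effect_spec(informative_region_ids = 1, delta = 0, gamma = 0,
                     noise_sd = 0)
  ses <- make_bold_session(study_design(n_subjects = 1), atl, eff,
                           seed = 2, drift_amplitude = 0, ar1 = 0)
  for (run in ses$runs) expect_true(all(run == 100))

  eff2 <- effect_spec(informative_region_ids = 1, delta = 2, gamma = 0,
                      noise_sd = 0)
  ses2 <- make_bold_session(study_design(n_subjects = 1), atl, eff2,
                            seed = 2, drift_amplitude = 0, ar1 = 0)
  inf <- atl$label_volume == 1
  v <- ses2$runs[[1]][, , , ]
  expect_gt(max(v) - 100, 1.5)          # threat blocks reach the amplitude
  out <- ses2$runs[[1]][!array(inf, dim(v)[1:3])][1]
  expect_equal(out, 100)                # non-informative voxels untouched
})

test_that("analytic stimulus images match their closed forms", {
  u <- make_stimulus_image("uniform", 32, 32, value = 128)
  expect_true(all(u == 128))
  cb <- make_stimulus_image("checkerboard", 64, 64, period = 8)
  expect_equal(mean(cb == 0), 0.5)
  expect_equal(mean(cb == 255), 0.5)
  vg <- make_stimulus_image("vertical_gradient", 16, 8)
  cm <- colMeans(regionmkl:::pixel_mean_rgb(vg))
  expect_true(all(diff(cm) > 0))
  expect_error(make_stimulus_image("swirl", 8, 8))
})
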