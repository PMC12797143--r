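test_that("generation is byte-identical under a fixed seed", {
  mask <- tiny_mask(c(14, 14, 14), type = "ball")
  cfg <- sim_config(mask, n_experiments = 6,
    loci = matrix(c(0, 0, 0), ncol = 3), seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  cfg2 <- cfg
  cfg2$seed <- 100L
  expect_false(identical(as.data.frame(generate_dataset(cfg2)),
    as.data.frame(a)))
})

test_that("certain reporting with no jitter and no noise reproduces the loci", {
  mask <- tiny_mask(c(14, 14, 14), type = "ball")
  loci <- matrix(c(0, 0, 0, 6, 6, 0), ncol = 3, byrow = TRUE)
  cfg <- sim_config(mask, n_experiments = 5, loci = loci,
    reporting_probability = 1, jitter_sd_mm = 0,
    noise_foci_range = c(0, 0), seed = 7)
  d <- generate_dataset(cfg)
  expect_equal(nrow(d), 5 * 2)
  for (id in unique(d$study_id)) {
    rows <- d[d$study_id == id, ]
    expect_equal(unname(as.matrix(rows[, c("x", "y", "z")])), loci)
  }
})

test_that("every generated focus lies inside the mask and counts obey config", {
  mask <- tiny_mask(c(14, 14, 14), type = "ball")
  cfg <- sim_config(mask, n_experiments = 10, subjects_range = c(5, 9),
    noise_foci_range = c(2, 4),
    loci = matrix(c(0, 0, 0), ncol = 3), jitter_sd_mm = 4, seed = 31)
  d <- generate_dataset(cfg)
  res <- world_to_voxel(d, mask$grid)
  expect_true(all(res$in_grid))
  lin <- res$i + (res$j - 1) * 14 + (res$k - 1) * 196
  expect_true(all(mask$inside[lin]))
  expect_true(all(d$n_subjects >= 5 & d$n_subjects <= 9))
  per <- table(d$study_id)
  expect_true(all(per >= 2 & per <= 5)) # 2-4 noise + 0-1 reported locus
  expect_equal(length(per), 10)
})

test_that("noise foci are uniform over the mask (goodness of fit)", {
  mask <- tiny_mask(c(12, 12, 12), type = "box")
  cfg <- sim_config(mask, n_experiments = 100, noise_foci_range = c(10, 10),
    loci = NULL, seed = 17)
  d <- generate_dataset(cfg)
  expect_equal(nrow(d), 1000)
  # coarse 2x2x2 partition of the box
  res <- world_to_voxel(d, mask$grid)
  octant <- paste(res$i > 6, res$j > 6, res$k > 6)
  tab <- table(octant)
  expect_equal(length(tab), 8)
  gof <- stats::chisq.test(as.vector(tab))
  expect_gt(gof$p.value, 0.01)
})

test_that("the paradigm trio shares loci as configured", {
  mask <- toy_mask(c(30, 30, 30), type = "ball")
  trio <- generate_paradigm_trio(seed = 5, mask = mask, n_loci = 10,
    shared_wm = 0.6, shared_ex = 0.3,
    n_experiments = c(execution = 3L, imagery = 4L, working_memory = 5L))
  expect_named(trio, c("execution", "imagery", "working_memory"))
  gt <- attr(trio, "ground_truth")
  shared_wm <- sum(apply(gt$working_memory, 1, function(r) {
    any(colSums(abs(t(gt$imagery) - r)) < 1e-9)
  }))
  shared_ex <- sum(apply(gt$execution, 1, function(r) {
    any(colSums(abs(t(gt$imagery) - r)) < 1e-9)
  }))
  expect_equal(shared_wm, 6)
  expect_equal(shared_ex, 3)
  expect_equal(unique(trio$imagery$paradigm), "imagery")
  expect_equal(length(unique(trio$working_memory$study_id)), 5)
  # trio generation is reproducible
  trio2 <- generate_paradigm_trio(seed = 5, mask = mask, n_loci = 10,
    shared_wm = 0.6, shared_ex = 0.3,
    n_experiments = c(execution = 3L, imagery = 4L, working_memory = 5L))
  expect_identical(as.data.frame(trio$imagery), as.data.frame(trio2$imagery))
})

test_that("full sharing and zero sharing behave as expected", {
  mask <- toy_mask(c(26, 26, 26), type = "ball")
  full <- generate_paradigm_trio(seed = 9, mask = mask, n_loci = 4,
    shared_wm = 1, shared_ex = 1,
    n_experiments = c(execution = 2L, imagery = 2L, working_memory = 2L))
  gt <- attr(full, "ground_truth")
  expect_equal(gt$working_memory, gt$imagery)
  expect_equal(gt$execution, gt$imagery)
  none <- generate_paradigm_trio(seed = 9, mask = mask, n_loci = 4,
    shared_wm = 0, shared_ex = 0,
    n_experiments = c(execution = 2L, imagery = 2L, working_memory = 2L))
  gtn <- attr(none, "ground_truth")
  expect_equal(nrow(unique(rbind(gtn$imagery, gtn$working_memory))), 8)
})
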