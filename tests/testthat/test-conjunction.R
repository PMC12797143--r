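test_that("conjunction is idempotent, commutative and grid-checked", {
  g <- tiny_grid(c(12, 12, 12))
  withr::with_seed(5, {
    a <- random_network(g, 40, "imagery")
    b <- random_network(g, 60, "working_memory")
  })
  caa <- min_conjunction(list(a, a), min_cluster_mm3 = 0)
  expect_equal(caa$values, a$ale)
  expect_equal(caa$significant, a$significant)
  cab <- min_conjunction(list(a, b), min_cluster_mm3 = 0)
  cba <- min_conjunction(list(b, a), min_cluster_mm3 = 0)
  expect_equal(cab$values, cba$values)
  g2 <- tiny_grid(c(10, 10, 10))
  withr::with_seed(6, c <- random_network(g2, 10))
  expect_error(min_conjunction(list(a, c)), "different grids")
})

test_that("disjoint supports conjoin to an empty map", {
  g <- tiny_grid(c(10, 10, 10))
  va <- array(0, g$shape); va[1:3, 1, 1] <- 0.05
  vb <- array(0, g$shape); vb[1:3, 5, 5] <- 0.04
  cj <- min_conjunction(list(make_network(va, g), make_network(vb, g)),
    min_cluster_mm3 = 0)
  expect_equal(cj$n_voxels, 0)
  expect_true(all(cj$values == 0))
})

test_that("three-way conjunction equals pairwise minimum applied associatively", {
  g <- tiny_grid(c(12, 12, 12))
  withr::with_seed(9, {
    nets <- list(
      random_network(g, 200, "imagery"),
      random_network(g, 220, "execution"),
      random_network(g, 240, "working_memory")
    )
  })
  direct <- min_conjunction(nets, min_cluster_mm3 = 0)
  ab <- min_conjunction(nets[1:2], min_cluster_mm3 = 0)
  ab_net <- make_network(ab$values, g, "ab")
  assoc <- min_conjunction(list(ab_net, nets[[3]]), min_cluster_mm3 = 0)
  expect_equal(assoc$values, direct$values)
  expect_equal(assoc$n_voxels, direct$n_voxels)
})

test_that("conjunction support shrinks with more inputs and with filtering", {
  g <- tiny_grid(c(12, 12, 12))
  withr::with_seed(14, {
    nets <- list(
      random_network(g, 400, "imagery"),
      random_network(g, 420, "execution"),
      random_network(g, 440, "working_memory")
    )
  })
  c2 <- min_conjunction(nets[1:2], min_cluster_mm3 = 0)
  c3 <- min_conjunction(nets, min_cluster_mm3 = 0)
  expect_lte(c3$n_voxels, c2$n_voxels)
  filt <- min_conjunction(nets[1:2], min_cluster_mm3 = 100)
  expect_lte(filt$n_voxels, filt$n_voxels_unfiltered)
  expect_true(all(filt$significant[filt$significant] &
    c2$significant[filt$significant]))
})

test_that("overlap counts match an exhaustive voxel comparison", {
  g <- tiny_grid(c(12, 12, 12))
  withr::with_seed(23, {
    a <- random_network(g, 150, "imagery")
    b <- random_network(g, 180, "working_memory")
  })
  st <- overlap_stats(a, b, min_cluster_mm3 = 0)
  brute <- sum(mapply(function(x, y) x && y,
    as.vector(a$significant), as.vector(b$significant)))
  expect_equal(st$n_overlap, brute)
  expect_equal(st$n_a, sum(a$significant))
  expect_equal(st$n_b, sum(b$significant))
  expect_lte(st$n_overlap, min(st$n_a, st$n_b))
  # raw intersection equals the unfiltered conjunction support
  cj <- min_conjunction(list(a, b), min_cluster_mm3 = 0)
  expect_equal(st$n_overlap, cj$n_voxels)
})

test_that("overlap percentages follow the printed rounding convention", {
  g <- tiny_grid(c(4, 4, 4))
  va <- array(0, g$shape); va[1:10] <- 0.05
  vb <- array(0, g$shape); vb[5:20] <- 0.04
  st <- overlap_stats(make_network(va, g, "imagery"),
    make_network(vb, g, "working_memory"), min_cluster_mm3 = 0)
  expect_equal(st$n_overlap, 6)
  expect_equal(st$pct_of_a, 60.0) # 6 of 10
  # containment gives 100%
  vc <- array(0, g$shape); vc[1:30] <- 0.04
  stc <- overlap_stats(make_network(va, g, "imagery"),
    make_network(vc, g, "working_memory"), min_cluster_mm3 = 0)
  expect_equal(stc$pct_of_a, 100.0)
  # empty denominator is NaN with a warning
  ve <- array(0, g$shape); ve[1] <- 0.01
  empty <- make_network(array(0, g$shape), g, "imagery")
  expect_warning(ste <- overlap_stats(empty, make_network(ve, g), 0), "empty")
  expect_true(is.nan(ste$pct_of_a))
})

test_that("half-away-from-zero rounding matches printed percentages", {
  expect_equal(round_half_up(98.6132 - 0.0132 + 0.05, 1), 98.7)
  expect_equal(round_half_up(2.45, 1), 2.5)
  expect_equal(round_half_up(-2.45, 1), -2.5)
  expect_equal(round_half_up(100 * 6 / 10, 1), 60.0)
})
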