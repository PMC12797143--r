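test_that("a single experiment's null is its within-mask MA histogram", {
  g <- tiny_grid(c(10, 10, 10))
  mask <- brain_mask(g, array(TRUE, g$shape))
  f <- make_foci("a2001", "imagery", 12L, c(0, 0, 0))
  ma <- compute_ma_map(f, g)
  null <- build_null(list(ma), mask, bin_width = 1e-5)
  w <- 1e-5
  v <- ma$values[mask$inside]
  bins <- floor(v / w + 1e-12)
  expected <- as.numeric(rowsum(rep(1 / length(v), length(v)), bins))
  got <- null$prob[null$prob > 0]
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(null$surv[1], 1) # P(ALE >= 0) = 1
  expect_equal(sum(null$prob), 1, tolerance = 1e-9)
})

test_that("the histogram null matches exhaustive enumeration bin for bin", {
  g <- voxel_grid(c(5, 1, 1), voxel_size = 2)
  mask <- brain_mask(g, array(TRUE, g$shape))
  w <- 1e-5
  for (n_exp in 2:3) {
    withr::with_seed(100 + n_exp, {
      mas <- lapply(seq_len(n_exp), function(e) {
        f <- make_foci(paste0("e", e), "imagery", sample(8:25, 1),
          c(stats::runif(1, -4, 4), 0, 0))
        compute_ma_map(f, g)
      })
    })
    null <- build_null(mas, mask, bin_width = w)
    expect_equal(null$method, "exact")
    oracle <- enumerate_null(mas, mask, w)
    expect_equal(length(null$prob), length(oracle))
    expect_equal(null$prob, oracle, tolerance = 1e-12)
  }
})

test_that("sequential binned integration agrees with enumeration at bin scale", {
  g <- voxel_grid(c(5, 1, 1), voxel_size = 2)
  mask <- brain_mask(g, array(TRUE, g$shape))
  w <- 1e-5
  withr::with_seed(11, {
    mas <- lapply(1:3, function(e) {
      f <- make_foci(paste0("e", e), "imagery", sample(8:25, 1),
        c(stats::runif(1, -4, 4), 0, 0))
      compute_ma_map(f, g)
    })
  })
  exact <- build_null(mas, mask, bin_width = w)
  binned <- build_null(mas, mask, bin_width = w, max_exact = 1)
  expect_equal(binned$method, "binned")
  expect_equal(sum(binned$prob), 1, tolerance = 1e-9)
  # coupling bound: each of the three floors lowers a score by < one bin,
  # so binned scores sit within [exact - 3 bins, exact]; the survival
  # curves must therefore bracket each other under a 3-bin shift
  shift <- 3L
  n <- max(length(exact$surv), length(binned$surv))
  se <- c(exact$surv, numeric(n - length(exact$surv)))
  sb <- c(binned$surv, numeric(n - length(binned$surv)))
  expect_true(all(sb <= se + 1e-12))
  idx <- (shift + 1):n
  expect_true(all(sb[idx - shift] >= se[idx] - 1e-12))
})

test_that("p-values are the null tail at the observed score", {
  g <- voxel_grid(c(5, 1, 1), voxel_size = 2)
  mask <- brain_mask(g, array(TRUE, g$shape))
  withr::with_seed(21, {
    mas <- lapply(1:2, function(e) {
      f <- make_foci(paste0("e", e), "imagery", 15L,
        c(stats::runif(1, -4, 4), 0, 0))
      compute_ma_map(f, g)
    })
  })
  w <- 1e-5
  null <- build_null(mas, mask, bin_width = w)
  ale <- compute_ale_map(mas)
  p <- ale_p_values(ale, null, mask)
  oracle <- enumerate_null(mas, mask, w)
  surv_oracle <- rev(cumsum(rev(oracle)))
  for (v in which(mask$inside)) {
    b <- floor(ale$values[v] / w + 1e-12) + 1
    expect_equal(p[v], surv_oracle[b], tolerance = 1e-12)
  }
  # monotone: p never increases with the score
  ord <- order(ale$values[mask$inside])
  expect_true(all(diff(p[mask$inside][ord]) <= 1e-15))
  # zero score means p = 1
  z <- array(0, g$shape)
  pz <- ale_p_values(z, null, mask)
  expect_true(all(pz[mask$inside] == 1))
})

test_that("scores beyond the null's top bin warn and get the smallest tail", {
  g <- voxel_grid(c(5, 1, 1), voxel_size = 2)
  mask <- brain_mask(g, array(TRUE, g$shape))
  f <- make_foci("e1", "imagery", 15L, c(0, 0, 0))
  null <- build_null(list(compute_ma_map(f, g)), mask)
  high <- array(0.9, g$shape)
  expect_warning(p <- ale_p_values(high, null, mask), "top bin")
  expect_true(all(p[mask$inside] > 0))
  expect_equal(unique(p[mask$inside]), min(null$surv[null$surv > 0]))
})

test_that("degenerate null parameters error", {
  g <- voxel_grid(c(5, 1, 1), voxel_size = 2)
  mask <- brain_mask(g, array(TRUE, g$shape))
  f <- make_foci("e1", "imagery", 15L, c(0, 0, 0))
  ma <- compute_ma_map(f, g)
  expect_error(build_null(list(ma), mask, bin_width = 0), "positive")
  expect_error(build_null(list(), mask), "no MA maps")
})
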