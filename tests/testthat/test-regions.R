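box_template <- function(g, name, i, j, k) {
  m <- array(FALSE, g$shape)
  m[i, j, k] <- TRUE
  region_template(m, name, g)
}

test_that("template merging is a voxelwise union", {
  g <- tiny_grid(c(10, 10, 10))
  a <- box_template(g, "BA9", 1:4, 1:4, 1:4)
  b <- box_template(g, "BA46", 3:6, 3:6, 3:6)
  expect_equal(merge_templates(list(a, a), "A")$mask, a$mask)
  disjoint <- merge_templates(list(
    box_template(g, "p1", 1:2, 1:2, 1:2),
    box_template(g, "p2", 8:9, 8:9, 8:9)
  ), "D")
  expect_equal(sum(disjoint$mask), 8 + 8)
  dlpfc <- merge_templates(list(a, b), "DLPFC")
  expect_equal(dlpfc$mask, a$mask | b$mask)
  expect_equal(sum(dlpfc$mask), sum(a$mask) + sum(b$mask) -
    sum(a$mask & b$mask))
  expect_match(dlpfc$source, "BA9")
})

test_that("derived region columns reproduce the printed arithmetic", {
  counts <- tibble::tibble(
    vol_area_mi = 649, vol_area_mi_wm = 640, vol_area_mi_ex = 37
  )
  row <- region_overlap_derive(counts)
  expect_equal(row$pct_wm, 98.6)
  expect_equal(row$pct_ex, 5.7)
  expect_equal(row$diff_overlap, 603)
  expect_equal(row$diff_pct, 92.9)
})

test_that("region rows count triple conjunctions correctly", {
  g <- tiny_grid(c(12, 12, 12))
  withr::with_seed(41, {
    mi <- random_network(g, 300, "imagery")
    ex <- random_network(g, 260, "execution")
    wm <- random_network(g, 320, "working_memory")
  })
  tmpl <- box_template(g, "box", 3:9, 3:9, 3:9)
  row <- region_overlap_row(tmpl, mi, ex, wm)
  # independent set arithmetic
  t_mi <- tmpl$mask & mi$significant
  expect_equal(row$vol_area_mi, sum(t_mi))
  expect_equal(row$vol_area_mi_wm, sum(t_mi & wm$significant))
  expect_equal(row$vol_area_mi_ex, sum(t_mi & ex$significant))
  expect_lte(row$vol_area_mi_wm, row$vol_area_mi)
  expect_lte(row$vol_area_mi_ex, row$vol_area_mi)
  # inclusion-exclusion sanity on the quadruple intersection
  quad <- sum(t_mi & ex$significant & wm$significant)
  expect_gte(quad, row$vol_area_mi_wm + row$vol_area_mi_ex - row$vol_area_mi)
  expect_lte(quad, min(row$vol_area_mi_wm, row$vol_area_mi_ex))
})

test_that("identical comparison networks zero every difference", {
  g <- tiny_grid(c(10, 10, 10))
  withr::with_seed(43, {
    mi <- random_network(g, 100, "imagery")
    ex <- random_network(g, 120, "execution")
  })
  tmpl <- box_template(g, "box", 2:8, 2:8, 2:8)
  row <- region_overlap_row(tmpl, mi, ex, ex)
  expect_equal(row$diff_overlap, 0)
})

test_that("a template disjoint from imagery yields zero counts and NaN pcts", {
  g <- tiny_grid(c(10, 10, 10))
  v <- array(0, g$shape); v[1:20] <- 0.05
  mi <- make_network(v, g, "imagery")
  tmpl <- box_template(g, "far", 9:10, 9:10, 9:10)
  expect_warning(row <- region_overlap_row(tmpl, mi, mi, mi), "empty")
  expect_equal(row$vol_area_mi, 0)
  expect_true(is.nan(row$pct_wm))
})

test_that("the region table covers every template and sorts by difference", {
  g <- tiny_grid(c(12, 12, 12))
  withr::with_seed(47, {
    mi <- random_network(g, 400, "imagery",
      draw = function(n) stats::runif(n))
    ex <- random_network(g, 350, "execution",
      draw = function(n) stats::runif(n))
    wm <- random_network(g, 500, "working_memory",
      draw = function(n) stats::runif(n))
  })
  templates <- lapply(1:6, function(t) {
    box_template(g, paste0("area", t), ((t - 1) %% 3) * 4 + 1:4, 1:12, 1:12)
  })
  full <- region_overlap_table(templates, mi, ex, wm)
  expect_equal(nrow(full), 6)
  expect_true(all(diff(full$diff_overlap) <= 0))
  expect_equal(unique(full$variant), "full")
  # a whole-grid template recovers the network volume
  whole <- region_template(array(TRUE, g$shape), "whole", g)
  expect_equal(region_overlap_row(whole, mi, ex, wm)$vol_area_mi,
    mi$total_voxels)
  # volume matching can only shrink each cell
  vm <- region_overlap_table(templates, mi, ex, wm, volume_matched = TRUE)
  expect_equal(unique(vm$variant), "volume_matched")
  key <- match(vm$area, full$area)
  for (col in c("vol_area_mi", "vol_area_mi_wm", "vol_area_mi_ex")) {
    expect_true(all(vm[[col]] <= full[[col]][key]))
  }
  # mutually exclusive templates cannot overcount the network
  excl <- lapply(1:3, function(t) {
    box_template(g, paste0("sl", t), (t - 1) * 4 + 1:4, 1:12, 1:12)
  })
  tab <- region_overlap_table(excl, mi, ex, wm)
  expect_lte(sum(tab$vol_area_mi), mi$total_voxels)
})
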