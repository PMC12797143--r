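test_that("reading groups foci into experiments and preserves row order", {
  f <- make_foci("kim2012", "imagery", 12L, c(0, 0, 0, 4, 0, 0))
  d <- foci_datasets(f)
  expect_named(d, "imagery")
  expect_equal(nrow(d$imagery), 2)
  expect_equal(unique(d$imagery$study_id), "kim2012")
  expect_equal(d$imagery$x, c(0, 4))
})

test_that("duplicate-paper letter suffixes separate experiments but not papers", {
  f <- dplyr::bind_rows(
    make_foci("smith2010a", "imagery", 10L, c(0, 0, 0)),
    make_foci("smith2010b", "imagery", 14L, c(4, 0, 0))
  )
  s <- dataset_summary(f)
  row <- s[s$paradigm == "imagery", ]
  expect_equal(row$experiments, 2)
  expect_equal(row$papers, 1)
  expect_equal(row$participants, 24)
})

test_that("summary rows sum to the all row, independently recomputed", {
  f <- trio_foci_fixture()
  s <- dataset_summary(f)
  all_row <- s[s$paradigm == "all", ]
  per <- s[s$paradigm != "all", ]
  expect_equal(nrow(per), 3)
  for (col in c("papers", "experiments", "participants", "foci")) {
    expect_equal(all_row[[col]], sum(per[[col]]))
  }
  # independent recomputation straight off the rows
  expect_equal(all_row$foci, nrow(f))
  per_exp <- unique(f[, c("study_id", "n_subjects")])
  expect_equal(all_row$participants, sum(per_exp$n_subjects))
  expect_equal(all_row$experiments, length(unique(f$study_id)))
})

test_that("summary counts are additive over dataset concatenation", {
  a <- make_foci("a2001", "imagery", 10L, c(0, 0, 0))
  b <- make_foci("b2002", "execution", 20L, c(4, 0, 0, 0, 4, 0))
  sa <- dataset_summary(a)
  sb <- dataset_summary(b)
  sab <- dataset_summary(dplyr::bind_rows(a, b))
  for (col in c("papers", "experiments", "participants", "foci")) {
    expect_equal(
      sab[[col]][sab$paradigm == "all"],
      sa[[col]][sa$paradigm == "all"] + sb[[col]][sb$paradigm == "all"]
    )
  }
})

test_that("schema and validation errors name the problem", {
  f <- make_foci("a2001", "imagery", 10L, c(0, 0, 0))
  expect_error(as_ale_foci(f[, setdiff(names(f), "x")]), "missing required")
  bad_n <- f
  bad_n$n_subjects <- 0L
  expect_error(as_ale_foci(bad_n), "n_subjects")
  bad_p <- f
  bad_p$paradigm <- "meditation"
  expect_error(as_ale_foci(bad_p), "paradigm")
  bad_x <- f
  bad_x$x <- NaN
  expect_error(as_ale_foci(bad_x), "finite")
})

test_that("read -> write -> read reproduces a coordinate table row for row", {
  src <- system.file("extdata", "synthetic_example_foci.tsv",
    package = "aleoverlap")
  f1 <- read_foci_table(src)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_foci_table(f1, path)
  f2 <- read_foci_table(path)
  expect_equal(as.data.frame(f2), as.data.frame(f1))
})

test_that("a space-less table takes the declared default space", {
  f <- make_foci("a2001", "imagery", 10L, c(0, 0, 0))
  f$space <- NULL
  out <- as_ale_foci(f, space_default = "Talairach")
  expect_equal(out$space, "Talairach")
})

test_that("Talairach conversion matches the hand-computed matrix product", {
  # inverse of the published ICBM(SPM)->Tal affine applied to the origin,
  # computed independently and frozen
  f <- make_foci("a2001", "imagery", 10L, c(0, 0, 0), space = "Talairach")
  out <- tal2mni(f)
  expect_equal(out$space, "MNI")
  expect_equal(c(out$x, out$y, out$z),
    c(1.03865868, 1.45785175, -4.74800081),
    tolerance = 1e-7
  )
})

test_that("tal2mni is affine and invertible, and a no-op warns on MNI input", {
  a <- c(10, -20, 30)
  b <- c(-14, 6, -8)
  fa <- make_foci("a2001", "imagery", 10L, a, space = "Talairach")
  fb <- make_foci("a2001", "imagery", 10L, b, space = "Talairach")
  fm <- make_foci("a2001", "imagery", 10L, (a + b) / 2, space = "Talairach")
  ta <- tal2mni(fa)
  tb <- tal2mni(fb)
  tm <- tal2mni(fm)
  expect_equal(c(tm$x, tm$y, tm$z),
    (c(ta$x, ta$y, ta$z) + c(tb$x, tb$y, tb$z)) / 2,
    tolerance = 1e-9
  )
  # round trip through the forward matrix
  m <- lancaster_matrix("spm", "mni2tal")
  back <- m %*% c(ta$x, ta$y, ta$z, 1)
  expect_equal(as.numeric(back[1:3]), a, tolerance = 1e-9)
  mni <- make_foci("a2001", "imagery", 10L, a, space = "MNI")
  expect_warning(out <- tal2mni(mni), "no Talairach")
  expect_equal(out$x, mni$x)
})
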