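# Core NCC: the direct per-point form against an independent brute-force
# oracle, the fast surface path against the direct form, and the algebraic
# invariances of normalized correlation.

test_that("ncc_at_point matches the brute-force oracle at every offset", {
  set.seed(101)
  sample <- matrix(runif(144), 12, 12)
  template <- matrix(runif(9), 3, 3)
  for (i in 1:10) for (j in 1:10)
    expect_equal(ncc_at_point(sample, template, i, j),
                 oracle_ncc(sample, template, i, j), tolerance = 1e-9)
})

test_that("perfect and inverted-affine matches give +1 and -1", {
  set.seed(102)
  template <- matrix(runif(25), 5, 5)
  sample <- matrix(runif(100), 10, 10)
  sample[3:7, 4:8] <- template
  expect_equal(ncc_at_point(sample, template, 3, 4), 1.0, tolerance = 1e-12)
  sample[3:7, 4:8] <- -2 * template + 10   # negative affine map of template
  expect_equal(ncc_at_point(sample, template, 3, 4), -1.0, tolerance = 1e-12)
})

test_that("a zero-variance sample window scores 0, not NaN", {
  sample <- matrix(0.5, 8, 8)
  sample[6:8, 6:8] <- matrix(runif(9), 3, 3)
  template <- matrix(runif(9), 3, 3)
  expect_identical(ncc_at_point(sample, template, 1, 1), 0)
  surf <- ncc_surface(sample, template)
  expect_false(anyNA(surf$values))
  expect_identical(surf$values[1, 1], 0)
})

test_that("input validation: offsets, constant templates, oversized templates", {
  sample <- matrix(runif(64), 8, 8)
  template <- matrix(runif(9), 3, 3)
  expect_error(ncc_at_point(sample, template, 0, 1), "out of range")
  expect_error(ncc_at_point(sample, template, 7, 1), "out of range")
  expect_error(ncc_at_point(sample, matrix(1, 3, 3), 1, 1), "onstant template")
  expect_error(ncc_surface(matrix(runif(4), 2, 2), template), "larger than")
})

test_that("fast surface equals the direct form on random sample/template pairs", {
  set.seed(103)
  for (rep in 1:50) {
    M <- sample(8:32, 1); N <- sample(8:32, 1)
    K <- sample(2:7, 1); L <- sample(2:7, 1)
    s <- matrix(runif(M * N), M, N)
    tm <- matrix(runif(K * L), K, L)
    surf <- ncc_surface(s, tm)
    expect_identical(dim(surf$values), c(M - K + 1L, N - L + 1L))
    # every evaluated value within range
    expect_true(all(surf$values >= -1 - 1e-9 & surf$values <= 1 + 1e-9))
    # spot-check 12 random anchors against the direct per-point form
    ii <- sample(M - K + 1L, 12L, replace = TRUE)
    jj <- sample(N - L + 1L, 12L, replace = TRUE)
    for (p in 1:12)
      expect_equal(surf$values[ii[p], jj[p]],
                   ncc_at_point(s, tm, ii[p], jj[p]), tolerance = 1e-6)
  }
})

test_that("NCC is invariant to positive affine intensity maps of the sample", {
  set.seed(104)
  s <- matrix(runif(400), 20, 20)
  tm <- matrix(runif(16), 4, 4)
  s1 <- ncc_surface(s, tm)$values
  s2 <- ncc_surface(3.7 * s + 11, tm)$values
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("NCC is symmetric when sample and template have equal shape", {
  set.seed(105)
  a <- matrix(runif(36), 6, 6)
  b <- matrix(runif(36), 6, 6)
  expect_equal(ncc_at_point(a, b, 1, 1), ncc_at_point(b, a, 1, 1),
               tolerance = 1e-12)
})

test_that("skip patterns restrict evaluation to their lattice, values unchanged", {
  set.seed(106)
  s <- matrix(runif(400), 20, 20)
  tm <- matrix(runif(9), 3, 3)
  full <- ncc_surface(s, tm)
  # a mask evaluating everything is the identity
  all_on <- skip_pattern(matrix(TRUE, 1, 1))
  expect_equal(ncc_surface(s, tm, all_on)$values, full$values)
  # stride-2 lattice: evaluated flags exactly on the lattice, values agree
  p3 <- preset_pattern(3)
  sparse <- ncc_surface(s, tm, p3)
  lattice <- outer(seq_len(18) %% 2 == 1, seq_len(18) %% 2 == 1, `&`)
  expect_identical(unname(sparse$evaluated), lattice)
  expect_equal(sparse$values[sparse$evaluated],
               full$values[sparse$evaluated], tolerance = 1e-12)
  expect_true(all(is.na(sparse$values[!sparse$evaluated])))
})

test_that("max_over_library is the pointwise maximum with argmax attribution", {
  set.seed(107)
  s <- matrix(runif(225), 15, 15)
  tms <- lapply(1:3, function(k) matrix(runif(9), 3, 3))
  lib <- template_library(tms, ids = c("a", "b", "c"))
  mx <- max_over_library(s, lib)
  per <- lapply(tms, function(tm) ncc_surface(s, tm)$values)
  expect_equal(mx$values, pmax(per[[1]], per[[2]], per[[3]]), tolerance = 1e-12)
  # argmax agrees with which template attains the max
  for (q in sample(length(mx$values), 20)) {
    vals <- c(per[[1]][q], per[[2]][q], per[[3]][q])
    expect_equal(vals[mx$argmax[q]], max(vals))
  }
  # single template and exact-duplicate libraries
  one <- max_over_library(s, template_library(tms[1]))
  expect_equal(one$values, per[[1]])
  dup <- max_over_library(s, template_library(list(tms[[1]], tms[[1]])))
  expect_equal(dup$values, per[[1]], tolerance = 1e-12)
})

test_that("library validation: empty and mixed-shape libraries are rejected", {
  expect_error(template_library(list()), "non-empty")
  expect_error(template_library(list(matrix(runif(9), 3, 3),
                                     matrix(runif(16), 4, 4))),
               "share one K x L shape")
  expect_error(template_library(list(matrix(runif(9), 3, 3)), ids = c("a", "b")),
               "unique")
})

test_that("surfaces export to a flat (i, j, value, evaluated) table", {
  set.seed(108)
  s <- matrix(runif(100), 10, 10)
  tm <- matrix(runif(9), 3, 3)
  surf <- ncc_surface(s, tm, preset_pattern(1))
  df <- as.data.frame(surf)
  expect_identical(nrow(df), 64L)
  expect_named(df, c("i", "j", "value", "evaluated"))
  k <- which(df$i == 3 & df$j == 5)
  expect_equal(df$value[k], surf$values[3, 5])
  expect_identical(df$evaluated[k], surf$evaluated[3, 5])
})
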