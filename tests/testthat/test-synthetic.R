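# The synthetic scene generator and derived template libraries.

test_that("scene generation is bit-identical under a fixed seed", {
  a <- generate_scene(n_cells = 15, image_shape = c(100, 120), seed = 42)
  b <- generate_scene(n_cells = 15, image_shape = c(100, 120), seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- generate_scene(n_cells = 15, image_shape = c(100, 120), seed = 43)
  expect_false(identical(a$image, c$image))
})

test_that("an empty scene yields a zero count at any strong threshold", {
  sc <- generate_scene(n_cells = 0, image_shape = c(100, 120), seed = 1)
  expect_identical(nrow(sc$truth), 0L)
  lib <- template_library(lapply(1:4, ideal_template))
  expect_identical(count_cells(sc, lib, 0.60)$count, 0L)
  expect_identical(count_cells(sc, lib, 0.8)$count, 0L)
})

test_that("placement respects separation and border margins", {
  for (s in 1:3) {
    sc <- generate_scene(n_cells = 30, image_shape = c(200, 250),
                         min_separation = 16, seed = s)
    tr <- sc$truth
    expect_identical(nrow(tr), 30L)
    m <- sc$params$margin
    expect_true(all(tr$row >= m & tr$row <= 200 - m))
    expect_true(all(tr$col >= m & tr$col <= 250 - m))
    d <- as.matrix(dist(tr[, c("row", "col")], method = "maximum"))
    diag(d) <- Inf
    expect_gte(min(d), 16)
  }
  expect_error(generate_scene(n_cells = 500, image_shape = c(100, 100),
                              min_separation = 20),
               "infeasible packing")
})

test_that("planted-shape templates correlate strongly at true centers", {
  half <- 6
  for (s in 1:3) {
    sc <- generate_scene(seed = s)
    vals <- vapply(seq_len(nrow(sc$truth)), function(i) {
      tm <- ideal_template(sc$truth$shape_id[i])
      ncc_at_point(sc$image, tm, sc$truth$row[i] - half, sc$truth$col[i] - half)
    }, numeric(1))
    expect_gt(median(vals), 0.85)
    expect_gte(mean(vals > 0.8), 0.95)
    expect_gt(min(vals), 0.7)
  }
})

test_that("raising the noise never increases the mean center correlation", {
  half <- 6
  mean_ncc <- function(sigma, seed) {
    sc <- generate_scene(n_cells = 20, image_shape = c(150, 200),
                         min_separation = 18, noise_sd = sigma, seed = seed)
    mean(vapply(seq_len(nrow(sc$truth)), function(i) {
      tm <- ideal_template(sc$truth$shape_id[i])
      ncc_at_point(sc$image, tm, sc$truth$row[i] - half, sc$truth$col[i] - half)
    }, numeric(1)))
  }
  for (seed in 1:2) {
    curve <- vapply(c(0.01, 0.03, 0.06, 0.1), mean_ncc, numeric(1), seed = seed)
    expect_true(all(diff(curve) < 0))
  }
})

test_that("derived libraries contain the requested duplicates and crops", {
  sc <- generate_scene(n_cells = 20, image_shape = c(200, 250),
                       min_separation = 18, seed = 12)
  # half duplicates: exactly 5 identical pairs among 10 entries
  lib <- derive_library(sc, n_templates = 10, duplicate_fraction = 0.5,
                        jitter_fraction = 0, seed = 3)
  sim <- template_similarity(lib)
  pairs <- sum(sim[upper.tri(sim)] > 1 - 1e-9)
  expect_identical(pairs, 5L)
  expect_identical(sum(lib$manifest$kind == "duplicate"), 5L)

  # no duplicates, no jitter: every template is an exact cell-centred crop
  lib0 <- derive_library(sc, n_templates = 6, duplicate_fraction = 0,
                         jitter_fraction = 0, seed = 4)
  half <- 6
  for (k in seq_along(lib0$templates)) {
    man <- lib0$manifest[k, ]
    expect_equal(ncc_at_point(sc$image, lib0$templates[[k]],
                              man$row - half, man$col - half),
                 1.0, tolerance = 1e-9)
  }
  expect_error(derive_library(sc, n_templates = 50, duplicate_fraction = 0,
                              jitter_fraction = 0),
               "distinct cells")
})

test_that("exact duplicates are flagged with zero influence on the fixture", {
  sc <- tiny_scene(seed = 13)
  lib <- derive_library(sc, n_templates = 12, seed = 5)
  inf <- suppressWarnings(influence(sc, lib, 0.67))
  man <- lib$manifest
  dup <- man[man$kind == "duplicate", ]
  infl <- setNames(inf$table$influence_percent, inf$table$id)
  ord <- setNames(seq_len(nrow(man)), man$id)
  for (r in seq_len(nrow(dup))) {
    later <- if (ord[dup$id[r]] > ord[dup$source_id[r]]) dup$id[r]
             else dup$source_id[r]
    expect_identical(unname(infl[later]), 0)
  }
})

test_that("ground truth is recovered at the working threshold across seeds", {
  counts <- vapply(1:10, function(s) {
    sc <- generate_scene(seed = s)
    lib <- derive_library(sc, seed = s)
    suppressWarnings(count_cells(sc, lib, 0.67)$count)
  }, integer(1))
  expect_lte(mean(abs(counts - 60) / 60), 0.02)
  expect_true(all(abs(counts - 60) / 60 <= 0.05))
})
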