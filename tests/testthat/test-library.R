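# Template similarity, influence attribution and loss-budgeted pruning.

test_that("template similarity is NCC at full overlap", {
  set.seed(301)
  tms <- lapply(1:5, function(k) matrix(runif(25), 5, 5))
  lib <- template_library(tms)
  sim <- template_similarity(lib)
  expect_equal(unname(diag(sim)), rep(1, 5))
  expect_equal(sim, t(sim))
  for (a in 1:4) for (b in (a + 1):5)
    expect_equal(sim[a, b], oracle_ncc(tms[[a]], tms[[b]], 1, 1),
                 tolerance = 1e-9)
  # a negative affine transform is perfectly anti-correlated
  lib2 <- template_library(list(tms[[1]], -3 * tms[[1]] + 2))
  expect_equal(template_similarity(lib2)[1, 2], -1, tolerance = 1e-12)
})

test_that("a single-template library carries all influence; a duplicate none", {
  sc <- tiny_scene(seed = 6)
  A <- ideal_template(1)
  one <- suppressWarnings(influence(sc, template_library(list(A)), 0.67))
  expect_equal(one$table$influence_percent, 100)
  expect_gt(one$total_cells, 0)
  dup <- suppressWarnings(
    influence(sc, template_library(list(A, A), ids = c("A", "A_copy")), 0.67))
  expect_identical(dup$table$attributed_cells[2], 0L)
  expect_equal(dup$table$influence_percent[2], 0)
  expect_equal(sum(dup$table$influence_percent), 100, tolerance = 1e-6)
  expect_identical(sum(dup$table$attributed_cells), dup$total_cells)
})

test_that("influence matches independent first-detector bookkeeping", {
  # two well-separated planted shapes; library holds one template per shape
  # plus a near-duplicate of the first
  sc <- generate_scene(n_cells = 12, image_shape = c(140, 180),
                       min_separation = 24, n_shapes = 2, seed = 7)
  A <- ideal_template(1); B <- ideal_template(2)
  Aj <- A[c(2:13, 13), ]  # one-pixel shifted near-duplicate
  lib <- template_library(list(A, B, Aj), ids = c("A", "B", "A_jit"))
  rep_ <- suppressWarnings(influence(sc, lib, 0.67))

  # oracle: detect with each template separately, then attribute clusters
  # sequentially with Chebyshev-2 centroid overlap
  cents <- lapply(lib$templates, function(tm) {
    cl <- suppressWarnings(
      cluster_and_count(mark_points(ncc_surface(sc$image, tm), 0.67)))
    as.matrix(cl$clusters[, c("centroid_row", "centroid_col")])
  })
  accepted <- matrix(numeric(0), 0, 2)
  counts <- integer(3)
  for (k in 1:3) {
    if (nrow(cents[[k]])) for (r in seq_len(nrow(cents[[k]]))) {
      p <- cents[[k]][r, ]
      if (nrow(accepted) &&
          any(pmax(abs(accepted[, 1] - p[1]), abs(accepted[, 2] - p[2])) <= 2))
        next
      counts[k] <- counts[k] + 1L
      accepted <- rbind(accepted, p)
    }
  }
  expect_identical(rep_$table$attributed_cells, counts)
  expect_identical(rep_$total_cells, sum(counts))
  # both shapes contribute; the near-duplicate is (almost) fully shadowed
  expect_gt(rep_$table$attributed_cells[1], 0)
  expect_gt(rep_$table$attributed_cells[2], 0)
  expect_lt(rep_$table$influence_percent[3], 10)
})

test_that("zero-influence removal leaves the count unchanged (budget 0)", {
  sc <- tiny_scene(seed = 8)
  A <- ideal_template(1); B <- ideal_template(2)
  lib <- template_library(list(A, B, A, B), ids = c("A", "B", "Adup", "Bdup"))
  base <- suppressWarnings(count_cells(sc, lib, 0.67))$count
  pr <- suppressWarnings(prune_library(sc, lib, 0.67, loss_budget_percent = 0))
  expect_true(all(c("Adup", "Bdup") %in% pr$removal_log$id))
  re <- suppressWarnings(count_cells(sc, pr$pruned, 0.67))$count
  expect_identical(re, base)
  expect_equal(pr$pruned_count, re)
  zl <- pr$removal_log[pr$removal_log$stage == "zero-influence", ]
  expect_true(all(zl$loss_after_percent == 0))
})

test_that("pruning without removable templates keeps sole detectors", {
  # each template is the sole detector of its own shape's cells
  sc <- generate_scene(n_cells = 10, image_shape = c(120, 160),
                       min_separation = 22, n_shapes = 2, seed = 9)
  lib <- template_library(list(ideal_template(1), ideal_template(2)),
                          ids = c("A", "B"))
  inf <- suppressWarnings(influence(sc, lib, 0.67))
  expect_true(all(inf$table$attributed_cells > 0))  # each is a sole detector
  pr <- suppressWarnings(prune_library(sc, lib, 0.67, loss_budget_percent = 0))
  expect_identical(length(pr$pruned), 2L)
  expect_identical(nrow(pr$removal_log), 0L)
})

test_that("greedy pruning respects the loss budget, verified by recount", {
  scs <- lapply(1:2, function(s) tiny_scene(seed = s, n_cells = 10))
  lib <- derive_library(scs[[1]], n_templates = 12, seed = 2)
  base <- sum(vapply(scs, function(s)
    suppressWarnings(count_cells(s, lib, 0.67))$count, integer(1)))
  pr <- suppressWarnings(prune_library(scs, lib, 0.67, loss_budget_percent = 8.5))
  recount <- sum(vapply(scs, function(s)
    suppressWarnings(count_cells(s, pr$pruned, 0.67))$count, integer(1)))
  expect_equal(pr$pruned_count, recount)
  expect_equal(pr$baseline_count, base)
  expect_lte(pr$projected_loss_percent, 8.5)
  expect_lt(length(pr$pruned), length(lib))
  # removal order and realized losses are logged
  expect_identical(pr$removal_log$step, seq_len(nrow(pr$removal_log)))
  # the pruner refuses to empty the library
  pr_all <- suppressWarnings(prune_library(scs, lib, 0.67, 100))
  expect_gte(length(pr_all$pruned), 1L)
})

test_that("per-template evaluation count is linear in library size", {
  sc <- matrix(runif(40 * 50), 40, 50)
  tms <- lapply(1:6, function(k) matrix(runif(25), 5, 5))
  offsets <- (40 - 5 + 1) * (50 - 5 + 1)
  for (n in c(1, 3, 6)) {
    mx <- max_over_library(sc, template_library(tms[seq_len(n)]))
    expect_identical(mx$eval_count, offsets * n)
  }
  # shrinking a library cuts evaluations by exactly the size ratio
  ev150 <- offsets * 150
  ev20 <- offsets * 20
  expect_identical(round(100 * (1 - ev20 / ev150)), 87)
})
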