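# Periodic skip patterns for sparse NCC evaluation, and the analytic
# cluster detection-probability model that quantifies their accuracy cost.

#' Create a periodic evaluation mask
#'
#' A skip pattern is a small logical matrix tiled over the whole anchor grid
#' (anchored at (1, 1)); `TRUE` entries are evaluated, `FALSE` entries are
#' skipped. Skipped anchors are treated as unmarked by the detector.
#'
#' @param mask logical (or 0/1) matrix with at least one `TRUE`.
#' @param name optional label used in printing and reports.
#' @return object of class `skip_pattern` with fields `mask`, `period`
#'   (rows, cols), `density` (evaluated fraction) and `name`.
#' @examples
#' skip_pattern(matrix(c(TRUE, FALSE), 2, 1), "alternate rows")
#' @export
skip_pattern <- function(mask, name = NULL) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask) || any(is.na(mask)))
    stop("mask must be a logical matrix without NA", call. = FALSE)
  if (!any(mask))
    stop("mask must evaluate at least one point per period", call. = FALSE)
  structure(
    list(mask = mask, period = dim(mask),
         density = sum(mask) / length(mask),
         name = if (is.null(name)) "custom" else name),
    class = "skip_pattern")
}

#' @export
print.skip_pattern <- function(x, ...) {
  cat("Skip pattern '", x$name, "': period ", x$period[1L], "x", x$period[2L],
      sprintf(", density %d/%d, runtime reduction %d%%\n",
              sum(x$mask), length(x$mask), runtime_reduction(x)), sep = "")
  invisible(x)
}

#' The four preset heuristic evaluation patterns
#'
#' Reconstructs the four periodic masks used to thin sliding-window NCC
#' evaluation. The geometries are fixed by requiring that each pattern's
#' (runtime reduction, best-case skipped points in a 3x3 cluster) pair be
#' (50%, 3), (50%, 4), (75%, 5) and (89%, 8) respectively:
#'
#' * Pattern 1 - evaluate alternate rows (period 2x1, density 1/2);
#' * Pattern 2 - checkerboard (period 2x2, density 1/2);
#' * Pattern 3 - every other point both horizontally and vertically
#'   (stride 2 in both axes, density 1/4);
#' * Pattern 4 - one point per 3x3 tile (stride 3, density 1/9).
#'
#' Custom masks can be supplied anywhere a pattern is accepted via
#' [skip_pattern()] or [read_pattern()].
#'
#' @param k preset index, 1 to 4.
#' @return a [skip_pattern()].
#' @examples
#' runtime_reduction(preset_pattern(4))  # 89
#' @export
preset_pattern <- function(k) {
  if (length(k) != 1L || !(k %in% 1:4))
    stop("preset pattern index must be 1, 2, 3 or 4", call. = FALSE)
  mask <- switch(k,
    matrix(c(TRUE, FALSE), 2L, 1L),                       # alternate rows
    matrix(c(TRUE, FALSE, FALSE, TRUE), 2L, 2L),          # checkerboard
    matrix(c(TRUE, FALSE, FALSE, FALSE), 2L, 2L),         # stride 2 x 2
    {m <- matrix(FALSE, 3L, 3L); m[1L, 1L] <- TRUE; m})   # stride 3 x 3
  skip_pattern(mask, paste0("P", k))
}

#' Tile a pattern mask over an anchor grid
#'
#' @param pattern a [skip_pattern()].
#' @param dim integer c(rows, cols) of the target grid.
#' @return logical matrix of the requested size, `TRUE` where evaluated.
#' @export
tile_pattern <- function(pattern, dim) {
  stopifnot(inherits(pattern, "skip_pattern"))
  p <- pattern$period
  ri <- ((seq_len(dim[1L]) - 1L) %% p[1L]) + 1L
  ci <- ((seq_len(dim[2L]) - 1L) %% p[2L]) + 1L
  pattern$mask[ri, ci, drop = FALSE]
}

#' Runtime reduction of a skip pattern
#'
#' Fraction of sliding-window NCC evaluations a pattern avoids, computed by
#' exact lattice counting over one period: `100 * (1 - density)`, rounded to
#' the nearest integer percent.
#'
#' @param pattern a [skip_pattern()].
#' @return integer percent.
#' @export
runtime_reduction <- function(pattern) {
  stopifnot(inherits(pattern, "skip_pattern"))
  n <- length(pattern$mask)
  as.integer(round(100 * (n - sum(pattern$mask)) / n))
}

#' Skipped points inside a cluster window
#'
#' For a cluster of shape m x n, the number of anchor points a pattern skips
#' depends on where the cluster falls relative to the pattern period. This
#' brute-forces all period alignments and returns the best and worst case.
#'
#' @param pattern a [skip_pattern()].
#' @param cluster_shape integer c(m, n), e.g. `c(3, 3)`.
#' @return list with `s_min` and `s_max`, the minimum and maximum skipped
#'   points over all alignments.
#' @examples
#' skipped_in_cluster(preset_pattern(3), c(3, 3))$s_min  # 5
#' @export
skipped_in_cluster <- function(pattern, cluster_shape) {
  stopifnot(inherits(pattern, "skip_pattern"))
  m <- as.integer(cluster_shape[1L]); n <- as.integer(cluster_shape[2L])
  stopifnot(m >= 1L, n >= 1L)
  p <- pattern$period
  big <- tile_pattern(pattern, c(p[1L] + m - 1L, p[2L] + n - 1L))
  s <- integer(0)
  for (a in seq_len(p[1L])) {
    for (b in seq_len(p[2L])) {
      win <- big[a:(a + m - 1L), b:(b + n - 1L), drop = FALSE]
      s <- c(s, sum(!win))
    }
  }
  list(s_min = min(s), s_max = max(s))
}

#' Analytic cluster detection probability under a skip pattern
#'
#' A detected cell appears as a cluster of t marked-capable anchor points,
#' each of which (in the critical region near the threshold) exceeds the
#' threshold independently with probability `p_mark`. If a pattern skips s
#' of the t points, the probability that the sparse detector still marks at
#' least one point, conditional on the full detector having marked at least
#' one, is
#' \deqn{P = \frac{1 - (1-p)^{t-s}}{1 - (1-p)^t}}
#' with `t - s` evaluated points in the numerator. At s = 0 this is exactly 1.
#'
#' @param p_mark per-point mark probability, in (0, 1).
#' @param t total points in the cluster (e.g. 9 for a 3x3 cluster).
#' @param s skipped points in the cluster, `0 <= s < t`.
#' @return detection probability in (0, 1\].
#' @examples
#' detection_probability(0.5, 9, 3)  # 0.986...
#' @export
detection_probability <- function(p_mark, t, s) {
  if (!is.numeric(p_mark) || any(p_mark <= 0) || any(p_mark >= 1))
    stop("p_mark must lie strictly inside (0, 1)", call. = FALSE)
  if (any(s < 0) || any(s >= t))
    stop("skipped points s must satisfy 0 <= s < t", call. = FALSE)
  q <- 1 - p_mark
  (1 - q^(t - s)) / (1 - q^t)
}

#' Monte-Carlo validation of the detection-probability model
#'
#' Draws `reps` clusters of t independent Bernoulli(`p_mark`) marks, erases
#' the marks at s skipped points, and returns the fraction of clusters with
#' at least one surviving mark among those whose full set of t points
#' contained at least one mark (the conditioning event of the closed form).
#'
#' @inheritParams detection_probability
#' @param reps number of simulated clusters.
#' @param seed optional integer seed for reproducibility.
#' @return list with `p_hat` (empirical conditional probability),
#'   `n_conditioned` (clusters satisfying the conditioning event) and `se`
#'   (binomial standard error of `p_hat`).
#' @export
simulate_detection <- function(p_mark, t, s, reps, seed = NULL) {
  stopifnot(reps >= 1)
  if (p_mark <= 0 || p_mark >= 1)
    stop("p_mark must lie strictly inside (0, 1)", call. = FALSE)
  if (s < 0 || s >= t)
    stop("skipped points s must satisfy 0 <= s < t", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  marks <- matrix(stats::runif(reps * t) < p_mark, nrow = reps)
  any_org <- rowSums(marks) > 0
  # marks are iid so which s points are erased is immaterial; keep the first t-s
  surv <- marks[, seq_len(t - s), drop = FALSE]
  any_surv <- rowSums(surv) > 0
  n <- sum(any_org)
  p_hat <- if (n) sum(any_surv & any_org) / n else NA_real_
  list(p_hat = p_hat, n_conditioned = n,
       se = if (n) sqrt(p_hat * (1 - p_hat) / n) else NA_real_)
}

#' Summary table of the preset patterns
#'
#' Reports, for each preset (or supplied) pattern: runtime reduction,
#' best/worst-case skipped points within a cluster, and the analytic
#' detection probability at the best-case alignment.
#'
#' @param patterns list of [skip_pattern()]s; defaults to the four presets.
#' @param p_mark per-point mark probability for the critical region.
#' @param cluster_shape cluster extent, default 3x3.
#' @return data.frame with one row per pattern.
#' @export
pattern_table <- function(patterns = lapply(1:4, preset_pattern),
                          p_mark = 0.5, cluster_shape = c(3, 3)) {
  t_tot <- prod(cluster_shape)
  rows <- lapply(patterns, function(p) {
    s <- skipped_in_cluster(p, cluster_shape)
    data.frame(
      pattern = p$name,
      runtime_reduction_pct = runtime_reduction(p),
      skipped_points = s$s_min,
      skipped_points_worst = s$s_max,
      total_points = t_tot,
      detection_probability_pct =
        round(100 * detection_probability(p_mark, t_tot, s$s_min), 1))
  })
  do.call(rbind, rows)
}

#' Read a custom pattern mask from a text grid
#'
#' The file holds a whitespace-separated grid of 0/1 values, one period row
#' per line; 1 marks an evaluated anchor.
#'
#' @param path file path.
#' @param name optional pattern label (defaults to the file name).
#' @return a [skip_pattern()].
#' @export
read_pattern <- function(path, name = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  skip_pattern(m, if (is.null(name)) basename(path) else name)
}
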