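# Core normalized cross-correlation (NCC) machinery: a direct per-point
# reference implementation and a fast running-sum surface evaluator.

#' Validate a sample image matrix
#'
#' Sample images are plain numeric matrices (rows x cols, top-left origin)
#' of finite intensities in arbitrary units.
#'
#' @param sample numeric matrix.
#' @return the matrix, invisibly, after validation.
#' @keywords internal
check_sample_image <- function(sample) {
  if (!is.matrix(sample) || !is.numeric(sample))
    stop("sample image must be a numeric matrix", call. = FALSE)
  if (nrow(sample) < 1L || ncol(sample) < 1L)
    stop("sample image must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(sample)))
    stop("sample image contains non-finite intensities", call. = FALSE)
  invisible(sample)
}

check_template <- function(template) {
  if (!is.matrix(template) || !is.numeric(template))
    stop("template must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(template)))
    stop("template contains non-finite intensities", call. = FALSE)
  if (stats::var(as.vector(template)) <= 0 || length(template) < 2L)
    stop("constant template: NCC is undefined for a template with zero pixel variance",
         call. = FALSE)
  invisible(template)
}

#' Normalized cross-correlation at a single offset (reference implementation)
#'
#' Computes the NCC value R(i, j) between a K x L template and the K x L
#' window of the sample image whose top-left pixel is at (i, j), by direct
#' double summation:
#' \deqn{R(i,j) = \frac{\sum_{x,y} (\omega(x,y)-\bar\omega)\,(f(x+i-1,y+j-1)-\bar f_{ij})}
#'   {\sqrt{\sum_{x,y}(\omega(x,y)-\bar\omega)^2 \sum_{x,y}(f(x+i-1,y+j-1)-\bar f_{ij})^2}}}
#' where \eqn{\omega} is the template, \eqn{f} the sample, and the bars are
#' per-window means. Offsets are 1-based (row, col) anchors of the template's
#' top-left corner, so valid anchors satisfy \eqn{1 \le i \le M-K+1},
#' \eqn{1 \le j \le N-L+1}.
#'
#' This direct form is deliberately simple; it is the testing oracle for the
#' fast surface evaluator in [ncc_surface()].
#'
#' If the sample window has zero intensity variance the correlation is
#' undefined; by convention the function returns 0 (maximally irrelevant),
#' never NaN.
#'
#' @param sample numeric matrix, M x N sample image.
#' @param template numeric matrix, K x L cell patch with positive variance.
#' @param i,j 1-based row/column anchor of the window.
#' @return a single NCC value in \[-1, 1\].
#' @examples
#' img <- matrix(runif(100), 10, 10)
#' ncc_at_point(img, img[3:5, 4:6], 3, 4)  # exact self-match: 1
#' @export
ncc_at_point <- function(sample, template, i, j) {
  check_sample_image(sample)
  check_template(template)
  M <- nrow(sample); N <- ncol(sample)
  K <- nrow(template); L <- ncol(template)
  if (K > M || L > N)
    stop("template (", K, "x", L, ") larger than sample (", M, "x", N, ")",
         call. = FALSE)
  if (length(i) != 1L || length(j) != 1L || i < 1L || j < 1L ||
      i > M - K + 1L || j > N - L + 1L)
    stop("offset (", i, ", ", j, ") out of range for a ", K, "x", L,
         " template on a ", M, "x", N, " image", call. = FALSE)
  win <- sample[i:(i + K - 1L), j:(j + L - 1L), drop = FALSE]
  wd <- template - mean(template)
  fd <- win - mean(win)
  den <- sqrt(sum(wd^2) * sum(fd^2))
  if (den <= .zero_var_tol(win)) return(0)
  sum(wd * fd) / den
}

# Threshold below which a window's deviation energy counts as zero variance.
# Scaled to the window's magnitude so it tracks the cancellation error of the
# running-sum tables.
.zero_var_tol <- function(win) {
  1e-12 * (sum(win^2) + 1)
}

#' Full NCC correlation surface for one template
#'
#' Evaluates R(i, j) for every valid anchor, producing an
#' (M-K+1) x (N-L+1) surface. The implementation uses summed-area tables for
#' the per-window mean and deviation energy plus a shift-and-accumulate
#' cross term, all in double precision; it agrees with [ncc_at_point()] to
#' better than 1e-6 everywhere.
#'
#' An optional periodic [skip_pattern()] suppresses evaluation off its
#' lattice: suppressed anchors carry `evaluated = FALSE` and `NA` values.
#'
#' @inheritParams ncc_at_point
#' @param pattern optional [skip_pattern()]; `NULL` evaluates every anchor.
#' @return an object of class `ncc_surface`: list with `values`
#'   ((M-K+1) x (N-L+1) matrix, `NA` where skipped), `evaluated` (logical
#'   matrix), `template_shape`, and `eval_count` (number of evaluated
#'   anchors).
#' @seealso [max_over_library()] for the pointwise maximum over a library.
#' @export
ncc_surface <- function(sample, template, pattern = NULL) {
  check_sample_image(sample)
  check_template(template)
  M <- nrow(sample); N <- ncol(sample)
  K <- nrow(template); L <- ncol(template)
  if (K > M || L > N)
    stop("template (", K, "x", L, ") larger than sample (", M, "x", N, ")",
         call. = FALSE)
  P <- M - K + 1L; Q <- N - L + 1L

  wd <- template - mean(template)
  tss_t <- sum(wd^2)

  # summed-area tables with a zero border row/col
  sat  <- .sat(sample)
  sat2 <- .sat(sample * sample)
  win_sum  <- .window_sum(sat,  K, L)
  win_sum2 <- .window_sum(sat2, K, L)
  win_tss <- pmax(win_sum2 - win_sum * win_sum / (K * L), 0)

  # cross term: sum_{x,y} wd[x,y] * f[x+i-1, y+j-1]; since sum(wd) = 0 this
  # already equals the mean-centred numerator
  cross <- matrix(0, P, Q)
  for (x in seq_len(K)) {
    for (y in seq_len(L)) {
      w <- wd[x, y]
      if (w != 0)
        cross <- cross + w * sample[x:(x + P - 1L), y:(y + Q - 1L), drop = FALSE]
    }
  }

  den <- sqrt(win_tss * tss_t)
  zero <- win_tss <= 1e-12 * (win_sum2 + 1)
  values <- matrix(0, P, Q)
  ok <- !zero
  values[ok] <- cross[ok] / den[ok]
  values[values > 1] <- 1
  values[values < -1] <- -1

  evaluated <- matrix(TRUE, P, Q)
  if (!is.null(pattern)) {
    evaluated <- tile_pattern(pattern, c(P, Q))
    values[!evaluated] <- NA_real_
  }
  new_ncc_surface(values, evaluated, c(K, L))
}

.sat <- function(x) {
  s <- apply(x, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

.window_sum <- function(sat, K, L) {
  M <- nrow(sat) - 1L; N <- ncol(sat) - 1L
  P <- M - K + 1L; Q <- N - L + 1L
  ri <- seq_len(P); ci <- seq_len(Q)
  sat[ri + K, ci + L, drop = FALSE] - sat[ri, ci + L, drop = FALSE] -
    sat[ri + K, ci, drop = FALSE] + sat[ri, ci, drop = FALSE]
}

new_ncc_surface <- function(values, evaluated, template_shape,
                            argmax = NULL, template_ids = NULL,
                            eval_count = sum(evaluated)) {
  structure(
    list(values = values, evaluated = evaluated,
         template_shape = as.integer(template_shape),
         argmax = argmax, template_ids = template_ids,
         eval_count = as.numeric(eval_count)),
    class = "ncc_surface")
}

#' @export
print.ncc_surface <- function(x, ...) {
  d <- dim(x$values)
  cat("NCC surface: ", d[1L], " x ", d[2L], " anchors (template ",
      x$template_shape[1L], "x", x$template_shape[2L], ")\n", sep = "")
  cat("  evaluated: ", sum(x$evaluated), " of ", length(x$evaluated),
      sprintf(" (%.1f%%)\n", 100 * mean(x$evaluated)), sep = "")
  v <- x$values[x$evaluated]
  if (length(v))
    cat(sprintf("  value range: [%.4f, %.4f]\n", min(v), max(v)))
  if (!is.null(x$template_ids))
    cat("  max over ", length(x$template_ids), " templates\n", sep = "")
  invisible(x)
}

#' @export
dim.ncc_surface <- function(x) dim(x$values)

#' Pointwise maximum NCC surface over a template library
#'
#' Computes one correlation surface per library template and takes the
#' pointwise maximum, recording for every anchor which template achieved it.
#' A point is later counted as a cell when this maximum exceeds the
#' detection threshold. All templates must share one K x L shape.
#'
#' @inheritParams ncc_surface
#' @param library a [template_library()].
#' @return an `ncc_surface` whose `argmax` field holds, per anchor, the
#'   index (into `library`) of the maximizing template, and whose
#'   `eval_count` is (evaluated anchors) x (library size) - the evaluation
#'   ledger used for runtime-reduction accounting.
#' @export
max_over_library <- function(sample, library, pattern = NULL) {
  library <- as_template_library(library)
  if (length(library$templates) == 0L)
    stop("empty template library", call. = FALSE)
  stack <- ncc_stack(sample, library, pattern)
  max_of_stack(stack, library, pattern)
}

# Per-template surfaces as a list of value matrices (shared by influence
# scoring and pruning, which need each template's surface separately).
ncc_stack <- function(sample, library, pattern = NULL) {
  library <- as_template_library(library)
  lapply(library$templates, function(tm) ncc_surface(sample, tm, pattern))
}

# Pointwise max + argmax over a subset of a cached stack.
max_of_stack <- function(stack, library, pattern = NULL, subset = NULL) {
  if (is.null(subset)) subset <- seq_along(stack)
  if (length(subset) == 0L) stop("empty template library", call. = FALSE)
  first <- stack[[subset[1L]]]
  best <- first$values
  # argmax stores positions within the (possibly subset) library ordering
  arg <- matrix(1L, nrow(best), ncol(best))
  for (pos in seq_along(subset)[-1L]) {
    v <- stack[[subset[pos]]]$values
    better <- !is.na(v) & (is.na(best) | v > best)
    best[better] <- v[better]
    arg[better] <- pos
  }
  evaluated <- first$evaluated
  arg[!evaluated] <- NA_integer_
  new_ncc_surface(best, evaluated, first$template_shape,
                  argmax = arg, template_ids = library$ids[subset],
                  eval_count = sum(evaluated) * length(subset))
}

#' Export a correlation surface as a flat table
#'
#' @param x an `ncc_surface`.
#' @param ... unused.
#' @return data.frame with 1-based anchor coordinates `i`, `j`, the NCC
#'   `value` (`NA` where skipped) and the `evaluated` flag.
#' @export
as.data.frame.ncc_surface <- function(x, ...) {
  d <- dim(x$values)
  data.frame(
    i = rep(seq_len(d[1L]), times = d[2L]),
    j = rep(seq_len(d[2L]), each = d[1L]),
    value = as.vector(x$values),
    evaluated = as.vector(x$evaluated))
}

#' Write a correlation surface to CSV
#'
#' @param surface an `ncc_surface`.
#' @param path output CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}
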