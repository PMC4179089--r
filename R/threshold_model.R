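# Linear count-vs-threshold model C(T) ~ alpha*T + beta and its inversion,
# used to compensate counting loss after library pruning or sparse
# evaluation.

#' Fit the linear count-versus-threshold model
#'
#' The number of counted cells depends approximately linearly (and
#' inversely) on the detection threshold over the strong-correlation range.
#' This fits C(T) = alpha*T + beta by ordinary least squares through the
#' total counts observed at a grid of thresholds, all within \[0.60, 1\]
#' (0.60 is the lowest threshold still indicating a strong correlation).
#'
#' Counting at each grid point reuses one max-over-library surface per
#' sample, so the grid costs little beyond a single count.
#'
#' @inheritParams influence
#' @param thresholds numeric grid of at least 2 distinct values in
#'   \[0.60, 1\]; default 8 points over \[0.60, 0.67\].
#' @return object of class `threshold_model`: `alpha` (cells per unit
#'   threshold, expected negative), `beta` (intercept, cells), `fit_range`,
#'   `residual` (root-mean-square fit error, cells) and `data` (the
#'   threshold/count table). If every count is identical, `alpha` is 0 and a
#'   warning notes that inversion is impossible.
#' @seealso [compensate_threshold()], [coef.threshold_model()],
#'   [predict.threshold_model()]
#' @examples
#' m <- structure(list(alpha = -1000, beta = 1000), class = "threshold_model")
#' compensate_threshold(m, 365)$threshold  # 0.635
#' @export
fit_count_model <- function(samples, library, thresholds = NULL,
                            pattern = NULL, max_cluster_shape = c(3, 3)) {
  if (is.null(thresholds)) thresholds <- seq(0.60, 0.67, length.out = 8L)
  thresholds <- sort(unique(as.numeric(thresholds)))
  if (length(thresholds) < 2L)
    stop("need at least 2 distinct thresholds to fit a line", call. = FALSE)
  if (any(thresholds < 0.60 - 1e-12) || any(thresholds > 1))
    stop("thresholds must lie in [0.60, 1] (0.60 is the weakest threshold ",
         "still indicating a strong correlation)", call. = FALSE)
  samples <- .as_sample_list(samples)
  library <- as_template_library(library)

  surfaces <- lapply(samples, function(im) max_over_library(im, library, pattern))
  counts <- vapply(thresholds, function(T) {
    sum(vapply(surfaces, function(surf) {
      cluster_and_count(mark_points(surf, T), max_cluster_shape,
                        pattern)$count
    }, numeric(1L)))
  }, numeric(1L))
  .fit_threshold_line(thresholds, counts)
}

# OLS line through (threshold, count) pairs; split out so exact synthetic
# count tables can be fitted directly in tests.
.fit_threshold_line <- function(thresholds, counts) {
  if (length(unique(counts)) == 1L) {
    warning("counts identical at every threshold: alpha = 0, ",
            "threshold compensation is impossible", call. = FALSE)
    alpha <- 0; beta <- counts[1L]; resid <- 0
  } else {
    fit <- stats::lm(counts ~ thresholds)
    alpha <- unname(stats::coef(fit)[2L])
    beta <- unname(stats::coef(fit)[1L])
    resid <- sqrt(mean(stats::residuals(fit)^2))
  }
  structure(
    list(alpha = alpha, beta = beta,
         fit_range = range(thresholds), residual = resid,
         data = data.frame(threshold = thresholds, count = counts)),
    class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Count-vs-threshold model: C(T) = alpha*T + beta\n")
  cat(sprintf("  alpha = %.4f cells per unit threshold\n", x$alpha))
  cat(sprintf("  beta  = %.4f cells\n", x$beta))
  cat(sprintf("  fitted over T in [%.3f, %.3f], RMS residual %.3f cells\n",
              x$fit_range[1L], x$fit_range[2L], x$residual))
  invisible(x)
}

#' @export
coef.threshold_model <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' Predicted counts from a threshold model
#' @param object a `threshold_model`.
#' @param thresholds thresholds at which to predict (default: fitted grid).
#' @param ... unused.
#' @export
predict.threshold_model <- function(object, thresholds = NULL, ...) {
  if (is.null(thresholds)) thresholds <- object$data$threshold
  object$alpha * thresholds + object$beta
}

#' @export
plot.threshold_model <- function(x, ...) {
  graphics::plot(x$data$threshold, x$data$count,
                 xlab = "threshold T", ylab = "counted cells C(T)",
                 main = "Count vs threshold", ...)
  graphics::abline(a = x$beta, b = x$alpha, lty = 2)
  invisible(x)
}

#' Invert the count model to compensate an accuracy loss
#'
#' Solves C(T*) = target for T* = (target - beta) / alpha and clamps the
#' result into \[0.60, T_hi\] (T_hi = upper end of the fitted range). When
#' the target lies outside the reachable range the returned threshold is the
#' clamped boundary and `clamped` is `TRUE`: the loss cannot be fully
#' compensated by threshold adjustment alone.
#'
#' @param model a `threshold_model` with nonzero `alpha`.
#' @param target_count desired cell count (typically the un-optimized
#'   pipeline's count at the original threshold).
#' @return list: `threshold` (T*), `clamped` (logical), `target_count`,
#'   `predicted_count` (model count at T*).
#' @export
compensate_threshold <- function(model, target_count) {
  stopifnot(inherits(model, "threshold_model"))
  if (!is.finite(model$alpha) || model$alpha == 0)
    stop("cannot invert the count model: alpha is zero", call. = FALSE)
  t_star <- (target_count - model$beta) / model$alpha
  t_hi <- if (!is.null(model$fit_range)) model$fit_range[2L] else 1
  clamped <- t_star < 0.60 - 1e-9 || t_star > t_hi + 1e-9
  t_star <- min(max(t_star, 0.60), t_hi)
  list(threshold = t_star, clamped = clamped,
       target_count = target_count,
       predicted_count = model$alpha * t_star + model$beta)
}

#' True/false positive table against ground truth
#'
#' When ground truth is available (synthetic scenes), tabulates the true
#' positive rate (detected cells within matching distance of a true center,
#' over true cells) and false positive rate (unmatched detections over true
#' cells) across a threshold grid - the material for an ROC-style
#' calibration curve.
#'
#' @param scene a [generate_scene()] result.
#' @param library a [template_library()].
#' @param thresholds threshold grid.
#' @param match_radius Chebyshev distance (pixels) within which a detection
#'   centroid matches a true center; default half the template extent.
#' @param pattern optional [skip_pattern()].
#' @return data.frame: threshold, count, true_positives, false_positives,
#'   tpr, fpr.
#' @export
roc_table <- function(scene, library, thresholds = seq(0.60, 0.67, length.out = 8L),
                      match_radius = NULL, pattern = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  library <- as_template_library(library)
  if (is.null(match_radius)) match_radius <- ceiling(max(library$shape) / 2)
  half <- (library$shape - 1) / 2
  surf <- max_over_library(scene$image, library, pattern)
  truth <- scene$truth
  rows <- lapply(thresholds, function(T) {
    cl <- cluster_and_count(mark_points(surf, T), pattern = pattern)
    det <- cl$clusters
    tp <- 0L
    if (nrow(det) > 0L && nrow(truth) > 0L) {
      # anchor centroid + template half-extent = detected cell center
      dr <- det$centroid_row + half[1L]
      dc <- det$centroid_col + half[2L]
      used <- rep(FALSE, nrow(det))
      for (i in seq_len(nrow(truth))) {
        cheb <- pmax(abs(dr - truth$row[i]), abs(dc - truth$col[i]))
        hit <- which(!used & cheb <= match_radius)
        if (length(hit)) { used[hit[1L]] <- TRUE; tp <- tp + 1L }
      }
    }
    fp <- cl$count - tp
    data.frame(threshold = T, count = cl$count, true_positives = tp,
               false_positives = fp,
               tpr = if (nrow(truth)) tp / nrow(truth) else NA_real_,
               fpr = if (nrow(truth)) fp / nrow(truth) else NA_real_)
  })
  do.call(rbind, rows)
}
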