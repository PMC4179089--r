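# End-to-end pipelines binding the modules together: batch counting with
# reports, and the joint optimization (library pruning + skip pattern +
# threshold compensation).

#' Count cells across a batch of images, with reports
#'
#' Runs the counting pipeline on each image and optionally writes, per
#' image, a cluster CSV, a marked-overlay PNG and a run log. The report
#' carries the NCC evaluation ledger used for runtime-reduction accounting:
#' evaluations performed = evaluated anchors x library size, exactly.
#'
#' @param images list of images (matrices, file paths or `synthetic_scene`
#'   objects), or a single one.
#' @param library a [template_library()] or a library directory path.
#' @param threshold detection threshold.
#' @param pattern optional [skip_pattern()], preset index 1-4, or `NULL`.
#' @param max_cluster_shape expected cluster extent c(m, n).
#' @param out_dir optional output directory for CSVs, overlays and the log.
#' @param overlay write marked-overlay PNGs (only with `out_dir`).
#' @return object of class `count_report`: `table` (data.frame: image,
#'   count, marked_points, evaluated_offsets, total_offsets, ncc_evaluations),
#'   `results` (list of [count_cells()] objects) and `config`.
#' @export
run_count <- function(images, library, threshold = 0.67, pattern = NULL,
                      max_cluster_shape = c(3, 3), out_dir = NULL,
                      overlay = FALSE) {
  if (is.character(library)) library <- read_library(library)
  library <- as_template_library(library)
  pattern <- .resolve_pattern(pattern)
  if (!is.list(images) || inherits(images, "synthetic_scene"))
    images <- list(images)
  labels <- names(images)
  if (is.null(labels))
    labels <- vapply(seq_along(images), function(k) {
      if (is.character(images[[k]])) basename(images[[k]])
      else sprintf("image%02d", k)
    }, character(1L))
  mats <- .as_sample_list(images)

  results <- vector("list", length(mats))
  rows <- vector("list", length(mats))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(mats)) {
    res <- count_cells(mats[[k]], library, threshold, pattern,
                       max_cluster_shape)
    results[[k]] <- res
    rows[[k]] <- data.frame(
      image = labels[k], count = res$count,
      marked_points = sum(res$marks$marks),
      evaluated_offsets = sum(res$surface$evaluated),
      total_offsets = res$total_offsets,
      ncc_evaluations = res$eval_count,
      stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      stem <- file.path(out_dir, sub("\\.[^.]+$", "", labels[k]))
      write_clusters_csv(res, paste0(stem, "_clusters.csv"))
      if (overlay)
        write_overlay_png(mats[[k]], res, paste0(stem, "_overlay.png"))
    }
  }
  tab <- do.call(rbind, rows)
  config <- list(threshold = threshold,
                 pattern = if (is.null(pattern)) "none" else pattern$name,
                 max_cluster_shape = max_cluster_shape,
                 library_size = length(library))
  if (!is.null(out_dir)) {
    utils::write.csv(tab, file.path(out_dir, "counts.csv"), row.names = FALSE)
    writeLines(c("cellncc run_count",
                 paste0("  threshold: ", threshold),
                 paste0("  pattern: ", config$pattern),
                 paste0("  library size: ", length(library)),
                 paste0("  images: ", nrow(tab)),
                 paste0("  total count: ", sum(tab$count))),
               file.path(out_dir, "run_log.txt"))
  }
  structure(list(table = tab, results = results, config = config),
            class = "count_report")
}

.resolve_pattern <- function(pattern) {
  if (is.null(pattern)) return(NULL)
  if (inherits(pattern, "skip_pattern")) return(pattern)
  if (is.numeric(pattern) && length(pattern) == 1L)
    return(preset_pattern(pattern))
  if (is.character(pattern) && length(pattern) == 1L) {
    p <- tolower(pattern)
    if (p %in% c("none", "full")) return(NULL)
    if (grepl("^p?[1-4]$", p))
      return(preset_pattern(as.integer(sub("^p", "", p))))
    if (file.exists(pattern)) return(read_pattern(pattern))
  }
  stop("cannot interpret '", pattern,
       "' as a skip pattern (use a skip_pattern, 1-4, 'none' or a mask file)",
       call. = FALSE)
}

#' @export
print.count_report <- function(x, ...) {
  cat("cellncc count report (threshold ", format(x$config$threshold),
      ", pattern ", x$config$pattern, ", ", x$config$library_size,
      " templates)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("total cells: ", sum(x$table$count), "\n", sep = "")
  invisible(x)
}

#' Jointly optimize library and threshold, and compare pipelines
#'
#' The full optimization workflow:
#'
#' 1. count the calibration images with the full library at the original
#'    threshold (the reference the optimization must preserve);
#' 2. prune duplicated/similar templates under the loss budget
#'    ([prune_library()]);
#' 3. fit the count-vs-threshold line for the optimized configuration
#'    (pruned library plus skip pattern) over the threshold grid
#'    ([fit_count_model()]);
#' 4. invert it to the compensated threshold that restores the reference
#'    count ([compensate_threshold()]); if the counts never vary over the
#'    grid (alpha = 0) there is no loss to compensate and the original
#'    threshold is kept;
#' 5. count the calibration images with the optimized pipeline and report
#'    the comparison, including the exact NCC evaluation ledger.
#'
#' @inheritParams run_count
#' @param calibration list of calibration images.
#' @param loss_budget_percent pruning loss budget (percent of the reference
#'   count), default 8.5.
#' @param thresholds grid for the count model fit (default 8 points over
#'   \[0.60, 0.67\]).
#' @return object of class `optimized_pipeline`: `pruning`
#'   (a `pruned_library`), `model` (`threshold_model`), `compensated`
#'   (threshold + clamp flag), `original` and `optimized` count tables,
#'   and `summary` (totals, loss before/after compensation, evaluation
#'   counts and their ratio).
#' @export
run_optimize <- function(calibration, library, threshold = 0.67,
                         loss_budget_percent = 8.5, pattern = 1,
                         thresholds = NULL, max_cluster_shape = c(3, 3)) {
  if (is.character(library)) library <- read_library(library)
  library <- as_template_library(library)
  pattern <- .resolve_pattern(pattern)
  if (is.null(thresholds)) thresholds <- seq(0.60, 0.67, length.out = 8L)
  if (!is.list(calibration) || inherits(calibration, "synthetic_scene"))
    calibration <- list(calibration)
  if (length(calibration) == 0L)
    stop("empty calibration set", call. = FALSE)
  mats <- .as_sample_list(calibration)

  original <- run_count(mats, library, threshold, pattern = NULL,
                        max_cluster_shape = max_cluster_shape)
  target <- sum(original$table$count)

  pruning <- prune_library(mats, library, threshold, loss_budget_percent,
                           pattern = NULL,
                           max_cluster_shape = max_cluster_shape)

  model <- withCallingHandlers(
    fit_count_model(mats, pruning$pruned, thresholds, pattern,
                    max_cluster_shape),
    warning = function(w) invokeRestart("muffleWarning"))

  if (model$alpha == 0) {
    comp <- list(threshold = threshold, clamped = FALSE,
                 target_count = target,
                 predicted_count = model$beta)
    compensated_note <- "counts constant over the grid; original threshold kept"
  } else {
    comp <- compensate_threshold(model, target)
    compensated_note <- if (comp$clamped)
      "compensated threshold clamped; loss not fully compensable" else ""
  }

  optimized <- run_count(mats, pruning$pruned, comp$threshold, pattern,
                         max_cluster_shape = max_cluster_shape)

  orig_total <- sum(original$table$count)
  opt_total <- sum(optimized$table$count)
  uncomp_total <- pruning$pruned_count
  ev_orig <- sum(original$table$ncc_evaluations)
  ev_opt <- sum(optimized$table$ncc_evaluations)
  summary <- list(
    original_count = orig_total,
    pruned_uncompensated_count = uncomp_total,
    optimized_count = opt_total,
    loss_before_compensation_percent =
      if (orig_total) 100 * (orig_total - uncomp_total) / orig_total else 0,
    loss_after_compensation_percent =
      if (orig_total) 100 * abs(orig_total - opt_total) / orig_total else 0,
    library_size = c(original = length(library), pruned = length(pruning$pruned)),
    ncc_evaluations = c(original = ev_orig, optimized = ev_opt),
    evaluation_ratio = ev_opt / ev_orig,
    note = compensated_note)
  structure(
    list(pruning = pruning, model = model, compensated = comp,
         original = original$table, optimized = optimized$table,
         threshold = threshold, pattern = pattern, summary = summary),
    class = "optimized_pipeline")
}

#' @export
print.optimized_pipeline <- function(x, ...) {
  s <- x$summary
  cat("cellncc optimized pipeline\n")
  cat(sprintf("  library: %d -> %d templates\n",
              s$library_size["original"], s$library_size["pruned"]))
  cat("  pattern: ", if (is.null(x$pattern)) "none" else x$pattern$name,
      "\n", sep = "")
  cat(sprintf("  threshold: %.3f -> %.4f%s\n", x$threshold,
              x$compensated$threshold,
              if (isTRUE(x$compensated$clamped)) " (clamped)" else ""))
  cat(sprintf("  counts: original %d | pruned (uncompensated) %d | optimized %d\n",
              s$original_count, s$pruned_uncompensated_count,
              s$optimized_count))
  cat(sprintf("  loss: %.2f%% before compensation, %.2f%% after\n",
              s$loss_before_compensation_percent,
              s$loss_after_compensation_percent))
  cat(sprintf("  NCC evaluations: %s -> %s (ratio %.4f, reduction %.1f%%)\n",
              format(s$ncc_evaluations["original"], big.mark = ","),
              format(s$ncc_evaluations["optimized"], big.mark = ","),
              s$evaluation_ratio, 100 * (1 - s$evaluation_ratio)))
  if (nzchar(s$note)) cat("  note: ", s$note, "\n", sep = "")
  invisible(x)
}
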