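# Template library container, disk format (patch images + manifest),
# influence scoring and loss-budgeted pruning.

#' Create a template library
#'
#' An ordered collection of K x L cell patches with unique IDs. Order is
#' significant: influence attribution iterates templates in library order,
#' so duplicated or similar patches later in the order are the ones scored
#' as redundant. All templates must share one shape and have positive pixel
#' variance.
#'
#' @param templates list of numeric K x L matrices.
#' @param ids character vector of unique IDs (default `tpl01`, `tpl02`, ...).
#' @param manifest optional data.frame of per-template metadata (one row per
#'   template; must contain an `id` column if supplied).
#' @return object of class `template_library`.
#' @export
template_library <- function(templates, ids = NULL, manifest = NULL) {
  if (!is.list(templates) || length(templates) == 0L)
    stop("templates must be a non-empty list of matrices", call. = FALSE)
  for (tm in templates) check_template(tm)
  shapes <- vapply(templates, dim, integer(2L))
  if (any(shapes[1L, ] != shapes[1L, 1L]) || any(shapes[2L, ] != shapes[2L, 1L]))
    stop("all templates in a library must share one K x L shape", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("tpl%02d", seq_along(templates))
  ids <- as.character(ids)
  if (length(ids) != length(templates) || anyDuplicated(ids))
    stop("template ids must be unique, one per template", call. = FALSE)
  names(templates) <- ids
  if (!is.null(manifest)) {
    if (!is.data.frame(manifest) || is.null(manifest$id) ||
        !identical(as.character(manifest$id), ids))
      stop("manifest must be a data.frame with an id column matching the templates",
           call. = FALSE)
  }
  structure(list(templates = templates, ids = ids,
                 shape = unname(shapes[, 1L]), manifest = manifest),
            class = "template_library")
}

as_template_library <- function(x) {
  if (inherits(x, "template_library")) return(x)
  if (is.matrix(x)) return(template_library(list(x)))
  if (is.list(x)) return(template_library(x))
  stop("cannot interpret object of class '", class(x)[1L],
       "' as a template library", call. = FALSE)
}

#' @export
length.template_library <- function(x) length(x$templates)

#' @export
print.template_library <- function(x, ...) {
  cat("Template library: ", length(x), " templates of ",
      x$shape[1L], "x", x$shape[2L], " pixels\n", sep = "")
  cat("  ids: ", paste(utils::head(x$ids, 8L), collapse = ", "),
      if (length(x) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Subset a template library (order preserved)
#' @param x a `template_library`.
#' @param i index vector (integer, logical or ID).
#' @export
`[.template_library` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$ids)
  template_library(x$templates[i], x$ids[i],
                   if (!is.null(x$manifest)) x$manifest[i, , drop = FALSE])
}

#' Write a template library to a directory
#'
#' Writes each patch as an 8-bit grayscale PNG plus a `manifest.csv`
#' (columns: id, filename, order, then any extra manifest metadata).
#'
#' @param library a [template_library()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_library <- function(library, dir) {
  library <- as_template_library(library)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(library$ids, ".png")
  for (k in seq_along(library$templates))
    write_sample_image(library$templates[[k]], file.path(dir, files[k]))
  man <- data.frame(id = library$ids, filename = files,
                    order = seq_along(library$ids), stringsAsFactors = FALSE)
  if (!is.null(library$manifest)) {
    extra <- library$manifest[, setdiff(names(library$manifest),
                                        names(man)), drop = FALSE]
    if (ncol(extra)) man <- cbind(man, extra)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a template library from a directory
#'
#' Expects the layout written by [write_library()]: patch images plus a
#' manifest CSV with `id`, `filename` and `order` columns; templates are
#' loaded in manifest order.
#'
#' @param dir library directory.
#' @param manifest manifest path (default `dir/manifest.csv`).
#' @return a [template_library()].
#' @export
read_library <- function(dir, manifest = file.path(dir, "manifest.csv")) {
  if (!file.exists(manifest))
    stop("library manifest not found: ", manifest, call. = FALSE)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  man <- man[order(man$order), , drop = FALSE]
  tm <- lapply(file.path(dir, man$filename), read_sample_image)
  template_library(tm, man$id, manifest = man)
}

#' Pairwise template similarity matrix
#'
#' Full-overlap (single-offset) NCC between every pair of templates; the
#' diagonal is 1 and an exact duplicate pair scores 1. A diagnostic for
#' duplicated/similar library content.
#'
#' @param library a [template_library()].
#' @return symmetric numeric matrix with template IDs as dimnames.
#' @export
template_similarity <- function(library) {
  library <- as_template_library(library)
  n <- length(library)
  centred <- lapply(library$templates, function(tm) {
    d <- tm - mean(tm)
    d / sqrt(sum(d^2))
  })
  sim <- diag(1, n)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        v <- sum(centred[[a]] * centred[[b]])
        sim[a, b] <- sim[b, a] <- min(1, max(-1, v))
      }
    }
  }
  dimnames(sim) <- list(library$ids, library$ids)
  sim
}

# ---- influence scoring -----------------------------------------------------

# Per-sample, per-template cluster centroid tables at a fixed threshold.
# This cache is the workhorse for influence scoring and greedy pruning:
# attribution for any template subset/order is pure bookkeeping on it.
template_cluster_cache <- function(samples, library, threshold,
                                   pattern = NULL, max_cluster_shape = c(3, 3)) {
  samples <- .as_sample_list(samples)
  library <- as_template_library(library)
  lapply(samples, function(im) {
    stack <- ncc_stack(im, library, pattern)
    cents <- lapply(stack, function(surf) {
      cl <- cluster_and_count(mark_points(surf, threshold),
                              max_cluster_shape, pattern)
      as.matrix(cl$clusters[, c("centroid_row", "centroid_col")])
    })
    list(stack = stack, centroids = cents)
  })
}

.as_sample_list <- function(samples) {
  if (inherits(samples, "synthetic_scene")) samples <- list(samples)
  if (is.matrix(samples)) samples <- list(samples)
  if (!is.list(samples) || length(samples) == 0L)
    stop("samples must be a non-empty list of images", call. = FALSE)
  lapply(samples, function(s) {
    if (inherits(s, "synthetic_scene")) s$image
    else if (is.character(s) && length(s) == 1L) read_sample_image(s)
    else {check_sample_image(s); s}
  })
}

# Sequential first-detector attribution over a template subset (original
# library order within the subset). Returns attributed cluster counts per
# subset position.
.attribute <- function(centroid_lists, subset, overlap_radius) {
  counts <- integer(length(subset))
  for (sample_cl in centroid_lists) {
    accepted <- matrix(numeric(0), 0L, 2L)
    for (pos in seq_along(subset)) {
      cents <- sample_cl[[subset[pos]]]
      if (nrow(cents) == 0L) next
      for (r in seq_len(nrow(cents))) {
        p <- cents[r, ]
        if (nrow(accepted) > 0L) {
          cheb <- pmax(abs(accepted[, 1L] - p[1L]), abs(accepted[, 2L] - p[2L]))
          if (any(cheb <= overlap_radius)) next
        }
        counts[pos] <- counts[pos] + 1L
        accepted <- rbind(accepted, p)
      }
    }
  }
  counts
}

#' Influence of each library template on the cell count
#'
#' Scores how many cells each template is the *first* to detect when
#' templates are applied in library order: a cluster found by template k is
#' attributed to k only if it overlaps no cluster already attributed to an
#' earlier template (centroids within Chebyshev distance `max(m, n) - 1`
#' count as the same cell). Influence is the attributed share of the total,
#' in percent. Exact duplicates of an earlier template therefore score 0%,
#' which is what makes them safely removable.
#'
#' @param samples list of sample images (matrices, file paths or
#'   `synthetic_scene` objects); totals aggregate over all of them.
#' @param library a [template_library()].
#' @param threshold detection threshold.
#' @param pattern optional [skip_pattern()].
#' @param max_cluster_shape expected cluster extent c(m, n).
#' @param cache precomputed [template_cluster_cache] (internal reuse).
#' @return object of class `influence_report`: data.frame-like list with
#'   `table` (id, attributed_cells, influence_percent) and `total_cells`.
#' @export
influence <- function(samples, library, threshold = 0.67, pattern = NULL,
                      max_cluster_shape = c(3, 3), cache = NULL) {
  library <- as_template_library(library)
  if (is.null(cache))
    cache <- template_cluster_cache(samples, library, threshold, pattern,
                                    max_cluster_shape)
  centroid_lists <- lapply(cache, `[[`, "centroids")
  radius <- max(max_cluster_shape) - 1L
  counts <- .attribute(centroid_lists, seq_along(library$templates), radius)
  total <- sum(counts)
  if (total == 0L) {
    warning("no cells detected on the calibration samples; all influences are zero",
            call. = FALSE)
    pct <- rep(0, length(counts))
  } else pct <- 100 * counts / total
  structure(
    list(table = data.frame(id = library$ids,
                            attributed_cells = counts,
                            influence_percent = pct,
                            stringsAsFactors = FALSE),
         total_cells = total, threshold = threshold),
    class = "influence_report")
}

#' @export
print.influence_report <- function(x, ...) {
  cat("Influence report (", x$total_cells, " attributed cells, threshold ",
      format(x$threshold), ")\n", sep = "")
  tab <- x$table
  tab$influence_percent <- round(tab$influence_percent, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

# Union cell count for a subset of the library on every cached sample.
.subset_count <- function(cache, library, subset, threshold, pattern,
                          max_cluster_shape) {
  vapply(cache, function(sample_cache) {
    surf <- max_of_stack(sample_cache$stack, library, pattern, subset)
    cluster_and_count(mark_points(surf, threshold),
                      max_cluster_shape, pattern)$count
  }, numeric(1L))
}

#' Prune duplicated and similar templates under a loss budget
#'
#' Two stages, both assessed by re-counting the calibration samples:
#'
#' 1. remove every zero-influence template (their detections are fully
#'    covered by earlier templates, so removal is projected lossless);
#' 2. greedily remove the lowest-influence remaining template (ties broken
#'    by library order), re-scoring influence after every removal, while the
#'    cumulative count loss relative to the full library stays within
#'    `loss_budget_percent`.
#'
#' The pruner never empties the library: if everything else is removable it
#' keeps the single highest-influence template.
#'
#' @inheritParams influence
#' @param loss_budget_percent maximum tolerated count loss, in percent of
#'   the full-library count (aggregated over the calibration samples).
#' @return list of class `pruned_library`: `pruned` (the reduced
#'   [template_library()]), `projected_loss_percent` (realized loss on the
#'   calibration samples), `baseline_count`, `pruned_count`, and
#'   `removal_log` (data.frame: id, step, stage, influence_at_removal,
#'   loss_after_percent).
#' @export
prune_library <- function(samples, library, threshold = 0.67,
                          loss_budget_percent = 8.5, pattern = NULL,
                          max_cluster_shape = c(3, 3)) {
  if (loss_budget_percent < 0)
    stop("loss budget must be >= 0", call. = FALSE)
  library <- as_template_library(library)
  cache <- template_cluster_cache(samples, library, threshold, pattern,
                                  max_cluster_shape)
  centroid_lists <- lapply(cache, `[[`, "centroids")
  radius <- max(max_cluster_shape) - 1L
  all_idx <- seq_along(library$templates)
  baseline <- sum(.subset_count(cache, library, all_idx, threshold, pattern,
                                max_cluster_shape))
  loss_pct <- function(cnt) {
    if (baseline == 0) 0 else 100 * (baseline - cnt) / baseline
  }

  log_id <- character(0); log_stage <- character(0)
  log_infl <- numeric(0); log_loss <- numeric(0)
  keep <- all_idx

  # stage 1: drop all zero-influence templates at once
  counts <- .attribute(centroid_lists, keep, radius)
  zero <- keep[counts == 0L]
  if (length(zero) > 0L && length(zero) < length(keep)) {
    keep <- setdiff(keep, zero)
    cnt <- sum(.subset_count(cache, library, keep, threshold, pattern,
                             max_cluster_shape))
    log_id <- library$ids[zero]
    log_stage <- rep("zero-influence", length(zero))
    log_infl <- rep(0, length(zero))
    log_loss <- rep(loss_pct(cnt), length(zero))
  }

  # stage 2: greedy removal under the budget, re-scoring after each removal
  repeat {
    if (length(keep) <= 1L) break
    counts <- .attribute(centroid_lists, keep, radius)
    total <- sum(counts)
    infl <- if (total == 0L) rep(0, length(counts)) else 100 * counts / total
    cand_pos <- which.min(infl)  # ties: earliest library order wins
    trial <- keep[-cand_pos]
    cnt <- sum(.subset_count(cache, library, trial, threshold, pattern,
                             max_cluster_shape))
    if (loss_pct(cnt) > loss_budget_percent) break
    log_id <- c(log_id, library$ids[keep[cand_pos]])
    log_stage <- c(log_stage, "greedy")
    log_infl <- c(log_infl, infl[cand_pos])
    log_loss <- c(log_loss, loss_pct(cnt))
    keep <- trial
  }

  final_count <- sum(.subset_count(cache, library, keep, threshold, pattern,
                                   max_cluster_shape))
  removal_log <- data.frame(
    id = log_id, step = seq_along(log_id),
    stage = log_stage, influence_at_removal = log_infl,
    loss_after_percent = log_loss, stringsAsFactors = FALSE)
  structure(
    list(pruned = library[keep],
         projected_loss_percent = loss_pct(final_count),
         baseline_count = baseline, pruned_count = final_count,
         removal_log = removal_log, threshold = threshold),
    class = "pruned_library")
}

#' @export
print.pruned_library <- function(x, ...) {
  n_rm <- nrow(x$removal_log)
  cat("Library pruning: removed ", n_rm, " template(s), kept ",
      length(x$pruned), "\n", sep = "")
  cat(sprintf("  calibration count %d -> %d (loss %.2f%%)\n",
              x$baseline_count, x$pruned_count, x$projected_loss_percent))
  if (n_rm > 0L) {
    tab <- x$removal_log
    tab$influence_at_removal <- round(tab$influence_at_removal, 2)
    tab$loss_after_percent <- round(tab$loss_after_percent, 2)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Write a pruning removal log and new manifest
#'
#' @param pruned a `pruned_library` result.
#' @param dir output directory; writes the pruned library (patches +
#'   manifest) plus `removal_log.csv`.
#' @export
write_pruned_library <- function(pruned, dir) {
  stopifnot(inherits(pruned, "pruned_library"))
  write_library(pruned$pruned, dir)
  utils::write.csv(pruned$removal_log, file.path(dir, "removal_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}
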