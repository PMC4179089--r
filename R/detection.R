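# Marking, clustering and counting: turn a max-over-library correlation
# surface into a cell count.

#' Mark anchors whose NCC exceeds a threshold
#'
#' An anchor is marked when its (maximum-over-library) NCC value is strictly
#' greater than the threshold; ties are excluded. Skipped anchors are never
#' marked.
#'
#' @param surface an `ncc_surface` (usually from [max_over_library()]).
#' @param threshold detection threshold in \[-1, 1\].
#' @return object of class `mark_matrix`: list with logical `marks`,
#'   `threshold`, and the originating `surface`.
#' @export
mark_points <- function(surface, threshold) {
  stopifnot(inherits(surface, "ncc_surface"))
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold < -1 || threshold > 1)
    stop("threshold must be a single value in [-1, 1]", call. = FALSE)
  marks <- surface$evaluated & !is.na(surface$values) &
    surface$values > threshold
  marks[is.na(marks)] <- FALSE
  structure(list(marks = marks, threshold = threshold, surface = surface),
            class = "mark_matrix")
}

#' @export
print.mark_matrix <- function(x, ...) {
  cat("Mark matrix: ", sum(x$marks), " marked of ", length(x$marks),
      " anchors (threshold ", format(x$threshold), ")\n", sep = "")
  invisible(x)
}

#' Group marked anchors into clusters and count cells
#'
#' A single cell typically produces a cluster of marked anchors of extent up
#' to m x n (default 3x3). Clusters are connected components of the marked
#' set under a Chebyshev-distance link: radius 1 (8-connectivity) when every
#' anchor was evaluated, widened to `max(m, n) - 1` when a skip pattern is
#' active, so that the surviving marks of one cell - no longer 8-adjacent
#' after thinning - still merge into a single cluster.
#'
#' Components larger than m x n are still counted as one cell (the cap is a
#' physical expectation, not a splitting rule); a warning reports how many
#' exceed it.
#'
#' @param marks a `mark_matrix` from [mark_points()].
#' @param max_cluster_shape integer c(m, n) expected cluster extent.
#' @param pattern the [skip_pattern()] used when evaluating the surface, or
#'   `NULL` if every anchor was evaluated.
#' @return object of class `cell_clusters`: list with `count`, `clusters`
#'   (data.frame: cluster_id, centroid_row, centroid_col, size, template_id),
#'   `members` (list of per-cluster anchor coordinate matrices),
#'   `max_cluster_shape` and the link `radius` used.
#' @export
cluster_and_count <- function(marks, max_cluster_shape = c(3, 3),
                              pattern = NULL) {
  stopifnot(inherits(marks, "mark_matrix"))
  m <- as.integer(max_cluster_shape[1L]); n <- as.integer(max_cluster_shape[2L])
  stopifnot(m >= 1L, n >= 1L)
  radius <- if (is.null(pattern)) 1L else max(m, n) - 1L
  radius <- max(radius, 1L)
  comp <- .label_components(marks$marks, radius)
  surface <- marks$surface

  k <- comp$n
  members <- vector("list", k)
  clusters <- data.frame(cluster_id = integer(0), centroid_row = numeric(0),
                         centroid_col = numeric(0), size = integer(0),
                         template_id = character(0),
                         stringsAsFactors = FALSE)
  if (k > 0L) {
    idx <- which(marks$marks, arr.ind = TRUE)
    lab <- comp$labels[marks$marks]
    ord <- order(lab)
    idx <- idx[ord, , drop = FALSE]; lab <- lab[ord]
    split_at <- split(seq_len(nrow(idx)), lab)
    cr <- cc <- sz <- numeric(k); tid <- character(k)
    oversize <- 0L
    for (g in seq_len(k)) {
      pts <- idx[split_at[[g]], , drop = FALSE]
      members[[g]] <- pts
      cr[g] <- mean(pts[, 1L]); cc[g] <- mean(pts[, 2L])
      sz[g] <- nrow(pts)
      ext <- c(diff(range(pts[, 1L])) + 1L, diff(range(pts[, 2L])) + 1L)
      if (ext[1L] > m || ext[2L] > n) oversize <- oversize + 1L
      tid[g] <- .peak_template(surface, pts)
    }
    if (oversize > 0L)
      warning(oversize, " cluster(s) exceed the expected ", m, "x", n,
              " extent; each still counted as one cell", call. = FALSE)
    clusters <- data.frame(cluster_id = seq_len(k), centroid_row = cr,
                           centroid_col = cc, size = as.integer(sz),
                           template_id = tid, stringsAsFactors = FALSE)
  }
  structure(list(count = k, clusters = clusters, members = members,
                 max_cluster_shape = c(m, n), radius = radius,
                 threshold = marks$threshold),
            class = "cell_clusters")
}

# ID of the arg-max template at the cluster's peak anchor (NA-safe).
.peak_template <- function(surface, pts) {
  if (is.null(surface) || is.null(surface$argmax)) return(NA_character_)
  v <- surface$values[pts]
  p <- pts[which.max(v), , drop = FALSE]
  k <- surface$argmax[p]
  if (is.na(k)) NA_character_
  else if (!is.null(surface$template_ids)) {
    # argmax stores indices into the original library ordering
    ids <- surface$template_ids
    if (!is.null(names(ids))) ids <- unname(ids)
    # indices may exceed the subset length when a subset was taken; guard
    if (k >= 1 && k <= length(ids)) ids[k] else as.character(k)
  } else as.character(k)
}

# Connected-component labelling of a logical matrix where two TRUE cells are
# linked iff their Chebyshev distance is <= radius. BFS with a label matrix.
.label_components <- function(mask, radius) {
  M <- nrow(mask); N <- ncol(mask)
  labels <- matrix(0L, M, N)
  idx <- which(mask)
  n_comp <- 0L
  if (length(idx) == 0L) return(list(labels = labels, n = 0L))
  queue <- integer(length(idx))
  for (start in idx) {
    if (labels[start] != 0L) next
    n_comp <- n_comp + 1L
    labels[start] <- n_comp
    queue[1L] <- start; head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      r <- ((cur - 1L) %% M) + 1L
      cl <- ((cur - 1L) %/% M) + 1L
      for (dc in -radius:radius) {
        c2 <- cl + dc
        if (c2 < 1L || c2 > N) next
        base <- (c2 - 1L) * M
        for (dr in -radius:radius) {
          r2 <- r + dr
          if (r2 < 1L || r2 > M) next
          pos <- base + r2
          if (mask[pos] && labels[pos] == 0L) {
            labels[pos] <- n_comp
            tail <- tail + 1L
            if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
            queue[tail] <- pos
          }
        }
      }
    }
  }
  list(labels = labels, n = n_comp)
}

#' @export
print.cell_clusters <- function(x, ...) {
  cat("Cell clusters: ", x$count, " cluster(s), link radius ", x$radius, "\n",
      sep = "")
  if (x$count > 0L) {
    cat("  sizes: ", paste(utils::head(x$clusters$size, 10L), collapse = ", "),
        if (x$count > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Count cells in a sample image
#'
#' The full detection pipeline: maximum-over-library NCC surface, threshold
#' marking, cluster grouping, count. The count is monotonically
#' non-increasing in the threshold, and under any skip pattern the marked
#' set is a subset of the fully evaluated marked set.
#'
#' @inheritParams max_over_library
#' @param threshold detection threshold (default 0.67, a strong correlation).
#' @param max_cluster_shape expected cluster extent c(m, n), default 3x3.
#' @return object of class `cell_count`: list with `count`, `clusters`
#'   ([cluster_and_count()] result), `marks`, `surface`, `threshold`,
#'   `eval_count` (NCC evaluations performed = evaluated anchors x library
#'   size) and `total_offsets`.
#' @examples
#' sc <- generate_scene(n_cells = 8, image_shape = c(80, 100),
#'                      min_separation = 16, seed = 1)
#' lib <- derive_library(sc, n_templates = 3, duplicate_fraction = 0,
#'                       jitter_fraction = 0, seed = 1)
#' count_cells(sc$image, lib, threshold = 0.67)
#' @export
count_cells <- function(sample, library, threshold = 0.67, pattern = NULL,
                        max_cluster_shape = c(3, 3)) {
  if (inherits(sample, "synthetic_scene")) sample <- sample$image
  surf <- max_over_library(sample, library, pattern)
  marks <- mark_points(surf, threshold)
  clus <- cluster_and_count(marks, max_cluster_shape, pattern)
  structure(
    list(count = clus$count, clusters = clus, marks = marks, surface = surf,
         threshold = threshold, pattern = pattern,
         eval_count = surf$eval_count,
         total_offsets = length(surf$values)),
    class = "cell_count")
}

#' @export
print.cell_count <- function(x, ...) {
  cat("cellncc count\n")
  cat("  cells counted: ", x$count, "\n", sep = "")
  cat("  threshold:     ", format(x$threshold), "\n", sep = "")
  cat("  marked points: ", sum(x$marks$marks), "\n", sep = "")
  cat("  NCC evaluations: ", format(x$eval_count, big.mark = ","),
      " (", format(100 * x$eval_count /
                     (x$total_offsets * length(x$surface$template_ids)),
                   digits = 4), "% of full grid x library)\n", sep = "")
  invisible(x)
}

#' Write detected clusters to CSV
#'
#' @param count a `cell_count` or `cell_clusters` object.
#' @param path output CSV path.
#' @export
write_clusters_csv <- function(count, path) {
  cl <- if (inherits(count, "cell_count")) count$clusters$clusters
        else count$clusters
  utils::write.csv(cl, path, row.names = FALSE)
  invisible(path)
}
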