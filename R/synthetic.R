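# Seeded synthetic lensless blood-sample scenes with ground truth, and
# template libraries derived from them (including exact duplicates and
# jittered near-duplicates), so the whole pipeline is testable without
# instrument data.

# Base shape variants for the cell shadow model: a dark central disk plus a
# brighter diffraction-like ring, both Gaussian radial profiles. Columns:
# disk width (px), disk depth, ring radius (px), ring width (px), ring gain.
.shape_presets <- function() {
  matrix(c(
    1.5, 0.35, 4.8, 1.0, 0.20,
    3.6, 0.25, 7.2, 1.8, 0.08,
    2.2, 0.30, 3.2, 1.1, 0.22,
    1.2, 0.12, 5.8, 0.9, 0.30),
    nrow = 4L, byrow = TRUE,
    dimnames = list(NULL, c("disk_sd", "disk_depth", "ring_r",
                            "ring_sd", "ring_gain")))
}

#' Generate a synthetic blood-sample scene with ground truth
#'
#' Emulates a lensless (in-line holographic) blood-sample image: dozens of
#' small cell "shadows" (dark disk plus bright diffraction-like ring) drawn
#' from a small set of shape variants, placed on a background with a linear
#' intensity gradient and Gaussian pixel noise. Cell centers keep a minimum
#' Chebyshev separation and stay clear of the borders so that full
#' template-sized crops exist around every cell.
#'
#' Every random draw flows from the single `seed`, so a fixed seed yields a
#' bit-identical scene.
#'
#' @param n_cells number of planted cells (default 60).
#' @param image_shape integer c(rows, cols), default 300 x 400.
#' @param min_separation minimum Chebyshev distance between cell centers
#'   (pixels, default 14).
#' @param template_shape shape c(K, L) of the crops [derive_library()] will
#'   take, default 13 x 13; controls the border margin.
#' @param background mean background intensity on the \[0, 1\] scale.
#' @param gradient c(row, col) peak-to-peak linear background drift.
#' @param noise_sd Gaussian pixel noise standard deviation. The default
#'   (0.03) keeps the NCC of an exact planted-shape template above 0.8 at
#'   essentially every true center.
#' @param n_shapes number of shape variants used (1 to 4).
#' @param shape_jitter relative SD of per-cell perturbation of the shape
#'   parameters (cells of one variant are similar, not identical).
#' @param seed integer seed.
#' @return object of class `synthetic_scene`: `image` (matrix in \[0, 1\]),
#'   `truth` (data.frame: row, col, shape_id) and `params`.
#' @export
generate_scene <- function(n_cells = 60, image_shape = c(300, 400),
                           min_separation = 14, template_shape = c(13, 13),
                           background = 0.55, gradient = c(0.06, 0.10),
                           noise_sd = 0.03, n_shapes = 4,
                           shape_jitter = 0.04, seed = 1) {
  M <- as.integer(image_shape[1L]); N <- as.integer(image_shape[2L])
  stopifnot(M >= 1L, N >= 1L, n_cells >= 0, n_shapes >= 1, n_shapes <= 4)
  margin <- ceiling(max(template_shape) / 2) + 2L
  usable <- (M - 2L * margin) * (N - 2L * margin)
  if (n_cells > 0 && (usable <= 0 || n_cells * min_separation^2 > usable))
    stop("infeasible packing: ", n_cells, " cells at separation ",
         min_separation, " do not fit a ", M, "x", N, " image", call. = FALSE)
  set.seed(seed)

  # background: linear gradient + noise
  img <- background +
    gradient[1L] * (matrix(seq_len(M), M, N) / M - 0.5) +
    gradient[2L] * (matrix(seq_len(N), M, N, byrow = TRUE) / N - 0.5)

  # place centers by rejection sampling with a bounded retry budget
  centers <- matrix(numeric(0), 0L, 2L)
  shape_id <- integer(0)
  if (n_cells > 0) {
    tries <- 0L; max_tries <- 1000L * n_cells
    while (nrow(centers) < n_cells) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n_cells, " cells after ", max_tries,
             " attempts; reduce n_cells or min_separation", call. = FALSE)
      cand <- c(sample(margin:(M - margin), 1L), sample(margin:(N - margin), 1L))
      if (nrow(centers) > 0L) {
        cheb <- pmax(abs(centers[, 1L] - cand[1L]), abs(centers[, 2L] - cand[2L]))
        if (any(cheb < min_separation)) next
      }
      centers <- rbind(centers, cand)
      shape_id <- c(shape_id, sample.int(n_shapes, 1L))
    }
  }

  presets <- .shape_presets()
  r_max <- 9L  # render window half-extent; covers the widest ring
  for (k in seq_len(nrow(centers))) {
    p <- presets[shape_id[k], ]
    p <- p * (1 + shape_jitter * stats::rnorm(length(p)))
    r0 <- centers[k, 1L]; c0 <- centers[k, 2L]
    rr <- max(1L, r0 - r_max):min(M, r0 + r_max)
    cc <- max(1L, c0 - r_max):min(N, c0 + r_max)
    d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
    img[rr, cc] <- img[rr, cc] -
      p["disk_depth"] * exp(-d^2 / (2 * p["disk_sd"]^2)) +
      p["ring_gain"] * exp(-(d - p["ring_r"])^2 / (2 * p["ring_sd"]^2))
  }

  img <- img + stats::rnorm(M * N, sd = noise_sd)
  img[img < 0] <- 0; img[img > 1] <- 1

  truth <- data.frame(row = as.integer(centers[, 1L]),
                      col = as.integer(centers[, 2L]),
                      shape_id = shape_id)
  structure(
    list(image = img, truth = truth,
         params = list(n_cells = n_cells, image_shape = c(M, N),
                       min_separation = min_separation,
                       template_shape = as.integer(template_shape),
                       background = background, gradient = gradient,
                       noise_sd = noise_sd, n_shapes = n_shapes,
                       shape_jitter = shape_jitter, seed = seed,
                       margin = margin)),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  p <- x$params
  cat("Synthetic scene: ", p$image_shape[1L], "x", p$image_shape[2L],
      " px, ", nrow(x$truth), " planted cells (", p$n_shapes,
      " shape variants), noise sd ", p$noise_sd, ", seed ", p$seed, "\n",
      sep = "")
  invisible(x)
}

#' Ideal (noise-free) template for a shape variant
#'
#' Renders the exact planted disk-plus-ring profile on a flat background -
#' useful as a known-perfect template in tests.
#'
#' @param shape_id variant index (1 to 4).
#' @param template_shape crop shape c(K, L).
#' @param background flat background level.
#' @return numeric K x L matrix.
#' @export
ideal_template <- function(shape_id, template_shape = c(13, 13),
                           background = 0.55) {
  p <- .shape_presets()[shape_id, ]
  K <- template_shape[1L]; L <- template_shape[2L]
  r0 <- (K + 1) / 2; c0 <- (L + 1) / 2
  d <- sqrt(outer((seq_len(K) - r0)^2, (seq_len(L) - c0)^2, `+`))
  background - p["disk_depth"] * exp(-d^2 / (2 * p["disk_sd"]^2)) +
    p["ring_gain"] * exp(-(d - p["ring_r"])^2 / (2 * p["ring_sd"]^2))
}

# Crop a K x L patch centred on (row, col) with optional (dr, dc) offset.
.crop <- function(image, center, shape, offset = c(0L, 0L)) {
  K <- shape[1L]; L <- shape[2L]
  r0 <- center[1L] + offset[1L] - (K - 1L) %/% 2L
  c0 <- center[2L] + offset[2L] - (L - 1L) %/% 2L
  if (r0 < 1L || c0 < 1L || r0 + K - 1L > nrow(image) ||
      c0 + L - 1L > ncol(image))
    stop("crop window falls outside the image", call. = FALSE)
  image[r0:(r0 + K - 1L), c0:(c0 + L - 1L), drop = FALSE]
}

#' Derive a template library from a synthetic scene
#'
#' Crops template patches centered on true cells, then appends redundant
#' entries mimicking a manually collected library: exact duplicates (copies
#' of earlier entries) and jittered near-duplicates (re-crops of
#' already-used cells offset by up to `jitter` pixels). Base cells are
#' sampled across the scene's shape variants (round-robin) so every
#' appearance class present in the scene is represented, as a human curator
#' marking "representative" cells would do. Entry order is randomized under
#' the seed; the manifest records each entry's kind and source.
#'
#' @param scene a [generate_scene()] result.
#' @param n_templates library size.
#' @param duplicate_fraction fraction of entries that are exact duplicates.
#' @param jitter_fraction fraction of entries that are jittered re-crops.
#' @param jitter maximum per-axis offset (pixels) of a jittered re-crop.
#' @param seed integer seed.
#' @return a [template_library()] whose manifest has columns id, kind
#'   (base/duplicate/jitter), source_id, row, col, shape_id.
#' @export
derive_library <- function(scene, n_templates = 12, duplicate_fraction = 1/3,
                           jitter_fraction = 1/3, jitter = 1, seed = 1) {
  stopifnot(inherits(scene, "synthetic_scene"), n_templates >= 1)
  set.seed(seed)
  shape <- scene$params$template_shape
  truth <- scene$truth
  n_dup <- round(duplicate_fraction * n_templates)
  n_jit <- round(jitter_fraction * n_templates)
  n_base <- n_templates - n_dup - n_jit
  if (n_base < 1L)
    stop("duplicate_fraction + jitter_fraction leave no base templates",
         call. = FALSE)
  if (n_base > nrow(truth))
    stop("n_templates requires ", n_base, " distinct cells but the scene has ",
         nrow(truth), call. = FALSE)

  # base cells: round-robin over shape variants, random cell within each
  by_shape <- split(seq_len(nrow(truth)), truth$shape_id)
  by_shape <- lapply(by_shape, sample)
  base_cells <- integer(0)
  v <- 1L
  while (length(base_cells) < n_base) {
    grp <- by_shape[[((v - 1L) %% length(by_shape)) + 1L]]
    take <- setdiff(grp, base_cells)
    if (length(take)) base_cells <- c(base_cells, take[1L])
    v <- v + 1L
    if (v > 10L * n_base && length(base_cells) < n_base)
      stop("not enough distinct cells for the requested library", call. = FALSE)
  }

  entries <- vector("list", n_templates)
  kind <- character(n_templates); source_id <- character(n_templates)
  cell_row <- cell_col <- sid <- integer(n_templates)
  ids <- sprintf("tpl%02d", seq_len(n_templates))

  for (k in seq_len(n_base)) {
    ci <- base_cells[k]
    entries[[k]] <- .crop(scene$image, c(truth$row[ci], truth$col[ci]), shape)
    kind[k] <- "base"; source_id[k] <- ids[k]
    cell_row[k] <- truth$row[ci]; cell_col[k] <- truth$col[ci]
    sid[k] <- truth$shape_id[ci]
  }
  # jittered re-crops of already-used cells
  jit_src <- sample(rep_len(seq_len(n_base), max(n_jit, 1L)), n_jit)
  for (k in seq_len(n_jit)) {
    src <- jit_src[k]; ci <- base_cells[src]
    off <- c(0L, 0L)
    while (all(off == 0L))
      off <- sample(seq.int(-jitter, jitter), 2L, replace = TRUE)
    pos <- n_base + k
    entries[[pos]] <- .crop(scene$image, c(truth$row[ci], truth$col[ci]),
                            shape, off)
    kind[pos] <- "jitter"; source_id[pos] <- ids[src]
    cell_row[pos] <- truth$row[ci]; cell_col[pos] <- truth$col[ci]
    sid[pos] <- truth$shape_id[ci]
  }
  # exact duplicates of distinct earlier entries where possible
  n_earlier <- n_base + n_jit
  dup_src <- if (n_dup <= n_earlier) sample.int(n_earlier, n_dup)
             else sample(rep_len(seq_len(n_earlier), n_dup), n_dup)
  for (k in seq_len(n_dup)) {
    src <- dup_src[k]
    pos <- n_earlier + k
    entries[[pos]] <- entries[[src]]
    kind[pos] <- "duplicate"; source_id[pos] <- ids[src]
    cell_row[pos] <- cell_row[src]; cell_col[pos] <- cell_col[src]
    sid[pos] <- sid[src]
  }

  perm <- sample.int(n_templates)
  # entries are shuffled and re-labelled positionally; old entry o ends up
  # at new position order(perm)[o], so old id ids[o] maps to ids[order(perm)[o]]
  new_id_of_old <- ids[order(perm)]
  manifest <- data.frame(
    id = ids, kind = kind[perm],
    source_id = new_id_of_old[match(source_id[perm], ids)],
    row = cell_row[perm], col = cell_col[perm], shape_id = sid[perm],
    stringsAsFactors = FALSE)
  template_library(entries[perm], ids, manifest = manifest)
}

#' Write a scene to disk
#'
#' Writes the image as PNG (or TIFF by extension) and the ground-truth
#' table as CSV.
#'
#' @param scene a [generate_scene()] result.
#' @param image_path output image path (.png or .tif/.tiff).
#' @param truth_path output CSV path (default: image path with
#'   `_truth.csv`).
#' @export
write_scene <- function(scene, image_path,
                        truth_path = sub("\\.[^.]+$", "_truth.csv", image_path)) {
  stopifnot(inherits(scene, "synthetic_scene"))
  write_sample_image(scene$image, image_path)
  utils::write.csv(scene$truth, truth_path, row.names = FALSE)
  invisible(image_path)
}
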