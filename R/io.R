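# Image I/O: 8/16-bit grayscale PNG and TIFF, color converted to grayscale
# by channel average, plus a marked-overlay writer.

#' Read a grayscale sample image
#'
#' Reads PNG or TIFF (by extension) into a numeric matrix on the \[0, 1\]
#' scale. Color inputs are converted to grayscale by averaging the color
#' channels (luminance average); an alpha channel, if present, is dropped.
#'
#' @param path image file path.
#' @return numeric matrix (rows x cols).
#' @export
read_sample_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use PNG or TIFF): ", path,
         call. = FALSE))
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    ch <- min(nch, 3L)  # drop alpha
    img <- apply(img[, , seq_len(ch), drop = FALSE], c(1L, 2L), mean)
  }
  check_sample_image(img)
  img
}

#' Write a grayscale image
#'
#' Writes a numeric matrix as 8-bit (PNG) or native float (TIFF) grayscale;
#' values are clamped to \[0, 1\].
#'
#' @param image numeric matrix.
#' @param path output path (.png, .tif or .tiff).
#' @export
write_sample_image <- function(image, path) {
  check_sample_image(image)
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)",
         call. = FALSE))
  invisible(path)
}

#' Write a marked-overlay image
#'
#' Reproduces the classic counting visual: the grayscale sample with marked
#' anchors highlighted in red and cluster centroids in green. Mark and
#' centroid positions are shifted by half the template extent so they sit
#' over the detected cell centers.
#'
#' @param sample the sample image (matrix or `synthetic_scene`).
#' @param count a [count_cells()] result for that image.
#' @param path output PNG path.
#' @export
write_overlay_png <- function(sample, count, path) {
  if (inherits(sample, "synthetic_scene")) sample <- sample$image
  check_sample_image(sample)
  stopifnot(inherits(count, "cell_count"))
  img <- pmin(pmax(sample, 0), 1)
  rgb <- array(rep(img, 3L), c(dim(img), 3L))
  half <- (count$surface$template_shape - 1L) %/% 2L
  mk <- which(count$marks$marks, arr.ind = TRUE)
  if (nrow(mk) > 0L) {
    r <- pmin(mk[, 1L] + half[1L], nrow(img))
    c <- pmin(mk[, 2L] + half[2L], ncol(img))
    rgb[cbind(r, c, 1L)] <- 1; rgb[cbind(r, c, 2L)] <- 0
    rgb[cbind(r, c, 3L)] <- 0
  }
  cl <- count$clusters$clusters
  if (nrow(cl) > 0L) {
    r <- pmin(pmax(round(cl$centroid_row) + half[1L], 1L), nrow(img))
    c <- pmin(pmax(round(cl$centroid_col) + half[2L], 1L), ncol(img))
    rgb[cbind(r, c, 1L)] <- 0; rgb[cbind(r, c, 2L)] <- 1
    rgb[cbind(r, c, 3L)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
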