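# Independent brute-force oracles, written before the fast paths they check.

# Per-pixel mean/variance NCC with explicit loops; deliberately shares no
# code with the package implementation.
oracle_ncc <- function(sample, template, i, j) {
  K <- nrow(template); L <- ncol(template)
  wm <- 0; fm <- 0
  for (x in 1:K) for (y in 1:L) {
    wm <- wm + template[x, y]
    fm <- fm + sample[i + x - 1L, j + y - 1L]
  }
  wm <- wm / (K * L); fm <- fm / (K * L)
  num <- 0; dw <- 0; df <- 0
  for (x in 1:K) for (y in 1:L) {
    a <- template[x, y] - wm
    b <- sample[i + x - 1L, j + y - 1L] - fm
    num <- num + a * b
    dw <- dw + a * a
    df <- df + b * b
  }
  if (df <= 1e-12) return(0)
  num / sqrt(dw * df)
}

# Connected components of a logical matrix where cells link iff their
# Chebyshev distance is <= radius: O(n^2) union-find over marked points.
oracle_components <- function(mask, radius) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (a in seq_len(n - 1L)) {
    if (n < 2L) break
    for (b in (a + 1L):n) {
      d <- max(abs(pts[a, 1L] - pts[b, 1L]), abs(pts[a, 2L] - pts[b, 2L]))
      if (d <= radius) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1L))))
}

# Small default scene shared by the slower end-to-end tests.
tiny_scene <- function(seed = 1, n_cells = 10, ...) {
  generate_scene(n_cells = n_cells, image_shape = c(120, 160),
                 min_separation = 22, seed = seed, ...)
}

# Build an ncc_surface-like object directly from a value matrix (for
# detection tests that need exact hand-chosen surfaces).
surface_from_values <- function(values, evaluated = NULL) {
  if (is.null(evaluated)) evaluated <- matrix(TRUE, nrow(values), ncol(values))
  v <- values
  v[!evaluated] <- NA_real_
  structure(list(values = v, evaluated = evaluated,
                 template_shape = c(1L, 1L), argmax = NULL,
                 template_ids = NULL, eval_count = sum(evaluated)),
            class = "ncc_surface")
}
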