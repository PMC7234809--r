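# Image-pair similarity metrics used as the across-context perceptual
# regressor: RGB-histogram sum-of-squared-differences, HOG-vector
# correlation, and a pluggable keypoint-descriptor distance.
#
# Images are integer arrays h x w x 3 with 8-bit intensities (0-255).

check_image_pair <- function(a, b) {
  if (length(dim(a)) != 3L || length(dim(b)) != 3L ||
      dim(a)[3L] != 3L || dim(b)[3L] != 3L) {
    stop("images must be h x w x 3 arrays", call. = FALSE)
  }
  if (!all(dim(a) == dim(b))) {
    stop("image shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  rng <- range(a, b)
  if (rng[1L] < 0 || rng[2L] > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read an RGB raster image as a 0-255 array
#'
#' @param path PNG file path (requires the `png` package).
#' @return Integer array h x w x 3 with values 0-255.
#' @export
read_image_rgb <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG images requires the 'png' package", call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3L] >= 3L) img <- img[, , 1:3, drop = FALSE]
  else img <- array(img[, , 1L], c(dim(img)[1:2], 3L))
  array(as.integer(round(img * 255)), dim = dim(img))
}

#' RGB-histogram sum of squared differences
#'
#' For each color channel, pixel counts are accumulated over the 256
#' intensity bins (0-255); the score is the sum over channels and bins of
#' squared count differences. Zero for identical images; smaller means
#' more similar. Position-invariant by construction.
#'
#' @param a,b images (h x w x 3, 0-255).
#' @return Non-negative scalar.
#' @export
rgb_histogram_ssd <- function(a, b) {
  check_image_pair(a, b)
  total <- 0
  for (ch in 1:3) {
    ha <- tabulate(as.integer(a[, , ch]) + 1L, nbins = 256L)
    hb <- tabulate(as.integer(b[, , ch]) + 1L, nbins = 256L)
    total <- total + sum((ha - hb)^2)
  }
  total
}

# Luminance as the channel mean, gradient by central differences.
to_gray <- function(img) (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3

image_gradients <- function(g) {
  h <- nrow(g); w <- ncol(g)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1L)] <- (g[, 3:w] - g[, 1:(w - 2L)]) / 2
  gy[2:(h - 1L), ] <- (g[3:h, ] - g[1:(h - 2L), ]) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2),
       # unsigned orientation in [0, pi)
       ori = (atan2(gy, gx) + pi) %% pi)
}

# Magnitude-weighted orientation histograms over fixed-size cells,
# concatenated row-major; incomplete border cells are dropped.
hog_vector <- function(img, cell_px = 16L, n_orientations = 8L) {
  g <- to_gray(img)
  if (nrow(g) < cell_px || ncol(g) < cell_px) {
    stop("image smaller than one HOG cell (", cell_px, " px)",
         call. = FALSE)
  }
  gr <- image_gradients(g)
  n_cy <- nrow(g) %/% cell_px
  n_cx <- ncol(g) %/% cell_px
  bin <- pmin(floor(gr$ori / pi * n_orientations) + 1L, n_orientations)
  out <- numeric(n_cy * n_cx * n_orientations)
  k <- 0L
  for (cy in seq_len(n_cy)) {
    for (cx in seq_len(n_cx)) {
      ry <- ((cy - 1L) * cell_px + 1L):(cy * cell_px)
      rx <- ((cx - 1L) * cell_px + 1L):(cx * cell_px)
      h <- vapply(seq_len(n_orientations), function(b) {
        sum(gr$mag[ry, rx][bin[ry, rx] == b])
      }, numeric(1))
      out[(k + 1L):(k + n_orientations)] <- h
      k <- k + n_orientations
    }
  }
  out
}

#' Histogram-of-oriented-gradients similarity
#'
#' Builds magnitude-weighted gradient-orientation histograms over
#' fixed-size cells for both images, concatenates them, and returns the
#' Pearson correlation of the two vectors. Sensitive to edge orientation,
#' so a rotated copy scores lower than the original.
#'
#' @param a,b images (h x w x 3, 0-255).
#' @param cell_px cell size in pixels (default 16).
#' @param n_orientations orientation bins over 0-180 degrees (default 8).
#' @return Correlation in `[-1, 1]`.
#' @export
hog_similarity <- function(a, b, cell_px = 16L, n_orientations = 8L) {
  check_image_pair(a, b)
  va <- hog_vector(a, cell_px, n_orientations)
  vb <- hog_vector(b, cell_px, n_orientations)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero-gradient image: HOG correlation undefined", call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Built-in Harris-corner patch-descriptor backend
#'
#' A simple, fully in-package keypoint backend: corners are local maxima
#' of the Harris response, and each keypoint's descriptor is its
#' surrounding grayscale patch, normalized to zero mean and unit norm.
#' Tolerant of mild photometric changes; it is not a SURF implementation
#' (no scale/rotation invariance).
#'
#' @param max_keypoints keep at most this many strongest corners.
#' @param patch_px descriptor patch side length (odd; default 9).
#' @param kappa Harris sensitivity constant (default 0.05).
#' @return A backend function `image -> list(keypoints, descriptors)`.
#' @export
patch_descriptor_backend <- function(max_keypoints = 100L, patch_px = 9L,
                                     kappa = 0.05) {
  stopifnot(patch_px %% 2L == 1L)
  half <- patch_px %/% 2L
  function(img) {
    g <- to_gray(img)
    gr <- image_gradients(g)
    sxx <- box_blur(gr$gx^2); syy <- box_blur(gr$gy^2)
    sxy <- box_blur(gr$gx * gr$gy)
    resp <- (sxx * syy - sxy^2) - kappa * (sxx + syy)^2
    h <- nrow(g); w <- ncol(g)
    ok <- matrix(FALSE, h, w)
    inner_r <- (half + 2L):(h - half - 1L)
    inner_c <- (half + 2L):(w - half - 1L)
    if (length(inner_r) < 1L || length(inner_c) < 1L) {
      return(list(keypoints = matrix(numeric(0), 0, 2),
                  descriptors = matrix(numeric(0), 0, patch_px^2)))
    }
    for (r in inner_r) for (cc in inner_c) {
      v <- resp[r, cc]
      if (v > 0 && v == max(resp[(r - 1L):(r + 1L), (cc - 1L):(cc + 1L)])) {
        ok[r, cc] <- TRUE
      }
    }
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      return(list(keypoints = matrix(numeric(0), 0, 2),
                  descriptors = matrix(numeric(0), 0, patch_px^2)))
    }
    strength <- resp[ok]
    keep <- order(strength, decreasing = TRUE)[
      seq_len(min(max_keypoints, nrow(idx)))]
    idx <- idx[keep, , drop = FALSE]
    desc <- t(apply(idx, 1L, function(rc) {
      p <- g[(rc[1L] - half):(rc[1L] + half),
             (rc[2L] - half):(rc[2L] + half)]
      p <- p - mean(p)
      nrm <- sqrt(sum(p^2))
      if (nrm > 0) p <- p / nrm
      as.numeric(p)
    }))
    list(keypoints = idx, descriptors = desc)
  }
}

box_blur <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  out[2:(h - 1L), ] <- (m[1:(h - 2L), ] + m[2:(h - 1L), ] + m[3:h, ]) / 3
  m2 <- out
  out[, 2:(w - 1L)] <- (m2[, 1:(w - 2L)] + m2[, 2:(w - 1L)] +
                          m2[, 3:w]) / 3
  out
}

#' Mean matched keypoint-descriptor distance
#'
#' Detects keypoints and descriptors in both images with the supplied
#' backend, matches each descriptor to its nearest neighbour in the other
#' image by Euclidean distance (both directions, so the score is
#' symmetric), and returns the mean matched distance; lower means more
#' similar.
#'
#' @param a,b images (h x w x 3, 0-255).
#' @param backend a function `image -> list(keypoints, descriptors)`;
#'   default [patch_descriptor_backend()]. Pass any SURF-like detector
#'   with the same contract to swap the descriptor stage.
#' @return List with `mean_distance` and `n_matches`.
#' @export
keypoint_descriptor_distance <- function(a, b,
                                         backend =
                                           patch_descriptor_backend()) {
  check_image_pair(a, b)
  if (!is.function(backend)) {
    stop("capability error: no keypoint-descriptor backend available; ",
         "supply a function(image) -> list(keypoints, descriptors), ",
         "e.g. patch_descriptor_backend()", call. = FALSE)
  }
  da <- backend(a)$descriptors
  db <- backend(b)$descriptors
  if (nrow(da) == 0L || nrow(db) == 0L) {
    stop("no keypoints detected in one or both images", call. = FALSE)
  }
  nn_dist <- function(x, y) {
    # rows of x matched to nearest rows of y
    cross <- x %*% t(y)
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * cross
    sqrt(pmax(apply(d2, 1L, min), 0))
  }
  d <- c(nn_dist(da, db), nn_dist(db, da))
  list(mean_distance = mean(d), n_matches = length(d))
}
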