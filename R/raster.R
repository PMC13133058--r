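#' @useDynLib veinfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- raster images -----------------------------------------------------
#
# Images are plain numeric matrices (H x W, grayscale) or H x W x 3 arrays
# (RGB). Two value ranges are supported, mirroring common file formats:
# "unit" (float in [0,1]) and "uint8" (integers in [0,255]). The range is
# inferred from the data; all operations preserve the range of their input.

#' Infer the intensity scale of a raster image
#'
#' @param img numeric matrix or array.
#' @return 1 for unit-range floats, 255 for 8-bit images.
#' @keywords internal
raster_scale <- function(img) {
  if (!is.numeric(img)) stop("image must be numeric")
  if (any(!is.finite(img))) stop("image contains non-finite values")
  if (max(img) > 1 + 1e-9) 255 else 1
}

n_channels <- function(img) {
  if (is.matrix(img)) 1L else if (length(dim(img)) == 3L) dim(img)[3L] else
    stop("image must be a matrix or a 3-d array")
}

assert_gray <- function(img) {
  if (n_channels(img) != 1L) stop("expected a single-channel image")
  invisible(img)
}

assert_rgb <- function(img) {
  if (n_channels(img) != 3L) stop("expected a 3-channel RGB image")
  invisible(img)
}

assert_binary <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be strictly two-valued {0,1}")
  invisible(mask)
}

clip_range <- function(img, scale) pmin(pmax(img, 0), scale)

#' Convert an RGB image to grayscale
#'
#' BT.601 luminance: `0.299 R + 0.587 G + 0.114 B`. The value range of the
#' input (unit float or 8-bit) is preserved; 8-bit inputs are rounded to
#' integer intensities.
#'
#' @param rgb H x W x 3 numeric array.
#' @return H x W numeric matrix.
#' @export
to_grayscale <- function(rgb) {
  assert_rgb(rgb)
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  if (raster_scale(rgb) == 255) g <- round(g)
  g
}

#' Structuring element for morphological operations
#'
#' @param shape one of "ellipse", "disk", "square" ("ellipse" and "disk"
#'   are synonyms: a discrete disc).
#' @param size odd side length in pixels, >= 1.
#' @return object of class `struct_elem` wrapping a 0/1 kernel matrix.
#' @export
struct_elem <- function(shape = c("ellipse", "disk", "square"), size = 3L) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("structuring element size must be odd and >= 1")
  kern <- if (size == 1L) matrix(1, 1, 1) else if (shape == "square") {
    matrix(1, size, size)
  } else {
    # discrete disc: offsets within Euclidean radius (size-1)/2
    r <- (size - 1L) / 2
    ax <- -r:r
    (outer(ax^2, ax^2, `+`) <= r^2 + 1e-9) * 1
  }
  structure(list(shape = shape, size = size, kernel = kern),
            class = "struct_elem")
}

se_kernel <- function(se) {
  if (inherits(se, "struct_elem")) se$kernel else se
}

# Reflect-pad an image by `p` pixels on every side.
pad_reflect <- function(img, p) {
  if (p == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  ri <- c(pmin(p:1, h), seq_len(h), h + 1 - pmin(1:p, h))
  ci <- c(pmin(p:1, w), seq_len(w), w + 1 - pmin(1:p, w))
  img[ri, ci, drop = FALSE]
}

# 2-D correlation with reflect border handling (kernel must be odd-sized).
conv_reflect <- function(img, kernel) {
  k <- nrow(kernel)
  p <- (k - 1L) %/% 2L
  padded <- pad_reflect(img, p)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  if (p > 0) out <- out[(p + 1):(p + nrow(img)), (p + 1):(p + ncol(img)), drop = FALSE]
  out
}

gaussian_kernel <- function(sigma, size = NULL) {
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  ax <- seq_len(size) - (size + 1) / 2
  g <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# HSV (h in [0,360), s,v in [0,1]) -> RGB in [0,1]; vectorised.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- i %% 6
  r[idx == 0] <- v[idx == 0]; g[idx == 0] <- t[idx == 0]; b[idx == 0] <- p[idx == 0]
  r[idx == 1] <- q[idx == 1]; g[idx == 1] <- v[idx == 1]; b[idx == 1] <- p[idx == 1]
  r[idx == 2] <- p[idx == 2]; g[idx == 2] <- v[idx == 2]; b[idx == 2] <- t[idx == 2]
  r[idx == 3] <- p[idx == 3]; g[idx == 3] <- q[idx == 3]; b[idx == 3] <- v[idx == 3]
  r[idx == 4] <- t[idx == 4]; g[idx == 4] <- p[idx == 4]; b[idx == 4] <- v[idx == 4]
  r[idx == 5] <- v[idx == 5]; g[idx == 5] <- p[idx == 5]; b[idx == 5] <- q[idx == 5]
  cbind(r, g, b)
}

# Evaluate an expression with a private RNG stream, restoring the caller's
# RNG state afterwards (the expression is forced after set.seed).
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
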