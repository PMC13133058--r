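# ---- classical vein-map extraction ------------------------------------
#
# Eight-stage binarization flow turning an RGB leaf photo into a clean
# binary vein map: leaf segmentation (Otsu + largest contour + closing),
# CLAHE, homomorphic illumination correction, oriented Gabor bank with
# max-response pooling, weighted fusion, selective unsharp masking,
# percentile stretch + adaptive mean thresholding, and morphological
# cleanup. Veins are treated as locally *bright* structures of the
# enhanced image (the Gabor max-response makes them bright regardless of
# their raw polarity).

#' Configuration of the vein-extraction pipeline
#'
#' Houses every free parameter of the eight stages. The flow itself fixes
#' only the Gabor orientations (0--150 degrees in 30-degree steps) and
#' the equal fusion weights; the remaining defaults are standard values,
#' exposed here so that nothing is hard-coded.
#'
#' @param clahe_tiles tile grid `c(nx, ny)`.
#' @param clahe_clip relative clip limit (> 0), in units of the uniform
#'   histogram level (2 means "twice the average bin count").
#' @param homo_A high-frequency amplification (>= 0).
#' @param homo_B low-frequency gain (>= 0).
#' @param homo_k transition sharpness (> 0).
#' @param homo_D0 cutoff frequency in cycles across the image (> 0).
#' @param gabor_orientations_deg filter orientations in degrees.
#' @param gabor_scales odd kernel side lengths in pixels.
#' @param gabor_lambda sinusoid wavelength in pixels (> 0).
#' @param gabor_sigma Gaussian envelope scale in pixels (> 0).
#' @param gabor_gamma_aspect envelope aspect ratio (> 0).
#' @param gabor_psi carrier phase in radians.
#' @param fuse_w1,fuse_w2 fusion weights, must sum to 1.
#' @param fuse_bias additive bias (0--255 scale).
#' @param unsharp_alpha sharpening strength (> 0).
#' @param unsharp_sigma Gaussian blur scale of the low-pass (pixels).
#' @param adapt_window odd side of the local-mean neighbourhood.
#' @param adapt_C offset subtracted from the local mean (0--255 scale).
#' @param stretch_percentiles `c(p_low, p_high)` percentiles (0--100)
#'   mapped to the range ends before thresholding.
#' @param min_object_area components smaller than this many pixels are
#'   removed.
#' @param opening_se,closing_se [struct_elem()] for opening/closing.
#' @param median_kernel odd side of the final median filter (1 = off).
#' @return a `vein_pipeline_config` list.
#' @export
vein_pipeline_config <- function(clahe_tiles = c(8L, 8L),
                                 clahe_clip = 2,
                                 homo_A = 1.5, homo_B = 0.5,
                                 homo_k = 1, homo_D0 = 30,
                                 gabor_orientations_deg = c(0, 30, 60, 90, 120, 150),
                                 gabor_scales = c(15L, 21L),
                                 gabor_lambda = 8, gabor_sigma = 4,
                                 gabor_gamma_aspect = 0.5, gabor_psi = 0,
                                 fuse_w1 = 0.5, fuse_w2 = 0.5, fuse_bias = 0,
                                 unsharp_alpha = 1.0, unsharp_sigma = 2,
                                 adapt_window = 25L, adapt_C = 5,
                                 stretch_percentiles = c(2, 98),
                                 min_object_area = 30L,
                                 opening_se = struct_elem("ellipse", 3L),
                                 closing_se = struct_elem("ellipse", 7L),
                                 median_kernel = 3L) {
  if (abs(fuse_w1 + fuse_w2 - 1) > 1e-9) stop("fuse_w1 + fuse_w2 must equal 1")
  if (adapt_window %% 2L == 0L) stop("adapt_window must be odd")
  if (median_kernel %% 2L == 0L) stop("median_kernel must be odd")
  if (any(gabor_scales %% 2L == 0L)) stop("gabor_scales must be odd")
  if (stretch_percentiles[1] >= stretch_percentiles[2])
    stop("stretch_percentiles must satisfy p_low < p_high")
  if (homo_D0 <= 0) stop("homo_D0 must be > 0")
  structure(as.list(environment()), class = "vein_pipeline_config")
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustive 256-bin histogram scan maximizing the between-class variance
#' between foreground and background. When several thresholds attain the
#' maximal variance (a flat plateau across an empty histogram gap), the
#' centre of the plateau is returned. For a constant image the threshold
#' is defined as that constant and the mask is all-zero (with a warning).
#'
#' @param gray single-channel image.
#' @return list with `threshold` (on the image's intensity scale) and
#'   `mask` (H x W in `{0,1}`, 1 where `gray > threshold`).
#' @export
otsu_threshold <- function(gray) {
  assert_gray(gray)
  scale <- raster_scale(gray)
  b <- round(gray / scale * 255)
  if (max(b) == min(b)) {
    warning("constant image: Otsu threshold degenerate, returning empty mask")
    return(list(threshold = gray[1], mask = gray * 0))
  }
  hist <- tabulate(b + 1L, nbins = 256L)
  p <- hist / sum(hist)
  levels <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  # between-class variance for threshold t = foreground strictly above t
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  plateau <- which(sigma_b >= max(sigma_b) - 1e-9 * abs(max(sigma_b)))
  t_bin <- levels[floor(mean(range(plateau)))]
  thr <- t_bin / 255 * scale
  list(threshold = thr, mask = (b > t_bin) * 1)
}

.border_fraction <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  border <- c(mask[1, ], mask[h, ], mask[, 1], mask[, w])
  mean(border)
}

.largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask * 0)
  areas <- tabulate(lab[lab > 0])
  (lab == which.max(areas)) * 1
}

#' Segment the leaf blade from an RGB photo
#'
#' Otsu-binarizes the grayscale image, picks the foreground polarity as
#' the side of the threshold with the smaller border occupancy (the leaf
#' is central; the background touches the frame), keeps the largest
#' connected component, closes it with an elliptical structuring element
#' and fills fully enclosed holes.
#'
#' @param rgb H x W x 3 image.
#' @param closing_se [struct_elem()] used for morphological closing.
#' @return binary H x W leaf mask.
#' @export
leaf_mask <- function(rgb, closing_se = struct_elem("ellipse", 7L)) {
  assert_rgb(rgb)
  gray <- to_grayscale(rgb)
  ot <- withCallingHandlers(
    otsu_threshold(gray),
    warning = function(w) invokeRestart("muffleWarning"))
  mask <- ot$mask
  inv <- 1 - mask
  if (.border_fraction(mask) > .border_fraction(inv)) mask <- inv
  if (sum(mask) == 0)
    stop("empty foreground after Otsu segmentation of the leaf image")
  mask <- .largest_component(mask)
  mask <- (EBImage::closing(mask, se_kernel(closing_se)) > 0.5) * 1
  mask <- (EBImage::fillHull(mask) > 0.5) * 1
  mask
}

#' Contrast-limited adaptive histogram equalization
#'
#' Standard clip-then-redistribute CLAHE: the image is divided into a tile
#' grid, each tile's 256-bin histogram is clipped at the clip limit with
#' the excess redistributed uniformly, per-tile equalization mappings are
#' built from the clipped CDFs, and pixels are remapped by bilinear
#' interpolation between the four surrounding tile mappings. The value
#' range of the input is preserved.
#'
#' @param gray single-channel image.
#' @param tiles `c(nx, ny)` tile grid (columns x rows).
#' @param clip relative clip limit (> 0); large values disable clipping.
#' @return enhanced image, same dimensions and range.
#' @export
clahe <- function(gray, tiles = c(8L, 8L), clip = 2) {
  assert_gray(gray)
  if (clip <= 0) stop("clip limit must be > 0")
  scale <- raster_scale(gray)
  h <- nrow(gray); w <- ncol(gray)
  nx <- as.integer(tiles[1]); ny <- as.integer(if (length(tiles) > 1) tiles[2] else tiles[1])
  if (w %/% nx < 1 || h %/% ny < 1) {
    nx <- max(1L, min(nx, w)); ny <- max(1L, min(ny, h))
    message("clahe: tile grid reduced to ", nx, "x", ny, " to fit the image")
  }
  b <- round(gray / scale * 255)
  tile_h <- h / ny; tile_w <- w / nx
  # per-tile clipped-CDF mappings, 256 x ny x nx
  maps <- array(0, c(256, ny, nx))
  for (ty in seq_len(ny)) {
    r0 <- floor((ty - 1) * tile_h) + 1; r1 <- floor(ty * tile_h)
    for (tx in seq_len(nx)) {
      c0 <- floor((tx - 1) * tile_w) + 1; c1 <- floor(tx * tile_w)
      vals <- b[r0:r1, c0:c1]
      npix <- length(vals)
      hist <- tabulate(vals + 1L, nbins = 256L)
      limit <- max(clip * npix / 256, 1)
      excess <- sum(pmax(hist - limit, 0))
      hist <- pmin(hist, limit) + excess / 256
      maps[, ty, tx] <- round(cumsum(hist) * 255 / npix)
    }
  }
  # bilinear blend between tile-centre mappings
  rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  fy <- (rows - 0.5) / tile_h - 0.5; fx <- (cols - 0.5) / tile_w - 0.5
  y0 <- pmin(pmax(floor(fy), 0), ny - 1); x0 <- pmin(pmax(floor(fx), 0), nx - 1)
  y1 <- pmin(y0 + 1, ny - 1); x1 <- pmin(x0 + 1, nx - 1)
  wy <- pmin(pmax(fy - y0, 0), 1); wx <- pmin(pmax(fx - x0, 0), 1)
  bi <- as.vector(b) + 1
  g00 <- maps[cbind(bi, as.vector(y0) + 1, as.vector(x0) + 1)]
  g10 <- maps[cbind(bi, as.vector(y1) + 1, as.vector(x0) + 1)]
  g01 <- maps[cbind(bi, as.vector(y0) + 1, as.vector(x1) + 1)]
  g11 <- maps[cbind(bi, as.vector(y1) + 1, as.vector(x1) + 1)]
  out <- (1 - wy) * (1 - wx) * g00 + wy * (1 - wx) * g10 +
    (1 - wy) * wx * g01 + wy * wx * g11
  matrix(out, h, w) / 255 * scale
}

# Centered radial frequency distance for an h x w spectrum.
.freq_dist <- function(h, w) {
  fy <- c(0:floor(h / 2), -((ceiling(h / 2) - 1):1))  # cycles per image
  fx <- c(0:floor(w / 2), -((ceiling(w / 2) - 1):1))
  outer(fy^2, fx^2, `+`)^0.5
}

.homo_H <- function(D, A, B, k, D0) B + A * (1 - exp(-k * D^2 / D0^2))

#' Homomorphic illumination correction
#'
#' Log-transforms the image (`log(1 + I)` to tolerate zeros), applies the
#' Gaussian-style high-emphasis transfer function
#' `H(u,v) = B + A (1 - exp(-k D(u,v)^2 / D0^2))` in the 2-D Fourier
#' domain (D = distance from the centred zero frequency, in cycles per
#' image), inverse-transforms, exponentiates and min-max normalizes back
#' to the input range. With `A > 0` high frequencies (reflectance detail)
#' are amplified relative to the low-frequency illumination field.
#'
#' @param gray single-channel image.
#' @param A high-frequency amplification (>= 0).
#' @param B low-frequency gain (>= 0); `H` equals `B` at zero frequency
#'   and approaches `A + B` at high frequency.
#' @param k transition sharpness (> 0).
#' @param D0 cutoff frequency (> 0).
#' @return filtered image, same dimensions and range.
#' @export
homomorphic_filter <- function(gray, A = 1.5, B = 0.5, k = 1, D0 = 30) {
  assert_gray(gray)
  if (D0 <= 0) stop("D0 must be > 0")
  scale <- raster_scale(gray)
  x <- gray / scale
  L <- log1p(x)
  FL <- stats::fft(L)
  H <- .homo_H(.freq_dist(nrow(x), ncol(x)), A, B, k, D0)
  out <- Re(stats::fft(FL * H, inverse = TRUE)) / length(L)
  out <- expm1(out)
  rng <- range(out)
  if (diff(rng) < 1e-12) return(gray)
  (out - rng[1]) / diff(rng) * scale
}

#' Build one Gabor kernel
#'
#' `g(x,y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) cos(2 pi x'/lambda + psi)`
#' with `x' = x cos(theta) + y sin(theta)`, `y' = -x sin(theta) + y cos(theta)`.
#'
#' @param size odd kernel side length.
#' @param theta_deg orientation in degrees.
#' @param lambda wavelength (pixels), `sigma` envelope scale, `gamma`
#'   aspect ratio, `psi` phase.
#' @param lambda,sigma,gamma,psi Gabor parameters.
#' @return size x size numeric kernel (rows = y, columns = x).
#' @export
gabor_kernel <- function(size, theta_deg, lambda = 8, sigma = 4,
                         gamma = 0.5, psi = 0) {
  size <- as.integer(size)
  if (size %% 2L == 0L) stop("Gabor kernel size must be odd")
  half <- (size - 1L) %/% 2L
  ax <- -half:half
  x <- matrix(ax, size, size, byrow = TRUE)   # columns = x
  y <- matrix(ax, size, size)                 # rows = y
  th <- theta_deg * pi / 180
  xp <- x * cos(th) + y * sin(th)
  yp <- -x * sin(th) + y * cos(th)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / lambda + psi)
}

#' Maximum response over a Gabor filter bank
#'
#' Convolves the image with every (orientation, scale) kernel of the bank
#' and keeps the pixel-wise maximum response, preserving the strongest
#' vein evidence regardless of local orientation. The result is min-max
#' rescaled to the input range.
#'
#' @param gray single-channel image.
#' @param orientations_deg orientations in degrees (non-empty).
#' @param scales odd kernel sizes.
#' @param lambda,sigma,gamma,psi Gabor parameters, see [gabor_kernel()].
#' @return response image, same dimensions and range.
#' @export
gabor_max_response <- function(gray,
                               orientations_deg = c(0, 30, 60, 90, 120, 150),
                               scales = c(15L, 21L),
                               lambda = 8, sigma = 4, gamma = 0.5, psi = 0) {
  assert_gray(gray)
  if (length(orientations_deg) == 0) stop("orientations must be non-empty")
  scale <- raster_scale(gray)
  x <- gray / scale
  best <- matrix(-Inf, nrow(x), ncol(x))
  for (s in scales) for (th in orientations_deg) {
    k <- gabor_kernel(s, th, lambda, sigma, gamma, psi)
    best <- pmax(best, conv_reflect(x, k))
  }
  rng <- range(best)
  if (diff(rng) < 1e-12) return(gray * 0)
  (best - rng[1]) / diff(rng) * scale
}

#' Weighted fusion of two images
#'
#' `w1 * img1 + w2 * img2 + bias`, clipped to the shared value range.
#'
#' @param img1,img2 images of identical dimensions and range.
#' @param w1,w2 weights summing to 1.
#' @param bias additive bias on the images' intensity scale.
#' @return fused image.
#' @export
weighted_fuse <- function(img1, img2, w1 = 0.5, w2 = 0.5, bias = 0) {
  if (!identical(dim(img1), dim(img2))) stop("images must share dimensions")
  if (abs(w1 + w2 - 1) > 1e-9) stop("w1 + w2 must equal 1")
  scale <- max(raster_scale(img1), raster_scale(img2))
  clip_range(w1 * img1 + w2 * img2 + bias, scale)
}

#' Selective unsharp masking
#'
#' `I + alpha (I - I_blur)` with a Gaussian low-pass of scale `sigma`,
#' applied only where `interior == 1`; pixels outside the interior mask
#' are returned unchanged. Clipped to the input range.
#'
#' @param img single-channel image.
#' @param alpha sharpening strength (>= 0).
#' @param sigma Gaussian blur scale in pixels.
#' @param interior binary mask of the same dimensions (1 = sharpen here);
#'   `NULL` sharpens everywhere.
#' @return sharpened image.
#' @export
unsharp_sharpen <- function(img, alpha = 1.0, sigma = 2, interior = NULL) {
  assert_gray(img)
  if (alpha < 0) stop("alpha must be >= 0")
  if (is.null(interior)) interior <- img * 0 + 1
  if (!identical(dim(interior), dim(img)))
    stop("interior mask must match image dimensions")
  scale <- raster_scale(img)
  blur <- conv_reflect(img, gaussian_kernel(sigma))
  sharp <- clip_range(img + alpha * (img - blur), scale)
  img * (1 - interior) + sharp * interior
}

#' Percentile stretch followed by adaptive mean thresholding
#'
#' Intensities are first contrast-stretched so that the `p_low` and
#' `p_high` percentiles map to the range ends. Each pixel is then compared
#' with the mean of its `window x window` neighbourhood (reflect border
#' handling): the output is 1 where the stretched value exceeds the local
#' mean by more than the offset `C` (expressed on the 0--255 scale), i.e.
#' veins are the locally *bright* structures of the enhanced image, and a
#' flat neighbourhood never fires. Near-constant inputs (dynamic range
#' below one 8-bit intensity unit) short-circuit to an all-zero mask.
#'
#' @param img single-channel image.
#' @param window odd neighbourhood side, smaller than the image.
#' @param C offset subtracted from the local mean (0--255 scale).
#' @param percentiles `c(p_low, p_high)` in 0--100.
#' @return binary mask.
#' @export
adaptive_binarize <- function(img, window = 25L, C = 5,
                              percentiles = c(2, 98)) {
  assert_gray(img)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window >= min(dim(img))) stop("window must be smaller than the image")
  scale <- raster_scale(img)
  if (diff(range(img)) < scale / 255) return(img * 0)
  q <- stats::quantile(img, percentiles / 100, names = FALSE)
  if (q[2] - q[1] < 1e-12) q <- range(img)
  stretched <- clip_range((img - q[1]) / (q[2] - q[1]) * scale, scale)
  box <- matrix(1 / window^2, window, window)
  local_mean <- conv_reflect(stretched, box)
  (stretched > local_mean + C / 255 * scale) * 1
}

#' Clean a binary mask
#'
#' Removes connected components below an area threshold, applies a
#' morphological opening and a final median filter.
#'
#' @param mask binary image.
#' @param min_area components with fewer pixels are dropped.
#' @param opening_se [struct_elem()] for the opening (size 1 = no-op).
#' @param median_kernel odd median window (1 = off).
#' @return cleaned binary mask.
#' @export
clean_mask <- function(mask, min_area = 30L,
                       opening_se = struct_elem("ellipse", 3L),
                       median_kernel = 3L) {
  assert_binary(mask)
  if (min_area > 0 && sum(mask) > 0) {
    lab <- EBImage::bwlabel(mask)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0])
      keep <- which(areas >= min_area)
      mask <- (lab %in% keep) * 1
      dim(mask) <- dim(lab)
    }
  }
  se <- se_kernel(opening_se)
  if (nrow(se) > 1) mask <- (EBImage::opening(mask, se) > 0.5) * 1
  if (median_kernel > 1 && sum(mask) > 0) {
    r <- (as.integer(median_kernel) - 1L) %/% 2L
    mask <- (EBImage::medianFilter(mask, r) > 0.5) * 1
  }
  mask
}

#' Morphological thinning (Zhang-Suen)
#'
#' Optional post-processing that reduces the binary vein map to unit-width
#' centrelines. Off by default throughout the package: the extraction flow
#' itself ends at median filtering.
#'
#' @param mask binary image.
#' @param max_iter safety bound on thinning sweeps.
#' @return thinned binary mask.
#' @export
thin_mask <- function(mask, max_iter = 100L) {
  assert_binary(mask)
  m <- mask
  h <- nrow(m); w <- ncol(m)
  pad <- function(x) { y <- matrix(0, h + 2, w + 2); y[2:(h + 1), 2:(w + 1)] <- x; y }
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (phase in 0:1) {
      p <- pad(m)
      ri <- 2:(h + 1); ci <- 2:(w + 1)
      p2 <- p[ri - 1, ci];     p3 <- p[ri - 1, ci + 1]
      p4 <- p[ri, ci + 1];     p5 <- p[ri + 1, ci + 1]
      p6 <- p[ri + 1, ci];     p7 <- p[ri + 1, ci - 1]
      p8 <- p[ri, ci - 1];     p9 <- p[ri - 1, ci - 1]
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seq1 <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- Reduce(`+`, lapply(1:8, function(i) (seq1[[i]] == 0) & (seq1[[i + 1]] == 1)))
      cond <- m == 1 & bsum >= 2 & bsum <= 6 & a == 1
      cond <- cond & if (phase == 0) (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
        else (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Extract a binary vein map from an RGB leaf photo
#'
#' Composes the full eight-stage flow: grayscale conversion, leaf
#' segmentation, CLAHE, homomorphic filtering, Gabor max-response,
#' weighted fusion of the homomorphic and Gabor images, selective unsharp
#' masking on the (eroded) leaf interior, percentile stretch + adaptive
#' thresholding, intersection with the leaf mask, and morphological
#' cleanup. Stage failures are re-raised with the stage name attached.
#'
#' @param rgb H x W x 3 leaf image on a clean background.
#' @param cfg a [vein_pipeline_config()].
#' @param thin apply a final morphological thinning ([thin_mask()]).
#' @return list with `vein` (binary vein map), `leaf` (binary leaf mask)
#'   and `intermediates` (named list of per-stage images).
#' @export
extract_veins <- function(rgb, cfg = vein_pipeline_config(), thin = FALSE) {
  assert_rgb(rgb)
  inter <- list()
  stage <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    inter[[name]] <<- out
    out
  }
  gray <- stage("grayscale", function() to_grayscale(rgb))
  leaf <- stage("leaf_mask", function() leaf_mask(rgb, cfg$closing_se))
  enh <- stage("clahe", function() clahe(gray, cfg$clahe_tiles, cfg$clahe_clip))
  homo <- stage("homomorphic", function()
    homomorphic_filter(enh, cfg$homo_A, cfg$homo_B, cfg$homo_k, cfg$homo_D0))
  gab <- stage("gabor", function()
    gabor_max_response(homo, cfg$gabor_orientations_deg, cfg$gabor_scales,
                       cfg$gabor_lambda, cfg$gabor_sigma,
                       cfg$gabor_gamma_aspect, cfg$gabor_psi))
  fused <- stage("fuse", function()
    weighted_fuse(homo, gab, cfg$fuse_w1, cfg$fuse_w2, cfg$fuse_bias))
  interior <- (EBImage::erode(leaf, se_kernel(struct_elem("ellipse", 5L))) > 0.5) * 1
  sharp <- stage("unsharp", function()
    unsharp_sharpen(fused, cfg$unsharp_alpha, cfg$unsharp_sigma, interior))
  binm <- stage("adaptive_binarize", function()
    adaptive_binarize(sharp, cfg$adapt_window, cfg$adapt_C,
                      cfg$stretch_percentiles))
  binm <- stage("leaf_intersect", function() binm * interior)
  vein <- stage("clean", function()
    clean_mask(binm, cfg$min_object_area, cfg$opening_se, cfg$median_kernel))
  if (thin) vein <- stage("thin", function() thin_mask(vein))
  list(vein = vein, leaf = leaf, intermediates = inter)
}
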