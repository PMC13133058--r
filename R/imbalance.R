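# ---- class-frequency-aware augmentation and weighting ------------------
#
# Classes whose sample count falls below a threshold (800 by default)
# receive a "strong" augmentation tier (larger rotations, elastic
# distortion, Gaussian noise); all others receive a "light" tier. Class
# weights follow the balanced inverse-frequency scheme.

#' Class frequency table
#'
#' @param counts named non-negative integer vector of per-class sample
#'   counts.
#' @param minority_threshold classes with strictly fewer samples are
#'   treated as minority classes (default 800).
#' @return a `class_frequency_table`.
#' @export
class_frequency_table <- function(counts, minority_threshold = 800L) {
  if (length(counts) == 0) stop("counts must be non-empty")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by class")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts,
                 minority_threshold = as.integer(minority_threshold)),
            class = "class_frequency_table")
}

#' Minority classes of a frequency table
#'
#' Exactly the classes with `count < minority_threshold` (strict: a class
#' with exactly the threshold count is not a minority class).
#'
#' @param table a [class_frequency_table()].
#' @return character vector of minority class names.
#' @export
minority_classes <- function(table) {
  stopifnot(inherits(table, "class_frequency_table"))
  names(table$counts)[table$counts < table$minority_threshold]
}

#' Augmentation policy for one tier
#'
#' The strong tier must rotate at least as far as the light tier, and only
#' the strong tier may enable elastic distortion and Gaussian noise.
#'
#' @param tier "strong" or "light".
#' @param rotation_limit_deg maximal absolute rotation.
#' @param elastic enable elastic distortion (strong tier only).
#' @param elastic_alpha,elastic_sigma displacement amplitude (pixels) and
#'   smoothing scale of the elastic field.
#' @param gaussian_noise_var_range `c(lo, hi)` variance range of additive
#'   Gaussian noise on the unit intensity scale (strong tier only;
#'   `c(0, 0)` disables).
#' @param flip enable random horizontal flip.
#' @param shift_fraction maximal shift as a fraction of each dimension.
#' @return an `augmentation_policy`.
#' @export
augmentation_policy <- function(tier = c("light", "strong"),
                                rotation_limit_deg = NULL,
                                elastic = NULL,
                                elastic_alpha = 40, elastic_sigma = 6,
                                gaussian_noise_var_range = NULL,
                                flip = TRUE,
                                shift_fraction = NULL) {
  tier <- match.arg(tier)
  if (is.null(rotation_limit_deg))
    rotation_limit_deg <- if (tier == "strong") 40 else 15
  if (is.null(elastic)) elastic <- tier == "strong"
  if (is.null(gaussian_noise_var_range))
    gaussian_noise_var_range <- if (tier == "strong") c(0.005, 0.02) else c(0, 0)
  if (is.null(shift_fraction)) shift_fraction <- if (tier == "strong") 0.10 else 0.05
  if (tier == "light" && (elastic || any(gaussian_noise_var_range > 0)))
    stop("elastic distortion and Gaussian noise are reserved for the strong tier")
  structure(list(tier = tier, rotation_limit_deg = rotation_limit_deg,
                 elastic = elastic, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma,
                 gaussian_noise_var_range = gaussian_noise_var_range,
                 flip = flip, shift_fraction = shift_fraction),
            class = "augmentation_policy")
}

#' Choose the augmentation tier for a class
#'
#' Strong tier iff the class is a minority class of the table, light
#' otherwise.
#'
#' @param cls class name (must be present in the table).
#' @param table a [class_frequency_table()].
#' @param light,strong policy objects for the two tiers.
#' @return an [augmentation_policy()].
#' @export
policy_for_class <- function(cls, table,
                             light = augmentation_policy("light"),
                             strong = augmentation_policy("strong")) {
  stopifnot(inherits(table, "class_frequency_table"))
  if (!cls %in% names(table$counts)) stop("unknown class: ", cls)
  if (cls %in% minority_classes(table)) strong else light
}

#' Balanced inverse-frequency class weights
#'
#' `w_c = N_total / (K * N_c)` for K classes; the weight of the average
#' sample is exactly 1, i.e. `sum_c w_c N_c = N_total`.
#'
#' @param table a [class_frequency_table()] with all counts > 0.
#' @return named numeric vector of weights.
#' @export
class_weights <- function(table) {
  stopifnot(inherits(table, "class_frequency_table"))
  n <- table$counts
  if (any(n == 0)) stop("class weights undefined for zero-count classes")
  total <- sum(n)
  w <- total / (length(n) * n)
  stats::setNames(as.numeric(w), names(n))
}

.elastic_field <- function(h, w, alpha, sigma) {
  k <- gaussian_kernel(sigma)
  dx <- conv_reflect(matrix(stats::runif(h * w, -1, 1), h, w), k)
  dy <- conv_reflect(matrix(stats::runif(h * w, -1, 1), h, w), k)
  list(dy = dy / max(abs(dy), 1e-9) * alpha, dx = dx / max(abs(dx), 1e-9) * alpha)
}

.elastic_warp <- function(img, field, interp, fill) {
  h <- dim(img)[1]; w <- dim(img)[2]
  sy <- matrix(seq_len(h), h, w) + field$dy
  sx <- matrix(seq_len(w), h, w, byrow = TRUE) + field$dx
  sample_plane <- function(pl) {
    out <- matrix(fill, h, w)
    if (interp == "nearest") {
      ri <- round(sy); ci <- round(sx)
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      out[ok] <- pl[cbind(ri[ok], ci[ok])]
    } else {
      r0 <- floor(sy); c0 <- floor(sx); fr <- sy - r0; fc <- sx - c0
      ok <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
      out[ok] <- pl[cbind(r0[ok], c0[ok])] * (1 - fr[ok]) * (1 - fc[ok]) +
        pl[cbind(r0[ok] + 1, c0[ok])] * fr[ok] * (1 - fc[ok]) +
        pl[cbind(r0[ok], c0[ok] + 1)] * (1 - fr[ok]) * fc[ok] +
        pl[cbind(r0[ok] + 1, c0[ok] + 1)] * fr[ok] * fc[ok]
    }
    out
  }
  if (n_channels(img) == 1L) sample_plane(img) else {
    out <- img
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- sample_plane(img[, , ch])
    out
  }
}

#' Apply a stochastic augmentation
#'
#' Draws the tier's transforms (rotation, flip, shift, and for the strong
#' tier elastic distortion and Gaussian noise) from a seeded RNG and
#' applies them. Geometric transforms are photometric-free, so an optional
#' co-registered binary mask can be warped synchronously (nearest
#' neighbour; noise is never added to the mask). Dimensions and labels are
#' never changed; the same seed reproduces the same output.
#'
#' @param img image (matrix or H x W x 3 array).
#' @param policy an [augmentation_policy()].
#' @param rng_seed integer seed.
#' @param mask optional binary mask warped with the same geometry.
#' @param fill background fill value for exposed borders.
#' @return augmented image, or `list(img, mask)` when a mask is given.
#' @export
augment <- function(img, policy, rng_seed = 1L, mask = NULL, fill = 1) {
  stopifnot(inherits(policy, "augmentation_policy"))
  scale <- raster_scale(img)
  d <- dim(img)
  with_seed(rng_seed, {
    rot <- stats::runif(1, -policy$rotation_limit_deg, policy$rotation_limit_deg)
    do_flip <- policy$flip && stats::runif(1) < 0.5
    shift <- c(stats::runif(1, -1, 1), stats::runif(1, -1, 1)) *
      policy$shift_fraction * d[1:2]
    field <- if (policy$elastic)
      .elastic_field(d[1], d[2], policy$elastic_alpha, policy$elastic_sigma)
    noise_var <- if (any(policy$gaussian_noise_var_range > 0))
      stats::runif(1, policy$gaussian_noise_var_range[1],
                   policy$gaussian_noise_var_range[2]) else 0
    warp1 <- function(x, interp, f) {
      if (do_flip) x <- if (n_channels(x) == 1L) x[, rev(seq_len(d[2])), drop = FALSE]
        else x[, rev(seq_len(d[2])), , drop = FALSE]
      if (rot != 0 || any(shift != 0))
        x <- warp_affine(x, rot, shift, interp = interp, fill = f)
      if (!is.null(field)) x <- .elastic_warp(x, field, interp, f)
      x
    }
    out <- warp1(img, "bilinear", fill * scale)
    if (noise_var > 0) {
      out <- out + stats::rnorm(length(out), 0, sqrt(noise_var)) * scale
      out <- clip_range(out, scale)
    }
    if (is.null(mask)) out else {
      m <- warp1(mask, "nearest", 0)
      list(img = out, mask = (m > 0.5) * 1)
    }
  })
}
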