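# ---- procedural synthetic leaves --------------------------------------
#
# Renders parametric leaves (blade silhouette + vein tree) together with
# exact ground-truth masks, so segmentation and classification code can be
# exercised without any photographic data. Leaves are synthetic archetypes,
# not renderings of real species.

#' Define a synthetic species archetype
#'
#' An archetype fixes the appearance cues (blade shape, margin serration,
#' base colour and its per-leaf jitter) and the structural cues (venation
#' order, secondary vein angle and spacing, vein width) of one synthetic
#' species.
#'
#' @param name class label.
#' @param blade_shape one of "ovate", "lanceolate", "round", "lobed".
#' @param margin_serration number of marginal teeth around the outline
#'   (0 = entire margin).
#' @param base_color_hsv length-3 vector: hue in `[0,360)`, saturation and
#'   value in `[0,1]`.
#' @param color_jitter per-channel HSV standard deviations of the per-leaf
#'   colour jitter (all >= 0).
#' @param vein_order_count 1 (midrib only), 2 (+ secondaries) or
#'   3 (+ tertiaries).
#' @param secondary_vein_angle_deg angle between midrib and secondary
#'   veins, strictly inside (0, 90).
#' @param secondary_vein_spacing_px spacing of secondary vein attachment
#'   points along the midrib, in pixels; must exceed `vein_width_px`.
#' @param vein_width_px stroke width of the midrib in pixels (>= 1).
#' @return object of class `species_archetype`.
#' @export
leaf_archetype <- function(name,
                           blade_shape = c("ovate", "lanceolate", "round", "lobed"),
                           margin_serration = 0L,
                           base_color_hsv = c(110, 0.55, 0.45),
                           color_jitter = c(4, 0.03, 0.03),
                           vein_order_count = 2L,
                           secondary_vein_angle_deg = 45,
                           secondary_vein_spacing_px = 20,
                           vein_width_px = 3) {
  blade_shape <- match.arg(blade_shape)
  if (margin_serration < 0) stop("margin_serration must be >= 0")
  if (any(color_jitter < 0)) stop("color jitter std-devs must be >= 0")
  if (!vein_order_count %in% 1:3) stop("vein_order_count must be 1, 2 or 3")
  if (secondary_vein_angle_deg <= 0 || secondary_vein_angle_deg >= 90)
    stop("secondary_vein_angle_deg must be strictly between 0 and 90")
  if (vein_width_px < 1) stop("vein_width_px must be >= 1")
  if (secondary_vein_spacing_px <= vein_width_px)
    stop("secondary_vein_spacing_px must exceed vein_width_px")
  structure(list(name = as.character(name),
                 blade_shape = blade_shape,
                 margin_serration = as.integer(margin_serration),
                 base_color_hsv = base_color_hsv,
                 color_jitter = color_jitter,
                 vein_order_count = as.integer(vein_order_count),
                 secondary_vein_angle_deg = secondary_vein_angle_deg,
                 secondary_vein_spacing_px = secondary_vein_spacing_px,
                 vein_width_px = vein_width_px),
            class = "species_archetype")
}

#' Seven ready-made synthetic archetypes
#'
#' A convenience palette of distinct synthetic species covering the four
#' blade shapes, a range of pigments and clearly different venation
#' parameters. Useful for building multi-class test datasets.
#'
#' @return named list of [leaf_archetype()] objects.
#' @export
leaf_archetype_presets <- function() {
  list(
    synth01 = leaf_archetype("synth01", "ovate", 14, c(115, 0.60, 0.45),
                             vein_order_count = 2, secondary_vein_angle_deg = 50,
                             secondary_vein_spacing_px = 24, vein_width_px = 3),
    synth02 = leaf_archetype("synth02", "lanceolate", 0, c(95, 0.50, 0.55),
                             vein_order_count = 2, secondary_vein_angle_deg = 35,
                             secondary_vein_spacing_px = 18, vein_width_px = 2),
    synth03 = leaf_archetype("synth03", "round", 0, c(140, 0.45, 0.40),
                             vein_order_count = 3, secondary_vein_angle_deg = 55,
                             secondary_vein_spacing_px = 28, vein_width_px = 3),
    synth04 = leaf_archetype("synth04", "lobed", 0, c(80, 0.55, 0.50),
                             vein_order_count = 2, secondary_vein_angle_deg = 40,
                             secondary_vein_spacing_px = 22, vein_width_px = 3),
    synth05 = leaf_archetype("synth05", "ovate", 30, c(60, 0.45, 0.55),
                             vein_order_count = 2, secondary_vein_angle_deg = 65,
                             secondary_vein_spacing_px = 16, vein_width_px = 2),
    synth06 = leaf_archetype("synth06", "lanceolate", 20, c(125, 0.65, 0.35),
                             vein_order_count = 3, secondary_vein_angle_deg = 30,
                             secondary_vein_spacing_px = 20, vein_width_px = 3),
    synth07 = leaf_archetype("synth07", "round", 10, c(100, 0.35, 0.60),
                             vein_order_count = 2, secondary_vein_angle_deg = 45,
                             secondary_vein_spacing_px = 30, vein_width_px = 4)
  )
}

# Radial outline multiplier per blade shape; phi measured from the apex
# direction, in radians.
.blade_profile <- function(shape, phi, serration) {
  f <- switch(shape,
    round      = rep(1, length(phi)),
    ovate      = 1 + 0.16 * cos(phi),        # broader toward the base
    lanceolate = rep(1, length(phi)),
    lobed      = 1 + 0.20 * cos(5 * phi))
  if (serration > 0) f <- f * (1 + 0.022 * cos(serration * phi))
  f
}

.blade_semiaxes <- function(shape, H, W) {
  a <- 0.40 * H   # vertical semi-axis (rows)
  b <- switch(shape,
    round      = 0.40 * min(H, W),
    ovate      = 0.58 * a,
    lanceolate = 0.26 * a,
    lobed      = 0.34 * a)
  if (shape == "round") a <- b
  b <- min(b, 0.46 * W)
  c(a = a, b = b)
}

# Anti-aliased stroke rendering: max over segments of a soft coverage field.
# canvas: numeric matrix accumulator; p1/p2 = c(row, col).
.draw_segment <- function(canvas, p1, p2, halfwidth) {
  h <- nrow(canvas); w <- ncol(canvas)
  pad <- ceiling(halfwidth) + 1L
  r0 <- max(1L, floor(min(p1[1], p2[1])) - pad)
  r1 <- min(h, ceiling(max(p1[1], p2[1])) + pad)
  c0 <- max(1L, floor(min(p1[2], p2[2])) - pad)
  c1 <- min(w, ceiling(max(p1[2], p2[2])) + pad)
  if (r0 > r1 || c0 > c1) return(canvas)
  rr <- r0:r1; cc <- c0:c1
  py <- matrix(rr, length(rr), length(cc))
  px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  vy <- p2[1] - p1[1]; vx <- p2[2] - p1[2]
  len2 <- vy^2 + vx^2
  t <- if (len2 == 0) matrix(0, length(rr), length(cc)) else
    pmin(pmax(((py - p1[1]) * vy + (px - p1[2]) * vx) / len2, 0), 1)
  dy <- py - (p1[1] + t * vy); dx <- px - (p1[2] + t * vx)
  d <- sqrt(dy^2 + dx^2)
  cov <- pmin(pmax(halfwidth + 0.5 - d, 0), 1)
  canvas[rr, cc] <- pmax(canvas[rr, cc], cov)
  canvas
}

# Walk from a start point along a unit direction until leaving the mask;
# returns the end point (shortened a little to stay interior).
.ray_end <- function(mask, start, dir, step = 1) {
  h <- nrow(mask); w <- ncol(mask)
  p <- start; n <- 0
  repeat {
    q <- p + step * dir
    ri <- round(q[1]); ci <- round(q[2])
    if (ri < 1 || ri > h || ci < 1 || ci > w || mask[ri, ci] == 0) break
    p <- q
    n <- n + 1
    if (n > h + w) break
  }
  start + (p - start) * 0.93
}

# Inverse-mapped affine resampling (rotation about the centre + shift).
# interp: "bilinear" or "nearest". fill: scalar background value.
warp_affine <- function(img, angle_deg = 0, shift_rc = c(0, 0),
                        interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  chans <- n_channels(img)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angle_deg * pi / 180
  rows <- matrix(seq_len(h), h, w) - cy - shift_rc[1]
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) - cx - shift_rc[2]
  sy <- cos(th) * rows - sin(th) * cols + cy
  sx <- sin(th) * rows + cos(th) * cols + cx
  sample_plane <- function(pl) {
    out <- matrix(fill, h, w)
    if (interp == "nearest") {
      ri <- round(sy); ci <- round(sx)
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      out[ok] <- pl[cbind(ri[ok], ci[ok])]
    } else {
      r0 <- floor(sy); c0 <- floor(sx)
      fr <- sy - r0; fc <- sx - c0
      ok <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
      i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1, c0[ok])
      i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
      v <- pl[i00] * (1 - fr[ok]) * (1 - fc[ok]) + pl[i10] * fr[ok] * (1 - fc[ok]) +
        pl[i01] * (1 - fr[ok]) * fc[ok] + pl[i11] * fr[ok] * fc[ok]
      out[ok] <- v
    }
    out
  }
  if (chans == 1L) sample_plane(img) else {
    out <- array(fill, d)
    for (ch in seq_len(chans)) out[, , ch] <- sample_plane(img[, , ch])
    out
  }
}

# Low-pass filtered white noise in [-1, 1]-ish range, unit variance-ish.
.smooth_noise <- function(h, w, sigma = 3) {
  n <- matrix(stats::rnorm(h * w), h, w)
  s <- conv_reflect(n, gaussian_kernel(sigma))
  s / max(stats::sd(s), 1e-9)
}

.render_leaf <- function(arch, canvas, geom_seed, render_seed, jitter_render) {
  H <- canvas[1]; W <- canvas[2]
  geom <- with_seed(geom_seed, {
    list(scale = 1 + stats::rnorm(1, 0, 0.04),
         aspect = 1 + stats::rnorm(1, 0, 0.04),
         bow = stats::rnorm(1, 0, 1.5),
         h = arch$base_color_hsv[1] + stats::rnorm(1, 0, arch$color_jitter[1]),
         s = arch$base_color_hsv[2] + stats::rnorm(1, 0, arch$color_jitter[2]),
         v = arch$base_color_hsv[3] + stats::rnorm(1, 0, arch$color_jitter[3]),
         tex = .smooth_noise(H, W, sigma = 3))
  })
  ax <- .blade_semiaxes(arch$blade_shape, H, W)
  a <- ax["a"] * min(geom$scale, 1.05)
  b <- min(ax["b"] * geom$scale * geom$aspect, 0.46 * W)
  if (a < 16 || b < 5)
    stop("canvas too small to hold minimum blade (need at least 64x64)")
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rows <- matrix(seq_len(H), H, W); cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- (rows - cy) / a            # +1 toward the base (bottom)
  dx <- (cols - cx) / b
  rho <- sqrt(dx^2 + dy^2)
  phi <- atan2(dx, -dy)            # 0 at the apex direction
  f <- matrix(.blade_profile(arch$blade_shape, phi, arch$margin_serration), H, W)
  leaf <- (rho <= f) * 1

  # vein tree ------------------------------------------------------------
  hw <- arch$vein_width_px / 2
  soft <- matrix(0, H, W)
  apex <- c(cy - 0.93 * a, cx); base <- c(cy + 0.93 * a, cx)
  nseg <- 16
  tt <- seq(0, 1, length.out = nseg + 1)
  mid_pts <- cbind(base[1] + (apex[1] - base[1]) * tt,
                   cx + geom$bow * sin(pi * tt))
  for (i in seq_len(nseg))
    soft <- .draw_segment(soft, mid_pts[i, ], mid_pts[i + 1, ], hw)

  if (arch$vein_order_count >= 2) {
    th <- arch$secondary_vein_angle_deg * pi / 180
    mid_len <- 1.86 * a
    n_att <- max(1L, floor(mid_len / arch$secondary_vein_spacing_px))
    att_t <- (seq_len(n_att) - 0.5) / n_att * 0.92 + 0.04
    hw2 <- hw
    for (t0 in att_t) {
      p0 <- c(base[1] + (apex[1] - base[1]) * t0, cx + geom$bow * sin(pi * t0))
      for (sgn in c(-1, 1)) {
        dir <- c(-cos(th), sgn * sin(th))   # up the midrib, out to the margin
        p1 <- .ray_end(leaf, p0, dir)
        soft <- .draw_segment(soft, p0, p1, hw2)
        if (arch$vein_order_count >= 3) {
          seg_len <- sqrt(sum((p1 - p0)^2))
          n3 <- floor(seg_len / (arch$secondary_vein_spacing_px * 0.6))
          if (n3 >= 1) {
            hw3 <- max(hw2 * 0.6, 0.5)
            perp <- c(-dir[2], dir[1])
            for (j in seq_len(n3)) {
              q0 <- p0 + (p1 - p0) * (j - 0.25) / n3
              for (s2 in c(-1, 1)) {
                q1 <- q0 + s2 * perp * arch$secondary_vein_spacing_px * 0.35
                if (q1[1] >= 1 && q1[1] <= H && q1[2] >= 1 && q1[2] <= W &&
                    leaf[round(q1[1]), round(q1[2])] == 1)
                  soft <- .draw_segment(soft, q0, q1, hw3)
              }
            }
          }
        }
      }
    }
  }
  soft <- soft * leaf
  vein <- (soft >= 0.5) * leaf

  # colour ---------------------------------------------------------------
  s <- min(max(geom$s, 0.05), 1); v <- min(max(geom$v, 0.05), 0.95)
  rgbv <- hsv_to_rgb(geom$h, s, v)
  vmap <- pmin(v * (1 + 0.05 * geom$tex) + 0.12 * soft, 1)
  vmap <- pmax(vmap, 0.02)
  rgb <- array(1, c(H, W, 3))
  base_rgb <- hsv_to_rgb(rep(geom$h, 3), rep(s, 3), c(1, 1, 1))[1, ]
  for (ch in 1:3) {
    plane <- base_rgb[ch] * vmap   # value channel scales RGB at fixed hue/sat
    rgb[, , ch] <- plane * leaf + 1 * (1 - leaf)
  }

  if (jitter_render) {
    jit <- with_seed(render_seed, list(rot = stats::rnorm(1, 0, 2.5),
                                       gain = 1 + stats::rnorm(1, 0, 0.03)))
    rgb <- warp_affine(rgb, jit$rot, interp = "bilinear", fill = 1)
    rgb <- clip_range(rgb * jit$gain, 1)
    leaf <- warp_affine(leaf, jit$rot, interp = "nearest", fill = 0)
    vein <- warp_affine(vein, jit$rot, interp = "nearest", fill = 0)
    vein <- vein * leaf
  }

  list(rgb = rgb, vein_truth = vein, leaf_mask_truth = leaf)
}

new_leaf_record <- function(rgb, vein, leaf, label, instance_id,
                            render = 1L, split = "unassigned") {
  stopifnot(identical(dim(rgb)[1:2], dim(vein)), identical(dim(vein), dim(leaf)))
  structure(list(rgb = rgb, vein_truth = vein, leaf_mask_truth = leaf,
                 label = label, instance_id = instance_id,
                 render = as.integer(render), split = split),
            class = "leaf_record")
}

#' Render one synthetic leaf
#'
#' Deterministic given `(archetype, canvas, rng_seed)`: the same call twice
#' yields pixel-identical output. The vein tree is drawn as anti-aliased
#' polylines and re-binarized at 0.5 coverage; the background is uniform
#' white.
#'
#' @param archetype a [leaf_archetype()].
#' @param canvas `c(height, width)` in pixels, each >= 64.
#' @param rng_seed integer seed.
#' @return a `leaf_record`: list with `rgb` (H x W x 3 in `[0,1]`),
#'   `vein_truth` and `leaf_mask_truth` (H x W in `{0,1}`), `label`,
#'   `instance_id`, `split`.
#' @export
generate_leaf <- function(archetype, canvas = c(224L, 224L), rng_seed = 1L) {
  stopifnot(inherits(archetype, "species_archetype"))
  canvas <- as.integer(canvas)
  if (length(canvas) != 2L || any(canvas < 64L))
    stop("canvas too small to hold minimum blade (need at least 64x64)")
  r <- .render_leaf(archetype, canvas, geom_seed = rng_seed,
                    render_seed = rng_seed, jitter_render = FALSE)
  new_leaf_record(r$rgb, r$vein_truth, r$leaf_mask_truth,
                  archetype$name, paste0(archetype$name, "-1"))
}

#' Generate a labelled multi-class leaf dataset
#'
#' Renders exactly `counts_per_class[c]` leaves per class. Leaves are
#' grouped into physical leaf instances of `renders_per_instance` renders
#' each (the last instance of a class may hold fewer); renders of one
#' instance share geometry and colour and differ by small rotation and
#' illumination jitter. Instance ids have the form `"<class>-<index>"`.
#'
#' @param archetypes list of [leaf_archetype()] with unique names.
#' @param counts_per_class named integer vector, classes matching the
#'   archetype names; all counts >= 1.
#' @param renders_per_instance renders of each physical leaf (>= 1).
#' @param rng_seed integer seed; output is deterministic given it.
#' @param canvas `c(height, width)` per leaf.
#' @return list of `leaf_record`s.
#' @export
generate_leaf_dataset <- function(archetypes, counts_per_class,
                                  renders_per_instance = 1L,
                                  rng_seed = 1L, canvas = c(224L, 224L)) {
  names(archetypes) <- vapply(archetypes, `[[`, "", "name")
  if (anyDuplicated(names(archetypes)))
    stop("duplicate class names in archetypes")
  if (is.null(names(counts_per_class)) ||
      !all(names(counts_per_class) %in% names(archetypes)))
    stop("counts_per_class must be named by archetype names")
  if (any(counts_per_class < 1)) stop("all class counts must be >= 1")
  if (renders_per_instance < 1) stop("renders_per_instance must be >= 1")
  total <- sum(counts_per_class)
  seeds <- with_seed(rng_seed, sample.int(.Machine$integer.max - 1L, 2L * total))
  records <- vector("list", total)
  idx <- 0L
  for (cls in names(counts_per_class)) {
    arch <- archetypes[[cls]]
    n <- counts_per_class[[cls]]
    inst <- 0L
    made <- 0L
    while (made < n) {
      inst <- inst + 1L
      gseed <- seeds[idx + 1L]
      n_rend <- min(renders_per_instance, n - made)
      for (r in seq_len(n_rend)) {
        idx <- idx + 1L
        out <- .render_leaf(arch, canvas, geom_seed = gseed,
                            render_seed = seeds[total + idx],
                            jitter_render = r > 1L)
        records[[idx]] <- new_leaf_record(out$rgb, out$vein_truth,
                                          out$leaf_mask_truth, cls,
                                          paste0(cls, "-", inst), render = r)
      }
      made <- made + n_rend
    }
  }
  records
}

#' Write a leaf dataset to disk
#'
#' Writes `<root>/<class>/<instance>_<render>.png` for the RGB images, a
#' mirrored `<root>/masks/...` tree for the vein masks (8-bit, 0/255) and a
#' `manifest.csv` with columns path, mask_path, label, instance_id, split.
#'
#' @param records list of `leaf_record`s.
#' @param root output directory (created if missing).
#' @return invisibly, the manifest data frame.
#' @export
write_leaf_dataset <- function(records, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(rec) {
    stem <- paste0(rec$instance_id, "_", rec$render, ".png")
    rel <- file.path(rec$label, stem)
    mrel <- file.path("masks", rec$label, stem)
    dir.create(file.path(root, rec$label), showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(root, "masks", rec$label), showWarnings = FALSE,
               recursive = TRUE)
    png::writePNG(aperm(rec$rgb, c(1, 2, 3)), file.path(root, rel))
    png::writePNG(rec$vein_truth, file.path(root, mrel))
    data.frame(path = rel, mask_path = mrel, label = rec$label,
               instance_id = rec$instance_id, split = rec$split,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
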