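# Shared fixtures: tiny archetypes and cached synthetic leaves so the
# generator runs once per test session.

fix_env <- new.env()

small_archetype <- function(name = "tiny", ...) {
  defaults <- list(name = name, blade_shape = "ovate", margin_serration = 8L,
                   base_color_hsv = c(110, 0.55, 0.45),
                   vein_order_count = 2L, secondary_vein_angle_deg = 45,
                   secondary_vein_spacing_px = 18,
                   vein_width_px = 3)
  args <- utils::modifyList(defaults, list(...))
  do.call(leaf_archetype, args)
}

cached_leaf <- function(key = "default", canvas = c(128L, 128L), seed = 42L, ...) {
  if (is.null(fix_env[[key]]))
    fix_env[[key]] <- generate_leaf(small_archetype(...), canvas, seed)
  fix_env[[key]]
}

# tolerance-band overlap: fraction of truth pixels within `tol` px of a
# prediction pixel, and vice versa
band_recall <- function(pred, truth, tol = 2) {
  k <- EBImage::makeBrush(2 * tol + 1, "disc")
  dil <- (EBImage::dilate(pred, k) > 0.5) * 1
  sum(truth * dil) / max(sum(truth), 1)
}
band_precision <- function(pred, truth, tol = 2) {
  k <- EBImage::makeBrush(2 * tol + 1, "disc")
  dil <- (EBImage::dilate(truth, k) > 0.5) * 1
  sum(pred * dil) / max(sum(pred), 1)
}
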