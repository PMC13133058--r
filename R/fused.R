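# ---- fused leaf construction ------------------------------------------
#
# The fused leaf is the RGB image whose red channel is replaced by the
# binary vein map: green and blue carry appearance, red carries venation.

#' Crop an image to the bounding box of a leaf mask
#'
#' Tight axis-aligned bounding box of the mask's foreground pixels. Apply
#' the same call with the same mask to every co-registered image to keep
#' them aligned.
#'
#' @param img matrix or H x W x 3 array sharing the mask's spatial dims.
#' @param leaf binary mask, non-empty.
#' @return cropped image.
#' @export
crop_to_leaf_bbox <- function(img, leaf) {
  assert_binary(leaf)
  if (sum(leaf) == 0) stop("cannot crop to an empty leaf mask")
  if (!identical(dim(img)[1:2], dim(leaf)))
    stop("image and mask dimensions differ")
  rows <- range(which(rowSums(leaf) > 0))
  cols <- range(which(colSums(leaf) > 0))
  if (n_channels(img) == 1L) img[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  else img[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
}

#' Compose a fused leaf image
#'
#' Replaces the red channel of the RGB image by the vein map scaled to the
#' maximum intensity; green and blue are passed through unchanged. If the
#' vein map's resolution differs from the image it is resampled by
#' nearest neighbour and re-binarized at 0.5.
#'
#' @param rgb H x W x 3 image.
#' @param vein binary vein map.
#' @return object of class `fused_leaf`: H x W x 3 array whose red plane
#'   is two-valued `{0, max}` and whose green/blue planes equal the input.
#' @export
compose_fused <- function(rgb, vein) {
  assert_rgb(rgb)
  assert_binary(vein)
  scale <- raster_scale(rgb)
  if (!identical(dim(rgb)[1:2], dim(vein))) {
    v <- EBImage::resize(vein, w = nrow(rgb), h = ncol(rgb), filter = "none")
    vein <- (matrix(v, nrow(rgb), ncol(rgb)) > 0.5) * 1
  }
  out <- rgb
  out[, , 1] <- vein * scale
  structure(out, class = c("fused_leaf", class(out)))
}
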