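test_that("grayscale conversion follows BT.601 luminance", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(as.numeric(to_grayscale(px(255, 255, 255))), 255)
  expect_equal(as.numeric(to_grayscale(px(255, 0, 0))), 76)  # round(0.299*255)
  for (g in c(0, 13, 200)) expect_equal(as.numeric(to_grayscale(px(g, g, g))), g)
  ur <- array(runif(12), c(2, 2, 3))
  expect_equal(to_grayscale(ur),
               0.299 * ur[, , 1] + 0.587 * ur[, , 2] + 0.114 * ur[, , 3])
  expect_error(to_grayscale(matrix(0, 2, 2)), "3-channel")
})

# exhaustive-scan oracle: between-class variance of every threshold,
# computed directly from pixel subsets
otsu_oracle_curve <- function(gray) {
  b <- round(gray)  # uint8-range inputs
  vapply(0:255, function(t) {
    bg <- gray[b <= t]; fg <- gray[b > t]
    w0 <- length(bg) / length(gray); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    w0 * w1 * (mean(bg) - mean(fg))^2
  }, numeric(1))
}

test_that("Otsu equals the exhaustive 256-threshold scan", {
  set.seed(1)
  img <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  res <- otsu_threshold(img)
  curve <- otsu_oracle_curve(img)
  expect_gte(curve[res$threshold + 1], max(curve) - 1e-9)
  expect_identical(res$mask, (img > res$threshold) * 1)

  half <- matrix(c(rep(0, 100), rep(255, 100)), 20, 10)
  res2 <- otsu_threshold(half)
  expect_true(res2$threshold >= 0 && res2$threshold <= 254)
  curve2 <- otsu_oracle_curve(half)
  expect_gte(curve2[res2$threshold + 1], max(curve2) - 1e-9)
  expect_identical(sort(unique(as.vector(res2$mask))), c(0, 1))

  # bimodal Gaussian mixture: threshold lands between the modes
  set.seed(2)
  bim <- matrix(pmin(pmax(c(rnorm(800, 60, 10), rnorm(800, 200, 10)), 0), 255),
                40, 40)
  expect_lte(abs(otsu_threshold(bim)$threshold - 130), 15)
})

test_that("constant images degrade gracefully under Otsu", {
  cst <- matrix(100, 8, 8)
  expect_warning(res <- otsu_threshold(cst), "constant")
  expect_equal(res$threshold, 100)
  expect_true(all(res$mask == 0))
})

test_that("leaf segmentation recovers the synthetic blade", {
  rec <- cached_leaf()
  m <- leaf_mask(rec$rgb)
  iou <- sum(m * rec$leaf_mask_truth) / sum(pmax(m, rec$leaf_mask_truth))
  expect_gte(iou, 0.95)
  expect_error(leaf_mask(array(1, c(64, 64, 3))), "foreground|constant")
})

test_that("small blobs and interior holes are handled by mask refinement", {
  # only the largest component survives
  img <- array(1, c(64, 64, 3))
  img[10:40, 10:30, ] <- 0.2   # 500+ px blob
  img[50:53, 50:54, ] <- 0.2   # 20 px blob
  m <- leaf_mask(img)
  expect_true(all(m[50:53, 50:54] == 0))
  expect_true(all(m[12:38, 12:28] == 1))
  # a 1-px interior hole is filled
  img2 <- array(1, c(64, 64, 3))
  img2[16:48, 16:48, ] <- 0.2
  img2[30, 30, ] <- 1
  m2 <- leaf_mask(img2, struct_elem("ellipse", 3L))
  expect_identical(m2[30, 30], 1)
})

test_that("CLAHE preserves constants, expands low-contrast ranges and reduces
           to plain equalization for one unclipped tile", {
  cst <- matrix(100, 32, 32)
  expect_length(unique(as.vector(clahe(cst, c(4, 4), 2))), 1L)

  ramp <- matrix(rep(seq(100, 130, length.out = 64), each = 64), 64, 64)
  out <- clahe(ramp, c(4, 4), 4)
  expect_gt(diff(range(out)), diff(range(ramp)))

  set.seed(3)
  img <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
  out1 <- clahe(img, c(1, 1), clip = 1e9)
  cdf <- cumsum(tabulate(img + 1L, 256L))           # equalization oracle
  eq <- matrix(round(cdf[img + 1L] * 255 / length(img)), 48, 48)
  expect_equal(out1, eq)

  expect_message(clahe(matrix(runif(16), 4, 4), c(8, 8), 2), "reduced")
})

test_that("homomorphic transfer function hits its limits and boosts high
           frequencies relative to illumination", {
  H <- veinfuse:::.homo_H
  expect_equal(H(0, A = 1.5, B = 0.5, k = 1, D0 = 30), 0.5)     # H(D=0) = B
  expect_equal(H(1e6, A = 1.5, B = 0.5, k = 1, D0 = 30), 2.0)   # -> A + B
  expect_error(homomorphic_filter(matrix(0.5, 8, 8), D0 = 0), "D0")

  grad <- outer(seq(0.2, 1, length.out = 128), rep(1, 128))
  stripes <- outer(rep(1, 128), 1 + 0.2 * sin(2 * pi * (1:128) / 8))
  img <- grad * stripes * 127
  out <- homomorphic_filter(img, A = 1.5, B = 0.5, k = 1, D0 = 30)
  fin <- abs(stats::fft(img)); fout <- abs(stats::fft(out))
  stripe_ratio <- fout[1, 1 + 128 / 8] / fin[1, 1 + 128 / 8]
  grad_ratio <- fout[2, 1] / fin[2, 1]
  expect_gt(stripe_ratio, grad_ratio)
})

test_that("Gabor kernels and max response behave per the closed form", {
  k <- gabor_kernel(15, 0, lambda = 8, sigma = 4, gamma = 0.5, psi = 0)
  expect_equal(k[8, 8], 1)                 # exp(0) * cos(0)
  expect_error(gabor_kernel(14, 0), "odd")
  expect_error(gabor_max_response(matrix(0.5, 8, 8),
                                  orientations_deg = numeric(0)), "non-empty")

  vimg <- matrix(0, 64, 64); vimg[, 32:33] <- 255
  himg <- t(vimg)
  rv <- gabor_max_response(vimg, orientations_deg = 0, scales = 15L)
  rh <- gabor_max_response(himg, orientations_deg = 0, scales = 15L)
  expect_gte(mean(rv[, 32]), mean(rh[32, ]))
  expect_gt(mean(rv[, 32]), 200)
})

test_that("the six-orientation bank is approximately rotation invariant", {
  set.seed(2)
  img <- matrix(0, 96, 96)
  for (k in 1:6) {
    a <- runif(1, 0, pi); r0 <- runif(1, 20, 76); c0 <- runif(1, 20, 76)
    for (t in seq(-20, 20, by = 0.5)) {
      i <- round(r0 + t * sin(a)); j <- round(c0 + t * cos(a))
      if (i >= 3 && i <= 94 && j >= 3 && j <= 94) img[i + (-1:1), j] <- 1
    }
  }
  img <- img * 200 + 20
  r1 <- gabor_max_response(img)
  rot <- veinfuse:::warp_affine(img, 30, fill = 20)
  r2 <- gabor_max_response(rot)
  r1rot <- veinfuse:::warp_affine(r1, 30, fill = 20)
  ctr <- 25:72  # compare away from the rotation's exposed corners
  expect_lt(mean(abs(r2[ctr, ctr] - r1rot[ctr, ctr])) / 255, 0.03)
})

test_that("weighted fusion is exact arithmetic with clipping", {
  I <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(weighted_fuse(I, I, 0.5, 0.5, 0), I)
  expect_equal(weighted_fuse(I, matrix(0, 8, 8), 1, 0, 0), I)
  expect_equal(weighted_fuse(matrix(100, 4, 4), matrix(200, 4, 4), 0.5, 0.5, 10),
               matrix(160, 4, 4))
  expect_error(weighted_fuse(I, matrix(0, 4, 4), 0.5, 0.5), "dimensions")
  expect_error(weighted_fuse(I, I, 0.7, 0.5), "equal 1")
})

test_that("unsharp masking sharpens only the interior", {
  cst <- matrix(128, 16, 16)
  expect_equal(unsharp_sharpen(cst, 1, 2), cst)
  step <- matrix(60, 32, 32); step[, 17:32] <- 190
  interior <- matrix(0, 32, 32); interior[8:24, 8:24] <- 1
  out <- unsharp_sharpen(step, 1, 2, interior)
  expect_identical(out[interior == 0], step[interior == 0])
  band_in <- step[16, 15:19]; band_out <- out[16, 15:19]
  expect_gt(diff(range(band_out)), diff(range(band_in)))
  expect_error(unsharp_sharpen(step, -1, 2), "alpha")
})

test_that("adaptive thresholding matches a brute-force neighbourhood mean", {
  set.seed(4)
  img <- matrix(runif(32 * 32) * 255, 32, 32)
  got <- adaptive_binarize(img, 7L, 5, c(0, 100))
  # O(N^2 * window^2) double-loop oracle with symmetric reflection
  q <- range(img)
  st <- (img - q[1]) / (q[2] - q[1]) * 255
  refl <- function(i, n) if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i
  oracle <- matrix(0, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    s <- 0
    for (di in -3:3) for (dj in -3:3)
      s <- s + st[refl(i + di, 32), refl(j + dj, 32)]
    oracle[i, j] <- (st[i, j] > s / 49 + 5) * 1
  }
  expect_identical(got, oracle)

  # bright line on dark background
  line <- matrix(100, 40, 40); line[20, ] <- 200
  m <- adaptive_binarize(line, 15L, 5, c(0, 100))
  expect_true(all(m[20, ] == 1))
  expect_true(all(m[c(1:10, 30:40), ] == 0))

  # near-constant input short-circuits to empty
  expect_true(all(adaptive_binarize(matrix(100, 32, 32), 7L, 5) == 0))
  expect_error(adaptive_binarize(matrix(0.1, 8, 8), 9L, 5), "smaller")
})

test_that("mask cleanup removes speckles and is idempotent", {
  m <- matrix(0, 48, 48)
  m[10:40, 20:22] <- 1                       # 3-px-wide line
  set.seed(5)
  sp <- cbind(sample(1:48, 50, TRUE), sample(1:48, 50, TRUE))
  sp <- sp[abs(sp[, 2] - 21) > 4, , drop = FALSE]  # speckles off the line
  m_noisy <- m; m_noisy[sp] <- 1
  cleaned <- clean_mask(m_noisy, min_area = 5L, median_kernel = 1L)
  expect_true(all(cleaned[, c(1:15, 27:48)] == 0))
  expect_gt(sum(cleaned[, 20:22]), 60)

  single <- matrix(0, 16, 16); single[8, 8] <- 1
  expect_true(all(clean_mask(single, min_area = 5L, median_kernel = 1L) == 0))

  once <- clean_mask(m, min_area = 0L, median_kernel = 1L)
  twice <- clean_mask(once, min_area = 0L, median_kernel = 1L)
  expect_identical(once, twice)
})

test_that("the full pipeline recovers synthetic veins inside the leaf", {
  rec <- cached_leaf("pipe224", canvas = c(224L, 224L),
                     secondary_vein_spacing_px = 25, vein_width_px = 3)
  ev <- extract_veins(rec$rgb)
  expect_true(all(ev$vein %in% c(0, 1)))
  expect_true(all(ev$vein <= ev$leaf))                # strictly inside the leaf
  expect_gte(band_recall(ev$vein, rec$vein_truth, 2), 0.7)
  expect_gte(band_precision(ev$vein, rec$vein_truth, 2), 0.6)
  # every stage preserved the image dimensions
  dims <- vapply(ev$intermediates, function(x) dim(x)[1], numeric(1))
  expect_true(all(dims == 224))
  expect_error(extract_veins(array(1, c(96, 96, 3))),
               "leaf_mask.*foreground|foreground")
})

test_that("thinning reduces strokes to unit width but keeps connectivity", {
  m <- matrix(0, 32, 32); m[8:26, 14:17] <- 1
  th <- thin_mask(m)
  expect_lt(sum(th), sum(m) / 2)
  expect_equal(max(EBImage::bwlabel(th)), 1)
})
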