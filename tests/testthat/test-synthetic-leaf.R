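test_that("leaf generation is deterministic and respects the record contract", {
  rec1 <- generate_leaf(small_archetype(), c(96L, 96L), 7L)
  rec2 <- generate_leaf(small_archetype(), c(96L, 96L), 7L)
  expect_identical(rec1, rec2)
  expect_identical(dim(rec1$rgb)[1:2], dim(rec1$vein_truth))
  expect_identical(dim(rec1$vein_truth), dim(rec1$leaf_mask_truth))
  expect_true(all(rec1$vein_truth %in% c(0, 1)))
  # vein pixels strictly inside the leaf, non-empty and below half the blade
  expect_true(all(rec1$vein_truth <= rec1$leaf_mask_truth))
  expect_gt(sum(rec1$vein_truth), 0)
  expect_lt(sum(rec1$vein_truth), 0.5 * sum(rec1$leaf_mask_truth))
})

test_that("tiny canvases are rejected with an explanatory error", {
  expect_error(generate_leaf(small_archetype(), c(32L, 32L), 1L), "too small")
})

test_that("archetype invariants are enforced", {
  expect_error(small_archetype(secondary_vein_angle_deg = 0), "strictly between")
  expect_error(small_archetype(secondary_vein_angle_deg = 90), "strictly between")
  expect_error(small_archetype(secondary_vein_spacing_px = 3, vein_width_px = 3),
               "exceed")
  expect_error(small_archetype(color_jitter = c(-1, 0, 0)), ">= 0")
})

test_that("a midrib-only archetype yields one connected vein component", {
  # independent flood-fill oracle: EBImage connected-component labelling
  rec <- generate_leaf(small_archetype(vein_order_count = 1L), c(96L, 96L), 3L)
  lab <- EBImage::bwlabel(rec$vein_truth)
  expect_equal(max(lab), 1)
})

test_that("round unserrated blades are nearly convex", {
  rec <- generate_leaf(small_archetype(blade_shape = "round",
                                       margin_serration = 0L),
                       c(96L, 96L), 5L)
  m <- rec$leaf_mask_truth
  pts <- which(m == 1, arr.ind = TRUE)
  hull <- pts[grDevices::chull(pts), ]
  # convex hull area via the shoelace formula
  n <- nrow(hull)
  xs <- hull[, 2]; ys <- hull[, 1]
  hull_area <- abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
  defect <- (hull_area - sum(m)) / sum(m)
  expect_lt(abs(defect), 0.05)
})

test_that("dataset generation honours counts, instances and determinism", {
  ars <- list(small_archetype("A"), small_archetype("B", blade_shape = "round"))
  recs <- generate_leaf_dataset(ars, c(A = 10L, B = 10L),
                                renders_per_instance = 5L,
                                rng_seed = 1L, canvas = c(96L, 96L))
  labs <- vapply(recs, `[[`, "", "label")
  expect_identical(as.integer(table(labs)[c("A", "B")]), c(10L, 10L))
  # ceil(10/5) instances per class
  expect_length(unique(vapply(recs, `[[`, "", "instance_id")), 4L)
  grp <- table(vapply(recs, `[[`, "", "instance_id"))
  expect_true(all(grp == 5L))
  recs2 <- generate_leaf_dataset(ars, c(A = 10L, B = 10L), 5L, 1L, c(96L, 96L))
  expect_identical(recs, recs2)
})

test_that("single-count classes and duplicate names behave per contract", {
  ars <- list(small_archetype("A"))
  recs <- generate_leaf_dataset(ars, c(A = 1L), 1L, 2L, c(96L, 96L))
  expect_length(recs, 1L)
  expect_identical(recs[[1]]$instance_id, "A-1")
  expect_error(
    generate_leaf_dataset(list(small_archetype("A"), small_archetype("A")),
                          c(A = 2L), 1L, 1L, c(96L, 96L)),
    "duplicate")
})

test_that("venation-only archetype differences leave mean colour unchanged", {
  a1 <- small_archetype("v1", secondary_vein_angle_deg = 30,
                        secondary_vein_spacing_px = 14)
  a2 <- small_archetype("v2", secondary_vein_angle_deg = 65,
                        secondary_vein_spacing_px = 30)
  mean_rgb <- function(arch, seeds) {
    rowMeans(vapply(seeds, function(s) {
      r <- generate_leaf(arch, c(96L, 96L), s)
      apply(r$rgb, 3, mean)
    }, numeric(3)))
  }
  m1 <- mean_rgb(a1, 1:50)
  m2 <- mean_rgb(a2, 101:150)
  expect_true(all(abs(m1 - m2) < 2 / 255))
})

test_that("renders of one instance differ by jitter but share identity", {
  ars <- list(small_archetype("A"))
  recs <- generate_leaf_dataset(ars, c(A = 3L), renders_per_instance = 3L,
                                rng_seed = 9L, canvas = c(96L, 96L))
  expect_identical(unique(vapply(recs, `[[`, "", "instance_id")), "A-1")
  expect_false(identical(recs[[1]]$rgb, recs[[2]]$rgb))
})

test_that("datasets round-trip through the on-disk layout", {
  root <- withr::local_tempdir()
  ars <- list(small_archetype("A"), small_archetype("B", blade_shape = "round"))
  recs <- generate_leaf_dataset(ars, c(A = 4L, B = 4L), 2L, 1L, c(96L, 96L))
  manifest <- write_leaf_dataset(recs, root)
  expect_true(file.exists(file.path(root, "manifest.csv")))
  expect_true(all(file.exists(file.path(root, manifest$path))))
  expect_true(all(file.exists(file.path(root, manifest$mask_path))))
  loaded <- load_manifest(file.path(root, "manifest.csv"))
  expect_length(loaded, 8L)
  expect_equal(vapply(loaded, `[[`, "", "label"),
               vapply(recs, `[[`, "", "label"))
  # masks survive 8-bit quantization exactly
  expect_identical(loaded[[1]]$vein_truth, recs[[1]]$vein_truth)
})
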