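cfg_fast <- fusion_model_config()

test_that("jet colormapping of binary masks uses the two jet endpoints", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  jm <- jet_colormap(m)
  expect_identical(dim(jm), c(2L, 2L, 3L))
  expect_equal(jm[1, 1, ], c(0, 0, 128))     # 0 -> dark blue
  expect_equal(jm[2, 1, ], c(128, 0, 0))     # 1 -> dark red
  cols <- unique(apply(matrix(jm, 4, 3), 1, paste, collapse = ","))
  expect_length(cols, 2L)
  expect_equal(unique(as.vector(jet_colormap(matrix(0, 2, 2))[, , 3])), 128)
  expect_equal(unique(as.vector(jet_colormap(matrix(1, 2, 2))[, , 1])), 128)
  expect_error(jet_colormap(matrix(0.5, 2, 2)), "two-valued")
})

test_that("global average pooling of per-channel constants returns them", {
  x <- array(0, c(4, 5, 3))
  for (ch in 1:3) x[, , ch] <- ch * 1.5
  expect_equal(global_avg_pool(x), c(1.5, 3, 4.5))
})

test_that("the feature dimension chain is 1280 / 1024 / 2304", {
  m <- build_model("dual", cfg_fast, seed = 1L)
  img <- array(runif(224 * 224 * 3), c(224, 224, 3))
  vein <- matrix(rbinom(224 * 224, 1, 0.1), 224, 224)
  z_rgb <- branch_features(img, "rgb", m)
  z_skel <- branch_features(jet_colormap(vein) / 255, "skeleton", m)
  expect_length(z_rgb, 1280L)
  expect_length(z_skel, 1024L)
  fused <- fuse_features(z_rgb, z_skel)
  expect_length(fused, 2304L)
  expect_equal(as.numeric(fused), c(as.numeric(z_rgb), as.numeric(z_skel)))
  expect_error(fuse_features(z_skel, z_rgb), "source")
  expect_error(branch_features(array(0.1, c(64, 64, 3)), "rgb", m), "224")
})

test_that("all five variants build with the documented fused widths", {
  dims <- c(dual = 2304L, rgb_only = 1280L, skeleton_densenet = 1024L,
            skeleton_efficientnet = 1280L, fused_densenet = 1024L)
  for (v in names(dims))
    expect_identical(build_model(v, cfg_fast, seed = 2L)$feature_dim, dims[[v]])
  expect_error(build_model("vit", cfg_fast), "arg")
  expect_error(fusion_model_config(weights_mode = "random-trainable"), "frozen")
})

test_that("the classification head is simplex-valued and eval-deterministic", {
  set.seed(7)
  Z <- matrix(rnorm(6 * 2304), 6, 2304)
  p1 <- classification_head(Z, cfg = cfg_fast, n_class = 7L, rng_seed = 1L)
  p2 <- classification_head(Z, cfg = cfg_fast, n_class = 7L, rng_seed = 99L)
  expect_identical(p1$probabilities, p2$probabilities)  # eval ignores dropout
  expect_true(all(abs(rowSums(p1$probabilities) - 1) < 1e-6))
  expect_true(all(p1$probabilities >= 0))
  expect_error(classification_head(Z, cfg = cfg_fast, n_class = 1L), "2 classes")
  # softmax of zero logits (zero-initialized output layer) is uniform
  expect_equal(unique(round(as.vector(p1$probabilities), 12)), 1 / 7)
})

test_that("smoothed cross-entropy matches its closed forms", {
  # eps = 0, perfect prediction -> 0
  y <- diag(2)
  expect_equal(smoothed_crossentropy(y, y, eps = 0), 0)
  # eps = 0, p = 0.5 on two classes -> ln 2
  p <- matrix(0.5, 2, 2)
  expect_equal(smoothed_crossentropy(y, p, eps = 0), log(2))
  # uniform prediction over C = 7: loss = ln 7 for any eps
  y7 <- diag(7)
  p7 <- matrix(1 / 7, 7, 7)
  expect_equal(smoothed_crossentropy(y7, p7, eps = 0.01), log(7))
  expect_equal(smoothed_crossentropy(y7, p7, eps = 0.3), log(7))
  # eps = 0 equals plain cross-entropy on random batches
  set.seed(8)
  for (rep in 1:5) {
    praw <- matrix(stats::rexp(5 * 7), 5, 7)
    pr <- praw / rowSums(praw)
    yt <- veinfuse:::.one_hot(sample.int(7, 5, TRUE), 7L)
    plain <- -mean(log(pr[yt == 1]))
    expect_lt(abs(smoothed_crossentropy(yt, pr, eps = 0) - plain), 1e-10)
  }
  # sample weights multiply per-sample terms
  w <- c(2, 0)
  expect_equal(smoothed_crossentropy(y, p, eps = 0, sample_weights = w), log(2))
  # zero probability on a positively-weighted target entry warns
  expect_warning(smoothed_crossentropy(y, matrix(c(0, 1, 1, 0), 2, 2), eps = 0),
                 "floored")
})

test_that("training fits a separable problem, freezes backbones and stops early", {
  ars <- list(small_archetype("A", base_color_hsv = c(100, 0.6, 0.4)),
              small_archetype("B", base_color_hsv = c(55, 0.5, 0.6),
                              blade_shape = "round"))
  recs <- generate_leaf_dataset(ars, c(A = 25L, B = 25L), 5L, 31L,
                                canvas = c(224L, 224L))
  labs <- vapply(recs, `[[`, "", "label")
  for (i in seq_along(recs))
    recs[[i]]$split <- if (recs[[i]]$instance_id %in% c("A-5", "B-5")) "val" else "train"
  m <- build_model("rgb_only", fusion_model_config(max_epochs = 30L), seed = 31L)
  before <- serialize(m$backbones, NULL)
  cache <- new.env()
  fit <- train_model(m, recs, rng_seed = 31L, feature_cache = cache)
  after <- serialize(fit$backbones, NULL)
  expect_identical(before, after)            # frozen backbone, bit-identical
  h <- fit$history
  expect_lte(h$train_loss[nrow(h)], h$train_loss[1])  # monotone trend
  pr <- predict(fit, recs[labs == "A"][1:5], feature_cache = cache)
  expect_identical(dim(pr$probabilities), c(5L, 2L))
  expect_true(all(abs(rowSums(pr$probabilities) - 1) < 1e-6))
  pr2 <- predict(fit, recs[labs == "A"][1:5], feature_cache = cache)
  expect_identical(pr$probabilities, pr2$probabilities)

  # early stopping halts on a plateau well before max_epochs
  cfg_es <- fusion_model_config(max_epochs = 40L, early_stopping_patience = 3L,
                                learning_rate = 1e-12)
  m2 <- build_model("rgb_only", cfg_es, seed = 31L)
  fit2 <- train_model(m2, recs, rng_seed = 31L, feature_cache = cache)
  expect_lt(nrow(fit2$history), 40L)
  expect_error(predict(build_model("rgb_only", cfg_fast), recs[1:2]),
               "not been trained")
})

test_that("class weighting lifts minority-class probability mass", {
  mk <- function(nm, hue) small_archetype(nm, base_color_hsv = c(hue, 0.5, 0.45),
                                          color_jitter = c(5, 0.04, 0.04))
  ars <- list(mk("maj", 95), mk("min", 120))
  run_seed <- function(seed) {
    recs <- generate_leaf_dataset(ars, c(maj = 60L, min = 16L), 1L, seed,
                                  canvas = c(224L, 224L))
    lab <- vapply(recs, `[[`, "", "label")
    idx_maj <- which(lab == "maj"); idx_min <- which(lab == "min")
    for (i in idx_maj[1:50]) recs[[i]]$split <- "train"
    for (i in idx_maj[51:60]) recs[[i]]$split <- "test"
    for (i in idx_min[1:5]) recs[[i]]$split <- "train"
    for (i in idx_min[6:16]) recs[[i]]$split <- "test"
    test <- recs[vapply(recs, `[[`, "", "split") == "test"]
    truth <- vapply(test, `[[`, "", "label")
    cache <- new.env()
    out <- lapply(c(TRUE, FALSE), function(cw) {
      m <- build_model("rgb_only",
                       fusion_model_config(class_weighting = cw,
                                           max_epochs = 150L,
                                           early_stopping_patience = 150L),
                       seed = seed)
      m <- train_model(m, recs, rng_seed = seed, feature_cache = cache)
      pr <- predict(m, test, feature_cache = cache)
      pmin_col <- pr$probabilities[truth == "min", which(m$classes == "min")]
      list(pmass = mean(pmin_col), recall = mean(pmin_col > 0.5))
    })
    c(pmass_w = out[[1]]$pmass, pmass_u = out[[2]]$pmass,
      rec_w = out[[1]]$recall, rec_u = out[[2]]$recall)
  }
  res <- vapply(c(11L, 12L), run_seed, numeric(4))
  expect_gt(median(res["pmass_w", ]), median(res["pmass_u", ]))
  expect_gte(median(res["rec_w", ]), median(res["rec_u", ]))
})
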