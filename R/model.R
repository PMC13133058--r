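# ---- dual-branch classifier -------------------------------------------
#
# Five model variants share one design: a frozen convolutional backbone
# per input stream, global average pooling, optional concatenation of the
# pooled streams, and a trainable head (dense 128 ReLU with L2, dropout,
# dense softmax) optimized with Adam under label-smoothed, class-weighted
# cross-entropy.

#' Training and architecture configuration
#'
#' Defaults follow the reference training regime: 224 x 224 inputs,
#' batch 16, up to 50 epochs with early stopping, Adam at 1e-5 with
#' learning-rate reduction on plateau, label smoothing 0.01, dropout 0.5,
#' a 128-unit head with L2 1e-4, and class-weight balancing enabled.
#'
#' @param image_size input side length (pixels).
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap (early stopping may end sooner).
#' @param learning_rate Adam learning rate (> 0).
#' @param label_smoothing_eps label smoothing in `[0, 1)`.
#' @param dropout_rate head dropout in `[0, 1]`.
#' @param head_units hidden units of the head.
#' @param l2_lambda L2 penalty on the hidden dense weights.
#' @param class_weighting enable balanced inverse-frequency sample
#'   weights.
#' @param rgb_backbone,skeleton_backbone backbone names for the two
#'   streams.
#' @param weights_mode "random-frozen" (seeded random weights) or
#'   "pretrained-frozen" (user-supplied weight lists). Backbones are
#'   always frozen; fine-tuning them is out of scope.
#' @param early_stopping_patience epochs of non-improving validation loss
#'   tolerated before stopping.
#' @param lr_plateau_factor,lr_plateau_patience learning-rate reduction on
#'   plateau.
#' @param augment_rounds extra augmented copies of every training sample
#'   materialized before feature extraction (0 = none). Augmentation
#'   tiers follow the class-frequency rule with `minority_threshold`.
#' @param minority_threshold threshold for the strong augmentation tier.
#' @return a `fusion_model_config`.
#' @export
fusion_model_config <- function(image_size = 224L, batch_size = 16L,
                                max_epochs = 50L, learning_rate = 1e-5,
                                label_smoothing_eps = 0.01,
                                dropout_rate = 0.5, head_units = 128L,
                                l2_lambda = 1e-4, class_weighting = TRUE,
                                rgb_backbone = "mobilenet_v2",
                                skeleton_backbone = "densenet121",
                                weights_mode = c("random-frozen",
                                                 "pretrained-frozen",
                                                 "random-trainable"),
                                early_stopping_patience = 10L,
                                lr_plateau_factor = 0.5,
                                lr_plateau_patience = 5L,
                                augment_rounds = 0L,
                                minority_threshold = 800L) {
  weights_mode <- match.arg(weights_mode)
  if (weights_mode == "random-trainable")
    stop("backbones are frozen by design; 'random-trainable' is not supported")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (label_smoothing_eps < 0 || label_smoothing_eps >= 1)
    stop("label_smoothing_eps must be in [0, 1)")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]")
  structure(as.list(environment()), class = "fusion_model_config")
}

#' Jet colour-mapping of a binary mask
#'
#' The classic jet colormap restricted to the binary domain: value 0 maps
#' to jet's dark-blue endpoint (0, 0, 128) and value 1 to its dark-red
#' endpoint (128, 0, 0), producing the 3-channel image the skeleton
#' backbones expect.
#'
#' @param mask H x W binary image.
#' @return H x W x 3 uint8-range array containing exactly the two
#'   endpoint colours.
#' @export
jet_colormap <- function(mask) {
  assert_binary(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- array(0, c(h, w, 3))
  out[, , 1] <- mask * 128
  out[, , 3] <- (1 - mask) * 128
  out
}

#' Concatenate the two branch feature vectors
#'
#' RGB coordinates first, skeleton second; 1,280 + 1,024 = 2,304.
#'
#' @param z_rgb feature vector tagged `source = "rgb"`.
#' @param z_skel feature vector tagged `source = "skeleton"`.
#' @return fused feature vector (tagged `source = "fused"`).
#' @export
fuse_features <- function(z_rgb, z_skel) {
  if (!identical(attr(z_rgb, "source"), "rgb"))
    stop("z_rgb must carry source tag 'rgb'")
  if (!identical(attr(z_skel, "source"), "skeleton"))
    stop("z_skel must carry source tag 'skeleton'")
  structure(c(as.numeric(z_rgb), as.numeric(z_skel)), source = "fused")
}

#' Build a classifier
#'
#' @param variant one of "dual" (MobileNetV2 on RGB + DenseNet121 on
#'   jet-mapped vein masks, concatenated), "rgb_only" (MobileNetV2),
#'   "skeleton_densenet", "skeleton_efficientnet" (the two skeleton-only
#'   baselines), "fused_densenet" (DenseNet121 on fused images).
#' @param cfg a [fusion_model_config()].
#' @param seed seed for the random-frozen backbone weights and the head
#'   initialization.
#' @param backbone_weights optional named list (`rgb`, `skeleton`) of
#'   pretrained weight lists when `weights_mode = "pretrained-frozen"`.
#' @return an (untrained) `veinfuse_model`.
#' @export
build_model <- function(variant = c("dual", "rgb_only", "skeleton_densenet",
                                    "skeleton_efficientnet", "fused_densenet"),
                        cfg = fusion_model_config(), seed = 1L,
                        backbone_weights = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(cfg, "fusion_model_config"))
  need <- switch(variant,
    dual = list(rgb = cfg$rgb_backbone, skeleton = cfg$skeleton_backbone),
    rgb_only = list(rgb = cfg$rgb_backbone),
    skeleton_densenet = list(skeleton = "densenet121"),
    skeleton_efficientnet = list(skeleton = "efficientnet_b0"),
    fused_densenet = list(fused = "densenet121"))
  make_wts <- function(arch, branch) {
    if (cfg$weights_mode == "pretrained-frozen") {
      w <- backbone_weights[[branch]]
      if (is.null(w)) stop("pretrained-frozen mode needs backbone_weights for ",
                           branch)
      return(w)
    }
    # seed depends on the architecture, not the branch, so every variant
    # built from one seed shares identical backbone weights (as shared
    # pretrained backbones would be)
    ws <- seed + switch(arch, mobilenet_v2 = 1L, densenet121 = 2L,
                        efficientnet_b0 = 3L)
    w <- switch(arch,
                mobilenet_v2 = mobilenet_v2_weights(ws),
                densenet121 = densenet121_weights(ws),
                efficientnet_b0 = efficientnet_b0_weights(ws))
    w$tag <- paste0(arch, "@", ws)
    w
  }
  backbones <- lapply(seq_along(need), function(i)
    make_wts(need[[i]], names(need)[i]))
  names(backbones) <- names(need)
  feat_dim <- sum(vapply(need, backbone_feature_dim, 1L))
  structure(list(variant = variant, cfg = cfg, seed = seed,
                 backbones = backbones, feature_dim = feat_dim,
                 head = NULL, classes = NULL, trained = FALSE),
            class = "veinfuse_model")
}

#' Pooled branch features for one image
#'
#' Runs the branch's frozen backbone on a 224 x 224 x 3 input normalized
#' per that backbone's convention and returns the globally
#' average-pooled feature vector, tagged with its source.
#'
#' @param img H x W x 3 image (224 x 224).
#' @param branch "rgb" or "skeleton".
#' @param model a `veinfuse_model` holding the branch's weights.
#' @return numeric feature vector with a `source` attribute.
#' @export
branch_features <- function(img, branch = c("rgb", "skeleton"), model) {
  branch <- match.arg(branch)
  wts <- model$backbones[[branch]]
  if (is.null(wts)) stop("model variant '", model$variant,
                         "' has no ", branch, " branch")
  structure(backbone_forward(wts, img), source = branch)
}

# ---- head --------------------------------------------------------------

.softmax_rows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

.init_head <- function(d, units, n_class, seed) with_seed(seed, {
  lim <- sqrt(6 / (d + units))
  list(W1 = matrix(stats::runif(d * units, -lim, lim), d, units),
       b1 = rep(0, units),
       W2 = matrix(0, units, n_class),  # zero-init softmax layer
       b2 = rep(0, n_class))
})

.head_forward <- function(head, Z, cfg, mode = "eval", drop_mask = NULL) {
  H <- .relu(sweep(Z %*% head$W1, 2, head$b1, `+`))
  if (mode == "train" && cfg$dropout_rate > 0) {
    H <- H * drop_mask / (1 - cfg$dropout_rate)
  }
  logits <- sweep(H %*% head$W2, 2, head$b2, `+`)
  list(H = H, probs = .softmax_rows(logits))
}

#' Classification head of the fusion models
#'
#' Dense (128 units, ReLU, L2-regularized) -> dropout (train mode only)
#' -> dense softmax over the classes. In eval mode the head is
#' deterministic.
#'
#' @param z feature matrix (n x d) or single feature vector.
#' @param head head parameter list (`W1`, `b1`, `W2`, `b2`); when `NULL` a
#'   freshly initialized head for `n_class` classes is used.
#' @param cfg a [fusion_model_config()].
#' @param mode "train" (dropout active, seeded) or "eval".
#' @param n_class number of classes when initializing (>= 2).
#' @param rng_seed dropout seed in train mode.
#' @return `prediction_batch`: list with `probabilities` (rows on the
#'   simplex) and `labels_pred` (argmax indices).
#' @export
classification_head <- function(z, head = NULL, cfg = fusion_model_config(),
                                mode = c("eval", "train"), n_class = 2L,
                                rng_seed = 1L) {
  mode <- match.arg(mode)
  Z <- if (is.matrix(z)) z else matrix(z, 1)
  if (is.null(head)) {
    if (n_class < 2L) stop("need at least 2 classes")
    head <- .init_head(ncol(Z), cfg$head_units, n_class, rng_seed)
  }
  dm <- if (mode == "train")
    with_seed(rng_seed, matrix(stats::rbinom(nrow(Z) * cfg$head_units, 1,
                                             1 - cfg$dropout_rate),
                               nrow(Z), cfg$head_units))
  fw <- .head_forward(head, Z, cfg, mode, dm)
  structure(list(probabilities = fw$probs,
                 labels_pred = max.col(fw$probs, ties.method = "first")),
            class = "prediction_batch")
}

#' Label-smoothed categorical cross-entropy
#'
#' `L = -(1/N) sum_i w_i sum_c [y_ic (1 - eps) + eps/C] log(p_ic)`.
#' Probabilities are floored at 1e-12 (with a warning if any fall at or
#' below zero).
#'
#' @param y_true n x C one-hot matrix.
#' @param y_pred n x C probability matrix or a `prediction_batch`.
#' @param eps label smoothing in `[0, 1)`.
#' @param sample_weights optional per-sample weights (default 1).
#' @return mean loss (a single number).
#' @export
smoothed_crossentropy <- function(y_true, y_pred, eps = 0.01,
                                  sample_weights = NULL) {
  if (inherits(y_pred, "prediction_batch")) y_pred <- y_pred$probabilities
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)")
  if (!identical(dim(y_true), dim(y_pred)))
    stop("y_true and y_pred must share dimensions")
  C <- ncol(y_true)
  target <- y_true * (1 - eps) + eps / C
  if (any(y_pred[target > 0] <= 0))
    warning("non-positive probabilities floored at 1e-12")
  p <- pmax(y_pred, 1e-12)
  ll <- -rowSums(target * log(p))
  if (is.null(sample_weights)) mean(ll) else mean(sample_weights * ll)
}

# ---- training ----------------------------------------------------------

.record_input <- function(rec, variant) {
  switch(variant,
         rgb_only = list(rgb = rec$rgb),
         dual = list(rgb = rec$rgb, skeleton = jet_colormap(rec$vein_truth)),
         skeleton_densenet = ,
         skeleton_efficientnet = list(skeleton = jet_colormap(rec$vein_truth)),
         fused_densenet = list(fused = unclass(
           compose_fused(rec$rgb, rec$vein_truth))))
}

.resize_to <- function(img, side) {
  d <- dim(img)
  if (d[1] == side && d[2] == side) return(img)
  out <- EBImage::resize(img, w = side, h = side)
  array(out, c(side, side, d[3]))
}

.record_features <- function(model, rec, cache = NULL) {
  side <- model$cfg$image_size
  ins <- .record_input(rec, model$variant)
  feats <- lapply(names(ins), function(nm) {
    key <- if (!is.null(cache) && !is.null(model$backbones[[nm]]$tag) &&
               !is.null(rec$instance_id))
      paste(model$backbones[[nm]]$tag, nm, rec$label, rec$instance_id,
            rec$render, sep = "|")
    if (!is.null(key) && !is.null(cache[[key]])) return(cache[[key]])
    img <- .resize_to(ins[[nm]], side)
    z <- backbone_forward(model$backbones[[nm]], img)
    if (!is.null(key)) cache[[key]] <- z
    z
  })
  unlist(feats)
}

.features_matrix <- function(model, records, verbose = FALSE, cache = NULL) {
  Z <- matrix(0, length(records), model$feature_dim)
  for (i in seq_along(records)) {
    Z[i, ] <- .record_features(model, records[[i]], cache)
    if (verbose && i %% 25 == 0) message("  features: ", i, "/", length(records))
  }
  Z
}

.one_hot <- function(y_idx, C) {
  Y <- matrix(0, length(y_idx), C)
  Y[cbind(seq_along(y_idx), y_idx)] <- 1
  Y
}

.augmented_records <- function(records, rounds, threshold, seed) {
  if (rounds < 1) return(records)
  counts <- table(vapply(records, `[[`, "", "label"))
  tab <- class_frequency_table(stats::setNames(as.integer(counts),
                                               names(counts)), threshold)
  extra <- list()
  for (r in seq_len(rounds)) for (i in seq_along(records)) {
    rec <- records[[i]]
    pol <- policy_for_class(rec$label, tab)
    a <- augment(rec$rgb, pol, rng_seed = seed + r * 100003L + i,
                 mask = rec$vein_truth)
    rec$rgb <- a$img; rec$vein_truth <- a$mask
    # distinct id so augmented views never alias cached originals
    rec$instance_id <- paste0(rec$instance_id, "#aug", r)
    extra[[length(extra) + 1L]] <- rec
  }
  c(records, extra)
}

#' Train a classifier on split-tagged leaf records
#'
#' Extracts frozen-backbone features for the train and validation splits
#' (optionally materializing class-frequency-aware augmented copies of the
#' training samples first) and optimizes the head with Adam under
#' label-smoothed, class-weighted cross-entropy, with early stopping on
#' the validation loss and learning-rate reduction on plateau. Runs are
#' deterministic given the seed.
#'
#' @param model an untrained `veinfuse_model` from [build_model()].
#' @param records list of `leaf_record`s carrying `split` tags ("train"
#'   and "val"; other tags are ignored).
#' @param rng_seed integer seed for shuffling and dropout.
#' @param verbose log per-epoch metrics.
#' @param feature_cache optional environment memoizing pooled backbone
#'   features across calls (keyed by backbone and record identity); useful
#'   when several variants are trained on the same records.
#' @return the trained model, with a `history` data frame (epoch, lr,
#'   train/val loss and accuracy) attached.
#' @export
train_model <- function(model, records, rng_seed = 1L, verbose = FALSE,
                        feature_cache = NULL) {
  stopifnot(inherits(model, "veinfuse_model"))
  cfg <- model$cfg
  splits <- vapply(records, `[[`, "", "split")
  train_recs <- records[splits == "train"]
  val_recs <- records[splits == "val"]
  if (length(train_recs) == 0) stop("no records tagged split = 'train'")
  if (model$variant %in% c("dual", "skeleton_densenet", "skeleton_efficientnet",
                           "fused_densenet") &&
      any(vapply(train_recs, function(r) is.null(r$vein_truth), TRUE)))
    stop("variant '", model$variant, "' requires paired vein masks")
  train_recs <- .augmented_records(train_recs, cfg$augment_rounds,
                                   cfg$minority_threshold, rng_seed)

  classes <- sort(unique(vapply(train_recs, `[[`, "", "label")))
  C <- length(classes)
  if (C < 2) stop("need at least 2 classes to train")
  y_tr <- match(vapply(train_recs, `[[`, "", "label"), classes)
  Z_tr <- .features_matrix(model, train_recs, verbose, feature_cache)
  Y_tr <- .one_hot(y_tr, C)
  have_val <- length(val_recs) > 0
  if (have_val) {
    y_va <- match(vapply(val_recs, `[[`, "", "label"), classes)
    Z_va <- .features_matrix(model, val_recs, verbose, feature_cache)
    Y_va <- .one_hot(y_va, C)
  }

  sw <- rep(1, length(y_tr))
  if (cfg$class_weighting) {
    counts <- stats::setNames(tabulate(y_tr, C), classes)
    w <- class_weights(class_frequency_table(counts, cfg$minority_threshold))
    sw <- as.numeric(w[classes][y_tr])
  }

  head <- .init_head(model$feature_dim, cfg$head_units, C, rng_seed)
  adam <- lapply(head, function(p) list(m = p * 0, v = p * 0))
  lr <- cfg$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-7
  step <- 0L
  eps <- cfg$label_smoothing_eps
  best_val <- Inf; best_head <- head; wait_stop <- 0L; wait_lr <- 0L
  hist_rows <- list()

  eval_split <- function(Z, Y, y_idx) {
    fw <- .head_forward(head, Z, cfg, "eval")
    list(loss = smoothed_crossentropy(Y, fw$probs, eps) +
           cfg$l2_lambda * sum(head$W1^2),
         acc = mean(max.col(fw$probs, ties.method = "first") == y_idx))
  }

  n <- nrow(Z_tr)
  rng_epoch <- with_seed(rng_seed, sample.int(1e9, cfg$max_epochs * 2L))
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(rng_epoch[2L * epoch - 1L], sample.int(n))
    dropseed <- rng_epoch[2L * epoch]
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    bi <- 0L
    for (idx in batches) {
      bi <- bi + 1L
      Zb <- Z_tr[idx, , drop = FALSE]
      Yb <- Y_tr[idx, , drop = FALSE]
      wb <- sw[idx]
      nb <- length(idx)
      dm <- with_seed(dropseed + bi,
                      matrix(stats::rbinom(nb * cfg$head_units, 1,
                                           1 - cfg$dropout_rate),
                             nb, cfg$head_units))
      fw <- .head_forward(head, Zb, cfg, "train", dm)
      target <- Yb * (1 - eps) + eps / C
      dlogits <- (fw$probs - target) * wb / nb
      gW2 <- t(fw$H) %*% dlogits
      gb2 <- colSums(dlogits)
      dH <- dlogits %*% t(head$W2)
      dH <- dH * (fw$H > 0) * dm / (1 - cfg$dropout_rate)
      gW1 <- t(Zb) %*% dH + 2 * cfg$l2_lambda * head$W1
      gb1 <- colSums(dH)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      step <- step + 1L
      for (nm in names(head)) {
        adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * grads[[nm]]
        adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * grads[[nm]]^2
        mh <- adam[[nm]]$m / (1 - beta1^step)
        vh <- adam[[nm]]$v / (1 - beta2^step)
        head[[nm]] <- head[[nm]] - lr * mh / (sqrt(vh) + adam_eps)
      }
    }
    tr <- eval_split(Z_tr, Y_tr, y_tr)
    va <- if (have_val) eval_split(Z_va, Y_va, y_va) else tr
    hist_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                     train_loss = tr$loss, train_acc = tr$acc,
                                     val_loss = va$loss, val_acc = va$acc)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2g  train %.4f/%.3f  val %.4f/%.3f",
                      epoch, lr, tr$loss, tr$acc, va$loss, va$acc))
    if (va$loss < best_val - 1e-6) {
      best_val <- va$loss; best_head <- head; wait_stop <- 0L; wait_lr <- 0L
    } else {
      wait_stop <- wait_stop + 1L; wait_lr <- wait_lr + 1L
      if (wait_lr >= cfg$lr_plateau_patience) {
        lr <- lr * cfg$lr_plateau_factor; wait_lr <- 0L
      }
      if (wait_stop >= cfg$early_stopping_patience) break
    }
  }
  model$head <- best_head
  model$classes <- classes
  model$trained <- TRUE
  model$history <- do.call(rbind, hist_rows)
  model
}

#' Predict class probabilities for leaf records
#'
#' @param object a trained `veinfuse_model`.
#' @param records list of `leaf_record`s.
#' @param feature_cache optional feature memo, see [train_model()].
#' @param ... unused.
#' @return `prediction_batch` with `probabilities` (n x C, rows summing to
#'   1), `labels_pred` (argmax indices) and `classes`.
#' @export
predict.veinfuse_model <- function(object, records, feature_cache = NULL, ...) {
  if (!isTRUE(object$trained)) stop("model has not been trained")
  Z <- .features_matrix(object, records, cache = feature_cache)
  fw <- .head_forward(object$head, Z, object$cfg, "eval")
  structure(list(probabilities = fw$probs,
                 labels_pred = max.col(fw$probs, ties.method = "first"),
                 classes = object$classes),
            class = "prediction_batch")
}
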