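#' Pre-training and supervised-training configurations
#'
#' Defaults follow the framework's published regime: learning rate 1.5e-4,
#' decoupled weight decay 0.05 with betas (0.9, 0.95), batch size 32;
#' 50 pre-training epochs keeping the minimum-validation-loss checkpoint, and
#' up to 100 supervised epochs with early-stopping patience 10 keeping the
#' maximum-validation-accuracy checkpoint. Desk-scale runs override `epochs`
#' and `batch_size`.
#'
#' @param epochs positive integer.
#' @param lr learning rate.
#' @param weight_decay decoupled weight decay coefficient.
#' @param betas Adam moment coefficients.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling shuffling, masking and initialization.
#' @return a `pretrain_config`.
#' @export
pretrain_config <- function(epochs = 50L, lr = 1.5e-4, weight_decay = 0.05,
                            betas = c(0.9, 0.95), batch_size = 32L, seed = 0L) {
  if (epochs < 1L) config_error("epochs must be >= 1")
  if (lr <= 0 || weight_decay < 0 || batch_size < 1L)
    config_error("invalid pre-training hyperparameters")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, betas = betas,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 checkpoint_policy = "min-validation-loss"),
            class = "pretrain_config")
}

#' @rdname pretrain_config
#' @param early_stop_patience epochs without a strict validation-accuracy
#'   improvement before stopping.
#' @param freeze_encoder keep pre-trained encoder weights fixed (feature
#'   extraction); the framework's default regime.
#' @param augmentations subset of `c("rotation", "hflip", "color_jitter",
#'   "gaussian_blur", "elastic")`, applied to training images only.
#' @export
supervised_config <- function(epochs = 100L, early_stop_patience = 10L,
                              lr = 1.5e-4, weight_decay = 0.05,
                              betas = c(0.9, 0.95), batch_size = 32L,
                              freeze_encoder = TRUE,
                              augmentations = character(0), seed = 0L) {
  if (epochs < 1L) config_error("epochs must be >= 1")
  if (early_stop_patience >= epochs)
    config_error("patience must be smaller than epochs")
  allowed <- c("rotation", "hflip", "color_jitter", "gaussian_blur", "elastic")
  if (!all(augmentations %in% allowed))
    config_error("unknown augmentation name")
  structure(list(epochs = as.integer(epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr = lr, weight_decay = weight_decay, betas = betas,
                 batch_size = as.integer(batch_size),
                 freeze_encoder = isTRUE(freeze_encoder),
                 augmentations = augmentations, seed = as.integer(seed),
                 checkpoint_policy = "max-validation-accuracy"),
            class = "supervised_config")
}

# --- image access & normalization -------------------------------------------

# Resolve manifest rows to in-memory images: either from a named list keyed
# by image_id or by reading PNGs relative to `root`.
get_images <- function(manifest, images = NULL, root = NULL) {
  ids <- manifest$image_id
  if (!is.null(images)) {
    miss <- setdiff(ids, names(images))
    if (length(miss)) data_error(paste("missing images for ids:",
                                       paste(utils::head(miss, 3),
                                             collapse = ", ")))
    return(images[ids])
  }
  if (is.null(root)) data_error("provide either `images` or `root`")
  out <- lapply(seq_along(ids), function(i) {
    a <- png::readPNG(file.path(root, manifest$image_path[i]))
    if (length(dim(a)) == 3L) a <- a[, , 1]
    a
  })
  names(out) <- ids
  out
}

# Per-source pixel mean/sd computed on a training split.
compute_norm_stats <- function(manifest, imgs) {
  out <- list()
  for (s in unique(manifest$source_id)) {
    px <- unlist(imgs[manifest$image_id[manifest$source_id == s]])
    out[[s]] <- c(mean = mean(px), sd = max(stats::sd(px), 1e-6))
  }
  out
}

normalize_img <- function(img, st) (img - st[["mean"]]) / st[["sd"]]

# Source-aware normalization with fallback stats computed from the images at
# hand when a source was never seen during pre-training.
norm_for_source <- function(norm, source_id, manifest = NULL, imgs = NULL) {
  st <- norm[[source_id]]
  if (is.null(st)) {
    px <- unlist(imgs[manifest$image_id[manifest$source_id == source_id]])
    st <- c(mean = mean(px), sd = max(stats::sd(px), 1e-6))
  }
  st
}

# --- self-supervised pre-training --------------------------------------------

#' Self-supervised masked-autoencoder pre-training
#'
#' Trains an MAE on the fused (label-free) training set, computing the masked
#' reconstruction loss on a fresh random mask per image per epoch, and
#' returns the checkpoint with the minimum fused-validation loss. Per-epoch
#' train/validation losses are logged. Encoder inputs are standardized with
#' per-source mean/sd computed on the training split; reconstruction targets
#' stay on the raw `[0, 1]` pixel scale.
#'
#' @param fusion a [fuse_for_pretraining()] result.
#' @param mae an `mae_config` or preset name.
#' @param cfg a [pretrain_config()].
#' @param images named list of image matrices keyed by image id, or `NULL` to
#'   read PNGs under `root`.
#' @param root directory image paths are relative to (when `images` is NULL).
#' @param log_path optional CSV path for the per-epoch loss log.
#' @param verbose print per-epoch losses.
#' @return an `mae_checkpoint`: best parameters, config, normalization stats,
#'   per-epoch log, best epoch, seed and provenance.
#' @export
pretrain <- function(fusion, mae, cfg = pretrain_config(), images = NULL,
                     root = NULL, log_path = NULL, verbose = FALSE) {
  if (!inherits(fusion, "fusion_result")) config_error("fusion_result required")
  if (is.character(mae)) mae <- mae_preset(mae)
  if (nrow(fusion$fused_train) == 0L || nrow(fusion$fused_val) == 0L)
    data_error("fused train and validation sets must be nonempty")
  model <- build_mae(mae, rng_seed = cfg$seed)
  tr_imgs <- get_images(fusion$fused_train, images, root)
  va_imgs <- get_images(fusion$fused_val, images, root)
  norm <- compute_norm_stats(fusion$fused_train, tr_imgs)
  grid <- mae$patch_grid
  tr_src <- fusion$fused_train$source_id
  va_src <- fusion$fused_val$source_id

  epoch_losses <- function(p, idx, imgs, srcs, seed_tag) {
    # plain-forward mean loss with deterministic per-image masks
    mean(vapply(idx, function(i) {
      plan <- sample_mask(grid, mae$mask_ratio, derive_seed(cfg$seed, seed_tag, i))
      xin <- normalize_img(imgs[[i]], norm[[srcs[i]]])
      as.numeric(mae_loss_node(model_with(p), xin, imgs[[i]], plan, p))
    }, numeric(1)))
  }
  model_with <- function(p) { m <- model; m$params <- p; m }

  n_tr <- length(tr_imgs)
  state <- adamw_init(model$params)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 11L, ep), sample(n_tr))
    tr_loss_sum <- 0
    for (bstart in seq(1L, n_tr, by = cfg$batch_size)) {
      bidx <- ord[bstart:min(bstart + cfg$batch_size - 1L, n_tr)]
      step <- with_tape({
        leaves <- lapply(model$params, ad_leaf)
        losses <- lapply(bidx, function(i) {
          plan <- sample_mask(grid, mae$mask_ratio,
                              derive_seed(cfg$seed, ep, i))
          xin <- normalize_img(tr_imgs[[i]], norm[[tr_src[i]]])
          mae_loss_node(model, xin, tr_imgs[[i]], plan, leaves)
        })
        total <- op_scale(Reduce(op_add, losses), 1 / length(bidx))
        ad_backward(total)
        list(loss = as.numeric(nval(total)),
             grads = lapply(leaves, function(l) l$grad))
      })
      if (!is.finite(step$loss))
        train_error(sprintf("divergence: non-finite loss at epoch %d", ep))
      upd <- adamw_step(model$params, step$grads, state, cfg$lr,
                        cfg$weight_decay, cfg$betas)
      model$params <- upd$params
      state <- upd$state
      tr_loss_sum <- tr_loss_sum + step$loss * length(bidx)
    }
    tr_loss <- tr_loss_sum / n_tr
    va_loss <- epoch_losses(model$params, seq_along(va_imgs), va_imgs,
                            va_src, 999L)
    if (!is.finite(va_loss))
      train_error(sprintf("divergence: non-finite validation loss at epoch %d", ep))
    log <- rbind(log, data.frame(epoch = ep, train_loss = tr_loss,
                                 val_loss = va_loss))
    if (verbose) message(sprintf("epoch %d train %.5f val %.5f", ep, tr_loss,
                                 va_loss))
    if (va_loss < best$loss)
      best <- list(loss = va_loss, params = model$params, epoch = ep)
  }
  if (!is.null(log_path)) utils::write.csv(log, log_path, row.names = FALSE)
  structure(list(params = best$params, config = mae, norm = norm, log = log,
                 best_epoch = best$epoch, seed = cfg$seed,
                 provenance = sprintf(
                   "MAE pre-training on %d fused images, %d epochs, seed %d",
                   n_tr, cfg$epochs, cfg$seed)),
            class = "mae_checkpoint")
}

# --- supervised transfer ------------------------------------------------------

#' Three-dense-layer classification head specification
#'
#' @param hidden_dims two hidden widths; the head is
#'   `d_enc -> d1 -> d2 -> 2` with ReLU activations and a softmax output over
#'   (NORMAL, AMD).
#' @return a `head_spec`.
#' @export
head_spec <- function(hidden_dims = c(512L, 256L)) {
  if (length(hidden_dims) != 2L || any(hidden_dims < 1L))
    config_error("hidden_dims must be two positive widths")
  structure(list(hidden_dims = as.integer(hidden_dims), n_classes = 2L),
            class = "head_spec")
}

#' Build a classifier from a pre-trained encoder (or from scratch)
#'
#' Replaces the MAE decoder with a classification head: mean-pooled final
#' encoder tokens feed three successive dense layers (ReLU) ending in two
#' logits, turned into class probabilities by a softmax. With a checkpoint
#' the encoder weights equal the checkpoint bit-exactly; with `NULL` the
#' encoder is randomly initialized (the no-pre-training ablation arm).
#'
#' @param encoder_ckpt an `mae_checkpoint`, or `NULL` for random
#'   initialization.
#' @param config required when `encoder_ckpt` is NULL: the `mae_config` (or
#'   preset name) describing the encoder. When both are given the families
#'   must match.
#' @param head a [head_spec()].
#' @param freeze keep encoder weights fixed during supervised training.
#' @param rng_seed seed for head (and, without a checkpoint, encoder)
#'   initialization.
#' @return an `rt_classifier` handle.
#' @export
build_classifier <- function(encoder_ckpt = NULL, config = NULL,
                             head = head_spec(), freeze = TRUE,
                             rng_seed = 0L) {
  if (is.character(config)) config <- mae_preset(config)
  if (!is.null(encoder_ckpt)) {
    if (!inherits(encoder_ckpt, "mae_checkpoint"))
      config_error("encoder_ckpt must be an mae_checkpoint")
    if (!is.null(config) &&
        config$encoder$family != encoder_ckpt$config$encoder$family)
      config_error("encoder family mismatch between checkpoint and config")
    config <- encoder_ckpt$config
  } else if (is.null(config)) {
    config_error("config is required when no encoder checkpoint is given")
  }
  base <- build_mae(config, rng_seed = rng_seed)
  enc_names <- grep("^enc\\.", names(base$params), value = TRUE)
  params <- base$params[enc_names]
  if (!is.null(encoder_ckpt))
    params <- encoder_ckpt$params[enc_names]
  es <- enc_stage_dims(config)
  d_enc <- es$dims[length(es$dims)]
  d1 <- head$hidden_dims[1]; d2 <- head$hidden_dims[2]
  # He-scaled init for the ReLU head (the transformer's small residual-branch
  # init would make a plain dense stack start near-dead)
  params <- c(params, with_seed(derive_seed(rng_seed, 101L), list(
    "head.w1" = init_mat(d_enc, d1, sd = sqrt(2 / d_enc)),
    "head.b1" = matrix(0, 1, d1),
    "head.w2" = init_mat(d1, d2, sd = sqrt(2 / d1)),
    "head.b2" = matrix(0, 1, d2),
    # near-zero final layer: logits start at ~0 so early epochs move the
    # decision rule instead of unwinding large random predictions
    "head.w3" = init_mat(d2, 2L, sd = 0.01),
    "head.b3" = matrix(0, 1, 2L)
  )))
  structure(list(config = config, params = params, geom = base$geom,
                 head = head, freeze = isTRUE(freeze),
                 norm = encoder_ckpt$norm %||% list(),
                 pretrained = !is.null(encoder_ckpt)),
            class = "rt_classifier")
}

# Mean-pooled final-stage encoder features for one (already normalized)
# image; plain matrices in, plain 1 x d_enc matrix out.
classifier_features <- function(clf, image, p = NULL) {
  if (is.null(p)) p <- clf$params
  nval(op_colmeans(mae_encode(clf, image, plan = NULL, p = p)))
}

# Pooled encoder features are standardized per dimension with statistics
# computed on the training split (stored in the checkpoint): the raw pooled
# token means vary on a scale far too small for a ReLU head to train on.
standardize_feats <- function(feats, fn) {
  if (is.null(fn)) return(feats)
  v <- nval(feats)
  ctr <- op_add(feats, matrix(-fn$mean, 1L))
  op_mul(ctr, matrix(1 / fn$sd, nrow(v), ncol(v), byrow = TRUE))
}

feat_stats <- function(feats) {
  s <- apply(feats, 2, stats::sd)
  # floor relative to the typical feature scale: near-constant dimensions
  # must not explode to huge standardized values on held-out data
  list(mean = colMeans(feats),
       sd = pmax(s, 0.1 * stats::median(s), 1e-12))
}

head_forward <- function(feats, p, fn = NULL) {
  h0 <- standardize_feats(feats, fn)
  h1 <- op_relu(linear_fwd(h0, p[["head.w1"]], p[["head.b1"]]))
  h2 <- op_relu(linear_fwd(h1, p[["head.w2"]], p[["head.b2"]]))
  linear_fwd(h2, p[["head.w3"]], p[["head.b3"]])
}

# Softmax AMD probability for a feature matrix (class order NORMAL, AMD).
head_scores <- function(feats, p, fn = NULL) {
  logits <- nval(head_forward(feats, p, fn))
  e <- exp(logits - apply(logits, 1, max))
  (e / rowSums(e))[, 2]
}

#' Predict AMD probabilities for a set of images
#'
#' @param ckpt a `classifier_checkpoint` (or `rt_classifier`).
#' @param manifest manifest of images to score.
#' @param images,root image access as in [pretrain()].
#' @return data frame with `image_id`, `y_true` (1 = AMD) and `score`
#'   (softmax probability of AMD).
#' @export
predict_classifier <- function(ckpt, manifest, images = NULL, root = NULL) {
  imgs <- get_images(manifest, images, root)
  feats <- classifier_feature_matrix(ckpt, manifest, imgs)
  data.frame(image_id = manifest$image_id,
             y_true = as.integer(manifest$class_label == "AMD"),
             score = head_scores(feats, ckpt$params, ckpt$feat_norm),
             stringsAsFactors = FALSE)
}

classifier_feature_matrix <- function(clf, manifest, imgs) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    st <- norm_for_source(clf$norm, manifest$source_id[i], manifest, imgs)
    classifier_features(clf, normalize_img(imgs[[manifest$image_id[i]]], st))
  })
  do.call(rbind, rows)
}

#' Supervised training of the classification head
#'
#' Trains the classifier on binary-labeled manifests with cross-entropy on
#' the softmax logits, early stopping after `early_stop_patience` epochs
#' without a strict validation-accuracy improvement, and returns the
#' checkpoint with maximum validation accuracy. With a frozen encoder,
#' features are extracted once and only the head is optimized; augmentations
#' (training images only) force per-epoch feature re-extraction.
#'
#' @param clf an [build_classifier()] handle.
#' @param train_manifest,val_manifest binary-labeled `oct_manifest`s.
#' @param cfg a [supervised_config()].
#' @param images,root image access as in [pretrain()].
#' @param log_path optional CSV path for the per-epoch log.
#' @return a `classifier_checkpoint`.
#' @export
train_classifier <- function(clf, train_manifest, val_manifest,
                             cfg = supervised_config(), images = NULL,
                             root = NULL, log_path = NULL) {
  labs <- unique(train_manifest$class_label)
  if (!all(sort(labs) == c("AMD", "NORMAL")))
    data_error("training set must contain both NORMAL and AMD (and only those)")
  if (nrow(val_manifest) == 0L) data_error("validation set must be nonempty")
  freeze <- clf$freeze && cfg$freeze_encoder
  tr_imgs <- get_images(train_manifest, images, root)
  va_imgs <- get_images(val_manifest, images, root)
  if (!length(clf$norm))
    clf$norm <- compute_norm_stats(train_manifest, tr_imgs)
  y_tr <- as.integer(train_manifest$class_label == "AMD")  # 1 = AMD
  y_va <- as.integer(val_manifest$class_label == "AMD")
  onehot <- cbind(1 - y_tr, y_tr)

  head_names <- grep("^head\\.", names(clf$params), value = TRUE)
  train_names <- if (freeze) head_names else names(clf$params)
  enc_snapshot <- clf$params[grep("^enc\\.", names(clf$params))]

  feats_ref <- classifier_feature_matrix(clf, train_manifest, tr_imgs)
  fn <- feat_stats(feats_ref)
  feats_tr <- if (freeze && !length(cfg$augmentations)) feats_ref else NULL
  feats_va <- classifier_feature_matrix(clf, val_manifest, va_imgs)

  state <- adamw_init(clf$params[train_names])
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, params = clf$params, epoch = 0L)
  stale <- 0L
  n <- nrow(train_manifest)
  for (ep in seq_len(cfg$epochs)) {
    ep_feats <- feats_tr
    ep_imgs <- tr_imgs
    if (is.null(ep_feats)) {
      if (length(cfg$augmentations)) {
        ep_imgs <- lapply(seq_len(n), function(i)
          augment_image(tr_imgs[[i]], cfg$augmentations,
                        derive_seed(cfg$seed, ep, i)))
        names(ep_imgs) <- names(tr_imgs)
      }
      if (freeze)
        ep_feats <- classifier_feature_matrix(clf, train_manifest, ep_imgs)
    }
    ord <- with_seed(derive_seed(cfg$seed, 17L, ep), sample(n))
    ep_loss_sum <- 0
    for (bstart in seq(1L, n, by = cfg$batch_size)) {
      bidx <- ord[bstart:min(bstart + cfg$batch_size - 1L, n)]
      step <- with_tape({
        leaves <- lapply(clf$params[train_names], ad_leaf)
        p_all <- clf$params
        p_all[train_names] <- leaves
        fe <- if (freeze) ep_feats[bidx, , drop = FALSE] else {
          frows <- lapply(bidx, function(i) {
            st <- norm_for_source(clf$norm, train_manifest$source_id[i],
                                  train_manifest, ep_imgs)
            op_colmeans(mae_encode(clf, normalize_img(
              ep_imgs[[train_manifest$image_id[i]]], st), NULL, p_all))
          })
          Reduce(op_rbind2, frows)
        }
        lsm <- op_logsoftmax_rows(head_forward(fe, p_all, fn))
        loss <- op_scale(op_sum(op_mul(lsm, onehot[bidx, , drop = FALSE])),
                         -1 / length(bidx))
        ad_backward(loss)
        list(loss = as.numeric(nval(loss)),
             grads = lapply(leaves, function(l) l$grad))
      })
      if (!is.finite(step$loss))
        train_error(sprintf("divergence at supervised epoch %d", ep))
      upd <- adamw_step(clf$params[train_names], step$grads, state, cfg$lr,
                        cfg$weight_decay, cfg$betas)
      clf$params[train_names] <- upd$params
      state <- upd$state
      ep_loss_sum <- ep_loss_sum + step$loss * length(bidx)
    }
    # validation (never augmented)
    va_scores <- head_scores(feats_va, clf$params, fn)
    va_pred <- as.integer(va_scores >= 0.5)
    va_acc <- mean(va_pred == y_va)
    va_lsm <- nval(op_logsoftmax_rows(head_forward(feats_va, clf$params, fn)))
    va_loss <- -mean(va_lsm[cbind(seq_along(y_va), y_va + 1L)])
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss_sum / n,
                                 val_loss = va_loss, val_acc = va_acc))
    if (va_acc > best$acc) {  # strictly greater resets patience; ties do not
      best <- list(acc = va_acc, params = clf$params, epoch = ep)
      stale <- 0L
    } else {
      if (va_acc == best$acc)  # among ties keep the most-trained weights
        best <- list(acc = va_acc, params = clf$params, epoch = ep)
      stale <- stale + 1L
      if (stale >= cfg$early_stop_patience) break
    }
  }
  if (!is.null(log_path)) utils::write.csv(log, log_path, row.names = FALSE)
  if (freeze) best$params[names(enc_snapshot)] <- enc_snapshot
  structure(list(params = best$params, config = clf$config, geom = clf$geom,
                 head = clf$head, norm = clf$norm, feat_norm = fn,
                 freeze = freeze,
                 log = log, best_epoch = best$epoch, seed = cfg$seed,
                 train_ids = train_manifest$image_id,
                 provenance = sprintf(
                   "supervised head training on %d images, best epoch %d",
                   n, best$epoch)),
            class = c("classifier_checkpoint", "rt_classifier"))
}

# --- training-time augmentations (training images only) ----------------------

augment_image <- function(img, set, seed) {
  with_seed(seed, {
    h <- nrow(img); w <- ncol(img)
    if ("hflip" %in% set && stats::runif(1) < 0.5) img <- img[, w:1]
    if ("rotation" %in% set) {
      ang <- stats::runif(1, -15, 15) * pi / 180
      ctr <- c((h + 1) / 2, (w + 1) / 2)
      r <- rep(seq_len(h), times = w); c <- rep(seq_len(w), each = h)
      sr <- round(ctr[1] + cos(ang) * (r - ctr[1]) - sin(ang) * (c - ctr[2]))
      sc <- round(ctr[2] + sin(ang) * (r - ctr[1]) + cos(ang) * (c - ctr[2]))
      ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
      out <- matrix(0, h, w)
      out[cbind(r[ok], c[ok])] <- img[cbind(sr[ok], sc[ok])]
      img <- out
    }
    if ("color_jitter" %in% set) {
      img <- clamp01(img * stats::runif(1, 0.8, 1.2) +
                       stats::runif(1, -0.2, 0.2))
    }
    if ("gaussian_blur" %in% set) img <- gauss_blur(img, stats::runif(1, 0.1, 1))
    if ("elastic" %in% set) {
      shift <- round(2 * sin(2 * pi * seq_len(w) / w +
                               stats::runif(1, 0, 2 * pi)))
      for (j in seq_len(w)) {
        s <- shift[j]
        if (s != 0) img[, j] <- img[pmin(pmax(seq_len(h) + s, 1), h), j]
      }
      img
    }
    img
  })
}
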