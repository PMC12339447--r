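test_that("pre-training reduces the masked validation loss on synthetic data", {
  px <- shared_pretrain()
  log <- px$ck$log
  expect_equal(nrow(log), 3)
  expect_lt(log$val_loss[3], log$val_loss[1])
  expect_equal(px$ck$best_epoch, which.min(log$val_loss))
  expect_true(all(is.finite(c(log$train_loss, log$val_loss))))
})

test_that("pre-training rejects empty schedules and is seed-deterministic", {
  expect_error(pretrain_config(epochs = 0), "epochs")
  set <- tiny_labeled_set(12, seed = 41)
  fus <- fuse_for_pretraining(list(set$manifest), rng_seed = 2)
  cfg <- pretrain_config(epochs = 2, batch_size = 8, seed = 9)
  ck1 <- pretrain(fus, "vit-tiny", cfg, images = set$images)
  ck2 <- pretrain(fus, "vit-tiny", cfg, images = set$images)
  expect_identical(ck1$log, ck2$log)
  expect_identical(ck1$params, ck2$params)
})

test_that("transfer is exact: classifier encoder equals the checkpoint", {
  px <- shared_pretrain()
  clf <- build_classifier(px$ck, head = head_spec(c(16, 8)), rng_seed = 3)
  enc_names <- grep("^enc\\.", names(px$ck$params), value = TRUE)
  expect_identical(clf$params[enc_names], px$ck$params[enc_names])
  # encoder forward outputs equal the pretrained MAE encoder's
  set.seed(6)
  for (i in 1:10) {
    img <- matrix(stats::runif(64 * 64), 64)
    mae_model <- import_weights(build_mae(px$ck$config, 0), px$ck$params)
    f_mae <- colMeans(retmae:::nval(retmae:::mae_encode(mae_model, img)))
    f_clf <- as.numeric(retmae:::classifier_features(clf, img))
    expect_identical(f_clf, unname(f_mae))
  }
})

test_that("frozen means frozen: encoder bits survive supervised training", {
  px <- shared_pretrain()
  set <- px$set
  trm <- manifest_split(set$manifest, "train")
  vam <- manifest_split(set$manifest, "val")
  clf <- build_classifier(px$ck, head = head_spec(c(16, 8)), freeze = TRUE,
                          rng_seed = 3)
  fit <- train_classifier(clf, trm, vam,
                          supervised_config(epochs = 6, early_stop_patience = 3,
                                            lr = 1e-3, batch_size = 16,
                                            seed = 4),
                          images = set$images)
  enc_names <- grep("^enc\\.", names(px$ck$params), value = TRUE)
  expect_identical(fit$params[enc_names], px$ck$params[enc_names])
  # ... while the head has moved
  expect_false(identical(fit$params[["head.w1"]], clf$params[["head.w1"]]))
})

test_that("head parameter count follows the closed form", {
  px <- shared_pretrain()
  clf <- build_classifier(px$ck, head = head_spec(c(512, 256)), rng_seed = 1)
  d_in <- nrow(clf$params[["head.w1"]])
  head_n <- sum(vapply(clf$params[grep("^head\\.", names(clf$params))],
                       length, numeric(1)))
  expect_equal(head_n,
               d_in * 512 + 512 + 512 * 256 + 256 + 256 * 2 + 2)
})

test_that("the classifier learns separable synthetic data", {
  les <- list(AMD = lesion_params("AMD", n_bumps = 3, bump_amplitude = 8,
                                  bump_width = 5))
  gen <- generate_source(noiseless_domain(), 200, 1L,
                         c(NORMAL = 0.5, AMD = 0.5), rng_seed = 77,
                         lesions = les)
  man <- split_random_stratified(gen$manifest, c(0.6, 0.2, 0.2), 77)
  fus <- fuse_for_pretraining(list(man), rng_seed = 1)
  ck <- pretrain(fus, "swinv2-tiny",
                 pretrain_config(epochs = 3, batch_size = 16, seed = 2),
                 images = gen$images)
  clf <- build_classifier(ck, head = head_spec(c(32, 16)), rng_seed = 5)
  fit <- train_classifier(clf, manifest_split(man, "train"),
                          manifest_split(man, "val"),
                          supervised_config(epochs = 30,
                                            early_stop_patience = 20,
                                            lr = 1e-3, batch_size = 16,
                                            seed = 5),
                          images = gen$images)
  expect_gt(max(fit$log$val_acc), 0.8)
})

test_that("early stopping halts after `patience` stale epochs", {
  set <- tiny_labeled_set(30, seed = 11)
  trm <- manifest_split(set$manifest, "train")
  vam <- manifest_split(set$manifest, "val")
  clf <- build_classifier(NULL, config = "vit-tiny",
                          head = head_spec(c(8, 4)), rng_seed = 2)
  # lr 0 freezes the head: validation accuracy can never strictly improve,
  # so training must stop exactly `patience` epochs after the first
  fit <- train_classifier(clf, trm, vam,
                          supervised_config(epochs = 50,
                                            early_stop_patience = 4,
                                            lr = 0 + 1e-12, batch_size = 16,
                                            seed = 3),
                          images = set$images)
  expect_equal(nrow(fit$log), 1 + 4)
  expect_equal(max(fit$log$val_acc), fit$log$val_acc[1])
  expect_equal(fit$best_epoch, nrow(fit$log))  # most-trained among ties
})

test_that("degenerate supervised inputs are rejected", {
  set <- tiny_labeled_set(30, seed = 11)
  trm <- manifest_split(set$manifest, "train")
  vam <- manifest_split(set$manifest, "val")
  single <- as_manifest(as.data.frame(trm)[trm$class_label == "NORMAL", ])
  clf <- build_classifier(NULL, config = "vit-tiny", rng_seed = 1)
  expect_error(train_classifier(clf, single, vam, images = set$images),
               "both NORMAL and AMD")
  expect_error(supervised_config(epochs = 5, early_stop_patience = 10),
               "patience")
  expect_error(supervised_config(augmentations = "cutmix"), "augmentation")
  expect_error(build_classifier(NULL, config = NULL), "config is required")
})

test_that("family mismatch between checkpoint and config is rejected", {
  px <- shared_pretrain()
  expect_error(build_classifier(px$ck, config = mae_preset("vit-tiny")),
               "family mismatch")
})

test_that("augmentations perturb training images but keep them valid", {
  img <- generate_bscan(noiseless_domain(), lesion_params("AMD"), 3)
  full <- c("rotation", "hflip", "color_jitter", "gaussian_blur", "elastic")
  a1 <- retmae:::augment_image(img, full, seed = 5)
  a2 <- retmae:::augment_image(img, full, seed = 5)
  expect_identical(a1, a2)                       # deterministic per seed
  expect_false(identical(a1, retmae:::augment_image(img, full, seed = 6)))
  expect_equal(dim(a1), dim(img))
  expect_true(all(a1 >= 0 & a1 <= 1))
  flipped <- retmae:::augment_image(img, "hflip", seed = 2)
  expect_true(identical(flipped, img) || identical(flipped, img[, 64:1]))
})

test_that("checkpoints round trip through disk with a JSON sidecar", {
  px <- shared_pretrain()
  f <- tempfile(fileext = ".rds")
  save_checkpoint(px$ck, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, px$ck$params)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$family, "swinv2")
  expect_equal(side$best_epoch, px$ck$best_epoch)
})
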