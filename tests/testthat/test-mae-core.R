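test_that("patch grids count patches and reject bad geometry", {
  expect_equal(patch_grid(c(224, 224), 16)$n_patches, 196)
  expect_equal(patch_grid(c(64, 64), 8)$n_patches, 64)
  expect_error(patch_grid(c(65, 64), 8), "divisible")
  expect_error(patch_grid(c(8, 8), 8), "4 patches")
})

test_that("patchify and unpatchify are exact inverses on random images", {
  grid <- patch_grid(c(64, 64), 8)
  set.seed(1)
  for (i in 1:100) {
    x <- matrix(stats::runif(64 * 64), 64)
    expect_identical(unpatchify(patchify(x, grid), grid), x)
  }
  # patch order is row-major over the grid
  x <- matrix(0, 64, 64); x[1:8, 9:16] <- 1  # grid row 1, column 2
  expect_true(all(patchify(x, grid)[2, ] == 1))
})

test_that("masks have exact floor(ratio * P) cardinality across ratios", {
  for (ratio in c(0.2, 0.5, 0.7, 0.8)) {
    grid <- patch_grid(c(64, 64), 8)
    for (s in 1:250) {
      plan <- sample_mask(grid, ratio, s)
      expect_equal(sum(plan$mask), floor(ratio * grid$n_patches))
      expect_equal(sum(plan$pixel_mask), sum(plan$mask) * 64)
    }
  }
  expect_equal(sum(sample_mask(patch_grid(c(224, 224), 16), 0.7, 1)$mask), 137)
  g <- patch_grid(c(64, 64), 8)
  expect_identical(sample_mask(g, 0.7, 5)$mask, sample_mask(g, 0.7, 5)$mask)
  expect_false(identical(sample_mask(g, 0.7, 5)$mask,
                         sample_mask(g, 0.7, 6)$mask))
  expect_error(sample_mask(g, 0.001, 1), "none or all")
  expect_error(sample_mask(g, 1.2, 1), "between 0 and 1")
})

test_that("the masked loss follows its closed form and ignores unmasked pixels", {
  # perfect reconstruction
  x <- matrix(stats::runif(16), 4)
  m <- matrix(c(rep(1, 8), rep(0, 8)), 4)
  expect_equal(masked_mse_loss(x, x, m, 0.5), 0)
  # full-mask limit reduces to plain MSE
  expect_equal(masked_mse_loss(matrix(0, 1, 2), matrix(1, 1, 2),
                               matrix(1, 1, 2), 1), 1.0)
  # hand-computed example
  expect_equal(masked_mse_loss(matrix(c(1, 0, 0, 0), 1),
                               matrix(c(0, 0, 0, 0.5), 1),
                               matrix(c(1, 0, 0, 1), 1), 0.5), 0.625)
  expect_error(masked_mse_loss(x, x, m, 0), "positive")
  # locality: perturbing unmasked pixels leaves the loss unchanged
  set.seed(2)
  xh <- matrix(stats::runif(16), 4)
  l0 <- masked_mse_loss(x, xh, m, 0.5)
  xh2 <- xh; xh2[m == 0] <- xh2[m == 0] + stats::rnorm(sum(m == 0))
  expect_identical(masked_mse_loss(x, xh2, m, 0.5), l0)
  # equivalence with the masked-pixel mean MSE at the exact ratio
  for (i in 1:20) {
    g <- patch_grid(c(32, 32), 8)
    plan <- sample_mask(g, 0.5, i)
    a <- matrix(stats::runif(1024), 32); b <- matrix(stats::runif(1024), 32)
    direct <- mean(((a - b)^2)[plan$pixel_mask])
    ratio_exact <- sum(plan$pixel_mask) / length(a)
    expect_equal(masked_mse_loss(a, b, plan$pixel_mask, ratio_exact), direct,
                 tolerance = 1e-12)
  }
})

test_that("architecture presets carry the published configuration", {
  sv2 <- mae_preset("swinv2-paper")
  expect_equal(sv2$encoder$embed_dim, 96)
  expect_equal(sv2$encoder$depths, c(2L, 2L, 6L, 2L))
  expect_equal(sv2$encoder$heads, c(3L, 6L, 12L, 24L))
  expect_equal(sv2$decoder_embed, 768)
  sw <- mae_preset("swin-paper")
  expect_equal(sw$encoder$depths, c(2L, 2L, 18L, 2L))
  expect_equal(sw$encoder$heads, c(6L, 12L, 24L, 48L))
  vit <- mae_preset("vit-paper")
  expect_equal(vit$encoder$embed_dim, 1024)
  expect_equal(vit$encoder$depths, 6L)
  expect_equal(vit$encoder$heads, 4L)
  expect_equal(vit$decoder_embed, 1024)
  expect_equal(vit$decoder_depths, 4L)
  expect_equal(vit$decoder_heads, 4L)
  expect_equal(vit$mask_ratio, 0.7)
  expect_error(mae_preset("resmae-tiny"), "unknown")
  expect_error(mae_config(backbone_spec("vit", 32, 2, 2, embed_patch = 8),
                          c(64, 64), 8, mask_ratio = 1.5,
                          32, 1, 2), "mask_ratio")
})

test_that("tiny forward passes are deterministic, fast, and well shaped", {
  for (nm in c("swinv2-tiny", "swin-tiny", "vit-tiny")) {
    cfg <- mae_preset(nm)
    model <- build_mae(cfg, rng_seed = 1)
    img <- matrix(stats::runif(64 * 64), 64)
    plan <- sample_mask(cfg$patch_grid, 0.7, 3)
    t0 <- Sys.time()
    r1 <- forward_reconstruct(model, img, plan)
    dt <- as.numeric(Sys.time() - t0, units = "secs")
    expect_lt(dt, 1)  # one CPU core, 64x64 input
    r2 <- forward_reconstruct(model, img, plan)
    expect_identical(r1, r2)
    expect_equal(dim(r1), c(64L, 64L))
    expect_true(all(is.finite(r1)))
    expect_true(is.finite(masked_mse_loss(img, r1, plan$pixel_mask,
                                          plan$m_ratio)))
  }
  model <- build_mae(mae_preset("swinv2-tiny"), 1)
  expect_error(forward_reconstruct(model, matrix(0, 32, 32),
                                   sample_mask(patch_grid(c(32, 32), 8),
                                               0.5, 1)),
               "does not match")
})

test_that("weight export and import reproduce forward outputs exactly", {
  cfg <- mae_preset("swinv2-tiny")
  m1 <- build_mae(cfg, rng_seed = 1)
  img <- matrix(stats::runif(64 * 64), 64)
  plan <- sample_mask(cfg$patch_grid, 0.7, 3)
  w <- export_weights(m1)
  expect_true(all(c("enc.embed.w", "enc.mask_token", "dec.out.w") %in% names(w)))
  m2 <- import_weights(build_mae(cfg, rng_seed = 99), w)
  expect_identical(forward_reconstruct(m1, img, plan),
                   forward_reconstruct(m2, img, plan))
  # stable naming across builds
  expect_identical(names(export_weights(build_mae(cfg, 5))), names(w))
  expect_error(import_weights(m1, w[-1]), "missing weights")
})

test_that("differently seeded builds differ but share structure", {
  cfg <- mae_preset("vit-tiny")
  a <- build_mae(cfg, 1); b <- build_mae(cfg, 2)
  expect_identical(names(a$params), names(b$params))
  expect_false(identical(a$params[["enc.embed.w"]], b$params[["enc.embed.w"]]))
  expect_identical(build_mae(cfg, 1)$params, a$params)
})
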