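#' Encoder backbone specification
#'
#' @param family `"vit"`, `"swin"`, or `"swinv2"`.
#' @param embed_dim embedding dimension at the first stage.
#' @param depths integer vector: transformer blocks per stage (ViT has a
#'   single stage).
#' @param heads integer vector: attention heads per stage; same length as
#'   `depths`.
#' @param window_size attention window edge for the windowed families.
#' @param embed_patch patch-embedding size in pixels (4 for the Swin
#'   families, equal to the mask patch for ViT).
#' @return a `backbone_spec`.
#' @export
backbone_spec <- function(family = c("vit", "swin", "swinv2"), embed_dim,
                          depths, heads, window_size = 7L, embed_patch) {
  family <- match.arg(family)
  if (length(depths) != length(heads))
    config_error("depths and heads must have the same length")
  if (any(c(embed_dim, depths, heads, window_size, embed_patch) <= 0))
    config_error("backbone dimensions must be positive")
  structure(list(family = family, embed_dim = as.integer(embed_dim),
                 depths = as.integer(depths), heads = as.integer(heads),
                 window_size = as.integer(window_size),
                 embed_patch = as.integer(embed_patch)),
            class = "backbone_spec")
}

#' Masked-autoencoder configuration
#'
#' Declarative description of a full MAE: encoder backbone, decoder schedule,
#' masking grid and ratio. Use [mae_preset()] for the named `*-paper` /
#' `*-tiny` configurations.
#'
#' @param encoder a [backbone_spec()].
#' @param image_size integer (height, width).
#' @param mask_patch mask patch size in pixels (the masking granularity).
#' @param mask_ratio fraction of mask patches hidden; default 0.7.
#' @param decoder_embed decoder embedding dimension.
#' @param decoder_depths,decoder_heads per-resolution decoder schedule
#'   (coarse to fine for the windowed families).
#' @param mlp_ratio MLP expansion factor inside blocks.
#' @param scale `"paper"` or `"tiny"`.
#' @return an `mae_config`.
#' @export
mae_config <- function(encoder, image_size, mask_patch, mask_ratio = 0.7,
                       decoder_embed, decoder_depths, decoder_heads,
                       mlp_ratio = 4, scale = "paper") {
  if (mask_ratio <= 0 || mask_ratio >= 1)
    config_error("mask_ratio must lie strictly in (0, 1)")
  if (mask_patch %% encoder$embed_patch != 0L)
    config_error("mask_patch must be a multiple of embed_patch")
  grid <- patch_grid(image_size, mask_patch)
  structure(list(encoder = encoder, image_size = as.integer(image_size),
                 mask_patch = as.integer(mask_patch), mask_ratio = mask_ratio,
                 decoder_embed = as.integer(decoder_embed),
                 decoder_depths = as.integer(decoder_depths),
                 decoder_heads = as.integer(decoder_heads),
                 mlp_ratio = mlp_ratio, scale = scale, patch_grid = grid),
            class = "mae_config")
}

#' Named MAE presets
#'
#' `*-paper` presets use 224x224 inputs with a 16 px mask patch: the ViT
#' encoder has embedding dimension 1024, 4 heads and 6 layers with a
#' 1024-wide 4-layer decoder; the Swin encoder has embedding size 96, depths
#' (2, 2, 18, 2) and heads (6, 12, 24, 48); the SwinV2 encoder has depths
#' (2, 2, 6, 2) and heads (3, 6, 12, 24); both windowed families use a
#' 768-wide mirrored decoder. `*-tiny` presets are 64x64 desk-scale models
#' with the same topology in miniature (window 4).
#'
#' @param name one of `vit-paper`, `swin-paper`, `swinv2-paper`, `vit-tiny`,
#'   `swin-tiny`, `swinv2-tiny`.
#' @param mask_ratio masking ratio override (default 0.7).
#' @return an `mae_config`.
#' @export
mae_preset <- function(name, mask_ratio = 0.7) {
  switch(name,
    "vit-paper" = mae_config(
      backbone_spec("vit", 1024, depths = 6L, heads = 4L, embed_patch = 16L),
      image_size = c(224L, 224L), mask_patch = 16L, mask_ratio = mask_ratio,
      decoder_embed = 1024L, decoder_depths = 4L, decoder_heads = 4L,
      scale = "paper"),
    "swin-paper" = mae_config(
      backbone_spec("swin", 96, depths = c(2L, 2L, 18L, 2L),
                    heads = c(6L, 12L, 24L, 48L), window_size = 7L,
                    embed_patch = 4L),
      image_size = c(224L, 224L), mask_patch = 16L, mask_ratio = mask_ratio,
      decoder_embed = 768L, decoder_depths = c(2L, 18L, 2L, 2L),
      decoder_heads = c(48L, 24L, 12L, 6L), scale = "paper"),
    "swinv2-paper" = mae_config(
      backbone_spec("swinv2", 96, depths = c(2L, 2L, 6L, 2L),
                    heads = c(3L, 6L, 12L, 24L), window_size = 7L,
                    embed_patch = 4L),
      image_size = c(224L, 224L), mask_patch = 16L, mask_ratio = mask_ratio,
      decoder_embed = 768L, decoder_depths = c(2L, 6L, 2L, 2L),
      decoder_heads = c(24L, 12L, 6L, 3L), scale = "paper"),
    "vit-tiny" = mae_config(
      backbone_spec("vit", 32, depths = 2L, heads = 2L, embed_patch = 8L),
      image_size = c(64L, 64L), mask_patch = 8L, mask_ratio = mask_ratio,
      decoder_embed = 32L, decoder_depths = 1L, decoder_heads = 2L,
      mlp_ratio = 2, scale = "tiny"),
    "swin-tiny" = mae_config(
      backbone_spec("swin", 16, depths = c(1L, 1L), heads = c(2L, 2L),
                    window_size = 4L, embed_patch = 4L),
      image_size = c(64L, 64L), mask_patch = 8L, mask_ratio = mask_ratio,
      decoder_embed = 16L, decoder_depths = c(1L, 1L),
      decoder_heads = c(2L, 2L), mlp_ratio = 2, scale = "tiny"),
    "swinv2-tiny" = mae_config(
      backbone_spec("swinv2", 16, depths = c(1L, 1L), heads = c(2L, 2L),
                    window_size = 4L, embed_patch = 4L),
      image_size = c(64L, 64L), mask_patch = 8L, mask_ratio = mask_ratio,
      decoder_embed = 16L, decoder_depths = c(1L, 1L),
      decoder_heads = c(2L, 2L), mlp_ratio = 2, scale = "tiny"),
    config_error(paste("unknown MAE preset:", name))
  )
}

# --- model construction ------------------------------------------------------

# Stage dims/grids for the encoder; stage s has dim C * 2^(s-1) and grid
# (g0 / 2^(s-1)) with g0 the embed-patch grid.
enc_stage_dims <- function(cfg) {
  enc <- cfg$encoder
  s <- length(enc$depths)
  g0h <- cfg$image_size[1] %/% enc$embed_patch
  g0w <- cfg$image_size[2] %/% enc$embed_patch
  list(dims = enc$embed_dim * 2L^(seq_len(s) - 1L),
       gh = g0h %/% 2L^(seq_len(s) - 1L), gw = g0w %/% 2L^(seq_len(s) - 1L))
}

dec_stage_dims <- function(cfg) {
  s <- length(cfg$decoder_depths)
  es <- enc_stage_dims(cfg)
  list(dims = cfg$decoder_embed %/% 2L^(seq_len(s) - 1L),
       gh = es$gh[length(es$gh)] * 2L^(seq_len(s) - 1L),
       gw = es$gw[length(es$gw)] * 2L^(seq_len(s) - 1L))
}

init_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

add_block_params <- function(P, prefix, dim, heads, family, wn, mlp_ratio) {
  P[[paste0(prefix, ".attn.wq")]] <- init_mat(dim, dim)
  P[[paste0(prefix, ".attn.bq")]] <- matrix(0, 1, dim)
  P[[paste0(prefix, ".attn.wk")]] <- init_mat(dim, dim)
  P[[paste0(prefix, ".attn.bk")]] <- matrix(0, 1, dim)
  P[[paste0(prefix, ".attn.wv")]] <- init_mat(dim, dim)
  P[[paste0(prefix, ".attn.bv")]] <- matrix(0, 1, dim)
  P[[paste0(prefix, ".attn.wo")]] <- init_mat(dim, dim)
  P[[paste0(prefix, ".attn.bo")]] <- matrix(0, 1, dim)
  if (family != "vit") {
    P[[paste0(prefix, ".attn.relbias")]] <-
      matrix(0, (2L * wn - 1L)^2, heads)
    if (family == "swinv2")
      P[[paste0(prefix, ".attn.log_tau")]] <- matrix(log(10), 1, heads)
  }
  P[[paste0(prefix, ".ln1.g")]] <- matrix(1, 1, dim)
  P[[paste0(prefix, ".ln1.b")]] <- matrix(0, 1, dim)
  P[[paste0(prefix, ".ln2.g")]] <- matrix(1, 1, dim)
  P[[paste0(prefix, ".ln2.b")]] <- matrix(0, 1, dim)
  hid <- round(dim * mlp_ratio)
  P[[paste0(prefix, ".mlp.w1")]] <- init_mat(dim, hid)
  P[[paste0(prefix, ".mlp.b1")]] <- matrix(0, 1, hid)
  P[[paste0(prefix, ".mlp.w2")]] <- init_mat(hid, dim)
  P[[paste0(prefix, ".mlp.b2")]] <- matrix(0, 1, dim)
  P
}

#' Build a masked autoencoder
#'
#' Materializes the parameter set for an [mae_config()] (deterministically for
#' a fixed seed) and precomputes the static grid geometry (window partitions,
#' shift masks, merge/expand permutations, relative-position-bias indices).
#'
#' @param config an `mae_config`.
#' @param rng_seed seed for weight initialization.
#' @return an `rt_mae` model handle supporting [forward_reconstruct()],
#'   [count_parameters()], [export_weights()] and [import_weights()].
#' @export
build_mae <- function(config, rng_seed = 0L) {
  if (!inherits(config, "mae_config")) config_error("config must be mae_config")
  enc <- config$encoder
  es <- enc_stage_dims(config)
  ds <- dec_stage_dims(config)
  pe <- enc$embed_patch
  with_seed(rng_seed, {
    P <- list()
    P[["enc.embed.w"]] <- init_mat(pe * pe, enc$embed_dim)
    P[["enc.embed.b"]] <- matrix(0, 1, enc$embed_dim)
    P[["enc.mask_token"]] <- init_mat(1, enc$embed_dim)
    geom <- list()
    t0 <- es$gh[1] * es$gw[1]
    if (enc$family == "vit")
      P[["enc.pos"]] <- init_mat(t0, enc$embed_dim)
    for (s in seq_along(enc$depths)) {
      for (b in seq_len(enc$depths[s])) {
        prefix <- sprintf("enc.s%d.b%d", s, b)
        gm <- block_geometry(enc$family, enc$heads[s], es$gh[s], es$gw[s],
                             enc$window_size, shifted = (b %% 2L == 0L))
        geom[[prefix]] <- gm
        P <- add_block_params(P, prefix, es$dims[s], enc$heads[s], enc$family,
                              gm$wn %||% 0L, config$mlp_ratio)
      }
      if (s < length(enc$depths)) {
        P[[sprintf("enc.m%d.ln.g", s)]] <- matrix(1, 1, 4L * es$dims[s])
        P[[sprintf("enc.m%d.ln.b", s)]] <- matrix(0, 1, 4L * es$dims[s])
        P[[sprintf("enc.m%d.w", s)]] <- init_mat(4L * es$dims[s],
                                                 2L * es$dims[s])
        P[[sprintf("enc.m%d.b", s)]] <- matrix(0, 1, 2L * es$dims[s])
        geom[[sprintf("enc.m%d", s)]] <- merge_indices(es$gh[s], es$gw[s])
      }
    }
    c_last <- es$dims[length(es$dims)]
    P[["dec.proj.w"]] <- init_mat(c_last, config$decoder_embed)
    P[["dec.proj.b"]] <- matrix(0, 1, config$decoder_embed)
    if (enc$family == "vit") {
      P[["dec.pos"]] <- init_mat(t0, config$decoder_embed)
      for (b in seq_len(config$decoder_depths[1])) {
        prefix <- sprintf("dec.s1.b%d", b)
        geom[[prefix]] <- block_geometry("vit", config$decoder_heads[1],
                                         es$gh[1], es$gw[1], 0L, FALSE)
        P <- add_block_params(P, prefix, config$decoder_embed,
                              config$decoder_heads[1], "vit", 0L,
                              config$mlp_ratio)
      }
      P[["dec.out.w"]] <- init_mat(config$decoder_embed, pe * pe)
      P[["dec.out.b"]] <- matrix(0, 1, pe * pe)
    } else {
      for (j in seq_along(config$decoder_depths)) {
        for (b in seq_len(config$decoder_depths[j])) {
          prefix <- sprintf("dec.s%d.b%d", j, b)
          gm <- block_geometry(enc$family, config$decoder_heads[j],
                               ds$gh[j], ds$gw[j], enc$window_size,
                               shifted = (b %% 2L == 0L))
          geom[[prefix]] <- gm
          P <- add_block_params(P, prefix, ds$dims[j], config$decoder_heads[j],
                                enc$family, gm$wn %||% 0L, config$mlp_ratio)
        }
        if (j < length(config$decoder_depths)) {
          P[[sprintf("dec.e%d.w", j)]] <- init_mat(ds$dims[j], 2L * ds$dims[j])
          P[[sprintf("dec.e%d.b", j)]] <- matrix(0, 1, 2L * ds$dims[j])
          geom[[sprintf("dec.e%d", j)]] <- expand_perm(ds$gh[j], ds$gw[j])
        }
      }
      d_last <- ds$dims[length(ds$dims)]
      P[["dec.out.w"]] <- init_mat(d_last, pe * pe)
      P[["dec.out.b"]] <- matrix(0, 1, pe * pe)
    }
    # embed-token -> mask-patch lookup (dense mask-token substitution)
    k <- config$mask_patch %/% pe
    gmw <- config$patch_grid$gw
    r <- rep(seq_len(es$gh[1]), each = es$gw[1])
    cc <- rep(seq_len(es$gw[1]), times = es$gh[1])
    geom[["tok2mask"]] <- ((r - 1L) %/% k) * gmw + ((cc - 1L) %/% k) + 1L
    structure(list(config = config, params = P, geom = geom),
              class = "rt_mae")
  })
}

# Encoder forward over one image. `plan` NULL means no masking (classifier
# path). `p` may be the plain parameter list (inference) or leaf nodes
# (training). Returns the final token matrix (T_last x C_last).
mae_encode <- function(model, image, plan = NULL, p = NULL) {
  cfg <- model$config; enc <- cfg$encoder; geom <- model$geom
  if (is.null(p)) p <- model$params
  es <- enc_stage_dims(cfg)
  egrid <- patch_grid(cfg$image_size, enc$embed_patch)
  if (!all(dim(image) == cfg$image_size))
    config_error("image does not match the model's configured size")
  x <- linear_fwd(patchify(image, egrid), p[["enc.embed.w"]],
                  p[["enc.embed.b"]])
  if (!is.null(plan)) {
    mt <- plan$mask[geom$tok2mask]
    if (all(mt) || !any(mt)) config_error("mask plan hides none or all tokens")
    tn <- egrid$n_patches
    keep <- matrix(as.numeric(!mt), tn, enc$embed_dim)
    hide <- matrix(as.numeric(mt), tn, enc$embed_dim)
    mtok <- op_gather_rows(p[["enc.mask_token"]], rep(1L, tn))
    x <- op_add(op_mul(x, keep), op_mul(mtok, hide))
  }
  if (enc$family == "vit") x <- op_add(x, p[["enc.pos"]])
  for (s in seq_along(enc$depths)) {
    for (b in seq_len(enc$depths[s])) {
      prefix <- sprintf("enc.s%d.b%d", s, b)
      x <- block_fwd(x, p, prefix, geom[[prefix]])
    }
    if (s < length(enc$depths)) {
      mi <- geom[[sprintf("enc.m%d", s)]]
      merged <- op_cbind(lapply(mi, function(ix) op_gather_rows(x, ix)))
      merged <- op_layernorm(merged, p[[sprintf("enc.m%d.ln.g", s)]],
                             p[[sprintf("enc.m%d.ln.b", s)]])
      x <- linear_fwd(merged, p[[sprintf("enc.m%d.w", s)]],
                      p[[sprintf("enc.m%d.b", s)]])
    }
  }
  x
}

# Decoder forward: final encoder tokens -> per-embed-patch pixel predictions.
mae_decode <- function(model, xe, p = NULL) {
  cfg <- model$config; geom <- model$geom
  if (is.null(p)) p <- model$params
  x <- linear_fwd(xe, p[["dec.proj.w"]], p[["dec.proj.b"]])
  if (cfg$encoder$family == "vit") {
    x <- op_add(x, p[["dec.pos"]])
    for (b in seq_len(cfg$decoder_depths[1]))
      x <- block_fwd(x, p, sprintf("dec.s1.b%d", b),
                     geom[[sprintf("dec.s1.b%d", b)]])
  } else {
    ds <- dec_stage_dims(cfg)
    for (j in seq_along(cfg$decoder_depths)) {
      for (b in seq_len(cfg$decoder_depths[j]))
        x <- block_fwd(x, p, sprintf("dec.s%d.b%d", j, b),
                       geom[[sprintf("dec.s%d.b%d", j, b)]])
      if (j < length(cfg$decoder_depths)) {
        y <- linear_fwd(x, p[[sprintf("dec.e%d.w", j)]],
                        p[[sprintf("dec.e%d.b", j)]])
        half <- ds$dims[j] %/% 2L
        pieces <- lapply(1:4, function(kk)
          op_slice_cols(y, (kk - 1L) * half + 1L, kk * half))
        x <- op_gather_rows(op_rbind(pieces), geom[[sprintf("dec.e%d", j)]])
      }
    }
  }
  linear_fwd(x, p[["dec.out.w"]], p[["dec.out.b"]])
}

#' Reconstruct a full image from a masked view
#'
#' Runs the dense-mask-token MAE forward pass in inference mode: masked
#' embed patches are replaced by the learned mask token, the encoder
#' processes the full grid, and the decoder predicts every pixel.
#'
#' @param model an `rt_mae` from [build_mae()].
#' @param image numeric matrix matching the configured image size.
#' @param plan a [sample_mask()] plan on the model's mask grid.
#' @return reconstruction matrix with the input's shape.
#' @export
forward_reconstruct <- function(model, image, plan) {
  if (!inherits(plan, "mask_plan")) config_error("plan must be a mask_plan")
  if (plan$grid$n_patches != model$config$patch_grid$n_patches)
    config_error("mask plan grid does not match the model")
  tok <- mae_decode(model, mae_encode(model, image, plan))
  egrid <- patch_grid(model$config$image_size, model$config$encoder$embed_patch)
  unpatchify(nval(tok), egrid)
}

# In-graph masked loss on patchified targets (identical to the pixel-space
# loss because patchify is a rearrangement). `x_in` is the (possibly
# standardized) encoder input; `x_target` the raw reconstruction target.
mae_loss_node <- function(model, x_in, x_target, plan, p) {
  egrid <- patch_grid(model$config$image_size,
                      model$config$encoder$embed_patch)
  target <- patchify(x_target, egrid)
  wmat <- patchify(plan$pixel_mask * 1, egrid)
  out <- mae_decode(model, mae_encode(model, x_in, plan, p), p)
  diff <- op_sub(out, target)
  op_scale(op_sum(op_mul(op_mul(diff, diff), wmat)),
           1 / (plan$m_ratio * length(x_target)))
}

#' Export / import model weights as named matrices
#'
#' Weight names are stable across runs for a fixed configuration; importing
#' exported weights reproduces forward outputs exactly.
#'
#' @param model an `rt_mae` (or `rt_classifier`) handle.
#' @return `export_weights`: named list of matrices.
#' @export
export_weights <- function(model) model$params

#' @rdname export_weights
#' @param weights named list as produced by [export_weights()].
#' @export
import_weights <- function(model, weights) {
  missing_w <- setdiff(names(model$params), names(weights))
  if (length(missing_w))
    config_error(paste("missing weights:", paste(missing_w, collapse = ", ")))
  model$params <- weights[names(model$params)]
  model
}

#' Save / load a checkpoint (weights + config + provenance sidecar)
#'
#' The checkpoint itself is an RDS archive of named tensors; a JSON sidecar
#' (`<path>.json`) records the configuration, seed and provenance so a report
#' can be regenerated from its artifacts.
#'
#' @param ckpt a checkpoint list (as returned by [pretrain()] or
#'   [train_classifier()]).
#' @param path file path (conventionally `*.rds`).
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  side <- list(class = class(ckpt)[1],
               family = ckpt$config$encoder$family %||% NULL,
               scale = ckpt$config$scale %||% NULL,
               seed = ckpt$seed %||% NULL,
               provenance = ckpt$provenance %||% NULL,
               best_epoch = ckpt$best_epoch %||% NULL)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
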