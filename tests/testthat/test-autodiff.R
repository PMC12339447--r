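# The reverse-mode engine is validated against central finite differences on
# composite graphs covering every op the models use.

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x2 <- x; x2[i] <- x2[i] + eps
    x3 <- x; x3[i] <- x3[i] - eps
    g[i] <- (f(x2) - f(x3)) / (2 * eps)
  }
  g
}

analytic_grad <- function(build, x0) {
  retmae:::with_tape({
    leaf <- retmae:::ad_leaf(x0)
    loss <- build(leaf)
    retmae:::ad_backward(loss)
    leaf$grad
  })
}

test_that("composite graphs match finite differences", {
  set.seed(7)
  w <- matrix(stats::rnorm(12), 4, 3)
  gamma <- matrix(stats::runif(3, 0.5, 1.5), 1)
  beta <- matrix(stats::rnorm(3), 1)
  x0 <- matrix(stats::rnorm(8), 2, 4)
  build <- function(x) {
    h <- retmae:::op_gelu(retmae:::op_mm(x, w))
    h <- retmae:::op_layernorm(h, gamma, beta)
    s <- retmae:::op_softmax_rows(h)
    retmae:::op_sum(retmae:::op_mul(s, s))
  }
  ana <- analytic_grad(build, x0)
  num <- num_grad(function(x) {
    h <- (x %*% w) * stats::pnorm(x %*% w)
    h <- t(apply(h, 1, function(r) (r - mean(r)) /
                   sqrt(mean((r - mean(r))^2) + 1e-5))) *
      matrix(gamma, 2, 3, byrow = TRUE) + matrix(beta, 2, 3, byrow = TRUE)
    e <- exp(h - apply(h, 1, max)); s <- e / rowSums(e)
    sum(s * s)
  }, x0)
  expect_lt(max(abs(ana - num)), 1e-6)
})

test_that("gather, slice, bind and reshape ops propagate exact gradients", {
  set.seed(8)
  x0 <- matrix(stats::rnorm(12), 4, 3)
  idx <- c(2L, 2L, 4L, 1L)
  build <- function(x) {
    g <- retmae:::op_gather_rows(x, idx)
    a <- retmae:::op_slice_cols(g, 1, 2)
    b <- retmae:::op_slice_cols(g, 2, 3)
    h <- retmae:::op_cbind2(a, b)
    r <- retmae:::op_reshape(retmae:::op_t(h), 2, 8)
    retmae:::op_sum(retmae:::op_mul(r, r))
  }
  ana <- analytic_grad(build, x0)
  num <- num_grad(function(x) {
    g <- x[idx, , drop = FALSE]
    h <- cbind(g[, 1:2], g[, 2:3])
    sum(h * h)
  }, x0)
  expect_lt(max(abs(ana - num)), 1e-7)
})

test_that("fused windowed attention matches finite differences in both families", {
  set.seed(4)
  heads <- 2
  win_idx <- list(1:4, 5:8)
  riv <- retmae:::relbias_index(2)
  q0 <- matrix(stats::rnorm(32), 8); k0 <- matrix(stats::rnorm(32), 8)
  v0 <- matrix(stats::rnorm(32), 8)
  tab0 <- matrix(stats::rnorm(9 * heads, 0, 0.1), 9)
  tau0 <- matrix(log(5), 1, heads)
  masks <- list(matrix(0, 4, 4), ifelse(diag(4) == 1, 0, -1e9))
  for (family in c("swin", "swinv2")) {
    f <- function(q, k, v, tab, tau)
      sum(retmae:::op_window_mhsa(q, k, v, tab, tau, win_idx, heads, family,
                                  riv = riv, masks = masks)^2)
    grads <- retmae:::with_tape({
      lq <- retmae:::ad_leaf(q0); lk <- retmae:::ad_leaf(k0)
      lv <- retmae:::ad_leaf(v0); lt <- retmae:::ad_leaf(tab0)
      lu <- retmae:::ad_leaf(tau0)
      o <- retmae:::op_window_mhsa(lq, lk, lv, lt,
                                   if (family == "swinv2") lu else NULL,
                                   win_idx, heads, family, riv = riv,
                                   masks = masks)
      retmae:::ad_backward(retmae:::op_sum(retmae:::op_mul(o, o)))
      list(q = lq$grad, k = lk$grad, v = lv$grad, tab = lt$grad,
           tau = lu$grad)
    })
    for (which in c("q", "k", "v", "tab")) {
      base <- list(q = q0, k = k0, v = v0, tab = tab0)
      ng <- base[[which]] * 0
      for (i in seq_along(ng)) {
        eps <- 1e-6
        b2 <- base; b2[[which]][i] <- b2[[which]][i] + eps
        b3 <- base; b3[[which]][i] <- b3[[which]][i] - eps
        ng[i] <- (f(b2$q, b2$k, b2$v, b2$tab, tau0) -
                    f(b3$q, b3$k, b3$v, b3$tab, tau0)) / (2 * eps)
      }
      expect_lt(max(abs(ng - grads[[which]])), 1e-6)
    }
  }
})

test_that("full tiny MAE gradients agree with finite differences", {
  cfg <- mae_config(
    backbone_spec("swinv2", 8, depths = c(2, 2), heads = c(2, 2),
                  window_size = 4, embed_patch = 4),
    image_size = c(32, 32), mask_patch = 8, mask_ratio = 0.5,
    decoder_embed = 8, decoder_depths = c(2, 2), decoder_heads = c(2, 2),
    mlp_ratio = 2, scale = "tiny")
  m <- build_mae(cfg, 1)
  # temperate attention for well-conditioned finite differences
  for (pn in grep("log_tau", names(m$params), value = TRUE))
    m$params[[pn]][] <- 0
  set.seed(5)
  im <- matrix(stats::runif(32 * 32), 32)
  plan <- sample_mask(cfg$patch_grid, 0.5, 5)
  grads <- retmae:::with_tape({
    leaves <- lapply(m$params, retmae:::ad_leaf)
    loss <- retmae:::mae_loss_node(m, im, im, plan, leaves)
    retmae:::ad_backward(loss)
    lapply(leaves, function(l) l$grad)
  })
  f <- function(P) as.numeric(retmae:::mae_loss_node(
    { mm <- m; mm$params <- P; mm }, im, im, plan, P))
  set.seed(3)
  for (pn in sample(names(m$params), 10)) {
    P <- m$params
    k <- sample(length(P[[pn]]), 1)
    eps <- 1e-5
    P2 <- P; P2[[pn]][k] <- P2[[pn]][k] + eps
    P3 <- P; P3[[pn]][k] <- P3[[pn]][k] - eps
    num <- (f(P2) - f(P3)) / (2 * eps)
    ana <- grads[[pn]][k]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-4), 2e-2)
  }
})

test_that("one AdamW step matches the closed-form decoupled update", {
  # quadratic loss 0.5 * c * theta^2 at theta0: gradient c * theta0
  theta0 <- 3; cq <- 2; lr <- 0.1; wd <- 0.05; betas <- c(0.9, 0.95)
  eps <- 1e-8
  g <- cq * theta0
  params <- list(th = matrix(theta0, 1, 1))
  st <- retmae:::adamw_init(params)
  upd <- retmae:::adamw_step(params, list(th = matrix(g, 1, 1)), st, lr, wd,
                             betas, eps)
  mhat <- g            # (1-b1) g / (1-b1)
  vhat <- g^2
  expected <- theta0 - lr * (mhat / (sqrt(vhat) + eps) + wd * theta0)
  expect_equal(as.numeric(upd$params$th), expected, tolerance = 1e-10)
  # second step recursion
  upd2 <- retmae:::adamw_step(upd$params, list(th = matrix(g, 1, 1)),
                              upd$state, lr, wd, betas, eps)
  m2 <- (betas[1] * (1 - betas[1]) * g + (1 - betas[1]) * g) / (1 - betas[1]^2)
  v2 <- (betas[2] * (1 - betas[2]) * g^2 + (1 - betas[2]) * g^2) /
    (1 - betas[2]^2)
  expected2 <- as.numeric(upd$params$th) -
    lr * (m2 / (sqrt(v2) + eps) + wd * as.numeric(upd$params$th))
  expect_equal(as.numeric(upd2$params$th), expected2, tolerance = 1e-10)
})
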