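# Transformer layer forwards (shared by training and inference paths) and
# static grid geometry: window partitions, shift masks, merge/expand
# permutations, relative-position-bias indexing. Geometry is computed once
# per architecture and cached on the model handle.

linear_fwd <- function(x, w, b) op_add(op_mm(x, w), b)

mlp_fwd <- function(x, p, prefix) {
  h <- op_gelu(linear_fwd(x, p[[paste0(prefix, ".w1")]],
                          p[[paste0(prefix, ".b1")]]))
  linear_fwd(h, p[[paste0(prefix, ".w2")]], p[[paste0(prefix, ".b2")]])
}

# Token index vectors (row-major grid order) for each window of a gh x gw
# grid partitioned into wn x wn windows.
window_indices <- function(gh, gw, wn) {
  out <- list()
  for (wr in seq_len(gh %/% wn)) for (wc in seq_len(gw %/% wn)) {
    rows <- ((wr - 1L) * wn + 1L):(wr * wn)
    cols <- ((wc - 1L) * wn + 1L):(wc * wn)
    out[[length(out) + 1L]] <- as.integer(outer(cols, (rows - 1L) * gw, "+"))
  }
  out
}

# Cyclic-shift permutation: perm[new position] = old position, where the
# shifted grid at (r, c) shows the original token at (r + s, c + s) (wrapped).
shift_perm <- function(gh, gw, s) {
  r <- rep(seq_len(gh), each = gw)
  c <- rep(seq_len(gw), times = gh)
  r2 <- ((r - 1L + s) %% gh) + 1L
  c2 <- ((c - 1L + s) %% gw) + 1L
  (r2 - 1L) * gw + c2
}

# Additive attention masks (0 / -1e9) per window for a shifted partition:
# tokens from different pre-shift regions must not attend to each other.
shift_attn_masks <- function(gh, gw, wn, s, win_idx) {
  seg <- function(n) {
    id <- integer(n)
    id[seq_len(n - wn)] <- 0L
    if (wn - s >= 1L) id[(n - wn + 1L):(n - s)] <- 1L
    id[(n - s + 1L):n] <- 2L
    id
  }
  rid <- seg(gh); cid <- seg(gw)
  region <- as.vector(t(outer(rid, cid, function(a, b) a * 3L + b)))  # row-major
  region <- region[shift_perm(gh, gw, s)]
  lapply(win_idx, function(idx) {
    r <- region[idx]
    m <- outer(r, r, "!=") * -1e9
    m
  })
}

# Relative-position-bias index vector: for a wn x wn window, entry
# (i - 1) * wn^2 ... laid out so that matrix(riv, Tw, Tw) gives index[i, j]
# of token pair (query i, key j) into the (2 wn - 1)^2 bias table.
relbias_index <- function(wn) {
  tw <- wn * wn
  # token order inside a window is row-major (rows of the grid)
  r <- rep(seq_len(wn), each = wn)
  c <- rep(seq_len(wn), times = wn)
  idx <- matrix(0L, tw, tw)
  for (i in seq_len(tw)) for (j in seq_len(tw)) {
    dr <- r[i] - r[j] + wn       # 1 .. 2wn-1
    dc <- c[i] - c[j] + wn
    idx[i, j] <- (dr - 1L) * (2L * wn - 1L) + dc
  }
  as.integer(idx)  # column-major vector; matrix(., tw, tw) restores [i, j]
}

# Patch-merging gather indices: four interleaved sub-grids of an even
# gh x gw grid, each listed row-major over the gh/2 x gw/2 output grid.
merge_indices <- function(gh, gw) {
  g2h <- gh %/% 2L; g2w <- gw %/% 2L
  r2 <- rep(seq_len(g2h), each = g2w)
  c2 <- rep(seq_len(g2w), times = g2h)
  at <- function(dr, dc) (2L * (r2 - 1L) + dr - 1L) * gw + (2L * (c2 - 1L) + dc)
  list(at(1L, 1L), at(2L, 1L), at(1L, 2L), at(2L, 2L))
}

# Patch-expanding permutation: rbind(piece1..piece4) (each T rows, offsets
# (0,0),(1,0),(0,1),(1,1)) reordered to row-major over the 2gh x 2gw grid.
expand_perm <- function(gh, gw) {
  tn <- gh * gw
  pos <- integer(4L * tn)
  r <- rep(seq_len(gh), each = gw)
  c <- rep(seq_len(gw), times = gh)
  off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    nr <- 2L * (r - 1L) + off[[k]][1] + 1L
    nc <- 2L * (c - 1L) + off[[k]][2] + 1L
    pos[(k - 1L) * tn + seq_len(tn)] <- (nr - 1L) * (2L * gw) + nc
  }
  order_of <- integer(4L * tn)
  order_of[pos] <- seq_len(4L * tn)
  order_of  # perm[new row] = stacked row
}

# Fused windowed multi-head self-attention: one tape node for the whole
# (windows x heads) attention pattern, with a hand-derived backward. q, k, v
# are the projected token matrices (T x C); `tab` the relative-position-bias
# table ((2wn-1)^2 x H) indexed by `riv`; `tau` the 1 x H log-temperatures
# (SwinV2 cosine attention); `masks` constant additive matrices per window.
# Keeping the inner loops free of tape nodes is what makes desk-scale
# training affordable in R.
op_window_mhsa <- function(q, k, v, tab, tau, win_idx, heads, family,
                           riv = NULL, masks = NULL) {
  vq <- nval(q); vk <- nval(k); vv <- nval(v)
  vtab <- if (!is.null(tab)) nval(tab) else NULL
  vtau <- if (!is.null(tau)) nval(tau) else NULL
  d <- ncol(vq); dh <- d %/% heads
  tw <- length(win_idx[[1]])
  cosine <- family == "swinv2"
  taus <- if (cosine) pmin(exp(as.numeric(vtau)), 100) else NULL
  bias_h <- if (!is.null(vtab))
    lapply(seq_len(heads), function(h) matrix(vtab[riv, h], tw, tw)) else NULL
  out <- matrix(0, nrow(vq), d)
  st <- vector("list", length(win_idx) * heads)  # softmax/cache for backward
  for (w in seq_along(win_idx)) {
    idx <- win_idx[[w]]
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      qh <- vq[idx, cols, drop = FALSE]
      kh <- vk[idx, cols, drop = FALSE]
      if (cosine) {
        nq <- sqrt(rowSums(qh * qh) + 1e-8); qn <- qh / nq
        nk <- sqrt(rowSums(kh * kh) + 1e-8); kn <- kh / nk
        cmat <- qn %*% t(kn)
        s <- cmat * taus[h]
      } else {
        s <- qh %*% t(kh) / sqrt(dh)
      }
      if (!is.null(bias_h)) s <- s + bias_h[[h]]
      if (!is.null(masks)) s <- s + masks[[w]]
      e <- exp(s - apply(s, 1L, max))
      a <- e / rowSums(e)
      out[idx, cols] <- a %*% vv[idx, cols, drop = FALSE]
      st[[(w - 1L) * heads + h]] <-
        if (cosine) list(a = a, qn = qn, kn = kn, nq = nq, nk = nk, c = cmat)
        else list(a = a, qh = qh, kh = kh)
    }
  }
  ins <- list(q, k, v, tab, tau)
  live <- vapply(ins, is_node, logical(1))
  if (!any(live)) return(out)
  memo <- new.env(parent = emptyenv())
  backward_all <- function(g) {
    if (!is.null(memo$done)) return(invisible(NULL))
    dq <- matrix(0, nrow(vq), d); dk <- dq; dv <- dq
    dtab <- if (!is.null(vtab)) matrix(0, nrow(vtab), heads) else NULL
    dtau <- if (cosine) numeric(heads) else NULL
    for (w in seq_along(win_idx)) {
      idx <- win_idx[[w]]
      for (h in seq_len(heads)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        cc <- st[[(w - 1L) * heads + h]]
        go <- g[idx, cols, drop = FALSE]
        vh <- vv[idx, cols, drop = FALSE]
        da <- go %*% t(vh)
        dv[idx, cols] <- dv[idx, cols] + t(cc$a) %*% go
        ds <- cc$a * (da - rowSums(da * cc$a))
        if (!is.null(dtab)) {
          rs <- rowsum(as.vector(ds), riv)
          z <- numeric(nrow(vtab))
          z[as.integer(rownames(rs))] <- rs[, 1]
          dtab[, h] <- dtab[, h] + z
        }
        if (cosine) {
          dtau[h] <- dtau[h] + sum(ds * cc$c)
          dc <- ds * taus[h]
          dqn <- dc %*% cc$kn
          dkn <- t(dc) %*% cc$qn
          dq[idx, cols] <- dq[idx, cols] +
            (dqn - cc$qn * rowSums(dqn * cc$qn)) / cc$nq
          dk[idx, cols] <- dk[idx, cols] +
            (dkn - cc$kn * rowSums(dkn * cc$kn)) / cc$nk
        } else {
          dq[idx, cols] <- dq[idx, cols] + ds %*% cc$kh / sqrt(dh)
          dk[idx, cols] <- dk[idx, cols] + t(ds) %*% cc$qh / sqrt(dh)
        }
      }
    }
    memo$dq <- dq; memo$dk <- dk; memo$dv <- dv
    memo$dtab <- dtab
    if (cosine) {
      ev <- exp(as.numeric(vtau))
      memo$dtau <- matrix(dtau * ev * (ev < 100), 1L, heads)
    }
    memo$done <- TRUE
    invisible(NULL)
  }
  vjps <- list(
    function(g) { backward_all(g); memo$dq },
    function(g) { backward_all(g); memo$dk },
    function(g) { backward_all(g); memo$dv },
    function(g) { backward_all(g); memo$dtab },
    function(g) { backward_all(g); memo$dtau }
  )
  record(out, ins[live], vjps[live])
}

# Multi-head attention over one token set (optionally windowed outside).
# family: "vit"/"swin" use scaled dot product; "swinv2" uses cosine attention
# with a learned clamped per-head temperature.
attention_fwd <- function(x, p, prefix, heads, family, win_idx,
                          riv = NULL, masks = NULL) {
  q <- linear_fwd(x, p[[paste0(prefix, ".wq")]], p[[paste0(prefix, ".bq")]])
  k <- linear_fwd(x, p[[paste0(prefix, ".wk")]], p[[paste0(prefix, ".bk")]])
  v <- linear_fwd(x, p[[paste0(prefix, ".wv")]], p[[paste0(prefix, ".bv")]])
  o <- op_window_mhsa(q, k, v,
                      tab = p[[paste0(prefix, ".relbias")]],
                      tau = p[[paste0(prefix, ".log_tau")]],
                      win_idx = win_idx, heads = heads, family = family,
                      riv = riv, masks = masks)
  linear_fwd(o, p[[paste0(prefix, ".wo")]], p[[paste0(prefix, ".bo")]])
}

# One transformer block over the full token matrix. For windowed families the
# token set is partitioned (possibly after a cyclic shift), attention runs
# per window, and windows are reassembled. ViT attends globally.
# Swin/ViT use pre-norm residuals; SwinV2 uses residual-post-norm.
block_fwd <- function(x, p, prefix, cfg_block) {
  fam <- cfg_block$family
  heads <- cfg_block$heads
  attn_over_tokens <- function(xt) {
    if (fam == "vit") {
      attention_fwd(xt, p, paste0(prefix, ".attn"), heads, fam,
                    win_idx = list(seq_len(nrow(nval(xt)))))
    } else {
      gm <- cfg_block  # window geometry
      xs <- if (gm$shift > 0L) op_gather_rows(xt, gm$perm) else xt
      o <- attention_fwd(xs, p, paste0(prefix, ".attn"), heads, fam,
                         win_idx = gm$win_idx, riv = gm$riv,
                         masks = if (gm$shift > 0L) gm$masks else NULL)
      if (gm$shift > 0L) op_gather_rows(o, gm$unperm) else o
    }
  }
  if (fam == "swinv2") {
    a <- attn_over_tokens(x)
    x <- op_add(x, op_layernorm(a, p[[paste0(prefix, ".ln1.g")]],
                                p[[paste0(prefix, ".ln1.b")]]))
    m <- mlp_fwd(x, p, paste0(prefix, ".mlp"))
    op_add(x, op_layernorm(m, p[[paste0(prefix, ".ln2.g")]],
                           p[[paste0(prefix, ".ln2.b")]]))
  } else {
    a <- attn_over_tokens(op_layernorm(x, p[[paste0(prefix, ".ln1.g")]],
                                       p[[paste0(prefix, ".ln1.b")]]))
    x <- op_add(x, a)
    m <- mlp_fwd(op_layernorm(x, p[[paste0(prefix, ".ln2.g")]],
                              p[[paste0(prefix, ".ln2.b")]]), p,
                 paste0(prefix, ".mlp"))
    op_add(x, m)
  }
}

# Precompute per-block window geometry for a grid and window size.
block_geometry <- function(family, heads, gh, gw, window, shifted) {
  if (family == "vit")
    return(list(family = family, heads = heads))
  wn <- min(window, gh, gw)
  shift <- if (shifted && wn < gh) wn %/% 2L else 0L
  win_idx <- window_indices(gh, gw, wn)
  restore <- integer(gh * gw)
  restore[unlist(win_idx)] <- seq_len(gh * gw)
  g <- list(family = family, heads = heads, wn = wn, tw = wn * wn,
            shift = shift, win_idx = win_idx, restore = restore,
            riv = relbias_index(wn))
  if (shift > 0L) {
    g$perm <- shift_perm(gh, gw, shift)
    g$unperm <- order(g$perm)
    g$masks <- shift_attn_masks(gh, gw, wn, shift, win_idx)
  }
  g
}
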