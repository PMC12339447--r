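#' Patch grid over an image
#'
#' @param image_size integer (height, width) in pixels.
#' @param patch_size patch edge in pixels; must divide both dimensions.
#' @return a `patch_grid`: list with `image_size`, `patch_size`, grid shape
#'   `(gh, gw)` and total patch count `n_patches`.
#' @export
patch_grid <- function(image_size, patch_size) {
  image_size <- as.integer(image_size); patch_size <- as.integer(patch_size)
  if (any(image_size %% patch_size != 0L))
    config_error("image dimensions must be divisible by patch_size")
  gh <- image_size[1] %/% patch_size; gw <- image_size[2] %/% patch_size
  if (gh * gw < 4L) config_error("grid must contain at least 4 patches")
  structure(list(image_size = image_size, patch_size = patch_size,
                 gh = gh, gw = gw, n_patches = gh * gw),
            class = "patch_grid")
}

#' Split an image into an ordered patch sequence (and back)
#'
#' Patch order is row-major over the patch grid; pixels within a patch are
#' flattened column-major (R's native order). `unpatchify(patchify(x)) == x`
#' bit-exactly.
#'
#' @param image numeric `H x W` matrix.
#' @param grid a [patch_grid()].
#' @return `patchify`: a `n_patches x patch_size^2` matrix; `unpatchify`: the
#'   reassembled image.
#' @export
patchify <- function(image, grid) {
  p <- grid$patch_size
  if (!all(dim(image) == grid$image_size))
    config_error("image does not match the patch grid")
  out <- matrix(0, grid$n_patches, p * p)
  for (gi in seq_len(grid$gh)) for (gj in seq_len(grid$gw)) {
    out[(gi - 1L) * grid$gw + gj, ] <-
      image[((gi - 1L) * p + 1L):(gi * p), ((gj - 1L) * p + 1L):(gj * p)]
  }
  out
}

#' @rdname patchify
#' @param patches matrix as produced by `patchify`.
#' @export
unpatchify <- function(patches, grid) {
  p <- grid$patch_size
  if (nrow(patches) != grid$n_patches || ncol(patches) != p * p)
    config_error("patch matrix does not match the grid")
  img <- matrix(0, grid$image_size[1], grid$image_size[2])
  for (gi in seq_len(grid$gh)) for (gj in seq_len(grid$gw)) {
    img[((gi - 1L) * p + 1L):(gi * p), ((gj - 1L) * p + 1L):(gj * p)] <-
      matrix(patches[(gi - 1L) * grid$gw + gj, ], p, p)
  }
  img
}

#' Sample a random patch mask
#'
#' Masks exactly `floor(mask_ratio * n_patches)` patches, chosen uniformly
#' without replacement; deterministic for a fixed seed.
#'
#' @param grid a [patch_grid()].
#' @param mask_ratio masking ratio in (0, 1); the framework's default is 0.7.
#' @param rng_seed integer seed.
#' @return a `mask_plan`: list with logical `mask` (length `n_patches`,
#'   `TRUE` = masked), `m_ratio`, the pixel-level logical `pixel_mask`, and
#'   the grid.
#' @export
sample_mask <- function(grid, mask_ratio, rng_seed) {
  if (mask_ratio <= 0 || mask_ratio >= 1)
    config_error("mask_ratio must lie strictly between 0 and 1")
  n_masked <- floor(mask_ratio * grid$n_patches)
  if (n_masked < 1L || n_masked >= grid$n_patches)
    config_error("mask would hide none or all patches; adjust ratio or grid")
  chosen <- with_seed(rng_seed, sample(grid$n_patches, n_masked))
  mask <- rep(FALSE, grid$n_patches)
  mask[chosen] <- TRUE
  structure(list(mask = mask, m_ratio = mask_ratio,
                 pixel_mask = mask_to_pixels(mask, grid), grid = grid),
            class = "mask_plan")
}

# Upsample a patch mask to pixel resolution.
mask_to_pixels <- function(mask, grid) {
  p <- grid$patch_size
  px <- matrix(FALSE, grid$image_size[1], grid$image_size[2])
  for (i in which(mask)) {
    gi <- (i - 1L) %/% grid$gw + 1L
    gj <- (i - 1L) %% grid$gw + 1L
    px[((gi - 1L) * p + 1L):(gi * p), ((gj - 1L) * p + 1L):(gj * p)] <- TRUE
  }
  px
}

#' Masked reconstruction loss
#'
#' The pre-training objective: mean squared error restricted to masked
#' pixels, normalized by the mask ratio,
#' `(1 / m_ratio) * (1 / N) * sum((x_hat - x)^2 * m)`,
#' where `m` is the pixel mask and `N` the total pixel count. The value does
#' not depend on the reconstruction at unmasked pixels, and when `m_ratio`
#' equals the exact masked fraction it equals the plain MSE over masked
#' pixels.
#'
#' @param x original image (matrix).
#' @param x_hat reconstruction, same shape.
#' @param pixel_mask logical (or 0/1) matrix, same shape; TRUE = masked.
#' @param m_ratio mask ratio in (0, 1].
#' @return nonnegative scalar loss.
#' @export
masked_mse_loss <- function(x, x_hat, pixel_mask, m_ratio) {
  if (m_ratio <= 0) config_error("m_ratio must be positive")
  if (!all(dim(x) == dim(x_hat)) || !all(dim(x) == dim(pixel_mask)))
    config_error("x, x_hat and pixel_mask must share one shape")
  n <- length(x)
  sum((x_hat - x)^2 * as.numeric(pixel_mask)) / (m_ratio * n)
}
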