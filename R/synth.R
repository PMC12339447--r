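#' Domain parameters for one synthetic OCT source
#'
#' Describes the acquisition characteristics of one simulated data source
#' (device/site): image geometry, number of retinal bands, band reflectivity,
#' multiplicative speckle scale, optical blur, and an affine intensity shift.
#' Varying these across sources creates the multi-source domain gaps the
#' framework is designed to bridge.
#'
#' @param source_id short string identifying the source.
#' @param image_size integer (height, width) in pixels.
#' @param n_layers number of retinal bands (reflective layers).
#' @param layer_contrast reflectivity of each band, in `[0, 1]`; length
#'   `n_layers`. Defaults to an alternating bright/dark profile with a bright
#'   outermost (RPE-like) band.
#' @param speckle_sigma standard deviation of the log-normal multiplicative
#'   speckle (0 disables noise).
#' @param blur_sigma Gaussian point-spread sigma in pixels (0 disables blur).
#' @param intensity_gain,intensity_offset affine device shift applied after
#'   rendering: `gain * img + offset`.
#' @param background_level vitreous/background intensity in `[0, 1]`.
#' @param patch_size patch size (px) the downstream model grid will use; the
#'   generator refuses images smaller than twice this value.
#' @return an object of class `oct_domain`.
#' @export
domain_params <- function(source_id,
                          image_size = c(64L, 64L),
                          n_layers = 5L,
                          layer_contrast = NULL,
                          speckle_sigma = 0.2,
                          blur_sigma = 0.5,
                          intensity_gain = 1.0,
                          intensity_offset = 0.0,
                          background_level = 0.05,
                          patch_size = 8L) {
  if (is.null(layer_contrast)) {
    base <- rep(c(0.55, 0.25), length.out = n_layers)
    base[n_layers] <- 0.9          # outermost band (RPE-like) is brightest
    if (n_layers >= 2L) base[n_layers - 1L] <- 0.2
    layer_contrast <- base
  }
  d <- structure(list(
    source_id = as.character(source_id),
    image_size = as.integer(image_size),
    n_layers = as.integer(n_layers),
    layer_contrast = as.numeric(layer_contrast),
    speckle_sigma = speckle_sigma,
    blur_sigma = blur_sigma,
    intensity_gain = intensity_gain,
    intensity_offset = intensity_offset,
    background_level = background_level,
    patch_size = as.integer(patch_size)
  ), class = "oct_domain")
  validate_domain(d)
  d
}

validate_domain <- function(d) {
  if (length(d$image_size) != 2L || any(d$image_size <= 0L))
    config_error("image_size must be two positive integers")
  if (d$n_layers < 1L || length(d$layer_contrast) != d$n_layers)
    config_error("layer_contrast must have one value per band")
  if (any(d$layer_contrast < 0) || any(d$layer_contrast > 1))
    config_error("layer_contrast values must lie in [0, 1]")
  if (!is.finite(d$speckle_sigma) || d$speckle_sigma < 0)
    config_error("speckle_sigma must be finite and >= 0")
  if (!is.finite(d$blur_sigma) || d$blur_sigma < 0)
    config_error("blur_sigma must be finite and >= 0")
  if (d$background_level < 0 || d$background_level > 1)
    config_error("background_level must lie in [0, 1]")
  if (any(d$image_size < 2L * d$patch_size))
    config_error("image_size must be at least twice the configured patch size")
  invisible(d)
}

#' Lesion parameters for one synthetic class
#'
#' Controls the morphology added on top of the normal layered anatomy.
#' `AMD` renders drusen-like dome deformations of the outer band; `CNV_LIKE`
#' renders larger domes plus a fluid pocket; `DME_LIKE` renders a fluid
#' pocket only. `NORMAL` must be lesion-free.
#'
#' @param class_label one of `"NORMAL"`, `"AMD"`, `"CNV_LIKE"`, `"DME_LIKE"`.
#' @param n_bumps number of dome deformations (0 for NORMAL/DME_LIKE).
#' @param bump_amplitude dome height in pixels.
#' @param bump_width dome Gaussian half-width in pixels.
#' @param fluid_pocket whether a hyporeflective fluid pocket is added.
#' @param pocket_size pocket radius in pixels.
#' @return an object of class `oct_lesion`.
#' @export
lesion_params <- function(class_label = c("NORMAL", "AMD", "CNV_LIKE", "DME_LIKE"),
                          n_bumps = NULL, bump_amplitude = 6, bump_width = 4,
                          fluid_pocket = NULL, pocket_size = 6) {
  class_label <- match.arg(class_label)
  if (is.null(n_bumps))
    n_bumps <- switch(class_label, NORMAL = 0L, AMD = 2L, CNV_LIKE = 3L,
                      DME_LIKE = 0L)
  if (is.null(fluid_pocket))
    fluid_pocket <- class_label %in% c("CNV_LIKE", "DME_LIKE")
  l <- structure(list(
    class_label = class_label, n_bumps = as.integer(n_bumps),
    bump_amplitude = bump_amplitude, bump_width = bump_width,
    fluid_pocket = isTRUE(fluid_pocket), pocket_size = pocket_size
  ), class = "oct_lesion")
  if (l$class_label == "NORMAL" && (l$n_bumps != 0L || l$fluid_pocket))
    config_error("NORMAL must have no bumps and no fluid pocket")
  if (l$n_bumps > 0L && (l$bump_amplitude <= 0 || l$bump_width <= 0))
    config_error("bump amplitude and width must be positive when bumps present")
  if (l$fluid_pocket && l$pocket_size <= 0)
    config_error("pocket_size must be positive when fluid_pocket is set")
  l
}

# Separable Gaussian blur with replicate padding.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  blur_1d <- function(m) { # along rows (first dim)
    n <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

#' Render one synthetic OCT B-scan
#'
#' Deterministically renders a layered-band B-scan for the given source
#' domain and lesion morphology: smooth curved retinal bands, optional
#' drusen-like domes deforming the outer band, optional fluid pocket,
#' multiplicative log-normal speckle, Gaussian blur, and an affine device
#' intensity shift. Pixel values are clipped to `[0, 1]`.
#'
#' The RNG is split into independent anatomy / lesion / noise streams so
#' that, for a fixed seed, the lesion-free render of the same eye is obtained
#' by passing `lesion_params("NORMAL")` (useful for lesion-contrast checks).
#'
#' @param domain an `oct_domain`.
#' @param lesion an `oct_lesion`.
#' @param rng_seed integer seed; identical inputs and seed give bit-identical
#'   images.
#' @param anatomy_seed optional separate seed for the anatomy stream, used to
#'   keep all scans of one subject anatomically consistent.
#' @return an `height x width` numeric matrix in `[0, 1]`, with attributes
#'   `boundaries` (band boundary rows per column) and `bump_boxes` (list of
#'   lesion bounding boxes `c(x0, x1, y0, y1)`).
#' @export
generate_bscan <- function(domain, lesion, rng_seed, anatomy_seed = NULL) {
  validate_domain(domain)
  if (!inherits(lesion, "oct_lesion")) config_error("lesion must be oct_lesion")
  h <- domain$image_size[1]; w <- domain$image_size[2]
  x <- seq_len(w)
  if (is.null(anatomy_seed)) anatomy_seed <- derive_seed(rng_seed, 1L)

  # --- anatomy stream: curvature, band thicknesses -------------------------
  anat <- with_seed(anatomy_seed, {
    amp <- stats::runif(2, 0.01, 0.035) * h
    ph <- stats::runif(2, 0, 2 * pi)
    fr <- c(1, 2)
    pert <- amp[1] * cos(2 * pi * fr[1] * x / w + ph[1]) +
      amp[2] * cos(2 * pi * fr[2] * x / w + ph[2])
    thick <- stats::runif(domain$n_layers, 0.6, 1.4)
    list(pert = pert, thick = thick / sum(thick))
  })
  top <- 0.18 * h + 0.10 * h * ((x - w / 2) / (w / 2))^2 + anat$pert
  depth <- 0.62 * h
  # boundaries[k, ] is the row of the top of band k; row n_layers+1 is bottom
  boundaries <- matrix(0, domain$n_layers + 1L, w)
  boundaries[1L, ] <- top
  for (k in seq_len(domain$n_layers))
    boundaries[k + 1L, ] <- boundaries[k, ] + anat$thick[k] * depth

  # --- lesion stream: dome deformations of the outer boundary --------------
  bump_boxes <- list()
  pocket <- NULL
  if (lesion$n_bumps > 0L || lesion$fluid_pocket) {
    les <- with_seed(derive_seed(rng_seed, 2L), {
      cx <- if (lesion$n_bumps > 0L)
        stats::runif(lesion$n_bumps, 0.15 * w, 0.85 * w) else numeric(0)
      pc <- c(stats::runif(1, 0.35 * w, 0.65 * w))
      list(cx = cx, pocket_cx = pc)
    })
    if (lesion$n_bumps > 0L) {
      kb <- domain$n_layers  # top boundary row index of the outermost band
      for (j in seq_len(lesion$n_bumps)) {
        d <- lesion$bump_amplitude *
          exp(-0.5 * ((x - les$cx[j]) / lesion$bump_width)^2)
        boundaries[kb, ] <- boundaries[kb, ] - d
        x0 <- max(1, floor(les$cx[j] - 2 * lesion$bump_width))
        x1 <- min(w, ceiling(les$cx[j] + 2 * lesion$bump_width))
        yc <- boundaries[kb, round(les$cx[j])]
        bump_boxes[[j]] <- c(x0 = x0, x1 = x1,
                             y0 = max(1, floor(yc - 1)),
                             y1 = min(h, ceiling(yc + lesion$bump_amplitude + 1)))
      }
    }
    if (lesion$fluid_pocket) {
      mid <- ceiling(domain$n_layers / 2)
      cyx <- (boundaries[mid, ] + boundaries[mid + 1L, ]) / 2
      pocket <- list(cx = les$pocket_cx, cy = cyx[round(les$pocket_cx)],
                     rx = lesion$pocket_size * 1.6, ry = lesion$pocket_size)
    }
  }

  # --- render bands ---------------------------------------------------------
  rowidx <- matrix(seq_len(h), h, w)
  img <- matrix(domain$background_level, h, w)
  for (k in seq_len(domain$n_layers)) {
    up <- matrix(boundaries[k, ], h, w, byrow = TRUE)
    lo <- matrix(boundaries[k + 1L, ], h, w, byrow = TRUE)
    img[rowidx > up & rowidx <= lo] <- domain$layer_contrast[k]
  }
  if (!is.null(pocket)) {
    cxm <- matrix(x, h, w, byrow = TRUE)
    inside <- ((cxm - pocket$cx) / pocket$rx)^2 +
      ((rowidx - pocket$cy) / pocket$ry)^2 <= 1
    img[inside] <- img[inside] * 0.15
  }

  # --- noise stream ---------------------------------------------------------
  if (domain$speckle_sigma > 0) {
    img <- img * with_seed(derive_seed(rng_seed, 3L), {
      matrix(exp(stats::rnorm(h * w, 0, domain$speckle_sigma) -
                   domain$speckle_sigma^2 / 2), h, w)
    })
  }
  img <- gauss_blur(img, domain$blur_sigma)
  img <- clamp01(domain$intensity_gain * img + domain$intensity_offset)
  attr(img, "boundaries") <- boundaries
  attr(img, "bump_boxes") <- bump_boxes
  img
}

#' Generate a full synthetic source: subject-grouped scans plus manifest
#'
#' Assigns `n_subjects` subjects to classes by largest-remainder apportionment
#' of `class_mix`, renders `scans_per_subject` B-scans per subject (all scans
#' of a subject share its class label and anatomy), and returns the images
#' together with a manifest. Deterministic for a fixed seed.
#'
#' @param domain an `oct_domain`.
#' @param n_subjects,scans_per_subject positive integer counts.
#' @param class_mix named proportions over class labels, summing to 1.
#' @param rng_seed integer seed.
#' @param lesions optional named list of `oct_lesion` overrides per class.
#' @param cap maximum total number of scans (guards accidental huge runs).
#' @return list with `images` (named list of matrices, keyed by image id) and
#'   `manifest` (an `oct_manifest` data frame).
#' @export
generate_source <- function(domain, n_subjects, scans_per_subject, class_mix,
                            rng_seed, lesions = NULL, cap = 100000L) {
  validate_domain(domain)
  if (n_subjects < 1L || scans_per_subject < 1L)
    config_error("subject and scan counts must be positive")
  if (as.double(n_subjects) * scans_per_subject > cap)
    config_error(sprintf("requested %d scans exceeds the cap of %d",
                         n_subjects * scans_per_subject, cap))
  stopifnot_prob_vector(class_mix, "class_mix")
  labels <- names(class_mix)
  if (is.null(labels)) config_error("class_mix must be named by class label")
  counts <- largest_remainder(n_subjects, as.numeric(class_mix))
  subj_class <- rep(labels, counts)

  rows <- vector("list", n_subjects * scans_per_subject)
  images <- vector("list", n_subjects * scans_per_subject)
  ids <- character(n_subjects * scans_per_subject)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    cls <- subj_class[s]
    les <- if (!is.null(lesions[[cls]])) lesions[[cls]] else lesion_params(cls)
    subject_id <- sprintf("%s_sub%03d", domain$source_id, s)
    aseed <- derive_seed(rng_seed, 7L, s)
    for (k in seq_len(scans_per_subject)) {
      i <- i + 1L
      image_id <- sprintf("%s_sub%03d_img%04d", domain$source_id, s, k)
      img <- generate_bscan(domain, les, derive_seed(rng_seed, s, k),
                            anatomy_seed = aseed)
      images[[i]] <- img
      ids[i] <- image_id
      rows[[i]] <- data.frame(
        image_path = file.path(domain$source_id, paste0(image_id, ".png")),
        source_id = domain$source_id, subject_id = subject_id,
        class_label = cls, split = "unassigned",
        stringsAsFactors = FALSE)
    }
  }
  names(images) <- ids
  manifest <- as_manifest(do.call(rbind, rows))
  list(images = images, manifest = manifest)
}

#' Built-in multi-source study presets
#'
#' Three heterogeneous synthetic sources ("src1" is the large Kermany-like
#' archive, "src2" the small subject-grouped set, "src3" the stratified
#' volume-derived set) with distinct contrast, speckle, blur, and affine
#' intensity shifts, plus the class mixes used by the two training phases:
#' pre-training keeps all four categories, supervised training is binary with
#' an 80:20 NORMAL:AMD imbalance.
#'
#' @param profile `"tiny"` (64x64, patch 8) or `"paper"` (224x224, patch 16).
#' @return list with `domains` (list of three `oct_domain`), `pretrain_mix`,
#'   and `supervised_mix`.
#' @export
oct_study_presets <- function(profile = c("tiny", "paper")) {
  profile <- match.arg(profile)
  sz <- if (profile == "tiny") c(64L, 64L) else c(224L, 224L)
  ps <- if (profile == "tiny") 8L else 16L
  domains <- list(
    domain_params("src1", image_size = sz, n_layers = 5L, speckle_sigma = 0.20,
                  blur_sigma = 0.5, intensity_gain = 1.00,
                  intensity_offset = 0.00, patch_size = ps),
    domain_params("src2", image_size = sz, n_layers = 4L, speckle_sigma = 0.35,
                  blur_sigma = 1.0, intensity_gain = 0.85,
                  intensity_offset = 0.06, background_level = 0.08,
                  patch_size = ps),
    domain_params("src3", image_size = sz, n_layers = 6L, speckle_sigma = 0.15,
                  blur_sigma = 0.7, intensity_gain = 1.15,
                  intensity_offset = -0.04, background_level = 0.03,
                  patch_size = ps)
  )
  list(domains = domains,
       pretrain_mix = c(NORMAL = 0.55, AMD = 0.15, CNV_LIKE = 0.15,
                        DME_LIKE = 0.15),
       supervised_mix = c(NORMAL = 0.8, AMD = 0.2))
}

#' Write a generated source to disk as 8-bit PNGs plus manifest CSV
#'
#' @param gen result of [generate_source()].
#' @param out_dir output directory; images go to `<out_dir>/<source_id>/`.
#' @return invisibly, the manifest with `image_path` relative to `out_dir`.
#' @export
write_source <- function(gen, out_dir) {
  man <- gen$manifest
  src_dir <- file.path(out_dir, man$source_id[1])
  dir.create(src_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(man))) {
    img <- gen$images[[manifest_image_id(man$image_path[i])]]
    img8 <- round(clamp01(as.matrix(img)) * 255) / 255
    png::writePNG(img8, target = file.path(out_dir, man$image_path[i]))
  }
  write_manifest(man, file.path(out_dir, paste0("manifest_",
                                                man$source_id[1], ".csv")))
  invisible(man)
}
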