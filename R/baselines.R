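#' Baseline classifier architectures with exact parameter accounting
#'
#' Builds a declarative layer-by-layer description of the two standard
#' baseline classifiers used for comparison — ResNet-50 and ViT-Base
#' (patch 16, 224 input) — with a 2-way softmax head, and the exact trainable
#' parameter count of every layer (convolution kernels without bias as in the
#' reference implementations, batch-norm scale/shift, attention and MLP
#' weights, biases). With the binary head these count to 23.5 M (ResNet-50)
#' and 86 M (ViT-Base), matching the published sizes.
#'
#' @param name `"resnet50"` or `"vit_base"`.
#' @param n_classes output classes (default 2: NORMAL vs AMD).
#' @return an `rt_baseline`: list with `name`, `n_classes` and a `layers`
#'   data frame (`layer`, `n_params`); use [count_parameters()] for totals.
#' @export
build_baseline <- function(name = c("resnet50", "vit_base"), n_classes = 2L) {
  name <- match.arg(name)
  layers <- if (name == "resnet50") resnet50_layers(n_classes)
            else vit_base_layers(n_classes)
  structure(list(name = name, n_classes = as.integer(n_classes),
                 layers = layers),
            class = "rt_baseline")
}

resnet50_layers <- function(n_classes) {
  rows <- list()
  add <- function(layer, n) rows[[length(rows) + 1L]] <<-
    data.frame(layer = layer, n_params = as.numeric(n))
  conv <- function(k, cin, cout) k * k * cin * cout      # no conv bias
  bn <- function(c) 2 * c                                # scale + shift
  add("conv1 7x7x3x64", conv(7, 3, 64))
  add("bn1", bn(64))
  stages <- list(c(blocks = 3, mid = 64,  out = 256),
                 c(blocks = 4, mid = 128, out = 512),
                 c(blocks = 6, mid = 256, out = 1024),
                 c(blocks = 3, mid = 512, out = 2048))
  cin <- 64
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    for (b in seq_len(st["blocks"])) {
      pre <- sprintf("layer%d.block%d", si, b)
      add(paste0(pre, ".conv1 1x1"), conv(1, cin, st["mid"]))
      add(paste0(pre, ".bn1"), bn(st["mid"]))
      add(paste0(pre, ".conv2 3x3"), conv(3, st["mid"], st["mid"]))
      add(paste0(pre, ".bn2"), bn(st["mid"]))
      add(paste0(pre, ".conv3 1x1"), conv(1, st["mid"], st["out"]))
      add(paste0(pre, ".bn3"), bn(st["out"]))
      if (b == 1L) {  # projection shortcut on the first block of each stage
        add(paste0(pre, ".downsample"), conv(1, cin, st["out"]))
        add(paste0(pre, ".downsample.bn"), bn(st["out"]))
      }
      cin <- st["out"]
    }
  }
  add("fc", 2048 * n_classes + n_classes)
  do.call(rbind, rows)
}

vit_base_layers <- function(n_classes, embed = 768, depth = 12, mlp = 3072,
                            patches = 196) {
  rows <- list()
  add <- function(layer, n) rows[[length(rows) + 1L]] <<-
    data.frame(layer = layer, n_params = as.numeric(n))
  add("patch_embed 16x16x3", 16 * 16 * 3 * embed + embed)
  add("cls_token", embed)
  add("pos_embed", (patches + 1) * embed)
  for (b in seq_len(depth)) {
    pre <- sprintf("block%d", b)
    add(paste0(pre, ".norm1"), 2 * embed)
    add(paste0(pre, ".attn.qkv"), embed * 3 * embed + 3 * embed)
    add(paste0(pre, ".attn.proj"), embed * embed + embed)
    add(paste0(pre, ".norm2"), 2 * embed)
    add(paste0(pre, ".mlp.fc1"), embed * mlp + mlp)
    add(paste0(pre, ".mlp.fc2"), mlp * embed + embed)
  }
  add("norm", 2 * embed)
  add("head", embed * n_classes + n_classes)
  do.call(rbind, rows)
}
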