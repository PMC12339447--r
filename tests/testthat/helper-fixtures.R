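# Shared fixtures, built in code. Heavier objects are memoized per test run.

.fixture_env <- new.env()

noiseless_domain <- function(source_id = "t1", ...) {
  domain_params(source_id, speckle_sigma = 0, blur_sigma = 0, ...)
}

# A small split-assigned manifest with images, one source, binary classes.
tiny_labeled_set <- function(n_subjects = 30, seed = 11) {
  key <- paste0("lab", n_subjects, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    gen <- generate_source(noiseless_domain(), n_subjects, 1L,
                           c(NORMAL = 0.5, AMD = 0.5), rng_seed = seed)
    man <- split_random_stratified(gen$manifest, c(0.6, 0.2, 0.2), seed)
    .fixture_env[[key]] <- list(images = gen$images, manifest = man)
  }
  .fixture_env[[key]]
}

manifest_split <- function(man, split) {
  as_manifest(as.data.frame(man)[man$split == split, , drop = FALSE])
}

# Plain manifest data frame without image files (for split/fusion logic).
fake_manifest <- function(n, source = "s", class_label = "NORMAL",
                          split = "unassigned", offset = 0) {
  as_manifest(data.frame(
    image_path = sprintf("%s/%s_img%04d.png", source, source,
                         offset + seq_len(n)),
    source_id = source,
    subject_id = sprintf("%s_sub%03d", source, offset + seq_len(n)),
    class_label = rep_len(class_label, n),
    split = rep_len(split, n),
    stringsAsFactors = FALSE))
}

# One shared pretrained checkpoint on a small fused set (used by transfer,
# freezing and reconstruction-improvement tests).
shared_pretrain <- function() {
  if (is.null(.fixture_env$ck)) {
    set <- tiny_labeled_set(24, seed = 31)
    fus <- fuse_for_pretraining(list(set$manifest), rng_seed = 1)
    .fixture_env$ck <- pretrain(
      fus, "swinv2-tiny", pretrain_config(epochs = 3, batch_size = 16,
                                          seed = 5),
      images = set$images)
    .fixture_env$ck_set <- set
  }
  list(ck = .fixture_env$ck, set = .fixture_env$ck_set)
}
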