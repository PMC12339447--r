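#' Dataset manifests
#'
#' A manifest is a data frame with one row per B-scan and columns
#' `image_path`, `source_id`, `subject_id`, `class_label`, `split`
#' (one of `train`, `val`, `test`, `unassigned`), plus a derived unique
#' `image_id` (the image file name without extension). Manifests carry a
#' free-text `provenance` attribute recording how they were produced.
#'
#' @param df data frame with the manifest columns.
#' @param provenance free-text note.
#' @return an `oct_manifest` data frame.
#' @export
as_manifest <- function(df, provenance = "") {
  req <- c("image_path", "source_id", "subject_id", "class_label", "split")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    data_error(paste("manifest missing columns:",
                     paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$image_id <- manifest_image_id(df$image_path)
  bad <- !df$split %in% c("train", "val", "test", "unassigned")
  if (any(bad))
    data_error(sprintf("invalid split value(s): %s",
                       paste(unique(df$split[bad]), collapse = ", ")))
  if (anyDuplicated(df$image_id))
    data_error("duplicate image_id in manifest")
  rownames(df) <- NULL
  structure(df, class = c("oct_manifest", "data.frame"),
            provenance = provenance)
}

manifest_image_id <- function(path) sub("\\.[A-Za-z]+$", "", basename(path))

#' @rdname as_manifest
#' @param path CSV file path.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_manifest(df, provenance = paste("read from", path))
}

#' @rdname as_manifest
#' @param manifest an `oct_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("image_path", "source_id", "subject_id", "class_label", "split")
  utils::write.csv(as.data.frame(manifest)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map labels to the binary NORMAL/AMD task
#'
#' Optionally relabels drusen images as AMD (drusen mark early AMD), then
#' drops every record whose label is neither NORMAL nor AMD. The input is
#' not modified.
#'
#' @param manifest an `oct_manifest`.
#' @param drusen_to_amd relabel `DRUSEN` (any case) to `AMD` before filtering.
#' @return a filtered `oct_manifest` with labels in `{NORMAL, AMD}`.
#' @export
map_labels_binary <- function(manifest, drusen_to_amd = TRUE) {
  if (nrow(manifest) == 0L) data_error("manifest is empty")
  lab <- manifest$class_label
  if (drusen_to_amd) lab[toupper(lab) == "DRUSEN"] <- "AMD"
  keep <- lab %in% c("NORMAL", "AMD")
  out <- as.data.frame(manifest)[keep, , drop = FALSE]
  out$class_label <- lab[keep]
  if (nrow(out) == 0L) data_error("empty after filtering to NORMAL/AMD")
  as_manifest(out, provenance = paste0(attr(manifest, "provenance"),
                                       "; binary filter (drusen_to_amd=",
                                       drusen_to_amd, ")"))
}

#' Stratified random split
#'
#' Assigns `train`/`val`/`test` per class with largest-remainder rounding
#' (remainders go to train first); deterministic for a fixed seed.
#'
#' @param manifest an `oct_manifest`.
#' @param ratios length-3 positive proportions (train, val, test) summing to 1.
#' @param rng_seed integer seed.
#' @return the manifest with `split` assigned.
#' @export
split_random_stratified <- function(manifest, ratios = c(0.8, 0.1, 0.1),
                                    rng_seed = 1L) {
  if (length(ratios) != 3L || any(ratios <= 0))
    config_error("ratios must be three positive values")
  stopifnot_prob_vector(ratios, "split ratios")
  df <- as.data.frame(manifest)
  for (cls in unique(df$class_label)) {
    idx <- which(df$class_label == cls)
    if (length(idx) < 3L)
      data_error(sprintf("class %s has %d records; need >= 3 to fill splits",
                         cls, length(idx)))
    # largest-remainder per class (fractional-part ties toward train), then
    # guarantee every split is populated: with >= 3 records none may be empty
    counts <- largest_remainder(length(idx), ratios)
    while (any(counts == 0L)) {
      counts[which.max(counts)] <- counts[which.max(counts)] - 1L
      counts[which(counts == 0L)[1]] <- 1L
    }
    perm <- with_seed(derive_seed(rng_seed, match(cls, unique(df$class_label))),
                      sample(idx))
    df$split[perm] <- rep(c("train", "val", "test"), counts)
  }
  as_manifest(df, provenance = paste0(attr(manifest, "provenance"),
                                      "; stratified split seed=", rng_seed))
}

#' Subject-wise split
#'
#' Orders subjects lexicographically by `subject_id` within each class and
#' assigns the first `n_train` subjects to training, the next `n_val` to
#' validation, and the final `n_test` to testing, at subject granularity
#' (all scans of a subject share one split).
#'
#' @param manifest an `oct_manifest`.
#' @param n_train,n_val,n_test subject counts per class; must sum to the
#'   number of subjects in every class, and val/test must be nonzero.
#' @return the manifest with `split` assigned.
#' @export
split_by_subject <- function(manifest, n_train, n_val, n_test) {
  if (n_val < 1L || n_test < 1L || n_train < 1L)
    config_error("each split needs at least one subject")
  df <- as.data.frame(manifest)
  for (cls in unique(df$class_label)) {
    subs <- sort(unique(df$subject_id[df$class_label == cls]))
    if (length(subs) != n_train + n_val + n_test)
      data_error(sprintf(
        "class %s has %d subjects but counts sum to %d", cls, length(subs),
        n_train + n_val + n_test))
    assign_split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    df$split[df$class_label == cls] <-
      assign_split[match(df$subject_id[df$class_label == cls], subs)]
  }
  as_manifest(df, provenance = paste0(attr(manifest, "provenance"),
                                      "; subject split ", n_train, "/",
                                      n_val, "/", n_test))
}

#' Deduplicate exact byte-identical image files
#'
#' Optional filter removing records whose image file content hashes equal an
#' earlier record's (first occurrence kept). Requires image files on disk.
#'
#' @param manifest an `oct_manifest`.
#' @param root directory that `image_path` is relative to.
#' @return the deduplicated manifest.
#' @export
dedup_exact <- function(manifest, root = ".") {
  hashes <- vapply(manifest$image_path, function(p) {
    f <- file.path(root, p)
    if (!file.exists(f)) data_error(paste("missing image file:", f))
    paste(as.character(readBin(f, "raw", file.size(f))), collapse = "")
  }, character(1))
  keep <- !duplicated(hashes)
  as_manifest(as.data.frame(manifest)[keep, , drop = FALSE],
              provenance = paste0(attr(manifest, "provenance"),
                                  "; dedup_exact removed ", sum(!keep)))
}

#' Fuse multiple sources for self-supervised pre-training
#'
#' Concatenates and shuffles the per-source training splits into one fused
#' training set (likewise validation), while every test split stays held out
#' per source. All class labels are retained: pre-training is label-free and
#' uses every category. Test isolation is asserted by image id.
#'
#' @param manifests list of `oct_manifest`s with splits assigned.
#' @param rng_seed integer seed for the shuffle.
#' @return an object of class `fusion_result`: list with `fused_train`,
#'   `fused_val`, and `held_out_tests` (named by source).
#' @export
fuse_for_pretraining <- function(manifests, rng_seed = 1L) {
  if (!length(manifests)) data_error("no manifests to fuse")
  all_df <- lapply(manifests, as.data.frame)
  ids <- unlist(lapply(all_df, `[[`, "image_id"))
  if (anyDuplicated(ids))
    data_error("duplicate image_id across sources; refusing to fuse")
  if (any(vapply(all_df, function(d) any(d$split == "unassigned"), logical(1))))
    data_error("all manifests must have assigned splits before fusion")

  take <- function(split) do.call(rbind, lapply(all_df, function(d)
    d[d$split == split, , drop = FALSE]))
  tr <- take("train"); va <- take("val")
  if (is.null(tr) || nrow(tr) == 0L) data_error("fused training set is empty")
  tr <- tr[with_seed(derive_seed(rng_seed, 1L), sample(nrow(tr))), ,
           drop = FALSE]
  va <- va[with_seed(derive_seed(rng_seed, 2L), sample(nrow(va))), ,
           drop = FALSE]

  tests <- lapply(all_df, function(d) {
    as_manifest(d[d$split == "test", , drop = FALSE],
                provenance = paste("held-out test:", d$source_id[1]))
  })
  names(tests) <- vapply(all_df, function(d) d$source_id[1], character(1))

  if (any(tr$image_id %in% unlist(lapply(tests, `[[`, "image_id"))))
    data_error("test-set leakage: fused training shares image ids with a test set")

  structure(list(
    fused_train = as_manifest(tr, provenance = "fused training set"),
    fused_val = as_manifest(va, provenance = "fused validation set"),
    held_out_tests = tests
  ), class = "fusion_result")
}

#' @rdname fuse_for_pretraining
#' @param fusion a `fusion_result`.
#' @param out_dir directory for `fused_train.csv`, `fused_val.csv`, and
#'   per-source `test_<source>.csv`.
#' @export
write_fusion <- function(fusion, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(fusion$fused_train, file.path(out_dir, "fused_train.csv"))
  write_manifest(fusion$fused_val, file.path(out_dir, "fused_val.csv"))
  for (s in names(fusion$held_out_tests))
    write_manifest(fusion$held_out_tests[[s]],
                   file.path(out_dir, paste0("test_", s, ".csv")))
  invisible(out_dir)
}
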