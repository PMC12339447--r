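#' Synthesize the three-source desk-scale study
#'
#' Emulates the study layout with the built-in simulator: source 1 is a large
#' mixed-category archive (stratified 80/10/10 split, one scan per subject),
#' source 2 a small subject-grouped set with three equal classes split at
#' subject granularity (10/2/3 subjects per class), and source 3 a binary
#' imbalanced set (stratified split). Pre-training keeps all categories;
#' supervised manifests are produced with [map_labels_binary()].
#'
#' @param seed integer seed.
#' @param n_train_per_source target training-split size per source.
#' @param profile simulator profile, `"tiny"` or `"paper"`.
#' @return list with `manifests` (split-assigned, all categories), `images`
#'   (named list over all sources), and the `presets` used.
#' @export
synth_study <- function(seed = 1L, n_train_per_source = 150L,
                        profile = "tiny") {
  pre <- oct_study_presets(profile)
  # source 1: stratified archive with all four categories
  n1 <- ceiling(n_train_per_source / 0.8)
  g1 <- generate_source(pre$domains[[1]], n_subjects = n1,
                        scans_per_subject = 1L, class_mix = pre$pretrain_mix,
                        rng_seed = derive_seed(seed, 1L))
  m1 <- split_random_stratified(g1$manifest, c(0.8, 0.1, 0.1),
                                rng_seed = derive_seed(seed, 21L))
  # source 2: subject-grouped, 15 subjects per class, subject-wise 10/2/3
  spc <- max(1L, round(n_train_per_source / 30))
  g2 <- generate_source(pre$domains[[2]], n_subjects = 45L,
                        scans_per_subject = spc,
                        class_mix = c(NORMAL = 1/3, AMD = 1/3, DME_LIKE = 1/3),
                        rng_seed = derive_seed(seed, 2L))
  m2 <- split_by_subject(g2$manifest, 10L, 2L, 3L)
  # source 3: binary, imbalanced, stratified
  n3 <- ceiling(n_train_per_source / 0.8)
  g3 <- generate_source(pre$domains[[3]], n_subjects = n3,
                        scans_per_subject = 1L,
                        class_mix = pre$supervised_mix,
                        rng_seed = derive_seed(seed, 3L))
  m3 <- split_random_stratified(g3$manifest, c(0.8, 0.1, 0.1),
                                rng_seed = derive_seed(seed, 23L))
  list(manifests = list(src1 = m1, src2 = m2, src3 = m3),
       images = c(g1$images, g2$images, g3$images),
       presets = pre)
}

# Stratified subsample of a split-assigned manifest's training records.
subsample_train <- function(manifest, fraction, rng_seed) {
  df <- as.data.frame(manifest)
  keep <- rep(TRUE, nrow(df))
  tr <- which(df$split == "train")
  drop <- c()
  for (cls in unique(df$class_label[tr])) {
    idx <- tr[df$class_label[tr] == cls]
    n_keep <- max(1L, floor(fraction * length(idx)))
    sel <- with_seed(derive_seed(rng_seed, match(cls, unique(df$class_label))),
                     sample(idx, n_keep))
    drop <- c(drop, setdiff(idx, sel))
  }
  if (length(drop)) keep[drop] <- FALSE
  as_manifest(df[keep, , drop = FALSE],
              provenance = paste0(attr(manifest, "provenance"),
                                  "; train subsampled to ", fraction))
}

#' Run one experiment protocol end to end
#'
#' Wires simulate, prepare, pre-train, supervised training and
#' cross-evaluation into the study's experiment arms:
#' `full` (fused pre-training, one classifier per source, 3x3 evaluation),
#' `no_ssl` (randomly initialized encoder), `no_fusion` (per-source
#' pre-training), `unseen_pretrain` (pre-training and supervised training on
#' source 1 only, evaluation on all test sets), and `half_data` (supervised
#' training sets subsampled to 50%).
#'
#' @param experiment one of the five protocol names.
#' @param seed integer seed for the whole run.
#' @param out artifact directory (manifests, logs, config snapshot, report);
#'   `NULL` for no artifacts.
#' @param n_train_per_source,profile study size, see [synth_study()].
#' @param mae_name MAE preset for the encoder.
#' @param pretrain_epochs,supervised_epochs,patience,batch_size,lr_head,head_dims
#'   desk-scale training knobs.
#' @param study optional pre-built [synth_study()] result to reuse across
#'   arms (must match `seed`).
#' @return list with per-train-source `eval_report`s plus run metadata.
#' @export
run_experiment <- function(experiment = c("full", "no_ssl", "no_fusion",
                                          "unseen_pretrain", "half_data"),
                           seed = 1L, out = NULL,
                           n_train_per_source = 150L, profile = "tiny",
                           mae_name = "swinv2-tiny",
                           pretrain_epochs = 4L, supervised_epochs = 40L,
                           patience = 10L, batch_size = 32L, lr_head = 1e-3,
                           head_dims = c(32L, 16L), study = NULL) {
  experiment <- match.arg(experiment)
  if (!is.null(out)) {
    if (dir.exists(out) && length(list.files(out)))
      config_error(paste("output directory not empty:", out))
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    on.exit({  # quarantine partial artifacts if we fail before the marker
      if (!file.exists(file.path(out, "DONE")))
        file.rename(out, paste0(out, ".quarantine"))
    }, add = TRUE)
  }
  if (is.null(study)) study <- synth_study(seed, n_train_per_source, profile)
  mans <- study$manifests
  imgs <- study$images
  sources <- names(mans)

  pcfg <- pretrain_config(epochs = pretrain_epochs, batch_size = batch_size,
                          seed = derive_seed(seed, 31L))
  scfg <- supervised_config(epochs = supervised_epochs,
                            early_stop_patience = patience,
                            batch_size = batch_size, lr = lr_head,
                            seed = derive_seed(seed, 37L))

  # pre-training arm
  ckpts <- list()
  if (experiment %in% c("full", "half_data")) {
    fus <- fuse_for_pretraining(mans, rng_seed = derive_seed(seed, 41L))
    ck <- pretrain(fus, mae_name, pcfg, images = imgs,
                   log_path = if (!is.null(out))
                     file.path(out, "pretrain_log.csv") else NULL)
    for (s in sources) ckpts[[s]] <- ck
  } else if (experiment == "no_fusion") {
    for (s in sources) {
      fus <- fuse_for_pretraining(mans[s], rng_seed = derive_seed(seed, 41L))
      ckpts[[s]] <- pretrain(fus, mae_name, pcfg, images = imgs)
    }
  } else if (experiment == "unseen_pretrain") {
    fus <- fuse_for_pretraining(mans[sources[1]],
                                rng_seed = derive_seed(seed, 41L))
    ckpts[[sources[1]]] <- pretrain(fus, mae_name, pcfg, images = imgs)
  } # no_ssl: no checkpoints

  # supervised arms + cross evaluation
  binary <- lapply(mans, map_labels_binary)
  tests <- lapply(binary, function(m)
    as_manifest(as.data.frame(m)[m$split == "test", , drop = FALSE]))
  train_sources <- if (experiment == "unseen_pretrain") sources[1] else sources
  reports <- list()
  for (s in train_sources) {
    bm <- binary[[s]]
    if (experiment == "half_data")
      bm <- subsample_train(bm, 0.5, derive_seed(seed, 53L))
    trm <- as_manifest(as.data.frame(bm)[bm$split == "train", , drop = FALSE])
    vam <- as_manifest(as.data.frame(bm)[bm$split == "val", , drop = FALSE])
    clf <- build_classifier(encoder_ckpt = ckpts[[s]],
                            config = if (is.null(ckpts[[s]])) mae_name else NULL,
                            head = head_spec(head_dims), freeze = TRUE,
                            rng_seed = derive_seed(seed, 61L, match(s, sources)))
    fit <- train_classifier(clf, trm, vam, scfg, images = imgs,
                            log_path = if (!is.null(out))
                              file.path(out, paste0("train_log_", s, ".csv"))
                            else NULL)
    reports[[s]] <- cross_evaluate(fit, tests, images = imgs)
  }

  meta <- list(experiment = experiment, seed = seed,
               n_train_per_source = n_train_per_source, profile = profile,
               mae = mae_name, pretrain_epochs = pretrain_epochs,
               supervised_epochs = supervised_epochs)
  if (!is.null(out)) {
    for (s in sources)
      write_manifest(mans[[s]], file.path(out, paste0("manifest_", s, ".csv")))
    yaml::write_yaml(meta, file.path(out, "config_snapshot.yaml"))
    write_experiment_report(reports, file.path(out, "report.json"))
    writeLines(format(Sys.time()), file.path(out, "DONE"))
  }
  list(reports = reports, meta = meta)
}

#' @rdname write_eval_report
#' @export
write_experiment_report <- function(reports, path) {
  jsonlite::write_json(
    lapply(reports, function(rep)
      lapply(rep, function(r) r[setdiff(names(r), "undefined")])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Desk-scale ablation run: pre-training benefit and fusion benefit
#'
#' Runs one seed of the two directional comparisons on a fresh synthetic
#' three-source study: (a) frozen-encoder classifiers on all three sources
#' with fused self-supervised pre-training versus a randomly initialized
#' encoder ("no SSL"), and (b) a source-1 classifier whose encoder was
#' pre-trained on source 1 alone, evaluated on the other two sources'
#' held-out tests, versus the fused arm on the same cells.
#'
#' @param seed integer seed for data, initialization and training.
#' @param n_train_per_source training images per source (default 150).
#' @param pretrain_epochs MAE epochs per pre-training arm.
#' @param supervised_epochs,patience,lr_head,batch_size head-training knobs.
#' @return list with `auroc_ssl` and `auroc_no_ssl` (named 9-cell vectors),
#'   and `auroc_fused_foreign` / `auroc_single_foreign` (source-1 classifier
#'   AUC-ROC on the two non-pre-training sources).
#' @export
ssl_ablation_run <- function(seed, n_train_per_source = 150L,
                             pretrain_epochs = 4L, supervised_epochs = 40L,
                             patience = 10L, lr_head = 1e-3,
                             batch_size = 32L) {
  study <- synth_study(seed, n_train_per_source)
  bins <- lapply(study$manifests, map_labels_binary)
  tests <- lapply(bins, function(b)
    as_manifest(as.data.frame(b)[b$split == "test", , drop = FALSE]))
  pcfg <- pretrain_config(epochs = pretrain_epochs, batch_size = batch_size,
                          seed = derive_seed(seed, 31L))
  scfg <- supervised_config(epochs = supervised_epochs,
                            early_stop_patience = patience, lr = lr_head,
                            batch_size = batch_size,
                            seed = derive_seed(seed, 37L))
  train_eval <- function(src, ck) {
    b <- bins[[src]]
    clf <- build_classifier(ck, config = if (is.null(ck)) "swinv2-tiny" else NULL,
                            head = head_spec(c(32L, 16L)),
                            rng_seed = derive_seed(seed, 61L))
    fit <- train_classifier(
      clf,
      as_manifest(as.data.frame(b)[b$split == "train", , drop = FALSE]),
      as_manifest(as.data.frame(b)[b$split == "val", , drop = FALSE]),
      scfg, images = study$images)
    rep <- cross_evaluate(fit, tests, images = study$images)
    vapply(rep, `[[`, numeric(1), "auroc")
  }
  ck_fused <- pretrain(fuse_for_pretraining(study$manifests,
                                            rng_seed = derive_seed(seed, 41L)),
                       "swinv2-tiny", pcfg, images = study$images)
  ck_single <- pretrain(fuse_for_pretraining(study$manifests["src1"],
                                             rng_seed = derive_seed(seed, 41L)),
                        "swinv2-tiny", pcfg, images = study$images)
  a_ssl <- unlist(lapply(names(bins), function(s) {
    v <- train_eval(s, ck_fused); names(v) <- paste(s, names(v), sep = "->"); v
  }))
  a_no <- unlist(lapply(names(bins), function(s) {
    v <- train_eval(s, NULL); names(v) <- paste(s, names(v), sep = "->"); v
  }))
  single_src1 <- train_eval("src1", ck_single)
  list(auroc_ssl = a_ssl, auroc_no_ssl = a_no,
       auroc_fused_foreign = a_ssl[c("src1->src2", "src1->src3")],
       auroc_single_foreign = single_src1[c("src2", "src3")])
}
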