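test_that("binary label mapping relabels drusen and filters other classes", {
  man <- fake_manifest(8)
  man$class_label <- c(rep("NORMAL", 5), rep("DRUSEN", 2), "DME")
  out <- map_labels_binary(man)
  expect_equal(sum(out$class_label == "NORMAL"), 5)
  expect_equal(sum(out$class_label == "AMD"), 2)
  expect_equal(nrow(out), 7)
  # original untouched
  expect_equal(sum(man$class_label == "DRUSEN"), 2)
  # identity on binary input
  bin <- fake_manifest(6)
  bin$class_label <- rep(c("NORMAL", "AMD"), 3)
  expect_equal(map_labels_binary(bin)$class_label, bin$class_label)
  # drusen kept as non-AMD when mapping disabled
  expect_equal(nrow(map_labels_binary(man, drusen_to_amd = FALSE)), 5)
  # degenerate
  dme <- fake_manifest(4, class_label = "DME")
  expect_error(map_labels_binary(dme), "empty after filtering")
})

test_that("stratified split follows ratios with largest-remainder rounding", {
  man <- fake_manifest(200)
  man$class_label <- rep(c("NORMAL", "AMD"), each = 100)
  sp <- split_random_stratified(man, c(0.8, 0.1, 0.1), rng_seed = 4)
  for (cls in c("NORMAL", "AMD")) {
    tab <- table(sp$split[sp$class_label == cls])
    expect_equal(unname(tab[c("train", "val", "test")]), c(80L, 10L, 10L),
                 ignore_attr = TRUE)
  }
  # 10 per class -> 8/1/1
  small <- fake_manifest(20)
  small$class_label <- rep(c("NORMAL", "AMD"), each = 10)
  sps <- split_random_stratified(small, c(0.8, 0.1, 0.1), rng_seed = 4)
  expect_equal(unname(table(sps$split[sps$class_label == "AMD"])[
    c("train", "val", "test")]), c(8L, 1L, 1L), ignore_attr = TRUE)
  # determinism
  expect_identical(as.data.frame(sp),
                   as.data.frame(split_random_stratified(man, c(0.8, 0.1, 0.1),
                                                         rng_seed = 4)))
  expect_error(split_random_stratified(man, c(1, 0, 0)), "positive")
  tiny <- fake_manifest(2, class_label = "AMD")
  expect_error(split_random_stratified(tiny), ">= 3")
})

test_that("subject-wise split preserves subject integrity", {
  rows <- do.call(rbind, lapply(1:15, function(s) data.frame(
    image_path = sprintf("d/s%02d_i%d.png", s, 1:4),
    source_id = "d", subject_id = sprintf("sub%02d", s),
    class_label = rep(c("NORMAL", "AMD", "DME"), each = 5)[s],
    split = "unassigned", stringsAsFactors = FALSE)))
  man <- as_manifest(rows)
  sp <- split_by_subject(man, 3, 1, 1)
  # every subject's scans share one split
  expect_true(all(tapply(sp$split, sp$subject_id,
                         function(x) length(unique(x))) == 1))
  for (cls in unique(sp$class_label)) {
    subs <- tapply(sp$split[sp$class_label == cls],
                   sp$subject_id[sp$class_label == cls], unique)
    expect_equal(unname(table(factor(subs, c("train", "val", "test")))),
                 c(3L, 1L, 1L), ignore_attr = TRUE)
  }
  # first subjects (lexicographically) go to training
  expect_true(all(sp$split[sp$subject_id == "sub01"] == "train"))
  expect_error(split_by_subject(man, 10, 2, 3), "subjects")
  expect_error(split_by_subject(man, 5, 0, 0), "at least one")
})

test_that("fusion concatenates trains, shuffles, and isolates test sets", {
  mk <- function(src, n_train, n_val, n_test, offset = 0) {
    m <- fake_manifest(n_train + n_val + n_test, source = src,
                       offset = offset)
    m$split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    as_manifest(m)
  }
  a <- mk("a", 80, 10, 10); b <- mk("b", 100, 10, 10); c3 <- mk("c", 120, 10, 10)
  fus <- fuse_for_pretraining(list(a, b, c3), rng_seed = 2)
  expect_equal(nrow(fus$fused_train), 300)
  expect_equal(nrow(fus$fused_val), 30)
  expect_named(fus$held_out_tests, c("a", "b", "c"))
  # conservation and permutation
  expect_setequal(fus$fused_train$image_id,
                  c(a$image_id[a$split == "train"],
                    b$image_id[b$split == "train"],
                    c3$image_id[c3$split == "train"]))
  total <- nrow(fus$fused_train) + nrow(fus$fused_val) +
    sum(vapply(fus$held_out_tests, nrow, numeric(1)))
  expect_equal(total, nrow(a) + nrow(b) + nrow(c3))
  # isolation: no fused training id in any test set
  test_ids <- unlist(lapply(fus$held_out_tests, `[[`, "image_id"))
  expect_length(intersect(fus$fused_train$image_id, test_ids), 0)
  # single source: fusion equals that source's train up to order
  f1 <- fuse_for_pretraining(list(a), rng_seed = 9)
  expect_setequal(f1$fused_train$image_id, a$image_id[a$split == "train"])
  # duplicates across sources rejected (guards accidental double fusion)
  expect_error(fuse_for_pretraining(list(a, a), rng_seed = 1), "duplicate")
  # unassigned splits rejected
  expect_error(fuse_for_pretraining(list(fake_manifest(5)), rng_seed = 1),
               "assigned")
})

test_that("manifests round trip through CSV and enforce invariants", {
  man <- fake_manifest(5)
  f <- tempfile(fileext = ".csv")
  write_manifest(man, f)
  back <- read_manifest(f)
  expect_equal(as.data.frame(back), as.data.frame(man), ignore_attr = TRUE)
  expect_equal(readLines(f, n = 1),
               "image_path,source_id,subject_id,class_label,split")
  dup <- rbind(as.data.frame(man), as.data.frame(man)[1, ])
  expect_error(as_manifest(dup), "duplicate")
  bad <- as.data.frame(man); bad$split[1] <- "holdout"
  expect_error(as_manifest(bad), "invalid split")
})

test_that("exact-byte deduplication keeps first occurrences", {
  d <- noiseless_domain("dd")
  g <- generate_source(d, 4, 1, c(NORMAL = 1), rng_seed = 2)
  out <- tempfile(); dir.create(file.path(out, "dd"), recursive = TRUE)
  # write two identical files and two distinct ones
  ids <- g$manifest$image_id
  png::writePNG(g$images[[ids[1]]], file.path(out, g$manifest$image_path[1]))
  png::writePNG(g$images[[ids[1]]], file.path(out, g$manifest$image_path[2]))
  png::writePNG(g$images[[ids[3]]], file.path(out, g$manifest$image_path[3]))
  png::writePNG(g$images[[ids[4]]], file.path(out, g$manifest$image_path[4]))
  kept <- dedup_exact(g$manifest, root = out)
  expect_equal(nrow(kept), 3)
  expect_true(ids[1] %in% kept$image_id && !(ids[2] %in% kept$image_id))
})
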