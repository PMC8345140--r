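# Dataset ingestion, mask conversion, splitting and augmentation

test_that("patch folders round-trip through PNG with instance labels intact", {
  dir <- withr::local_tempdir()
  ids <- write_synth_patches(6, dir,
                             synth_patch_config(patch_size = 48,
                                                n_nuclei = c(2L, 4L),
                                                radius = c(3, 6)),
                             seed = 20)
  patches <- load_patch_folder(dir)
  expect_length(patches, 6)
  for (p in patches) {
    expect_equal(dim(p$image)[1:2], dim(p$gt_binary))
    expect_true(all(p$gt_binary %in% 0:1))
    if (!is.null(p$gt_instances)) {
      # binary mask must be the thresholded instance map
      expect_equal(p$gt_binary, instances_to_binary(p$gt_instances))
      # round-trip preserved the label values exactly
      orig <- generate_patch(synth_patch_config(
        patch_size = 48, n_nuclei = c(2L, 4L), radius = c(3, 6),
        seed = 20 + match(p$source_id, ids)))
      expect_equal(p$gt_instances, orig$labels)
    }
  }
})

test_that("folder loading reports missing masks and dimension mismatches", {
  dir <- withr::local_tempdir()
  write_synth_patches(2, dir, synth_patch_config(patch_size = 32,
                                                 n_nuclei = 2L,
                                                 radius = c(3, 5)), seed = 1)
  # orphan image
  file.copy(file.path(dir, "images", "patch0001.png"),
            file.path(dir, "images", "orphan.png"))
  expect_error(load_patch_folder(dir), "missing mask.*orphan")
  file.remove(file.path(dir, "images", "orphan.png"))
  # wrong-sized mask
  file.remove(file.path(dir, "masks", "patch0002.tif"))
  write_mask(matrix(0L, 16, 16), file.path(dir, "masks", "patch0002.tif"))
  expect_error(load_patch_folder(dir), "dimension mismatch.*patch0002")
})

test_that("instances_to_binary thresholds labels and is idempotent", {
  expect_true(all(instances_to_binary(matrix(0L, 4, 4)) == 0))
  m <- matrix(0L, 8, 8); m[1:4, 1:5] <- 1L; m[6:8, 2:7] <- 2L
  b <- instances_to_binary(m)
  expect_equal(sum(b), 20 + 18)
  expect_equal(instances_to_binary(b), b)
  expect_error(instances_to_binary(matrix(-1L, 2, 2)), ">= 0")
})

test_that("split_dataset uses largest-remainder sizes and is a partition", {
  sp <- split_dataset(1:10, c(0.6, 0.1, 0.3), seed = 1)
  expect_equal(as.vector(table(sp$partition)[c("train", "train_val", "test")]),
               c(6, 1, 3))
  # all-train degenerate ratios
  sp1 <- split_dataset(1:3, c(1, 0, 0), seed = 1)
  expect_true(all(sp1$partition == "train"))
  # determinism
  expect_identical(split_dataset(1:100, seed = 9), split_dataset(1:100, seed = 9))
  expect_error(split_dataset(1:10, c(0.5, 0.2, 0.2)), "sum to 1")

  # partition property across many N and seeds
  for (n in c(3, 7, 23, 57)) for (s in 1:3) {
    ids <- paste0("id", seq_len(n))
    sp <- split_dataset(ids, c(0.6, 0.1, 0.3), seed = s)
    expect_setequal(sp$id, ids)
    expect_equal(nrow(sp), n)
    sizes <- table(factor(sp$partition, c("train", "train_val", "test")))
    base <- floor(c(0.6, 0.1, 0.3) * n)
    expect_equal(sum(sizes), n)
    expect_true(all(sizes >= base))
    expect_true(all(sizes <= base + 1))
  }
})

test_that("grouped splitting keeps groups in one partition", {
  ids <- sprintf("p%02d", 1:30)
  grp <- rep(sprintf("core%02d", 1:10), each = 3)
  sp <- split_dataset(ids, c(0.6, 0.1, 0.3), seed = 4, group = grp)
  by_grp <- tapply(sp$partition, grp, function(z) length(unique(z)))
  expect_true(all(by_grp == 1))
})

test_that("flips are exact involutions that preserve per-label counts", {
  p <- generate_patch(synth_patch_config(patch_size = 48, n_nuclei = 4L,
                                         radius = c(3, 6), seed = 8))
  patch <- list(image = p$image, gt_binary = (p$labels > 0) * 1L,
                gt_instances = p$labels)
  twice <- augment_patch(augment_patch(patch, "hflip"), "hflip")
  expect_equal(twice, patch)
  v <- augment_patch(patch, "vflip")
  cnt <- function(lab) tabulate(lab[lab > 0], nbins = max(lab))
  expect_equal(cnt(v$gt_instances), cnt(patch$gt_instances))
  expect_error(augment_patch(patch, "sharpen"), "unknown augmentation")
})

test_that("warp augmentations approximately conserve foreground", {
  p <- generate_patch(synth_patch_config(patch_size = 64, n_nuclei = 5L,
                                         radius = c(4, 7), seed = 12))
  patch <- list(image = p$image, gt_binary = (p$labels > 0) * 1L,
                gt_instances = p$labels)
  # zero-amplitude elastic transform is the identity
  expect_equal(augment_patch(patch, "elastic", elastic_alpha = 0), patch)
  fg0 <- sum(patch$gt_binary)
  for (s in 1:5) {
    el <- augment_patch(patch, "elastic", seed = s)
    expect_lt(abs(sum(el$gt_binary) - fg0) / fg0, 0.05)
    # image and mask receive the same geometric transform: nuclei stay brown
    expect_lt(mean(el$image[, , 3][el$gt_binary > 0]),
              mean(el$image[, , 3][el$gt_binary == 0]))
    ssr <- augment_patch(patch, "shift_scale_rotate", seed = s,
                         shift_limit = 0.05, scale_limit = 0, rotate_limit = 30)
    expect_lt(abs(sum(ssr$gt_binary) - fg0) / fg0, 0.05)
  }
})
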