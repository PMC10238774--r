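test_that("the synthetic generator writes the requested layout and counts", {
  fx <- make_synth_fixture()
  man <- fx$manifest
  expect_s3_class(man, "dataset_manifest")
  expect_equal(unname(manifest_counts(man)), c(12L, 12L))
  expect_equal(sum(man$split == "train"), 12L)
  expect_equal(sum(man$split == "val"), 6L)
  expect_equal(sum(man$split == "test"), 6L)
  expect_true(all(file.exists(man$path)))
  # n_per_class convenience: counts (5, 5)
  dir2 <- withr::local_tempdir()
  man2 <- generate_synthetic_dataset(synth_config(n_per_class = 5, seed = 1),
                                     dir2)
  expect_equal(unname(manifest_counts(man2)), c(5L, 5L))
})

test_that("the generator is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- synth_config(counts = list(train = c(NORMAL = 3, PNEUMONIA = 3)),
                      seed = 7L)
  m1 <- generate_synthetic_dataset(cfg, d1)
  m2 <- generate_synthetic_dataset(cfg, d2)
  for (i in seq_len(nrow(m1)))
    expect_identical(readBin(m1$path[i], "raw", 1e6),
                     readBin(m2$path[i], "raw", 1e6))
  d3 <- withr::local_tempdir()
  cfg2 <- synth_config(counts = list(train = c(NORMAL = 3, PNEUMONIA = 3)),
                       seed = 8L)
  m3 <- generate_synthetic_dataset(cfg2, d3)
  expect_false(identical(readBin(m1$path[1], "raw", 1e6),
                         readBin(m3$path[1], "raw", 1e6)))
})

test_that("pneumonia-like images are brighter and threshold-separable", {
  dir <- withr::local_tempdir()
  man <- generate_synthetic_dataset(
    synth_config(counts = list(train = c(NORMAL = 40, PNEUMONIA = 40)),
                 seed = 11L), dir)
  imgs <- lapply(man$path, function(p) png::readPNG(p))
  mean_int <- vapply(imgs, mean, 0)
  max_int <- vapply(imgs, max, 0)
  lbl <- man$label
  expect_gt(mean(mean_int[lbl == 1]), mean(mean_int[lbl == 0]))
  # a single max-intensity threshold separates the classes (>= 95%)
  ths <- sort(max_int)
  acc <- vapply(ths, function(t) mean((max_int >= t) == lbl), 0)
  expect_gte(max(acc), 0.95)
})

test_that("manifest scanning validates the directory structure", {
  expect_error(load_manifest(file.path(tempdir(), "nope-missing")),
               "does not exist")
  empty <- withr::local_tempdir()
  expect_error(load_manifest(empty), "no train/val/test")
  broken <- withr::local_tempdir()
  dir.create(file.path(broken, "train", "NORMAL"), recursive = TRUE)
  expect_error(load_manifest(broken), "PNEUMONIA")
  # empty files are skipped with a warning
  fx <- make_synth_fixture()
  bad <- file.path(fx$dir, "train", "NORMAL", "broken.png")
  file.create(bad)
  expect_warning(man <- load_manifest(fx$dir), "empty file")
  expect_false(bad %in% man$path)
})

test_that("preprocessing rescales 0-255 input, resizes, and is idempotent", {
  m255 <- matrix(c(0, 255, 128, 64), 2, 2)
  out <- preprocess(m255, preprocess_config(target_size = c(2L, 2L)))
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 1)
  expect_equal(out[1, 2], 128 / 255)
  big <- matrix(runif(100 * 80), 100, 80)
  small <- preprocess(big, preprocess_config(target_size = c(50L, 50L)))
  expect_equal(dim(small), c(50L, 50L))
  expect_true(all(small >= 0 & small <= 1))
  # idempotence on conformant input
  expect_equal(preprocess(small, preprocess_config(target_size = c(50L, 50L))),
               small, tolerance = 1e-12)
  # 3-channel input collapses to luminance
  rgb <- array(runif(10 * 10 * 3), c(10, 10, 3))
  g <- preprocess(rgb, preprocess_config(target_size = c(10L, 10L)))
  expect_equal(dim(g), c(10L, 10L))
  expect_error(preprocess(matrix(-3, 2, 2)), "outside")
  # the enhancement hook defaults to identity and is applied when given
  sq <- preprocess(g, preprocess_config(target_size = c(10L, 10L),
                                        enhance = function(m) m^2))
  expect_equal(sq, g^2, tolerance = 1e-12)
  expect_error(preprocess_config(enhance = 3), "function")
})

test_that("split sizes follow the round/floor/remainder formula", {
  expect_equal(split_counts(5856), c(train = 4392, val = 292, test = 1172))
  expect_equal(split_counts(0), c(train = 0, val = 0, test = 0))
  expect_equal(split_counts(100, c(1, 0, 0)),
               c(train = 100, val = 0, test = 0))
  expect_error(split_counts(10, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("split assignment partitions the records, stratified by class", {
  fx <- make_synth_fixture(counts = list(train = c(NORMAL = 20, PNEUMONIA = 30)))
  man <- split_dataset(fx$manifest, seed = 3L)
  expect_equal(sort(unique(man$split)), sort(c("train", "val", "test")))
  # splits partition the records exactly
  expect_equal(sum(table(man$split)), 50L)
  expect_false(any(is.na(man$split)))
  # per-class assignment follows the round/floor/remainder formula
  for (lbl in 0:1) {
    n_l <- sum(man$label == lbl)
    got <- as.integer(table(man$split[man$label == lbl])[c("train", "val", "test")])
    expect_equal(got, as.integer(split_counts(n_l)))
  }
  # no record in two splits, deterministic under seed
  man2 <- split_dataset(fx$manifest, seed = 3L)
  expect_identical(man$split, man2$split)
  expect_error(split_dataset(fx$manifest, fractions = c(0.9, 0.2, 0.1)),
               "sum to 1")
})

test_that("class weights and oversampling balance the classes", {
  fx <- make_synth_fixture(counts = list(train = c(NORMAL = 4, PNEUMONIA = 10)))
  w <- balance(fx$manifest)
  expect_equal(unname(w["PNEUMONIA"]), 14 / 20)
  expect_equal(unname(w["NORMAL"]), 14 / 8)
  over <- balance(fx$manifest, "oversample", seed = 5L)
  expect_equal(unname(manifest_counts(over)), c(10L, 10L))
  expect_true(all(over$path %in% fx$manifest$path))
  # balanced input gives unit weights
  fx2 <- make_synth_fixture(counts = list(train = c(NORMAL = 5, PNEUMONIA = 5)))
  expect_equal(unname(balance(fx2$manifest)), c(1, 1))
})

test_that("augmentation is seeded, clipped, and identity when disabled", {
  set.seed(51)
  img <- matrix(runif(30 * 30), 30, 30)
  off <- augment_config(hflip = FALSE, max_rotation = 0, max_shift = 0)
  expect_identical(augment(img, off, seed = 1), img)
  a1 <- augment(img, augment_config(), seed = 9)
  a2 <- augment(img, augment_config(), seed = 9)
  expect_identical(a1, a2)
  a3 <- augment(img, augment_config(), seed = 10)
  expect_false(identical(a1, a3))
  for (s in 1:5) {
    a <- augment(img, augment_config(), seed = s)
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(dim(a), dim(img))
  }
})

test_that("split loading yields encoded quaternion batches with labels", {
  fx <- make_synth_fixture()
  tr <- load_split(fx$manifest, "train")
  expect_equal(dim(tr$x), c(50L, 50L, 4L, 12L))
  expect_equal(sort(unique(tr$y)), c(0L, 1L))
  expect_error(load_split(fx$manifest, "nope"), "no records")
})
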