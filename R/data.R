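# Dataset handling: directory manifests in the two-level
# <root>/{train,val,test}/{NORMAL,PNEUMONIA} layout, preprocessing,
# stratified splitting, class balancing, augmentation, and a seeded
# synthetic generator of chest-X-ray-like images. The generator emulates the
# one visual cue that separates the classes in real pneumonia radiographs —
# bright localized opacities inside the lung fields — on top of a smooth
# dark background with two brighter elliptical "lung" regions and Gaussian
# sensor noise.

SPLITS <- c("train", "val", "test")
CLASSES <- c("NORMAL", "PNEUMONIA")

#' Synthetic dataset configuration
#'
#' Defaults give the package's standard desk-scale study set: 200 training,
#' 25 validation and 50 test images per class at 50 x 50 pixels, with 2-6
#' bright blobs of peak intensity 0.45 on pneumonia-like images and pixel
#' noise of sd 0.05. The seed fully determines every image; the two classes
#' differ only by the presence of the blobs.
#'
#' @param counts Named list with entries `train`, `val`, `test`, each a
#'   vector `c(NORMAL = , PNEUMONIA = )`. Overridden by `n_per_class`.
#' @param n_per_class Convenience: one count per class, all placed in the
#'   train split (scalar, or named `c(NORMAL = , PNEUMONIA = )`).
#' @param image_size Square image side in pixels.
#' @param blob_count_range Integer range of opacities per pneumonia image.
#' @param blob_intensity Peak added intensity of one opacity (image scale
#'   0-1); 0 makes the classes indistinguishable.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(counts = list(train = c(NORMAL = 200, PNEUMONIA = 200),
                                       val = c(NORMAL = 25, PNEUMONIA = 25),
                                       test = c(NORMAL = 50, PNEUMONIA = 50)),
                         n_per_class = NULL, image_size = 50L,
                         blob_count_range = c(2L, 6L), blob_intensity = 0.45,
                         noise_sd = 0.05, seed = 1L) {
  if (!is.null(n_per_class)) {
    if (is.null(names(n_per_class)))
      n_per_class <- c(NORMAL = n_per_class[[1]],
                       PNEUMONIA = n_per_class[[length(n_per_class)]])
    counts <- list(train = n_per_class)
  }
  structure(list(counts = counts, image_size = as.integer(image_size),
                 blob_count_range = as.integer(blob_count_range),
                 blob_intensity = blob_intensity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# one lung-field background image (values in [0, 1]) drawn from the current
# RNG stream; lungs are two soft-edged ellipses brighter than the field
synth_background <- function(n) {
  gx <- matrix(seq(0, 1, length.out = n), n, n)        # rows
  gy <- t(gx)                                          # cols
  img <- matrix(0.08, n, n)
  for (cx in c(0.30, 0.70)) {
    ecy <- 0.52 + runif(1, -0.03, 0.03)
    ecx <- cx + runif(1, -0.03, 0.03)
    ax <- 0.17 + runif(1, -0.02, 0.02)
    ay <- 0.30 + runif(1, -0.03, 0.03)
    d2 <- ((gy - ecx) / ax)^2 + ((gx - ecy) / ay)^2
    img <- img + 0.25 / (1 + exp((d2 - 1) * 8))
  }
  img
}

synth_image <- function(cfg, pneumonia) {
  n <- cfg$image_size
  img <- synth_background(n)
  lungmask <- img > 0.2
  if (pneumonia) {
    k <- sample(cfg$blob_count_range[1]:cfg$blob_count_range[2], 1L)
    inside <- which(lungmask, arr.ind = TRUE)
    centers <- inside[sample(nrow(inside), k, replace = TRUE), , drop = FALSE]
    rows <- matrix(seq_len(n), n, n)
    cols <- t(rows)
    for (b in seq_len(k)) {
      sg <- runif(1, 1.5, 3.5)
      amp <- cfg$blob_intensity * runif(1, 0.7, 1.3)
      img <- img + amp * exp(-((rows - centers[b, 1])^2 +
                               (cols - centers[b, 2])^2) / (2 * sg^2))
    }
  }
  img <- img + rnorm(n * n, sd = cfg$noise_sd)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic chest-X-ray-like dataset on disk
#'
#' Writes grayscale PNGs in the two-level directory convention
#' `<out_dir>/{train,val,test}/{NORMAL,PNEUMONIA}/`. NORMAL images are the
#' lung-field background plus noise; PNEUMONIA images additionally carry
#' bright Gaussian opacities inside the lung regions. Fully deterministic
#' under `cfg$seed` (same seed, byte-identical files).
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return The [load_manifest()] of the generated tree.
#' @export
generate_synthetic_dataset <- function(cfg = synth_config(), out_dir) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  for (split in names(cfg$counts)) {
    for (cls in CLASSES) {
      dir <- file.path(out_dir, split, cls)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      n_img <- cfg$counts[[split]][[cls]]
      for (i in seq_len(n_img)) {
        img <- synth_image(cfg, pneumonia = cls == "PNEUMONIA")
        png::writePNG(img, file.path(dir, sprintf("%s_%04d.png", tolower(cls), i)))
      }
    }
  }
  load_manifest(out_dir)
}

#' Build a dataset manifest from a directory tree
#'
#' Scans `<root>/{train,val,test}/{NORMAL,PNEUMONIA}/` (class-subdirectory
#' names matched case-insensitively; split directories are optional but at
#' least one must exist, and each present split must contain both class
#' subdirectories). Files are ordered lexicographically, so the manifest is
#' deterministic. Empty files are skipped with a warning.
#'
#' @param root_dir Dataset root directory.
#' @return A data frame of class `dataset_manifest` with columns `path`,
#'   `class` (NORMAL/PNEUMONIA), `label` (N = 0, P = 1) and `split`.
#' @export
load_manifest <- function(root_dir) {
  if (!dir.exists(root_dir)) stop("dataset root '", root_dir, "' does not exist")
  subdirs <- list.dirs(root_dir, recursive = FALSE, full.names = FALSE)
  splits <- subdirs[tolower(subdirs) %in% SPLITS]
  if (length(splits) == 0L)
    stop("no train/val/test directory found under '", root_dir, "'")
  recs <- list()
  for (split in splits) {
    cls_dirs <- list.dirs(file.path(root_dir, split), recursive = FALSE,
                          full.names = FALSE)
    for (cls in CLASSES) {
      hit <- cls_dirs[toupper(cls_dirs) == cls]
      if (length(hit) == 0L)
        stop("split '", split, "' is missing a ", cls, " subdirectory")
      files <- sort(list.files(file.path(root_dir, split, hit[1]),
                               pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                               full.names = TRUE))
      ok <- file.size(files) > 0
      if (any(!ok)) {
        warning("skipping ", sum(!ok), " empty file(s) in ",
                file.path(split, hit[1]))
        files <- files[ok]
      }
      if (length(files))
        recs[[paste(split, cls)]] <- data.frame(
          path = files, class = cls, label = as.integer(cls == "PNEUMONIA"),
          split = tolower(split), stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  if (is.null(man) || nrow(man) == 0L)
    stop("no images found under '", root_dir, "'")
  class(man) <- c("dataset_manifest", "data.frame")
  man
}

#' @rdname load_manifest
#' @param manifest A `dataset_manifest`.
#' @return `manifest_counts` returns the per-class record tallies
#'   `c(PNEUMONIA = , NORMAL = )`.
#' @export
manifest_counts <- function(manifest) {
  c(PNEUMONIA = sum(manifest$label == 1L), NORMAL = sum(manifest$label == 0L))
}

#' Preprocessing configuration
#'
#' @param target_size Output (H, W) in pixels; default 50 x 50.
#' @param rescale If `TRUE`, inputs on the 0-255 scale (max > 1) are divided
#'   by 255 so that pixel 255 maps to 1.0; inputs already in \[0, 1\] are
#'   left alone, making preprocessing idempotent.
#' @param interpolation `"bilinear"` or `"nearest"` resampling.
#' @param enhance Optional enhancement hook: a function mapping a \[0, 1\]
#'   matrix to a \[0, 1\] matrix, applied after rescaling and before
#'   resizing. `NULL` (the default) is the identity — the pipeline stage
#'   exists without committing to any particular enhancement algorithm.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = c(50L, 50L), rescale = TRUE,
                              interpolation = c("bilinear", "nearest"),
                              enhance = NULL) {
  interpolation <- match.arg(interpolation)
  if (any(target_size < 1L)) stop("target_size must be positive")
  if (!is.null(enhance) && !is.function(enhance))
    stop("enhance must be NULL or a function(image) -> image")
  structure(list(target_size = as.integer(target_size), rescale = rescale,
                 interpolation = interpolation, enhance = enhance),
            class = "preprocess_config")
}

#' Preprocess one image
#'
#' Converts to grayscale (Rec. 709 luminance) when given a 3-channel array,
#' rescales 0-255 inputs to \[0, 1\], and resizes to the target size.
#'
#' @param image A numeric matrix (H x W), array (H x W x 3), or a path to a
#'   PNG file.
#' @param cfg A [preprocess_config()].
#' @return Numeric matrix of dimension `target_size` with values in \[0, 1\].
#' @export
preprocess <- function(image, cfg = preprocess_config()) {
  if (is.character(image)) image <- read_image(image)
  if (length(dim(image)) == 3L) {
    if (dim(image)[3] >= 3L) image <- luminance(image)
    else image <- image[, , 1]
  }
  if (!is.matrix(image)) stop("cannot interpret input as an image")
  if (cfg$rescale && max(image) > 1) image <- image / 255
  if (min(image) < 0 || max(image) > 1)
    stop("image values outside [0, 1] after rescaling")
  if (!is.null(cfg$enhance)) {
    image <- cfg$enhance(image)
    if (min(image) < 0 || max(image) > 1)
      stop("enhancement hook produced values outside [0, 1]")
  }
  resize_bilinear(image, cfg$target_size[1], cfg$target_size[2],
                  nearest = cfg$interpolation == "nearest")
}

read_image <- function(path) {
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot read image '", path, "': ",
                                           conditionMessage(e)))
  img
}

# separable bilinear (or nearest) resampling with edge clamping
resize_bilinear <- function(m, ho, wo, nearest = FALSE) {
  h <- nrow(m); w <- ncol(m)
  if (h == ho && w == wo) return(m)
  sy <- (seq_len(ho) - 0.5) * h / ho + 0.5
  sx <- (seq_len(wo) - 0.5) * w / wo + 0.5
  if (nearest) {
    return(m[pmin(pmax(round(sy - 0.5) + 0L, 1L), h),
             pmin(pmax(round(sx - 0.5) + 0L, 1L), w), drop = FALSE])
  }
  y0 <- pmin(pmax(floor(sy - 1e-9), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(sx - 1e-9), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
       m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
       m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
       m[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

#' Split-size arithmetic
#'
#' Train/validation/test sizes for `n` records at the given fractions:
#' `train = round(f1 * n)`, `val = floor(f2 * n)`, `test` the remainder.
#'
#' @param n Number of records.
#' @param fractions Length-3 fractions summing to 1 (default 75/5/20).
#' @return Named integer vector `c(train, val, test)` summing to `n`.
#' @export
split_counts <- function(n, fractions = c(0.75, 0.05, 0.20)) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1")
  tr <- round(fractions[1] * n)
  va <- floor(fractions[2] * n)
  c(train = tr, val = va, test = n - tr - va)
}

#' Assign train/val/test splits to a manifest
#'
#' Shuffles deterministically under `seed` and assigns splits stratified by
#' class: the split-size formula of [split_counts()] is applied to each
#' class separately, so per-class counts follow the formula exactly while
#' the global totals can differ by a record from an unstratified partition
#' of the same fractions. No record lands in two splits.
#'
#' @param manifest A `dataset_manifest` (existing `split` values are
#'   overwritten).
#' @param fractions Train/val/test fractions summing to 1.
#' @param seed Integer seed.
#' @return The manifest with a new `split` column.
#' @export
split_dataset <- function(manifest, fractions = c(0.75, 0.05, 0.20), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1")
  if (nrow(manifest) == 0L) return(manifest)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  manifest$split <- NA_character_
  for (lbl in unique(manifest$label)) {
    idx <- sample(which(manifest$label == lbl))
    k <- split_counts(length(idx), fractions)
    manifest$split[idx] <- rep(SPLITS, times = k)
  }
  manifest
}

#' Class balancing
#'
#' `"class-weights"` returns the inverse-frequency weights
#' `w_l = N / (2 N_l)` (so that the weighted class masses are equal);
#' `"oversample"` duplicates minority-class records (drawn with replacement
#' under `seed`) until both classes have equal counts.
#'
#' @param manifest A `dataset_manifest` (typically the train split).
#' @param mode `"class-weights"` or `"oversample"`.
#' @param seed Seed for oversampling draws.
#' @return Named weights `c(PNEUMONIA = , NORMAL = )`, or the resampled
#'   manifest.
#' @export
balance <- function(manifest, mode = c("class-weights", "oversample"),
                    seed = 1L) {
  mode <- match.arg(mode)
  counts <- manifest_counts(manifest)
  if (any(counts == 0L))
    stop("cannot balance: class ", names(counts)[counts == 0L][1],
         " has zero records")
  if (mode == "class-weights") {
    n <- sum(counts)
    return(n / (2 * counts))
  }
  need <- max(counts) - counts
  extra <- list()
  for (cls in names(need)[need > 0L]) {
    rows <- which(manifest$class == cls)
    add <- with_seed(seed, sample(rows, need[[cls]], replace = TRUE))
    extra[[cls]] <- manifest[add, , drop = FALSE]
  }
  out <- do.call(rbind, c(list(manifest), extra, list(make.row.names = FALSE)))
  class(out) <- class(manifest)
  out
}

#' Augmentation configuration and seeded augmentation
#'
#' Random horizontal flip, rotation up to `max_rotation` degrees, and
#' translation up to `max_shift` of the image side, sampled under `seed`;
#' output values are re-clipped to \[0, 1\]. With everything disabled the
#' function is the identity.
#'
#' @param hflip Allow horizontal flips?
#' @param max_rotation Maximum absolute rotation in degrees.
#' @param max_shift Maximum absolute shift as a fraction of the image side.
#' @return `augment_config`: a config list. `augment`: the transformed
#'   image matrix.
#' @export
augment_config <- function(hflip = TRUE, max_rotation = 10, max_shift = 0.1) {
  structure(list(hflip = hflip, max_rotation = max_rotation,
                 max_shift = max_shift), class = "augment_config")
}

#' @rdname augment_config
#' @param image Numeric matrix in \[0, 1\].
#' @param cfg An `augment_config`.
#' @param seed Integer seed; the same seed gives the same transform.
#' @export
augment <- function(image, cfg = augment_config(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- image
  if (cfg$hflip && runif(1) < 0.5) out <- out[, rev(seq_len(ncol(out)))]
  ang <- if (cfg$max_rotation > 0)
    runif(1, -cfg$max_rotation, cfg$max_rotation) * pi / 180 else 0
  shift <- if (cfg$max_shift > 0)
    runif(2, -cfg$max_shift, cfg$max_shift) * dim(out) else c(0, 0)
  if (ang != 0 || any(shift != 0)) out <- warp_image(out, ang, shift)
  pmin(pmax(out, 0), 1)
}

# inverse-mapped rotation about the center plus translation, bilinear
# sampling with zero fill outside the source
warp_image <- function(m, angle, shift) {
  h <- nrow(m); w <- ncol(m)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gy <- matrix(seq_len(h), h, w) - cy
  gx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  ca <- cos(-angle); sa <- sin(-angle)
  sy <- ca * (gy - shift[1]) - sa * (gx - shift[2]) + cy
  sx <- sa * (gy - shift[1]) + ca * (gx - shift[2]) + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  val <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- numeric(length(yy))
    v[ok] <- m[cbind(yy[ok], xx[ok])]
    v
  }
  out <- val(y0, x0) * (1 - fy) * (1 - fx) + val(y0 + 1, x0) * fy * (1 - fx) +
    val(y0, x0 + 1) * (1 - fy) * fx + val(y0 + 1, x0 + 1) * fy * fx
  matrix(out, h, w)
}

#' Load and encode a manifest split as a quaternion feature map batch
#'
#' @param manifest A `dataset_manifest`.
#' @param split One of train/val/test.
#' @param cfg A [preprocess_config()].
#' @return List with `x` (a `qfmap` (H, W, 4, N)) and `y` (labels 0/1).
#' @export
load_split <- function(manifest, split, cfg = preprocess_config()) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("manifest has no records in split '", split, "'")
  imgs <- lapply(rows$path, preprocess, cfg = cfg)
  list(x = encode_batch(imgs), y = rows$label)
}
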