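#' Specification for a synthetic ultrasound-like dataset
#'
#' Describes a class-structured phantom dataset: per-class counts, image
#' geometry, speckle strength and lesion-geometry parameters. The three
#' classes emulate the salient/subtle contrast of breast-ultrasound
#' screening: `normal` images are speckled background only, `benign` lesions
#' are smooth hypoechoic (dark) ellipses, and `malignant` lesions are
#' ellipses perturbed by radial spicules with a faint posterior shadow.
#' Lesion brightness is identical for the two lesion classes, so the
#' presence of a lesion is an intensity cue (easy) while benign-vs-malignant
#' differs only in fine-scale margin shape (hard).
#'
#' @param n_normal,n_benign,n_malignant nonnegative class counts.
#' @param image_size pixels per side (square), at least 16. Default 64;
#'   larger sizes (e.g. 224) are supported.
#' @param speckle_strength positive scale of the multiplicative
#'   folded-normal speckle.
#' @param benign_axis_range relative semi-axis range of the benign ellipse,
#'   as a fraction of the image side.
#' @param spicule_count number of angular spikes on malignant margins.
#' @param spicule_amplitude relative radial amplitude of the spicules.
#' @param lesion_depth multiplicative darkening of lesion interiors in
#'   (0, 1); shared by both lesion classes.
#' @param shadow_strength attenuation of the posterior shadow band under
#'   malignant lesions (0 disables).
#' @param seed integer seed; generation is a pure function of (spec, seed).
#' @return object of class `fldpsim_dataset_spec`.
#' @seealso [generate_dataset()]
#' @export
dataset_spec <- function(n_normal, n_benign, n_malignant,
                         image_size = 64,
                         speckle_strength = 0.35,
                         benign_axis_range = c(0.10, 0.18),
                         spicule_count = 9,
                         spicule_amplitude = 0.40,
                         lesion_depth = 0.55,
                         shadow_strength = 0.12,
                         seed = 1L) {
  counts <- c(n_normal = n_normal, n_benign = n_benign,
              n_malignant = n_malignant)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      config_error(nm, "must be a single nonnegative integer")
    }
  }
  if (!is.numeric(image_size) || image_size < 16) {
    config_error("image_size", "must be at least 16 pixels")
  }
  if (!is.numeric(speckle_strength) || speckle_strength <= 0) {
    config_error("speckle_strength", "must be positive")
  }
  if (length(benign_axis_range) != 2 || any(benign_axis_range <= 0) ||
      benign_axis_range[1] > benign_axis_range[2]) {
    config_error("benign_axis_range", "must be an increasing positive pair")
  }
  structure(list(
    n_normal = as.integer(n_normal),
    n_benign = as.integer(n_benign),
    n_malignant = as.integer(n_malignant),
    image_size = as.integer(image_size),
    speckle_strength = speckle_strength,
    benign_axis_range = benign_axis_range,
    spicule_count = as.integer(spicule_count),
    spicule_amplitude = spicule_amplitude,
    lesion_depth = lesion_depth,
    shadow_strength = shadow_strength,
    seed = as.integer(seed)
  ), class = "fldpsim_dataset_spec")
}

CLASS_LEVELS <- c("normal", "benign", "malignant")

# One smooth background field: base level, mild vertical gain gradient and a
# few broad Gaussian bumps mimicking tissue texture at low frequency.
phantom_background <- function(n) {
  row_idx <- matrix(seq_len(n), n, n)
  col_idx <- matrix(seq_len(n), n, n, byrow = TRUE)
  bg <- 0.50 + 0.08 * (row_idx / n - 0.5)
  for (j in seq_len(3)) {
    cx <- stats::runif(1, 0.2 * n, 0.8 * n)
    cy <- stats::runif(1, 0.2 * n, 0.8 * n)
    s <- stats::runif(1, 0.25 * n, 0.45 * n)
    a <- stats::runif(1, -0.06, 0.06)
    bg <- bg + a * exp(-((row_idx - cy)^2 + (col_idx - cx)^2) / (2 * s^2))
  }
  bg
}

# Smooth lesion membership in [0,1] from an elliptical radial coordinate.
# `margin_fun(theta)` perturbs the unit boundary; `edge` sets margin softness.
lesion_mask <- function(n, center, axes, angle, edge, margin_fun = NULL) {
  row_idx <- matrix(seq_len(n), n, n)
  col_idx <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- row_idx - center[1]
  dx <- col_idx - center[2]
  u <- cos(angle) * dx + sin(angle) * dy
  v <- -sin(angle) * dx + cos(angle) * dy
  rho <- sqrt((u / axes[1])^2 + (v / axes[2])^2)
  boundary <- 1
  if (!is.null(margin_fun)) {
    theta <- atan2(v / axes[2], u / axes[1])
    boundary <- boundary + margin_fun(theta)
  }
  1 / (1 + exp((rho - boundary) / edge))
}

draw_phantom <- function(spec, label) {
  n <- spec$image_size
  img <- phantom_background(n)
  if (label != "normal") {
    center <- stats::runif(2, 0.32 * n, 0.68 * n)
    ax <- stats::runif(2, spec$benign_axis_range[1] * n,
                       spec$benign_axis_range[2] * n)
    angle <- stats::runif(1, 0, pi)
    if (label == "benign") {
      # smooth, well-circumscribed margin
      mask <- lesion_mask(n, center, ax, angle, edge = 0.08)
    } else {
      # spiculated margin: sum of random angular harmonics, sharp edge
      k <- sample(4:12, spec$spicule_count, replace = TRUE)
      ph <- stats::runif(spec$spicule_count, 0, 2 * pi)
      w <- abs(stats::rnorm(spec$spicule_count))
      w <- w / sum(w)
      amp <- spec$spicule_amplitude
      margin_fun <- function(theta) {
        m <- 0
        for (i in seq_along(k)) m <- m + w[i] * sin(k[i] * theta + ph[i])
        amp * m
      }
      mask <- lesion_mask(n, center, ax, angle, edge = 0.04,
                          margin_fun = margin_fun)
    }
    img <- img * (1 - spec$lesion_depth * mask)
    if (label == "malignant" && spec$shadow_strength > 0) {
      # faint posterior acoustic shadow under the lesion footprint
      col_profile <- apply(mask, 2, max)
      row_fade <- pmax(0, (seq_len(n) - center[1]) / n)
      shadow <- outer(row_fade, col_profile)
      img <- img * (1 - spec$shadow_strength * shadow)
    }
  }
  speckle <- abs(1 + spec$speckle_strength * stats::rnorm(n * n))
  img <- img * matrix(speckle, n, n)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic class-structured phantom dataset
#'
#' Produces exactly the requested number of samples per class. Generation is
#' a pure function of the spec (including its seed): each image draws from
#' an RNG stream derived from `(seed, label, index)`, so repeat calls are
#' bit-identical and independent of generation order.
#'
#' @param spec a [dataset_spec()].
#' @return list of image samples; each has `sample_id`, `pixels` (square
#'   matrix of intensities in `[0, 1]`), `label` and `split_tag` (`NA` until
#'   a split is applied).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "fldpsim_dataset_spec"))
  counts <- c(normal = spec$n_normal, benign = spec$n_benign,
              malignant = spec$n_malignant)
  samples <- vector("list", sum(counts))
  pos <- 0L
  for (label in CLASS_LEVELS) {
    for (i in seq_len(counts[[label]])) {
      pos <- pos + 1L
      px <- withr::with_seed(
        derive_seed(spec$seed, "img", label, i),
        draw_phantom(spec, label)
      )
      samples[[pos]] <- list(
        sample_id = sprintf("%s_%05d", label, i),
        pixels = px,
        label = label,
        split_tag = NA_character_
      )
    }
  }
  samples
}

#' Extract the label vector of a sample list
#' @param samples list of image samples.
#' @return character vector of labels.
#' @export
sample_labels <- function(samples) {
  vapply(samples, function(s) s$label, character(1))
}

#' Construct a classification task view over a three-class dataset
#'
#' `screen` merges benign and malignant into a single `abnormal` class
#' (normal vs abnormal); `diagnose` drops normal samples and keeps
#' benign vs malignant; `threeclass` is the identity relabeling.
#'
#' @param samples list of image samples carrying the original labels.
#' @param task one of `"screen"`, `"diagnose"`, `"threeclass"`.
#' @return a task view: `task`, `relabel_map`, `sample_ids`, `labels`
#'   (relabeled, in `class_levels` order) and `class_levels`.
#' @export
construct_task <- function(samples, task = c("screen", "diagnose", "threeclass")) {
  task <- match.arg(task)
  labels <- sample_labels(samples)
  stopifnot(all(labels %in% CLASS_LEVELS))
  map <- switch(task,
    screen = c(normal = "normal", benign = "abnormal", malignant = "abnormal"),
    diagnose = c(benign = "benign", malignant = "malignant"),
    threeclass = c(normal = "normal", benign = "benign", malignant = "malignant")
  )
  keep <- labels %in% names(map)
  new_labels <- unname(map[labels[keep]])
  class_levels <- unique(unname(map))
  missing <- setdiff(class_levels, unique(new_labels))
  if (length(missing) > 0) {
    stop(sprintf("untrainable task '%s': empty class '%s'",
                 task, missing[1]))
  }
  structure(list(
    task = task,
    relabel_map = map,
    sample_ids = vapply(samples[keep], function(s) s$sample_id, character(1)),
    labels = new_labels,
    class_levels = class_levels,
    index = which(keep)
  ), class = "fldpsim_task_view")
}

# ImageNet channel statistics used by the pretrained-backbone convention.
IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

# Separable Catmull-Rom (bicubic) resampling.
cubic_kernel <- function(t) {
  at <- abs(t)
  ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
         ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
}

resize_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  centers <- (seq_len(n_out) - 0.5) * scale - 0.5  # 0-based input coords
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    base <- floor(centers[i])
    taps <- base + (-1:2)
    wt <- cubic_kernel(centers[i] - taps)
    wt <- wt / sum(wt)
    taps <- pmin(pmax(taps, 0), n_in - 1) + 1  # clamp, back to 1-based
    for (j in seq_along(taps)) w[i, taps[j]] <- w[i, taps[j]] + wt[j]
  }
  w
}

#' Bicubic resize of a square intensity matrix
#' @param pixels numeric matrix.
#' @param target_size output side length.
#' @return resized matrix.
#' @export
resize_bicubic <- function(pixels, target_size) {
  if (nrow(pixels) == target_size && ncol(pixels) == target_size) {
    return(pixels)
  }
  wr <- resize_weights(nrow(pixels), target_size)
  wc <- resize_weights(ncol(pixels), target_size)
  wr %*% pixels %*% t(wc)
}

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Preprocess one image sample
#'
#' The chain mirrors a standard transfer-learning ultrasound pipeline:
#' bicubic resize to `target_size`, CLAHE contrast enhancement, Gaussian
#' noise reduction, then standardization with the fixed ImageNet channel
#' statistics. With `channels = "replicate"` (default) the grayscale image
#' is replicated across the three channels and standardized per channel,
#' yielding an `target_size x target_size x 3` array; with
#' `channels = "single"` the mean of the channel means/sds is used and the
#' output stays a matrix.
#'
#' @param sample an image sample.
#' @param target_size output side length (>= 16).
#' @param clahe_clip CLAHE clip limit.
#' @param kernel_size Gaussian kernel side (odd).
#' @param clahe_grid CLAHE tile grid (contextual regions per side).
#' @param sigma Gaussian kernel standard deviation in pixels.
#' @param channels `"replicate"` or `"single"`.
#' @return the sample with standardized `pixels` and an `audit` attribute
#'   recording mean/sd/min/max after every stage.
#' @export
preprocess <- function(sample, target_size = 224, clahe_clip = 2.0,
                       kernel_size = 3, clahe_grid = 8, sigma = 0.8,
                       channels = c("replicate", "single")) {
  channels <- match.arg(channels)
  if (target_size < 16) config_error("target_size", "must be at least 16")
  audit <- list()
  note <- function(stage, x) {
    if (!all(is.finite(x))) {
      stop(sprintf("preprocess: non-finite pixels after stage '%s'", stage))
    }
    audit[[length(audit) + 1]] <<- data.frame(
      stage = stage, mean = mean(x), sd = stats::sd(as.vector(x)),
      min = min(x), max = max(x))
  }
  x <- resize_bicubic(sample$pixels, target_size)
  x <- pmin(pmax(x, 0), 1)  # bicubic can overshoot; intensities stay in [0,1]
  note("resize", x)
  if (stats::sd(as.vector(x)) > 0) {
    img <- EBImage::clahe(EBImage::Image(x), nx = clahe_grid, ny = clahe_grid,
                          limit = clahe_clip)
    x <- pmin(pmax(EBImage::imageData(img), 0), 1)
  }
  note("clahe", x)
  k <- gaussian_kernel(kernel_size, sigma)
  x <- EBImage::imageData(
    EBImage::filter2(EBImage::Image(x), k, boundary = "replicate"))
  note("smooth", x)
  if (channels == "replicate") {
    out <- array(0, dim = c(target_size, target_size, 3))
    for (c3 in 1:3) out[, , c3] <- (x - IMAGENET_MEAN[c3]) / IMAGENET_SD[c3]
  } else {
    out <- (x - mean(IMAGENET_MEAN)) / mean(IMAGENET_SD)
  }
  note("standardize", out)
  sample$pixels <- out
  attr(sample, "audit") <- do.call(rbind, audit)
  sample
}

#' Split a dataset into train/validation/test at the image level
#'
#' The held-out test set is drawn first from the full sample set, so every
#' downstream configuration sharing the same seed evaluates on the identical
#' global test set; train and validation are then drawn from the remainder.
#' Set sizes follow a deterministic rounding rule: `n_test = round(f_test *
#' N)`, `n_val = round(f_val * N)`, train takes the remainder.
#'
#' @param samples list of image samples.
#' @param fractions numeric `(train, val, test)` fractions, positive,
#'   summing to 1 (tolerance 1e-9).
#' @param seed integer seed.
#' @return a split assignment: `fractions`, `tags` (named by sample id),
#'   `seed`.
#' @export
split_dataset <- function(samples, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0)) {
    config_error("fractions", "must be three positive numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    config_error("fractions", "must sum to 1")
  }
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  n <- length(ids)
  n_test <- round(fractions[3] * n)
  n_val <- round(fractions[2] * n)
  test_ids <- withr::with_seed(derive_seed(seed, "split", "test"),
                               sample(ids, n_test))
  rest <- setdiff(ids, test_ids)
  val_ids <- withr::with_seed(derive_seed(seed, "split", "val"),
                              sample(rest, n_val))
  tags <- stats::setNames(rep("train", n), ids)
  tags[test_ids] <- "test"
  tags[val_ids] <- "val"
  structure(list(fractions = fractions, tags = tags, seed = as.integer(seed)),
            class = "fldpsim_split")
}

#' Apply a split assignment to a sample list
#' @param samples list of image samples.
#' @param split a split assignment from [split_dataset()].
#' @return the samples with `split_tag` set.
#' @export
apply_split <- function(samples, split) {
  lapply(samples, function(s) {
    s$split_tag <- unname(split$tags[[s$sample_id]])
    s
  })
}

#' Persist a dataset as 8-bit grayscale PNGs with a CSV manifest
#' @param samples list of image samples (raw, in `[0, 1]`).
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    path <- file.path("images", paste0(s$sample_id, ".png"))
    png::writePNG(s$pixels, file.path(dir, path))
    data.frame(sample_id = s$sample_id, path = path, label = s$label,
               split_tag = s$split_tag)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write / read a dataset spec as YAML
#' @param spec a [dataset_spec()].
#' @param path YAML file path.
#' @export
write_dataset_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
}

#' @rdname write_dataset_spec
#' @export
read_dataset_spec <- function(path) {
  do.call(dataset_spec, yaml::read_yaml(path))
}
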