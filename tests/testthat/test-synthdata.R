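test_that("generate_dataset returns the exact requested class counts", {
  spec <- dataset_spec(10, 10, 10, image_size = 16, seed = 1)
  s <- generate_dataset(spec)
  expect_length(s, 30)
  expect_equal(unname(table(sample_labels(s))[c("normal", "benign", "malignant")]),
               rep(10L, 3), ignore_attr = TRUE)
  expect_length(generate_dataset(dataset_spec(0, 0, 0, image_size = 16)), 0)
})

test_that("generated intensities are finite, bounded and square", {
  s <- generate_dataset(dataset_spec(3, 3, 3, image_size = 24, seed = 2))
  for (x in s) {
    expect_true(all(is.finite(x$pixels)))
    expect_true(all(x$pixels >= 0 & x$pixels <= 1))
    expect_equal(dim(x$pixels), c(24, 24))
    expect_true(x$label %in% c("normal", "benign", "malignant"))
  }
})

test_that("generation is a pure function of spec and seed", {
  a <- generate_dataset(dataset_spec(4, 4, 4, image_size = 16, seed = 7))
  b <- generate_dataset(dataset_spec(4, 4, 4, image_size = 16, seed = 7))
  c <- generate_dataset(dataset_spec(4, 4, 4, image_size = 16, seed = 8))
  expect_identical(lapply(a, `[[`, "pixels"), lapply(b, `[[`, "pixels"))
  expect_false(identical(lapply(a, `[[`, "pixels"), lapply(c, `[[`, "pixels")))
})

test_that("invalid dataset specs name the offending field", {
  expect_error(dataset_spec(-1, 5, 5), "n_normal")
  expect_error(dataset_spec(5, 5, 5, image_size = 8), "image_size")
  expect_error(dataset_spec(5, 5, 5, speckle_strength = 0), "speckle_strength")
})

test_that("task views relabel and filter according to the task contract", {
  s <- stub_samples(5, 4, 3)
  screen <- construct_task(s, "screen")
  expect_length(screen$labels, 12)
  expect_equal(sum(screen$labels == "abnormal"), 7)
  expect_equal(sum(screen$labels == "normal"), 5)

  diag <- construct_task(s, "diagnose")
  expect_length(diag$labels, 7)
  expect_false("normal" %in% diag$labels)

  three <- construct_task(s, "threeclass")
  expect_equal(three$labels, sample_labels(s))
})

test_that("task construction reproduces the emulated cohort arithmetic", {
  s <- stub_samples(5283, 6847, 3717)
  screen <- construct_task(s, "screen")
  expect_length(screen$labels, 15847)
  expect_equal(sum(screen$labels == "abnormal"), 10564)
  diag <- construct_task(s, "diagnose")
  expect_length(diag$labels, 10564)
})

test_that("a task with an empty class is rejected as untrainable", {
  expect_error(construct_task(stub_samples(3, 0, 2), "diagnose"), "empty")
  expect_error(construct_task(stub_samples(0, 2, 2), "screen"), "empty")
})

test_that("preprocessing produces the contracted output shape and audit", {
  s <- generate_dataset(dataset_spec(1, 1, 1, image_size = 32, seed = 3))
  p <- preprocess(s[[2]], target_size = 24)
  expect_equal(dim(p$pixels), c(24, 24, 3))
  expect_true(all(is.finite(p$pixels)))
  expect_equal(attr(p, "audit")$stage,
               c("resize", "clahe", "smooth", "standardize"))
  p1 <- preprocess(s[[2]], target_size = 24, channels = "single")
  expect_equal(dim(p1$pixels), c(24, 24))
})

test_that("standardization identities hold on constant images", {
  s <- list(sample_id = "c", pixels = matrix(0.7, 20, 20), label = "normal",
            split_tag = NA_character_)
  p <- preprocess(s, target_size = 20, channels = "single")
  expect_equal(stats::sd(as.vector(p$pixels)), 0)
  # a constant image at the single-channel normalization mean maps to zero
  mu <- mean(c(0.485, 0.456, 0.406))
  s$pixels <- matrix(mu, 20, 20)
  p <- preprocess(s, target_size = 20, channels = "single")
  expect_equal(max(abs(p$pixels)), 0, tolerance = 1e-12)
})

test_that("bicubic resize is exact on constants and preserves size contract", {
  expect_equal(resize_bicubic(matrix(0.4, 30, 30), 17),
               matrix(0.4, 17, 17), tolerance = 1e-12)
  x <- matrix(runif(64^2), 64)
  expect_equal(dim(resize_bicubic(x, 224)), c(224, 224))
  expect_identical(resize_bicubic(x, 64), x)
})

test_that("splits are disjoint, exhaustive and deterministic", {
  s <- stub_samples(40, 30, 30)
  sp <- split_dataset(s, c(0.8, 0.1, 0.1), seed = 7)
  expect_equal(sum(sp$tags == "train"), 80)
  expect_equal(sum(sp$tags == "val"), 10)
  expect_equal(sum(sp$tags == "test"), 10)
  expect_setequal(names(sp$tags), vapply(s, `[[`, "", "sample_id"))
  sp2 <- split_dataset(s, c(0.8, 0.1, 0.1), seed = 7)
  expect_identical(sp$tags, sp2$tags)
})

test_that("split disjointness holds across random sizes (property)", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(3:300, 1)
      nn <- sample(0:n, 1); nb <- sample(0:(n - nn), 1)
      s <- stub_samples(nn, nb, n - nn - nb)
      sp <- split_dataset(s, seed = i)
      expect_length(sp$tags, n)
      expect_true(all(sp$tags %in% c("train", "val", "test")))
      # realized fractions within 1/N of request via the rounding rule
      expect_lte(abs(sum(sp$tags == "test") / n - 0.1), 1 / n + 1e-12)
    }
  })
})

test_that("the split rounding rule at the emulated cohort size", {
  s <- stub_samples(5283, 6847, 3717)
  sp <- split_dataset(s, seed = 1)
  expect_equal(sum(sp$tags == "test"), round(0.1 * 15847))  # 1585
  expect_equal(sum(sp$tags == "val"), 1585)
  expect_equal(sum(sp$tags == "train"), 15847 - 2 * 1585)
})

test_that("the shared test set depends only on the seed, not later fractions", {
  s <- stub_samples(50, 50, 50)
  t1 <- names(which(split_dataset(s, c(0.8, 0.1, 0.1), seed = 3)$tags == "test"))
  t2 <- names(which(split_dataset(s, c(0.7, 0.2, 0.1), seed = 3)$tags == "test"))
  expect_setequal(t1, t2)
})

test_that("bad split fractions are rejected", {
  s <- stub_samples(5, 5, 5)
  expect_error(split_dataset(s, c(0.8, 0.1, 0.2)), "sum to 1")
  expect_error(split_dataset(s, c(0.9, 0.1)), "three")
})

test_that("dataset round-trips through PNG + manifest and YAML spec", {
  dir <- withr::local_tempdir()
  spec <- dataset_spec(2, 1, 1, image_size = 16, seed = 4)
  s <- apply_split(generate_dataset(spec), split_dataset(generate_dataset(spec), seed = 1))
  man <- write_dataset(s, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 4)
  px <- png::readPNG(file.path(dir, man$path[1]))
  expect_equal(dim(px), c(16, 16))
  write_dataset_spec(spec, file.path(dir, "spec.yaml"))
  spec2 <- read_dataset_spec(file.path(dir, "spec.yaml"))
  expect_equal(spec2$n_normal, 2L)
  expect_identical(generate_dataset(spec2)[[1]]$pixels, s[[1]]$pixels)
})
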