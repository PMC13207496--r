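make_pop <- function(n_per_class, classes = c("a", "b")) {
  labels <- rep(classes, n_per_class)
  ids <- sprintf("x%04d", seq_along(labels))
  list(ids = ids, labels = stats::setNames(labels, ids))
}

manifest_partition_ok <- function(manifests, ids) {
  got <- unlist(lapply(manifests, `[[`, "sample_ids"))
  expect_equal(sort(got), sort(ids))
  expect_equal(sum(duplicated(got)), 0)
  for (m in manifests) expect_equal(m$n_k, length(m$sample_ids))
}

test_that("IID partitioning balances sizes and class mix", {
  pop <- make_pop(c(400, 400))
  m <- partition_iid(pop$ids, unname(pop$labels), K = 8, seed = 1)
  expect_equal(vapply(m, `[[`, 0L, "n_k"), rep(100L, 8))
  for (mk in m) {
    expect_equal(unname(table(pop$labels[mk$sample_ids])), c(50L, 50L),
                 ignore_attr = TRUE)
  }
  manifest_partition_ok(m, pop$ids)
})

test_that("IID degenerate cases: K = 1 and remainder balancing", {
  pop <- make_pop(10, classes = "a")
  expect_equal(partition_iid(pop$ids, unname(pop$labels), 1)[[1]]$n_k, 10L)
  sizes <- sort(vapply(partition_iid(pop$ids, unname(pop$labels), 3, seed = 2),
                       `[[`, 0L, "n_k"), decreasing = TRUE)
  expect_equal(sizes, c(4L, 3L, 3L))
  expect_error(partition_iid(pop$ids, unname(pop$labels), 11), "exceeds")
})

test_that("Dirichlet partitioning is a partition for random configs (property)", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- sample(50:300, 1)
      pop <- make_pop(c(n, n %/% 2, n %/% 3), c("a", "b", "c"))
      K <- sample(2:6, 1)
      alpha <- stats::runif(1, 0.2, 50)
      m <- partition_dirichlet(pop$ids, unname(pop$labels), K, alpha, seed = i)
      manifest_partition_ok(m, pop$ids)
    }
  })
})

test_that("huge concentration recovers the global class mix on every client", {
  pop <- make_pop(c(4000, 4000))
  m <- partition_dirichlet(pop$ids, unname(pop$labels), K = 8, alpha = 1e6,
                           seed = 3)
  for (mk in m) {
    frac <- mean(pop$labels[mk$sample_ids] == "a")
    expect_lt(abs(frac - 0.5), 0.02)
  }
  single <- partition_dirichlet(pop$ids, unname(pop$labels), 1, 0.5, seed = 1)
  expect_equal(single[[1]]$n_k, 8000L)
})

test_that("heterogeneity decreases with the concentration parameter", {
  pop <- make_pop(c(260, 340, 200), c("a", "b", "c"))
  p_global <- as.vector(table(factor(unname(pop$labels), c("a", "b", "c")))) / 800
  mean_tv <- function(alpha) {
    tv <- vapply(1:50, function(seed) {
      m <- partition_dirichlet(pop$ids, unname(pop$labels), 8, alpha, seed = seed)
      mean(vapply(m, function(mk) {
        p_k <- as.vector(table(factor(unname(pop$labels[mk$sample_ids]),
                                      c("a", "b", "c")))) / max(mk$n_k, 1)
        sum(abs(p_k - p_global)) / 2
      }, numeric(1)))
    }, numeric(1))
    mean(tv)
  }
  tvs <- vapply(c(0.5, 10, 100), mean_tv, numeric(1))
  expect_gt(tvs[1], tvs[2])
  expect_gt(tvs[2], tvs[3])
})

test_that("quantity skew conserves the total and respects the degenerate case", {
  pop <- make_pop(c(300, 300, 200), c("a", "b", "c"))
  m <- partition_dirichlet(pop$ids, unname(pop$labels), 8, 0.5, seed = 4)
  m0 <- apply_quantity_skew(m, pop$labels, 0, seed = 4)
  expect_equal(sum(vapply(m0, `[[`, 0L, "n_k")), 800L)
  expect_lte(max(abs(vapply(m0, `[[`, 0L, "n_k") -
                       vapply(m, `[[`, 0L, "n_k"))), 1L)
  withr::with_seed(31, {
    for (i in 1:5) {
      sdlog <- stats::runif(1, 0.1, 0.8)
      ms <- apply_quantity_skew(m, pop$labels, sdlog, seed = i)
      manifest_partition_ok(ms, pop$ids)
    }
  })
})

test_that("log-normal size targets spread client sizes (median ratio > 2)", {
  pop <- make_pop(c(300, 300, 200), c("a", "b", "c"))
  m <- partition_dirichlet(pop$ids, unname(pop$labels), 8, 0.5, seed = 4)
  ratios <- vapply(1:100, function(seed) {
    sizes <- vapply(apply_quantity_skew(m, pop$labels, 0.5, seed = seed),
                    `[[`, 0L, "n_k")
    max(sizes) / max(min(sizes), 1)
  }, numeric(1))
  expect_gt(stats::median(ratios), 2)
})

test_that("feature skew draws are bounded, deterministic and per-client", {
  m <- lapply(1:4, function(k) list(client_id = k, sample_ids = character(0),
                                    n_k = 0L, augmentation_spec = NULL))
  a <- assign_feature_skew(m, c(-0.2, 0.2), c(0.8, 1.2), c(-15, 15), seed = 9)
  b <- assign_feature_skew(m, c(-0.2, 0.2), c(0.8, 1.2), c(-15, 15), seed = 9)
  for (k in 1:4) {
    sp <- a[[k]]$augmentation_spec
    expect_gte(sp$brightness, -0.2); expect_lte(sp$brightness, 0.2)
    expect_gte(sp$contrast, 0.8); expect_lte(sp$contrast, 1.2)
    expect_gte(sp$rotation, -15); expect_lte(sp$rotation, 15)
    expect_identical(sp, b[[k]]$augmentation_spec)
  }
  ident <- assign_feature_skew(m, c(0, 0), c(1, 1), c(0, 0), seed = 1)
  px <- matrix(runif(64), 8)
  expect_equal(apply_augmentation(px, ident[[1]]$augmentation_spec), px)
})

test_that("partition summary arithmetic and fixture integrity", {
  one <- list(list(client_id = 1,
                   sample_ids = sprintf("s%d", 1:10), n_k = 10L,
                   augmentation_spec = NULL))
  labels <- stats::setNames(rep(c("a", "b", "c"), c(5, 3, 2)),
                            sprintf("s%d", 1:10))
  s <- summarize_partition(one, labels)
  expect_equal(s$pct_a[1], 50.0)
  expect_equal(s$pct_b[1], 30.0)
  expect_equal(s$pct_c[1], 20.0)

  fx <- fixture_client_table()
  sm <- summarize_partition(fx$manifests, fx$labels)
  cl <- sm[sm$client != "global", ]
  expect_equal(sum(cl$total), 15847)
  expect_equal(min(cl$total), 847)
  expect_equal(max(cl$total), 3247)
  # per-client percentages reproduce the printed table exactly
  expect_equal(cl$pct_normal, fx$counts$pct_normal)
  expect_equal(cl$pct_benign, fx$counts$pct_benign)
  expect_equal(cl$pct_malignant, fx$counts$pct_malignant)
  expect_equal(cl$total, fx$counts$total)
})

test_that("the composed non-IID pipeline yields a valid augmented partition", {
  pop <- make_pop(c(200, 260, 140), c("normal", "benign", "malignant"))
  cfg <- partition_config(K = 5, alpha = 0.5, quantity_log_sd = 0.3, seed = 2)
  m <- partition_clients(pop$ids, unname(pop$labels), cfg)
  manifest_partition_ok(m, pop$ids)
  expect_true(all(vapply(m, function(mk) !is.null(mk$augmentation_spec), TRUE)))
  dir <- withr::local_tempdir()
  write_manifests(m, dir)
  expect_true(file.exists(file.path(dir, "client_manifests.csv")))
  expect_true(file.exists(file.path(dir, "augmentation_specs.json")))
})
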