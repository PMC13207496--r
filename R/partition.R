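#' Client partitioning configuration
#'
#' @param mode `"iid"` or `"noniid"`.
#' @param K client count (>= 1).
#' @param alpha Dirichlet concentration for label skew (> 0); smaller
#'   values give more heterogeneous per-client class mixes.
#' @param quantity_log_sd log-normal shape parameter for quantity skew
#'   (0 disables).
#' @param brightness_range,contrast_range,rotation_range per-client feature
#'   skew draw ranges (additive delta, multiplicative factor, degrees).
#' @param allow_empty_clients permit clients with zero samples instead of
#'   re-drawing.
#' @param seed integer seed.
#' @return object of class `fldpsim_partition_config`.
#' @export
partition_config <- function(mode = c("noniid", "iid"), K = 8, alpha = 0.5,
                             quantity_log_sd = 0.3,
                             brightness_range = c(-0.1, 0.1),
                             contrast_range = c(0.9, 1.1),
                             rotation_range = c(-10, 10),
                             allow_empty_clients = FALSE,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (K < 1) config_error("K", "must be at least 1")
  if (alpha <= 0) config_error("alpha", "must be positive")
  if (quantity_log_sd < 0) config_error("quantity_log_sd", "must be nonnegative")
  for (nm in c("brightness_range", "contrast_range", "rotation_range")) {
    r <- get(nm)
    if (length(r) != 2 || r[1] > r[2]) config_error(nm, "must be lo <= hi")
  }
  structure(list(mode = mode, K = as.integer(K), alpha = alpha,
                 quantity_log_sd = quantity_log_sd,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 rotation_range = rotation_range,
                 allow_empty_clients = allow_empty_clients,
                 seed = as.integer(seed)),
            class = "fldpsim_partition_config")
}

new_manifest <- function(client_id, sample_ids) {
  list(client_id = client_id, sample_ids = sample_ids,
       n_k = length(sample_ids),
       augmentation_spec = list(brightness = 0, contrast = 1, rotation = 0))
}

#' IID partitioning: stratified round-robin
#'
#' Client sizes differ by at most one and each client's class proportions
#' match the global proportions as closely as integer rounding permits.
#'
#' @param sample_ids character vector of (training) sample ids.
#' @param labels matching label vector.
#' @param K number of clients.
#' @param seed integer seed.
#' @return list of client manifests.
#' @export
partition_iid <- function(sample_ids, labels, K, seed = 1L) {
  stopifnot(length(sample_ids) == length(labels))
  if (K > length(sample_ids)) {
    stop("K exceeds the number of training samples")
  }
  assign <- withr::with_seed(derive_seed(seed, "iid"), {
    out <- stats::setNames(integer(length(sample_ids)), sample_ids)
    # shuffle clients' class-wise round-robin start so no client is favored
    offset <- 0L
    for (lab in unique(labels)) {
      ids <- sample(sample_ids[labels == lab])
      out[ids] <- ((seq_along(ids) - 1L + offset) %% K) + 1L
      offset <- offset + length(ids)
    }
    out
  })
  lapply(seq_len(K), function(k) {
    new_manifest(k, names(assign)[assign == k])
  })
}

rdirichlet1 <- function(alpha_vec) {
  g <- stats::rgamma(length(alpha_vec), shape = alpha_vec, rate = 1)
  if (sum(g) == 0) g[which.max(alpha_vec)] <- 1
  g / sum(g)
}

#' Dirichlet label-skew partitioning
#'
#' Each client's class proportions are an independent draw from
#' `Dirichlet(alpha * p)` where `p` is the global class distribution.
#' Proportions are realized as integer quotas by largest-remainder rounding
#' against balanced per-client target sizes, then filled by sampling without
#' replacement from per-class pools (a depleted pool truncates the quota;
#' leftover samples go to the clients furthest below target).
#'
#' @inheritParams partition_iid
#' @param alpha Dirichlet concentration (> 0).
#' @param allow_empty permit empty clients; otherwise the draw is repeated
#'   (up to 100 attempts) until every client is nonempty.
#' @return list of client manifests.
#' @export
partition_dirichlet <- function(sample_ids, labels, K, alpha, seed = 1L,
                                allow_empty = FALSE) {
  stopifnot(length(sample_ids) == length(labels))
  if (alpha <= 0) config_error("alpha", "must be positive")
  n <- length(sample_ids)
  classes <- sort(unique(labels))
  p <- as.vector(table(factor(labels, classes))) / n
  target <- largest_remainder(rep(1, K), n)
  for (attempt in seq_len(100)) {
    draw_seed <- derive_seed(seed, "dirichlet", attempt)
    manifests <- withr::with_seed(draw_seed, {
      props <- t(vapply(seq_len(K), function(k) rdirichlet1(alpha * p),
                        numeric(length(classes))))
      if (length(classes) == 1) props <- matrix(1, K, 1)
      quota <- matrix(0L, K, length(classes))
      for (k in seq_len(K)) {
        quota[k, ] <- largest_remainder(props[k, ], target[k])
      }
      pools <- lapply(classes, function(cl) sample(sample_ids[labels == cl]))
      names(pools) <- classes
      out <- lapply(seq_len(K), function(k) character(0))
      for (ci in seq_along(classes)) {
        pool <- pools[[ci]]
        for (k in seq_len(K)) {
          take <- min(quota[k, ci], length(pool))  # depleted pool truncates
          if (take > 0) {
            out[[k]] <- c(out[[k]], pool[seq_len(take)])
            pool <- pool[-seq_len(take)]
          }
        }
        pools[[ci]] <- pool
      }
      # every sample assigned exactly once: leftovers to most-short clients
      leftover <- unlist(pools, use.names = FALSE)
      for (id in leftover) {
        short <- target - vapply(out, length, integer(1))
        k <- which.max(short)
        out[[k]] <- c(out[[k]], id)
      }
      lapply(seq_len(K), function(k) new_manifest(k, out[[k]]))
    })
    sizes <- vapply(manifests, function(m) m$n_k, integer(1))
    if (allow_empty || all(sizes > 0) || K > n) {
      return(manifests)
    }
  }
  stop("partition_dirichlet: could not produce nonempty clients in 100 attempts")
}

#' Apply log-normal quantity skew to client manifests
#'
#' Target client sizes are drawn log-normally and rescaled to conserve the
#' training-set total (the largest client absorbs the rounding residue);
#' samples are then re-allocated from per-class pools so that each client
#' keeps its prior class proportions as closely as integer quotas permit.
#'
#' @param manifests list of client manifests.
#' @param labels named label vector covering all manifest sample ids.
#' @param quantity_log_sd log-normal shape (0 leaves sizes unchanged up to
#'   rounding).
#' @param seed integer seed.
#' @return re-allocated list of client manifests.
#' @export
apply_quantity_skew <- function(manifests, labels, quantity_log_sd, seed = 1L) {
  K <- length(manifests)
  total <- sum(vapply(manifests, function(m) m$n_k, integer(1)))
  for (attempt in seq_len(100)) {
    draws <- withr::with_seed(derive_seed(seed, "qskew", attempt),
                              stats::rlnorm(K, meanlog = 0,
                                            sdlog = quantity_log_sd))
    target <- largest_remainder(draws, total)
    resid <- total - sum(target)  # zero by construction of largest_remainder
    target[which.max(target)] <- target[which.max(target)] + resid
    if (all(target >= 1)) break
    if (attempt == 100) stop("apply_quantity_skew: client target below 1 after 100 attempts")
  }
  classes <- sort(unique(unname(labels)))
  # per-client class proportions before re-targeting
  props <- t(vapply(manifests, function(m) {
    tab <- table(factor(unname(labels[m$sample_ids]), classes))
    if (m$n_k == 0) rep(1 / length(classes), length(classes))
    else as.vector(tab) / m$n_k
  }, numeric(length(classes))))
  pool_sizes <- as.vector(table(factor(unname(labels), classes)))
  # integer quota matrix: per class, allocate the class pool across clients
  # in proportion to target_k * prop_kc (largest remainder per class), so
  # column sums match the pools exactly and the grand total is conserved.
  quota <- matrix(0L, K, length(classes))
  for (ci in seq_along(classes)) {
    w <- target * props[, ci]
    if (sum(w) == 0) w <- target
    quota[, ci] <- largest_remainder(w, pool_sizes[ci])
  }
  withr::with_seed(derive_seed(seed, "qskew-fill"), {
    pools <- lapply(classes, function(cl) {
      ids <- unlist(lapply(manifests, function(m) m$sample_ids))
      sample(ids[unname(labels[ids]) == cl])
    })
    out <- vector("list", K)
    for (k in seq_len(K)) {
      ids <- character(0)
      for (ci in seq_along(classes)) {
        take <- quota[k, ci]
        if (take > 0) {
          ids <- c(ids, pools[[ci]][seq_len(take)])
          pools[[ci]] <- pools[[ci]][-seq_len(take)]
        }
      }
      out[[k]] <- new_manifest(manifests[[k]]$client_id, ids)
      out[[k]]$augmentation_spec <- manifests[[k]]$augmentation_spec
    }
    out
  })
}

#' Assign per-client feature-skew augmentation specs
#'
#' Each client receives one fixed draw of (brightness delta, contrast
#' factor, rotation degrees), a pure function of `(client_id, seed)`,
#' applied lazily to all its samples at load time so stored pixels remain
#' canonical.
#'
#' @param manifests list of client manifests.
#' @param brightness_range,contrast_range,rotation_range draw ranges
#'   (`lo <= hi`).
#' @param seed integer seed.
#' @return manifests with `augmentation_spec` populated.
#' @export
assign_feature_skew <- function(manifests,
                                brightness_range = c(-0.1, 0.1),
                                contrast_range = c(0.9, 1.1),
                                rotation_range = c(-10, 10),
                                seed = 1L) {
  for (nm in c("brightness_range", "contrast_range", "rotation_range")) {
    r <- get(nm)
    if (length(r) != 2 || r[1] > r[2]) config_error(nm, "must be lo <= hi")
  }
  lapply(manifests, function(m) {
    m$augmentation_spec <- withr::with_seed(
      derive_seed(seed, "fskew", m$client_id),
      list(brightness = stats::runif(1, brightness_range[1], brightness_range[2]),
           contrast = stats::runif(1, contrast_range[1], contrast_range[2]),
           rotation = stats::runif(1, rotation_range[1], rotation_range[2]))
    )
    m
  })
}

#' Apply a client's augmentation spec to an image matrix
#'
#' Load-time feature skew: contrast scaling about mid-gray, additive
#' brightness, then rotation about the image center (bilinear, replicate
#' border), clipped back to `[0, 1]`.
#'
#' @param pixels intensity matrix in `[0, 1]`.
#' @param spec an `augmentation_spec` from a client manifest.
#' @return transformed matrix.
#' @export
apply_augmentation <- function(pixels, spec) {
  x <- (pixels - 0.5) * spec$contrast + 0.5 + spec$brightness
  if (abs(spec$rotation) > 1e-12) {
    x <- EBImage::imageData(EBImage::rotate(
      EBImage::Image(x), spec$rotation,
      output.dim = dim(pixels), bg.col = mean(x)))
  }
  pmin(pmax(x, 0), 1)
}

#' Summarize a client partition (sizes and class percentages)
#'
#' @param manifests list of client manifests.
#' @param labels named label vector covering all manifest sample ids.
#' @return data frame with one row per client plus a `global` row: total
#'   sample count and per-class percentages (one decimal).
#' @export
summarize_partition <- function(manifests, labels) {
  classes <- sort(unique(unname(labels)))
  rows <- lapply(manifests, function(m) {
    tab <- table(factor(unname(labels[m$sample_ids]), classes))
    pct <- if (m$n_k > 0) round(100 * as.vector(tab) / m$n_k, 1) else rep(NA_real_, length(classes))
    df <- data.frame(client = as.character(m$client_id), total = m$n_k)
    df[paste0("pct_", classes)] <- as.list(pct)
    df
  })
  out <- do.call(rbind, rows)
  all_ids <- unlist(lapply(manifests, function(m) m$sample_ids))
  tab <- table(factor(unname(labels[all_ids]), classes))
  gdf <- data.frame(client = "global", total = length(all_ids))
  gdf[paste0("pct_", classes)] <- as.list(round(100 * as.vector(tab) / length(all_ids), 1))
  rbind(out, gdf)
}

#' Partition a training split under a partition configuration
#'
#' Runs the configured pipeline: IID stratified round-robin, or Dirichlet
#' label skew followed by log-normal quantity re-targeting and per-client
#' feature-skew assignment (label skew first, then size re-targeting).
#'
#' @param sample_ids training sample ids.
#' @param labels matching label vector.
#' @param config a [partition_config()].
#' @return list of client manifests.
#' @export
partition_clients <- function(sample_ids, labels, config) {
  stopifnot(inherits(config, "fldpsim_partition_config"))
  names(labels) <- sample_ids
  if (config$mode == "iid") {
    return(partition_iid(sample_ids, labels, config$K, config$seed))
  }
  m <- partition_dirichlet(sample_ids, labels, config$K, config$alpha,
                           config$seed, config$allow_empty_clients)
  if (config$quantity_log_sd > 0) {
    m <- apply_quantity_skew(m, labels, config$quantity_log_sd, config$seed)
  }
  assign_feature_skew(m, config$brightness_range, config$contrast_range,
                      config$rotation_range, config$seed)
}

#' Write client manifests as CSV plus a JSON augmentation sidecar
#' @param manifests list of client manifests.
#' @param dir output directory.
#' @export
write_manifests <- function(manifests, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- do.call(rbind, lapply(manifests, function(m) {
    data.frame(client_id = m$client_id, sample_id = m$sample_ids)
  }))
  utils::write.csv(df, file.path(dir, "client_manifests.csv"), row.names = FALSE)
  aug <- lapply(manifests, function(m) m$augmentation_spec)
  names(aug) <- vapply(manifests, function(m) as.character(m$client_id), character(1))
  jsonlite::write_json(aug, file.path(dir, "augmentation_specs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(df)
}

#' Load the packaged client-manifest fixture
#'
#' A transcription of the study's non-IID client table (eight clients,
#' Dirichlet label skew with log-normal quantity skew): per-client integer
#' class counts obtained from the published totals and one-decimal class
#' percentages by largest-remainder rounding, which reproduces every
#' printed percentage exactly. This is one unreported-seed realization and
#' is shipped as a static fixture rather than re-derived.
#'
#' @return list with `manifests` (synthetic ids) and `labels` (named
#'   vector), plus the raw `counts` data frame.
#' @export
fixture_client_table <- function() {
  path <- system.file("extdata", "client_table_fixture.csv",
                      package = "fldpsim")
  counts <- utils::read.csv(path)
  labels <- character(0)
  manifests <- vector("list", nrow(counts))
  for (k in seq_len(nrow(counts))) {
    ids <- c(
      sprintf("c%d_normal_%04d", k, seq_len(counts$n_normal[k])),
      sprintf("c%d_benign_%04d", k, seq_len(counts$n_benign[k])),
      sprintf("c%d_malignant_%04d", k, seq_len(counts$n_malignant[k]))
    )
    lab <- rep(c("normal", "benign", "malignant"),
               c(counts$n_normal[k], counts$n_benign[k], counts$n_malignant[k]))
    labels <- c(labels, stats::setNames(lab, ids))
    manifests[[k]] <- new_manifest(counts$client[k], ids)
  }
  list(manifests = manifests, labels = labels, counts = counts)
}
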