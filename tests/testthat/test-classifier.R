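toy_cnn_config <- function(...) {
  args <- utils::modifyList(
    list(backbone = "smallcnn", n_classes = 2L, feature_dim = 8L,
         conv_filters = c(4L, 8L), conv_kernel = c(3L, 3L),
         conv_stride = c(2L, 2L), epochs = 5L, batch_size = 8L,
         augment = FALSE, seed = 1L), list(...))
  do.call(model_config, args)
}

toy_split <- function(meta, n_val = 2) {
  cmp <- unique(meta$compound_id)
  part <- rep("train", length(cmp))
  part[seq_len(n_val)] <- "val"
  manual_split(cmp, meta$moa[match(cmp, meta$compound_id)], part)
}

test_that("a single batch can be memorized to training accuracy 1", {
  ds <- toy_image_dataset(seed = 2, n_per_class = 6, H = 12, shift = 1)
  sp <- toy_split(ds$meta)
  cfg <- toy_cnn_config(epochs = 60, batch_size = 12, lr = 5e-3, patience = 60)
  m <- train_classifier(ds, sp, 1, cfg)
  part <- partition_of(ds$meta, sp, 1)
  train_idx <- which(part == "train")
  p <- predict(m, subset_image_dataset(ds, train_idx))
  expect_equal(mean(p$pred == p$truth), 1)
})

test_that("predictions live on the probability simplex and are order-invariant", {
  ds <- toy_image_dataset(seed = 3)
  sp <- toy_split(ds$meta)
  m <- train_classifier(ds, sp, 1, toy_cnn_config())
  p <- predict(m, ds)
  probs <- as.matrix(p[, grep("^prob_", names(p))])
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(p)), tolerance = 1e-12)
  # argmax label equals the maximal-probability class for every record
  expect_equal(p$pred,
               sub("^prob_", "", colnames(probs)[max.col(probs, "first")]))
  # permuting the dataset permutes the records identically
  ord <- rev(seq_len(ncol(ds$x)))
  p2 <- predict(m, subset_image_dataset(ds, ord))
  expect_equal(p2$well, p$well[ord])
  expect_equal(as.matrix(p2[, grep("^prob_", names(p2))]),
               probs[ord, ], tolerance = 1e-12)
})

test_that("embeddings are deterministic, sized, and usable by a linear probe", {
  ds <- toy_image_dataset(seed = 4, n_per_class = 10, shift = 2)
  sp <- toy_split(ds$meta)
  m <- train_classifier(ds, sp, 1,
                        toy_cnn_config(feature_dim = 6L, epochs = 30L,
                                       lr = 5e-3, patience = 30L))
  emb <- extract_features(m, ds)
  fc <- grep("^f[0-9]+$", names(emb), value = TRUE)
  expect_length(fc, 6)
  # identical inputs give identical embeddings
  dup <- subset_image_dataset(ds, c(1, 1))
  e2 <- extract_features(m, dup)
  expect_equal(as.numeric(e2[1, fc]), as.numeric(e2[2, fc]))
  # linear probe on embeddings separates the separable classes
  z <- as.matrix(emb[, fc])
  fit <- suppressWarnings(
    stats::glm(factor(emb$moa) ~ z, family = stats::binomial()))
  acc <- mean((stats::fitted(fit) > 0.5) == (emb$moa == "B"))
  expect_gte(acc, 0.9)
})

test_that("channel mismatch and empty partitions raise errors", {
  ds <- toy_image_dataset(seed = 5)
  sp <- toy_split(ds$meta)
  m <- train_classifier(ds, sp, 1, toy_cnn_config())
  wrong <- toy_image_dataset(seed = 5, H = 12, C = 3)
  expect_error(predict(m, wrong), "do not match")
  no_val <- manual_split(unique(ds$meta$compound_id),
                         ds$meta$moa[!duplicated(ds$meta$compound_id)],
                         rep("train", 12))
  expect_error(train_classifier(ds, no_val, 1, toy_cnn_config()),
               "empty validation")
})

test_that("training refuses a split that leaks test compounds into training", {
  ds <- toy_image_dataset(seed = 6)
  cmp <- unique(ds$meta$compound_id)
  leaky <- manual_split(c(cmp, cmp[3]),
                        c(ds$meta$moa[match(cmp, ds$meta$compound_id)], "A"),
                        c(rep(c("train", "val", "test"), 4), "train"))
  expect_error(train_classifier(ds, leaky, 1, toy_cnn_config()), "leakage")
})

test_that("training is reproducible for a fixed seed", {
  ds <- toy_image_dataset(seed = 7)
  sp <- toy_split(ds$meta)
  m1 <- train_classifier(ds, sp, 1, toy_cnn_config(seed = 5L))
  m2 <- train_classifier(ds, sp, 1, toy_cnn_config(seed = 5L))
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$log, m2$log)
})

mlp_features <- function(seed, sep = 6, n_cmp = 12, sites = 10, d = 10,
                         permute = FALSE) {
  withr::with_seed(seed, {
    moas <- rep(c("A", "B", "C"), length.out = n_cmp)
    centers <- matrix(rnorm(3 * d), 3, d, dimnames = list(c("A", "B", "C")))
    centers <- centers / sqrt(rowSums(centers^2)) * sep
    rows <- lapply(seq_len(n_cmp), function(i) {
      x <- matrix(rnorm(sites * d), sites, d) + matrix(centers[moas[i], ],
                                                       sites, d, byrow = TRUE)
      colnames(x) <- paste0("f", seq_len(d))
      dplyr::bind_cols(tibble::tibble(plate_id = "P01",
                                      well = sprintf("W%02d_%s", i, seq_len(sites)),
                                      compound_id = sprintf("C%02d", i),
                                      moa = moas[i]),
                       tibble::as_tibble(x))
    })
    out <- dplyr::bind_rows(rows)
    if (permute) out$moa <- sample(out$moa)
    out
  })
}

mlp_split <- function(features) {
  cmp <- unique(features$compound_id)
  moa <- features$moa[match(cmp, features$compound_id)]
  manual_split(cmp, moa, rep(c("train", "train", "val", "test"),
                             length.out = length(cmp)))
}

test_that("the feature network separates Gaussian classes and not noise", {
  feats <- mlp_features(seed = 30)
  sp <- mlp_split(feats)
  cfg <- model_config(backbone = "mlp", n_classes = 3L, hidden_units = 32L,
                      epochs = 40L, batch_size = 16L, lr = 5e-3,
                      patience = 40L, seed = 2L)
  m <- train_feature_mlp(feats, sp, 1, cfg)
  part <- partition_of(feats, sp, 1)
  test_idx <- which(part == "test")
  f1 <- macro_f1(predict(m, feats[test_idx, ]))
  expect_gte(f1, 0.95)

  perm <- mlp_features(seed = 30, permute = TRUE)
  m0 <- train_feature_mlp(perm, sp, 1, cfg)
  part0 <- partition_of(perm, sp, 1)
  f10 <- macro_f1(predict(m0, perm[part0 == "test", ]))
  expect_lt(f10, 0.6) # chance-like: no class structure to transfer
})

test_that("a linearly separable toy problem is fitted perfectly", {
  # four distinct points, each duplicated as a validation compound, so the
  # checkpoint with perfect validation F1 has necessarily fitted all points
  pts <- rbind(c(1, 1), c(1, 2), c(5, 5), c(5, 6))
  x <- rbind(pts, pts)
  colnames(x) <- c("f1", "f2")
  moa <- rep(rep(c("A", "B"), each = 2), 2)
  feats <- dplyr::bind_cols(
    tibble::tibble(plate_id = "P01", well = sprintf("A%02d", 1:8),
                   compound_id = paste0("C", 1:8), moa = moa),
    tibble::as_tibble(x))
  sp <- manual_split(paste0("C", 1:8), moa,
                     rep(c("train", "val"), each = 4))
  cfg <- model_config(backbone = "mlp", n_classes = 2L, hidden_units = 8L,
                      epochs = 200L, batch_size = 4L, lr = 1e-2,
                      patience = 200L, seed = 3L)
  m <- train_feature_mlp(feats, sp, 1, cfg)
  p <- predict(m, feats)
  expect_equal(p$pred, p$truth)
})
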