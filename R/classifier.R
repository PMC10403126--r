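#' Model configuration for the image CNN and the feature-table MLP
#'
#' The image backbone is a small configurable convolutional network
#' (3 stages of strided valid convolutions with ReLU, global average pooling,
#' then a fully connected feature layer whose post-activation output is the
#' "penultimate-layer" embedding, and a softmax output over the 11 classes).
#' The feature-table benchmark is a fully connected network with one hidden
#' layer (default 512 units) followed by ReLU and batch normalization.
#' Larger backbones for full-resolution data can be expressed through
#' `conv_filters`/`conv_kernel`/`conv_stride` without code changes.
#'
#' @param backbone `"smallcnn"` for images, `"mlp"` for feature tables
#' @param n_classes number of output classes (10 MoAs + DMSO = 11)
#' @param feature_dim width of the penultimate embedding layer (CNN)
#' @param hidden_units hidden width of the feature MLP
#' @param conv_filters,conv_kernel,conv_stride per-stage CNN shape vectors
#' @param lr Adam learning rate
#' @param epochs maximum training epochs
#' @param batch_size minibatch size
#' @param patience early-stopping patience (epochs without validation
#'   macro-F1 improvement)
#' @param augment apply random horizontal/vertical flips to training images
#'   (ignored by the MLP backbone)
#' @param seed integer seed for initialization and batch shuffling
#' @return a `model_config` list
#' @export
model_config <- function(backbone = c("smallcnn", "mlp"),
                         n_classes = 11L,
                         feature_dim = 64L,
                         hidden_units = 512L,
                         conv_filters = c(16L, 32L, 64L),
                         conv_kernel = c(5L, 5L, 3L),
                         conv_stride = c(2L, 2L, 2L),
                         lr = 2e-3,
                         epochs = 20L,
                         batch_size = 32L,
                         patience = 6L,
                         augment = TRUE,
                         seed = 1L) {
  backbone <- match.arg(backbone)
  stopifnot(n_classes >= 2, feature_dim >= 1, hidden_units >= 1,
            length(conv_filters) == length(conv_kernel),
            length(conv_kernel) == length(conv_stride),
            epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(backbone = backbone, n_classes = as.integer(n_classes),
                 feature_dim = as.integer(feature_dim),
                 hidden_units = as.integer(hidden_units),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 conv_stride = as.integer(conv_stride),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "model_config")
}

# fixed class vocabulary: MoA classes alphabetically, control class last
moa_levels <- function(moa) {
  lv <- setdiff(sort(unique(moa)), "DMSO")
  if ("DMSO" %in% moa) c(lv, "DMSO") else lv
}

build_layers <- function(config, input_dim) {
  if (config$backbone == "smallcnn") {
    stopifnot(length(input_dim) == 3)
    layers <- list()
    dim_cur <- input_dim
    for (s in seq_along(config$conv_filters)) {
      cv <- layer_conv(dim_cur, config$conv_filters[s],
                       config$conv_kernel[s], config$conv_stride[s])
      layers <- c(layers, list(cv, layer_relu()))
      dim_cur <- cv$out_dim
    }
    layers <- c(layers, list(layer_gap(dim_cur),
                             layer_dense(dim_cur[3], config$feature_dim),
                             layer_relu(),
                             layer_dense(config$feature_dim, config$n_classes)))
    feature_layer <- length(layers) - 1L # post-ReLU embedding
  } else {
    stopifnot(length(input_dim) == 1)
    layers <- list(layer_dense(input_dim, config$hidden_units),
                   layer_relu(),
                   layer_batchnorm(config$hidden_units),
                   layer_dense(config$hidden_units, config$n_classes))
    feature_layer <- 3L # batch-norm output is the penultimate representation
  }
  list(layers = layers, feature_layer = feature_layer)
}

# Shared training loop: X is D x n, y integer classes, idx_train/idx_val
# index columns. Checkpoint = epoch with best validation macro-F1.
nn_fit <- function(X, y, idx_train, idx_val, config, input_dim, classes) {
  if (!length(idx_train)) stop("empty training partition")
  if (!length(idx_val)) stop("empty validation partition")
  # index permutations implementing horizontal/vertical image flips
  flips <- NULL
  if (config$augment && length(input_dim) == 3) {
    a <- array(seq_len(prod(input_dim)), input_dim)
    flips <- list(seq_len(prod(input_dim)),
                  as.vector(a[rev(seq_len(input_dim[1])), , , drop = FALSE]),
                  as.vector(a[, rev(seq_len(input_dim[2])), , drop = FALSE]),
                  as.vector(a[rev(seq_len(input_dim[1])),
                              rev(seq_len(input_dim[2])), , drop = FALSE]))
  }
  with_seed(config$seed, {
    arch <- build_layers(config, input_dim)
    layers <- arch$layers
    state <- adam_init(layers)
    t <- 0L
    best <- list(f1 = -Inf, layers = layers, epoch = 0L)
    log <- vector("list", config$epochs)
    stale <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(idx_train)
      losses <- c()
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        Xb <- X[, b, drop = FALSE]
        if (!is.null(flips)) {
          v <- sample.int(4, length(b), replace = TRUE)
          for (f in 2:4) {
            sel <- v == f
            if (any(sel)) Xb[, sel] <- Xb[flips[[f]], sel, drop = FALSE]
          }
        }
        stepr <- nn_train_step(layers, Xb, y[b])
        t <- t + 1L
        upd <- adam_step(stepr$layers, stepr$grads, state, t, config$lr)
        layers <- upd$layers
        state <- upd$state
        losses <- c(losses, stepr$loss)
      }
      val_pred <- max.col(t(nn_forward(layers,
                                       X[, idx_val, drop = FALSE])$out),
                          ties.method = "first")
      vf1 <- macro_f1(tibble::tibble(truth = classes[y[idx_val]],
                                     pred = classes[val_pred]))
      log[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                  val_macro_f1 = vf1)
      if (vf1 > best$f1) {
        best <- list(f1 = vf1, layers = layers, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
    list(layers = best$layers, best_epoch = best$epoch,
         log = dplyr::bind_rows(log))
  })
}

#' Train the multi-channel image classifier
#'
#' Trains the configured CNN backbone on the training partition of one split
#' and selects the checkpoint with the best validation macro-F1. The split is
#' audited for compound leakage before training. Deterministic for a fixed
#' `config$seed`.
#'
#' @param dataset an `image_dataset` from [build_image_dataset()]
#' @param splits a [make_splits()] `split_set`
#' @param split split index to train on
#' @param config a [model_config()] with backbone `"smallcnn"`
#' @return a `moa_model`: trained layers, class vocabulary, training log,
#'   best epoch, and everything needed for [predict()] /
#'   [extract_features()]
#' @export
train_classifier <- function(dataset, splits, split = 1L,
                             config = model_config()) {
  stopifnot(inherits(dataset, "image_dataset"), inherits(config, "model_config"),
            config$backbone == "smallcnn")
  audit_split(dataset$meta, splits, split)
  part <- partition_of(dataset$meta, splits, split)
  classes <- moa_levels(dataset$meta$moa)
  if (length(classes) != config$n_classes)
    stop(sprintf("dataset has %d classes but model is configured for %d",
                 length(classes), config$n_classes))
  y <- match(dataset$meta$moa, classes)
  fit <- nn_fit(dataset$x, y,
                which(!is.na(part) & part == "train"),
                which(!is.na(part) & part == "val"),
                config, dataset$dims, classes)
  structure(list(layers = fit$layers, classes = classes, config = config,
                 input = "image", dims = dataset$dims,
                 modality = dataset$modality,
                 normalization = dataset$normalization,
                 feature_layer = build_layers(config, dataset$dims)$feature_layer,
                 best_epoch = fit$best_epoch, log = fit$log,
                 split = as.integer(split),
                 train_compounds = sort(unique(
                   dataset$meta$compound_id[!is.na(part) & part == "train"]))),
            class = "moa_model")
}

#' Train the feature-table benchmark network
#'
#' Fully connected classifier (one hidden layer, ReLU, batch normalization)
#' on per-site feature vectors, mirroring the benchmark applied to
#' segmentation-derived feature sets. Expects features already normalized at
#' the plate level against DMSO (see [normalize_features_dmso()]).
#'
#' @param features feature table (site rows with `f*` columns and metadata)
#' @param splits a `split_set`
#' @param split split index
#' @param config a [model_config()] with backbone `"mlp"`
#' @return a `moa_model`
#' @export
train_feature_mlp <- function(features, splits, split = 1L,
                              config = model_config(backbone = "mlp")) {
  stopifnot(inherits(config, "model_config"), config$backbone == "mlp")
  assert_cols(features, c("plate_id", "well", "compound_id", "moa"))
  audit_split(features, splits, split)
  part <- partition_of(features, splits, split)
  classes <- moa_levels(features$moa)
  if (length(classes) != config$n_classes)
    stop(sprintf("feature table has %d classes but model is configured for %d",
                 length(classes), config$n_classes))
  y <- match(features$moa, classes)
  X <- t(feature_matrix(features))
  fit <- nn_fit(X, y,
                which(!is.na(part) & part == "train"),
                which(!is.na(part) & part == "val"),
                config, nrow(X), classes)
  structure(list(layers = fit$layers, classes = classes, config = config,
                 input = "feature", dims = nrow(X),
                 feature_layer = build_layers(config, nrow(X))$feature_layer,
                 best_epoch = fit$best_epoch, log = fit$log,
                 split = as.integer(split),
                 train_compounds = sort(unique(
                   features$compound_id[!is.na(part) & part == "train"]))),
            class = "moa_model")
}

#' @export
print.moa_model <- function(x, ...) {
  cat(sprintf("<moa_model %s: %d classes, best epoch %d (val macro-F1 %.3f)>\n",
              x$config$backbone, length(x$classes), x$best_epoch,
              max(x$log$val_macro_f1)))
  invisible(x)
}

model_input_matrix <- function(object, newdata) {
  if (object$input == "image") {
    stopifnot(inherits(newdata, "image_dataset"))
    if (!identical(newdata$dims, object$dims))
      stop(sprintf("image dims/channels %s do not match the model's %s",
                   paste(newdata$dims, collapse = "x"),
                   paste(object$dims, collapse = "x")))
    list(X = newdata$x, meta = newdata$meta)
  } else {
    assert_cols(newdata, c("plate_id", "well", "compound_id", "moa"))
    X <- t(feature_matrix(newdata))
    if (nrow(X) != object$dims)
      stop(sprintf("feature dimension %d does not match the model's %d",
                   nrow(X), object$dims))
    list(X = X, meta = newdata)
  }
}

#' Predict MoA class probabilities for sites
#'
#' @param object a trained `moa_model`
#' @param newdata an `image_dataset` (CNN) or feature table (MLP)
#' @param ... unused
#' @return tibble of prediction records: site identity columns, one
#'   `prob_<class>` column per class (rows sum to 1), `pred` (argmax class)
#'   and `truth`
#' @export
predict.moa_model <- function(object, newdata, ...) {
  inp <- model_input_matrix(object, newdata)
  P <- softmax_probs(nn_forward(object$layers, inp$X)$out)
  pred <- object$classes[max.col(t(P), ties.method = "first")]
  probs <- t(P)
  colnames(probs) <- paste0("prob_", object$classes)
  meta_cols <- intersect(c("plate_id", "well", "site", "compound_id", "moa"),
                         names(inp$meta))
  out <- dplyr::bind_cols(inp$meta[, meta_cols, drop = FALSE],
                          tibble::as_tibble(probs))
  out$truth <- inp$meta$moa
  out$pred <- pred
  out
}

#' Extract penultimate-layer embeddings
#'
#' Runs the model in inference mode up to its embedding layer (the
#' post-activation fully connected layer for the CNN; the batch-normalized
#' hidden layer for the MLP) and returns one feature vector per site.
#'
#' @param model a trained `moa_model`
#' @param newdata an `image_dataset` or feature table
#' @return tibble: site identity columns plus embedding columns `f1..fK`
#'   (`K = feature_dim` for the CNN, `hidden_units` for the MLP)
#' @export
extract_features <- function(model, newdata) {
  stopifnot(inherits(model, "moa_model"))
  inp <- model_input_matrix(model, newdata)
  E <- nn_forward(model$layers, inp$X, upto = model$feature_layer)$out
  emb <- t(E)
  colnames(emb) <- paste0("f", seq_len(ncol(emb)))
  meta_cols <- intersect(c("plate_id", "well", "site", "compound_id", "moa"),
                         names(inp$meta))
  dplyr::bind_cols(inp$meta[, meta_cols, drop = FALSE], tibble::as_tibble(emb))
}

#' Plate-level DMSO normalization of a feature table
#'
#' Standardizes every feature by the mean and standard deviation of the DMSO
#' site rows of the same plate, the feature-space analogue of DMSO plate
#' normalization of images.
#'
#' @param features site-level feature table with `plate_id`, `compound_id`
#'   and `f*` columns
#' @return the table with features replaced by their normalized values
#' @export
normalize_features_dmso <- function(features) {
  assert_cols(features, c("plate_id", "compound_id"))
  fc <- feature_cols(features)
  if (!length(fc)) stop("no feature columns found")
  out <- features
  for (p in unique(features$plate_id)) {
    on_plate <- features$plate_id == p
    ctrl <- on_plate & features$compound_id == "DMSO"
    if (!any(ctrl)) stop(sprintf("plate %s has no DMSO rows", p))
    m <- as.matrix(features[ctrl, fc, drop = FALSE])
    mu <- colMeans(m)
    s <- apply(m, 2, sd)
    if (any(!is.finite(s)) || any(s < 1e-12))
      stop(sprintf("plate %s has a zero-variance DMSO feature", p))
    out[on_plate, fc] <- sweep(sweep(as.matrix(features[on_plate, fc,
                                                        drop = FALSE]),
                                     2, mu), 2, s, "/")
  }
  out
}
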