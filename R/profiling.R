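#' Aggregate site-level features to well-level profiles
#'
#' Arithmetic mean of every feature over the sites of each well.
#'
#' @param features site-level table with `plate_id`, `well` keys, metadata
#'   and `f*` feature columns
#' @return tibble of well profiles (one row per well), metadata preserved
#' @export
aggregate_sites_to_wells <- function(features) {
  assert_cols(features, c("plate_id", "well"))
  fc <- feature_cols(features)
  if (!length(fc)) stop("no feature columns found")
  keys <- intersect(c("plate_id", "well", "compound_id", "moa"),
                    names(features))
  dplyr::summarise(dplyr::group_by(features,
                                   dplyr::across(dplyr::all_of(keys))),
                   dplyr::across(dplyr::all_of(fc), mean), .groups = "drop")
}

#' Grit score: replicate strength relative to controls
#'
#' For each profile \eqn{i} of a perturbation group (default grouping:
#' compound), let \eqn{R_i} be its Pearson correlations to the other
#' replicate profiles of the same group and \eqn{C_i} its correlations to
#' the control profiles. The grit score is the mean z-transformed replicate
#' correlation,
#' \deqn{grit_i = \frac{1}{|R_i|} \sum_{r \in R_i} \frac{r - \bar C_i}{sd(C_i)},}
#' i.e. how far above its control-correlation background a profile's
#' replicate agreement sits. High grit means a strong, reproducible
#' phenotype. With `control_stats = "pooled"` the normalizing mean/sd are
#' taken from the control-vs-control correlation distribution, shared by all
#' profiles, instead of each profile's own control correlations.
#'
#' @param profiles well profiles with metadata and `f*` columns
#' @param group_key metadata column defining replicate groups
#' @param control_label value of `group_key` marking control profiles
#' @param control_stats `"per_profile"` (default) or `"pooled"`
#' @return tibble: profile identity, `grit`, and a `reason` column that is
#'   `NA` for scored profiles and explains missing scores (singleton group,
#'   zero control-correlation spread) otherwise
#' @export
grit <- function(profiles, group_key = "compound_id", control_label = "DMSO",
                 control_stats = c("per_profile", "pooled")) {
  control_stats <- match.arg(control_stats)
  assert_cols(profiles, group_key)
  x <- feature_matrix(profiles)
  groups <- profiles[[group_key]]
  is_ctrl <- groups == control_label
  if (sum(is_ctrl) < 2) stop("need at least two control profiles")
  cc <- cor(t(x)) # profile-by-profile Pearson correlations
  ctrl_idx <- which(is_ctrl)
  if (control_stats == "pooled") {
    pool <- cc[ctrl_idx, ctrl_idx][upper.tri(diag(length(ctrl_idx)))]
    pool_mu <- mean(pool)
    pool_sd <- sd(pool)
  }
  n <- nrow(x)
  score <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in which(!is_ctrl)) {
    reps <- setdiff(which(groups == groups[i]), i)
    if (!length(reps)) { reason[i] <- "singleton group"; next }
    if (control_stats == "per_profile") {
      ci <- cc[i, ctrl_idx]
      mu <- mean(ci); s <- sd(ci)
    } else {
      mu <- pool_mu; s <- pool_sd
    }
    if (!is.finite(s) || s == 0) {
      reason[i] <- "zero control correlation spread"
      next
    }
    score[i] <- mean((cc[i, reps] - mu) / s)
  }
  keys <- intersect(c("plate_id", "well", "compound_id", "moa"),
                    names(profiles))
  out <- profiles[, keys, drop = FALSE]
  out$grit <- score
  out$reason <- reason
  out[!is_ctrl, , drop = FALSE]
}

#' Accuracy binned by grit score
#'
#' Sorts samples by grit, cuts them into `n_bins` contiguous equal-count
#' bins (any remainder goes to the lowest bins) and reports each bin's mean
#' grit and classification accuracy -- the accuracy-versus-phenotype-strength
#' curve.
#'
#' @param grit numeric grit score per sample
#' @param correct logical, whether the sample was classified correctly
#' @param n_bins number of bins
#' @return tibble: `bin`, `n`, `mean_grit`, `accuracy`
#' @export
bin_accuracy_by_grit <- function(grit, correct, n_bins = 10) {
  stopifnot(length(grit) == length(correct))
  keep <- is.finite(grit)
  grit <- grit[keep]; correct <- as.logical(correct[keep])
  n <- length(grit)
  if (n < n_bins)
    stop(sprintf("%d samples cannot fill %d bins", n, n_bins))
  ord <- order(grit)
  base <- n %/% n_bins
  rem <- n - base * n_bins
  sizes <- rep(base, n_bins)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin_of <- rep(seq_len(n_bins), times = sizes)
  mean_grit <- as.numeric(tapply(grit[ord], bin_of, mean))
  accuracy <- as.numeric(tapply(correct[ord], bin_of, mean))
  tibble::tibble(bin = seq_len(n_bins), n = sizes,
                 mean_grit = mean_grit, accuracy = accuracy)
}

#' Fit a regularized sphering (whitening) transform on control profiles
#'
#' ZCA whitening with a trace-scaled ridge: with control mean \eqn{\mu_c}
#' and covariance \eqn{\Sigma_c},
#' \deqn{W = (\Sigma_c + \lambda \tfrac{tr \Sigma_c}{d} I)^{-1/2}}
#' via symmetric eigendecomposition, and profiles transform as
#' \eqn{x' = W (x - \mu_c)}. Small \eqn{\lambda} drives the control
#' distribution towards white noise; large \eqn{\lambda} degenerates to
#' centering plus uniform scaling.
#'
#' @param controls matrix (or `f*` table) of control profiles, one per row
#' @param lambda regularization parameter, > 0
#' @return a `sphering_transform`: `center`, `W` (symmetric positive
#'   definite), `lambda`
#' @export
fit_sphering <- function(controls, lambda = 0.1) {
  if (is.data.frame(controls)) controls <- feature_matrix(controls)
  controls <- as.matrix(controls)
  if (nrow(controls) < 2) stop("need at least two control profiles")
  if (!all(is.finite(controls))) stop("control profiles contain non-finite values")
  if (lambda <= 0) stop("`lambda` must be > 0")
  mu <- colMeans(controls)
  S <- cov(controls)
  d <- ncol(controls)
  ridge <- lambda * sum(diag(S)) / d
  eg <- eigen(S + ridge * diag(d), symmetric = TRUE)
  W <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  W <- (W + t(W)) / 2
  structure(list(center = mu, W = W, lambda = lambda),
            class = "sphering_transform")
}

#' Apply a sphering transform
#'
#' @param object a `sphering_transform` from [fit_sphering()]
#' @param newdata profile matrix or `f*` table
#' @param ... unused
#' @return object of the same kind as `newdata` with transformed features
#' @export
predict.sphering_transform <- function(object, newdata, ...) {
  is_df <- is.data.frame(newdata)
  x <- if (is_df) feature_matrix(newdata) else as.matrix(newdata)
  if (ncol(x) != length(object$center))
    stop("feature dimension does not match the fitted transform")
  z <- sweep(x, 2, object$center) %*% object$W
  if (is_df) {
    newdata[, feature_cols(newdata)] <- z
    newdata
  } else z
}

#' @export
print.sphering_transform <- function(x, ...) {
  cat(sprintf("<sphering_transform: d = %d, lambda = %g>\n",
              length(x$center), x$lambda))
  invisible(x)
}

#' Mean average precision of label retrieval by cosine similarity
#'
#' For every reference well, all other wells are ranked by cosine similarity
#' (descending; ties broken by stable well-identifier order) and a ranked
#' well counts as a hit when its label matches the reference's. Average
#' precision is the mean of precision-at-hit over all hit positions,
#' evaluated until every same-label well has been retrieved; mAP is the mean
#' AP over wells. Control wells and labels represented by a single well are
#' excluded (with a warning for the latter).
#'
#' @param profiles well profiles with `f*` columns
#' @param label_col metadata column holding the matching label (e.g. MoA)
#' @param exclude values of `label_col` to drop before matching (controls)
#' @return list: `map` (scalar), `ap` (per-well tibble)
#' @export
mean_average_precision <- function(profiles, label_col = "moa",
                                   exclude = "DMSO") {
  assert_cols(profiles, c("plate_id", "well", label_col))
  profiles <- profiles[!(profiles[[label_col]] %in% exclude), , drop = FALSE]
  labels <- profiles[[label_col]]
  tab <- table(labels)
  single <- names(tab)[tab < 2]
  if (length(single)) {
    warning(sprintf("label(s) with a single well excluded from matching: %s",
                    paste(single, collapse = ", ")))
    keep <- !(labels %in% single)
    profiles <- profiles[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (nrow(profiles) < 2) stop("need at least two wells after exclusions")
  sim <- cosine_matrix(feature_matrix(profiles))
  uid <- well_uid(profiles$plate_id, profiles$well)
  n <- nrow(profiles)
  ap <- numeric(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-sim[i, others], uid[others])]
    hits <- labels[ord] == labels[i]
    ranks <- which(hits)
    ap[i] <- mean(cumsum(hits)[ranks] / ranks)
  }
  per_well <- tibble::tibble(plate_id = profiles$plate_id,
                             well = profiles$well, label = labels, ap = ap)
  list(map = mean(ap), ap = per_well)
}

#' Cosine similarity within and across classes
#'
#' All pairwise cosine similarities between sample vectors, partitioned into
#' same-class and different-class pairs, with the difference of the two means
#' as a separation summary.
#'
#' @param x matrix of vectors (rows) or `f*` table
#' @param labels class label per row
#' @return list: `within`, `across` (numeric vectors of similarities),
#'   `separation` (mean within minus mean across)
#' @export
cosine_within_across <- function(x, labels) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  stopifnot(nrow(x) == length(labels))
  if (any(table(labels) < 2)) stop("every class needs at least two samples")
  sim <- cosine_matrix(x)
  same <- outer(labels, labels, "==")
  ut <- upper.tri(sim)
  list(within = sim[ut & same], across = sim[ut & !same],
       separation = mean(sim[ut & same]) - mean(sim[ut & !same]))
}

#' Plate-to-plate correlation of control features
#'
#' Averages the control feature vectors of each plate (optionally first
#' within each split, then across splits) and returns the Pearson
#' correlation matrix between the plate mean vectors. In the absence of
#' batch effects all off-diagonal entries should be uniformly high; spread
#' or structure in this matrix is a plate-effect signature.
#'
#' @param features control feature rows with `plate_id`, optional `split`,
#'   and `f*` columns
#' @return plate x plate correlation matrix (diagonal 1); entries for plates
#'   with constant feature vectors are `NA` and flagged via attribute
#'   `"degenerate_plates"`
#' @export
plate_correlation_matrix <- function(features) {
  assert_cols(features, "plate_id")
  fc <- feature_cols(features)
  if (!length(fc)) stop("no feature columns found")
  keys <- c("plate_id", intersect("split", names(features)))
  means <- dplyr::summarise(dplyr::group_by(features,
                                            dplyr::across(dplyr::all_of(keys))),
                            dplyr::across(dplyr::all_of(fc), mean),
                            .groups = "drop")
  means <- dplyr::summarise(dplyr::group_by(means, .data$plate_id),
                            dplyr::across(dplyr::all_of(fc), mean),
                            .groups = "drop")
  m <- as.matrix(means[, fc, drop = FALSE])
  rownames(m) <- means$plate_id
  const <- apply(m, 1, sd) == 0
  cm <- suppressWarnings(cor(t(m)))
  diag(cm) <- 1
  if (any(const)) {
    cm[const, ] <- NA_real_
    cm[, const] <- NA_real_
    diag(cm) <- ifelse(const, NA_real_, 1)
    warning(sprintf("plate(s) with constant control features: %s",
                    paste(rownames(m)[const], collapse = ", ")))
  }
  attr(cm, "degenerate_plates") <- rownames(m)[const]
  cm
}
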