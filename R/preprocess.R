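#' Gaussian background correction for brightfield images
#'
#' Brightfield illumination is typically inhomogeneous across the field of
#' view. Each z-plane is smoothed with a large separable Gaussian filter to
#' estimate the slowly varying background, which is then subtracted.
#' Fluorescence images bypass this correction. The kernel is parameterized as
#' a fraction of the image side so resolution changes do not alter the
#' physical scale of the filter; the default fraction corresponds to a
#' 101-pixel kernel on a 2160-pixel image. The Gaussian sd is kernel_side/4
#' and boundaries are handled by reflection, so a constant plane maps to an
#' exactly zero plane.
#'
#' @param image a `site_image` with modality `"BF"`
#' @param kernel_frac kernel side as a fraction of the image side, in (0, 1)
#' @return background-corrected `site_image` (per-plane mean approximately 0)
#' @export
correct_background <- function(image, kernel_frac = 101 / 2160) {
  stopifnot(inherits(image, "site_image"))
  if (!identical(attr(image, "modality"), "BF"))
    stop("background correction applies to BF images only; FL bypasses it")
  if (!(kernel_frac > 0 && kernel_frac < 1))
    stop("`kernel_frac` must be in (0, 1)")
  d <- dim(image)
  side <- round(kernel_frac * d[1])
  side <- max(3L, side + (side %% 2 == 0)) # odd, >= 3
  if (side > d[1] || side > d[2])
    stop(sprintf("Gaussian kernel (%d px) larger than image (%d px)",
                 side, min(d[1:2])))
  Sx <- gaussian_smoother(d[1], side)
  Sy <- gaussian_smoother(d[2], side)
  out <- unclass(image)
  for (ch in seq_len(d[3])) {
    plane <- out[, , ch]
    out[, , ch] <- plane - Sx %*% plane %*% t(Sy)
  }
  rewrap_site_image(out, image)
}

# n x n row-stochastic smoothing operator: 1D Gaussian of side `side`
# (sd = side/4) with reflected boundary indices
gaussian_smoother <- function(n, side) {
  r <- (side - 1L) %/% 2L
  k <- exp(-((-r:r)^2) / (2 * (side / 4)^2))
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + (-r:r)
    j <- ifelse(j < 1L, 1L - j, j)       # reflect at the top edge
    j <- ifelse(j > n, 2L * n + 1L - j, j) # reflect at the bottom edge
    for (t in seq_along(j)) S[i, j[t]] <- S[i, j[t]] + k[t]
  }
  S
}

#' Pooled per-channel DMSO pixel statistics of one plate
#'
#' Mean and standard deviation of the pixel intensities over all DMSO control
#' sites of a plate, computed per channel by pooling every pixel of every
#' DMSO site. Brightfield images are expected to be background-corrected
#' before the statistics are taken.
#'
#' @param images list of `site_image`s: the DMSO sites of one plate
#' @return tibble (class `plate_channel_stats`): `plate_id`, `channel`,
#'   `mean`, `sd`, `n_pixels`
#' @export
compute_dmso_stats <- function(images) {
  if (!length(images)) stop("plate has zero DMSO sites")
  stopifnot(all(vapply(images, inherits, logical(1), "site_image")))
  plates <- unique(vapply(images, attr, character(1), "plate_id"))
  if (length(plates) != 1)
    stop("all DMSO images must come from a single plate")
  nc <- dim(images[[1]])[3]
  # pool all pixels of all sites, per channel
  sums <- numeric(nc); sqs <- numeric(nc); npx <- 0
  for (img in images) {
    if (dim(img)[3] != nc) stop("channel count differs between DMSO sites")
    m <- matrix(unclass(img), ncol = nc)
    sums <- sums + colSums(m)
    sqs <- sqs + colSums(m^2)
    npx <- npx + nrow(m)
  }
  mu <- sums / npx
  # pooled sample sd over the concatenated pixel list (n - 1 denominator)
  s2 <- (sqs - npx * mu^2) / (npx - 1)
  s <- sqrt(pmax(s2, 0))
  if (any(s < 1e-8))
    stop(sprintf("degenerate plate %s: DMSO channel %d has zero pixel sd",
                 plates, which(s < 1e-8)[1]))
  out <- tibble::tibble(plate_id = plates, channel = seq_len(nc),
                        mean = mu, sd = s, n_pixels = npx)
  class(out) <- c("plate_channel_stats", class(out))
  out
}

#' DMSO plate-level normalization
#'
#' Standardizes each channel by the plate's pooled DMSO pixel statistics:
#' \eqn{x' = (x - \mu)/\sigma}. This mitigates plate-level effects while
#' preserving each treatment's intensity relative to the plate's controls.
#'
#' @param image a `site_image`
#' @param stats [compute_dmso_stats()] output for the image's plate
#' @return normalized `site_image`
#' @export
normalize_dmso_plate <- function(image, stats) {
  stopifnot(inherits(image, "site_image"),
            inherits(stats, "plate_channel_stats"))
  if (!identical(attr(image, "plate_id"), stats$plate_id[1]))
    stop(sprintf("plate mismatch: image is from %s, stats from %s",
                 attr(image, "plate_id"), stats$plate_id[1]))
  d <- dim(image)
  if (d[3] != nrow(stats)) stop("channel count does not match stats")
  out <- unclass(image)
  for (ch in seq_len(d[3]))
    out[, , ch] <- (out[, , ch] - stats$mean[ch]) / stats$sd[ch]
  rewrap_site_image(out, image)
}

#' Site-level normalization
#'
#' Standardizes each channel of an image by that image's own per-channel
#' pixel mean and standard deviation. This removes any per-channel affine
#' transform (gains, offsets) entirely -- and with it all relative intensity
#' information between treatments.
#'
#' @param image a `site_image`
#' @return normalized `site_image` (per channel: mean 0, sd 1)
#' @export
normalize_site <- function(image) {
  stopifnot(inherits(image, "site_image"))
  d <- dim(image)
  out <- unclass(image)
  for (ch in seq_len(d[3])) {
    plane <- out[, , ch]
    s <- sd(plane)
    if (!is.finite(s) || s < 1e-8)
      stop(sprintf("channel %d is constant; site normalization undefined", ch))
    out[, , ch] <- (plane - mean(plane)) / s
  }
  rewrap_site_image(out, image)
}

#' Render and preprocess every site of a screen into a model-ready dataset
#'
#' Convenience wrapper that renders all sites of a plate map, applies
#' background correction (BF only) and one of the two normalization
#' strategies, and flattens the images into a feature-major matrix.
#'
#' @param map plate map from [generate_layout()]
#' @param config the [screen_config()]
#' @param modality `"BF"` or `"FL"`
#' @param normalization `"dmso"` (plate-level DMSO statistics) or `"site"`
#' @param kernel_frac background-correction kernel fraction (BF only)
#' @return an `image_dataset`: list with `x` (matrix, pixels x images),
#'   `meta` (site record tibble), `dims`, `modality`, `normalization`
#' @export
build_image_dataset <- function(map, config, modality = c("BF", "FL"),
                                normalization = c("dmso", "site"),
                                kernel_frac = 101 / 2160) {
  modality <- match.arg(modality)
  normalization <- match.arg(normalization)
  recs <- site_records(map, config)
  effects <- plate_effects(config, modality)
  imgs <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    img <- render_site(recs[i, ], config, modality, effects)
    if (modality == "BF") img <- correct_background(img, kernel_frac)
    imgs[[i]] <- img
  }
  if (normalization == "dmso") {
    for (p in unique(recs$plate_id)) {
      idx_dmso <- which(recs$plate_id == p & recs$compound_id == "DMSO")
      if (!length(idx_dmso))
        stop(sprintf("plate %s has no DMSO sites to normalize against", p))
      st <- compute_dmso_stats(imgs[idx_dmso])
      idx_all <- which(recs$plate_id == p)
      for (i in idx_all) imgs[[i]] <- normalize_dmso_plate(imgs[[i]], st)
    }
  } else {
    imgs <- lapply(imgs, normalize_site)
  }
  H <- config$image_size
  nc <- n_channels(config, modality)
  x <- matrix(0, H * H * nc, length(imgs))
  for (i in seq_along(imgs)) x[, i] <- as.numeric(imgs[[i]])
  structure(list(x = x, meta = recs, dims = c(H, H, nc), modality = modality,
                 normalization = normalization),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset %s/%s: %d sites of %dx%dx%d>\n", x$modality,
              x$normalization, ncol(x$x), x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}
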