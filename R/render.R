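#' Injected per-plate nuisance parameters (ground truth)
#'
#' Every plate/channel pair receives a multiplicative gain (centred on 1) and
#' an additive offset (centred on 0); brightfield planes additionally get a
#' smooth low-frequency illumination field parameterized by random
#' frequencies and phases. All parameters are drawn from seeded streams
#' derived from the config seed and are returned here so that recovery tests
#' can assert against the known truth.
#'
#' @param config a [screen_config()]
#' @param modality `"FL"` or `"BF"`
#' @return tibble: `plate_id`, `channel`, `gain`, `offset`, and for BF the
#'   illumination parameters `illum_amp`, `illum_fx`, `illum_fy`,
#'   `illum_phase_x`, `illum_phase_y`
#' @export
plate_effects <- function(config, modality = c("FL", "BF")) {
  modality <- match.arg(modality)
  nc <- n_channels(config, modality)
  out <- vector("list", config$n_plates)
  for (p in seq_len(config$n_plates)) {
    out[[p]] <- with_seed(
      mix_seed(config$seed, 202L, p, if (modality == "BF") 1L else 2L), {
        tibble::tibble(
          plate_id = sprintf("P%02d", p),
          channel = seq_len(nc),
          gain = rnorm(nc, 1, config$plate_gain_sd),
          offset = rnorm(nc, 0, config$plate_offset_sd),
          illum_amp = if (modality == "BF") config$bf_illumination_amp else 0,
          illum_fx = runif(nc, 0.5, 1.5),
          illum_fy = runif(nc, 0.5, 1.5),
          illum_phase_x = runif(nc, 0, 2 * pi),
          illum_phase_y = runif(nc, 0, 2 * pi)
        )
      })
  }
  dplyr::bind_rows(out)
}

# Well-spread unit directions: K rows in d dims. For K <= 2d, antipodal
# pairs of randomly rotated orthogonal axes (classes maximally separated,
# mirroring an assay that picks distinguishable MoAs); random otherwise.
spread_directions <- function(K, d, seed) {
  with_seed(seed, {
    if (K <= 2 * d) {
      rot <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
      axes <- rbind(diag(d), -diag(d))[seq_len(K), , drop = FALSE]
      axes %*% rot
    } else {
      m <- matrix(rnorm(K * d), K, d)
      m / sqrt(rowSums(m^2))
    }
  })
}

# MoA- and compound-level phenotype directions in channel space.
# Each MoA gets a fixed well-spread unit direction; each compound a smaller
# offset direction, so compounds of one class are similar but distinct.
phenotype_directions <- function(config, modality) {
  nc <- n_channels(config, modality)
  moas <- names(config$moa_compound_counts)
  moa_dir <- spread_directions(length(moas), nc,
                               mix_seed(config$seed, 303L, nc))
  rownames(moa_dir) <- moas
  comp_dir <- with_seed(mix_seed(config$seed, 304L, nc), {
    m <- matrix(rnorm(config$n_compounds * nc), config$n_compounds, nc)
    m / sqrt(rowSums(m^2))
  })
  rownames(comp_dir) <- sprintf("C%03d", seq_len(config$n_compounds))
  list(moa = moa_dir, compound = comp_dir)
}

# per-channel intensity multipliers for one treatment
channel_factors <- function(config, modality, compound_id, moa) {
  nc <- n_channels(config, modality)
  if (compound_id == "DMSO") return(rep(1, nc))
  dirs <- phenotype_directions(config, modality)
  eff <- compound_effect(config, compound_id)
  d <- (1 - config$compound_offset_frac) * dirs$moa[moa, ] +
    config$compound_offset_frac * dirs$compound[compound_id, ]
  exp(0.5 * eff * d)
}

smooth_illumination_field <- function(H, W, amp, fx, fy, px, py) {
  gx <- seq(0, 2 * pi, length.out = H)
  gy <- seq(0, 2 * pi, length.out = W)
  amp * outer(sin(fx * gx + px), sin(fy * gy + py))
}

#' Render one imaging site of the synthetic screen
#'
#' The phenotype model is deliberately simple: a field of Gaussian "cell"
#' blobs shared across channels, whose per-channel amplitude is scaled by an
#' MoA-specific (plus smaller compound-specific) direction raised with the
#' compound's effect size and whose density is mildly modulated by the class.
#' On top of the biology sit the injected nuisances: per-plate gain/offset,
#' a smooth illumination field (brightfield only) and pixel noise. DMSO wells
#' have effect zero. Rendering is deterministic per
#' (config seed, plate, well, site).
#'
#' @param record one row of [site_records()] (or of a plate map, with a
#'   `site` column added)
#' @param config the [screen_config()]
#' @param modality `"BF"` (z-planes, with illumination inhomogeneity) or
#'   `"FL"` (fluorescence channels)
#' @param effects optional precomputed [plate_effects()] table (recomputed
#'   if omitted)
#' @return a `site_image`: numeric array `image_size x image_size x channels`
#'   of nonnegative intensities with metadata attributes
#' @export
render_site <- function(record, config, modality = c("BF", "FL"),
                        effects = NULL) {
  modality <- match.arg(modality)
  stopifnot(inherits(config, "screen_config"))
  record <- as.list(record[c("plate_id", "well", "site", "compound_id", "moa")])
  if (anyNA(record)) stop("record must carry plate_id, well, site, compound_id, moa")
  if (is.null(effects)) effects <- plate_effects(config, modality)
  eff <- effects[effects$plate_id == record$plate_id, , drop = FALSE]
  if (!nrow(eff)) stop(sprintf("no plate effects for plate '%s'", record$plate_id))

  H <- config$image_size
  nc <- n_channels(config, modality)
  fac <- channel_factors(config, modality, record$compound_id, record$moa)
  e_comp <- if (record$compound_id == "DMSO") 0 else
    compound_effect(config, record$compound_id)
  dens_mod <- if (record$compound_id == "DMSO") 0 else {
    dirs <- phenotype_directions(config, modality)
    mean(dirs$moa[record$moa, ]) # class-specific density shift, in [-1, 1]
  }

  plate_idx <- as.integer(sub("^P", "", record$plate_id))
  well_key <- match(record$well, well_grid(config$wells_per_plate)$well)
  if (is.na(well_key)) stop(sprintf("unknown well '%s'", record$well))
  site_seed <- mix_seed(config$seed, 404L, plate_idx, well_key,
                        as.integer(record$site),
                        if (modality == "BF") 1L else 2L)

  img <- with_seed(site_seed, {
    n_cells <- max(1L, round(config$cells_per_site *
                               (1 + 0.25 * e_comp * dens_mod)))
    cx <- runif(n_cells, 1, H)
    cy <- runif(n_cells, 1, H)
    r0 <- H * (config$cell_radius_frac %||% (1 / 16))
    r <- pmax(1.5, rnorm(n_cells, r0, r0 / 4))
    a <- runif(n_cells, 0.6, 1.4)
    # each cell is a soft cytoplasm blob plus a sharper nucleus, so images
    # retain fine structure that survives background high-pass filtering
    cyto <- matrix(0, H, H)
    nuc <- matrix(0, H, H)
    gi <- seq_len(H)
    for (k in seq_len(n_cells)) {
      bx <- exp(-((gi - cx[k])^2) / (2 * r[k]^2))
      by <- exp(-((gi - cy[k])^2) / (2 * r[k]^2))
      cyto <- cyto + a[k] * outer(bx, by)
      rn <- r[k] / 3
      nx <- exp(-((gi - cx[k])^2) / (2 * rn^2))
      ny <- exp(-((gi - cy[k])^2) / (2 * rn^2))
      nuc <- nuc + a[k] * outer(nx, ny)
    }
    ch_w <- with_seed(mix_seed(config$seed, 505L, nc), {
      list(base = runif(nc, 0.4, 0.8),       # channel base brightness
           w_cyto = runif(nc, 0.3, 1),       # compartment weights per channel
           w_nuc = runif(nc, 0.3, 1))
    })
    arr <- array(0, dim = c(H, H, nc))
    for (ch in seq_len(nc)) {
      plane <- 0.1 + ch_w$base[ch] * fac[ch] *
        (ch_w$w_cyto[ch] * cyto + ch_w$w_nuc[ch] * nuc)
      plane <- eff$gain[ch] * plane + eff$offset[ch]
      if (modality == "BF" && config$bf_illumination_amp > 0)
        plane <- plane + smooth_illumination_field(
          H, H, eff$illum_amp[ch], eff$illum_fx[ch], eff$illum_fy[ch],
          eff$illum_phase_x[ch], eff$illum_phase_y[ch])
      if (config$noise_sd > 0)
        plane <- plane + rnorm(H * H, 0, config$noise_sd)
      arr[, , ch] <- plane
    }
    pmax(arr, 0) # intensities are nonnegative
  })
  site_image(img, modality, record$plate_id, record$well, record$site)
}

#' Construct a site image object
#'
#' @param pixels numeric array H x W x channels
#' @param modality `"BF"` or `"FL"`
#' @param plate_id,well,site identity of the site
#' @return a `site_image` array with metadata attributes
#' @export
site_image <- function(pixels, modality, plate_id, well, site) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, all(is.finite(pixels)))
  structure(pixels, class = "site_image", modality = modality,
            plate_id = plate_id, well = well, site = as.integer(site))
}

#' @export
print.site_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<site_image %s %s/%s site %d: %dx%d px, %d channel(s)>\n",
              attr(x, "modality"), attr(x, "plate_id"), attr(x, "well"),
              attr(x, "site"), d[1], d[2], d[3]))
  invisible(x)
}

# rebuild a site_image around new pixel data, keeping metadata
rewrap_site_image <- function(pixels, template) {
  site_image(pixels, attr(template, "modality"), attr(template, "plate_id"),
             attr(template, "well"), attr(template, "site"))
}
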