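#' Write / read a site image as multi-page TIFF
#'
#' One 16-bit page per channel, in channel order (z-plane order for
#' brightfield). Pixel values are affinely mapped from
#' `[offset, offset + scale]` onto the unsigned 16-bit grid, so values on
#' that grid round-trip exactly; the mapping and the site identity are kept
#' in a small JSON sidecar next to the TIFF (`<path>.json`), since baseline
#' TIFF tags cannot carry negative-intensity scaling. Normalized images
#' (which contain negative values) therefore round-trip too, up to 16-bit
#' quantization.
#'
#' @param image a `site_image`
#' @param path output path
#' @param offset,scale affine storage mapping; by default the image's own
#'   range, recorded in the sidecar
#' @return `write_site_tiff` returns `path` invisibly; `read_site_tiff`
#'   returns a `site_image`
#' @export
write_site_tiff <- function(image, path, offset = NULL, scale = NULL) {
  stopifnot(inherits(image, "site_image"))
  d <- dim(image)
  rng <- range(image)
  offset <- offset %||% rng[1]
  scale <- scale %||% max(rng[2] - offset, .Machine$double.eps)
  if (rng[1] < offset || rng[2] > offset + scale)
    stop(sprintf("pixel range [%.3g, %.3g] outside the storage window [%g, %g]",
                 rng[1], rng[2], offset, offset + scale))
  pages <- lapply(seq_len(d[3]),
                  function(ch) (unclass(image)[, , ch] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(modality = attr(image, "modality"),
         plate_id = attr(image, "plate_id"), well = attr(image, "well"),
         site = attr(image, "site"), offset = offset, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_site_tiff
#' @export
read_site_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else
    list(modality = "FL", plate_id = NA_character_, well = NA_character_,
         site = 1L, offset = 0, scale = 1)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (ch in seq_along(pages))
    arr[, , ch] <- pages[[ch]] * meta$scale + meta$offset
  site_image(arr, meta$modality, meta$plate_id, meta$well,
             as.integer(meta$site))
}

#' Feature-table CSV round trip at full precision
#'
#' Thin wrappers that write/read pipeline tables with full double precision
#' and a schema check on reading.
#'
#' @param x tibble to write
#' @param path file path
#' @param required columns that must be present on read
#' @return `write_table_csv` returns `path` invisibly; `read_table_csv` the
#'   tibble
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path, required = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(required)) assert_cols(x, required, path)
  x
}

#' Read a plate map from CSV, validating its schema and well uniqueness
#'
#' @param path CSV path
#' @param config optional [screen_config()] for full invariant checking
#' @return validated plate-map tibble
#' @export
read_plate_map <- function(path, config = NULL) {
  map <- read_table_csv(path, required = c("plate_id", "well", "compound_id",
                                           "moa"))
  validate_plate_map(map, config)
  class(map) <- c("plate_map", class(map))
  map
}

write_metrics_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
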