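# Shared desk-scale fixtures, generated in code at test time.

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    n_plates = 2, wells_per_plate = 96, sites_per_well = 1, image_size = 24,
    moa_compound_counts = c(A = 3L, B = 3L), dmso_wells_per_plate = 8,
    n_features = 8, seed = seed), list(...))
  do.call(screen_config, args)
}

# a small flat image dataset with known labels for classifier unit tests
toy_image_dataset <- function(seed = 1, n_per_class = 6, H = 12, C = 2,
                              shift = 3) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- matrix(rnorm(H * H * C * n), H * H * C, n)
    lab <- rep(c("A", "B"), each = n_per_class)
    x[seq_len(H * H), lab == "B"] <- x[seq_len(H * H), lab == "B"] + shift
    meta <- tibble::tibble(
      plate_id = "P01", well = sprintf("A%02d", seq_len(n)), site = 1L,
      compound_id = sprintf("C%03d", rep(seq_len(n_per_class * 2))),
      moa = lab)
    structure(list(x = x, meta = meta, dims = c(H, H, C), modality = "FL",
                   normalization = "site"),
              class = "image_dataset")
  })
}

# a well-profile tibble around a plain feature matrix
well_tbl <- function(x, plate = "P01", compound = NULL, moa = NULL) {
  n <- nrow(x)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  dplyr::bind_cols(
    tibble::tibble(plate_id = plate, well = sprintf("A%02d", seq_len(n)),
                   compound_id = compound %||% sprintf("C%02d", seq_len(n)),
                   moa = moa %||% "A"),
    tibble::as_tibble(x))
}

# split set covering given compounds: explicit partition, shared DMSO wells
manual_split <- function(compounds, moa, partition,
                         dmso_wells = tibble::tibble(
                           plate_id = character(), well = character(),
                           partition = character())) {
  structure(list(
    assignments = tibble::tibble(split = 1L, compound_id = compounds,
                                 moa = moa, partition = partition),
    dmso_wells = dmso_wells, n_splits = 1L, seed = 0L),
    class = "split_set")
}
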