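#' Generate an engineered per-site feature table
#'
#' Feature-space surrogate for a morphological-profiling feature set (the
#' kind a segmentation-and-measurement pipeline would produce): each site's
#' vector is drawn from
#' \deqn{x = e_c (\,(1-\alpha)\, m_{MoA} + \alpha\, o_{compound}) + b_{plate} + \epsilon}
#' where \eqn{m_{MoA}} and \eqn{o_{compound}} are fixed random unit
#' directions, \eqn{e_c} is the compound's effect size, \eqn{b_{plate}} is an
#' additive per-plate batch vector with sd `plate_offset_sd`, and
#' \eqn{\epsilon} is isotropic Gaussian noise. DMSO sites have effect zero.
#' Deterministic for a fixed config seed.
#'
#' @param config a [screen_config()]
#' @param map optional plate map (generated from `config` if omitted)
#' @param noise_sd per-feature noise sd (defaults to
#'   `config$feature_noise_sd`)
#' @return tibble with metadata columns (`plate_id`, `well`, `site`,
#'   `compound_id`, `moa`, replicate indices) and feature columns
#'   `f1..f<n_features>`; the injected per-plate batch vectors are attached
#'   as attribute `"plate_truth"`
#' @export
generate_feature_table <- function(config, map = NULL, noise_sd = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (is.null(map)) map <- generate_layout(config)
  noise_sd <- noise_sd %||% config$feature_noise_sd %||% config$noise_sd
  d <- config$n_features
  recs <- site_records(map, config)
  n <- nrow(recs)

  moas <- names(config$moa_compound_counts)
  moa_dir <- spread_directions(length(moas), d, mix_seed(config$seed, 606L))
  rownames(moa_dir) <- moas
  comp_dir <- with_seed(mix_seed(config$seed, 607L), {
    m <- matrix(rnorm(config$n_compounds * d), config$n_compounds, d)
    m / sqrt(rowSums(m^2))
  })
  rownames(comp_dir) <- sprintf("C%03d", seq_len(config$n_compounds))
  plate_ids <- sprintf("P%02d", seq_len(config$n_plates))
  plate_vec <- with_seed(mix_seed(config$seed, 608L),
    matrix(rnorm(config$n_plates * d, 0, config$plate_offset_sd),
           config$n_plates, d))
  rownames(plate_vec) <- plate_ids
  colnames(plate_vec) <- paste0("f", seq_len(d))

  alpha <- config$compound_offset_frac
  mean_mat <- matrix(0, n, d)
  treated <- recs$compound_id != "DMSO"
  if (any(treated)) {
    eff <- vapply(recs$compound_id[treated],
                  function(cid) compound_effect(config, cid), numeric(1))
    mean_mat[treated, ] <- eff *
      ((1 - alpha) * moa_dir[recs$moa[treated], , drop = FALSE] +
         alpha * comp_dir[recs$compound_id[treated], , drop = FALSE])
  }
  mean_mat <- mean_mat + plate_vec[recs$plate_id, , drop = FALSE]
  x <- mean_mat + with_seed(mix_seed(config$seed, 609L),
                            matrix(rnorm(n * d, 0, noise_sd), n, d))
  colnames(x) <- paste0("f", seq_len(d))
  out <- dplyr::bind_cols(recs, tibble::as_tibble(x))
  attr(out, "plate_truth") <- tibble::as_tibble(plate_vec, rownames = "plate_id")
  out
}
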