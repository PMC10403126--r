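#' Screen configuration with graded phenotype strength
#'
#' A compact screen in which every MoA class carries compounds at each of
#' several effect-size levels, so that phenotype strength is decoupled from
#' class identity. This is the study design behind the parameter-recovery
#' analyses: classification accuracy and profile-matching performance should
#' rise with the replicate-strength (grit) of the underlying phenotype, and
#' injected effect size is the ground-truth dial.
#'
#' Defaults: 10 MoA classes x 2 compounds per level, levels spanning zero
#' (solvent-indistinguishable) to 1.5 (saturated classification), 96-pixel
#' images at one imaged site per well, pixel noise 0.15 so the classifier's
#' accuracy transition falls mid-range, and a compound-offset fraction of
#' 0.2.
#'
#' @param seed integer seed
#' @param levels effect-size levels
#' @param compounds_per_level compounds per (MoA, level) cell
#' @param image_size image side in pixels
#' @param sites_per_well imaged sites per well
#' @param noise_sd pixel noise
#' @param compound_offset_frac within-MoA compound offset fraction
#' @return a [screen_config()] whose `effect_size` is a named per-compound
#'   vector; the level of each compound is attached as attribute `"levels"`
#' @export
graded_screen_config <- function(seed,
                                 levels = c(0, 0.3, 0.6, 1, 1.5),
                                 compounds_per_level = 2L,
                                 image_size = 96,
                                 sites_per_well = 1,
                                 noise_sd = 0.15,
                                 compound_offset_frac = 0.2) {
  moas <- names(default_moa_counts())
  per_moa <- length(levels) * compounds_per_level
  cfg <- screen_config(
    n_plates = 2, sites_per_well = sites_per_well, image_size = image_size,
    moa_compound_counts = setNames(rep(as.integer(per_moa), length(moas)),
                                   moas),
    compound_offset_frac = compound_offset_frac, noise_sd = noise_sd,
    seed = seed)
  eff <- setNames(rep(rep(levels, each = compounds_per_level),
                      times = length(moas)),
                  sprintf("C%03d", seq_len(cfg$n_compounds)))
  cfg$effect_size <- eff
  attr(cfg, "levels") <- levels
  cfg
}

#' Train on a graded screen and join test accuracy with grit
#'
#' Runs one replicate of the parameter-recovery experiment: generate a
#' [graded_screen_config()] screen, train the image classifier on one
#' compound-stratified split, predict its held-out test compounds, compute
#' grit scores from well-level profiles of the engineered feature table
#' (profiled at `feature_sites` sites per well), and join per-site
#' correctness with per-well grit.
#'
#' @param seed replicate seed (drives screen, split and training)
#' @param modality image modality to train on
#' @param config optional [graded_screen_config()] override
#' @param model optional [model_config()] override
#' @param feature_sites sites per well used for the feature-table profiles
#' @param kernel_frac background-correction kernel fraction (BF only)
#' @return tibble of test-site records: `plate_id`, `well`, `compound_id`,
#'   `effect`, `correct`, `grit`, plus attributes `"macro_f1"` and
#'   `"predictions"`
#' @export
grit_recovery_run <- function(seed, modality = "FL", config = NULL,
                              model = NULL, feature_sites = 5L,
                              kernel_frac = 0.25) {
  cfg <- config %||% graded_screen_config(seed)
  mc <- model %||% model_config(backbone = "smallcnn", feature_dim = 32,
                                conv_filters = c(8L, 16L, 32L), epochs = 12,
                                batch_size = 16, seed = seed)
  map <- generate_layout(cfg)
  sp <- make_splits(map, 1, seed = seed)
  ds <- build_image_dataset(map, cfg, modality, "dmso",
                            kernel_frac = kernel_frac)
  m <- train_classifier(ds, sp, 1, mc)
  part <- partition_of(ds$meta, sp, 1)
  idx <- which(!is.na(part) & part == "test")
  tds <- subset_image_dataset(ds, idx)
  p <- predict(m, tds)
  p$correct <- p$pred == p$truth

  cfg_feat <- cfg
  cfg_feat$sites_per_well <- as.integer(feature_sites)
  feats <- normalize_features_dmso(generate_feature_table(cfg_feat, map))
  g <- grit(aggregate_sites_to_wells(feats))

  rec <- dplyr::inner_join(
    p[, c("plate_id", "well", "compound_id", "correct")],
    g[, c("plate_id", "well", "grit")], by = c("plate_id", "well"))
  eff <- cfg$effect_size
  rec$effect <- ifelse(rec$compound_id == "DMSO", 0,
                       unname(eff[rec$compound_id]))
  attr(rec, "macro_f1") <- macro_f1(p)
  attr(rec, "predictions") <- p
  rec
}

#' Feature-space grit and mAP across effect-size levels
#'
#' For each effect level, generates a uniform-effect screen's feature table,
#' computes the mean grit of its treated well profiles and the sphered
#' mean-average-precision of MoA retrieval. Both quantities should be
#' increasing functions of the injected effect size.
#'
#' @param seed replicate seed
#' @param levels effect-size levels to sweep
#' @param lambda sphering regularization applied before matching
#' @param sites_per_well sites per well of the feature screen
#' @return tibble: `level`, `mean_grit`, `map`
#' @export
map_effect_sweep <- function(seed, levels = c(0, 0.3, 0.6, 1, 1.5),
                             lambda = 0.1, sites_per_well = 5L) {
  out <- lapply(levels, function(e) {
    cfg <- screen_config(
      n_plates = 2, sites_per_well = sites_per_well,
      moa_compound_counts = setNames(rep(5L, 10),
                                     names(default_moa_counts())),
      effect_size = e, seed = mix_seed(seed, round(1000 * e)))
    feats <- normalize_features_dmso(generate_feature_table(cfg))
    wells <- aggregate_sites_to_wells(feats)
    g <- grit(wells)
    ctrl <- wells[wells$compound_id == "DMSO", ]
    tr <- fit_sphering(ctrl, lambda)
    sph <- predict(tr, wells[wells$compound_id != "DMSO", ])
    tibble::tibble(level = e, mean_grit = mean(g$grit, na.rm = TRUE),
                   map = mean_average_precision(sph)$map)
  })
  dplyr::bind_rows(out)
}

#' Subset an image dataset by record index
#'
#' @param dataset an `image_dataset`
#' @param idx integer indices into its site records
#' @return the subset `image_dataset`
#' @export
subset_image_dataset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "image_dataset"))
  structure(list(x = dataset$x[, idx, drop = FALSE],
                 meta = dataset$meta[idx, , drop = FALSE],
                 dims = dataset$dims, modality = dataset$modality,
                 normalization = dataset$normalization),
            class = "image_dataset")
}
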