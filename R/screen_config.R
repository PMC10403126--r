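#' Configuration of a synthetic high-content screen
#'
#' Describes the plate, replicate and phenotype structure of a simulated
#' screen. The defaults mirror a realistic 18-plate, 384-well assay in which
#' ten MoA classes with 18--33 compounds each (231 compounds in total) are
#' replicated six times: three technical replicates (same plate) on each of
#' two biological-replicate plates, imaged at several sites per well, with
#' a DMSO solvent-control well set on every plate.
#'
#' Images are generated at `image_size` x `image_size` pixels (default 96,
#' far below microscope resolution) so that the full pipeline runs in minutes
#' on one CPU; all spatial kernels downstream are expressed as fractions of
#' the image side so the choice of resolution does not change the analysis.
#'
#' @param n_plates number of plates; must be a multiple of
#'   `biological_rep_plates`
#' @param wells_per_plate plate capacity (default 384, laid out 16 x 24)
#' @param sites_per_well fields of view imaged per well
#' @param moa_compound_counts named integer vector: compounds per MoA class
#' @param dmso_wells_per_plate DMSO control wells on every plate
#' @param technical_reps on-plate replicate wells per compound
#' @param biological_rep_plates number of plates carrying the same compound
#'   set (biological replicates)
#' @param image_size pixels per image side
#' @param fl_channels number of fluorescence channels
#' @param bf_planes number of brightfield z-planes
#' @param effect_size nonnegative phenotype strength; either a scalar applied
#'   to every compound or a named vector keyed by compound id (`"C001"`, ...)
#' @param compound_offset_frac size of the per-compound offset relative to the
#'   MoA direction (compounds within an MoA are similar but not identical)
#' @param plate_gain_sd,plate_offset_sd standard deviations of the per-plate
#'   multiplicative gain (around 1) and additive offset (around 0) batch
#'   effects, drawn independently per plate and channel
#' @param bf_illumination_amp amplitude of the smooth low-frequency
#'   illumination field added to brightfield planes only
#' @param noise_sd pixel-level Gaussian noise standard deviation
#' @param feature_noise_sd per-feature noise sd of the engineered feature
#'   table (default 0.5: site profiles are classifiable well above chance
#'   and replicate wells correlate at roughly 0.2-0.5, as typical of
#'   morphological-profiling feature sets)
#' @param n_features dimensionality of the engineered feature table
#' @param cells_per_site expected number of cell bodies rendered per site
#' @param cell_radius_frac cell body radius as a fraction of the image side
#'   (default 1/16: a wide-field view holds roughly fifteen large adherent
#'   cells across)
#' @param seed integer seed; every stream of randomness in the generator is
#'   derived from it
#' @return an object of class `screen_config` (a validated list)
#' @export
#' @examples
#' cfg <- screen_config(n_plates = 2, sites_per_well = 1, seed = 1,
#'                      moa_compound_counts = c(A = 2, B = 2))
#' cfg$n_compounds
screen_config <- function(n_plates = 18,
                          wells_per_plate = 384,
                          sites_per_well = 5,
                          moa_compound_counts = default_moa_counts(),
                          dmso_wells_per_plate = 8,
                          technical_reps = 3,
                          biological_rep_plates = 2,
                          image_size = 96,
                          fl_channels = 5,
                          bf_planes = 6,
                          effect_size = 1,
                          compound_offset_frac = 0.3,
                          plate_gain_sd = 0.1,
                          plate_offset_sd = 0.1,
                          bf_illumination_amp = 0.2,
                          noise_sd = 0.05,
                          feature_noise_sd = 0.5,
                          n_features = 50,
                          cells_per_site = 25,
                          cell_radius_frac = 1 / 16,
                          seed = 1L) {
  counts <- c(n_plates = n_plates, wells_per_plate = wells_per_plate,
              sites_per_well = sites_per_well,
              dmso_wells_per_plate = dmso_wells_per_plate,
              technical_reps = technical_reps,
              biological_rep_plates = biological_rep_plates,
              image_size = image_size, fl_channels = fl_channels,
              bf_planes = bf_planes, n_features = n_features)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  if (n_plates %% biological_rep_plates != 0)
    stop("`n_plates` must be a multiple of `biological_rep_plates`")
  if (is.null(names(moa_compound_counts)) || any(!nzchar(names(moa_compound_counts))))
    stop("`moa_compound_counts` must be a named vector (MoA -> compound count)")
  if (any(moa_compound_counts < 1))
    stop("each MoA needs at least one compound")
  if ("DMSO" %in% names(moa_compound_counts))
    stop("'DMSO' is reserved for the solvent control and cannot be an MoA class")
  if (any(effect_size < 0)) stop("`effect_size` must be nonnegative")
  stopifnot(plate_gain_sd >= 0, plate_offset_sd >= 0,
            bf_illumination_amp >= 0, noise_sd >= 0,
            compound_offset_frac >= 0)

  n_compounds <- sum(moa_compound_counts)
  cfg <- list(
    n_plates = as.integer(n_plates),
    wells_per_plate = as.integer(wells_per_plate),
    sites_per_well = as.integer(sites_per_well),
    moa_compound_counts = moa_compound_counts,
    dmso_wells_per_plate = as.integer(dmso_wells_per_plate),
    technical_reps = as.integer(technical_reps),
    biological_rep_plates = as.integer(biological_rep_plates),
    image_size = as.integer(image_size),
    fl_channels = as.integer(fl_channels),
    bf_planes = as.integer(bf_planes),
    effect_size = effect_size,
    compound_offset_frac = compound_offset_frac,
    plate_gain_sd = plate_gain_sd,
    plate_offset_sd = plate_offset_sd,
    bf_illumination_amp = bf_illumination_amp,
    noise_sd = noise_sd,
    feature_noise_sd = feature_noise_sd,
    n_features = as.integer(n_features),
    cells_per_site = cells_per_site,
    cell_radius_frac = cell_radius_frac,
    n_compounds = as.integer(n_compounds),
    seed = as.integer(seed)
  )
  class(cfg) <- "screen_config"
  cfg
}

#' Default compounds-per-MoA table
#'
#' Ten MoA classes with the compound counts of the default assay design
#' (231 compounds in total): ATPase, Aurora kinase, HDAC, HSP, JAK, PARP and
#' protein-synthesis inhibitors, retinoid-receptor agonists, topoisomerase
#' and tubulin-polymerization inhibitors.
#'
#' @return named integer vector of length 10
#' @export
default_moa_counts <- function() {
  c("ATPase-i" = 18L, "AuroraK-i" = 20L, "HDAC-i" = 33L, "HSP-i" = 24L,
    "JAK-i" = 21L, "PARP-i" = 21L, "Prot.Synth.-i" = 23L, "Ret.Rec.Ag" = 19L,
    "Topo.-i" = 32L, "Tub.Pol.-i" = 20L)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat(sprintf("  %d plates x %d wells, %d site(s)/well, %d DMSO wells/plate\n",
              x$n_plates, x$wells_per_plate, x$sites_per_well,
              x$dmso_wells_per_plate))
  cat(sprintf("  %d MoA classes, %d compounds, %d tech x %d bio replicates\n",
              length(x$moa_compound_counts), x$n_compounds,
              x$technical_reps, x$biological_rep_plates))
  cat(sprintf("  images %dpx: %d FL channels | %d BF z-planes; seed %d\n",
              x$image_size, x$fl_channels, x$bf_planes, x$seed))
  invisible(x)
}

# effect size for one compound id under this config
compound_effect <- function(config, compound_id) {
  e <- config$effect_size
  if (length(e) == 1L && is.null(names(e))) return(unname(e))
  if (is.null(names(e))) stop("vector `effect_size` must be named by compound id")
  if (!compound_id %in% names(e))
    stop(sprintf("no effect size given for compound '%s'", compound_id))
  unname(e[[compound_id]])
}

n_channels <- function(config, modality) {
  switch(match.arg(modality, c("FL", "BF")),
         FL = config$fl_channels, BF = config$bf_planes)
}

#' Read or write a screen configuration as YAML
#'
#' @param config a `screen_config`
#' @param path file path
#' @return `write_screen_config` returns `path` invisibly;
#'   `read_screen_config` returns a `screen_config`.
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  x <- unclass(config)
  x$n_compounds <- NULL # derived
  x$moa_compound_counts <- as.list(x$moa_compound_counts)
  if (!is.null(names(x$effect_size))) x$effect_size <- as.list(x$effect_size)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_screen_config
#' @export
read_screen_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$moa_compound_counts <- unlist(x$moa_compound_counts)
  if (is.list(x$effect_size)) x$effect_size <- unlist(x$effect_size)
  do.call(screen_config, x)
}
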