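#' Generate a plate layout for a synthetic screen
#'
#' Compounds are stratified by MoA across biological-replicate plate groups
#' (each group of `biological_rep_plates` plates carries the same compound
#' set), then placed at seeded random well coordinates. Replicate wells of a
#' compound occupy different coordinates on the plates of a group, mimicking
#' designed layouts that decorrelate well position from treatment. Every plate
#' additionally receives `dmso_wells_per_plate` DMSO control wells.
#'
#' @param config a [screen_config()]
#' @return a tibble (class `plate_map`) with one row per treatment well:
#'   `plate_id`, `well_row`, `well_col`, `well`, `compound_id`, `moa`,
#'   `biological_rep_index`, `technical_rep_index` (`NA` for DMSO wells)
#' @export
#' @examples
#' map <- generate_layout(screen_config(
#'   n_plates = 2, sites_per_well = 1,
#'   moa_compound_counts = c(A = 3, B = 2), seed = 7))
#' table(map$moa)
generate_layout <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  with_seed(mix_seed(config$seed, 101L), generate_layout_impl(config))
}

generate_layout_impl <- function(config) {
  n_groups <- config$n_plates %/% config$biological_rep_plates
  moas <- names(config$moa_compound_counts)

  # compound registry: C001.. in MoA blocks
  compounds <- tibble::tibble(
    compound_id = sprintf("C%03d", seq_len(config$n_compounds)),
    moa = rep(moas, times = config$moa_compound_counts)
  )

  # stratified deal of compounds to plate groups: shuffle within MoA, then
  # round-robin so each group gets a near-equal share of every class
  group_of <- integer(config$n_compounds)
  start <- 0L
  for (m in moas) {
    idx <- sample(which(compounds$moa == m))
    group_of[idx] <- ((start + seq_along(idx) - 1L) %% n_groups) + 1L
    start <- start + length(idx)
  }

  grid <- well_grid(config$wells_per_plate)
  rows_out <- vector("list", config$n_plates)

  for (g in seq_len(n_groups)) {
    comp_g <- compounds[group_of == g, , drop = FALSE]
    need <- nrow(comp_g) * config$technical_reps + config$dmso_wells_per_plate
    if (need > config$wells_per_plate)
      stop(sprintf(paste0("plate group %d cannot hold its assignment: needs %d",
                          " wells but plates have %d (deficit %d)"),
                   g, need, config$wells_per_plate,
                   need - config$wells_per_plate))
    comp_g <- comp_g[sample(nrow(comp_g)), , drop = FALSE]

    placements <- vector("list", config$biological_rep_plates)
    for (b in seq_len(config$biological_rep_plates)) {
      repeat {
        wells <- grid[sample(nrow(grid), need), , drop = FALSE]
        n_treat <- nrow(comp_g) * config$technical_reps
        treat <- wells[seq_len(n_treat), , drop = FALSE]
        treat$compound_id <- rep(comp_g$compound_id, each = config$technical_reps)
        treat$moa <- rep(comp_g$moa, each = config$technical_reps)
        treat$technical_rep_index <- rep(seq_len(config$technical_reps),
                                         times = nrow(comp_g))
        dmso <- wells[seq_len(config$dmso_wells_per_plate) + n_treat, ,
                      drop = FALSE]
        dmso$compound_id <- "DMSO"
        dmso$moa <- "DMSO"
        dmso$technical_rep_index <- NA_integer_
        cand <- dplyr::bind_rows(treat, dmso)
        # biological replicates must sit at different coordinates than on
        # the earlier plates of the group
        clash <- FALSE
        for (prev in placements[seq_len(b - 1L)]) {
          shared <- dplyr::inner_join(
            cand[cand$compound_id != "DMSO", c("compound_id", "well")],
            prev[prev$compound_id != "DMSO", c("compound_id", "well")],
            by = c("compound_id", "well"))
          if (nrow(shared) > 0) { clash <- TRUE; break }
        }
        if (!clash) { placements[[b]] <- cand; break }
      }
    }

    for (b in seq_len(config$biological_rep_plates)) {
      plate_idx <- (g - 1L) * config$biological_rep_plates + b
      p <- placements[[b]]
      p$plate_id <- sprintf("P%02d", plate_idx)
      p$biological_rep_index <- ifelse(p$compound_id == "DMSO", NA_integer_, b)
      rows_out[[plate_idx]] <- p
    }
  }

  map <- dplyr::bind_rows(rows_out)
  map <- map[, c("plate_id", "well_row", "well_col", "well", "compound_id",
                 "moa", "biological_rep_index", "technical_rep_index")]
  map <- dplyr::arrange(map, .data$plate_id, .data$well_row, .data$well_col)
  class(map) <- c("plate_map", class(map))
  validate_plate_map(map, config)
  map
}

# 16 x 24 (or smaller) well coordinate grid
well_grid <- function(wells_per_plate) {
  n_rows <- 16L
  n_cols <- as.integer(ceiling(wells_per_plate / n_rows))
  g <- expand.grid(well_row = LETTERS[seq_len(n_rows)],
                   well_col = seq_len(n_cols),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[seq_len(min(nrow(g), wells_per_plate)), , drop = FALSE]
  g$well <- sprintf("%s%02d", g$well_row, g$well_col)
  tibble::as_tibble(g)
}

validate_plate_map <- function(map, config = NULL) {
  assert_cols(map, c("plate_id", "well", "compound_id", "moa"), "plate map")
  dup <- duplicated(map[, c("plate_id", "well")])
  if (any(dup))
    stop(sprintf("duplicate well assignment: %s %s",
                 map$plate_id[dup][1], map$well[dup][1]))
  if (!is.null(config)) {
    treat <- map[map$compound_id != "DMSO", ]
    per <- dplyr::count(treat, .data$compound_id, .data$plate_id)
    if (any(per$n != config$technical_reps))
      stop("each compound must have exactly `technical_reps` wells per plate")
    plates_per <- dplyr::count(dplyr::distinct(treat, .data$compound_id,
                                               .data$plate_id),
                               .data$compound_id)
    if (any(plates_per$n != config$biological_rep_plates))
      stop("each compound must appear on exactly `biological_rep_plates` plates")
    dmso_per <- dplyr::count(map[map$compound_id == "DMSO", ], .data$plate_id)
    if (nrow(dmso_per) != config$n_plates ||
        any(dmso_per$n != config$dmso_wells_per_plate))
      stop("each plate must have exactly `dmso_wells_per_plate` DMSO wells")
  }
  invisible(map)
}

#' Expand a plate map to one record per imaging site
#'
#' @param map a plate map from [generate_layout()]
#' @param config the matching [screen_config()]
#' @return tibble with the plate-map columns plus `site`
#' @export
site_records <- function(map, config) {
  tidyr::crossing(map, site = seq_len(config$sites_per_well))
}
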