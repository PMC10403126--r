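#' Compound-level stratified train/validation/test splits
#'
#' Produces `n_splits` splits of a screen at the compound level. Per MoA,
#' compounds are shuffled and dealt into `n_splits` disjoint test folds whose
#' sizes differ by at most one (remainders are distributed round-robin across
#' splits, walking the MoAs in seed-shuffled order, so test-set sizes stay
#' balanced and the folds exactly cover the compound set). Within each split,
#' the non-test compounds are shuffled and assigned 80/20 to training and
#' validation, again stratified per MoA. DMSO control wells are assigned once
#' per plate -- `dmso_wells` wells to train/val/test respectively -- and the
#' same physical wells are reused by every split.
#'
#' @param map plate map from [generate_layout()]
#' @param n_splits number of splits (test folds)
#' @param seed integer seed
#' @param dmso_wells integer vector `c(train, val, test)` DMSO wells per plate
#' @param test_frac fraction of compounds in each test fold; compounds are
#'   dealt into `max(n_splits, round(1/test_frac))` disjoint folds and the
#'   first `n_splits` of them serve as test sets, so with `n_splits = 5` and
#'   the default `test_frac = 0.2` the folds exactly cover the compound set,
#'   while a single split still holds out ~20 percent
#' @param val_frac fraction of non-test compounds assigned to validation
#' @return a `split_set`: list with `assignments` (tibble: `split`,
#'   `compound_id`, `moa`, `partition`), `dmso_wells` (tibble: `plate_id`,
#'   `well`, `partition`, shared by all splits), `n_splits`, `seed`
#' @export
#' @examples
#' cfg <- screen_config(n_plates = 2, moa_compound_counts = c(A = 6, B = 5),
#'                      sites_per_well = 1, seed = 3)
#' sp <- make_splits(generate_layout(cfg), n_splits = 5, seed = 3)
#' table(sp$assignments$partition, sp$assignments$split)
make_splits <- function(map, n_splits = 5, seed = 1L,
                        dmso_wells = c(train = 5L, val = 1L, test = 2L),
                        test_frac = 0.2, val_frac = 0.2) {
  validate_plate_map(map)
  stopifnot(n_splits >= 1, length(dmso_wells) == 3, all(dmso_wells >= 0),
            test_frac > 0, test_frac <= 1)
  n_folds <- max(as.integer(n_splits), as.integer(round(1 / test_frac)))
  compounds <- dplyr::distinct(map[map$compound_id != "DMSO", ],
                               .data$compound_id, .data$moa)
  tab <- table(compounds$moa)
  if (any(tab < n_splits))
    stop(sprintf("MoA '%s' has %d compounds but %d splits were requested",
                 names(tab)[which.min(tab)], min(tab), n_splits))

  with_seed(mix_seed(seed, 717L), {
    moa_order <- sample(names(tab))
    fold_of <- integer(nrow(compounds))
    rr <- 0L # round-robin pointer for remainder folds
    for (m in moa_order) {
      idx <- sample(which(compounds$moa == m))
      n <- length(idx)
      base <- n %/% n_folds
      rem <- n - base * n_folds
      sizes <- rep(base, n_folds)
      if (rem > 0) {
        extra <- ((rr + seq_len(rem) - 1L) %% n_folds) + 1L
        sizes[extra] <- sizes[extra] + 1L
        rr <- rr + rem
      }
      fold_of[idx] <- rep(seq_len(n_folds), times = sizes)
    }
    compounds$fold <- fold_of

    assignments <- vector("list", n_splits)
    for (k in seq_len(n_splits)) {
      part <- character(nrow(compounds))
      part[compounds$fold == k] <- "test"
      for (m in names(tab)) {
        rest <- which(compounds$moa == m & compounds$fold != k)
        rest <- sample(rest)
        n_val <- if (length(rest) >= 2) max(1L, round(val_frac * length(rest)))
                 else 0L
        part[rest[seq_len(n_val)]] <- "val"
        part[rest[setdiff(seq_along(rest), seq_len(n_val))]] <- "train"
      }
      assignments[[k]] <- tibble::tibble(split = k,
                                         compound_id = compounds$compound_id,
                                         moa = compounds$moa,
                                         partition = part)
    }

    # fixed DMSO well identities, chosen once and shared across splits
    dmso_map <- dplyr::distinct(map[map$compound_id == "DMSO", ],
                                .data$plate_id, .data$well)
    need <- sum(dmso_wells)
    dm <- lapply(split(dmso_map, dmso_map$plate_id), function(pm) {
      if (nrow(pm) < need)
        stop(sprintf("plate %s has %d DMSO wells; %d are needed (%s)",
                     pm$plate_id[1], nrow(pm), need,
                     paste(dmso_wells, collapse = "/")))
      pick <- pm[sample(nrow(pm), need), ]
      pick$partition <- rep(c("train", "val", "test"), times = dmso_wells)
      pick
    })
    out <- list(assignments = dplyr::bind_rows(assignments),
                dmso_wells = dplyr::bind_rows(dm),
                n_splits = as.integer(n_splits), seed = as.integer(seed))
    class(out) <- "split_set"
    out
  })
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("<split_set: %d splits over %d compounds; DMSO wells %s>\n",
              x$n_splits, length(unique(x$assignments$compound_id)),
              paste(table(x$dmso_wells$partition)[c("train", "val", "test")],
                    collapse = "/")))
  invisible(x)
}

#' Partition site records according to one split
#'
#' Maps every site record of a dataset to `train`, `val`, `test` (or `NA`
#' for DMSO wells outside the split's fixed control-well assignment).
#'
#' @param meta site records (rows with `plate_id`, `well`, `compound_id`)
#' @param splits a [make_splits()] `split_set`
#' @param split which split to use
#' @return character vector of partitions, aligned with `meta` rows
#' @export
partition_of <- function(meta, splits, split = 1L) {
  stopifnot(inherits(splits, "split_set"))
  a <- splits$assignments[splits$assignments$split == split, ]
  if (!nrow(a)) stop(sprintf("split %d not present", split))
  part <- a$partition[match(meta$compound_id, a$compound_id)]
  is_dmso <- meta$compound_id == "DMSO"
  key <- paste(meta$plate_id, meta$well)
  dkey <- paste(splits$dmso_wells$plate_id, splits$dmso_wells$well)
  part[is_dmso] <- splits$dmso_wells$partition[match(key[is_dmso], dkey)]
  part
}

#' Audit a split for test-compound leakage
#'
#' Confirms, at the level of individual site records, that the images
#' reachable from the training partition share no compound with the test
#' partition, and that every record lands in at most one partition.
#'
#' @param meta site records
#' @param splits a `split_set`
#' @param split split index
#' @return invisibly `TRUE`; errors if leakage is detected
#' @export
audit_split <- function(meta, splits, split = 1L) {
  a <- splits$assignments[splits$assignments$split == split, ]
  multi <- tapply(a$partition, a$compound_id, function(p) length(unique(p)))
  if (any(multi > 1))
    stop(sprintf("compound leakage: assigned to several partitions: %s",
                 paste(names(multi)[multi > 1], collapse = ", ")))
  part <- partition_of(meta, splits, split)
  train_cmp <- unique(meta$compound_id[!is.na(part) & part == "train"])
  test_cmp <- unique(meta$compound_id[!is.na(part) & part == "test"])
  leak <- setdiff(intersect(train_cmp, test_cmp), "DMSO")
  if (length(leak))
    stop(sprintf("compound leakage between train and test: %s",
                 paste(leak, collapse = ", ")))
  invisible(TRUE)
}
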