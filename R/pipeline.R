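#' Configuration of an end-to-end pipeline run
#'
#' Bundles a screen configuration with the analysis settings of a full run.
#' Stage-level seeds (layout/rendering, splitting, training) are derived from
#' the single `seed` so individual stages can be varied independently.
#'
#' @param screen a [screen_config()]
#' @param n_splits number of compound-level splits to train/evaluate
#' @param normalization `"dmso"` or `"site"` image normalization
#' @param kernel_frac brightfield background-correction kernel as a fraction
#'   of the image side; at desk-scale resolutions choose it so the kernel
#'   spans about two cell diameters
#' @param modalities image modalities to train on
#' @param cnn,mlp [model_config()]s for the image CNN and feature MLP
#' @param lambda_sweep sphering regularization values for the matching task
#' @param map_lambda sphering strength used for the grit-vs-mAP analysis
#' @param n_bins grit bins
#' @param seed master seed of the run
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(screen = screen_config(),
                            n_splits = 5L,
                            normalization = c("dmso", "site"),
                            kernel_frac = 101 / 2160,
                            modalities = c("BF", "FL"),
                            cnn = model_config(backbone = "smallcnn"),
                            mlp = model_config(backbone = "mlp"),
                            lambda_sweep = c(0.001, 0.01, 0.1, 1),
                            map_lambda = 0.1,
                            n_bins = 10L,
                            seed = 1L) {
  normalization <- match.arg(normalization)
  modalities <- match.arg(modalities, c("BF", "FL"), several.ok = TRUE)
  structure(list(screen = screen, n_splits = as.integer(n_splits),
                 normalization = normalization, kernel_frac = kernel_frac,
                 modalities = modalities,
                 cnn = cnn, mlp = mlp, lambda_sweep = lambda_sweep,
                 map_lambda = map_lambda, n_bins = as.integer(n_bins),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Desk-scale demonstration configuration
#'
#' A small screen (2 plates, 10 MoA classes with four compounds each, one
#' site per well, 48-pixel images) and compact models, sized so the full
#' pipeline -- both modalities plus the feature benchmark over two splits --
#' runs in a few minutes on one CPU.
#'
#' @param seed master seed
#' @return a `pipeline_config`
#' @export
demo_pipeline_config <- function(seed = 1L) {
  scr <- screen_config(
    n_plates = 2, sites_per_well = 1, image_size = 48,
    moa_compound_counts = setNames(rep(4L, 10), names(default_moa_counts())),
    effect_size = 2, n_features = 30, seed = mix_seed(seed, 1L))
  pipeline_config(
    screen = scr, n_splits = 2L, kernel_frac = 0.25,
    cnn = model_config(backbone = "smallcnn", feature_dim = 32,
                       conv_filters = c(8L, 16L, 32L), epochs = 18,
                       patience = 12, batch_size = 16,
                       seed = mix_seed(seed, 4L)),
    mlp = model_config(backbone = "mlp", hidden_units = 64, epochs = 60,
                       patience = 20, lr = 5e-3, batch_size = 32,
                       seed = mix_seed(seed, 5L)),
    seed = seed)
}

stage_done <- function(dir) file.exists(file.path(dir, ".done"))
mark_done <- function(dir) {
  writeLines(as.character(Sys.time()), file.path(dir, ".done"))
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, split, train, evaluate, profile and match
#' in order, writing each stage's outputs under its own subdirectory of
#' `run_dir`. A stage whose `.done` sentinel already exists is skipped when
#' `resume = TRUE`, so deleting one stage's directory recomputes that stage
#' onward. All metric outputs are deterministic functions of the config and
#' its seed. A run manifest (config snapshot, seeds, stage status, output
#' checksums, timestamp) is written last.
#'
#' @param config a [pipeline_config()]
#' @param run_dir output directory (created if needed)
#' @param resume skip stages whose outputs already exist
#' @param stages subset of stages to run (in pipeline order)
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config = demo_pipeline_config(),
                         run_dir = tempfile("moabench_run_"),
                         resume = TRUE,
                         stages = c("simulate", "preprocess", "split", "train",
                                    "evaluate", "profile", "match")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  scr <- config$screen
  dirs <- setNames(file.path(run_dir, c("simulate", "preprocess", "split",
                                        "train", "evaluate", "profile",
                                        "match")),
                   c("simulate", "preprocess", "split", "train", "evaluate",
                     "profile", "match"))
  status <- list()
  run_stage <- function(name, fn) {
    d <- dirs[[name]]
    if (!(name %in% stages)) { status[[name]] <<- "not requested"; return() }
    if (resume && stage_done(d)) { status[[name]] <<- "resumed"; return() }
    unlink(d, recursive = TRUE)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    ok <- tryCatch({ fn(d); TRUE },
                   error = function(e)
                     stop(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)), call. = FALSE))
    mark_done(d)
    status[[name]] <<- "computed"
  }

  # -- simulate ---------------------------------------------------------------
  run_stage("simulate", function(d) {
    map <- generate_layout(scr)
    write_table_csv(map, file.path(d, "plate_map.csv"))
    for (m in config$modalities)
      write_table_csv(plate_effects(scr, m),
                      file.path(d, sprintf("plate_effects_%s.csv", m)))
    feats <- generate_feature_table(scr, map)
    write_table_csv(feats, file.path(d, "feature_table.csv"))
    write_table_csv(attr(feats, "plate_truth"),
                    file.path(d, "plate_truth.csv"))
    write_screen_config(scr, file.path(d, "screen_config.yaml"))
  })
  map <- read_plate_map(file.path(dirs[["simulate"]], "plate_map.csv"), scr)

  # -- preprocess -------------------------------------------------------------
  run_stage("preprocess", function(d) {
    for (m in config$modalities) {
      ds <- build_image_dataset(map, scr, m, config$normalization,
                                kernel_frac = config$kernel_frac)
      saveRDS(ds, file.path(d, sprintf("dataset_%s.rds", m)))
    }
    feats <- read_table_csv(file.path(dirs[["simulate"]], "feature_table.csv"))
    write_table_csv(normalize_features_dmso(feats),
                    file.path(d, "feature_table_norm.csv"))
  })

  # -- split ------------------------------------------------------------------
  run_stage("split", function(d) {
    sp <- make_splits(map, config$n_splits, seed = mix_seed(config$seed, 2L))
    write_table_csv(sp$assignments, file.path(d, "assignments.csv"))
    write_table_csv(sp$dmso_wells, file.path(d, "dmso_wells.csv"))
  })
  read_split_set <- function() {
    structure(list(
      assignments = read_table_csv(file.path(dirs[["split"]],
                                             "assignments.csv")),
      dmso_wells = read_table_csv(file.path(dirs[["split"]],
                                            "dmso_wells.csv")),
      n_splits = config$n_splits, seed = mix_seed(config$seed, 2L)),
      class = "split_set")
  }

  # -- train ------------------------------------------------------------------
  run_stage("train", function(d) {
    sp <- read_split_set()
    feats <- read_table_csv(file.path(dirs[["preprocess"]],
                                      "feature_table_norm.csv"))
    for (k in seq_len(config$n_splits)) {
      for (m in config$modalities) {
        ds <- readRDS(file.path(dirs[["preprocess"]],
                                sprintf("dataset_%s.rds", m)))
        cfg <- config$cnn
        cfg$seed <- mix_seed(config$cnn$seed, k, match(m, c("BF", "FL")))
        model <- train_classifier(ds, sp, k, cfg)
        save_model_outputs(model, ds, sp, k, m, d)
      }
      cfg <- config$mlp
      cfg$seed <- mix_seed(config$mlp$seed, k)
      model <- train_feature_mlp(feats, sp, k, cfg)
      save_model_outputs(model, feats, sp, k, "CP", d)
    }
  })

  # -- evaluate ---------------------------------------------------------------
  run_stage("evaluate", function(d) {
    models <- c(config$modalities, "CP")
    per_split <- list()
    pooled <- list()
    for (m in models) {
      recs <- collect_predictions(dirs[["train"]], m, config$n_splits)
      pooled[[m]] <- recs
      for (k in seq_len(config$n_splits))
        per_split[[sprintf("%s_split%d", m, k)]] <-
          macro_f1(recs[recs$split == k, ])
      write_table_csv(pooled_per_class_f1(recs, config$n_splits),
                      file.path(d, sprintf("per_class_f1_%s.csv", m)))
      write_table_csv(compound_accuracy(recs),
                      file.path(d, sprintf("compound_accuracy_%s.csv", m)))
    }
    metrics <- list(normalization = config$normalization,
                    macro_f1 = per_split)
    if (length(models) == 3) {
      acc <- lapply(models, function(m)
        read_table_csv(file.path(d, sprintf("compound_accuracy_%s.csv", m))))
      # degenerate at very small scale when a model scores every compound
      # identically; record the reason instead of failing the run
      ag <- tryCatch(modality_agreement(acc[[1]], acc[[2]], acc[[3]]),
                     error = function(e) conditionMessage(e))
      metrics$agreement <- if (is.character(ag)) list(undefined = ag) else
        list(pearson_ab = ag$pearson_ab, pearson_ac = ag$pearson_ac,
             better_set = ag$better_set, worse_set = ag$worse_set)
    }
    write_metrics_json(metrics, file.path(d, "metrics.json"))
  })

  # -- profile ----------------------------------------------------------------
  run_stage("profile", function(d) {
    feats <- read_table_csv(file.path(dirs[["preprocess"]],
                                      "feature_table_norm.csv"))
    wells <- aggregate_sites_to_wells(feats)
    g <- grit(wells)
    write_table_csv(g, file.path(d, "grit.csv"))
    for (m in c(config$modalities, "CP")) {
      recs <- collect_predictions(dirs[["train"]], m, config$n_splits)
      recs$correct <- recs$pred == recs$truth
      recs <- dplyr::inner_join(recs, g[, c("plate_id", "well", "grit")],
                                by = c("plate_id", "well"))
      bins <- bin_accuracy_by_grit(recs$grit, recs$correct,
                                   min(config$n_bins, nrow(recs)))
      write_table_csv(bins, file.path(d, sprintf("grit_accuracy_%s.csv", m)))
      emb <- collect_embeddings(dirs[["train"]], m, config$n_splits)
      # sites whose embedding is identically zero carry no direction
      emb <- emb[rowSums(feature_matrix(emb)^2) > 0, , drop = FALSE]
      treated <- emb[emb$compound_id != "DMSO", ]
      cw <- cosine_within_across(treated, treated$moa)
      write_metrics_json(list(separation = cw$separation,
                              mean_within = mean(cw$within),
                              mean_across = mean(cw$across)),
                         file.path(d, sprintf("cosine_%s.json", m)))
      ctrl <- emb[emb$compound_id == "DMSO", ]
      pc <- plate_correlation_matrix(ctrl)
      write_table_csv(tibble::as_tibble(pc, rownames = "plate_id"),
                      file.path(d, sprintf("plate_correlation_%s.csv", m)))
    }
  })

  # -- match ------------------------------------------------------------------
  run_stage("match", function(d) {
    feats <- read_table_csv(file.path(dirs[["preprocess"]],
                                      "feature_table_norm.csv"))
    wells <- aggregate_sites_to_wells(feats)
    ctrl <- wells[wells$compound_id == "DMSO", ]
    sweep_res <- lapply(config$lambda_sweep, function(lam) {
      tr <- fit_sphering(ctrl, lam)
      sph <- predict(tr, wells[wells$compound_id != "DMSO", ])
      tibble::tibble(lambda = lam,
                     map = mean_average_precision(sph)$map)
    })
    sweep_tab <- dplyr::bind_rows(sweep_res)
    write_table_csv(sweep_tab, file.path(d, "map_sweep.csv"))
    tr <- fit_sphering(ctrl, config$map_lambda)
    sph <- predict(tr, wells[wells$compound_id != "DMSO", ])
    mres <- mean_average_precision(sph)
    g <- read_table_csv(file.path(dirs[["profile"]], "grit.csv"))
    ap <- dplyr::inner_join(mres$ap, g[, c("plate_id", "well", "grit")],
                            by = c("plate_id", "well"))
    nb <- min(config$n_bins, sum(is.finite(ap$grit)))
    bins <- dplyr::summarise(
      dplyr::group_by(ap, bin = dplyr::ntile(.data$grit, nb)),
      n = dplyr::n(), mean_grit = mean(.data$grit), mean_ap = mean(.data$ap),
      .groups = "drop")
    write_table_csv(bins, file.path(d, "map_by_grit.csv"))
    write_metrics_json(list(map_lambda = config$map_lambda, map = mres$map),
                       file.path(d, "map.json"))
  })

  # -- manifest ---------------------------------------------------------------
  files <- list.files(run_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("moabench")),
    seed = config$seed,
    stage_seeds = list(layout = scr$seed, split = mix_seed(config$seed, 2L),
                       cnn = config$cnn$seed, mlp = config$mlp$seed),
    normalization = config$normalization,
    stages = status,
    checksums = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  write_metrics_json(manifest, file.path(run_dir, "manifest.json"))
  invisible(manifest)
}

save_model_outputs <- function(model, data, splits, k, tag, dir) {
  part <- partition_of(if (inherits(data, "image_dataset")) data$meta else data,
                       splits, k)
  idx <- which(!is.na(part) & part == "test")
  test_data <- if (inherits(data, "image_dataset"))
    subset_image_dataset(data, idx) else data[idx, , drop = FALSE]
  recs <- predict(model, test_data)
  recs$split <- k
  write_table_csv(recs, file.path(dir, sprintf("predictions_%s_split%d.csv",
                                               tag, k)))
  emb <- extract_features(model, test_data)
  emb$split <- k
  write_table_csv(emb, file.path(dir, sprintf("embeddings_%s_split%d.csv",
                                              tag, k)))
  write_table_csv(model$log, file.path(dir, sprintf("trainlog_%s_split%d.csv",
                                                    tag, k)))
  invisible(NULL)
}

collect_predictions <- function(train_dir, tag, n_splits) {
  dplyr::bind_rows(lapply(seq_len(n_splits), function(k)
    read_table_csv(file.path(train_dir,
                             sprintf("predictions_%s_split%d.csv", tag, k)),
                   required = c("truth", "pred"))))
}

collect_embeddings <- function(train_dir, tag, n_splits) {
  dplyr::bind_rows(lapply(seq_len(n_splits), function(k)
    read_table_csv(file.path(train_dir,
                             sprintf("embeddings_%s_split%d.csv", tag, k)))))
}
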