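test_that("default configuration encodes the ten-class, 231-compound assay", {
  counts <- default_moa_counts()
  expect_length(counts, 10)
  expect_identical(unname(counts),
                   c(18L, 20L, 33L, 24L, 21L, 21L, 23L, 19L, 32L, 20L))
  cfg <- screen_config()
  expect_equal(cfg$n_compounds, 231L)
  expect_equal(cfg$n_plates, 18L)
  expect_equal(cfg$fl_channels, 5L)
  expect_equal(cfg$bf_planes, 6L)
})

test_that("configuration validation rejects impossible screens", {
  expect_error(screen_config(n_plates = 0), "counts")
  expect_error(screen_config(moa_compound_counts = c(3, 4)), "named")
  expect_error(screen_config(moa_compound_counts = c(DMSO = 3)), "reserved")
  expect_error(screen_config(effect_size = -1), "nonnegative")
  expect_error(screen_config(n_plates = 3, biological_rep_plates = 2),
               "multiple")
})

test_that("configuration survives a YAML round trip", {
  cfg <- tiny_config(seed = 42, effect_size = c(C001 = 1, C002 = 0.5,
                                                C003 = 2, C004 = 0, C005 = 1,
                                                C006 = 3))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_screen_config(cfg, path)
  cfg2 <- read_screen_config(path)
  expect_equal(cfg2[order(names(cfg2))], cfg[order(names(cfg))])
})

test_that("layout places every compound six times across a plate pair", {
  map <- generate_layout(screen_config(seed = 5))
  treat <- map[map$compound_id != "DMSO", ]
  expect_equal(length(unique(treat$compound_id)), 231L)
  wells_per_compound <- table(treat$compound_id)
  expect_true(all(wells_per_compound == 6))
  recs <- site_records(map, screen_config(seed = 5))
  expect_true(all(table(recs$compound_id[recs$compound_id != "DMSO"]) == 30))
})

test_that("degenerate replication yields one well per compound", {
  cfg <- tiny_config(technical_reps = 1, biological_rep_plates = 1,
                     n_plates = 1)
  map <- generate_layout(cfg)
  treat <- map[map$compound_id != "DMSO", ]
  expect_true(all(table(treat$compound_id) == 1))
})

test_that("layout invariants hold across seeds", {
  for (seed in 1:15) {
    cfg <- tiny_config(seed = seed, moa_compound_counts = c(A = 4L, B = 5L,
                                                            C = 3L))
    map <- generate_layout(cfg)
    # no well double-booked
    expect_false(anyDuplicated(map[, c("plate_id", "well")]) > 0)
    treat <- map[map$compound_id != "DMSO", ]
    per_plate <- table(treat$compound_id, treat$plate_id)
    expect_true(all(per_plate %in% c(0L, cfg$technical_reps)))
    # biological replicates sit at different coordinates
    by_cmp <- split(treat, treat$compound_id)
    for (b in by_cmp) {
      plates <- split(b$well, b$plate_id)
      expect_length(plates, cfg$biological_rep_plates)
      expect_length(Reduce(intersect, plates), 0)
    }
    dmso <- map[map$compound_id == "DMSO", ]
    expect_true(all(table(dmso$plate_id) == cfg$dmso_wells_per_plate))
  }
})

test_that("layout generation is reproducible and errors on overflow", {
  cfg <- tiny_config(seed = 7)
  expect_identical(generate_layout(cfg), generate_layout(cfg))
  over <- tiny_config(wells_per_plate = 16,
                      moa_compound_counts = c(A = 10L, B = 10L))
  expect_error(generate_layout(over), "deficit")
})

test_that("null phenotype renders compound sites like DMSO sites", {
  cfg <- tiny_config(effect_size = 0, noise_sd = 0, plate_gain_sd = 0,
                     plate_offset_sd = 0, bf_illumination_amp = 0)
  map <- generate_layout(cfg)
  recs <- site_records(map, cfg)
  cmp <- recs[recs$compound_id != "DMSO", ][1, ]
  dmso <- recs[recs$compound_id == "DMSO" & recs$plate_id == cmp$plate_id, ][1, ]
  img_c <- render_site(cmp, cfg, "FL")
  img_d <- render_site(dmso, cfg, "FL")
  # same generative law: channel means and sds agree closely (different
  # random cell placements, so not pixel-identical)
  expect_equal(apply(img_c, 3, mean), apply(img_d, 3, mean), tolerance = 0.2)
  expect_equal(apply(img_c, 3, sd), apply(img_d, 3, sd), tolerance = 0.25)
})

test_that("brightfield planes carry a smooth illumination field; FL is flat", {
  cfg_on <- tiny_config(image_size = 48, noise_sd = 0,
                        bf_illumination_amp = 0.5)
  cfg_off <- tiny_config(image_size = 48, noise_sd = 0,
                         bf_illumination_amp = 0)
  map <- generate_layout(cfg_on)
  rec <- site_records(map, cfg_on)[1, ]
  # identical cell content, so the difference isolates the injected field
  field <- unclass(render_site(rec, cfg_on, "BF")) -
    unclass(render_site(rec, cfg_off, "BF"))
  rm_field <- rowMeans(field[, , 1])
  expect_gt(diff(range(field[, , 1])), 0.1)
  # smooth: adjacent-pixel steps are a small fraction of the field's range
  expect_lt(max(abs(diff(field[, , 1][, 24]))), 0.1 * diff(range(field[, , 1])))
  # FL rendering carries no illumination field at all
  expect_equal(unclass(render_site(rec, cfg_on, "FL")),
               unclass(render_site(rec, cfg_off, "FL")))
})

test_that("plate nuisance parameters are shared within and differ between plates", {
  cfg <- tiny_config()
  eff <- plate_effects(cfg, "FL")
  expect_equal(nrow(eff), cfg$n_plates * cfg$fl_channels)
  g1 <- eff$gain[eff$plate_id == "P01"]
  g2 <- eff$gain[eff$plate_id == "P02"]
  expect_false(isTRUE(all.equal(g1, g2)))
  # rendering twice within a plate uses the identical parameters
  expect_identical(plate_effects(cfg, "FL"), plate_effects(cfg, "FL"))
})

test_that("site rendering is deterministic per identity", {
  cfg <- tiny_config()
  map <- generate_layout(cfg)
  rec <- site_records(map, cfg)[3, ]
  expect_identical(render_site(rec, cfg, "BF"), render_site(rec, cfg, "BF"))
})

test_that("null-effect feature tables have indistinguishable class means", {
  cfg <- tiny_config(effect_size = 0, plate_offset_sd = 0, n_features = 6,
                     sites_per_well = 3, moa_compound_counts = c(A = 4L, B = 4L))
  feats <- generate_feature_table(cfg)
  fm <- feature_matrix(feats)
  mA <- colMeans(fm[feats$moa == "A", ])
  mB <- colMeans(fm[feats$moa == "B", ])
  n_eff <- min(sum(feats$moa == "A"), sum(feats$moa == "B"))
  # class-mean gap within a few standard errors of zero
  expect_lt(max(abs(mA - mB)), 5 * cfg$feature_noise_sd / sqrt(n_eff))
})

test_that("strong effect with low noise separates classes in cosine space", {
  cfg <- tiny_config(effect_size = 30, plate_offset_sd = 0, noise_sd = 0,
                     feature_noise_sd = 1e-3, n_features = 12,
                     compound_offset_frac = 0,
                     moa_compound_counts = c(A = 3L, B = 3L))
  feats <- generate_feature_table(cfg)
  treated <- feats[feats$compound_id != "DMSO", ]
  cw <- cosine_within_across(treated, treated$moa)
  expect_gt(min(cw$within), 0.99)
  expect_lt(max(abs(cw$across)), 0.01)
})

test_that("plate offsets make DMSO profiles cluster by plate", {
  cfg <- tiny_config(n_plates = 4, biological_rep_plates = 2,
                     plate_offset_sd = 1, feature_noise_sd = 0.3,
                     sites_per_well = 2, dmso_wells_per_plate = 10,
                     n_features = 12)
  feats <- generate_feature_table(cfg)
  dmso <- aggregate_sites_to_wells(feats[feats$compound_id == "DMSO", ])
  sil <- silhouette_width(feature_matrix(dmso), dmso$plate_id)
  expect_gt(sil, 0)
  # cross-check against the reference implementation
  ref <- cluster::silhouette(as.integer(factor(dmso$plate_id)),
                             dist(feature_matrix(dmso)))
  expect_equal(sil, mean(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("injected effect size is monotonically recoverable from features", {
  gaps <- vapply(c(0, 0.5, 1, 2, 4), function(e) {
    cfg <- tiny_config(effect_size = e, plate_offset_sd = 0,
                       feature_noise_sd = 0.5, n_features = 10,
                       moa_compound_counts = c(A = 4L, B = 4L), seed = 11)
    feats <- generate_feature_table(cfg)
    fm <- feature_matrix(feats)
    sqrt(sum((colMeans(fm[feats$moa == "A", ]) -
                colMeans(fm[feats$moa == "B", ]))^2))
  }, numeric(1))
  expect_true(all(diff(gaps) >= 0))
})

test_that("feature generation is bit-reproducible", {
  cfg <- tiny_config(seed = 99)
  expect_identical(generate_feature_table(cfg), generate_feature_table(cfg))
})
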