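test_that("site-to-well aggregation is a group-by mean", {
  df <- tibble::tibble(plate_id = "P01", well = c("A01", "A01", "B01"),
                       compound_id = c("C1", "C1", "C2"), moa = "A",
                       f1 = c(1, 3, 7), f2 = c(3, 5, 2))
  w <- aggregate_sites_to_wells(df)
  expect_equal(w$f1[w$well == "A01"], 2)
  expect_equal(w$f2[w$well == "A01"], 4)
  expect_equal(w$f1[w$well == "B01"], 7) # single-site well: identity
  # shuffled input, brute-force oracle
  withr::with_seed(5, {
    big <- tibble::tibble(
      plate_id = sample(c("P01", "P02"), 60, TRUE),
      well = sample(c("A01", "B03", "C05"), 60, TRUE),
      compound_id = "C1", moa = "A",
      f1 = rnorm(60), f2 = rnorm(60), f3 = rnorm(60))
  })
  w2 <- aggregate_sites_to_wells(big[sample(nrow(big)), ])
  ref <- bf_well_means(as.data.frame(big), c("f1", "f2", "f3"))
  merged <- merge(as.data.frame(w2), ref, by = c("plate_id", "well"))
  expect_equal(merged$f1.x, merged$f1.y, tolerance = 1e-12)
  expect_equal(merged$f3.x, merged$f3.y, tolerance = 1e-12)
  expect_error(aggregate_sites_to_wells(dplyr::select(df, -well)), "missing")
})

test_that("grit matches its defining formula on random profiles", {
  withr::with_seed(11, {
    x <- matrix(rnorm(20 * 8), 20, 8)
  })
  prof <- well_tbl(x, compound = rep(c("DMSO", "C1", "C2", "C3"), each = 5),
                   moa = rep(c("DMSO", "A", "A", "B"), each = 5))
  g <- grit(prof)
  cc <- cor(t(x))
  for (i in which(prof$compound_id != "DMSO")) {
    reps <- setdiff(which(prof$compound_id == prof$compound_id[i]), i)
    ctrl <- which(prof$compound_id == "DMSO")
    expected <- mean((cc[i, reps] - mean(cc[i, ctrl])) / sd(cc[i, ctrl]))
    expect_equal(g$grit[g$well == prof$well[i]], expected, tolerance = 1e-12)
  }
})

test_that("grit is near zero for controls-like replicates and large for tight ones", {
  withr::with_seed(12, {
    noise <- matrix(rnorm(12 * 30), 12, 30)
    tight <- matrix(rep(rnorm(30), 4), 4, 30, byrow = TRUE) +
      matrix(rnorm(4 * 30, 0, 0.01), 4, 30)
  })
  prof <- well_tbl(rbind(noise, tight),
                   compound = rep(c("DMSO", "C1"), c(12, 4)),
                   moa = rep(c("DMSO", "A"), c(12, 4)))
  g <- grit(prof)
  expect_true(all(g$grit > 5)) # replicates at r ~ 1 vs control correlations ~ 0
  # pure-noise "replicates" have grit centred near zero
  prof2 <- well_tbl(noise, compound = rep(c("DMSO", "C1"), each = 6),
                    moa = rep(c("DMSO", "A"), each = 6))
  g2 <- grit(prof2)
  expect_lt(mean(abs(g2$grit)), 2)
})

test_that("grit is invariant to feature-wise affine rescaling", {
  withr::with_seed(13, {
    x <- matrix(rnorm(15 * 10), 15, 10)
  })
  cmp <- rep(c("DMSO", "C1", "C2"), each = 5)
  prof <- well_tbl(x, compound = cmp, moa = cmp)
  scaled <- well_tbl(x * 7 - 2, compound = cmp, moa = cmp)
  expect_equal(grit(prof)$grit, grit(scaled)$grit, tolerance = 1e-10)
})

test_that("grit reports reasons for unscorable profiles", {
  withr::with_seed(14, {
    x <- matrix(rnorm(6 * 8), 6, 8)
  })
  prof <- well_tbl(x, compound = c("DMSO", "DMSO", "C1", "C2", "C2", "C2"),
                   moa = c("DMSO", "DMSO", "A", "B", "B", "B"))
  g <- grit(prof)
  expect_true(is.na(g$grit[g$compound_id == "C1"]))
  expect_match(g$reason[g$compound_id == "C1"], "singleton")
  expect_true(all(is.finite(g$grit[g$compound_id == "C2"])))
  expect_error(grit(prof[3:6, ]), "control")
})

test_that("pooled control statistics give a shared normalization", {
  withr::with_seed(15, {
    x <- matrix(rnorm(12 * 9), 12, 9)
  })
  cmp <- rep(c("DMSO", "C1"), each = 6)
  prof <- well_tbl(x, compound = cmp, moa = cmp)
  g <- grit(prof, control_stats = "pooled")
  cc <- cor(t(x))
  pool <- cc[1:6, 1:6][upper.tri(diag(6))]
  i <- 7
  reps <- 8:12
  expected <- mean((cc[i, reps] - mean(pool)) / sd(pool))
  expect_equal(g$grit[1], expected, tolerance = 1e-12)
})

test_that("grit binning splits samples into ordered equal-count bins", {
  g <- c(10, 2, 7, 1, 9, 3, 8, 5, 6, 4)
  correct <- g > 5
  b <- bin_accuracy_by_grit(g, correct, 10)
  expect_equal(b$mean_grit, sort(g))
  expect_equal(b$n, rep(1L, 10))
  b2 <- bin_accuracy_by_grit(g, correct, 3)
  expect_equal(b2$n, c(4L, 3L, 3L)) # remainder to the lowest bins
  expect_true(all(b2$accuracy >= 0 & b2$accuracy <= 1))
  expect_equal(sum(b2$n), 10)
  expect_error(bin_accuracy_by_grit(g[1:3], correct[1:3], 10), "cannot fill")
})

test_that("sphering whitens the controls it was fitted on", {
  withr::with_seed(16, {
    d <- 6
    A <- matrix(rnorm(d * d), d)
    ctrl <- matrix(rnorm(400 * d), 400) %*% A
  })
  tr <- fit_sphering(ctrl, lambda = 1e-6)
  z <- predict(tr, ctrl)
  expect_lt(norm(cov(z) - diag(d), "F"), 0.01)
  expect_equal(tr$W, t(tr$W))
  expect_true(all(eigen(tr$W, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(fit_sphering(ctrl, lambda = 0), "lambda")
  expect_error(fit_sphering(ctrl[1, , drop = FALSE]), "two control")
})

test_that("strong regularization degenerates to centring plus uniform scaling", {
  withr::with_seed(17, {
    ctrl <- matrix(rnorm(100 * 5), 100)
    q <- matrix(rnorm(20 * 5), 20)
  })
  tr <- fit_sphering(ctrl, lambda = 1e8)
  z <- predict(tr, q)
  centred <- sweep(q, 2, colMeans(ctrl))
  # cosine structure of centred profiles is preserved
  cz <- cosine_matrix(z)
  cc <- cosine_matrix(centred)
  expect_equal(cz, cc, tolerance = 1e-4)
})

test_that("average precision follows the precision-at-hit definition", {
  # ranking [hit, miss, hit] -> AP = (1/1 + 2/3)/2 = 5/6
  expect_equal(bf_average_precision(c(TRUE, FALSE, TRUE)), 5 / 6)
  x <- rbind(c(1, 0), c(0.9, 0.1), c(0, 1))
  prof <- well_tbl(x, compound = c("C1", "C2", "C3"), moa = c("A", "A", "B"))
  expect_warning(res <- mean_average_precision(prof), "single well")
  # B has one well -> dropped; remaining two A wells rank each other first
  expect_equal(res$map, 1)
})

test_that("separated label clusters give mAP 1 and match brute force", {
  onehot <- rbind(diag(3), diag(3))
  prof <- well_tbl(onehot + 1e-9, moa = rep(c("A", "B", "C"), 2))
  expect_equal(mean_average_precision(prof)$map, 1)
  withr::with_seed(18, {
    x <- matrix(rnorm(14 * 6), 14, 6)
    labs <- sample(c("A", "B", "C"), 14, replace = TRUE)
  })
  # ensure every label has at least two wells
  labs[1:6] <- rep(c("A", "B", "C"), 2)
  prof2 <- well_tbl(x, moa = labs)
  uid <- paste(prof2$plate_id, prof2$well, sep = ":")
  expect_equal(mean_average_precision(prof2)$map, bf_map(x, labs, uid),
               tolerance = 1e-12)
})

test_that("mAP is invariant under orthogonal rotation of all profiles", {
  withr::with_seed(19, {
    x <- matrix(rnorm(12 * 5), 12, 5)
    rot <- qr.Q(qr(matrix(rnorm(25), 5)))
  })
  labs <- rep(c("A", "B", "C"), each = 4)
  expect_equal(mean_average_precision(well_tbl(x, moa = labs))$map,
               mean_average_precision(well_tbl(x %*% rot, moa = labs))$map,
               tolerance = 1e-12)
})

test_that("random profiles score near the permutation-null mAP", {
  withr::with_seed(20, {
    x <- matrix(rnorm(30 * 8), 30, 8)
    labs <- rep(c("A", "B", "C"), each = 10)
    prof <- well_tbl(x, moa = labs)
    observed <- mean_average_precision(prof)$map
    null <- replicate(200, {
      prof$moa <- sample(prof$moa)
      mean_average_precision(prof)$map
    })
  })
  expect_gt(observed, quantile(null, 0.005))
  expect_lt(observed, quantile(null, 0.995))
})

test_that("cosine within/across matches an O(n^2) loop", {
  withr::with_seed(21, {
    x <- matrix(rnorm(50 * 7), 50, 7)
    labs <- sample(c("A", "B", "C", "D"), 50, replace = TRUE)
  })
  labs[1:8] <- rep(c("A", "B", "C", "D"), 2)
  got <- cosine_within_across(x, labs)
  ref <- bf_cosine_within_across(x, labs)
  expect_equal(sort(got$within), sort(ref$within), tolerance = 1e-12)
  expect_equal(sort(got$across), sort(ref$across), tolerance = 1e-12)
  expect_equal(got$separation, mean(ref$within) - mean(ref$across),
               tolerance = 1e-12)
  same <- matrix(1, 4, 3)
  expect_error(cosine_within_across(same * 0, rep(c("A", "B"), 2)), "zero")
  all_same <- cosine_within_across(same, rep(c("A", "B"), 2))
  expect_equal(unique(c(all_same$within, all_same$across)), 1)
})

test_that("plate correlation matrix flags degenerate plates and finds offsets", {
  f <- tibble::tibble(plate_id = rep(c("P01", "P02"), each = 4),
                      f1 = rep(c(1, 2), each = 4), f2 = rep(c(1, 2), each = 4),
                      f3 = rep(c(1, 2), each = 4))
  expect_warning(m <- plate_correlation_matrix(f), "constant")
  expect_true(all(is.na(m)))
  g <- tibble::tibble(plate_id = rep(c("P01", "P02"), each = 2),
                      f1 = c(1, 1, -1, -1), f2 = c(0, 0, 0, 0) + c(2, 2, 4, 4),
                      f3 = c(3, 3, 1, 1))
  m2 <- plate_correlation_matrix(g)
  expect_equal(diag(m2), c(P01 = 1, P02 = 1))
  expect_equal(m2["P01", "P02"], cor(c(1, 2, 3), c(-1, 4, 1)))
  # identical control features across plates give an all-ones matrix
  h <- tibble::tibble(plate_id = rep(c("P01", "P02", "P03"), each = 2),
                      f1 = rep(1:2, 3), f2 = rep(c(5, 0), 3),
                      f3 = rep(c(2, 8), 3))
  expect_equal(unname(plate_correlation_matrix(h)), matrix(1, 3, 3),
               ignore_attr = TRUE)
})

test_that("plate offsets widen the spread of off-plate correlations", {
  spread <- vapply(c(0, 1.5), function(off) {
    cfg <- tiny_config(n_plates = 6, biological_rep_plates = 2,
                       plate_offset_sd = off, feature_noise_sd = 0.3,
                       dmso_wells_per_plate = 6, n_features = 12, seed = 22)
    feats <- generate_feature_table(cfg)
    ctrl <- feats[feats$compound_id == "DMSO", ]
    m <- plate_correlation_matrix(ctrl)
    sd(m[upper.tri(m)])
  }, numeric(1))
  expect_gt(spread[2], spread[1])
})
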