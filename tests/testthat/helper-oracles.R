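# Independent brute-force reference implementations used to cross-check the
# package's metrics. These deliberately share no code with the package: plain
# loops and first-principles formulas.

bf_per_class_f1 <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  sapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  })
}

bf_macro_f1 <- function(truth, pred) mean(bf_per_class_f1(truth, pred))

bf_confusion <- function(truth, pred, classes) {
  m <- matrix(0, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(truth)) m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1
  m
}

bf_compound_accuracy <- function(compound, truth, pred) {
  keep <- compound != "DMSO"
  out <- data.frame()
  for (cmp in sort(unique(compound[keep]))) {
    i <- which(compound == cmp)
    out <- rbind(out, data.frame(compound_id = cmp,
                                 accuracy = mean(pred[i] == truth[i]),
                                 n_images = length(i)))
  }
  out
}

bf_cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

bf_cosine_within_across <- function(x, labels) {
  within <- c(); across <- c()
  n <- nrow(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- bf_cosine(x[i, ], x[j, ])
    if (labels[i] == labels[j]) within <- c(within, s)
    else across <- c(across, s)
  }
  list(within = within, across = across)
}

# AP of one reference against ranked candidates (hit = same label),
# precision averaged over the hit positions
bf_average_precision <- function(hits) {
  pos <- which(hits)
  mean(vapply(seq_along(pos), function(k) k / pos[k], numeric(1)))
}

bf_map <- function(x, labels, uid) {
  n <- nrow(x)
  ap <- numeric(n)
  for (i in seq_len(n)) {
    sims <- vapply(seq_len(n), function(j) bf_cosine(x[i, ], x[j, ]),
                   numeric(1))
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-sims[others], uid[others])]
    ap[i] <- bf_average_precision(labels[ord] == labels[i])
  }
  mean(ap)
}

bf_well_means <- function(df, fc) {
  key <- paste(df$plate_id, df$well)
  out <- NULL
  for (k in unique(key)) {
    rows <- df[key == k, ]
    out <- rbind(out, cbind(rows[1, c("plate_id", "well")],
                            t(colMeans(rows[, fc, drop = FALSE]))))
  }
  out
}

# random prediction-record instance for metric equivalence checks
random_records <- function(seed, n = 200, n_classes = 5, n_compounds = 12) {
  withr::with_seed(seed, {
    classes <- paste0("M", seq_len(n_classes))
    cmp <- paste0("C", sprintf("%02d", seq_len(n_compounds)))
    cmp_moa <- setNames(sample(classes, n_compounds, replace = TRUE), cmp)
    compound_id <- sample(cmp, n, replace = TRUE)
    tibble::tibble(
      compound_id = compound_id,
      truth = unname(cmp_moa[compound_id]),
      pred = sample(classes, n, replace = TRUE))
  })
}
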