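#' Per-class precision, recall and F1
#'
#' Classes absent from both truth and prediction are excluded; a class whose
#' precision-plus-recall denominator is zero gets F1 = 0 (the standard
#' convention, keeping the macro average defined).
#'
#' @param records tibble with `truth` and `pred` columns
#' @param classes optional fixed class vocabulary; defaults to the classes
#'   present in truth or prediction
#' @return tibble: `class`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `support`
#' @export
per_class_f1 <- function(records, classes = NULL) {
  assert_cols(records, c("truth", "pred"))
  if (!nrow(records)) stop("no prediction records")
  classes <- classes %||% sort(unique(c(records$truth, records$pred)))
  unknown <- setdiff(unique(c(records$truth, records$pred)), classes)
  if (length(unknown))
    stop(sprintf("label(s) outside the class vocabulary: %s",
                 paste(unknown, collapse = ", ")))
  out <- lapply(classes, function(cl) {
    tp <- sum(records$truth == cl & records$pred == cl)
    fp <- sum(records$truth != cl & records$pred == cl)
    fn <- sum(records$truth == cl & records$pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn, precision = prec,
                   recall = rec, f1 = f1, support = tp + fn)
  })
  dplyr::bind_rows(out)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of the per-class F1 scores, so every class counts equally
#' regardless of how many records it has. Classes absent from both truth and
#' prediction do not contribute.
#'
#' @inheritParams per_class_f1
#' @return scalar macro-F1 in `[0, 1]`
#' @export
macro_f1 <- function(records, classes = NULL) {
  mean(per_class_f1(records, classes)$f1)
}

#' Per-class F1 pooled over all test sets
#'
#' Pools the prediction records of several splits' test sets and computes
#' per-class F1 on the pooled records, plus a macro-average row -- the shape
#' of a combined per-MoA results table. Warns (and flags the result) if some
#' expected split is missing.
#'
#' @param records prediction records with `truth`, `pred` and `split` columns
#' @param n_splits number of splits expected to be present
#' @param classes optional fixed class vocabulary
#' @return per-class F1 tibble with a final `"macro"` row; attribute
#'   `"partial"` is `TRUE` when splits were missing
#' @export
pooled_per_class_f1 <- function(records, n_splits = 5, classes = NULL) {
  assert_cols(records, c("truth", "pred", "split"))
  present <- sort(unique(records$split))
  missing <- setdiff(seq_len(n_splits), present)
  partial <- length(missing) > 0
  if (partial)
    warning(sprintf("records cover splits {%s}; missing split(s): %s",
                    paste(present, collapse = ","),
                    paste(missing, collapse = ",")))
  tab <- per_class_f1(records, classes)
  macro <- tibble::tibble(class = "macro", tp = NA_integer_, fp = NA_integer_,
                          fn = NA_integer_, precision = NA_real_,
                          recall = NA_real_, f1 = mean(tab$f1),
                          support = sum(tab$support))
  out <- dplyr::bind_rows(tab, macro)
  attr(out, "partial") <- partial
  out
}

#' Confusion matrix
#'
#' @param records tibble with `truth` and `pred`
#' @param classes fixed class vocabulary (rows = truth, columns = prediction)
#' @param normalize row-normalize so each truth row sums to 1
#' @return square numeric matrix
#' @export
confusion_matrix <- function(records, classes = NULL, normalize = FALSE) {
  assert_cols(records, c("truth", "pred"))
  classes <- classes %||% sort(unique(c(records$truth, records$pred)))
  unknown <- setdiff(unique(c(records$truth, records$pred)), classes)
  if (length(unknown))
    stop(sprintf("label(s) outside the class vocabulary: %s",
                 paste(unknown, collapse = ", ")))
  m <- table(factor(records$truth, classes), factor(records$pred, classes))
  m <- unclass(m)
  names(dimnames(m)) <- c("truth", "pred")
  if (normalize) {
    rs <- rowSums(m)
    m <- m / ifelse(rs == 0, 1, rs)
  }
  m
}

#' Compound-level accuracy
#'
#' Fraction of each compound's test-set site images whose predicted class
#' equals the compound's MoA. DMSO is a control, not a compound, and is
#' excluded.
#'
#' @param records prediction records with `compound_id`, `truth`, `pred`
#' @return tibble: `compound_id`, `moa`, `accuracy`, `n_images`
#' @export
compound_accuracy <- function(records) {
  assert_cols(records, c("compound_id", "truth", "pred"))
  recs <- records[records$compound_id != "DMSO", ]
  if (!nrow(recs)) stop("no non-DMSO records; every compound needs test images")
  out <- dplyr::summarise(dplyr::group_by(recs, .data$compound_id,
                                          moa = .data$truth),
                          accuracy = mean(.data$pred == .data$truth),
                          n_images = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$compound_id)
}

#' Cross-modality agreement of compound accuracies
#'
#' Compares the compound-level accuracies of one model (`acc_a`, e.g.
#' brightfield) against two references (`acc_b`, `acc_c`, e.g. fluorescence
#' and a feature-based benchmark): Pearson correlations plus the compounds
#' falling in the "consistently better" box (accuracy at least `hi` for A
#' and at most `lo` for both references) and the "consistently worse" box
#' (the reverse).
#'
#' @param acc_a,acc_b,acc_c [compound_accuracy()] tables over the same
#'   compound set
#' @param hi,lo accuracy thresholds of the agreement boxes
#' @return list: `pearson_ab`, `pearson_ac`, `better_set`, `worse_set`,
#'   and the merged `table`
#' @export
modality_agreement <- function(acc_a, acc_b, acc_c, hi = 0.6, lo = 0.4) {
  for (x in list(acc_a, acc_b, acc_c)) assert_cols(x, c("compound_id", "accuracy"))
  if (!setequal(acc_a$compound_id, acc_b$compound_id) ||
      !setequal(acc_a$compound_id, acc_c$compound_id))
    stop("the three accuracy tables must cover the same compound set")
  m <- dplyr::inner_join(
    dplyr::inner_join(acc_a[, c("compound_id", "accuracy")],
                      acc_b[, c("compound_id", "accuracy")],
                      by = "compound_id", suffix = c("_a", "_b")),
    dplyr::rename(acc_c[, c("compound_id", "accuracy")], accuracy_c = "accuracy"),
    by = "compound_id")
  if (sd(m$accuracy_a) == 0 || sd(m$accuracy_b) == 0 || sd(m$accuracy_c) == 0)
    stop("Pearson correlation undefined: an accuracy vector is constant")
  list(pearson_ab = cor(m$accuracy_a, m$accuracy_b),
       pearson_ac = cor(m$accuracy_a, m$accuracy_c),
       better_set = m$compound_id[m$accuracy_a >= hi & m$accuracy_b <= lo &
                                    m$accuracy_c <= lo],
       worse_set = m$compound_id[m$accuracy_a <= lo & m$accuracy_b >= hi &
                                   m$accuracy_c >= hi],
       table = m)
}
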