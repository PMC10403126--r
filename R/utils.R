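#' @importFrom stats cor cov rnorm runif sd setNames quantile
#' @importFrom utils modifyList head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a base seed and integer keys
#'
#' Deterministic integer mixing so that independent simulation streams
#' (layout, per-site rendering, per-plate nuisance parameters, training)
#' can be derived from one user-facing seed without sharing state.
#' Result is always in [0, 2^31 - 2].
#'
#' @param seed base integer seed
#' @param ... integer keys identifying the stream (e.g. plate, well, site)
#' @return a single integer seed
#' @keywords internal
mix_seed <- function(seed, ...) {
  keys <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in keys) {
    # LCG-style mixing; doubles stay < 2^53 so arithmetic is exact
    s <- (s * 69069 + (as.double(k) + 1) * 30402457) %% 2147483647
    s <- (s * 40692 + 1103515245) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Pairwise cosine similarity
#'
#' @param x numeric matrix, one observation per row
#' @return symmetric matrix of cosine similarities between rows
#' @keywords internal
cosine_matrix <- function(x) {
  x <- as.matrix(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("cosine similarity undefined for zero vectors")
  xn <- x / nrm
  tcrossprod(xn)
}

#' Mean silhouette width of a grouping
#'
#' Plain euclidean silhouette used as a batch-effect diagnostic: how strongly
#' control profiles cluster by plate. Positive values mean profiles sit closer
#' to their own plate than to the nearest other plate.
#'
#' @param x numeric matrix of profiles (rows)
#' @param groups grouping factor (e.g. plate id), length `nrow(x)`
#' @return mean silhouette width (scalar)
#' @export
silhouette_width <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (nrow(x) != length(groups)) stop("`groups` must match rows of `x`")
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  d <- as.matrix(stats::dist(x))
  lev <- levels(droplevels(groups))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- groups == groups[i]
    if (sum(own) < 2) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(lev[lev != groups[i]],
                    function(g) mean(d[i, groups == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# stable well identifier, e.g. "P03:B07"
well_uid <- function(plate_id, well) paste(plate_id, well, sep = ":")

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

feature_cols <- function(df) grep("^f[0-9]+$", names(df), value = TRUE)

feature_matrix <- function(df) {
  fc <- feature_cols(df)
  if (!length(fc)) stop("no feature columns (named f1, f2, ...) found")
  as.matrix(df[, fc, drop = FALSE])
}
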