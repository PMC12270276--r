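#' @keywords internal
"_PACKAGE"

# Shared small helpers. Kept internal; user-facing contracts live in the
# module files.

stop_gbl <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_gbl(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_gbl(sprintf("'%s' must be TRUE or FALSE", name))
  x
}

# Column-wise z-scoring with an informative error on zero variance.
zscore_cols <- function(m, context = "column") {
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad))
    stop_gbl(sprintf("zero-variance %s(s): %s", context,
                     paste(colnames(m)[bad] %||% bad, collapse = ", ")))
  sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Midranks, the convention used throughout (Spearman, Mann-Whitney, ReHo).
midrank <- function(x) rank(x, ties.method = "average")

# Expand a covariate table into a numeric design matrix (no intercept
# column; the intercept is added by the callers). Characters/factors become
# treatment-coded indicators. Returns NULL for an empty covariate set.
expand_covariates <- function(covariates) {
  if (is.null(covariates) || NCOL(covariates) == 0L) return(NULL)
  covariates <- as.data.frame(covariates)
  for (j in seq_along(covariates)) {
    if (is.character(covariates[[j]]) || is.logical(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])
  }
  mm <- stats::model.matrix(~ ., data = covariates)
  mm[, -1L, drop = FALSE]
}

# Least-squares residuals of y on [1 | X]; errors on rank deficiency with
# the offending column names.
residualize <- function(y, design, what = "covariate") {
  X <- cbind(`(Intercept)` = 1, design)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop_gbl("rank-deficient ", what, " design; collinear column(s): ",
             paste(dropped, collapse = ", "))
  }
  qr.resid(qr_x, y)
}

# Deterministic child seeds below 2^31, derived from a user seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435 + 97 * as.numeric(k)) %% 2147483647)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
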