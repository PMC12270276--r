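#' First PLSR component for a univariate response
#'
#' Finds the unit-norm metabolite weight vector whose weighted sum of
#' metabolites (the per-subject metabolite score) has maximum covariance
#' with the microbial abundance. For a univariate response this component
#' has a closed form: the normalized cross-covariance vector
#' `cov(column_j, microbe) / ||.||`, which is also the leading singular
#' direction of the cross-covariance -- no iterative NIPALS is needed and
#' the result is exactly reproducible. The sign is fixed so that
#' `cov(scores, microbe) >= 0`.
#'
#' @param z_matrix numeric matrix, subjects x metabolites, columns already
#'   standardized (see [process_metabolome()]).
#' @param microbe numeric vector of per-subject microbial relative
#'   abundance (non-constant).
#' @return List with `weights` (unit norm) and `scores` (`z_matrix %*% weights`).
#' @export
plsr_first_component <- function(z_matrix, microbe) {
  z_matrix <- as.matrix(z_matrix)
  n <- nrow(z_matrix)
  if (n < 3L) stop_gbl("need >= 3 subjects")
  if (length(microbe) != n) stop_gbl("microbe length must match rows of z_matrix")
  if (stats::sd(microbe) == 0) stop_gbl("microbe vector is constant")
  mc <- microbe - mean(microbe)
  cc <- crossprod(z_matrix, mc) / (n - 1)   # per-column cross-covariance
  nrm <- sqrt(sum(cc^2))
  if (nrm == 0) stop_gbl("all metabolite columns are uncorrelated and constant-covariance zero")
  w <- as.numeric(cc / nrm)
  scores <- as.numeric(z_matrix %*% w)
  # cov(scores, microbe) = ||cc|| >= 0 by construction; keep the convention
  # explicit in case of numerically negative zero
  if (sum(scores * mc) < 0) { w <- -w; scores <- -scores }
  names(w) <- colnames(z_matrix)
  list(weights = w, scores = scores)
}

#' Overall microbe-metabolome association
#'
#' Pearson correlation between the microbial abundance and the PLSR
#' metabolite scores; under the sign convention of
#' [plsr_first_component()] it is non-negative.
#'
#' @param scores per-subject metabolite scores.
#' @param microbe per-subject microbial abundance.
#' @return A single correlation coefficient.
#' @export
overall_association <- function(scores, microbe) {
  if (stats::sd(scores) == 0 || stats::sd(microbe) == 0)
    stop_gbl("zero variance in scores or microbe")
  stats::cor(scores, microbe)
}

#' Permutation test of the overall association
#'
#' The subject labels of the microbial abundance are randomly shuffled
#' `n_perm` times (default 5000); the full first-component fit and the
#' overall correlation are recomputed for each shuffle. The one-sided
#' p-value on the sign-fixed correlation uses the add-one rule
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`, so `p > 0` always and
#' the smallest achievable value at 5000 shuffles is 1/5001 (~0.0002).
#'
#' @inheritParams plsr_first_component
#' @param n_perm number of random shuffles.
#' @param seed integer seed; the test is deterministic given the seed.
#' @param perms optional integer matrix (`n_perm` x n subjects), one
#'   permutation per row, overriding the random shuffles (used e.g. for
#'   exhaustive enumeration at small n).
#' @return List with `p_perm`, `r_obs`, `r_perm` (null draws), `n_perm`.
#' @export
permutation_test <- function(z_matrix, microbe, n_perm = 5000, seed = 1,
                             perms = NULL) {
  z_matrix <- as.matrix(z_matrix)
  n <- nrow(z_matrix)
  fit <- plsr_first_component(z_matrix, microbe)
  r_obs <- overall_association(fit$scores, microbe)
  if (is.null(perms)) {
    n_perm <- check_count(n_perm, "n_perm")
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(n)))
  } else {
    perms <- as.matrix(perms)
    if (ncol(perms) != n) stop_gbl("perms must have one column per subject")
    n_perm <- nrow(perms)
  }
  r_perm <- vapply(seq_len(n_perm), function(i) {
    mp <- microbe[perms[i, ]]
    f <- plsr_first_component(z_matrix, mp)
    overall_association(f$scores, mp)
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  list(p_perm = p, r_obs = r_obs, r_perm = r_perm, n_perm = n_perm)
}

#' Contribution loadings
#'
#' The contribution of each metabolite is its loading: the Pearson
#' correlation between that metabolite's column and the metabolite score
#' vector. Constant columns cannot be correlated; they get loading 0 and
#' are reported in the `flagged_constant` attribute.
#'
#' @inheritParams plsr_first_component
#' @param scores per-subject metabolite scores from [plsr_first_component()].
#' @return Named numeric vector of loadings in `[-1, 1]`.
#' @export
contribution_loadings <- function(z_matrix, scores) {
  z_matrix <- as.matrix(z_matrix)
  if (stats::sd(scores) == 0) stop_gbl("scores are constant")
  sdv <- apply(z_matrix, 2L, stats::sd)
  const <- sdv == 0
  loadings <- rep(0, ncol(z_matrix))
  loadings[!const] <- as.numeric(stats::cor(z_matrix[, !const, drop = FALSE],
                                            scores))
  names(loadings) <- colnames(z_matrix)
  if (any(const)) attr(loadings, "flagged_constant") <- colnames(z_matrix)[const]
  loadings
}

#' Select the top-20% positive and negative loading sets
#'
#' The strongly contributing metabolites: with `p` metabolites and
#' `k = floor(0.20 p)`, the `k` most-positive loadings form the positive
#' set and the `k` most-negative form the negative set. If fewer than `k`
#' loadings carry the required sign the set is truncated to those that do
#' (with a warning). Ties are broken by metabolite identifier order, so
#' selection is deterministic.
#'
#' @param loadings named loading vector from [contribution_loadings()].
#' @param fraction selected fraction per sign (default 0.20).
#' @return List with character vectors `plsr_pos` and `plsr_neg`.
#' @export
select_top20 <- function(loadings, fraction = 0.20) {
  p <- length(loadings)
  if (p < 5L) stop_gbl("need >= 5 metabolites to select the top 20%")
  k <- floor(fraction * p)
  if (k < 1L) stop_gbl("selection fraction yields an empty set")
  ids <- names(loadings) %||% as.character(seq_len(p))
  ord_desc <- order(-loadings, ids)   # ties by identifier order
  ord_asc <- order(loadings, ids)
  pos_pool <- ord_desc[loadings[ord_desc] > 0]
  neg_pool <- ord_asc[loadings[ord_asc] < 0]
  if (length(pos_pool) < k)
    warning(sprintf("only %d positive loadings available for a quota of %d",
                    length(pos_pool), k))
  if (length(neg_pool) < k)
    warning(sprintf("only %d negative loadings available for a quota of %d",
                    length(neg_pool), k))
  list(plsr_pos = ids[utils::head(pos_pool, k)],
       plsr_neg = ids[utils::head(neg_pool, k)])
}

#' Full microbe-metabolome PLSR linkage
#'
#' Runs the first-component fit, the overall correlation, the permutation
#' null, the contribution loadings and the top-20% selection for one ion
#' mode.
#'
#' @param processed a `processed_metabolome` (or a bare z-scored matrix).
#' @param microbe per-subject microbial abundance, aligned with the rows.
#' @param n_perm,seed see [permutation_test()].
#' @param fraction see [select_top20()].
#' @return An object of class `plsr_result` with fields `weights`,
#'   `scores`, `overall_r`, `p_perm`, `n_perm`, `loadings`, `plsr_pos`,
#'   `plsr_neg`, `ion_mode`.
#' @export
plsr_link <- function(processed, microbe, n_perm = 5000, seed = 1,
                      fraction = 0.20) {
  z <- if (inherits(processed, "processed_metabolome")) processed$z_matrix
       else as.matrix(processed)
  ion_mode <- if (inherits(processed, "processed_metabolome"))
    processed$ion_mode else NA_character_
  fit <- plsr_first_component(z, microbe)
  r <- overall_association(fit$scores, microbe)
  perm <- permutation_test(z, microbe, n_perm = n_perm, seed = seed)
  loadings <- contribution_loadings(z, fit$scores)
  sel <- select_top20(loadings, fraction)
  structure(list(weights = fit$weights, scores = fit$scores, overall_r = r,
                 p_perm = perm$p_perm, n_perm = perm$n_perm,
                 loadings = loadings, plsr_pos = sel$plsr_pos,
                 plsr_neg = sel$plsr_neg, ion_mode = ion_mode),
            class = "plsr_result")
}

#' @export
print.plsr_result <- function(x, ...) {
  cat(sprintf("plsr_result (%s mode): overall r = %.3f, permutation P = %.4g (%d shuffles)\n",
              x$ion_mode, x$overall_r, x$p_perm, x$n_perm))
  cat(sprintf("  %d metabolites; |PLSR+| = %d, |PLSR-| = %d\n",
              length(x$loadings), length(x$plsr_pos), length(x$plsr_neg)))
  invisible(x)
}

#' Write the ranked loading table of a PLSR result
#'
#' @param result a `plsr_result`.
#' @param path output TSV path.
#' @return Invisibly, the written data.frame (metabolite, loading, rank,
#'   selected set).
#' @export
write_loading_table <- function(result, path) {
  stopifnot(inherits(result, "plsr_result"))
  ord <- order(-result$loadings, names(result$loadings))
  df <- data.frame(metabolite_id = names(result$loadings)[ord],
                   loading = as.numeric(result$loadings[ord]),
                   rank = seq_along(ord),
                   set = ifelse(names(result$loadings)[ord] %in% result$plsr_pos,
                                "PLSR+",
                         ifelse(names(result$loadings)[ord] %in% result$plsr_neg,
                                "PLSR-", "")),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(df)
}
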