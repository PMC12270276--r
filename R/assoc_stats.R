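#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Compares the location of two groups (e.g. patient vs control microbial
#' relative abundance) without distributional assumptions. `U` is computed
#' from summed midranks of group A; the z-value uses the tie-corrected
#' variance and a 0.5 continuity correction toward the null; the two-sided
#' p comes from the normal approximation. For very small samples
#' (`n1 + n2 <= 12`) an exact mode enumerates all group assignments of
#' the observed values instead.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @param exact `"never"`, `"always"`, or `"auto"` (exact when
#'   `n1 + n2 <= 12`).
#' @return An object of class `group_test_result`: `u_statistic` (for
#'   group A), `z_value`, `p_value`, `direction` (sign of the A-minus-B
#'   location shift), `method`.
#' @export
mann_whitney <- function(group_a, group_b, exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 1L || n2 < 1L) stop_gbl("both groups must be non-empty")
  combined <- c(group_a, group_b)
  rk <- midrank(combined)
  r1 <- sum(rk[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  direction <- sign(u - mu)
  do_exact <- exact == "always" || (exact == "auto" && nn <= 12L)
  if (do_exact) {
    # permutation distribution of U over all C(n1+n2, n1) assignments
    splits <- utils::combn(nn, n1)
    u_all <- apply(splits, 2L, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    sigma <- stats::sd(u_all) * sqrt((ncol(splits) - 1) / ncol(splits))
    z <- if (sigma == 0) 0 else (u - mu) / sigma
    method <- "exact"
  } else {
    ties <- table(combined)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    var_u <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (var_u <= 0) {          # all observations tied
      z <- 0; p <- 1
    } else {
      z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(var_u)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(list(u_statistic = u, z_value = z, p_value = p,
                 direction = direction, n1 = n1, n2 = n2, method = method),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d/%d), z = %.3f, two-sided P = %.4g [%s]\n",
              x$u_statistic, x$n1, x$n2, x$z_value, x$p_value, x$method))
  invisible(x)
}

#' Partial Spearman correlation
#'
#' Rank correlation between `x` and `y` after removing the linear effect
#' of nuisance covariates from both rank vectors: `x` and `y` are
#' midrank-transformed, categorical covariates are expanded to indicator
#' columns, both rank vectors are residualized on the covariates (with
#' intercept) by least squares, and the partial coefficient is the Pearson
#' correlation of the residuals. The p-value uses the t distribution with
#' `n - k - 2` degrees of freedom (`k` = expanded covariate columns).
#' Rows with any missing value are dropped (complete cases), with the
#' exclusion count reported.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame of nuisance covariates (numeric
#'   or categorical); `NULL` reduces to the plain Spearman correlation.
#' @return An object of class `partial_corr_result`: `pr`, `p_value`,
#'   `n_effective`, `n_excluded`, `df`, `covariates` (names).
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  df_in <- data.frame(.x = x, .y = y)
  if (!is.null(covariates)) df_in <- cbind(df_in, as.data.frame(covariates))
  cc <- stats::complete.cases(df_in)
  n_excluded <- sum(!cc)
  df_in <- df_in[cc, , drop = FALSE]
  n <- nrow(df_in)
  design <- expand_covariates(df_in[, setdiff(names(df_in), c(".x", ".y")),
                                    drop = FALSE])
  k <- if (is.null(design)) 0L else ncol(design)
  if (n <= k + 2L) stop_gbl("need n > number of covariate columns + 2")
  rx <- midrank(df_in$.x); ry <- midrank(df_in$.y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop_gbl("x or y is constant; Spearman correlation undefined")
  if (!is.null(design)) {
    rx <- residualize(rx, design)
    ry <- residualize(ry, design)
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  vx <- sum(rx^2); vy <- sum(ry^2)
  if (vx < 1e-12 * n || vy < 1e-12 * n)
    stop_gbl("zero residual variance after adjusting for covariates")
  pr <- sum(rx * ry) / sqrt(vx * vy)
  dfree <- n - k - 2L
  tval <- pr * sqrt(dfree / max(1 - pr^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), dfree)
  structure(list(pr = pr, p_value = p, n_effective = n,
                 n_excluded = n_excluded, df = dfree,
                 covariates = if (is.null(design)) character() else colnames(design)),
            class = "partial_corr_result")
}

#' @export
print.partial_corr_result <- function(x, ...) {
  cat(sprintf("partial Spearman pr = %.3f, P = %.4g (n = %d, %d covariate column(s))\n",
              x$pr, x$p_value, x$n_effective, length(x$covariates)))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_(j >= i) m p_(j) / j`, capped at
#' 1 and mapped back to the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_gbl("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(m * p_values[ord] / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Covariate-adjusted correlation screen with FDR
#'
#' Computes the partial Spearman correlation of every feature x target
#' pair (e.g. metabolites x brain cluster means, or brain cluster means x
#' behaviors), then applies Benjamini-Hochberg FDR within the configured
#' family and flags pairs with `q < alpha`.
#'
#' @param features,targets data.frames of aligned per-subject columns.
#' @param covariates optional covariate data.frame (same rows).
#' @param family `"block"` (default: all pairs of this call form one
#'   family), `"per_feature"`, or `"per_target"`.
#' @param alpha FDR significance level (default 0.05).
#' @return data.frame with one row per pair: `feature`, `target`, `pr`,
#'   `p_raw`, `q_fdr`, `n_effective`, `significant`, `covariates`.
#' @export
correlation_screen <- function(features, targets, covariates = NULL,
                               family = c("block", "per_feature", "per_target"),
                               alpha = 0.05) {
  family <- match.arg(family)
  features <- as.data.frame(features); targets <- as.data.frame(targets)
  if (!ncol(features) || !ncol(targets)) stop_gbl("empty feature or target set")
  if (nrow(features) != nrow(targets))
    stop_gbl("features and targets must have aligned subject rows")
  grid <- expand.grid(feature = names(features), target = names(targets),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- partial_spearman(features[[grid$feature[i]]],
                          targets[[grid$target[i]]], covariates)
    data.frame(feature = grid$feature[i], target = grid$target[i],
               pr = r$pr, p_raw = r$p_value, n_effective = r$n_effective,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  fam <- switch(family, block = rep(1L, nrow(res)),
                per_feature = match(res$feature, unique(res$feature)),
                per_target = match(res$target, unique(res$target)))
  res$q_fdr <- NA_real_
  for (f in unique(fam))
    res$q_fdr[fam == f] <- fdr_adjust(res$p_raw[fam == f])
  res$significant <- res$q_fdr < alpha
  res$covariates <- paste(names(covariates %||% data.frame()), collapse = ",")
  res
}
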