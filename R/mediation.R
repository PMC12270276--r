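#' Point estimates of a single-mediator model
#'
#' The classic product-of-coefficients decomposition: three least-squares
#' fits, each including an intercept and the same nuisance covariates,
#'   M ~ X        (slope of X: path a)
#'   Y ~ X + M    (slope of M: path b; slope of X: direct effect c')
#'   Y ~ X        (slope of X: total effect c)
#' The indirect effect is `a * b`, and for OLS with identical covariate
#' sets the identity `c = a * b + c'` holds exactly.
#'
#' @param x,m,y per-subject treatment, mediator and outcome vectors.
#' @param covariates optional nuisance covariate data.frame.
#' @param standardize if `TRUE`, z-score x, m and y (on complete cases)
#'   before fitting; default `FALSE` (raw units).
#' @return An object of class `mediation_result` with `a`, `b`, `c`,
#'   `c_prime`, `indirect`, `n_effective`; CI fields are filled by
#'   [bootstrap_ci()] / [mediate()].
#' @export
fit_mediation <- function(x, m, y, covariates = NULL, standardize = FALSE) {
  df_in <- data.frame(.x = x, .m = m, .y = y)
  if (!is.null(covariates)) df_in <- cbind(df_in, as.data.frame(covariates))
  cc <- stats::complete.cases(df_in)
  df_in <- df_in[cc, , drop = FALSE]
  design <- expand_covariates(df_in[, setdiff(names(df_in), c(".x", ".m", ".y")),
                                    drop = FALSE])
  est <- mediation_paths(df_in$.x, df_in$.m, df_in$.y, design, standardize)
  structure(c(est, list(n_effective = nrow(df_in), n_excluded = sum(!cc),
                        standardize = standardize)),
            class = "mediation_result")
}

# Core path computation on clean numeric inputs; design is the expanded
# covariate matrix (or NULL). Kept free of data.frame overhead because the
# bootstrap calls it hundreds of thousands of times.
mediation_paths <- function(x, m, y, design, standardize = FALSE) {
  n <- length(x)
  k <- if (is.null(design)) 0L else ncol(design)
  if (n <= k + 3L) stop_gbl("need n > number of covariate columns + 3")
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0)
    stop_gbl("zero variance in x, m, or y")
  if (standardize) {
    x <- (x - mean(x)) / stats::sd(x)
    m <- (m - mean(m)) / stats::sd(m)
    y <- (y - mean(y)) / stats::sd(y)
  }
  base <- if (is.null(design)) matrix(1, n, 1) else cbind(1, design)
  X1 <- cbind(base, x)
  X2 <- cbind(base, x, m)
  q2 <- qr(X2)
  if (q2$rank < ncol(X2)) stop_gbl("rank-deficient mediation design")
  co2 <- qr.coef(q2, y)
  co1m <- qr.coef(qr(X1), m)
  co1y <- qr.coef(qr(X1), y)
  a <- unname(co1m[length(co1m)])
  c_total <- unname(co1y[length(co1y)])
  b <- unname(co2[length(co2)])
  c_prime <- unname(co2[length(co2) - 1L])
  list(a = a, b = b, c = c_total, c_prime = c_prime, indirect = a * b)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation: a = %.4f, b = %.4f, c' = %.4f, c = %.4f, indirect (a*b) = %.4f\n",
              x$a, x$b, x$c_prime, x$c, x$indirect))
  if (!is.null(x$ci_low))
    cat(sprintf("  bootstrap %g%% CI [%.4f, %.4f] (%d resamples)%s\n",
                100 * x$level, x$ci_low, x$ci_high, x$n_boot,
                if (isTRUE(x$significant)) " *significant*" else ""))
  invisible(x)
}

#' Bootstrap percentile CI for the indirect effect
#'
#' Subject rows are resampled with replacement `n_boot` times (default
#' 5000); the mediation model is refit on each resample and the CI is the
#' empirical percentile interval of the bootstrap indirect effects. The
#' indirect effect is declared significant when the CI excludes zero.
#' Degenerate resamples (rank-deficient or zero-variance) are redrawn,
#' with a redraw budget of `10 * n_boot`.
#'
#' @inheritParams fit_mediation
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param level confidence level, default 0.95.
#' @param seed integer seed; results are deterministic given the seed.
#' @return List with `ci_low`, `ci_high`, `significant`, `n_boot`,
#'   `boot_indirect` (the resampled effects).
#' @export
bootstrap_ci <- function(x, m, y, covariates = NULL, n_boot = 5000,
                         level = 0.95, seed = 1, standardize = FALSE) {
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  df_in <- data.frame(.x = x, .m = m, .y = y)
  if (!is.null(covariates)) df_in <- cbind(df_in, as.data.frame(covariates))
  df_in <- df_in[stats::complete.cases(df_in), , drop = FALSE]
  design <- expand_covariates(df_in[, setdiff(names(df_in), c(".x", ".m", ".y")),
                                    drop = FALSE])
  n <- nrow(df_in)
  set.seed(seed)
  boot <- numeric(n_boot)
  redraws <- 0L
  i <- 1L
  while (i <= n_boot) {
    ix <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(
      mediation_paths(df_in$.x[ix], df_in$.m[ix], df_in$.y[ix],
                      if (is.null(design)) NULL else design[ix, , drop = FALSE],
                      standardize),
      error = function(e) NULL)
    if (is.null(est)) {
      redraws <- redraws + 1L
      if (redraws > 10L * n_boot)
        stop_gbl("bootstrap redraw budget exceeded (degenerate resamples)")
      next
    }
    boot[i] <- est$indirect
    i <- i + 1L
  }
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 6))
  list(ci_low = ci[1], ci_high = ci[2],
       significant = ci[1] > 0 || ci[2] < 0,
       n_boot = n_boot, level = level, n_redraws = redraws,
       boot_indirect = boot)
}

#' Fit a mediation model with bootstrap inference
#'
#' Convenience wrapper combining [fit_mediation()] and [bootstrap_ci()].
#'
#' @inheritParams bootstrap_ci
#' @return A complete `mediation_result`.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 5000, level = 0.95,
                    seed = 1, standardize = FALSE) {
  fit <- fit_mediation(x, m, y, covariates, standardize)
  ci <- bootstrap_ci(x, m, y, covariates, n_boot = n_boot, level = level,
                     seed = seed, standardize = standardize)
  fit$ci_low <- ci$ci_low; fit$ci_high <- ci$ci_high
  fit$significant <- ci$significant; fit$n_boot <- ci$n_boot
  fit$level <- ci$level; fit$seed <- seed
  fit
}

#' Run mediation over a list of candidate (X, M, Y) triples
#'
#' Candidate triples are typically chained from [correlation_screen()]
#' results: a triple qualifies when its X-M pair and its M-Y pair were
#' both flagged significant. Results are ordered deterministically by
#' `(x_id, m_id, y_id)`.
#'
#' @param data data.frame holding all referenced columns per subject.
#' @param candidates data.frame with columns `x_id`, `m_id`, `y_id`.
#' @param covariates optional covariate data.frame (same rows as `data`).
#' @inheritParams bootstrap_ci
#' @return data.frame, one row per triple, with paths, CI, significance
#'   flag and provenance (`n_effective`, `n_boot`, `seed`); attribute
#'   `n_significant` carries the summary count.
#' @export
mediation_screen <- function(data, candidates, covariates = NULL,
                             n_boot = 5000, level = 0.95, seed = 1,
                             standardize = FALSE) {
  if (!all(c("x_id", "m_id", "y_id") %in% names(candidates)))
    stop_gbl("candidates must have x_id, m_id, y_id columns")
  if (nrow(candidates) == 0L) {
    warning("empty candidate list")
    out <- data.frame(x_id = character(), m_id = character(),
                      y_id = character(), a = numeric(), b = numeric(),
                      c = numeric(), c_prime = numeric(), indirect = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      significant = logical(), n_effective = integer(),
                      n_boot = integer(), seed = integer())
    attr(out, "n_significant") <- 0L
    return(out)
  }
  missing_cols <- setdiff(unique(unlist(candidates[c("x_id", "m_id", "y_id")])),
                          names(data))
  if (length(missing_cols))
    stop_gbl("candidate columns not in data: ", paste(missing_cols, collapse = ", "))
  candidates <- candidates[order(candidates$x_id, candidates$m_id,
                                 candidates$y_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    res <- mediate(data[[candidates$x_id[i]]], data[[candidates$m_id[i]]],
                   data[[candidates$y_id[i]]], covariates,
                   n_boot = n_boot, level = level,
                   seed = derive_seed(seed, i), standardize = standardize)
    data.frame(x_id = candidates$x_id[i], m_id = candidates$m_id[i],
               y_id = candidates$y_id[i], a = res$a, b = res$b, c = res$c,
               c_prime = res$c_prime, indirect = res$indirect,
               ci_low = res$ci_low, ci_high = res$ci_high,
               significant = res$significant, n_effective = res$n_effective,
               n_boot = res$n_boot, seed = res$seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$significant)
  out
}

#' Build mediation candidates by chaining two correlation screens
#'
#' Implements the chaining rule: a triple `(x, m, y)` is a candidate iff
#' the pair `(x, m)` is significant in the X-M screen and `(m, y)` is
#' significant in the M-Y screen.
#'
#' @param xm_screen,my_screen results of [correlation_screen()]; features
#'   of `xm_screen` are the treatments, targets of `xm_screen` and
#'   features of `my_screen` are the mediators, targets of `my_screen`
#'   are the outcomes.
#' @return data.frame of `x_id`, `m_id`, `y_id` triples.
#' @export
chain_candidates <- function(xm_screen, my_screen) {
  xm <- xm_screen[xm_screen$significant, c("feature", "target")]
  names(xm) <- c("x_id", "m_id")
  my <- my_screen[my_screen$significant, c("feature", "target")]
  names(my) <- c("m_id", "y_id")
  out <- merge(xm, my, by = "m_id")[, c("x_id", "m_id", "y_id")]
  out <- out[order(out$x_id, out$m_id, out$y_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
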