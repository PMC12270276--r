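# Independent oracles used across the suite. Each one recomputes a
# quantity from its textbook definition by direct summation/enumeration,
# deliberately avoiding the code paths it checks.

# DFT by explicit summation; single-sided amplitudes with the package's
# convention (2|X_k|/T, halved at the Nyquist bin), DC excluded.
oracle_amplitudes <- function(x, tr) {
  nt <- length(x)
  kmax <- floor(nt / 2)
  amp <- vapply(seq_len(kmax), function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(nt - 1)) / nt))
    im <- sum(x * sin(-2 * pi * k * (0:(nt - 1)) / nt))
    2 * sqrt(re^2 + im^2) / nt
  }, numeric(1))
  if (nt %% 2 == 0) amp[kmax] <- amp[kmax] / 2
  list(amp = amp, freq = seq_len(kmax) / (nt * tr))
}

oracle_alff <- function(x, tr, band = c(0.01, 0.1)) {
  o <- oracle_amplitudes(x, tr)
  sel <- o$freq >= band[1] - 1e-12 & o$freq <= band[2] + 1e-12
  mean(o$amp[sel])
}

oracle_falff <- function(x, tr, band = c(0.01, 0.1)) {
  o <- oracle_amplitudes(x, tr)
  sel <- o$freq >= band[1] - 1e-12 & o$freq <= band[2] + 1e-12
  if (sum(o$amp) == 0) 0 else sum(o$amp[sel]) / sum(o$amp)
}

# Literal Kendall's W: series in columns, ranks over time, S-summation.
oracle_kendall_w <- function(block) {
  nt <- nrow(block); m <- ncol(block)
  rk <- apply(block, 2L, rank)
  r_t <- rowSums(rk)
  s <- sum((r_t - mean(r_t))^2)
  12 * s / (m^2 * (nt^3 - nt))
}

# All-pairs FCD by double loop.
oracle_fcd <- function(series, thr) {
  nv <- ncol(series)
  counts <- integer(nv)
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    if (i == j) next
    if (stats::cor(series[, i], series[, j]) > thr)
      counts[i] <- counts[i] + 1L
  }
  counts
}

# First singular direction of the cross-covariance (SVD route).
oracle_plsr_weights <- function(z, microbe) {
  cc <- crossprod(z, microbe - mean(microbe)) / (nrow(z) - 1)
  sv <- svd(cc)
  w <- sv$u[, 1] * sign(sum(sv$u[, 1] * cc))
  as.numeric(w)
}

# Partial Spearman by explicit normal equations on midranks.
oracle_partial_spearman <- function(x, y, covs) {
  rx <- rank(x); ry <- rank(y)
  X <- cbind(1, as.matrix(covs))
  beta_x <- solve(t(X) %*% X, t(X) %*% rx)
  beta_y <- solve(t(X) %*% X, t(X) %*% ry)
  ex <- rx - X %*% beta_x; ey <- ry - X %*% beta_y
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

# Upper-tail hypergeometric by binomial-coefficient summation.
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# All permutations of 1..n (n! rows), lexicographic.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Small synthetic cohort for fast module tests.
small_config <- function(seed = 1, ...) {
  cohort_config(n_patients = 40, n_controls = 35, n_metabolites = 30,
                planted_pos_idx = 1:3, planted_neg_idx = 4:6,
                n_imaging = 3, seed = seed, ...)
}
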