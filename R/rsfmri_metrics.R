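#' Construct a masked 4-D BOLD volume
#'
#' @param data numeric 4-D array indexed `(x, y, z, t)`.
#' @param tr repetition time in seconds.
#' @param mask logical 3-D array with the same spatial shape; `NULL` means
#'   all voxels. Values outside the mask are ignored by every metric.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, tr, mask = NULL) {
  if (length(dim(data)) != 4L) stop_gbl("data must be a 4-D array (x, y, z, t)")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop_gbl("tr must be a single positive number of seconds")
  sp <- dim(data)[1:3]
  if (dim(data)[4] < 16L) stop_gbl("need >= 16 timepoints")
  if (is.null(mask)) mask <- array(TRUE, sp)
  if (!identical(dim(mask), sp)) stop_gbl("mask shape must match the spatial shape")
  mask <- array(as.logical(mask), sp)
  if (!any(mask)) stop_gbl("mask is empty")
  inside <- data[rep_mask_4d(mask, dim(data)[4])]
  if (any(!is.finite(inside))) stop_gbl("non-finite values inside the mask")
  structure(list(data = data, tr = tr, mask = mask), class = "volume4d")
}

rep_mask_4d <- function(mask, nt) array(mask, c(dim(mask), nt))

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume4d: %dx%dx%d voxels, %d timepoints, TR = %gs, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

# T x V matrix of in-mask time series (V = number of mask voxels, in
# array order), plus the index bookkeeping to scatter values back.
mask_series <- function(vol) {
  idx <- which(vol$mask)
  nt <- dim(vol$data)[4]
  m <- matrix(aperm(vol$data, c(4, 1, 2, 3)), nrow = nt)
  list(series = m[, idx, drop = FALSE], idx = idx, spatial = dim(vol$data)[1:3])
}

scatter_map <- function(values, idx, spatial) {
  out <- array(0, spatial)
  out[idx] <- values
  out
}

new_metric_map <- function(values, metric, band = NULL, standardized = FALSE,
                           flags = NULL) {
  structure(list(values = values, metric = metric, band = band,
                 standardized = standardized, flags = flags),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("metric_map: %s%s%s\n", x$metric,
              if (!is.null(x$band)) sprintf(" (band %g-%g Hz)", x$band[1], x$band[2]) else "",
              if (x$standardized) ", standardized to whole-brain mean 1" else ""))
  invisible(x)
}

# Single-sided amplitude spectrum of each column of a T x V matrix:
# a_k = 2|X_k|/T for 0 < f_k < Nyquist, a_k = |X_k|/T at the Nyquist bin
# (even T). DC is dropped. Returns the amplitudes (bins x V) and the
# frequency grid.
amplitude_spectrum <- function(series, tr) {
  nt <- nrow(series)
  ft <- stats::mvfft(series)
  k_max <- floor(nt / 2)
  k <- seq_len(k_max)
  amp <- 2 * Mod(ft[k + 1L, , drop = FALSE]) / nt
  if (nt %% 2 == 0) amp[k_max, ] <- amp[k_max, ] / 2
  list(amp = amp, freq = k / (nt * tr))
}

band_bins <- function(freq, band, tr) {
  if (length(band) != 2L || band[1] >= band[2] || band[1] < 0)
    stop_gbl("band must be (low, high) with 0 <= low < high")
  nyq <- 1 / (2 * tr)
  if (band[2] > nyq + 1e-12)
    stop_gbl(sprintf("band high %g Hz exceeds the Nyquist frequency %g Hz", band[2], nyq))
  sel <- which(freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12)
  if (!length(sel))
    stop_gbl(sprintf("no frequency bins fall in [%g, %g] Hz; bin spacing is %g Hz",
                     band[1], band[2], freq[1]))
  sel
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' The BOLD series of each voxel is Fourier-transformed; ALFF is the mean
#' of the single-sided amplitude spectrum (square root of power) over the
#' bins inside the low-frequency band, by convention computed on the
#' unfiltered series. The DC bin is excluded: a constant offset is not a
#' fluctuation.
#'
#' @param vol a [volume4d()].
#' @param band two-element numeric, Hz; default `c(0.01, 0.1)`.
#' @return A `metric_map` (zero outside the mask).
#' @export
alff <- function(vol, band = c(0.01, 0.1)) {
  stopifnot(inherits(vol, "volume4d"))
  ms <- mask_series(vol)
  sp <- amplitude_spectrum(ms$series, vol$tr)
  sel <- band_bins(sp$freq, band, vol$tr)
  vals <- colMeans(sp$amp[sel, , drop = FALSE])
  new_metric_map(scatter_map(vals, ms$idx, ms$spatial), "ALFF", band = band)
}

#' Fractional ALFF (fALFF)
#'
#' Ratio of the amplitude-spectrum mass inside the low-frequency band to
#' the mass over the entire frequency range (all bins above DC up to
#' Nyquist); lies in `[0, 1]`. An all-zero series has no spectral mass and
#' is assigned 0 (recorded in `flags`).
#'
#' @inheritParams alff
#' @return A `metric_map`.
#' @export
falff <- function(vol, band = c(0.01, 0.1)) {
  stopifnot(inherits(vol, "volume4d"))
  ms <- mask_series(vol)
  sp <- amplitude_spectrum(ms$series, vol$tr)
  sel <- band_bins(sp$freq, band, vol$tr)
  num <- colSums(sp$amp[sel, , drop = FALSE])
  den <- colSums(sp$amp)
  zero <- den == 0
  vals <- ifelse(zero, 0, num / den)
  new_metric_map(scatter_map(vals, ms$idx, ms$spatial), "fALFF", band = band,
                 flags = if (any(zero)) list(zero_series = ms$idx[zero]))
}

#' Band-pass filter a volume in the frequency domain
#'
#' Zeroes every Fourier bin (including DC) whose frequency falls outside
#' `[low, high]` Hz and inverts the transform. Intended to precede
#' [reho()], [fcd()] and [vmhc()], which are conventionally computed on
#' band-limited data, whereas ALFF/fALFF are computed on the raw series.
#'
#' @inheritParams alff
#' @return A `volume4d` with filtered data.
#' @export
bandpass <- function(vol, band = c(0.01, 0.1)) {
  stopifnot(inherits(vol, "volume4d"))
  ms <- mask_series(vol)
  nt <- nrow(ms$series)
  ft <- stats::mvfft(ms$series)
  freq_all <- c(0, seq_len(nt - 1)) / (nt * vol$tr)
  freq_fold <- pmin(freq_all, 1 / vol$tr - freq_all)  # two-sided grid
  keep <- freq_fold >= band[1] - 1e-12 & freq_fold <= band[2] + 1e-12
  ft[!keep, ] <- 0
  filt <- Re(stats::mvfft(ft, inverse = TRUE)) / nt
  data <- vol$data
  data[rep_mask_4d(vol$mask, nt)] <- as.numeric(t(filt))
  volume4d(data, vol$tr, vol$mask)
}

#' Regional homogeneity (ReHo)
#'
#' Kendall's coefficient of concordance between a voxel's time course and
#' those of its 26 nearest neighbors (the full 3x3x3 cube), restricted to
#' neighbors inside the mask. With `m` series of length `T`, each series is
#' rank-transformed and `W = 12 S / (m^2 (T^3 - T))` where `S` is the sum
#' of squared deviations of the per-timepoint rank sums from their mean.
#' No tie correction is applied. Isolated voxels (no in-mask neighbor) get
#' 0 and are flagged.
#'
#' @param vol a [volume4d()]; band-pass filter beforehand with
#'   [bandpass()] if desired.
#' @return A `metric_map` with `W` in `[0, 1]`.
#' @export
reho <- function(vol) {
  stopifnot(inherits(vol, "volume4d"))
  sp <- dim(vol$data)[1:3]
  nt <- dim(vol$data)[4]
  idx <- which(vol$mask)
  # rank each in-mask voxel's series once, stored by spatial linear index
  tm <- matrix(aperm(vol$data, c(4, 1, 2, 3)), nrow = nt)[, idx, drop = FALSE]
  rk <- matrix(0, nt, prod(sp))
  rk[, idx] <- apply(tm, 2L, midrank)
  coords <- which(vol$mask, arr.ind = TRUE)
  vals <- numeric(nrow(coords))
  isolated <- logical(nrow(coords))
  denom_T <- nt^3 - nt
  for (v in seq_len(nrow(coords))) {
    xs <- max(1L, coords[v, 1] - 1L):min(sp[1], coords[v, 1] + 1L)
    ys <- max(1L, coords[v, 2] - 1L):min(sp[2], coords[v, 2] + 1L)
    zs <- max(1L, coords[v, 3] - 1L):min(sp[3], coords[v, 3] + 1L)
    nb <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    lin <- (nb[, 3] - 1L) * sp[1] * sp[2] + (nb[, 2] - 1L) * sp[1] + nb[, 1]
    lin <- lin[vol$mask[lin]]
    m <- length(lin)
    if (m < 2L) { vals[v] <- 0; isolated[v] <- TRUE; next }
    r_t <- rowSums(rk[, lin, drop = FALSE])
    s <- sum((r_t - mean(r_t))^2)
    vals[v] <- 12 * s / (m^2 * denom_T)
  }
  new_metric_map(scatter_map(vals, idx, sp), "ReHo",
                 flags = if (any(isolated)) list(isolated = idx[isolated]))
}

#' Functional connectivity density (FCD)
#'
#' For each in-mask voxel, the number of other in-mask voxels whose time
#' course has a Pearson correlation strictly greater than `r_threshold`
#' (default 0.25) with it; self-connections are excluded, so the map is
#' integer-valued. Constant series cannot be correlated and receive a
#' count of 0 (flagged), and never count as connections of other voxels.
#'
#' @param vol a [volume4d()] (band-pass filtered by convention).
#' @param r_threshold correlation threshold; strictly-greater rule, so a
#'   pair at exactly the threshold is not counted.
#' @return A `metric_map` of non-negative integers.
#' @export
fcd <- function(vol, r_threshold = 0.25) {
  stopifnot(inherits(vol, "volume4d"))
  ms <- mask_series(vol)
  nv <- ncol(ms$series)
  if (nv < 2L) stop_gbl("FCD needs >= 2 mask voxels")
  sdv <- apply(ms$series, 2L, stats::sd)
  const <- sdv == 0
  z <- ms$series
  z[, !const] <- scale(ms$series[, !const, drop = FALSE])
  z[, const] <- 0
  r <- crossprod(z) / (nrow(z) - 1)
  counts <- colSums(r > r_threshold) - as.integer(!const)  # drop self (r=1)
  counts[const] <- 0L
  new_metric_map(scatter_map(counts, ms$idx, ms$spatial), "FCD",
                 flags = if (any(const)) list(constant_series = ms$idx[const]))
}

mirror_x <- function(a) a[dim(a)[1]:1, , , drop = FALSE]

#' Voxel-mirrored homotopic connectivity (VMHC)
#'
#' Pearson correlation between each voxel's time course and that of its
#' inter-hemispheric mirror, obtained by reflecting the first spatial axis
#' about the array midline (`i -> X + 1 - i`). The effective mask is the
#' intersection of the mask with its own reflection, so every retained
#' voxel has an in-mask counterpart.
#'
#' @param vol a [volume4d()].
#' @return A `metric_map` with values in `[-1, 1]`.
#' @export
vmhc <- function(vol) {
  stopifnot(inherits(vol, "volume4d"))
  sp <- dim(vol$data)[1:3]
  nt <- dim(vol$data)[4]
  eff <- vol$mask & mirror_x(vol$mask)
  if (!any(eff)) stop_gbl("effective (symmetrized) mask is empty")
  idx <- which(eff)
  coords <- which(eff, arr.ind = TRUE)
  mirror_coords <- coords
  mirror_coords[, 1] <- sp[1] + 1L - coords[, 1]
  tm <- matrix(aperm(vol$data, c(4, 1, 2, 3)), nrow = nt)
  lin <- function(cc) (cc[, 3] - 1L) * sp[1] * sp[2] + (cc[, 2] - 1L) * sp[1] + cc[, 1]
  a <- tm[, lin(coords), drop = FALSE]
  b <- tm[, lin(mirror_coords), drop = FALSE]
  ca <- sweep(a, 2L, colMeans(a)); cb <- sweep(b, 2L, colMeans(b))
  num <- colSums(ca * cb)
  den <- sqrt(colSums(ca^2) * colSums(cb^2))
  vals <- ifelse(den == 0, 0, num / den)
  new_metric_map(scatter_map(vals, idx, sp), "VMHC")
}

#' Rescale a metric map to a whole-brain mean of one
#'
#' Divides every in-mask value by the within-mask mean, the conventional
#' standardization applied before group statistics so that subjects are
#' comparable despite arbitrary signal units.
#'
#' @param map a `metric_map`.
#' @param mask logical 3-D array defining "whole brain".
#' @return The standardized `metric_map` (within-mask mean exactly 1).
#' @export
standardize_map <- function(map, mask) {
  stopifnot(inherits(map, "metric_map"))
  mu <- mean(map$values[mask])
  if (!is.finite(mu) || mu == 0)
    stop_gbl("degenerate map: within-mask mean is zero or non-finite")
  if (mu < 0 && map$metric %in% c("ALFF", "fALFF", "ReHo", "FCD"))
    stop_gbl("degenerate map: negative within-mask mean for non-negative metric ",
             map$metric)
  map$values <- map$values / mu
  map$values[!mask] <- 0
  map$standardized <- TRUE
  map
}

#' Extract per-cluster means from a metric map
#'
#' @param map a `metric_map`.
#' @param labels integer 3-D array, same shape as the map; label 0 is
#'   background. Clusters are the nonzero labels (e.g. from a group-level
#'   significance map); the mean map value over each cluster's voxels is
#'   what feeds the correlation and mediation stages.
#' @param mask optional logical array restricting the cluster voxels;
#'   labels with no in-mask voxel are omitted with a warning.
#' @return A data.frame with columns `label`, `n_voxels`, `mean_value`.
#' @export
extract_cluster_means <- function(map, labels, mask = NULL) {
  stopifnot(inherits(map, "metric_map"))
  if (!identical(dim(labels), dim(map$values)))
    stop_gbl("labels shape must match the map")
  if (is.null(mask)) mask <- array(TRUE, dim(labels))
  out <- lapply(sort(unique(labels[labels != 0])), function(lb) {
    sel <- labels == lb & mask
    if (!any(sel)) {
      warning("cluster label ", lb, " has no in-mask voxel; omitted")
      return(NULL)
    }
    data.frame(label = lb, n_voxels = sum(sel), mean_value = mean(map$values[sel]))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(label = integer(), n_voxels = integer(),
                      mean_value = numeric())
  out
}

#' Compute all five resting-state metrics with standardization
#'
#' Convenience wrapper: ALFF and fALFF on the raw series, then ReHo, FCD
#' and VMHC on the band-pass-filtered series, each rescaled to whole-brain
#' mean 1.
#'
#' @inheritParams alff
#' @param r_threshold FCD correlation threshold.
#' @param metrics subset of `c("ALFF","fALFF","ReHo","FCD","VMHC")`.
#' @return Named list of standardized `metric_map`s.
#' @export
compute_metrics <- function(vol, band = c(0.01, 0.1), r_threshold = 0.25,
                            metrics = c("ALFF", "fALFF", "ReHo", "FCD", "VMHC")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list()
  if ("ALFF" %in% metrics) out$ALFF <- alff(vol, band)
  if ("fALFF" %in% metrics) out$fALFF <- falff(vol, band)
  if (any(c("ReHo", "FCD", "VMHC") %in% metrics)) {
    volf <- bandpass(vol, band)
    if ("ReHo" %in% metrics) out$ReHo <- reho(volf)
    if ("FCD" %in% metrics) out$FCD <- fcd(volf, r_threshold)
    if ("VMHC" %in% metrics) out$VMHC <- vmhc(volf)
  }
  lapply(out, standardize_map, mask = vol$mask)
}
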