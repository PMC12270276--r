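#' Construct an untargeted-metabolomics peak-area panel
#'
#' Bundles the three peak-area matrices of one ion mode: study samples,
#' pooled-QC technical replicates, and instrument blanks. Zeros in the
#' sample matrix are the missingness code (untargeted peak tables carry no
#' NA convention); they are treated as missing by [filter_presence()] and
#' [impute_missing()].
#'
#' @param sample_areas numeric matrix, subjects x metabolites, peak areas
#'   (arbitrary units, all >= 0).
#' @param qc_areas numeric matrix, QC replicates x metabolites.
#' @param blank_areas numeric matrix, blank injections x metabolites.
#' @param ion_mode `"positive"` or `"negative"`.
#' @param metabolite_ids character vector of column identifiers; defaults to
#'   the column names of `sample_areas`.
#' @return An object of class `metabolite_panel`.
#' @export
metabolite_panel <- function(sample_areas, qc_areas, blank_areas,
                             ion_mode = c("positive", "negative"),
                             metabolite_ids = colnames(sample_areas)) {
  ion_mode <- match.arg(ion_mode)
  sample_areas <- as.matrix(sample_areas)
  qc_areas <- as.matrix(qc_areas)
  blank_areas <- as.matrix(blank_areas)
  p <- ncol(sample_areas)
  if (ncol(qc_areas) != p || ncol(blank_areas) != p)
    stop_gbl("sample, QC and blank matrices must have the same metabolite columns")
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("met_", seq_len(p))
  if (length(metabolite_ids) != p)
    stop_gbl("metabolite_ids length does not match the number of columns")
  for (m in list(sample_areas, qc_areas, blank_areas))
    if (any(!is.finite(m)) || any(m < 0))
      stop_gbl("peak areas must be finite and >= 0")
  colnames(sample_areas) <- colnames(qc_areas) <- colnames(blank_areas) <-
    metabolite_ids
  structure(list(sample_areas = sample_areas, qc_areas = qc_areas,
                 blank_areas = blank_areas, ion_mode = ion_mode,
                 metabolite_ids = metabolite_ids,
                 filter_log = empty_filter_log()),
            class = "metabolite_panel")
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf("metabolite_panel (%s mode): %d samples, %d QC, %d blanks, %d metabolites\n",
              x$ion_mode, nrow(x$sample_areas), nrow(x$qc_areas),
              nrow(x$blank_areas), length(x$metabolite_ids)))
  invisible(x)
}

empty_filter_log <- function() {
  data.frame(metabolite_id = character(), qc_blank_ratio = numeric(),
             rsd_percent = numeric(), presence_fraction = numeric(),
             kept = logical(), removal_reason = character(),
             stringsAsFactors = FALSE)
}

drop_metabolites <- function(panel, drop_idx, reason, stat_name, stat) {
  log_new <- data.frame(metabolite_id = panel$metabolite_ids,
                        qc_blank_ratio = NA_real_, rsd_percent = NA_real_,
                        presence_fraction = NA_real_,
                        kept = TRUE, removal_reason = NA_character_,
                        stringsAsFactors = FALSE)
  log_new[[stat_name]] <- stat
  log_new$kept <- !seq_along(panel$metabolite_ids) %in% drop_idx
  log_new$removal_reason[drop_idx] <- reason
  keep <- log_new$kept
  panel$filter_log <- merge_filter_log(panel$filter_log, log_new)
  panel$sample_areas <- panel$sample_areas[, keep, drop = FALSE]
  panel$qc_areas <- panel$qc_areas[, keep, drop = FALSE]
  panel$blank_areas <- panel$blank_areas[, keep, drop = FALSE]
  panel$metabolite_ids <- panel$metabolite_ids[keep]
  panel
}

merge_filter_log <- function(old, new) {
  if (nrow(old) == 0L) return(new)
  i <- match(new$metabolite_id, old$metabolite_id)
  for (col in c("qc_blank_ratio", "rsd_percent", "presence_fraction"))
    old[[col]][i] <- ifelse(is.na(old[[col]][i]), new[[col]], old[[col]][i])
  old$kept[i] <- old$kept[i] & new$kept
  old$removal_reason[i] <- ifelse(is.na(old$removal_reason[i]),
                                  new$removal_reason, old$removal_reason[i])
  old
}

#' Remove metabolites with a low QC/blank peak-area ratio
#'
#' A metabolite is removed when mean(QC areas) / mean(blank areas) falls
#' strictly below `threshold` (default 3): such peaks are indistinguishable
#' from chemical background. A blank mean of zero with a positive QC mean
#' gives an infinite ratio (kept). The ratio uses replicate means.
#'
#' @param panel a [metabolite_panel()].
#' @param threshold minimum acceptable QC/blank ratio; the rule is strictly
#'   `< threshold` removes, so a ratio of exactly 3 is kept.
#' @return The filtered panel; removals are recorded in `filter_log`.
#' @export
filter_blank_ratio <- function(panel, threshold = 3) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (nrow(panel$qc_areas) < 1L || nrow(panel$blank_areas) < 1L)
    stop_gbl("need at least one QC row and one blank row for the blank-ratio filter")
  qc_mean <- colMeans(panel$qc_areas)
  blank_mean <- colMeans(panel$blank_areas)
  ratio <- ifelse(blank_mean == 0,
                  ifelse(qc_mean > 0, Inf, NaN), qc_mean / blank_mean)
  # 0/0 (NaN): no QC signal at all; treat as background, remove.
  drop <- which(is.nan(ratio) | ratio < threshold)
  drop_metabolites(panel, drop, "qc_blank_ratio", "qc_blank_ratio", ratio)
}

#' Remove metabolites with irreproducible QC signal (high RSD)
#'
#' The relative standard deviation (coefficient of variation, percent)
#' across QC technical replicates measures instrument reproducibility.
#' Metabolites with RSD strictly greater than `max_rsd_percent` (default
#' 30) are discarded; exactly 30% is kept. The SD uses the n-1 denominator.
#' A QC mean of zero makes the RSD infinite (discarded).
#'
#' @param panel a [metabolite_panel()].
#' @param max_rsd_percent maximum acceptable RSD in percent.
#' @return The filtered panel.
#' @export
filter_rsd <- function(panel, max_rsd_percent = 30) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (nrow(panel$qc_areas) < 2L)
    stop_gbl("need >= 2 QC replicate rows to compute RSD")
  qc_mean <- colMeans(panel$qc_areas)
  qc_sd <- apply(panel$qc_areas, 2L, stats::sd)
  rsd <- ifelse(qc_mean == 0, Inf, 100 * qc_sd / qc_mean)
  drop <- which(rsd > max_rsd_percent)
  drop_metabolites(panel, drop, "rsd", "rsd_percent", rsd)
}

#' Keep metabolites detected in a minimum fraction of study samples
#'
#' A metabolite is kept iff its nonzero study-sample count divided by the
#' number of samples is at least `min_fraction` (default 0.80, i.e. exactly
#' 80% presence is kept). QC and blank rows do not count.
#'
#' @param panel a [metabolite_panel()].
#' @param min_fraction minimum nonzero fraction among study samples.
#' @return The filtered panel.
#' @export
filter_presence <- function(panel, min_fraction = 0.80) {
  stopifnot(inherits(panel, "metabolite_panel"))
  n <- nrow(panel$sample_areas)
  if (n < 1L) stop_gbl("panel has no study samples")
  presence <- colSums(panel$sample_areas > 0) / n
  drop <- which(presence < min_fraction)
  drop_metabolites(panel, drop, "presence", "presence_fraction", presence)
}

#' Impute missing (zero) peak areas
#'
#' Zeros in the study-sample matrix are replaced by one fifth of the
#' minimum positive value of the same metabolite column.
#'
#' @param panel a [metabolite_panel()] that already passed the filters.
#' @return The panel with the sample matrix imputed.
#' @export
impute_missing <- function(panel) {
  stopifnot(inherits(panel, "metabolite_panel"))
  m <- panel$sample_areas
  for (j in seq_len(ncol(m))) {
    zero <- m[, j] == 0
    if (!any(zero)) next
    pos <- m[m[, j] > 0, j]
    if (!length(pos))
      stop_gbl("column '", panel$metabolite_ids[j],
               "' has no positive value; cannot impute")
    m[zero, j] <- min(pos) / 5
  }
  panel$sample_areas <- m
  panel
}

#' Generalized logarithm
#'
#' `glog(x) = log2((x + sqrt(x^2 + lambda^2)) / 2)`, a variance-stabilizing
#' transform for peak-area data that behaves like `log2(x)` for large `x`
#' and stays finite at zero.
#'
#' @param x numeric vector (>= 0 in the intended use).
#' @param lambda positive transform parameter, in squared-area units.
#' @return Transformed values.
#' @export
glog <- function(x, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop_gbl("glog lambda must be a single positive number")
  log2((x + sqrt(x^2 + lambda^2)) / 2)
}

#' QC-normalize, glog-transform and z-score a filtered panel
#'
#' The final processing step: (1) each metabolite column is divided by its
#' pooled-QC replicate mean (absorbing per-metabolite scale); (2) a
#' generalized log transform is applied, with `lambda` defaulting to each
#' column's minimum positive normalized value; (3) each column is
#' standardized to mean 0, SD 1.
#'
#' @param panel a filtered, imputed [metabolite_panel()].
#' @param glog_lambda optional single lambda applied to every column (in
#'   normalized-area units). Default `NULL` uses the per-column minimum
#'   positive value.
#' @return An object of class `processed_metabolome` with elements
#'   `z_matrix` (subjects x surviving metabolites), `filter_log` (one row
#'   per input metabolite with the filter statistics, kept flag, and the
#'   single removal reason), and `ion_mode`.
#' @export
normalize_and_scale <- function(panel, glog_lambda = NULL) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (!is.null(glog_lambda) && (!is.numeric(glog_lambda) || glog_lambda <= 0))
    stop_gbl("glog_lambda must be positive")
  qc_mean <- colMeans(panel$qc_areas)
  if (any(qc_mean <= 0))
    stop_gbl("QC mean <= 0 for column(s): ",
             paste(panel$metabolite_ids[qc_mean <= 0], collapse = ", "))
  norm <- sweep(panel$sample_areas, 2L, qc_mean, "/")
  g <- norm
  for (j in seq_len(ncol(norm))) {
    lam <- glog_lambda
    if (is.null(lam)) {
      pos <- norm[norm[, j] > 0, j]
      if (!length(pos))
        stop_gbl("column '", panel$metabolite_ids[j],
                 "' has no positive value; cannot choose glog lambda")
      lam <- min(pos)
    }
    g[, j] <- glog(norm[, j], lam)
  }
  z <- zscore_cols(g, context = "post-glog column")
  log_full <- finalize_filter_log(panel)
  structure(list(z_matrix = z, filter_log = log_full,
                 ion_mode = panel$ion_mode),
            class = "processed_metabolome")
}

finalize_filter_log <- function(panel) {
  survivors <- data.frame(metabolite_id = panel$metabolite_ids,
                          qc_blank_ratio = NA_real_, rsd_percent = NA_real_,
                          presence_fraction = NA_real_, kept = TRUE,
                          removal_reason = NA_character_,
                          stringsAsFactors = FALSE)
  log_full <- merge_filter_log(panel$filter_log, survivors)
  rownames(log_full) <- NULL
  log_full
}

#' Run the full metabolomics QC cascade
#'
#' Fixed filter order: blank ratio, then RSD, then presence, then
#' imputation, then normalization/scaling. Each removed metabolite carries
#' exactly one removal reason (the first filter it failed).
#'
#' @param panel a raw [metabolite_panel()].
#' @param blank_ratio_threshold,max_rsd_percent,min_presence filter
#'   thresholds; defaults 3, 30, 0.80.
#' @param glog_lambda see [normalize_and_scale()].
#' @return A `processed_metabolome`.
#' @export
process_metabolome <- function(panel, blank_ratio_threshold = 3,
                               max_rsd_percent = 30, min_presence = 0.80,
                               glog_lambda = NULL) {
  panel <- filter_blank_ratio(panel, blank_ratio_threshold)
  panel <- filter_rsd(panel, max_rsd_percent)
  panel <- filter_presence(panel, min_presence)
  panel <- impute_missing(panel)
  normalize_and_scale(panel, glog_lambda)
}

#' @export
print.processed_metabolome <- function(x, ...) {
  cat(sprintf("processed_metabolome (%s mode): %d subjects x %d surviving metabolites (%d removed)\n",
              x$ion_mode, nrow(x$z_matrix), ncol(x$z_matrix),
              sum(!x$filter_log$kept)))
  invisible(x)
}

#' Read / write a metabolite panel as TSV
#'
#' The TSV layout has a `role` column (`sample` / `qc` / `blank`), a
#' `row_id` column, and one numeric column per metabolite.
#'
#' @param path TSV file path.
#' @param ion_mode passed to [metabolite_panel()].
#' @return `read_metabolite_panel` returns a `metabolite_panel`;
#'   `write_metabolite_panel` invisibly returns `path`.
#' @export
read_metabolite_panel <- function(path, ion_mode = c("positive", "negative")) {
  df <- read_tsv(path)
  if (!all(c("role", "row_id") %in% names(df)))
    stop_gbl("panel TSV must have 'role' and 'row_id' columns")
  met_cols <- setdiff(names(df), c("role", "row_id"))
  mat <- as.matrix(df[met_cols])
  rownames(mat) <- df$row_id
  metabolite_panel(mat[df$role == "sample", , drop = FALSE],
                   mat[df$role == "qc", , drop = FALSE],
                   mat[df$role == "blank", , drop = FALSE],
                   ion_mode = match.arg(ion_mode),
                   metabolite_ids = met_cols)
}

#' @rdname read_metabolite_panel
#' @param panel a [metabolite_panel()] to serialize.
#' @export
write_metabolite_panel <- function(panel, path) {
  stopifnot(inherits(panel, "metabolite_panel"))
  blocks <- list(sample = panel$sample_areas, qc = panel$qc_areas,
                 blank = panel$blank_areas)
  rows <- lapply(names(blocks), function(role) {
    m <- blocks[[role]]
    ids <- rownames(m) %||% paste0(role, "_", seq_len(nrow(m)))
    data.frame(role = role, row_id = ids, m, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
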