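#' Configuration of a synthetic gut-brain cohort
#'
#' Describes the ground truth of a simulated case-control study: group
#' sizes, the standardized patient-vs-control shift of the (log) microbial
#' abundance, which metabolites carry a microbe loading and how strong it
#' is, the planted metabolite-imaging-behavior mediation chains, residual
#' noise per layer, and how covariates leak into every layer (so that
#' partial, not marginal, correlations are the correct recovery target).
#'
#' Defaults mirror the emulated study where it states them (111 patients,
#' 102 controls) and are otherwise chosen once for adequate test power:
#' a log-scale abundance shift of 0.8 SD, 100 metabolites per ion mode of
#' which indices 1-10 load positively and 11-20 negatively on the microbe
#' with 0.8 per-SD effect, three mediation chains with paths
#' a = 0.5, b = 0.4, c' = 0.1, and unit residual SD in every layer.
#'
#' @param n_patients,n_controls group sizes.
#' @param n_metabolites metabolites per ion mode (before the deliberately
#'   failing QC columns are appended).
#' @param microbe_group_shift Cohen's d of the patient-minus-control shift
#'   on the log-abundance scale.
#' @param planted_pos_idx,planted_neg_idx disjoint metabolite index sets
#'   with positive / negative microbe loading.
#' @param beta_metab loading magnitude: latent metabolite change per SD of
#'   log microbial abundance.
#' @param mediation_specs list of chains, each
#'   `list(met_idx =, img_idx =, beh_idx =, a =, b =, c_prime =)`:
#'   metabolite (X) index, imaging-feature (M) index, behavior (Y) index
#'   and path coefficients (per-SD units for X).
#' @param n_imaging number of per-subject imaging feature columns
#'   (synthetic cluster means).
#' @param noise_sd named list of residual SDs per layer:
#'   `metabolite`, `imaging`, `behavior`.
#' @param covariate_effects named list of per-layer coefficients with
#'   which the standardized covariate sum (age, gender, education, site;
#'   plus head motion FD for the imaging layer) enters that layer.
#' @param qc list of panel nuisance settings: `n_qc_reps`, `n_blanks`,
#'   `qc_cv`, `blank_ratio`, `n_fail_blank`, `n_fail_rsd`,
#'   `n_fail_presence`, `zero_col_fraction`, `zero_fraction`.
#' @param seed integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 111, n_controls = 102,
                          n_metabolites = 100, microbe_group_shift = 0.8,
                          planted_pos_idx = 1:10, planted_neg_idx = 11:20,
                          beta_metab = 0.8,
                          mediation_specs = default_mediation_specs(),
                          n_imaging = 5,
                          noise_sd = list(metabolite = 1, imaging = 1,
                                          behavior = 1),
                          covariate_effects = list(metabolite = 0.1,
                                                   imaging = 0.1,
                                                   behavior = 0.1),
                          qc = list(n_qc_reps = 6, n_blanks = 3,
                                    qc_cv = 0.05, blank_ratio = 10,
                                    n_fail_blank = 2, n_fail_rsd = 2,
                                    n_fail_presence = 2,
                                    zero_col_fraction = 0.10,
                                    zero_fraction = 0.05),
                          seed = 1) {
  n_patients <- check_count(n_patients, "n_patients")
  n_controls <- check_count(n_controls, "n_controls")
  n_metabolites <- check_count(n_metabolites, "n_metabolites", min = 5L)
  n_imaging <- check_count(n_imaging, "n_imaging")
  if (length(intersect(planted_pos_idx, planted_neg_idx)))
    stop_gbl("planted_pos_idx and planted_neg_idx must be disjoint")
  if (length(c(planted_pos_idx, planted_neg_idx)) &&
      max(c(planted_pos_idx, planted_neg_idx)) > n_metabolites)
    stop_gbl("planted metabolite indices out of range")
  if (any(unlist(noise_sd) < 0)) stop_gbl("noise_sd entries must be >= 0")
  for (sp in mediation_specs) {
    if (!all(c("met_idx", "img_idx", "beh_idx", "a", "b", "c_prime") %in% names(sp)))
      stop_gbl("each mediation spec needs met_idx, img_idx, beh_idx, a, b, c_prime")
    if (sp$met_idx > n_metabolites || sp$img_idx > n_imaging ||
        sp$beh_idx > length(behavior_names()))
      stop_gbl("mediation spec index out of range")
  }
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 n_metabolites = n_metabolites,
                 microbe_group_shift = microbe_group_shift,
                 planted_pos_idx = as.integer(planted_pos_idx),
                 planted_neg_idx = as.integer(planted_neg_idx),
                 beta_metab = beta_metab, mediation_specs = mediation_specs,
                 n_imaging = n_imaging, noise_sd = noise_sd,
                 covariate_effects = covariate_effects, qc = qc,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

default_mediation_specs <- function() {
  list(list(met_idx = 1L, img_idx = 1L, beh_idx = 2L, a = 0.5, b = 0.4, c_prime = 0.1),
       list(met_idx = 2L, img_idx = 2L, beh_idx = 5L, a = 0.5, b = 0.4, c_prime = 0.1),
       list(met_idx = 3L, img_idx = 3L, beh_idx = 8L, a = 0.5, b = 0.4, c_prime = 0.1))
}

behavior_names <- function() {
  c("HAMD", "HAMA", "BDI", "RSAS", "RPAS", "TEPS",
    "CPT_IP_2", "CPT_IP_3", "CPT_IP_4", "DST_forward", "DST_backward")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config: %d patients / %d controls, %d metabolites, %d imaging features\n",
              x$n_patients, x$n_controls, x$n_metabolites, x$n_imaging))
  cat(sprintf("  microbe shift d = %g; %d+/%d- planted metabolites (beta = %g); %d mediation chains; seed %d\n",
              x$microbe_group_shift, length(x$planted_pos_idx),
              length(x$planted_neg_idx), x$beta_metab,
              length(x$mediation_specs), x$seed))
  invisible(x)
}

rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate the per-subject table of a synthetic cohort
#'
#' Draws covariates from simple parametric distributions (age normal;
#' gender and site Bernoulli; education discrete uniform; TIV, FD and BMI
#' truncated normal), a log-normal microbial relative abundance with the
#' configured patient-vs-control log-scale shift, latent metabolite
#' signals `beta_metab * z(log abundance) * sign_j + noise`, synthetic
#' imaging features `a * z(latent metabolite) + covariates + noise`, and
#' behaviors `b * M + c' * X + covariates + noise` per mediation chain.
#' The log abundance is closed to a relative abundance in `[0, 1]` by a
#' strictly monotone logistic map, so rank-based downstream statistics are
#' unaffected by the closure.
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per subject (patients first):
#'   identifiers, `group` (`"MDD"`/`"HC"`), covariates, `Alistipes`
#'   relative abundance, imaging feature columns `img_feat_*`, and the
#'   behavior columns. The full ground truth (config, latent draws,
#'   standardized microbe) is attached as attribute `"ground_truth"`.
#' @export
simulate_subjects <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_patients + config$n_controls
  is_patient <- rep(c(1L, 0L), c(config$n_patients, config$n_controls))
  age <- stats::rnorm(n, 35, 10)
  gender <- stats::rbinom(n, 1, 0.5)
  education <- sample(6:19, n, replace = TRUE)
  site <- stats::rbinom(n, 1, 0.5)
  tiv <- rnorm_trunc0(n, 1450, 120)
  fd <- rnorm_trunc0(n, 0.15, 0.06)
  bmi <- rnorm_trunc0(n, 23, 3)
  illness_duration <- ifelse(is_patient == 1,
                             rnorm_trunc0(n, 24, 18), NA_real_)
  antidepressant <- ifelse(is_patient == 1,
                           sample(c("SSRI", "SNRI", "NaSSA"), n, replace = TRUE),
                           "none")
  log_abund <- config$microbe_group_shift * is_patient + stats::rnorm(n)
  # logistic closure to a relative abundance; strictly monotone in log_abund
  alistipes <- exp(log_abund) / (exp(log_abund) + 99)
  z_microbe <- (log_abund - mean(log_abund)) / stats::sd(log_abund)
  zc <- function(v) (v - mean(v)) / stats::sd(v)
  cov_base <- zc(age) + gender - 0.5 + zc(education) + site - 0.5
  # latent metabolite layer (per-SD microbe loading + covariates + noise)
  sign_j <- integer(config$n_metabolites)
  sign_j[config$planted_pos_idx] <- 1L
  sign_j[config$planted_neg_idx] <- -1L
  latent <- sapply(seq_len(config$n_metabolites), function(j) {
    config$beta_metab * sign_j[j] * z_microbe +
      config$covariate_effects$metabolite * cov_base +
      stats::rnorm(n, 0, config$noise_sd$metabolite)
  })
  colnames(latent) <- sprintf("met_%03d", seq_len(config$n_metabolites))
  # imaging layer
  cov_img <- config$covariate_effects$imaging * (cov_base + zc(fd))
  imaging <- sapply(seq_len(config$n_imaging), function(k) {
    m <- cov_img + stats::rnorm(n, 0, config$noise_sd$imaging)
    for (sp in config$mediation_specs)
      if (sp$img_idx == k) m <- m + sp$a * zc(latent[, sp$met_idx])
    m
  })
  colnames(imaging) <- sprintf("img_feat_%d", seq_len(config$n_imaging))
  # behavior layer
  beh_base <- c(HAMD = 14, HAMA = 12, BDI = 15, RSAS = 12, RPAS = 15,
                TEPS = 75, CPT_IP_2 = 3, CPT_IP_3 = 2.5, CPT_IP_4 = 2,
                DST_forward = 8, DST_backward = 6)
  cov_beh <- config$covariate_effects$behavior * cov_base
  behaviors <- sapply(seq_along(behavior_names()), function(q) {
    y <- beh_base[q] + cov_beh + stats::rnorm(n, 0, config$noise_sd$behavior)
    for (sp in config$mediation_specs)
      if (sp$beh_idx == q)
        y <- y + sp$b * imaging[, sp$img_idx] + sp$c_prime * zc(latent[, sp$met_idx])
    y
  })
  colnames(behaviors) <- behavior_names()
  subjects <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         group = ifelse(is_patient == 1, "MDD", "HC"),
                         age = age, gender = gender, education = education,
                         site = site, TIV = tiv, FD = fd, BMI = bmi,
                         illness_duration = illness_duration,
                         antidepressant = antidepressant,
                         Alistipes = alistipes,
                         imaging, behaviors,
                         check.names = FALSE, stringsAsFactors = FALSE)
  attr(subjects, "ground_truth") <- list(config = config,
                                         log_abund = log_abund,
                                         z_microbe = z_microbe,
                                         latent_metabolites = latent,
                                         sign_j = sign_j)
  subjects
}

#' Simulate a raw metabolite peak-area panel with QC structure
#'
#' Maps the latent metabolite signals of [simulate_subjects()] to positive
#' peak areas (`area = exp(log-mean + 0.4 * latent)`), appends pooled-QC
#' technical replicates (pooled sample mean with a small CV) and blank
#' injections (pooled mean divided by `qc$blank_ratio`), injects zeros
#' into a fraction of columns (exercising imputation while staying above
#' the presence threshold), and appends deliberately failing metabolites
#' for each QC filter: low QC/blank ratio (about 2), irreproducible QC
#' replicates (alternating 0.3x / 1.7x the mean, RSD about 74%), and
#' sub-threshold presence. The intended survivor set and the failure
#' labels are recorded in the `"ground_truth"` attribute so filter tests
#' are exact set comparisons.
#'
#' @param config the [cohort_config()] used for `subjects`.
#' @param subjects output of [simulate_subjects()] under the same config.
#' @param ion_mode panel tag.
#' @return A [metabolite_panel()] with attribute `"ground_truth"` listing
#'   `intended_survivors`, `fail_blank`, `fail_rsd`, `fail_presence`,
#'   `zero_injected`.
#' @export
simulate_metabolite_panel <- function(config, subjects,
                                      ion_mode = c("positive", "negative")) {
  stopifnot(inherits(config, "cohort_config"))
  ion_mode <- match.arg(ion_mode)
  gt <- attr(subjects, "ground_truth")
  if (is.null(gt) || !identical(gt$config$seed, config$seed))
    stop_gbl("subjects must come from simulate_subjects() under the same config")
  set.seed(derive_seed(config$seed, if (ion_mode == "positive") 2L else 3L))
  latent <- gt$latent_metabolites
  n <- nrow(latent); p <- ncol(latent)
  qc <- config$qc
  log_mu <- stats::runif(p, log(1e5), log(1e7))
  areas <- exp(sweep(0.4 * latent, 2L, log_mu, "+"))
  ids <- colnames(latent)
  # zero injection (missingness) into a fraction of good columns, staying
  # above the presence threshold
  n_zero_cols <- floor(qc$zero_col_fraction * p)
  zero_cols <- if (n_zero_cols) sort(sample.int(p, n_zero_cols)) else integer()
  n_zero_rows <- max(1L, floor(qc$zero_fraction * n))
  for (j in zero_cols) areas[sample.int(n, n_zero_rows), j] <- 0
  pooled <- vapply(seq_len(p), function(j) mean(areas[areas[, j] > 0, j]),
                   numeric(1))
  qc_mat <- sapply(seq_len(p), function(j)
    pooled[j] * pmax(0.01, 1 + stats::rnorm(qc$n_qc_reps, 0, qc$qc_cv)))
  blank_mat <- sapply(seq_len(p), function(j)
    pooled[j] / qc$blank_ratio * pmax(0.01, 1 + stats::rnorm(qc$n_blanks, 0, 0.1)))
  add_fail <- function(kind, k, area_fun, qc_fun, blank_fun) {
    if (k == 0L) return(character())
    new_ids <- sprintf("met_fail_%s_%d", kind, seq_len(k))
    for (i in seq_len(k)) {
      mu <- exp(stats::runif(1, log(1e5), log(1e6)))
      a_col <- area_fun(mu); q_col <- qc_fun(mu); b_col <- blank_fun(mu)
      areas <<- cbind(areas, a_col); qc_mat <<- cbind(qc_mat, q_col)
      blank_mat <<- cbind(blank_mat, b_col)
    }
    ids <<- c(ids, new_ids)
    new_ids
  }
  norm_area <- function(mu) mu * exp(stats::rnorm(n, 0, 0.3))
  fail_blank <- add_fail("blank", qc$n_fail_blank,
    norm_area,
    function(mu) mu * (1 + stats::rnorm(qc$n_qc_reps, 0, qc$qc_cv)),
    function(mu) mu / 2 * rep(1, qc$n_blanks))              # ratio ~= 2 < 3
  fail_rsd <- add_fail("rsd", qc$n_fail_rsd,
    norm_area,
    function(mu) mu * rep_len(c(0.3, 1.7), qc$n_qc_reps),   # RSD ~= 74% > 30%
    function(mu) mu / qc$blank_ratio * rep(1, qc$n_blanks))
  n_present <- max(1L, ceiling(0.8 * n) - 1L)               # presence < 80%
  fail_presence <- add_fail("presence", qc$n_fail_presence,
    function(mu) { a <- numeric(n); a[sample.int(n, n_present)] <-
      mu * exp(stats::rnorm(n_present, 0, 0.3)); a },
    function(mu) mu * (1 + stats::rnorm(qc$n_qc_reps, 0, qc$qc_cv)),
    function(mu) mu / qc$blank_ratio * rep(1, qc$n_blanks))
  rownames(areas) <- subjects$subject_id
  panel <- metabolite_panel(areas, qc_mat, blank_mat, ion_mode = ion_mode,
                            metabolite_ids = ids)
  attr(panel, "ground_truth") <- list(
    intended_survivors = colnames(latent), fail_blank = fail_blank,
    fail_rsd = fail_rsd, fail_presence = fail_presence,
    zero_injected = colnames(latent)[zero_cols])
  panel
}

#' Simulate a band-limited 4-D BOLD volume
#'
#' Every voxel's series is the sum of the sinusoidal components whose
#' spatial support contains it, plus Gaussian noise; defaults (175
#' timepoints at TR = 2 s) match a typical resting-state run after
#' dropping initial volumes. With `mirror_symmetric = TRUE` the volume is
#' made exactly equal to its reflection across the midline of the first
#' spatial axis (noise included), the construction VMHC is tested against.
#'
#' @param shape integer 3-vector of spatial dimensions.
#' @param n_timepoints number of volumes.
#' @param tr repetition time, seconds.
#' @param components list of `list(freq =, amplitude =, support =, phase =)`;
#'   `support` is a logical array of `shape` (`NULL` = all voxels), phase
#'   defaults to 0 rad. All frequencies must be strictly below Nyquist.
#' @param noise_sd Gaussian noise SD added to every voxel series.
#' @param mirror_symmetric enforce exact left-right mirror symmetry.
#' @param mask optional logical array; default all voxels.
#' @param seed integer seed.
#' @return A [volume4d()].
#' @export
simulate_volume4d <- function(shape, n_timepoints = 175, tr = 2.0,
                              components = list(), noise_sd = 1,
                              mirror_symmetric = FALSE, mask = NULL,
                              seed = 1) {
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 16L)
  if (length(shape) != 3L) stop_gbl("shape must have three spatial dimensions")
  if (noise_sd < 0) stop_gbl("noise_sd must be >= 0")
  check_flag(mirror_symmetric, "mirror_symmetric")
  nyquist <- 1 / (2 * tr)
  for (cmp in components)
    if (cmp$freq >= nyquist)
      stop_gbl(sprintf("component frequency %g Hz >= Nyquist %g Hz",
                       cmp$freq, nyquist))
  set.seed(seed)
  tt <- (seq_len(n_timepoints) - 1) * tr
  data <- array(stats::rnorm(prod(shape) * n_timepoints, 0, noise_sd),
                c(shape, n_timepoints))
  for (cmp in components) {
    wave <- cmp$amplitude * sin(2 * pi * cmp$freq * tt + (cmp$phase %||% 0))
    support <- cmp$support %||% array(TRUE, shape)
    sup_idx <- which(support)
    for (t in seq_len(n_timepoints)) {
      slab <- data[, , , t, drop = FALSE]
      slab[sup_idx] <- slab[sup_idx] + wave[t]
      data[, , , t] <- slab
    }
  }
  if (mirror_symmetric && shape[1] > 1L) {
    half <- seq_len(floor(shape[1] / 2))
    data[shape[1] + 1L - half, , , ] <- data[half, , , , drop = FALSE]
  }
  volume4d(data, tr, mask)
}

#' Write / read the subject table as TSV
#'
#' @param subjects data.frame from [simulate_subjects()] (or compatible).
#' @param path TSV path.
#' @return `read_subject_table` returns the data.frame;
#'   `write_subject_table` invisibly returns `path`. The ground-truth
#'   attribute is not serialized here; see [write_ground_truth()].
#' @export
write_subject_table <- function(subjects, path) write_tsv(subjects, path)

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) read_tsv(path)

#' Serialize / restore the ground truth of a synthetic cohort
#'
#' The ground truth (realized config and exact planted draws) round-trips
#' losslessly through JSON.
#'
#' @param subjects output of [simulate_subjects()].
#' @param path JSON path.
#' @return `read_ground_truth` returns the ground-truth list.
#' @export
write_ground_truth <- function(subjects, path) {
  gt <- attr(subjects, "ground_truth")
  if (is.null(gt)) stop_gbl("subjects carry no ground-truth attribute")
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$config <- do.call(cohort_config, c(
    gt$config[setdiff(names(gt$config), "mediation_specs")],
    list(mediation_specs = lapply(seq_len(nrow(gt$config$mediation_specs)),
                                  function(i) as.list(gt$config$mediation_specs[i, ])))))
  gt$latent_metabolites <- as.matrix(gt$latent_metabolites)
  gt
}
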