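#' Assemble a pipeline configuration
#'
#' @param subjects subject table: data.frame or TSV path.
#' @param panels named list (by ion mode) of [metabolite_panel()] objects
#'   or panel TSV paths.
#' @param genus name of the microbial abundance column (default
#'   `"Alistipes"`).
#' @param annotations optional [annotation_map()], data.frame or TSV path
#'   (metabolite_id, pathway_id) for the enrichment stage.
#' @param imaging_cols,behavior_cols character vectors of subject-table
#'   columns holding the imaging cluster means and the behavior scores;
#'   defaults pick columns prefixed `img_feat_` and the standard behavior
#'   battery.
#' @param group_col,patient_label group column and patient level; the
#'   PLSR, correlation and mediation stages run within patients only, the
#'   group comparison uses both groups.
#' @param covariates_base base nuisance set (age, gender, education,
#'   site); `covariates_functional` additionally adjusts functional
#'   imaging measures for head motion (FD).
#' @param extra_covariates additional nuisance columns used when
#'   `validation = TRUE` (antidepressant type, illness duration, BMI).
#' @param n_perm,n_boot permutation and bootstrap counts (defaults 5000).
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param out_dir output directory (created if missing).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(subjects, panels, genus = "Alistipes",
                            annotations = NULL,
                            imaging_cols = NULL, behavior_cols = NULL,
                            group_col = "group", patient_label = "MDD",
                            covariates_base = c("age", "gender", "education", "site"),
                            covariates_functional = c("age", "gender", "education",
                                                      "site", "FD"),
                            extra_covariates = c("antidepressant",
                                                 "illness_duration", "BMI"),
                            n_perm = 5000, n_boot = 5000, fdr_alpha = 0.05,
                            seed = 1, out_dir = tempfile("gutbrainlink_run_")) {
  if (is.character(subjects)) subjects <- read_subject_table(subjects)
  panels <- lapply(stats::setNames(names(panels), names(panels)), function(mode) {
    p <- panels[[mode]]
    if (is.character(p)) read_metabolite_panel(p, ion_mode = mode) else p
  })
  if (!is.null(annotations) && !inherits(annotations, "annotation_map"))
    annotations <- annotation_map(annotations)
  if (is.null(imaging_cols))
    imaging_cols <- grep("^img_feat_", names(subjects), value = TRUE)
  if (is.null(behavior_cols))
    behavior_cols <- intersect(behavior_names(), names(subjects))
  stopifnot(genus %in% names(subjects), group_col %in% names(subjects))
  structure(list(subjects = subjects, panels = panels, genus = genus,
                 annotations = annotations, imaging_cols = imaging_cols,
                 behavior_cols = behavior_cols, group_col = group_col,
                 patient_label = patient_label,
                 covariates_base = covariates_base,
                 covariates_functional = covariates_functional,
                 extra_covariates = extra_covariates,
                 n_perm = n_perm, n_boot = n_boot, fdr_alpha = fdr_alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage_log <- function(report, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  c(report, line)
}

#' Run the full multistage linkage analysis
#'
#' Stage order: metabolomics QC per ion mode; Mann-Whitney group
#' comparison of the microbial abundance; first-component PLSR with
#' permutation null and top-20% selection within patients; pathway
#' enrichment of the selected sets (if annotations are supplied);
#' covariate-adjusted partial Spearman screens (metabolites and microbe
#' vs imaging, imaging vs behaviors) with FDR; candidate chaining and
#' bootstrap mediation. Every stage writes its TSV/JSON output under
#' `config$out_dir`, and a manifest (seeds, row/column counts, file MD5
#' hashes) plus a human-readable summary are produced at the end.
#'
#' @param config a [pipeline_config()].
#' @param validation if `TRUE`, the covariate-adjusted stages (screens and
#'   mediation) additionally adjust for the configured extra covariates;
#'   QC, the group test and PLSR selection are covariate-free and are
#'   unchanged by design.
#' @return Invisibly, a list with every stage result, the manifest and
#'   the summary lines; all also on disk.
#' @export
run_all <- function(config, validation = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  check_flag(validation, "validation")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  subjects <- config$subjects
  patients <- subjects[subjects[[config$group_col]] == config$patient_label, ,
                       drop = FALSE]
  if (!nrow(patients)) stop_gbl("stage plsr_link: no rows with ",
                                config$group_col, " == ", config$patient_label)
  report <- character()

  # 1. metabolomics QC
  processed <- list()
  for (mode in names(config$panels)) {
    processed[[mode]] <- tryCatch(process_metabolome(config$panels[[mode]]),
      error = function(e) stop_gbl("stage metabolome_qc (", mode, "): ",
                                   conditionMessage(e)))
    write_tsv(processed[[mode]]$filter_log, out(paste0("filter_log_", mode, ".tsv")))
    report <- stage_log(report, "metabolome_qc", sprintf(
      "%s mode: %d of %d metabolites survive QC",
      mode, ncol(processed[[mode]]$z_matrix),
      nrow(processed[[mode]]$filter_log)))
  }

  # 2. group comparison of the microbial abundance
  grp <- subjects[[config$group_col]]
  mw <- mann_whitney(subjects[[config$genus]][grp == config$patient_label],
                     subjects[[config$genus]][grp != config$patient_label])
  jsonlite::write_json(unclass(mw), out("group_test.json"), auto_unbox = TRUE,
                       digits = NA)
  report <- stage_log(report, "assoc_stats", sprintf(
    "%s %s vs rest: U = %g, z = %.3f, P = %.3g", config$genus,
    config$patient_label, mw$u_statistic, mw$z_value, mw$p_value))

  # 3. PLSR linkage within patients, per ion mode
  plsr <- list()
  for (mode in names(processed)) {
    z_full <- processed[[mode]]$z_matrix
    rows <- match(patients$subject_id, rownames(z_full))
    if (any(is.na(rows)))
      stop_gbl("stage plsr_link: panel rows do not cover all patients (", mode, ")")
    zp <- zscore_cols(z_full[rows, , drop = FALSE])
    plsr[[mode]] <- plsr_link(zp, patients[[config$genus]],
                              n_perm = config$n_perm,
                              seed = derive_seed(config$seed, 10L + match(mode, names(processed))))
    plsr[[mode]]$ion_mode <- mode
    write_loading_table(plsr[[mode]], out(paste0("plsr_loadings_", mode, ".tsv")))
    jsonlite::write_json(
      list(ion_mode = mode, overall_r = plsr[[mode]]$overall_r,
           p_perm = plsr[[mode]]$p_perm, n_perm = plsr[[mode]]$n_perm,
           plsr_pos = plsr[[mode]]$plsr_pos, plsr_neg = plsr[[mode]]$plsr_neg),
      out(paste0("plsr_result_", mode, ".json")), auto_unbox = TRUE, digits = NA)
    report <- stage_log(report, "plsr_link", sprintf(
      "%s mode: overall r = %.3f, P_perm = %.4g, |PLSR+| = |PLSR-| = %d",
      mode, plsr[[mode]]$overall_r, plsr[[mode]]$p_perm,
      length(plsr[[mode]]$plsr_pos)))
  }

  # 4. enrichment of the selected sets
  enrich_res <- list()
  if (!is.null(config$annotations)) {
    for (mode in names(plsr)) for (set in c("plsr_pos", "plsr_neg")) {
      tag <- paste0(mode, "_", sub("plsr_", "", set))
      enrich_res[[tag]] <- tryCatch(
        enrich(plsr[[mode]][[set]], config$annotations,
               universe = colnames(processed[[mode]]$z_matrix)),
        error = function(e) stop_gbl("stage enrichment (", tag, "): ",
                                     conditionMessage(e)))
      write_tsv(enrich_res[[tag]], out(paste0("enrichment_", tag, ".tsv")))
      report <- stage_log(report, "enrichment", sprintf(
        "%s: %d pathway(s) at q < %g", tag,
        sum(enrich_res[[tag]]$q_fdr < config$fdr_alpha), config$fdr_alpha))
    }
  }

  # 5. correlation screens within patients
  covs_fun <- config$covariates_functional
  if (validation) covs_fun <- c(covs_fun, config$extra_covariates)
  selected_ids <- unique(unlist(lapply(plsr, function(r) c(r$plsr_pos, r$plsr_neg))))
  met_features <- lapply(stats::setNames(names(processed), names(processed)),
    function(mode) {
      z <- processed[[mode]]$z_matrix
      z <- z[match(patients$subject_id, rownames(z)),
             intersect(selected_ids, colnames(z)), drop = FALSE]
      # ion modes share the metabolite id scheme; prefix to disambiguate
      colnames(z) <- paste0(substr(mode, 1, 3), "_", colnames(z))
      z
    })
  xm_features <- cbind(patients[config$genus],
                       do.call(cbind, lapply(met_features, as.data.frame)))
  names(xm_features) <- c(config$genus, unlist(lapply(met_features, colnames)))
  imaging <- patients[config$imaging_cols]
  behaviors <- patients[config$behavior_cols]
  covs <- patients[intersect(covs_fun, names(patients))]
  xm_screen <- correlation_screen(xm_features, imaging, covs,
                                  alpha = config$fdr_alpha)
  my_screen <- correlation_screen(imaging, behaviors, covs,
                                  alpha = config$fdr_alpha)
  write_tsv(xm_screen, out("screen_features_imaging.tsv"))
  write_tsv(my_screen, out("screen_imaging_behaviors.tsv"))
  report <- stage_log(report, "correlation_screen", sprintf(
    "features-imaging: %d/%d significant; imaging-behaviors: %d/%d significant",
    sum(xm_screen$significant), nrow(xm_screen),
    sum(my_screen$significant), nrow(my_screen)))

  # 6. mediation over chained candidates
  xm_met <- xm_screen[xm_screen$feature != config$genus, , drop = FALSE]
  candidates <- chain_candidates(xm_met, my_screen)
  med_data <- cbind(xm_features, imaging, behaviors)
  med <- mediation_screen(med_data, candidates, covariates = covs,
                          n_boot = config$n_boot,
                          seed = derive_seed(config$seed, 20L))
  write_tsv(med, out("mediation_results.tsv"))
  report <- stage_log(report, "mediation", sprintf(
    "%d candidate chain(s), %d significant", nrow(med),
    attr(med, "n_significant")))

  # manifest + summary
  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gutbrainlink")),
    seed = config$seed, n_perm = config$n_perm, n_boot = config$n_boot,
    fdr_alpha = config$fdr_alpha, validation = validation,
    n_subjects = nrow(subjects), n_patients = nrow(patients),
    covariates_functional = covs_fun,
    file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(report, out("summary.txt"))
  invisible(list(processed = processed, group_test = mw, plsr = plsr,
                 enrichment = enrich_res, xm_screen = xm_screen,
                 my_screen = my_screen, candidates = candidates,
                 mediation = med, manifest = manifest, report = report,
                 out_dir = config$out_dir))
}

#' Generate a complete synthetic study input set on disk
#'
#' Convenience wrapper used by the command-line interface: simulates the
#' subject table, one metabolite panel per ion mode, a small demo 4-D
#' volume with mask and cluster labels, and the ground truth, and writes
#' them under `out_dir`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @param volume_shape spatial shape of the demo volume.
#' @return Invisibly, the list of written paths.
#' @export
simulate_study <- function(config, out_dir, volume_shape = c(12, 12, 6)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- simulate_subjects(config)
  paths <- list(subjects = file.path(out_dir, "subjects.tsv"),
                ground_truth = file.path(out_dir, "ground_truth.json"))
  write_subject_table(subjects, paths$subjects)
  write_ground_truth(subjects, paths$ground_truth)
  for (mode in c("positive", "negative")) {
    panel <- simulate_metabolite_panel(config, subjects, ion_mode = mode)
    paths[[paste0("panel_", mode)]] <- file.path(out_dir,
                                                 paste0("panel_", mode, ".tsv"))
    write_metabolite_panel(panel, paths[[paste0("panel_", mode)]])
  }
  sup <- array(FALSE, volume_shape)
  sup[seq_len(max(1, volume_shape[1] %/% 2)), , ] <- TRUE
  vol <- simulate_volume4d(volume_shape,
                           components = list(list(freq = 0.05, amplitude = 2,
                                                  support = sup)),
                           noise_sd = 0.5, seed = derive_seed(config$seed, 30L))
  paths$bold <- file.path(out_dir, "bold.nii")
  write_nifti(vol$data, paths$bold, tr = vol$tr)
  paths$mask <- file.path(out_dir, "mask.nii")
  write_nifti(vol$mask, paths$mask)
  labels <- array(0L, volume_shape)
  labels[1:2, 1:2, 1] <- 1L; labels[3:4, 3:4, 2] <- 2L
  paths$labels <- file.path(out_dir, "labels.nii")
  write_nifti(array(as.numeric(labels), volume_shape), paths$labels)
  invisible(paths)
}
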