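make_panel <- function(sample, qc, blank, ids = NULL) {
  metabolite_panel(sample, qc, blank, ion_mode = "positive",
                   metabolite_ids = ids %||% paste0("m", seq_len(ncol(sample))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("blank-ratio filter follows the strict < threshold rule", {
  # QC means [300,100,90,500], blank means [100,50,10,100]:
  # ratios [3, 2, 9, 5]; only ratio 2 (< 3) is removed, exactly 3 is kept
  qc <- rbind(c(300, 100, 90, 500), c(300, 100, 90, 500))
  blank <- rbind(c(100, 50, 10, 100))
  sample <- matrix(1000, 5, 4)
  p <- filter_blank_ratio(make_panel(sample, qc, blank))
  expect_identical(p$metabolite_ids, c("m1", "m3", "m4"))
  expect_equal(p$filter_log$qc_blank_ratio, c(3, 2, 9, 5))
  expect_identical(p$filter_log$removal_reason,
                   c(NA, "qc_blank_ratio", NA, NA))

  # all blank means 0: infinite ratio, nothing removed
  p2 <- filter_blank_ratio(make_panel(sample, qc, matrix(0, 1, 4)))
  expect_length(p2$metabolite_ids, 4L)

  # QC = blank columns: ratio 1 < 3 everywhere, all removed
  p3 <- filter_blank_ratio(make_panel(sample, qc[1, , drop = FALSE],
                                      qc[1, , drop = FALSE]))
  expect_length(p3$metabolite_ids, 0L)

  expect_error(filter_blank_ratio(make_panel(sample, qc,
                                             matrix(0, 0, 4))), "blank")
})

test_that("RSD filter discards strictly above 30% with n-1 SD", {
  sample <- matrix(10, 4, 3)
  # col 1: [10,10,10] RSD 0 kept; col 2: [1,2,3] mean 2, sd 1, RSD 50%
  # discarded; col 3: RSD exactly at the threshold kept (strict >); the
  # boundary uses dyadic values (sd 0.25, mean 1) so RSD == 25 exactly
  x <- 1 + c(-0.25, 0, 0.25)
  qc <- cbind(c(10, 10, 10), c(1, 2, 3), x)
  blank <- matrix(0.0, 1, 3)
  p <- filter_rsd(make_panel(sample, qc, blank), max_rsd_percent = 25)
  expect_identical(p$metabolite_ids, c("m1", "m3"))
  expect_equal(p$filter_log$rsd_percent, c(0, 50, 25), tolerance = 1e-12)
  expect_error(filter_rsd(make_panel(sample, qc[1, , drop = FALSE], blank)),
               "QC replicate")
})

test_that("presence filter keeps at least 80% nonzero, boundary inclusive", {
  qc <- matrix(5, 2, 3); blank <- matrix(0, 1, 3)
  sample <- cbind(c(rep(1, 8), 0, 0),   # 8/10 kept (>= 0.80)
                  c(rep(1, 7), 0, 0, 0),# 7/10 removed
                  rep(0, 10))           # all-zero removed
  p <- filter_presence(make_panel(sample, qc, blank))
  expect_identical(p$metabolite_ids, "m1")
  expect_equal(p$filter_log$presence_fraction, c(0.8, 0.7, 0))
})

test_that("imputation replaces zeros by one fifth of the column minimum positive", {
  qc <- matrix(5, 2, 3); blank <- matrix(0, 1, 3)
  sample <- cbind(c(0, 2, 5), c(1, 2, 3), c(0, 0.5, 1))
  p <- impute_missing(make_panel(sample, qc, blank))
  expect_equal(p$sample_areas[, 1], c(0.4, 2, 5))
  expect_equal(p$sample_areas[, 2], c(1, 2, 3))   # no zeros: unchanged
  expect_equal(p$sample_areas[, 3], c(0.1, 0.5, 1))
})

test_that("glog is strictly increasing and normalize_and_scale z-scores exactly", {
  grid <- sort(c(0, 10^runif(50, -3, 3)))
  g <- glog(grid, lambda = 0.7)
  expect_true(all(diff(g) > 0))
  # closed form check on the grid
  expect_equal(g, log2((grid + sqrt(grid^2 + 0.49)) / 2), tolerance = 1e-12)
  expect_error(glog(1, lambda = 0), "positive")

  set.seed(42)
  sample <- matrix(exp(rnorm(60, 5)), 12, 5)
  qc <- matrix(exp(rnorm(15, 5)), 3, 5)
  blank <- matrix(1, 1, 5)
  proc <- normalize_and_scale(make_panel(sample, qc, blank))
  expect_lt(max(abs(colMeans(proc$z_matrix))), 1e-9)
  expect_lt(max(abs(apply(proc$z_matrix, 2, sd) - 1)), 1e-9)

  # identical column -> zero variance error naming the column
  sample[, 2] <- 7
  expect_error(normalize_and_scale(make_panel(sample, qc, blank)), "m2")
})

test_that("z-matrix is invariant to rescaling a raw column by k > 0", {
  set.seed(7)
  sample <- matrix(exp(rnorm(80, 3)), 16, 5)
  qc <- matrix(exp(rnorm(20, 3)), 4, 5)
  blank <- matrix(0.5, 2, 5)
  p1 <- normalize_and_scale(make_panel(sample, qc, blank))
  k <- 37.5
  sample2 <- sample; sample2[, 3] <- sample[, 3] * k
  qc2 <- qc; qc2[, 3] <- qc[, 3] * k
  blank2 <- blank; blank2[, 3] <- blank[, 3] * k
  p2 <- normalize_and_scale(make_panel(sample2, qc2, blank2))
  expect_equal(p1$z_matrix, p2$z_matrix, tolerance = 1e-10)
})

test_that("full cascade: one removal reason each, survivors + removed = input", {
  cfg <- small_config(seed = 11)
  subj <- simulate_subjects(cfg)
  panel <- simulate_metabolite_panel(cfg, subj)
  gt <- attr(panel, "ground_truth")
  proc <- process_metabolome(panel)
  log <- proc$filter_log
  expect_setequal(log$metabolite_id, panel$metabolite_ids)
  expect_identical(nrow(log), length(panel$metabolite_ids))
  expect_true(all(is.na(log$removal_reason[log$kept])))
  expect_true(all(!is.na(log$removal_reason[!log$kept])))
  # exact survivor set comparison against the generator's ground truth
  expect_setequal(colnames(proc$z_matrix), gt$intended_survivors)
  expect_setequal(log$metabolite_id[log$removal_reason == "qc_blank_ratio" &
                                      !is.na(log$removal_reason)], gt$fail_blank)
  expect_setequal(log$metabolite_id[log$removal_reason == "rsd" &
                                      !is.na(log$removal_reason)], gt$fail_rsd)
  expect_setequal(log$metabolite_id[log$removal_reason == "presence" &
                                      !is.na(log$removal_reason)], gt$fail_presence)
})

test_that("panel TSV round-trips", {
  cfg <- small_config(seed = 3)
  subj <- simulate_subjects(cfg)
  panel <- simulate_metabolite_panel(cfg, subj)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metabolite_panel(panel, path)
  p2 <- read_metabolite_panel(path, ion_mode = "positive")
  expect_equal(unname(p2$sample_areas), unname(panel$sample_areas),
               tolerance = 1e-12)
  expect_identical(p2$metabolite_ids, panel$metabolite_ids)
})
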