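# Volumes are small (<= 12x12x6) so every oracle comparison stays fast.

rand_vol <- function(shape = c(5, 4, 3), nt = 40, tr = 2, seed = 1,
                     mask = NULL) {
  set.seed(seed)
  volume4d(array(rnorm(prod(shape) * nt), c(shape, nt)), tr, mask)
}

test_that("ALFF/fALFF match the summation-DFT oracle and closed-form limits", {
  v <- rand_vol(seed = 5)
  a <- alff(v); fa <- falff(v)
  ms <- v$data
  for (vox in list(c(1, 1, 1), c(3, 2, 2), c(5, 4, 3))) {
    x <- ms[vox[1], vox[2], vox[3], ]
    expect_equal(a$values[vox[1], vox[2], vox[3]], oracle_alff(x, v$tr),
                 tolerance = 1e-10)
    expect_equal(fa$values[vox[1], vox[2], vox[3]], oracle_falff(x, v$tr),
                 tolerance = 1e-10)
  }

  # constant series -> ALFF 0 (DC excluded)
  vc <- volume4d(array(3.7, c(2, 2, 2, 32)), tr = 2)
  expect_true(all(alff(vc)$values == 0))

  # bin-aligned pure sinusoids: amplitude linearity and fALFF in {0, 1}
  nt <- 100; tr <- 2; tt <- (0:(nt - 1)) * tr
  d <- array(0, c(2, 1, 1, nt))
  d[1, 1, 1, ] <- 2 * sin(2 * pi * 0.05 * tt)
  d[2, 1, 1, ] <- 1 * sin(2 * pi * 0.05 * tt)
  vs <- volume4d(d, tr)
  av <- alff(vs)$values
  expect_equal(av[1, 1, 1] / av[2, 1, 1], 2, tolerance = 1e-6)
  expect_equal(falff(vs)$values[1, 1, 1], 1, tolerance = 1e-9)
  d_out <- array(sin(2 * pi * 0.2 * tt), c(1, 1, 1, nt))  # out of band
  expect_equal(falff(volume4d(d_out, tr))$values[1, 1, 1], 0, tolerance = 1e-9)

  # empty band errors with the bin grid reported
  expect_error(alff(rand_vol(nt = 20, tr = 0.1), band = c(0.011, 0.012)),
               "bin")
})

test_that("ALFF and fALFF are invariant to time reversal", {
  v <- rand_vol(seed = 9)
  vr <- volume4d(v$data[, , , dim(v$data)[4]:1], v$tr, v$mask)
  expect_equal(alff(v)$values, alff(vr)$values, tolerance = 1e-10)
  expect_equal(falff(v)$values, falff(vr)$values, tolerance = 1e-10)
})

test_that("ReHo equals the literal Kendall-W oracle and hits the W = 1 limits", {
  # interior voxel of a 3x3x3 full mask has the full 26-neighborhood
  set.seed(3)
  v <- rand_vol(shape = c(3, 3, 3), nt = 40, seed = 3)
  w <- reho(v)$values[2, 2, 2]
  block <- matrix(aperm(v$data, c(4, 1, 2, 3)), nrow = 40)  # 27 series
  expect_equal(w, oracle_kendall_w(block), tolerance = 1e-12)

  # corner voxel: 8-voxel neighborhood
  w_corner <- reho(v)$values[1, 1, 1]
  sub <- matrix(aperm(v$data[1:2, 1:2, 1:2, , drop = FALSE],
                      c(4, 1, 2, 3)), nrow = 40)
  expect_equal(w_corner, oracle_kendall_w(sub), tolerance = 1e-12)

  # identical non-constant series and strictly monotone series: W = 1
  base <- rnorm(40)
  vi <- volume4d(array(rep(base, each = 27), c(3, 3, 3, 40)), 2)
  expect_equal(reho(vi)$values[2, 2, 2], 1, tolerance = 1e-12)
  mono <- array(0, c(3, 3, 3, 40))
  for (t in 1:40) mono[, , , t] <- t + array(runif(27), c(3, 3, 3)) * 0.01
  expect_equal(reho(volume4d(mono, 2))$values[2, 2, 2], 1, tolerance = 1e-12)

  expect_true(all(reho(v)$values >= 0 & reho(v)$values <= 1))
})

test_that("ReHo flags isolated voxels with value 0", {
  mask <- array(FALSE, c(5, 4, 3))
  mask[1, 1, 1] <- TRUE; mask[5, 4, 3] <- TRUE  # two isolated voxels
  v <- rand_vol(mask = mask, seed = 2)
  r <- reho(v)
  expect_true(all(r$values == 0))
  expect_length(r$flags$isolated, 2L)
})

test_that("FCD equals the brute-force all-pairs oracle", {
  set.seed(11)
  shape <- c(10, 5, 4)                      # 200 voxels x 60 timepoints
  v <- volume4d(array(rnorm(prod(shape) * 60, sd = 1) +
                        rep(rnorm(60), each = prod(shape)) * 0.4,
                      c(shape, 60)), 2)
  got <- fcd(v, 0.25)$values[v$mask]
  series <- matrix(aperm(v$data, c(4, 1, 2, 3)), nrow = 60)
  expect_identical(as.integer(got), oracle_fcd(series, 0.25))

  # identical series: everyone connects to everyone else
  vi <- volume4d(array(rep(rnorm(30), each = 5), c(5, 1, 1, 30)), 2)
  expect_true(all(fcd(vi)$values == 4))

  # the threshold rule is strictly greater-than: a pair engineered just
  # below 0.25 is never counted, just above always is (an exactly-0.25
  # pair cannot be represented stably through floating point, so the two
  # one-sided probes pin the decision rule)
  t1 <- rnorm(40); t1 <- (t1 - mean(t1)) / sd(t1)
  e <- residuals(lm(rnorm(40) ~ t1)); e <- e / sd(e)
  mk <- function(r) {
    t2 <- r * t1 + sqrt(1 - r^2) * e
    d <- array(0, c(2, 1, 1, 40))
    d[1, 1, 1, ] <- t1; d[2, 1, 1, ] <- t2
    fcd(volume4d(d, 2), 0.25)$values
  }
  expect_true(all(mk(0.25 - 1e-6) == 0))
  expect_true(all(mk(0.25 + 1e-6) == 1))

  expect_error(fcd(rand_vol(mask = array(c(TRUE, rep(FALSE, 59)), c(5, 4, 3)))),
               ">= 2")
})

test_that("FCD and VMHC are invariant to permuting timepoints", {
  v <- rand_vol(seed = 13, nt = 30)
  set.seed(99); perm <- sample(30)
  vp <- volume4d(v$data[, , , perm], v$tr, v$mask)
  expect_equal(fcd(v)$values, fcd(vp)$values)
  expect_equal(vmhc(v)$values, vmhc(vp)$values, tolerance = 1e-12)
})

test_that("VMHC matches the per-pair correlation oracle and its limits", {
  v <- rand_vol(shape = c(6, 4, 3), nt = 40, seed = 21)
  m <- vmhc(v)$values
  for (vox in list(c(1, 2, 1), c(3, 4, 2), c(6, 1, 3))) {
    x <- v$data[vox[1], vox[2], vox[3], ]
    y <- v$data[7 - vox[1], vox[2], vox[3], ]
    expect_equal(m[vox[1], vox[2], vox[3]], cor(x, y), tolerance = 1e-12)
  }
  expect_true(all(m >= -1 & m <= 1))

  # mirror-symmetric volume: all VMHC = 1
  vs <- simulate_volume4d(c(6, 4, 3), n_timepoints = 32, tr = 2, noise_sd = 1,
                          mirror_symmetric = TRUE, seed = 4)
  expect_true(all(abs(vmhc(vs)$values[vs$mask] - 1) < 1e-10))

  # negated counterpart: VMHC = -1
  d <- vs$data; d[4:6, , , ] <- -d[4:6, , , ]
  expect_true(all(abs(vmhc(volume4d(d, 2))$values + 1) < 1e-10))

  # VMHC commutes with mirroring the volume
  vm <- volume4d(v$data[6:1, , , ], v$tr, v$mask[6:1, , , drop = FALSE])
  expect_equal(vmhc(vm)$values[6:1, , ], vmhc(v)$values, tolerance = 1e-12)
})

test_that("standardization rescales to mean 1, is idempotent and homogeneous", {
  v <- rand_vol(seed = 31)
  a <- alff(v)
  s <- standardize_map(a, v$mask)
  expect_lt(abs(mean(s$values[v$mask]) - 1), 1e-9)
  s2 <- standardize_map(s, v$mask)
  expect_equal(s$values, s2$values, tolerance = 1e-12)
  # scaling the input data by k > 0 leaves the standardized ALFF unchanged
  vk <- volume4d(v$data * 12.3, v$tr, v$mask)
  sk <- standardize_map(alff(vk), v$mask)
  expect_equal(s$values, sk$values, tolerance = 1e-10)
  zero <- a; zero$values[] <- 0
  expect_error(standardize_map(zero, array(TRUE, dim(zero$values))),
               "degenerate")
})

test_that("cluster means equal the per-label loop oracle and partition identity", {
  v <- rand_vol(shape = c(6, 6, 4), seed = 8)
  map <- alff(v)
  set.seed(5)
  labels <- array(sample(0:3, 144, replace = TRUE), c(6, 6, 4))
  cm <- extract_cluster_means(map, labels)
  for (lb in 1:3)
    expect_equal(cm$mean_value[cm$label == lb], mean(map$values[labels == lb]))

  # single-voxel cluster
  l1 <- array(0, c(6, 6, 4)); l1[2, 3, 1] <- 7L
  expect_equal(extract_cluster_means(map, l1)$mean_value, map$values[2, 3, 1])

  # two clusters partitioning the mask: size-weighted mean = whole-mask mean
  part <- array(1L, c(6, 6, 4)); part[1:3, , ] <- 2L
  cmp <- extract_cluster_means(map, part)
  expect_equal(sum(cmp$mean_value * cmp$n_voxels) / sum(cmp$n_voxels),
               mean(map$values))

  # label entirely outside the mask is omitted with a warning
  mask <- array(TRUE, c(6, 6, 4)); mask[6, 6, 4] <- FALSE
  lout <- array(0, c(6, 6, 4)); lout[6, 6, 4] <- 9L
  expect_warning(out <- extract_cluster_means(map, lout, mask), "omitted")
  expect_identical(nrow(out), 0L)
})

test_that("metric maps are zero outside the mask and bandpass precedes ReHo/FCD/VMHC", {
  mask <- array(FALSE, c(5, 4, 3)); mask[2:4, 2:3, 1:2] <- TRUE
  v <- rand_vol(mask = mask, seed = 17)
  for (f in list(alff, falff, reho, function(x) fcd(x), vmhc)) {
    mp <- f(v)
    expect_true(all(mp$values[!mask] == 0))
  }
  # bandpass removes an out-of-band tone almost entirely
  nt <- 100; tt <- (0:(nt - 1)) * 2
  d <- array(rep(sin(2 * pi * 0.2 * tt), each = 60), c(5, 4, 3, nt))
  vf <- bandpass(volume4d(d, 2, mask))
  expect_lt(max(abs(vf$data[rep_mask <- array(mask, c(5, 4, 3, nt))])), 1e-9)
})
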