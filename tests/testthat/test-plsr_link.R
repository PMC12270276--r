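test_that("first component matches the SVD oracle and trivial limits", {
  set.seed(1)
  # single column equal to the microbe: weight 1, perfect correlation
  microbe <- rnorm(20)
  z1 <- matrix(scale(microbe), ncol = 1)
  f1 <- plsr_first_component(z1, microbe)
  expect_equal(unname(f1$weights), 1)
  expect_equal(overall_association(f1$scores, microbe), 1, tolerance = 1e-12)

  # orthogonal columns, microbe equal to column 1: weights ~ (1, 0)
  a <- scale(rnorm(50)); b <- scale(residuals(lm(rnorm(50) ~ a)))
  f2 <- plsr_first_component(cbind(a, b), as.numeric(a))
  expect_equal(unname(f2$weights), c(1, 0), tolerance = 1e-10)

  # random matrix: scores align with the SVD of the cross-covariance
  z <- matrix(rnorm(200), 20, 10)
  m <- rnorm(20)
  f3 <- plsr_first_component(z, m)
  w_svd <- oracle_plsr_weights(z, m)
  expect_gte(abs(cor(f3$scores, as.numeric(z %*% w_svd))), 1 - 1e-9)

  expect_error(plsr_first_component(z, rep(1, 20)), "constant")
  expect_error(plsr_first_component(z[1:2, ], m[1:2]), ">= 3")
})

test_that("overall association matches the textbook formula and the null", {
  set.seed(2)
  x <- rnorm(100); y <- 2 * x + rnorm(100)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(overall_association(x, y), oracle, tolerance = 1e-12)
  big <- rnorm(10000)
  expect_lt(abs(overall_association(big, rnorm(10000))), 0.05)
  expect_error(overall_association(rep(1, 5), rnorm(5)), "variance")
})

test_that("permutation p matches exhaustive enumeration at n = 6", {
  set.seed(3)
  z <- matrix(rnorm(30), 6, 5)
  microbe <- rnorm(6)
  perms <- all_permutations(6)           # 720 shuffles
  res <- permutation_test(z, microbe, perms = perms)
  # independent enumeration through the SVD-oracle route
  r_null <- apply(perms, 1L, function(ix) {
    mp <- microbe[ix]
    w <- oracle_plsr_weights(z, mp)
    abs(cor(as.numeric(z %*% w), mp))    # sign-fixed r is |cor| here
  })
  r_obs <- abs(cor(as.numeric(z %*% oracle_plsr_weights(z, microbe)), microbe))
  expect_equal(res$p_perm, (1 + sum(r_null >= r_obs - 1e-12)) / (1 + 720),
               tolerance = 1e-12)
  # add-one formula: minimum achievable p at 5000 shuffles is 1/5001
  expect_gt(res$p_perm, 0)
  expect_equal((1 + 0) / (1 + 5000), 1 / 5001)
})

test_that("permutation test is deterministic under a fixed seed", {
  set.seed(4)
  z <- matrix(rnorm(15 * 8), 15, 8)
  m <- rnorm(15)
  p1 <- permutation_test(z, m, n_perm = 99, seed = 42)
  p2 <- permutation_test(z, m, n_perm = 99, seed = 42)
  expect_identical(p1$r_perm, p2$r_perm)
  expect_identical(p1$p_perm, p2$p_perm)
})

test_that("loadings match the per-column correlation oracle", {
  set.seed(5)
  z <- matrix(rnorm(40 * 6), 40, 6)
  colnames(z) <- paste0("m", 1:6)
  f <- plsr_first_component(z, rnorm(40))
  lo <- contribution_loadings(z, f$scores)
  for (j in 1:6) expect_equal(unname(lo[j]), cor(z[, j], f$scores),
                              tolerance = 1e-12)
  # single column: loading 1; orthogonal column: loading ~ 0
  z1 <- matrix(scale(rnorm(30)), ncol = 1, dimnames = list(NULL, "only"))
  f1 <- plsr_first_component(z1, as.numeric(z1) + rnorm(30, sd = 0.1))
  expect_equal(unname(contribution_loadings(z1, f1$scores)), 1,
               tolerance = 1e-12)
  zc <- cbind(z, const = 1)
  lo2 <- contribution_loadings(zc, f$scores)
  expect_equal(unname(lo2["const"]), 0)
  expect_identical(attr(lo2, "flagged_constant"), "const")
  # loading identity for z-scored columns: loading_j = cov(col, scores)/sd(scores)
  zs <- scale(z)
  fs <- plsr_first_component(zs, rnorm(40))
  los <- contribution_loadings(zs, fs$scores)
  expect_equal(unname(los),
               unname(as.numeric(cov(zs, fs$scores)) / sd(fs$scores) /
                        apply(zs, 2, sd)), tolerance = 1e-10)
})

test_that("top-20% selection sizes, tie-breaks and extreme ranks", {
  lo <- seq(-1, 1, length.out = 100)
  names(lo) <- sprintf("m%03d", 1:100)
  sel <- select_top20(lo)
  expect_length(sel$plsr_pos, 20L)
  expect_length(sel$plsr_neg, 20L)
  expect_setequal(sel$plsr_pos, names(lo)[81:100])  # k largest
  expect_setequal(sel$plsr_neg, names(lo)[1:20])    # k smallest
  # ties broken by identifier order
  lot <- setNames(rep(c(0.5, -0.5), each = 5), paste0("t", 1:10))
  selt <- select_top20(lot)
  expect_identical(selt$plsr_pos, c("t1", "t2"))
  expect_identical(selt$plsr_neg, c("t10", "t6"))
  # truncation with warning when a sign runs out
  lop <- setNames(c(abs(rnorm(9)) + 0.1, -0.2), paste0("p", sprintf("%02d", 1:10)))
  expect_warning(selp <- select_top20(lop), "negative")
  expect_length(selp$plsr_neg, 1L)
  expect_error(select_top20(setNames(rnorm(4), letters[1:4])), ">= 5")
})

test_that("sign convention: negating the microbe flips weights and swaps sets", {
  set.seed(6)
  z <- matrix(rnorm(30 * 20), 30, 20)
  colnames(z) <- sprintf("m%02d", 1:20)
  m <- rnorm(30)
  f <- plsr_first_component(z, m)
  fn <- plsr_first_component(z, -m)
  expect_equal(fn$weights, -f$weights, tolerance = 1e-12)
  expect_equal(overall_association(fn$scores, -m),
               overall_association(f$scores, m), tolerance = 1e-12)
  lo <- contribution_loadings(z, f$scores)
  lon <- contribution_loadings(z, fn$scores)
  sel <- select_top20(lo); seln <- select_top20(lon)
  expect_setequal(seln$plsr_pos, sel$plsr_neg)
  expect_setequal(seln$plsr_neg, sel$plsr_pos)
})

test_that("permutation p is invariant to common monotone rescaling of columns", {
  set.seed(7)
  z <- scale(matrix(rnorm(25 * 6), 25, 6))
  m <- rnorm(25)
  p1 <- permutation_test(z, m, n_perm = 50, seed = 9)
  p2 <- permutation_test(z * 3.7, m, n_perm = 50, seed = 9)
  expect_equal(p1$p_perm, p2$p_perm)
  expect_equal(p1$r_perm, p2$r_perm, tolerance = 1e-12)
})
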