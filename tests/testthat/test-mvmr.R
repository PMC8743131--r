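test_that("multivariable IVW recovers exact-fit direct effects", {
  set.seed(13)
  bx1 <- runif(10, 0.05, 0.2)
  bx2 <- runif(10, 0.05, 0.2)
  by <- 0.3 * bx1 - 0.2 * bx2
  h <- harmonized_set(cbind(bx1, bx2), matrix(1e-12, 10, 2), by,
                      rep(0.01, 10))
  h$sx[] <- 0.004
  res <- mvmr_ivw(h)
  expect_equal(res$direct_betas, c(0.3, -0.2), tolerance = 1e-10)
  # at the true coefficients with sx = 0 the adjusted Q vanishes
  h0 <- h; h0$sx[] <- 0
  expect_equal(mvmr_q(h0, c(0.3, -0.2))$Q, 0, tolerance = 1e-18)
})

test_that("multivariable IVW with one exposure equals univariable IVW", {
  set.seed(17)
  bx <- runif(12, 0.05, 0.2)
  by <- 0.25 * bx + rnorm(12, 0, 0.01)
  h1 <- harmonized_set(bx, rep(0.005, 12), by, rep(0.01, 12))
  uni <- mr_ivw(h1)
  multi <- mvmr_ivw(h1)
  expect_equal(multi$direct_betas, uni$beta)
  expect_equal(multi$ses, uni$se)
  expect_equal(multi$pvalues, uni$pvalue)
})

test_that("the single-exposure adjusted Q augments weights with exposure noise", {
  set.seed(19)
  bx <- runif(8, 0.05, 0.2)
  by <- 0.25 * bx + rnorm(8, 0, 0.01)
  h <- harmonized_set(bx, rep(0.02, 8), by, rep(0.01, 8))
  theta <- mr_ivw(h)$beta
  qa <- mvmr_q(h, theta)
  manual <- sum((by - theta * bx)^2 / (0.01^2 + theta^2 * 0.02^2))
  expect_equal(qa$Q, manual)
  expect_equal(qa$df, 7L)
  # with sx = 0 it reduces to the univariable Cochran Q at that beta
  h0 <- h; h0$sx[] <- 0
  expect_equal(mvmr_q(h0, theta)$Q, sum((by - theta * bx)^2 / 0.01^2))
})

test_that("identical exposure columns raise a collinearity error", {
  bx <- runif(10, 0.05, 0.2)
  h <- harmonized_set(cbind(bx, bx), matrix(0.005, 10, 2),
                      0.3 * bx, rep(0.01, 10))
  expect_error(mvmr_ivw(h), class = "mrlink_numeric_error")
  # but conditional strength is still defined, and is (near) zero
  expect_lt(conditional_f(h, 1), 0.1)
  expect_lt(conditional_f(h, 2), 0.1)
})

test_that("a null second exposure leaves the first direct effect nested", {
  sm <- simulate_mvmr(sim_config(n_snps = 100, theta = c(0.3, 0),
                                 bx_sd = c(0.02, 0), seed = 23))
  h <- h_from_mvmr(sm)
  multi <- mvmr_ivw(h, conditional_F = FALSE)
  h1 <- harmonized_set(h$bx[, 1], h$sx[, 1], h$by, h$sy)
  uni <- mr_ivw(h1)
  expect_equal(multi$direct_betas[1], uni$beta, tolerance = 3 * uni$se)
  expect_lt(abs(multi$direct_betas[2]), 3 * multi$ses[2])
})

test_that("conditional F tracks univariable strength for specific instruments", {
  set.seed(29)
  fs <- vapply(1:20, function(r) {
    sm <- simulate_mvmr(sim_config(n_snps = 100, theta = c(0.3, -0.2),
                                   exposure_cor = 0, seed = 2900 + r))
    h <- h_from_mvmr(sm)
    c(conditional_f(h, 1), mean(per_snp_f(harmonized_set(
      h$bx[, 1], h$sx[, 1], h$by, h$sy))$per_snp_F))
  }, c(0, 0))
  ratio <- mean(fs[1, ]) / mean(fs[2, ])
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
})

test_that("conditional F grows without bound as exposure noise shrinks", {
  set.seed(30)
  bx1 <- runif(10, 0.05, 0.2)
  bx2 <- runif(10, 0.05, 0.2)
  fs <- vapply(c(0.01, 0.001, 1e-4), function(s) {
    h <- harmonized_set(cbind(bx1, bx2), matrix(s, 10, 2),
                        0.3 * bx1, rep(0.01, 10))
    conditional_f(h, 1)
  }, 0)
  expect_true(all(diff(fs) > 0))
  expect_gt(fs[3] / fs[1], 1e3)
})

test_that("the Q minimizer coincides with IVW when exposure SEs vanish", {
  set.seed(31)
  bx1 <- runif(15, 0.05, 0.2)
  bx2 <- runif(15, 0.05, 0.2)
  by <- 0.3 * bx1 - 0.2 * bx2 + rnorm(15, 0, 0.01)
  h <- harmonized_set(cbind(bx1, bx2), matrix(1e-12, 15, 2), by,
                      rep(0.01, 15))
  h$sx[] <- 0
  rob <- mvmr_robust(h, boot_reps = 0)
  expect_equal(rob$robust$betas, rob$direct_betas, tolerance = 1e-6)
})

test_that("the minimized Q never exceeds Q at the IVW solution", {
  set.seed(37)
  for (r in 1:5) {
    sm <- simulate_mvmr(sim_config(n_snps = 60, theta = c(0.3, -0.2),
                                   exposure_cor = 0.4, seed = 3700 + r))
    h <- h_from_mvmr(sm)
    rob <- mvmr_robust(h, boot_reps = 0)
    expect_lte(rob$robust$Q_at_min, mvmr_q(h, rob$direct_betas)$Q + 1e-8)
  }
})

test_that("exact-fit data give a zero minimum of the adjusted Q", {
  set.seed(41)
  bx1 <- runif(10, 0.05, 0.2)
  bx2 <- runif(10, 0.05, 0.2)
  h <- harmonized_set(cbind(bx1, bx2), matrix(0.003, 10, 2),
                      0.3 * bx1 - 0.2 * bx2, rep(0.01, 10))
  rob <- mvmr_robust(h, boot_reps = 0)
  expect_equal(rob$robust$Q_at_min, 0, tolerance = 1e-10)
  expect_equal(rob$robust$betas, c(0.3, -0.2), tolerance = 1e-5)
})

test_that("row order does not change multivariable results", {
  set.seed(43)
  sm <- simulate_mvmr(sim_config(n_snps = 50, theta = c(0.3, -0.2),
                                 exposure_cor = 0.3, seed = 44))
  h <- h_from_mvmr(sm)
  perm <- sample(n_snps(h))
  hp <- harmonized_set(h$bx[perm, ], h$sx[perm, ], h$by[perm], h$sy[perm])
  a <- mvmr_ivw(h)
  b <- mvmr_ivw(hp)
  expect_equal(b$direct_betas, a$direct_betas)
  expect_equal(b$ses, a$ses)
  expect_equal(b$het$Q, a$het$Q)
})

test_that("robust MVMR is less biased than naive IVW under weak instruments", {
  sx <- 1 / sqrt(0.375 * 2e4)
  res <- t(vapply(1:60, function(r) {
    sm <- simulate_mvmr(sim_config(n_snps = 200, theta = c(0.3, -0.2),
                                   bx_sd = 2 * sx, ensure_significant = FALSE,
                                   exposure_cor = 0.3, n_exp = 2e4,
                                   n_out = 2e5, seed = 6000 + r))
    h <- h_from_mvmr(sm)
    c(mvmr_ivw(h, conditional_F = FALSE)$direct_betas[1],
      mvmr_robust(h, boot_reps = 0)$robust$betas[1])
  }, c(0, 0)))
  expect_gt(mean(abs(res[, 2] - 0.3) < abs(res[, 1] - 0.3)), 0.8)
})

test_that("bootstrap CIs are seeded, ordered and flag IVW concordance", {
  set.seed(47)
  sm <- simulate_mvmr(sim_config(n_snps = 60, theta = c(0.3, -0.2),
                                 exposure_cor = 0.3, seed = 48))
  h <- h_from_mvmr(sm)
  a <- mvmr_robust(h, boot_reps = 100, seed = 9)
  b <- mvmr_robust(h, boot_reps = 100, seed = 9)
  expect_identical(a$robust$ci, b$robust$ci)
  expect_true(all(a$robust$ci[, 1] <= a$robust$betas))
  expect_true(all(a$robust$betas <= a$robust$ci[, 2]))
  expect_true(all(a$robust$concordant))
  expect_error(mvmr_robust(h, boot_reps = 50, seed = 1),
               class = "mrlink_config_error")
})
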