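test_that("a fixed seed reproduces the simulation byte for byte", {
  cfg <- sim_config(n_snps = 50, theta = 0.2, palindromic_fraction = 0.2,
                    ld_blocks = list(n_blocks = 10, r2_range = c(0.3, 0.9)),
                    seed = 7)
  a <- simulate_pair(cfg)
  b <- simulate_pair(cfg)
  expect_identical(as.data.frame(a$exposure), as.data.frame(b$exposure))
  expect_identical(as.data.frame(a$outcome), as.data.frame(b$outcome))
  expect_identical(a$ld$pairs, b$ld$pairs)
  expect_identical(a$truth, b$truth)
})

test_that("emitted p-values equal the two-sided normal p of beta/se", {
  sim <- simulate_pair(sim_config(n_snps = 200, theta = 0.1, seed = 9))
  for (tab in list(sim$exposure, sim$outcome)) {
    implied <- 2 * pnorm(-abs(tab$beta / tab$se))
    expect_equal(tab$pvalue, pmax(implied, .Machine$double.xmin),
                 tolerance = 1e-10)
  }
})

test_that("truth labels partition variants into valid and pleiotropic sets", {
  sim <- simulate_pair(sim_config(n_snps = 100, theta = 0.2,
                                  pleiotropy = "directional",
                                  pleiotropy_mag = 0.02,
                                  pleiotropy_frac = 0.3, seed = 11))
  expect_equal(sum(!sim$truth$valid), 30)
  expect_true(all(sim$truth$alpha[sim$truth$valid] == 0))
  expect_true(all(sim$truth$alpha[!sim$truth$valid] != 0))
})

test_that("IVW on clean simulated data is consistent for the true effect", {
  sim <- simulate_pair(sim_config(n_snps = 200, theta = 0.2,
                                  n_exp = 2e5, n_out = 2e5, seed = 13))
  h <- harmonize(sim$exposure, sim$outcome)
  e <- mr_ivw(h)
  expect_lt(abs(e$beta - 0.2), 3 * e$se)
})

test_that("the configured palindromic fraction is excluded at harmonization", {
  sim <- simulate_pair(sim_config(n_snps = 100, theta = 0.2,
                                  palindromic_fraction = 0.2, seed = 15))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_equal(nrow(h$exclusions), 20)
  expect_setequal(h$exclusions$variant_id, sim$truth$palindromic)
})

test_that("LD blocks give clumping real work", {
  sim <- simulate_pair(sim_config(n_snps = 60, theta = 0.2,
                                  ld_blocks = list(n_blocks = 12,
                                                   r2_range = c(0.4, 0.9)),
                                  seed = 17))
  kept <- clump(sim$exposure, sim$ld)
  expect_equal(nrow(kept), 12)
})

test_that("two-exposure simulation supports direct-effect recovery", {
  sm <- simulate_mvmr(sim_config(n_snps = 150, theta = c(0.3, -0.2),
                                 exposure_cor = 0.3, seed = 19))
  h <- harmonize(list(sm$exposure1, sm$exposure2), sm$outcome)
  res <- mvmr_ivw(h, conditional_F = FALSE)
  expect_lt(abs(res$direct_betas[1] - 0.3), 3 * res$ses[1])
  expect_lt(abs(res$direct_betas[2] + 0.2), 3 * res$ses[2])
})

test_that("fixture bundles are deterministic and carry coherent truth records", {
  a <- fixture_bundle("adhd_to_ea")
  b <- fixture_bundle("adhd_to_ea")
  expect_identical(as.data.frame(a$exposure), as.data.frame(b$exposure))
  expect_identical(a$truth, b$truth)
  expect_error(fixture_bundle("nope"), class = "mrlink_config_error")
  expect_length(a$truth$instruments, 11)
  expect_length(a$truth$cognitive_instruments, 212)
  expect_true(all(a$truth$F_instruments >= 30 & a$truth$F_instruments <= 51))
  fx <- fixture_bundle("asd_to_ea")
  expect_length(fx$truth$instruments, 10)
  expect_true(all(fx$truth$F_instruments >= 26 & fx$truth$F_instruments <= 36))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_snps = 0, theta = 0.2, seed = 1),
               class = "mrlink_config_error")
  expect_error(sim_config(n_snps = 10, theta = c(1, 2, 3), seed = 1),
               class = "mrlink_config_error")
  expect_error(sim_config(n_snps = 10, theta = 0.2, pleiotropy_frac = 2,
                          seed = 1),
               class = "mrlink_config_error")
  expect_error(simulate_mvmr(sim_config(n_snps = 10, theta = 0.2, seed = 1)),
               class = "mrlink_config_error")
})
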