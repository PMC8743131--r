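test_that("one-SNP IVW equals the Wald ratio", {
  h <- harmonized_set(bx = 0.1, sx = 0.01, by = 0.05, sy = 0.01)
  e <- mr_ivw(h)
  expect_equal(e$beta, 0.5)
  expect_equal(e$n_snps, 1L)
})

test_that("IVW matches the closed-form weighted sums", {
  h <- harmonized_set(bx = c(0.1, 0.2), sx = c(0.01, 0.01),
                      by = c(0.05, 0.10), sy = c(0.01, 0.01))
  e <- mr_ivw(h)
  expect_equal(e$beta, 0.5)
  expect_equal(e$het$Q, 0)
  # hand-computed: se_fixed = sqrt(1 / (w * (0.01 + 0.04))) with w = 1e4
  expect_equal(mr_ivw(h, "fixed")$se, sqrt(1 / (1e4 * 0.05)))
  # at exact proportionality the multiplicative model does not inflate
  expect_equal(e$se, mr_ivw(h, "fixed")$se)
})

test_that("all estimators recover theta exactly under perfect proportionality", {
  set.seed(42)
  bx <- runif(8, 0.05, 0.2)
  theta <- 0.37
  h <- harmonized_set(bx, rep(0.005, 8), theta * bx, rep(0.01, 8))
  expect_equal(mr_ivw(h)$beta, theta)
  expect_equal(mr_ivw(h)$het$Q, 0)
  eg <- mr_egger(h)
  expect_equal(eg$beta, theta)
  expect_equal(eg$intercept$value, 0, tolerance = 1e-10)
  expect_equal(mr_weighted_median(h, boot_reps = 0)$beta, theta)
  expect_equal(mr_weighted_mode(h, boot_reps = 0)$beta, theta,
               tolerance = 1e-2)
  expect_equal(mr_raps(h)$beta, theta, tolerance = 1e-6)
})

test_that("Egger recovers an exact linear relationship with free intercept", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  h <- harmonized_set(bx, rep(0.01, 4), 0.02 + 0.5 * bx, rep(0.01, 4))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.5)
  expect_equal(e$intercept$value, 0.02)
  expect_equal(e$het$Q, 0, tolerance = 1e-20)
})

test_that("Egger is invariant under joint sign flips of (bx, by)", {
  set.seed(7)
  bx <- runif(6, 0.05, 0.2)
  by <- 0.01 + 0.4 * bx + rnorm(6, 0, 0.005)
  h1 <- harmonized_set(bx, rep(0.01, 6), by, rep(0.01, 6))
  flip <- c(1, -1, 1, -1, -1, 1)
  h2 <- harmonized_set(bx * flip, rep(0.01, 6), by * flip, rep(0.01, 6))
  expect_equal(mr_egger(h2)$beta, mr_egger(h1)$beta)
  expect_equal(mr_egger(h2)$intercept$value, mr_egger(h1)$intercept$value)
})

test_that("Egger requires at least three instruments", {
  h <- harmonized_set(c(0.1, 0.2), rep(0.01, 2), c(0.05, 0.1), rep(0.01, 2))
  expect_error(mr_egger(h), class = "mrlink_data_error")
})

test_that("Cochran's Q is permutation-invariant and zero only at exact fit", {
  set.seed(9)
  bx <- runif(10, 0.05, 0.2)
  by <- 0.3 * bx + rnorm(10, 0, 0.01)
  h <- harmonized_set(bx, rep(0.01, 10), by, rep(0.01, 10))
  perm <- sample(10)
  hp <- harmonized_set(bx[perm], rep(0.01, 10), by[perm], rep(0.01, 10))
  expect_equal(mr_ivw(hp)$het$Q, mr_ivw(h)$het$Q)
  expect_gt(mr_ivw(h)$het$Q, 0)
})

test_that("the weighted median interpolates cumulative standardized weights", {
  # equal weights, ratios 0.4/0.5/0.6
  bx <- rep(0.1, 3)
  h <- harmonized_set(bx, rep(0.01, 3), c(0.04, 0.05, 0.06), rep(0.01, 3))
  expect_equal(mr_weighted_median(h, boot_reps = 0)$beta, 0.5)
  # weights 0.98/0.01/0.01 on ratios 0.1/0.5/0.9: hand-evaluated
  # interpolation gives 0.1 + 0.4 * (0.5 - 0.49) / (0.985 - 0.49)
  bx2 <- sqrt(c(0.98, 0.01, 0.01))
  h2 <- harmonized_set(bx2, rep(0.01, 3), c(0.1, 0.5, 0.9) * bx2, rep(1, 3))
  expect_equal(mr_weighted_median(h2, boot_reps = 0)$beta,
               0.1 + 0.4 * 0.01 / 0.495)
})

test_that("weighted median bootstrap SE shrinks to zero with the noise", {
  bx <- c(0.1, 0.12, 0.15, 0.2)
  make_h <- function(s) harmonized_set(bx, rep(s, 4), 0.5 * bx, rep(s, 4))
  se_big <- mr_weighted_median(make_h(0.01), boot_reps = 200, seed = 1)$se
  se_small <- mr_weighted_median(make_h(1e-5), boot_reps = 200, seed = 1)$se
  expect_lt(se_small, se_big / 100)
})

test_that("zero exposure effects are a data error naming the variant", {
  h <- harmonized_set(c(0.1, 0, 0.2), rep(0.01, 3), c(0.05, 0, 0.1),
                      rep(0.01, 3), variant_id = c("a", "bad", "c"))
  expect_error(mr_weighted_median(h, boot_reps = 0), "bad",
               class = "mrlink_data_error")
})

test_that("the weighted mode finds the majority cluster", {
  bx <- rep(0.1, 4)
  h <- harmonized_set(bx, rep(0.01, 4), c(0.05, 0.05, 0.05, 0.5),
                      rep(0.01, 4))
  expect_equal(mr_weighted_mode(h, boot_reps = 0)$beta, 0.5,
               tolerance = 0.05)
  # doubling the bandwidth moves the estimate smoothly, not wildly
  wide <- mr_weighted_mode(h, bandwidth_factor = 2, boot_reps = 0)$beta
  expect_equal(wide, 0.5, tolerance = 0.2)
})

test_that("RAPS reduces to fixed-effect IVW without exposure noise", {
  set.seed(3)
  bx <- runif(10, 0.05, 0.2)
  by <- 0.25 * bx + rnorm(10, 0, 0.01)
  h <- harmonized_set(bx, rep(1e-12, 10), by, rep(0.01, 10))
  h$sx[] <- 0
  raps <- mr_raps(h, loss = "l2", overdispersion = FALSE)
  expect_equal(raps$beta, mr_ivw(h, "fixed")$beta, tolerance = 1e-6)
})

test_that("RAPS is less biased than IVW under weak instruments", {
  sx <- 1 / sqrt(0.375 * 2e4)
  res <- t(vapply(1:60, function(r) {
    sim <- simulate_pair(sim_config(n_snps = 200, theta = 0.2,
                                    bx_sd = 2 * sx, ensure_significant = FALSE,
                                    n_exp = 2e4, n_out = 2e5, seed = 5000 + r))
    h <- h_from_pair(sim)
    c(mr_ivw(h, "fixed")$beta, mr_raps(h)$beta)
  }, c(0, 0)))
  expect_gt(mean(abs(res[, 2] - 0.2) < abs(res[, 1] - 0.2)), 0.8)
})

test_that("per-SNP F statistics follow the squared z approximation", {
  h <- harmonized_set(c(0.05, 0.01), c(0.01, 0.01), c(0.02, 0.004),
                      rep(0.01, 2), variant_id = c("strong", "weak"))
  f <- per_snp_f(h)
  expect_equal(unname(f$per_snp_F), c(25, 1))
  expect_equal(f$min_F, 1)
  expect_equal(f$max_F, 25)
  expect_true(f$per_snp_F["weak"] < 10)
  h$sx[1, 1] <- 0
  expect_error(per_snp_f(h), "strong", class = "mrlink_data_error")
})

test_that("Steiger filtering retains variants explaining more exposure variance", {
  # forward variant: strong on exposure, weak on outcome; reverse variant
  # the other way around
  h <- harmonized_set(bx = c(0.05, 0.002), sx = c(0.005, 0.005),
                      by = c(0.01, 0.06), sy = c(0.005, 0.005),
                      variant_id = c("fwd", "rev"))
  st <- steiger_filter(h, n_exposure = 1e4, n_outcome = 1e4)
  expect_equal(st$filtered$variant_id, "fwd")
  expect_equal(st$report$retained, c(TRUE, FALSE))
  expect_true(all(c("r2_exposure", "r2_outcome", "steiger_p") %in%
                    names(st$report)))
  expect_error(steiger_filter(h, NULL, 1e4), class = "mrlink_config_error")
})

test_that("binary-trait r2 approximations behave as documented", {
  h <- harmonized_set(bx = 0.1, sx = 0.01, by = 0.01, sy = 0.01)
  st <- steiger_filter(h, 1e4, 1e4, exposure_binary = TRUE)
  expect_equal(st$report$r2_exposure, (0.1 / 0.01)^2 / 1e4)
  # the log-odds approximation needs allele frequencies
  expect_error(steiger_filter(h, 1e4, 1e4, exposure_binary = TRUE,
                              binary_method = "logodds"),
               class = "mrlink_config_error")
})

test_that("SIMEX equals plain Egger without exposure measurement error", {
  bx <- c(0.1, 0.2, 0.3, 0.15)
  h <- harmonized_set(bx, rep(1e-12, 4), 0.02 + 0.5 * bx, rep(0.01, 4))
  h$sx[] <- 0
  expect_equal(mr_egger_simex(h, reps = 100, seed = 1)$beta,
               mr_egger(h)$beta)
})

test_that("SIMEX output is deterministic for a fixed seed", {
  set.seed(21)
  bx <- runif(10, 0.05, 0.2)
  h <- harmonized_set(bx + rnorm(10, 0, 0.02), rep(0.02, 10),
                      0.3 * bx, rep(0.01, 10))
  a <- mr_egger_simex(h, reps = 100, seed = 5)
  b <- mr_egger_simex(h, reps = 100, seed = 5)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  expect_error(mr_egger_simex(h, lambdas = c(0, 1), reps = 100, seed = 1),
               class = "mrlink_config_error")
})

test_that("SIMEX corrects regression dilution more often than naive Egger", {
  wins <- vapply(1:100, function(r) {
    set.seed(7000 + r)
    n <- 50
    bx_true <- runif(n, 0.05, 0.2)
    h <- harmonized_set(bx_true + rnorm(n, 0, 0.04), rep(0.04, n),
                        0.3 * bx_true + rnorm(n, 0, 0.002), rep(0.002, n))
    naive <- mr_egger(h)$beta
    simex <- mr_egger_simex(h, reps = 100, seed = r)$beta
    abs(simex - 0.3) < abs(naive - 0.3)
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})
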