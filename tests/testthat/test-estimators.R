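test_that("Wald ratio arithmetic and symmetry", {
  est <- wald_ratio(list(beta = 0.5, se = 0.01), list(beta = 0.2, se = 0.05))
  expect_equal(est$estimate, 0.4)
  expect_equal(est$se, 0.1)
  expect_equal(est$ci_low, 0.4 - 1.96 * 0.1)
  expect_equal(est$ci_high, 0.4 + 1.96 * 0.1)

  expect_equal(wald_ratio(list(beta = 1, se = 0.1),
                          list(beta = 0.37, se = 0.05))$estimate, 0.37)
  for (seed in 1:10) {
    set.seed(seed)
    be <- rnorm(1); bo <- rnorm(1)
    est <- wald_ratio(list(beta = be, se = 0.1), list(beta = bo, se = 0.1))
    expect_equal(sign(est$estimate), sign(be) * sign(bo))
  }
  expect_error(wald_ratio(list(beta = 0, se = 1, snp_id = "rsX"),
                          list(beta = 1, se = 1)), "rsX")
})

test_that("IVW recovers an exact proportional relationship", {
  ds <- data.frame(exposure_beta = c(0.1, 0.2, 0.3),
                   exposure_se = rep(0.01, 3),
                   outcome_beta = c(0.05, 0.10, 0.15),
                   outcome_se = rep(0.01, 3))
  est <- mr_ivw(ds)
  expect_equal(est$estimate, 0.5, tolerance = 1e-12)
  expect_equal(est$n_snps, 3L)
  expect_error(mr_ivw(ds[0, ]), "at least 1")
  ds0 <- ds; ds0$exposure_beta <- 0
  expect_error(mr_ivw(ds0), "singular")
})

test_that("single-SNP IVW equals the Wald ratio", {
  ds <- data.frame(exposure_beta = 0.12, exposure_se = 0.01,
                   outcome_beta = 0.07, outcome_se = 0.02)
  ivw <- mr_ivw(ds)
  wald <- wald_ratio(list(beta = 0.12, se = 0.01),
                     list(beta = 0.07, se = 0.02))
  expect_equal(ivw$estimate, wald$estimate, tolerance = 1e-12)
  expect_equal(ivw$se, wald$se, tolerance = 1e-12)
})

test_that("IVW is scale-equivariant and row-order invariant", {
  ds <- make_fixture_dataset(101, L = 12, covariate = FALSE)
  est <- mr_ivw(ds)
  scaled <- ds
  scaled$exposure_beta <- scaled$exposure_beta * 2.7
  expect_equal(mr_ivw(scaled)$estimate, est$estimate / 2.7,
               tolerance = 1e-12)
  perm <- ds[sample(nrow(ds)), ]
  expect_equal(mr_ivw(perm)$estimate, est$estimate, tolerance = 1e-12)
  expect_equal(mr_ivw(perm)$se, est$se, tolerance = 1e-12)
})

test_that("WLS estimators match explicit normal-equations oracles", {
  for (seed in c(3, 17, 42, 88)) {
    L <- sample(5:20, 1)
    ds <- make_fixture_dataset(seed, L = L)
    w <- 1 / ds$outcome_se^2

    est <- mr_ivw(ds)
    o <- oracle_wls(matrix(ds$exposure_beta), ds$outcome_beta, w)
    expect_equal(est$estimate, o$coef, tolerance = 1e-10)
    expect_equal(est$se, o$se, tolerance = 1e-10)

    mv <- mvmr_ivw(ds)
    om <- oracle_wls(cbind(ds$exposure_beta, ds$covariate_beta),
                     ds$outcome_beta, w)
    expect_equal(mv$estimates, unname(om$coef), tolerance = 1e-10)
    expect_equal(mv$ses, unname(om$se), tolerance = 1e-10)

    eg <- mr_egger(ds)
    s <- ifelse(ds$exposure_beta < 0, -1, 1)
    oe <- oracle_wls(matrix(s * ds$exposure_beta), s * ds$outcome_beta, w,
                     intercept = TRUE)
    expect_equal(eg$egger_intercept[["estimate"]], oe$coef[1],
                 tolerance = 1e-10)
    expect_equal(eg$estimate, oe$coef[2], tolerance = 1e-10)
    expect_equal(eg$se, oe$se[2], tolerance = 1e-10)
  }
})

test_that("random-effects SEs never undercut fixed-effect SEs", {
  ds <- make_fixture_dataset(7, L = 15, covariate = FALSE)
  ds$outcome_beta <- ds$outcome_beta + rnorm(15, 0, 0.05)  # overdispersion
  expect_gte(mr_ivw(ds, random_effects = TRUE)$se, mr_ivw(ds)$se)
})

test_that("MVMR with a null covariate block equals univariable IVW", {
  ds <- make_fixture_dataset(5, L = 8)
  ds$covariate_beta <- 0
  mv <- mvmr_ivw(ds)
  uni <- mr_ivw(ds)
  expect_equal(mv$estimates[1], uni$estimate, tolerance = 1e-10)
  expect_equal(mv$ses[1], uni$se, tolerance = 1e-10)
  expect_true(is.na(mv$estimates[2]))   # unidentified coefficient
})

test_that("MVMR is invariant to the adjusted-association reparameterisation", {
  # constructing pi_A = pi_X - rho * pi_C exactly must leave the exposure
  # coefficient unchanged and shift the covariate coefficient by
  # +rho * beta1
  for (rho in c(-0.3, 0.1, 0.525)) {
    ds <- make_fixture_dataset(23, L = 12)
    adj <- ds
    adj$exposure_beta <- ds$exposure_beta - rho * ds$covariate_beta
    fit <- mvmr_ivw(ds)
    fit_adj <- mvmr_ivw(adj)
    expect_equal(fit_adj$estimates[1], fit$estimates[1], tolerance = 1e-10)
    expect_equal(fit_adj$estimates[2],
                 fit$estimates[2] + rho * fit$estimates[1],
                 tolerance = 1e-10)
  }
})

test_that("MVMR reports collinear designs", {
  ds <- make_fixture_dataset(9, L = 6)
  ds$covariate_beta <- 2 * ds$exposure_beta
  expect_error(mvmr_ivw(ds), "collinear")
})

test_that("Egger regression recovers an exact affine relationship", {
  bx <- c(0.05, 0.08, 0.12, 0.2, 0.31)
  ds <- data.frame(exposure_beta = bx, exposure_se = 0.01,
                   outcome_beta = 0.03 + 0.7 * bx, outcome_se = 0.02)
  est <- mr_egger(ds)
  expect_equal(est$estimate, 0.7, tolerance = 1e-12)
  expect_equal(est$egger_intercept[["estimate"]], 0.03, tolerance = 1e-12)

  flipped <- ds
  flipped$exposure_beta[2] <- -flipped$exposure_beta[2]
  flipped$outcome_beta[2] <- -flipped$outcome_beta[2]
  est2 <- mr_egger(flipped)
  expect_equal(est2$estimate, est$estimate, tolerance = 1e-12)
  expect_equal(est2$egger_intercept, est$egger_intercept, tolerance = 1e-12)

  expect_error(mr_egger(ds[1:2, ]), "at least 3")
})

test_that("weighted median obeys its defining balance property", {
  ds <- data.frame(exposure_beta = 1, exposure_se = 0.01,
                   outcome_beta = 1:5, outcome_se = 1)
  est <- mr_weighted_median(ds, n_boot = 50, seed = 1)
  expect_equal(est$estimate, 3)

  same <- data.frame(exposure_beta = c(1, 2, 4), exposure_se = 0.01,
                     outcome_beta = c(0.7, 1.4, 2.8),
                     outcome_se = c(0.3, 0.1, 0.5))
  expect_equal(mr_weighted_median(same, n_boot = 50, seed = 1)$estimate, 0.7,
               tolerance = 1e-12)

  # majority-valid fixture: 7 SNPs at ratio 0.4 with dominant weights,
  # 3 outliers at 2.0
  maj <- data.frame(exposure_beta = rep(1, 10), exposure_se = 0.01,
                    outcome_beta = c(rep(0.4, 7), rep(2, 3)),
                    outcome_se = c(rep(0.05, 7), rep(0.5, 3)))
  expect_equal(mr_weighted_median(maj, n_boot = 50, seed = 1)$estimate, 0.4,
               tolerance = 1e-6)

  for (seed in 1:5) {
    ds <- make_fixture_dataset(seed, L = 9, covariate = FALSE)
    est <- mr_weighted_median(ds, n_boot = 20, seed = 1)
    r <- ds$outcome_beta / ds$exposure_beta
    w <- ds$exposure_beta^2 / ds$outcome_se^2
    # matches the independent CDF-inversion oracle
    expect_equal(est$estimate, oracle_weighted_median(r, w),
                 tolerance = 1e-10)
  }
})

test_that("weighted median bootstrap SE is seeded and leaves the RNG alone", {
  ds <- make_fixture_dataset(3, L = 10, covariate = FALSE)
  set.seed(1234)
  before <- rnorm(1)
  set.seed(1234)
  e1 <- mr_weighted_median(ds, n_boot = 200, seed = 9)
  e2 <- mr_weighted_median(ds, n_boot = 200, seed = 9)
  after <- rnorm(1)
  expect_identical(e1$se, e2$se)
  expect_gt(e1$se, 0)
  expect_identical(before, after)   # caller's RNG stream undisturbed
})

test_that("weighted mode finds the dominant-weight cluster", {
  tight <- data.frame(exposure_beta = rep(1, 5), exposure_se = 0.01,
                      outcome_beta = c(0.39, 0.40, 0.40, 0.41, 0.40),
                      outcome_se = 0.05)
  est <- mr_weighted_mode(tight, n_boot = 30, seed = 2)
  expect_lt(abs(est$estimate - 0.4), 0.01)

  bimodal <- data.frame(
    exposure_beta = rep(1, 10), exposure_se = 0.01,
    outcome_beta = c(rnorm(7, 1, 0.02), rnorm(3, 3, 0.02)),
    outcome_se = c(rep(0.05, 7), rep(0.3, 3)))
  est2 <- mr_weighted_mode(bimodal, n_boot = 30, seed = 2)
  expect_lt(abs(est2$estimate - 1), 0.1)

  r <- bimodal$outcome_beta / bimodal$exposure_beta
  w <- bimodal$exposure_beta^2 / bimodal$outcome_se^2
  expect_equal(est2$estimate, oracle_mode_grid(r, w), tolerance = 1e-3)

  # rescaling all weights by a constant leaves the mode unchanged (the
  # estimator normalises weights internally)
  expect_equal(oracle_mode_grid(r, 10 * w), oracle_mode_grid(r, w),
               tolerance = 1e-12)
  expect_error(mr_weighted_mode(bimodal, bandwidth_factor = 0),
               "bandwidth_factor")
})

test_that("weighted mode matches the dense-grid oracle on random fixtures", {
  for (seed in c(2, 11, 31)) {
    ds <- make_fixture_dataset(seed, L = 12, covariate = FALSE)
    est <- mr_weighted_mode(ds, n_boot = 10, seed = 1)
    r <- ds$outcome_beta / ds$exposure_beta
    w <- ds$exposure_beta^2 / ds$outcome_se^2
    expect_equal(est$estimate, oracle_mode_grid(r, w), tolerance = 1e-3)
  }
})

test_that("mean F-statistic is the mean squared z", {
  expect_equal(mean_f_statistic(1, 0.1), 100)
  expect_equal(mean_f_statistic(c(0, 0), c(1, 2)), 0)
  expect_equal(mean_f_statistic(c(0.1, 0.2), c(0.05, 0.05)), (4 + 16) / 2)
})

test_that("conditional F matches a brute-force grid search", {
  ds <- make_fixture_dataset(77, L = 5)
  f1 <- conditional_f(ds, 1)
  o1 <- oracle_conditional_f(ds$exposure_beta, ds$exposure_se,
                             ds$covariate_beta, ds$covariate_se)
  expect_equal(f1, o1, tolerance = 1e-3)
  f2 <- conditional_f(ds, 2)
  o2 <- oracle_conditional_f(ds$covariate_beta, ds$covariate_se,
                             ds$exposure_beta, ds$exposure_se)
  expect_equal(f2, o2, tolerance = 1e-3)
})

test_that("conditional F limits: irrelevant and collinear other exposure", {
  ds <- data.frame(exposure_beta = c(0.1, 0.15, 0.2, 0.12),
                   exposure_se = rep(0.01, 4),
                   covariate_beta = rep(0, 4),
                   covariate_se = rep(1e-8, 4),
                   outcome_beta = rep(0.05, 4), outcome_se = rep(0.01, 4))
  f <- conditional_f(ds, 1)
  expect_equal(f, sum((ds$exposure_beta / ds$exposure_se)^2) / 3,
               tolerance = 1e-6)

  coll <- ds
  coll$covariate_beta <- 0.5 * coll$exposure_beta
  coll$covariate_se <- rep(0.01, 4)
  expect_lt(conditional_f(coll, 1), 0.05)
})

test_that("tidy_estimate produces the documented layout", {
  ds <- make_fixture_dataset(4, L = 8)
  td <- tidy_estimate(mr_ivw(ds))
  expect_identical(names(td), c("method", "exposure", "estimate", "se",
                                "ci_low", "ci_high", "n_snps", "f_statistic"))
  tm <- tidy_estimate(mvmr_ivw(ds))
  expect_equal(nrow(tm), 2L)
  expect_identical(tm$exposure, c("exposure", "covariate"))
})
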