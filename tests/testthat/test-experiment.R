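test_that("replication seeds follow the documented counter scheme", {
  expect_equal(replication_seed(10, 1), (10 + 7919) %% 2147483647)
  expect_equal(replication_seed(10, 3), (10 + 3 * 7919) %% 2147483647)
  seeds <- vapply(1:1000, function(r) replication_seed(1, r), integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("run_replication is deterministic and well-structured", {
  m <- build_model("confounded")
  a <- run_replication(m, n = 2e4, seed = 5, schemes = c("none", "exposure"))
  b <- run_replication(m, n = 2e4, seed = 5, schemes = c("none", "exposure"))
  expect_identical(a, b)

  expect_setequal(unique(a$scheme), c("none", "exposure"))
  # x2 univariable MR is undefined when the x2 GWAS would be adjusted for
  # itself: no such row under the exposure-adjusted scheme
  expect_false(any(a$scheme == "exposure" & a$analysis == "mr" &
                     a$exposure == "x2"))
  expect_true(all(c("estimate", "se", "ci_low", "ci_high", "n_snps",
                    "f_stat", "skipped") %in% names(a)))
  expect_true(is.numeric(attr(a, "rho_cx")))
})

test_that("replications with no discoverable instruments are flagged", {
  null <- build_model("correlated", overrides = list(
    snp_effect_mean = 0, snp_effect_sd = 0, beta_x1_y = 0, beta_x2_y = 0))
  res <- run_replication(null, n = 2000, seed = 1, schemes = "none")
  expect_true(all(res$skipped))
  expect_true(all(is.na(res$estimate)))
})

test_that("MVMR instrument sets are the union of both selections", {
  m <- build_model("confounded")
  seed <- replication_seed(42, 1)
  res <- run_replication(m, n = 1e5, seed = seed,
                         schemes = "none", estimators = c("ivw", "mvmr"))

  # independent recount with the same seed and the public API
  set.seed(seed)
  eff <- draw_snp_effects(m)
  sa <- simulate_sample(m, n = 1e5, effects = eff)
  sel_x1 <- select_instruments(gwas_scan(sa, "x1"), 5e-8)
  sel_x2 <- select_instruments(gwas_scan(sa, "x2"), 5e-8)
  expect_equal(res$n_snps[res$analysis == "mvmr"][1],
               length(union(sel_x1, sel_x2)))
  expect_equal(res$n_snps[res$analysis == "mr" & res$exposure == "x1"],
               length(sel_x1))
  # pleiotropy mechanism: covariate SNPs inside the exposure instrument set
  g2_ids <- sprintf("snp_%03d", 126:250)
  expect_gt(length(intersect(sel_x1, g2_ids)), 0)
})

test_that("unadjusted and exposure-adjusted MVMR x1 estimates nearly agree", {
  m <- build_model("correlated")
  res <- run_replication(m, n = 1e5, seed = replication_seed(3, 7),
                         schemes = c("none", "exposure"))
  x1_un <- res$estimate[res$scheme == "none" & res$analysis == "mvmr" &
                          res$exposure == "x1"]
  x1_ad <- res$estimate[res$scheme == "exposure" & res$analysis == "mvmr" &
                          res$exposure == "x1"]
  expect_lt(abs(x1_un - x1_ad), 0.02)
})

test_that("aggregation reproduces hand-computed summaries", {
  est <- c(0.38, 0.41, 0.40, 0.43, 0.39, 0.42, 0.40, 0.41, 0.38, 0.40)
  se <- rep(0.02, 10)
  reps <- data.frame(scheme = "none", analysis = "mvmr", exposure = "x1",
                     estimate = est, se = se,
                     ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
                     n_snps = 200L, f_stat = seq(100, 145, 5),
                     skipped = FALSE, rep = 1:10)
  m <- build_model("confounded")
  agg <- aggregate_replications(reps, m)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$mean_estimate, mean(est))
  expect_equal(agg$mean_model_se, 0.02)
  expect_equal(agg$empirical_sd, sd(est))
  expect_equal(agg$mean_f, mean(seq(100, 145, 5)))
  # truth for MVMR is the direct effect 0.4; all ten CIs contain it
  expect_equal(agg$truth, 0.4)
  expect_equal(agg$coverage, 1)
  expect_equal(agg$n_reps_used, 10L)

  # univariable MR is judged against the total effect (0.4 confounded)
  reps_mr <- reps
  reps_mr$analysis <- "mr"
  reps_mr$estimate <- reps_mr$estimate + 0.5   # CIs now all miss the truth
  reps_mr$ci_low <- reps_mr$ci_low + 0.5
  reps_mr$ci_high <- reps_mr$ci_high + 0.5
  agg_mr <- aggregate_replications(reps_mr, m)
  expect_equal(agg_mr$truth, 0.4)
  expect_equal(agg_mr$coverage, 0)

  # degenerate constant estimates: zero empirical SD, full coverage
  reps_c <- reps
  reps_c$estimate <- 0.4
  reps_c$ci_low <- 0.4 - 0.01
  reps_c$ci_high <- 0.4 + 0.01
  agg_c <- aggregate_replications(reps_c, m)
  expect_equal(agg_c$empirical_sd, 0)
  expect_equal(agg_c$coverage, 1)

  # skipped replications are dropped and counted
  reps_s <- reps
  reps_s$skipped[1:3] <- TRUE
  agg_s <- aggregate_replications(reps_s, m)
  expect_equal(agg_s$n_reps_used, 7L)
  expect_equal(agg_s$n_reps_skipped, 3L)
})

test_that("rendered tables have the study layout", {
  grid <- expand.grid(scenario = c("confounded", "correlated", "mediated"),
                      scheme = c("none", "exposure"),
                      analysis = "mr", exposure = c("x1", "x2"),
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$scheme == "exposure" & grid$exposure == "x2"), ]
  grid$truth <- 0.4
  grid$mean_estimate <- 0.394999
  grid$mean_model_se <- 0.0123
  grid$empirical_sd <- 0.0521
  grid$coverage <- 0.915
  grid$mean_f <- 222.34
  grid$n_reps_used <- 10L
  grid$n_reps_skipped <- 0L
  tab <- render_table(grid, "mr")
  lines <- strsplit(unclass(tab), "\n")[[1]]
  # 2 header lines + 3 scenario blocks of (title + 4 rows)
  expect_length(lines, 2 + 3 * 5)
  expect_match(lines[1], "Unadjusted")
  expect_match(lines[1], "Exposure adj.")
  body <- paste(lines, collapse = "\n")
  expect_match(body, "0.39")          # two-decimal rounding of 0.394999
  expect_false(grepl("0.395", body))
  expect_match(body, "222.3")         # one-decimal F
  expect_match(body, "—")        # em-dash for the missing x2 cells
  expect_match(body, "0.052")         # three-decimal empirical SD default
})

test_that("small Monte Carlo runs recover the structural parameters", {
  cfg <- scenario_config("correlated", n = 3e4, n_reps = 12, seed = 5,
                         schemes = "none")
  res <- run_scenario(cfg)
  s <- res$summaries
  mr <- s[s$analysis == "mr" & s$exposure == "x1", ]
  mc_se <- mr$empirical_sd / sqrt(mr$n_reps_used)
  expect_lt(abs(mr$mean_estimate - 0.4), 3 * mc_se + 0.01)
  mv <- s[s$analysis == "mvmr" & s$exposure == "x2", ]
  expect_lt(abs(mv$mean_estimate - 0.8),
            3 * mv$empirical_sd / sqrt(mv$n_reps_used) + 0.01)
  expect_equal(res$config$n_reps, 12L)
  expect_lt(abs(res$mean_rho_cx - 0.275), 0.03)
})
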