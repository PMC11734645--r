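# Independent oracles and fixture builders shared across test files.

# Brute-force per-SNP regression oracle via lm(), one model fit per SNP.
oracle_lm_scan <- function(sample, trait, adjust_for = NULL) {
  G <- sample$genotypes
  t_vec <- sample[[trait]]
  out <- lapply(seq_len(ncol(G)), function(j) {
    if (is.null(adjust_for)) {
      fit <- summary(lm(t_vec ~ G[, j]))
    } else {
      fit <- summary(lm(t_vec ~ G[, j] + sample[[adjust_for]]))
    }
    co <- fit$coefficients[2, ]
    c(beta = co[["Estimate"]], se = co[["Std. Error"]])
  })
  do.call(rbind, out)
}

# Explicit weighted normal-equations oracle for WLS with or without
# intercept (never reuses package code).
oracle_wls <- function(X, y, w, intercept = FALSE) {
  if (intercept) X <- cbind(1, X)
  A <- t(X) %*% (w * X)
  V <- solve(A)
  list(coef = drop(V %*% t(X) %*% (w * y)), se = sqrt(diag(V)))
}

# Random summary dataset fixture for estimator oracle tests.
make_fixture_dataset <- function(seed, L = 10, covariate = TRUE,
                                 slope = 0.4, cov_slope = 0.8) {
  set.seed(seed)
  bx <- rnorm(L, 0.08, 0.03)
  bc <- if (covariate) rnorm(L, 0.06, 0.04) else NULL
  by <- slope * bx + (if (covariate) cov_slope * bc else 0) +
    rnorm(L, 0, 0.005)
  df <- data.frame(snp_id = sprintf("snp_%02d", seq_len(L)),
                   exposure_beta = bx,
                   exposure_se = runif(L, 0.003, 0.01))
  if (covariate) {
    df$covariate_beta <- bc
    df$covariate_se <- runif(L, 0.003, 0.01)
  }
  df$outcome_beta <- by
  df$outcome_se <- runif(L, 0.004, 0.012)
  structure(df, class = c("summary_dataset", "data.frame"),
            adjustment_scheme = "none")
}

# Independent oracle for the interpolated weighted median: invert the
# piecewise-linear weighted CDF through the order-statistic midpoints.
oracle_weighted_median <- function(r, w) {
  ord <- order(r)
  p <- (cumsum(w[ord]) - w[ord] / 2) / sum(w)
  approx(p, r[ord], xout = 0.5, rule = 2, ties = "ordered")$y
}

# Dense-grid argmax oracle for the weighted kernel-density mode, using the
# same bandwidth convention as the estimator but an independent evaluation
# path.
oracle_mode_grid <- function(r, w, bandwidth_factor = 1, n_grid = 20001) {
  w <- w / sum(w)
  s <- min(sd(r), mad(r))
  if (s == 0) s <- sd(r)
  h <- bandwidth_factor * 0.9 * s * length(r)^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = n_grid)
  dens <- colSums(w * outer(r, grid, function(a, b) dnorm((b - a) / h)) / h)
  grid[which.max(dens)]
}

# Grid-search oracle for the conditional-F Q minimisation.
oracle_conditional_f <- function(bt, st, bo, so, step = 1e-4, lim = 5) {
  deltas <- seq(-lim, lim, by = step)
  q <- vapply(deltas, function(d) {
    sum((bt - d * bo)^2 / (st^2 + d^2 * so^2))
  }, numeric(1))
  min(q) / (length(bt) - 1)
}

# Interventional oracle for total effects: simulate the structural
# equations with x1 set exogenously (standard normal) and regress y on x1.
# Genetic scores are irrelevant for the causal contrast and set to zero.
oracle_do_x1_total_effect <- function(model, n = 2e5) {
  u <- rnorm(n)
  x1 <- rnorm(n)
  e2 <- rnorm(n, sd = model$sigma_x2)
  ey <- rnorm(n, sd = model$sigma_y)
  x2 <- if (model$scenario == "mediated") {
    model$beta_x1_x2 * x1 + model$u_x2 * u + e2
  } else {
    model$u_x2 * u + e2
  }
  y <- model$beta_x1_y * x1 + model$beta_x2_y * x2 + model$u_y * u + ey
  fit <- summary(lm(y ~ x1))
  c(est = fit$coefficients[2, 1], se = fit$coefficients[2, 2])
}

# Small well-formed summary-statistics file for io tests.
write_sumstats_fixture <- function(path, df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      snp_id = c("rs1", "rs2", "rs3"),
      effect_allele = c("A", "C", "G"),
      other_allele = c("G", "T", "T"),
      eaf = c(0.25, 0.4, 0.1),
      beta = c(0.05, -0.02, 0.11),
      se = c(0.01, 0.012, 0.02),
      pvalue = c(5e-7, 0.1, 3e-8),
      n = c(10000, 10000, 10000)
    )
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
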