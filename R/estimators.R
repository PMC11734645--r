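# Summary-data MR and MVMR estimators with weak-instrument diagnostics.
#
# All confidence intervals are normal 95% intervals (estimate +/- 1.96 se),
# matching the coverage convention used throughout the simulation study.

.Z95 <- 1.96

.new_mr_estimate <- function(method, estimate, se, n_snps,
                             f_statistic = NULL, egger_intercept = NULL,
                             q_statistic = NULL) {
  structure(
    list(method = method, estimate = estimate, se = se,
         ci_low = estimate - .Z95 * se, ci_high = estimate + .Z95 * se,
         n_snps = n_snps, f_statistic = f_statistic,
         egger_intercept = egger_intercept, q_statistic = q_statistic),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s): %.4f (se %.4f, 95%% CI %.4f to %.4f), %d SNPs\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$n_snps))
  if (!is.null(x$f_statistic)) {
    cat(sprintf("  mean instrument F: %.1f\n", x$f_statistic))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept: %.4f (se %.4f)\n",
                x$egger_intercept[1], x$egger_intercept[2]))
  }
  invisible(x)
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("MVMR-IVW estimate, %d SNPs\n", x$n_snps))
  for (i in seq_along(x$exposure_ids)) {
    cat(sprintf("  %s: %.4f (se %.4f, 95%% CI %.4f to %.4f), conditional F %.1f\n",
                x$exposure_ids[i], x$estimates[i], x$ses[i],
                x$ci_low[i], x$ci_high[i], x$conditional_f[i]))
  }
  invisible(x)
}

.check_dataset <- function(data, min_rows = 1L, covariate = FALSE) {
  stopifnot(is.data.frame(data))
  need <- c("exposure_beta", "exposure_se", "outcome_beta", "outcome_se")
  if (covariate) need <- c(need, "covariate_beta", "covariate_se")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("summary dataset lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) < min_rows) {
    stop("estimator needs at least ", min_rows, " instruments, got ",
         nrow(data), call. = FALSE)
  }
  invisible(data)
}

#' Wald ratio estimate from a single SNP
#'
#' `outcome_beta / exposure_beta`, with the first-order standard error
#' `|outcome_se / exposure_beta|`.
#'
#' @param g_exp,g_out Single-SNP associations: one-row data frames (or
#'   lists) with `beta` and `se` (optionally `snp_id`).
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(g_exp, g_out) {
  be <- g_exp$beta; bo <- g_out$beta; so <- g_out$se
  stopifnot(length(be) == 1L, length(bo) == 1L)
  if (be == 0) {
    id <- if (!is.null(g_exp$snp_id)) g_exp$snp_id else "<unnamed SNP>"
    stop("zero exposure association for ", id,
         ": Wald ratio undefined", call. = FALSE)
  }
  .new_mr_estimate("wald", bo / be, abs(so / be), 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted least squares of the SNP-outcome on the SNP-exposure
#' associations with no intercept and weights `1 / outcome_se^2`. This
#' estimates the total effect of the exposure on the outcome. The default
#' standard error is the fixed-effect one, `(sum w * bx^2)^(-1/2)`;
#' `random_effects = TRUE` applies the multiplicative random-effects
#' inflation `max(1, sqrt(Q / (L - 1)))` appropriate for overdispersed
#' applied data.
#'
#' @param data A `summary_dataset` (see [make_summary_dataset()]).
#' @param random_effects Inflate the SE by the root mean Q contribution?
#' @return An `mr_estimate` whose `f_statistic` is the mean single-SNP F of
#'   the exposure associations.
#' @export
mr_ivw <- function(data, random_effects = FALSE) {
  .check_dataset(data, 1L)
  bx <- data$exposure_beta
  by <- data$outcome_beta
  w <- 1 / data$outcome_se^2
  a <- sum(w * bx^2)
  if (a == 0) {
    stop("all exposure associations are zero: singular IVW design",
         call. = FALSE)
  }
  est <- sum(w * bx * by) / a
  se <- sqrt(1 / a)
  L <- nrow(data)
  q <- sum(w * (by - est * bx)^2)
  if (random_effects && L > 1L) se <- se * max(1, sqrt(q / (L - 1)))
  .new_mr_estimate("ivw", est, se, L,
                   f_statistic = mean_f_statistic(bx, data$exposure_se),
                   q_statistic = q)
}

#' Multivariable IVW MR estimate
#'
#' Weighted least squares of the SNP-outcome associations on the matrix of
#' SNP-exposure associations (exposure and covariate), no intercept,
#' weights `1 / outcome_se^2`. Estimates the direct effect of each exposure
#' conditional on the other; per-exposure standard errors come from the
#' weighted covariance matrix and conditional F-statistics from
#' [conditional_f()].
#'
#' @param data A `summary_dataset` with covariate columns.
#' @param random_effects Apply the multiplicative random-effects SE
#'   inflation `max(1, sqrt(Q / (L - k)))`.
#' @return An `mvmr_estimate` with fields `exposure_ids`, `estimates`,
#'   `ses`, `ci_low`, `ci_high`, `conditional_f`, `n_snps`.
#' @export
mvmr_ivw <- function(data, random_effects = FALSE) {
  .check_dataset(data, 3L, covariate = TRUE)
  X <- cbind(exposure = data$exposure_beta, covariate = data$covariate_beta)
  y <- data$outcome_beta
  w <- 1 / data$outcome_se^2
  b <- se <- c(NA_real_, NA_real_)
  zero_col <- colSums(X != 0) == 0L
  if (any(zero_col)) {
    # a column of exact zeros leaves that coefficient unidentified (NA);
    # the other exposure's fit reduces to univariable IVW
    j <- which(!zero_col)
    if (length(j) == 0L) stop("all associations are zero", call. = FALSE)
    a <- sum(w * X[, j]^2)
    b[j] <- sum(w * X[, j] * y) / a
    se[j] <- sqrt(1 / a)
  } else {
    A <- crossprod(X, w * X)
    if (rcond(A) < 1e-12) {
      stop("singular MVMR design: exposure and covariate associations are ",
           "collinear", call. = FALSE)
    }
    V <- solve(A)
    b <- drop(V %*% crossprod(X, w * y))
    se <- sqrt(diag(V))
  }
  L <- nrow(data)
  fitted <- drop(X %*% ifelse(is.na(b), 0, b))
  q <- sum(w * (y - fitted)^2)
  if (random_effects && L > 2L) se <- se * max(1, sqrt(q / (L - 2)))
  structure(
    list(exposure_ids = c("exposure", "covariate"),
         estimates = unname(b), ses = unname(se),
         ci_low = unname(b - .Z95 * se), ci_high = unname(b + .Z95 * se),
         conditional_f = c(conditional_f(data, 1L), conditional_f(data, 2L)),
         n_snps = L, q_statistic = q),
    class = "mvmr_estimate"
  )
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome on the SNP-exposure
#' associations *with* an intercept, weights `1 / outcome_se^2`. Each SNP
#' is first oriented so its exposure association is non-negative (flipping
#' the outcome association along with it), which makes the fit invariant to
#' arbitrary per-SNP sign conventions. The intercept estimates directional
#' pleiotropy; the slope is the causal estimate.
#'
#' @param data A `summary_dataset` with at least 3 instruments.
#' @param random_effects Apply the multiplicative SE inflation
#'   `max(1, sqrt(Q / (L - 2)))`.
#' @return An `mr_estimate` with `egger_intercept = c(estimate, se)`.
#' @export
mr_egger <- function(data, random_effects = FALSE) {
  .check_dataset(data, 3L)
  s <- ifelse(data$exposure_beta < 0, -1, 1)
  bx <- s * data$exposure_beta
  by <- s * data$outcome_beta
  w <- 1 / data$outcome_se^2
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= 0 || isTRUE(all.equal(stats::var(bx), 0))) {
    stop("degenerate Egger design: no spread in exposure associations",
         call. = FALSE)
  }
  slope <- (sw * swxy - swx * swy) / det
  inter <- (swxx * swy - swx * swxy) / det
  se_slope <- sqrt(sw / det)
  se_inter <- sqrt(swxx / det)
  L <- nrow(data)
  q <- sum(w * (by - inter - slope * bx)^2)
  if (random_effects && L > 2L) {
    infl <- max(1, sqrt(q / (L - 2)))
    se_slope <- se_slope * infl
    se_inter <- se_inter * infl
  }
  .new_mr_estimate("egger", slope, se_slope, L,
                   f_statistic = mean_f_statistic(data$exposure_beta,
                                                  data$exposure_se),
                   egger_intercept = c(estimate = inter, se = se_inter),
                   q_statistic = q)
}

# Weighted median of ratios: cumulative-weight midpoints crossing 1/2, with
# linear interpolation between the bracketing order statistics.
.weighted_median <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  k <- max(which(p < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

.ratio_inputs <- function(data) {
  if (any(data$exposure_beta == 0)) {
    stop("zero exposure association: per-SNP ratios undefined", call. = FALSE)
  }
  list(r = data$outcome_beta / data$exposure_beta,
       w = data$exposure_beta^2 / data$outcome_se^2)
}

# Parametric bootstrap SE for ratio-based estimators: resample both
# association sets from normals centred on the estimates.
.boot_se <- function(data, n_boot, seed, statistic) {
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  L <- nrow(data)
  ests <- vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(L, data$exposure_beta, data$exposure_se)
    by <- rnorm(L, data$outcome_beta, data$outcome_se)
    bx[bx == 0] <- .Machine$double.eps
    statistic(by / bx, bx^2 / data$outcome_se^2)
  }, numeric(1))
  sd(ests)
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Weighted median MR estimate
#'
#' Median of the per-SNP Wald ratios under inverse-variance weights
#' (first-order: `exposure_beta^2 / outcome_se^2`), consistent when SNPs
#' carrying at least half the weight are valid instruments. The standard
#' error comes from a seeded parametric bootstrap of both association sets.
#'
#' @param data A `summary_dataset` with at least 3 instruments.
#' @param n_boot Bootstrap draws for the SE.
#' @param seed Optional seed for the bootstrap (the caller's RNG state is
#'   restored afterwards).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000L, seed = NULL) {
  .check_dataset(data, 3L)
  ri <- .ratio_inputs(data)
  est <- .weighted_median(ri$r, ri$w)
  se <- .boot_se(data, n_boot, seed, .weighted_median)
  .new_mr_estimate("weighted_median", est, se, nrow(data),
                   f_statistic = mean_f_statistic(data$exposure_beta,
                                                  data$exposure_se))
}

# Mode of the weighted kernel density of ratios: normal kernel, modified
# Silverman bandwidth, dense-grid argmax refined by golden-section search.
.weighted_mode <- function(r, w, bandwidth_factor = 1) {
  w <- w / sum(w)
  s <- min(sd(r), mad(r))
  if (s == 0) s <- sd(r)
  if (s == 0) return(r[1])                       # all ratios identical
  h <- bandwidth_factor * 0.9 * s * length(r)^(-1 / 5)
  dens <- function(x) {
    vapply(x, function(xi) sum(w * dnorm((xi - r) / h)) / h, numeric(1))
  }
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 2048L)
  i <- which.max(dens(grid))
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  optimize(dens, c(lo, hi), maximum = TRUE)$maximum
}

#' Weighted mode MR estimate
#'
#' Mode of the inverse-variance-weighted kernel density of the per-SNP Wald
#' ratios (normal kernel, modified Silverman bandwidth
#' `0.9 * min(sd, mad) * L^(-1/5)` scaled by `bandwidth_factor`),
#' consistent when the largest weight class of SNPs is valid. The standard
#' error comes from a seeded parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Positive multiplier on the default bandwidth.
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(data, bandwidth_factor = 1, n_boot = 1000L,
                             seed = NULL) {
  .check_dataset(data, 3L)
  if (!is.numeric(bandwidth_factor) || bandwidth_factor <= 0) {
    stop("`bandwidth_factor` must be > 0", call. = FALSE)
  }
  ri <- .ratio_inputs(data)
  est <- .weighted_mode(ri$r, ri$w, bandwidth_factor)
  se <- .boot_se(data, n_boot, seed,
                 function(r, w) .weighted_mode(r, w, bandwidth_factor))
  .new_mr_estimate("weighted_mode", est, se, nrow(data),
                   f_statistic = mean_f_statistic(data$exposure_beta,
                                                  data$exposure_se))
}

#' Mean single-SNP F-statistic
#'
#' Mean over instruments of `(beta / se)^2`, the usual summary-data
#' instrument-strength diagnostic for univariable MR.
#'
#' @param beta,se Vectors of SNP-exposure associations and their SEs.
#' @return A single number.
#' @export
mean_f_statistic <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 1)
  mean((beta / se)^2)
}

#' Conditional F-statistic for one exposure in a two-exposure MVMR
#'
#' Instrument strength for the target exposure conditional on the other,
#' following the heterogeneity Q formulation: minimise
#' `Q(delta) = sum_j (b_target_j - delta * b_other_j)^2 /
#' (se_target_j^2 + delta^2 * se_other_j^2)` over `delta` (dense grid plus
#' local refinement) and report `Q(delta_hat) / (L - 1)`. Values well above
#' 10 indicate conditionally strong instruments; values near 0 indicate the
#' target exposure's associations are explained by the other exposure's.
#'
#' @param data A `summary_dataset` with covariate columns and >= 3 rows.
#' @param exposure Index of the target exposure: 1 (exposure) or 2
#'   (covariate).
#' @return A single number.
#' @export
conditional_f <- function(data, exposure = 1L) {
  .check_dataset(data, 3L, covariate = TRUE)
  stopifnot(exposure %in% c(1L, 2L))
  if (exposure == 1L) {
    bt <- data$exposure_beta; st <- data$exposure_se
    bo <- data$covariate_beta; so <- data$covariate_se
  } else {
    bt <- data$covariate_beta; st <- data$covariate_se
    bo <- data$exposure_beta; so <- data$exposure_se
  }
  qfun <- function(d) sum((bt - d * bo)^2 / (st^2 + d^2 * so^2))
  grid <- seq(-10, 10, length.out = 2001L)
  qs <- vapply(grid, qfun, numeric(1))
  i <- which.min(qs)
  lo <- grid[max(1L, i - 2L)]; hi <- grid[min(length(grid), i + 2L)]
  qmin <- min(qs[i], optimize(qfun, c(lo, hi))$objective)
  qmin / (nrow(data) - 1)
}

#' Export estimator results as a tidy data frame
#'
#' @param est An `mr_estimate` or `mvmr_estimate`.
#' @return Data frame with columns `method`, `exposure`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `n_snps`, `f_statistic`.
#' @export
tidy_estimate <- function(est) {
  if (inherits(est, "mr_estimate")) {
    data.frame(method = est$method, exposure = "exposure",
               estimate = est$estimate, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               n_snps = est$n_snps,
               f_statistic = if (is.null(est$f_statistic)) NA_real_
                             else est$f_statistic,
               stringsAsFactors = FALSE)
  } else if (inherits(est, "mvmr_estimate")) {
    data.frame(method = "mvmr_ivw", exposure = est$exposure_ids,
               estimate = est$estimates, se = est$ses,
               ci_low = est$ci_low, ci_high = est$ci_high,
               n_snps = est$n_snps, f_statistic = est$conditional_f,
               stringsAsFactors = FALSE)
  } else {
    stop("not an estimator result", call. = FALSE)
  }
}
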