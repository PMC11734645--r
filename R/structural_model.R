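# Structural models for the three simulated causal structures.
#
# All three data-generating processes are linear structural equation models
# over an exposure X1, a heritable covariate X2, an outcome Y and an
# unmeasured confounder U that loads on all three.  250 biallelic SNPs are
# split into two sets: G1 SNPs act directly on X1, G2 SNPs directly on X2.
# The scenarios differ only in the direct path between the two traits:
#
#   confounded : X2 -> X1 (the covariate confounds the X1-Y relation)
#   correlated : no direct path; X1 and X2 correlate only through U
#   mediated   : X1 -> X2 (the covariate mediates part of the X1 effect)

# Mean-square per-SNP effect implied by the instrument-strength anchors
# (mean single-SNP F of roughly 300 for X1 and 265 for X2 at n = 100,000
# with MAF 0.3, where E[F] ~ 1 + n * 2p(1-p) * E[effect^2] for unit-variance
# traits).
.EFFECT_MEANSQ <- c(g1 = 0.0071381, g2 = 0.0063167)

# Default SD of the per-SNP effect distributions.  The mean-square above
# pins mean instrument strength; the SD controls how many covariate SNPs
# leak through genome-wide selection for the exposure, and is calibrated so
# that the selection-driven univariable MR biases match the reference
# simulation results (see the methods vignette).
.EFFECT_SD <- c(g1 = 0.02, g2 = 0.05)

# Confounder-driven covariance between X1 and X2 (loadings are
# sqrt of this value on each trait).  Chosen so that the total correlation
# cor(X1, X2) equals 0.525 / 0.275 / 0.40 in the confounded / correlated /
# mediated scenarios once the direct path (0.25) is added.
.RHO_U <- c(confounded = 0.275, correlated = 0.275, mediated = 0.15)

.SCENARIOS <- c("confounded", "correlated", "mediated")

#' Build a structural model for one simulation scenario
#'
#' Returns the full parameterisation of the linear data-generating process
#' for one of the three causal structures. Defaults encode the reference
#' parameterisation: direct effects `beta_x1_y = 0.4` and `beta_x2_y = 0.8`,
#' a trait-trait path of 0.25 where the scenario has one, 125 + 125 SNPs at
#' MAF 0.3, and confounder loadings and residual noise calibrated so that
#' X1 and X2 have unit variance and their correlation is 0.525 (confounded),
#' 0.275 (correlated) or 0.40 (mediated).
#'
#' Any field can be overridden; residual standard deviations are
#' re-calibrated to preserve unit trait variances unless they are themselves
#' overridden.
#'
#' @param scenario One of `"confounded"`, `"correlated"`, `"mediated"`.
#' @param overrides Named list of fields to override. Recognised names are
#'   the fields of the returned object, e.g. `beta_x1_y`, `snp_effect_sd`,
#'   `maf`, `u_y`, `sigma_x1`. `snp_effect_mean` and `snp_effect_sd` may be
#'   length 1 (shared by both SNP sets) or length 2 (`g1`, `g2`); `maf` may
#'   be a single frequency or a `c(lo, hi)` range sampled uniformly per SNP.
#' @return An object of class `mr_dgp`.
#' @examples
#' m <- build_model("mediated")
#' m$beta_x1_x2
#' total_effects(m)
#' @export
build_model <- function(scenario = c("confounded", "correlated", "mediated"),
                        overrides = list()) {
  scenario <- match.arg(scenario)
  sd0 <- .EFFECT_SD
  base <- list(
    scenario = scenario,
    n_snps_g1 = 125L,
    n_snps_g2 = 125L,
    beta_x1_y = 0.4,
    beta_x2_y = 0.8,
    beta_x2_x1 = if (scenario == "confounded") 0.25 else 0,
    beta_x1_x2 = if (scenario == "mediated") 0.25 else 0,
    snp_effect_mean = sqrt(.EFFECT_MEANSQ - sd0^2),
    snp_effect_sd = sd0,
    maf = 0.3,
    rho_u = unname(.RHO_U[scenario]),
    u_x1 = NULL,
    u_x2 = NULL,
    u_y = 0.5,
    sigma_x1 = NULL,
    sigma_x2 = NULL,
    sigma_y = 1,
    positive_effects = FALSE
  )
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("`overrides` must be a fully named list", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(base))
    if (length(unknown)) {
      stop("unknown model field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    base[names(overrides)] <- overrides
  }
  # structural zero paths are scenario invariants, not free parameters
  if (scenario != "confounded" && !isTRUE(all.equal(base$beta_x2_x1, 0))) {
    stop("beta_x2_x1 must be 0 outside the confounded scenario", call. = FALSE)
  }
  if (scenario != "mediated" && !isTRUE(all.equal(base$beta_x1_x2, 0))) {
    stop("beta_x1_x2 must be 0 outside the mediated scenario", call. = FALSE)
  }
  base$snp_effect_mean <- .recycle2(base$snp_effect_mean, "snp_effect_mean")
  base$snp_effect_sd <- .recycle2(base$snp_effect_sd, "snp_effect_sd")
  if (any(base$snp_effect_sd < 0)) {
    stop("snp_effect_sd must be >= 0", call. = FALSE)
  }
  if (any(base$maf <= 0) || any(base$maf > 0.5)) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  model <- .calibrate_model(base, fixed = names(overrides))
  .validate_model(model)
  structure(model, class = "mr_dgp")
}

.recycle2 <- function(x, what) {
  if (!is.numeric(x) || !length(x) %in% c(1L, 2L)) {
    stop("`", what, "` must be numeric of length 1 or 2", call. = FALSE)
  }
  x <- rep_len(unname(x), 2L)
  names(x) <- c("g1", "g2")
  x
}

# Expected dosage variance 2p(1-p), averaged over a uniform MAF range.
.mean_dosage_var <- function(maf) {
  if (length(maf) == 1L) return(2 * maf * (1 - maf))
  lo <- min(maf); hi <- max(maf)
  # E[2p(1-p)] for p ~ U(lo, hi)
  m1 <- (lo + hi) / 2
  m2 <- (hi^3 - lo^3) / (3 * (hi - lo))
  2 * (m1 - m2)
}

# Fill in confounder loadings and residual SDs so that Var(X1) = Var(X2) = 1
# under the model's SNP-effect distribution.  Fields named in `fixed` were
# supplied by the user and are left untouched.
.calibrate_model <- function(m, fixed = character()) {
  vg <- .mean_dosage_var(m$maf)
  q1 <- m$n_snps_g1 * vg * (m$snp_effect_mean[["g1"]]^2 + m$snp_effect_sd[["g1"]]^2)
  q2 <- m$n_snps_g2 * vg * (m$snp_effect_mean[["g2"]]^2 + m$snp_effect_sd[["g2"]]^2)
  if (is.null(m$u_x1)) m$u_x1 <- sqrt(m$rho_u)
  if (is.null(m$u_x2)) m$u_x2 <- sqrt(m$rho_u)
  cu <- m$u_x1 * m$u_x2
  s1sq <- s2sq <- NA_real_
  if (m$scenario == "confounded") {
    s2sq <- 1 - q2 - m$u_x2^2
    var_x2 <- q2 + m$u_x2^2 + if ("sigma_x2" %in% fixed) m$sigma_x2^2 else s2sq
    s1sq <- 1 - m$beta_x2_x1^2 * var_x2 - q1 - m$u_x1^2 - 2 * m$beta_x2_x1 * cu
  } else if (m$scenario == "correlated") {
    s1sq <- 1 - q1 - m$u_x1^2
    s2sq <- 1 - q2 - m$u_x2^2
  } else { # mediated
    s1sq <- 1 - q1 - m$u_x1^2
    var_x1 <- q1 + m$u_x1^2 + if ("sigma_x1" %in% fixed) m$sigma_x1^2 else s1sq
    s2sq <- 1 - m$beta_x1_x2^2 * var_x1 - q2 - m$u_x2^2 - 2 * m$beta_x1_x2 * cu
  }
  if (!("sigma_x1" %in% fixed)) {
    if (s1sq < 0) {
      stop("calibration gives negative residual variance for x1 (",
           signif(s1sq, 3), "); reduce genetic or confounder variance",
           call. = FALSE)
    }
    m$sigma_x1 <- sqrt(s1sq)
  }
  if (!("sigma_x2" %in% fixed)) {
    if (s2sq < 0) {
      stop("calibration gives negative residual variance for x2 (",
           signif(s2sq, 3), "); reduce genetic or confounder variance",
           call. = FALSE)
    }
    m$sigma_x2 <- sqrt(s2sq)
  }
  # implied second moments (informational; exact for fixed SNP effects at
  # their expected mean square)
  var_x2 <- q2 + m$u_x2^2 + m$sigma_x2^2
  var_x1 <- q1 + m$u_x1^2 + m$sigma_x1^2
  if (m$scenario == "confounded") {
    var_x1 <- var_x1 + m$beta_x2_x1^2 * var_x2 + 2 * m$beta_x2_x1 * cu
    cov12 <- m$beta_x2_x1 * var_x2 + cu
  } else if (m$scenario == "mediated") {
    var_x2 <- var_x2 + m$beta_x1_x2^2 * var_x1 + 2 * m$beta_x1_x2 * cu
    cov12 <- m$beta_x1_x2 * var_x1 + cu
  } else {
    cov12 <- cu
  }
  m$var_x1 <- unname(var_x1)
  m$var_x2 <- unname(var_x2)
  m$cor_x1_x2 <- unname(cov12 / sqrt(var_x1 * var_x2))
  m
}

.validate_model <- function(m) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_msg(m$n_snps_g1 >= 1 && m$n_snps_g2 >= 1,
                "each SNP set needs at least one variant")
  stopifnot_msg(all(m$maf > 0) && all(m$maf <= 0.5),
                "maf must lie in (0, 0.5]")
  stopifnot_msg(length(m$maf) %in% c(1L, 2L), "maf must be a value or a range")
  stopifnot_msg(all(m$snp_effect_sd >= 0), "snp_effect_sd must be >= 0")
  stopifnot_msg(m$sigma_x1 >= 0 && m$sigma_x2 >= 0 && m$sigma_y >= 0,
                "residual standard deviations must be >= 0")
  stopifnot_msg(m$rho_u >= 0 && m$rho_u <= 1, "rho_u must lie in [0, 1]")
  invisible(m)
}

#' Total causal effects of the two traits on the outcome
#'
#' Path-traced total effects: the X1 total adds the mediated path
#' `beta_x1_x2 * beta_x2_y`, the X2 total adds the confounding path
#' `beta_x2_x1 * beta_x1_y`. For the default models these are
#' (0.4, 0.9) confounded, (0.4, 0.8) correlated and (0.6, 0.8) mediated.
#'
#' @param model An `mr_dgp` object from [build_model()].
#' @return Named numeric vector `c(x1 = , x2 = )`.
#' @export
total_effects <- function(model) {
  stopifnot(inherits(model, "mr_dgp"))
  c(x1 = model$beta_x1_y + model$beta_x1_x2 * model$beta_x2_y,
    x2 = model$beta_x2_y + model$beta_x2_x1 * model$beta_x1_y)
}

#' Direct causal effects of the two traits on the outcome
#'
#' @param model An `mr_dgp` object.
#' @return Named numeric vector `c(x1 = , x2 = )`.
#' @export
direct_effects <- function(model) {
  stopifnot(inherits(model, "mr_dgp"))
  c(x1 = model$beta_x1_y, x2 = model$beta_x2_y)
}

#' @export
print.mr_dgp <- function(x, ...) {
  te <- total_effects(x)
  cat("Structural model:", x$scenario, "scenario\n")
  cat(sprintf("  SNPs: %d (G1 -> x1) + %d (G2 -> x2), MAF %s\n",
              x$n_snps_g1, x$n_snps_g2,
              paste(format(x$maf), collapse = "-")))
  cat(sprintf("  direct effects on y: x1 %.3g, x2 %.3g; trait-trait path: %s\n",
              x$beta_x1_y, x$beta_x2_y,
              if (x$beta_x2_x1 != 0) sprintf("x2 -> x1 = %.3g", x$beta_x2_x1)
              else if (x$beta_x1_x2 != 0) sprintf("x1 -> x2 = %.3g", x$beta_x1_x2)
              else "none"))
  cat(sprintf("  total effects on y: x1 %.3g, x2 %.3g\n", te[["x1"]], te[["x2"]]))
  cat(sprintf("  confounder loadings: u_x1 %.3f, u_x2 %.3f, u_y %.3f\n",
              x$u_x1, x$u_x2, x$u_y))
  cat(sprintf("  residual SDs: x1 %.3f, x2 %.3f, y %.3f\n",
              x$sigma_x1, x$sigma_x2, x$sigma_y))
  cat(sprintf("  implied cor(x1, x2) %.3f (var x1 %.3f, var x2 %.3f)\n",
              x$cor_x1_x2, x$var_x1, x$var_x2))
  invisible(x)
}
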