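# Analytic predictions of the bias introduced by covariate adjustment.
#
# When a GWAS regresses a trait X on each variant conditional on a
# covariate C, and X and C share an unmeasured cause, C acts as a collider
# on the path from the variant to X.  For jointly normal, standardised
# (X, C) the adjusted association satisfies
#
#     pi_A = pi_X - rho_CX * pi_C
#
# where pi_X and pi_C are the unadjusted associations with X and C and
# rho_CX = cor(X, C).  Everything in this file follows from substituting
# that identity into the IVW and MVMR estimating equations.

#' Predicted covariate-adjusted SNP association
#'
#' `-pi_c * rho_cx + pi_x`: the association a covariate-adjusted GWAS
#' reports for a variant whose unadjusted associations with the trait and
#' the covariate are `pi_x` and `pi_c`. Exact for jointly normal
#' standardised trait and covariate; an approximation otherwise.
#'
#' @param pi_x,pi_c Unadjusted variant-trait and variant-covariate
#'   associations (vectorised).
#' @param rho_cx Correlation between trait and covariate, in `[-1, 1]`.
#' @return Predicted adjusted association(s).
#' @examples
#' adjusted_association(0.08, 0.1, 0.5)   # 0.08 - 0.05
#' @export
adjusted_association <- function(pi_x, pi_c, rho_cx) {
  if (any(abs(rho_cx) > 1)) stop("|rho_cx| must be <= 1", call. = FALSE)
  -pi_c * rho_cx + pi_x
}

#' Predicted MVMR covariate coefficient under covariate-adjusted GWAS
#'
#' When MVMR includes the adjustment covariate as a second exposure, the
#' exposure's direct-effect estimate is unaffected by the adjustment, but
#' the covariate coefficient converges to a biased value:
#' `beta2 + beta1 * rho_cx` when the *exposure* GWAS was adjusted, and
#' `beta2 - rho_cx` when the *outcome* GWAS was adjusted. The
#' outcome-adjusted expression follows the same substitution with the
#' outcome's correlation parameter and should be read as approximate: in
#' simulation the outcome-adjusted covariate estimate is close to `beta2`
#' because instrument selection keeps covariate-associated SNPs out of the
#' univariable analysis and the effective correlation parameter is the
#' covariate-outcome partial correlation rather than `rho_cx`.
#'
#' @param beta1 Direct effect of the exposure on the outcome.
#' @param beta2 Direct effect of the covariate on the outcome.
#' @param rho_cx Exposure-covariate correlation.
#' @param scheme `"exposure"` or `"outcome"`: which GWAS was adjusted.
#' @return The predicted probability limit of the MVMR covariate
#'   coefficient.
#' @examples
#' predicted_mvmr_covariate_estimate(0.4, 0.8, 0.525, "exposure")  # 1.01
#' @export
predicted_mvmr_covariate_estimate <- function(beta1, beta2, rho_cx,
                                              scheme = c("exposure", "outcome")) {
  scheme <- match.arg(scheme)
  if (any(abs(rho_cx) > 1)) stop("|rho_cx| must be <= 1", call. = FALSE)
  if (scheme == "exposure") beta2 + beta1 * rho_cx else beta2 - rho_cx
}

#' Predicted direction of the adjusted-exposure univariable IVW bias
#'
#' Univariable MR from a covariate-adjusted exposure GWAS is biased in the
#' direction opposite to the covariate's direct effect on the outcome,
#' provided covariate-associated SNPs enter the instrument set and the
#' exposure-covariate correlation is non-zero; otherwise there is no bias.
#'
#' @param beta2 Direct effect of the covariate on the outcome.
#' @param selected_pi_c Covariate associations of the selected instruments.
#' @param rho_cx Exposure-covariate correlation.
#' @return `-1`, `0` or `1`: the predicted sign of the bias.
#' @export
predicted_ivw_bias_direction <- function(beta2, selected_pi_c, rho_cx) {
  stopifnot(length(selected_pi_c) >= 1)
  if (any(abs(rho_cx) > 1)) stop("|rho_cx| must be <= 1", call. = FALSE)
  if (all(selected_pi_c == 0) || rho_cx == 0) return(0)
  -sign(beta2)
}
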