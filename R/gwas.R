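# GWAS emulation: single-SNP association scans, instrument selection and
# assembly of summary datasets.

# Sufficient statistics for every single-SNP regression on a sample,
# computed once per sample and memoised: per-SNP sums against the trait
# matrix plus the trait-level first and second moments.
.sample_stats <- function(sample) {
  cache <- sample$.cache
  if (is.null(cache$stats)) {
    M <- cbind(x1 = sample$x1, x2 = sample$x2, y = sample$y)
    st <- cpp_scan_stats(sample$genotypes, M)
    st$trait_sum <- colSums(M)
    st$trait_cross <- crossprod(M)
    st$n <- nrow(M)
    colnames(st$cross) <- colnames(M)
    cache$stats <- st
  }
  cache$stats
}

#' Single-SNP association scan over a simulated sample
#'
#' For each SNP fits the ordinary least squares regression
#' `trait ~ intercept + dosage` (plus the covariate when `adjust_for` is
#' given) and reports the slope on the dosage, its standard error, a
#' two-sided p-value from the normal reference, and the sample size. This
#' emulates the per-variant output of a (covariate-adjusted) GWAS.
#'
#' Covariate-adjusted scans estimate the SNP-trait association conditional
#' on the covariate; when the SNP acts on the covariate and an unmeasured
#' confounder links covariate and trait, that conditioning opens a collider
#' path and biases the reported association (see [adjusted_association()]).
#'
#' @param sample An `mr_sample` from [simulate_sample()].
#' @param trait One of `"x1"`, `"x2"`, `"y"`.
#' @param adjust_for Optional covariate trait name, different from `trait`.
#' @return A `snp_assoc` data frame with columns `snp_id`, `trait`,
#'   `adjusted_for`, `beta`, `se`, `pvalue`, `n`. SNPs with degenerate
#'   (constant) genotype columns are dropped with a warning.
#' @export
gwas_scan <- function(sample, trait = c("x1", "x2", "y"), adjust_for = NULL) {
  stopifnot(inherits(sample, "mr_sample"))
  trait <- match.arg(trait)
  if (!is.null(adjust_for)) {
    adjust_for <- match.arg(adjust_for, c("x1", "x2", "y"))
    if (adjust_for == trait) {
      stop("`adjust_for` must name a different trait", call. = FALSE)
    }
  }
  st <- .sample_stats(sample)
  n <- st$n
  snp_id <- colnames(sample$genotypes)

  sgg <- st$sum_gg - st$sum_g^2 / n               # centred sum g^2
  sgt <- st$cross[, trait] - st$sum_g * st$trait_sum[trait] / n
  stt <- st$trait_cross[trait, trait] - st$trait_sum[trait]^2 / n

  if (is.null(adjust_for)) {
    ok <- sgg > 0
    beta <- sgt / sgg
    rss <- stt - beta * sgt
    se <- sqrt(pmax(rss, 0) / ((n - 2) * sgg))
    df_note <- NULL
  } else {
    sgc <- st$cross[, adjust_for] - st$sum_g * st$trait_sum[adjust_for] / n
    sct <- st$trait_cross[adjust_for, trait] -
      st$trait_sum[adjust_for] * st$trait_sum[trait] / n
    scc <- st$trait_cross[adjust_for, adjust_for] -
      st$trait_sum[adjust_for]^2 / n
    sgt_c <- sgt - sgc * sct / scc
    sgg_c <- sgg - sgc^2 / scc
    stt_c <- stt - sct^2 / scc
    ok <- sgg_c > 0
    beta <- sgt_c / sgg_c
    rss <- stt_c - beta * sgt_c
    se <- sqrt(pmax(rss, 0) / ((n - 3) * sgg_c))
    sgg <- sgg_c
  }
  if (!all(ok)) {
    warning(sum(!ok), " SNP(s) with constant genotypes excluded from the ",
            trait, " scan: ", paste(snp_id[!ok], collapse = ", "),
            call. = FALSE)
  }
  z <- beta / se
  out <- data.frame(
    snp_id = snp_id,
    trait = trait,
    adjusted_for = if (is.null(adjust_for)) NA_character_ else adjust_for,
    beta = unname(beta),
    se = unname(se),
    pvalue = unname(2 * pnorm(-abs(z))),
    n = n,
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_assoc", "data.frame")
  out
}

#' Select instruments by association p-value
#'
#' @param assocs A `snp_assoc` data frame.
#' @param p_threshold Selection threshold; the conventional genome-wide
#'   significance level 5e-8 by default.
#' @return Character vector of selected SNP ids, input order preserved
#'   (possibly empty).
#' @export
select_instruments <- function(assocs, p_threshold = 5e-8) {
  stopifnot(is.data.frame(assocs), nrow(assocs) >= 1,
            all(c("snp_id", "pvalue") %in% names(assocs)))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold < 0 || p_threshold > 1) {
    stop("`p_threshold` must be a probability", call. = FALSE)
  }
  assocs$snp_id[assocs$pvalue < p_threshold]
}

#' Assemble a harmonised summary dataset for MR estimation
#'
#' Row-aligns exposure, outcome and (optionally) covariate associations on
#' an instrument set. For multivariable MR the instrument set should be the
#' union of the exposure-selected and covariate-selected SNPs.
#'
#' @param exposure,outcome `snp_assoc` data frames (or any data frame with
#'   `snp_id`, `beta`, `se`).
#' @param covariate Optional `snp_assoc` data frame for the second exposure.
#' @param instruments Character vector of SNP ids; every id must be present
#'   in every supplied association table.
#' @param scheme Which associations came from covariate-adjusted GWAS:
#'   `"none"`, `"exposure"`, `"outcome"` or `"both"` (recorded, not acted
#'   on).
#' @return A `summary_dataset` data frame with columns `snp_id`,
#'   `exposure_beta`, `exposure_se`, (`covariate_beta`, `covariate_se`,)
#'   `outcome_beta`, `outcome_se` and an `adjustment_scheme` attribute.
#' @export
make_summary_dataset <- function(exposure, outcome, covariate = NULL,
                                 instruments,
                                 scheme = c("none", "exposure", "outcome", "both")) {
  scheme <- match.arg(scheme)
  instruments <- as.character(instruments)
  if (length(instruments) == 0L) {
    stop("empty instrument set: no SNPs to estimate from", call. = FALSE)
  }
  if (anyDuplicated(instruments)) {
    stop("duplicated SNP id(s) in instrument set: ",
         paste(unique(instruments[duplicated(instruments)]), collapse = ", "),
         call. = FALSE)
  }
  pick <- function(tab, what) {
    stopifnot(is.data.frame(tab), all(c("snp_id", "beta", "se") %in% names(tab)))
    if (anyDuplicated(tab$snp_id)) {
      stop("duplicated SNP id(s) in ", what, " associations", call. = FALSE)
    }
    idx <- match(instruments, tab$snp_id)
    if (anyNA(idx)) {
      stop("SNP(s) missing from ", what, " associations: ",
           paste(instruments[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    tab[idx, c("beta", "se")]
  }
  ex <- pick(exposure, "exposure")
  ou <- pick(outcome, "outcome")
  out <- data.frame(snp_id = instruments,
                    exposure_beta = ex$beta, exposure_se = ex$se,
                    stringsAsFactors = FALSE)
  if (!is.null(covariate)) {
    cv <- pick(covariate, "covariate")
    out$covariate_beta <- cv$beta
    out$covariate_se <- cv$se
  }
  out$outcome_beta <- ou$beta
  out$outcome_se <- ou$se
  if (any(out$exposure_se <= 0) || any(out$outcome_se <= 0) ||
      (!is.null(covariate) && any(out$covariate_se <= 0))) {
    stop("all standard errors must be > 0", call. = FALSE)
  }
  rownames(out) <- NULL
  structure(out, class = c("summary_dataset", "data.frame"),
            adjustment_scheme = scheme)
}

#' Write SNP associations to a TSV file
#'
#' @param assocs A `snp_assoc` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_snp_associations <- function(assocs, path) {
  stopifnot(is.data.frame(assocs))
  write.table(assocs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP associations written by [write_snp_associations()]
#'
#' @param path TSV path with header
#'   `snp_id, trait, adjusted_for, beta, se, pvalue, n`.
#' @return A `snp_assoc` data frame.
#' @export
read_snp_associations <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "trait", "adjusted_for", "beta", "se", "pvalue", "n")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out$adjusted_for <- as.character(out$adjusted_for)
  class(out) <- c("snp_assoc", "data.frame")
  out
}
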