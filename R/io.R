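# Applied-mode I/O: GWAS summary-statistics files and allele
# harmonisation. Inputs are assumed pre-clumped for LD; matching is by
# variant id only.

.DEFAULT_COLUMNS <- c(snp_id = "snp_id", effect_allele = "effect_allele",
                      other_allele = "other_allele", eaf = "eaf",
                      beta = "beta", se = "se", pvalue = "pvalue", n = "n")

.complement <- function(a) chartr("ACGT", "TGCA", a)

#' Read a GWAS summary-statistics file
#'
#' Reads a tab-separated file of per-variant summary associations. Rows
#' with missing beta or standard error, non-positive standard errors, or
#' alleles outside A/C/G/T are dropped with a message; duplicated variant
#' ids are an error.
#'
#' @param path TSV file with a header.
#' @param columns Named character vector mapping the canonical names
#'   (`snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`) to the file's column names; unspecified entries keep
#'   the canonical name. `eaf`, `pvalue` and `n` are optional columns.
#' @param trait Trait label attached to the result.
#' @param adjusted_for Covariate label if the GWAS was covariate-adjusted.
#' @return A `gwas_sumstats` data frame with canonical column names.
#' @export
read_summary_stats <- function(path, columns = NULL, trait = "trait",
                               adjusted_for = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  map <- .DEFAULT_COLUMNS
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), names(map))
    if (length(bad)) {
      stop("unknown column mapping(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    map[names(columns)] <- columns
  }
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(map[required], names(raw))
  if (length(miss)) {
    stop("missing mapped column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(snp_id = as.character(raw[[map[["snp_id"]]]]),
                    effect_allele = toupper(raw[[map[["effect_allele"]]]]),
                    other_allele = toupper(raw[[map[["other_allele"]]]]),
                    stringsAsFactors = FALSE)
  num_col <- function(name, default = NA_real_) {
    col <- map[[name]]
    if (!col %in% names(raw)) return(rep(default, nrow(raw)))
    v <- raw[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad)) {
        stop("unparseable numeric in column '", col, "' of ", path,
             " at data line(s) ", paste(utils::head(bad, 5), collapse = ", "),
             call. = FALSE)
      }
      v <- parsed
    }
    v
  }
  out$eaf <- num_col("eaf")
  out$beta <- num_col("beta")
  out$se <- num_col("se")
  out$pvalue <- num_col("pvalue")
  out$n <- num_col("n")

  keep <- !is.na(out$beta) & !is.na(out$se) & out$se > 0
  allele_ok <- out$effect_allele %in% c("A", "C", "G", "T") &
    out$other_allele %in% c("A", "C", "G", "T")
  dropped <- sum(!keep | !allele_ok)
  if (dropped > 0) {
    message(dropped, " row(s) dropped from ", basename(path),
            " (missing beta/se, se <= 0, or non-SNP alleles)")
  }
  out <- out[keep & allele_ok, , drop = FALSE]
  if (anyDuplicated(out$snp_id)) {
    stop("duplicated variant id(s) in ", path, ": ",
         paste(unique(out$snp_id[duplicated(out$snp_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(out$eaf) & (out$eaf <= 0 | out$eaf >= 1))) {
    stop("effect-allele frequencies must lie in (0, 1)", call. = FALSE)
  }
  rownames(out) <- NULL
  structure(out, class = c("gwas_sumstats", "data.frame"),
            trait = trait, adjusted_for = adjusted_for)
}

#' Write a summary-statistics table
#'
#' @param sumstats A `gwas_sumstats` data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_summary_stats <- function(sumstats, path) {
  stopifnot(is.data.frame(sumstats))
  write.table(sumstats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Classify one variant's outcome alleles against the exposure's.
# Returns the action and whether the outcome effect direction flips.
.allele_action <- function(ea1, oa1, ea2, oa2) {
  if (ea2 == ea1 && oa2 == oa1) return(list(action = "kept", flip = FALSE))
  if (ea2 == oa1 && oa2 == ea1) return(list(action = "flipped", flip = TRUE))
  cea2 <- .complement(ea2); coa2 <- .complement(oa2)
  if (cea2 == ea1 && coa2 == oa1) return(list(action = "kept", flip = FALSE))
  if (cea2 == oa1 && coa2 == ea1) return(list(action = "flipped", flip = TRUE))
  list(action = "dropped_mismatch", flip = FALSE)
}

#' Harmonise two or three summary-statistics tables
#'
#' Intersects the variant sets, aligns every table to the exposure's effect
#' alleles (sign-flipping betas and complementing eaf where the effect and
#' other alleles are swapped, allowing for strand flips), drops
#' strand-ambiguous palindromic variants (A/T or C/G) whose effect-allele
#' frequency lies within `af_window` of 0.5 in any table (or is missing),
#' and drops variants whose allele pairs cannot be reconciled. The result
#' is idempotent: harmonising already-harmonised tables changes nothing.
#'
#' @param exposure,outcome `gwas_sumstats` tables keyed by variant id.
#' @param covariate Optional third table (second exposure for MVMR).
#' @param af_window Half-width of the intermediate-frequency exclusion zone
#'   around 0.5 for palindromic variants (default 0.08, i.e. drop when eaf
#'   is in (0.42, 0.58)).
#' @return A `harmonised` list: aligned `exposure` / `outcome` /
#'   `covariate` tables, a `dataset` ([make_summary_dataset()] output over
#'   the kept variants), and an `audit` data frame recording the per-variant
#'   action (`kept`, `flipped`, `dropped_palindromic`, `dropped_mismatch`).
#' @export
harmonise <- function(exposure, outcome, covariate = NULL, af_window = 0.08) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  ids <- intersect(exposure$snp_id, outcome$snp_id)
  if (!is.null(covariate)) ids <- intersect(ids, covariate$snp_id)
  if (length(ids) == 0L) {
    stop("no variants shared across the supplied tables", call. = FALSE)
  }
  ex <- exposure[match(ids, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(ids, outcome$snp_id), , drop = FALSE]
  cv <- if (!is.null(covariate)) {
    covariate[match(ids, covariate$snp_id), , drop = FALSE]
  }
  action <- character(length(ids))
  for (i in seq_along(ids)) {
    ea1 <- ex$effect_allele[i]; oa1 <- ex$other_allele[i]
    palindromic <- ea1 == .complement(oa1)
    if (palindromic) {
      eafs <- c(ex$eaf[i], ou$eaf[i], if (!is.null(cv)) cv$eaf[i])
      if (any(is.na(eafs)) || any(abs(eafs - 0.5) < af_window)) {
        action[i] <- "dropped_palindromic"
        next
      }
    }
    align <- function(tab) {
      if (palindromic) {
        # strand cannot distinguish the two orientations of an A/T or C/G
        # variant; outside the intermediate-frequency window the
        # orientation with concordant allele frequencies is taken
        valid <- tab$effect_allele[i] %in% c(ea1, oa1) &&
          tab$other_allele[i] %in% c(ea1, oa1) &&
          tab$effect_allele[i] != tab$other_allele[i]
        if (!valid) return(list(tab = tab, action = "dropped_mismatch"))
        flip <- abs((1 - tab$eaf[i]) - ex$eaf[i]) < abs(tab$eaf[i] - ex$eaf[i])
        act <- list(action = if (flip) "flipped" else "kept", flip = flip)
      } else {
        act <- .allele_action(ea1, oa1, tab$effect_allele[i],
                              tab$other_allele[i])
      }
      if (isTRUE(act$flip)) {
        tab$beta[i] <- -tab$beta[i]
        if (!is.na(tab$eaf[i])) tab$eaf[i] <- 1 - tab$eaf[i]
      }
      tab$effect_allele[i] <- ea1
      tab$other_allele[i] <- oa1
      list(tab = tab, action = act$action)
    }
    a_ou <- align(ou); ou <- a_ou$tab
    a_cv <- if (!is.null(cv)) {
      tmp <- align(cv); cv <- tmp$tab; tmp
    }
    acts <- c(a_ou$action, if (!is.null(cv)) a_cv$action)
    action[i] <- if ("dropped_mismatch" %in% acts) {
      "dropped_mismatch"
    } else if ("flipped" %in% acts) "flipped" else "kept"
  }
  keep <- action %in% c("kept", "flipped")
  if (!any(keep)) {
    stop("harmonisation left no usable variants", call. = FALSE)
  }
  audit <- data.frame(snp_id = ids, action = action, stringsAsFactors = FALSE)
  ex <- ex[keep, , drop = FALSE]; ou <- ou[keep, , drop = FALSE]
  if (!is.null(cv)) cv <- cv[keep, , drop = FALSE]
  scheme <- .infer_scheme(exposure, outcome)
  dataset <- make_summary_dataset(ex, ou, covariate = cv,
                                  instruments = ids[keep], scheme = scheme)
  structure(list(exposure = ex, outcome = ou, covariate = cv,
                 dataset = dataset, audit = audit, af_window = af_window),
            class = "harmonised")
}

.infer_scheme <- function(exposure, outcome) {
  ea <- !is.null(attr(exposure, "adjusted_for"))
  oa <- !is.null(attr(outcome, "adjusted_for"))
  if (ea && oa) "both" else if (ea) "exposure" else if (oa) "outcome" else "none"
}

#' @export
print.harmonised <- function(x, ...) {
  tab <- table(factor(x$audit$action,
                      c("kept", "flipped", "dropped_palindromic",
                        "dropped_mismatch")))
  cat("Harmonised summary data:", nrow(x$dataset), "variants retained\n")
  cat(sprintf("  kept %d, flipped %d, dropped palindromic %d, dropped mismatch %d\n",
              tab[["kept"]], tab[["flipped"]], tab[["dropped_palindromic"]],
              tab[["dropped_mismatch"]]))
  invisible(x)
}
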