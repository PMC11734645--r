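# Monte Carlo driver: replication protocol, aggregation and table
# rendering for the simulation study.

.SCHEMES <- c("none", "exposure", "outcome", "both")

# Recycled genotype buffers (one per sample role and problem size) so the
# Monte Carlo loop does not re-allocate two n x L integer matrices per
# replication.
.buffer_env <- new.env(parent = emptyenv())
.geno_buffer <- function(n, L, slot) {
  key <- sprintf("%s_%d_%d", slot, n, L)
  buf <- .buffer_env[[key]]
  if (is.null(buf)) {
    buf <- matrix(NA_integer_, n, L)
    colnames(buf) <- sprintf("snp_%03d", seq_len(L))
    .buffer_env[[key]] <- buf
  }
  buf
}
.SCHEME_LABELS <- c(none = "Unadjusted", exposure = "Exposure adj.",
                    outcome = "Outcome adj.", both = "Both adj.")

#' Derive a replication seed from a master seed
#'
#' Deterministic counter scheme (documented so any subset of replications
#' can be recomputed independently): `(master + 7919 * rep) mod (2^31 - 1)`.
#'
#' @param master Master seed (integer).
#' @param rep Replication number (1-based).
#' @return An integer seed.
#' @export
replication_seed <- function(master, rep) {
  as.integer((as.double(master) + 7919 * as.double(rep)) %% 2147483647)
}

#' Configuration for a Monte Carlo scenario run
#'
#' @param scenario Scenario name passed to [build_model()].
#' @param n Per-sample size (two samples are simulated per replication).
#' @param n_reps Number of replications.
#' @param seed Master seed; replication `r` uses
#'   [replication_seed()]`(seed, r)`.
#' @param p_threshold Instrument-selection p-value threshold.
#' @param schemes Adjustment schemes to evaluate (subset of `"none"`,
#'   `"exposure"`, `"outcome"`, `"both"`).
#' @param overrides Model overrides passed to [build_model()].
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario, n = 1e5, n_reps = 200L, seed = 1L,
                            p_threshold = 5e-8, schemes = .SCHEMES,
                            overrides = list()) {
  schemes <- match.arg(schemes, .SCHEMES, several.ok = TRUE)
  stopifnot(n_reps >= 1, length(schemes) >= 1)
  structure(
    list(scenario = scenario, model = build_model(scenario, overrides),
         n = n, n_reps = as.integer(n_reps), seed = as.integer(seed),
         p_threshold = p_threshold, schemes = schemes),
    class = "scenario_config"
  )
}

#' Run one Monte Carlo replication
#'
#' Simulates two independent samples from the same population draw (shared
#' per-SNP effects): an exposure sample, scanned for x1 (unadjusted and
#' adjusted for x2) and for x2, and an outcome sample scanned for y
#' (unadjusted and, where requested, adjusted for x2). Instruments are
#' selected in the exposure sample (`p < p_threshold`); for each adjustment
#' scheme the requested univariable IVW and multivariable IVW analyses are
#' run. For MVMR the instrument set is the union of the exposure-selected
#' and covariate-selected SNPs.
#'
#' Adjustment schemes follow the simulation study's table layout:
#' `"exposure"` uses the x2-adjusted x1 scan for both selection and
#' exposure associations, `"outcome"` uses the x2-adjusted y scan for the
#' outcome associations, `"both"` does both. The x2 univariable analysis is
#' only defined for unadjusted and outcome-adjusted schemes (adjusting the
#' x2 GWAS for x2 itself is meaningless); other cells are reported as `NA`.
#'
#' @param model An `mr_dgp` object.
#' @param n Per-sample size.
#' @param p_threshold Selection threshold.
#' @param schemes Character vector of schemes to evaluate.
#' @param seed Seed for this replication.
#' @param estimators Which analyses to run: subset of `"ivw"`, `"mvmr"`.
#' @param mvmr_random_effects Use the multiplicative random-effects SE for
#'   the MVMR fits (default `TRUE`). Instrument selection induces
#'   conditional heterogeneity that the fixed-effect MVMR interval
#'   ignores, making it anti-conservative; the residual-scaled SE restores
#'   near-nominal coverage for the unbiased coefficients. Univariable IVW
#'   keeps fixed-effect SEs, under which the adjusted-exposure analyses
#'   are diagnosed as decisively biased (zero coverage).
#' @return Data frame with one row per (scheme, analysis, exposure):
#'   estimate, se, normal 95% CI, instrument count and (conditional)
#'   F-statistic, with the empirical `cor(x1, x2)` of the exposure sample
#'   attached as attribute `rho_cx`. Analyses with an empty instrument set
#'   yield `NA` rows flagged `skipped`.
#' @export
run_replication <- function(model, n = 1e5, p_threshold = 5e-8,
                            schemes = c("none", "exposure"), seed = 1L,
                            estimators = c("ivw", "mvmr"),
                            mvmr_random_effects = TRUE) {
  stopifnot(inherits(model, "mr_dgp"))
  schemes <- match.arg(schemes, .SCHEMES, several.ok = TRUE)
  estimators <- match.arg(estimators, c("ivw", "mvmr"), several.ok = TRUE)
  set.seed(seed)
  eff <- draw_snp_effects(model)
  L <- model$n_snps_g1 + model$n_snps_g2
  sample_a <- simulate_sample(model, n, effects = eff,    # exposure sample
                              buffer = .geno_buffer(n, L, "a"))
  sample_b <- simulate_sample(model, n, effects = eff,    # outcome sample
                              buffer = .geno_buffer(n, L, "b"))

  need_adj_x1 <- any(schemes %in% c("exposure", "both"))
  need_adj_y <- any(schemes %in% c("outcome", "both"))
  scan_x1 <- gwas_scan(sample_a, "x1")
  scan_x1_adj <- if (need_adj_x1) gwas_scan(sample_a, "x1", adjust_for = "x2")
  scan_x2 <- gwas_scan(sample_a, "x2")
  scan_y <- gwas_scan(sample_b, "y")
  scan_y_adj <- if (need_adj_y) gwas_scan(sample_b, "y", adjust_for = "x2")
  rho_cx <- cor(sample_a$x1, sample_a$x2)

  instr_x1 <- select_instruments(scan_x1, p_threshold)
  instr_x1_adj <- if (need_adj_x1) select_instruments(scan_x1_adj, p_threshold)
  instr_x2 <- select_instruments(scan_x2, p_threshold)

  empty_row <- function(scheme, analysis, exposure) {
    data.frame(scheme = scheme, analysis = analysis, exposure = exposure,
               estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, n_snps = 0L, f_stat = NA_real_,
               skipped = TRUE, stringsAsFactors = FALSE)
  }
  rows <- vector("list", 0L)
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  for (scheme in schemes) {
    exp_scan <- if (scheme %in% c("exposure", "both")) scan_x1_adj else scan_x1
    exp_instr <- if (scheme %in% c("exposure", "both")) instr_x1_adj else instr_x1
    out_scan <- if (scheme %in% c("outcome", "both")) scan_y_adj else scan_y

    if ("ivw" %in% estimators) {
      if (length(exp_instr) == 0L) {
        add(empty_row(scheme, "mr", "x1"))
      } else {
        ds <- make_summary_dataset(exp_scan, out_scan,
                                   instruments = exp_instr, scheme = scheme)
        est <- mr_ivw(ds)
        add(data.frame(scheme = scheme, analysis = "mr", exposure = "x1",
                       estimate = est$estimate, se = est$se,
                       ci_low = est$ci_low, ci_high = est$ci_high,
                       n_snps = est$n_snps, f_stat = est$f_statistic,
                       skipped = FALSE, stringsAsFactors = FALSE))
      }
      # x2 on y: defined when the x2 GWAS itself is unadjusted
      if (scheme %in% c("none", "outcome")) {
        if (length(instr_x2) == 0L) {
          add(empty_row(scheme, "mr", "x2"))
        } else {
          ds2 <- make_summary_dataset(scan_x2, out_scan,
                                      instruments = instr_x2, scheme = scheme)
          est2 <- mr_ivw(ds2)
          add(data.frame(scheme = scheme, analysis = "mr", exposure = "x2",
                         estimate = est2$estimate, se = est2$se,
                         ci_low = est2$ci_low, ci_high = est2$ci_high,
                         n_snps = est2$n_snps, f_stat = est2$f_statistic,
                         skipped = FALSE, stringsAsFactors = FALSE))
        }
      }
    }
    if ("mvmr" %in% estimators) {
      union_instr <- union(exp_instr, instr_x2)
      if (length(union_instr) < 3L) {
        add(empty_row(scheme, "mvmr", "x1"))
        add(empty_row(scheme, "mvmr", "x2"))
      } else {
        dsm <- make_summary_dataset(exp_scan, out_scan, covariate = scan_x2,
                                    instruments = union_instr, scheme = scheme)
        mv <- mvmr_ivw(dsm, random_effects = mvmr_random_effects)
        add(data.frame(scheme = scheme, analysis = "mvmr",
                       exposure = c("x1", "x2"),
                       estimate = mv$estimates, se = mv$ses,
                       ci_low = mv$ci_low, ci_high = mv$ci_high,
                       n_snps = mv$n_snps, f_stat = mv$conditional_f,
                       skipped = FALSE, stringsAsFactors = FALSE))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rho_cx") <- rho_cx
  out
}

#' Aggregate replication results into table cells
#'
#' For every (scheme, analysis, exposure) cell: the mean estimate, the mean
#' model SE, the empirical SD of the estimates, the coverage of the normal
#' 95% CI against the truth, and the mean (conditional) F-statistic.
#' Coverage is judged against the *total* effect for univariable MR and the
#' *direct* effect for MVMR. Skipped replications (empty instrument sets)
#' are dropped and counted.
#'
#' @param replications Data frame of stacked [run_replication()] results
#'   with a `rep` column.
#' @param model The generating `mr_dgp` (supplies the true effects).
#' @return A data frame of `MonteCarloSummary` rows.
#' @export
aggregate_replications <- function(replications, model) {
  stopifnot(is.data.frame(replications), nrow(replications) >= 1)
  tot <- total_effects(model)
  dir <- direct_effects(model)
  truth_of <- function(analysis, exposure) {
    if (analysis == "mr") tot[[exposure]] else dir[[exposure]]
  }
  cells <- unique(replications[c("scheme", "analysis", "exposure")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- replications[replications$scheme == cell$scheme &
                        replications$analysis == cell$analysis &
                        replications$exposure == cell$exposure, ]
    ok <- sub[!sub$skipped & !is.na(sub$estimate), ]
    if (nrow(ok) == 0L) {
      stop("no successful replications for cell ",
           paste(cell, collapse = "/"), call. = FALSE)
    }
    truth <- truth_of(cell$analysis, cell$exposure)
    data.frame(
      scenario = model$scenario, scheme = cell$scheme,
      analysis = cell$analysis, exposure = cell$exposure,
      truth = truth,
      mean_estimate = mean(ok$estimate),
      mean_model_se = mean(ok$se),
      empirical_sd = sd(ok$estimate),
      coverage = mean(ok$ci_low <= truth & truth <= ok$ci_high),
      mean_f = mean(ok$f_stat),
      n_reps_used = nrow(ok),
      n_reps_skipped = nrow(sub) - nrow(ok),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run a full Monte Carlo scenario
#'
#' Runs `n_reps` replications of [run_replication()] under the
#' configuration and aggregates them with [aggregate_replications()].
#'
#' @param config A `scenario_config`.
#' @param estimators Passed to [run_replication()].
#' @param quiet Suppress the progress message?
#' @return An `mc_result` list: `scenario`, `model`, `config`,
#'   `replications` (per-rep rows), `summaries` (aggregated cells),
#'   `mean_rho_cx`.
#' @export
run_scenario <- function(config, estimators = c("ivw", "mvmr"),
                         quiet = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  reps <- vector("list", config$n_reps)
  rho <- numeric(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    res <- run_replication(config$model, n = config$n,
                           p_threshold = config$p_threshold,
                           schemes = config$schemes,
                           seed = replication_seed(config$seed, r),
                           estimators = estimators)
    res$rep <- r
    rho[r] <- attr(res, "rho_cx")
    reps[[r]] <- res
    if (!quiet && r %% 25L == 0L) {
      message(config$scenario, ": replication ", r, "/", config$n_reps)
    }
  }
  replications <- do.call(rbind, reps)
  structure(
    list(scenario = config$scenario, model = config$model, config = config,
         replications = replications,
         summaries = aggregate_replications(replications, config$model),
         mean_rho_cx = mean(rho)),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo result: %s scenario, %d reps, n = %g\n",
              x$scenario, x$config$n_reps, x$config$n))
  cat(sprintf("  mean cor(x1, x2) = %.3f\n", x$mean_rho_cx))
  print(x$summaries, digits = 3)
  invisible(x)
}

.fmt_cell <- function(value, digits) {
  if (is.na(value)) "—" else sprintf(paste0("%.", digits, "f"), value)
}

#' Render aggregated results as a simulation-study table
#'
#' Lays out the cells the way the study tables do: one block per scenario
#' with rows Mean estimate / Std. error / Coverage / F-statistic, and one
#' (x1, x2) column pair per adjustment scheme. Estimates and coverage are
#' printed to two decimals, standard errors to three, F-statistics to one;
#' unavailable cells (for example the x2 column of an exposure-adjusted
#' univariable analysis) print an em-dash.
#'
#' @param summaries Aggregated rows from one or more scenarios
#'   ([aggregate_replications()] output, possibly row-bound).
#' @param analysis `"mr"` (univariable) or `"mvmr"`.
#' @param se_source `"model"` (mean model SE) or `"empirical"` (SD of the
#'   estimates across replications); both are computed because either
#'   reading of a reported "Std. error" is defensible.
#' @return A single string (class `mc_table`) ready for `cat()`.
#' @export
render_table <- function(summaries, analysis = c("mr", "mvmr"),
                         se_source = c("empirical", "model")) {
  analysis <- match.arg(analysis)
  se_source <- match.arg(se_source)
  stopifnot(is.data.frame(summaries))
  sub <- summaries[summaries$analysis == analysis, ]
  if (nrow(sub) == 0L) stop("no rows for analysis ", analysis, call. = FALSE)
  scen <- intersect(.SCENARIOS, unique(sub$scenario))
  schemes <- intersect(.SCHEMES, unique(sub$scheme))
  se_col <- if (se_source == "empirical") "empirical_sd" else "mean_model_se"

  cell <- function(s, sch, exp, col) {
    row <- sub[sub$scenario == s & sub$scheme == sch & sub$exposure == exp, ]
    if (nrow(row) == 0L) NA_real_ else row[[col]]
  }
  header1 <- c("", unlist(lapply(schemes, function(sch)
    c(.SCHEME_LABELS[[sch]], ""))))
  header2 <- c("", rep(c("X1", "X2"), length(schemes)))
  lines <- list(header1, header2)
  for (s in scen) {
    title <- paste0(toupper(substring(s, 1, 1)), substring(s, 2))
    lines[[length(lines) + 1L]] <- c(title, rep("", 2L * length(schemes)))
    spec_rows <- list(
      c("Mean estimate", "mean_estimate", 2L),
      c("Std. error", se_col, 3L),
      c("Coverage", "coverage", 2L),
      c("F-statistic", "mean_f", 1L)
    )
    for (sr in spec_rows) {
      vals <- unlist(lapply(schemes, function(sch) {
        c(.fmt_cell(cell(s, sch, "x1", sr[2]), as.integer(sr[3])),
          .fmt_cell(cell(s, sch, "x2", sr[2]), as.integer(sr[3])))
      }))
      lines[[length(lines) + 1L]] <- c(sr[1], vals)
    }
  }
  mat <- do.call(rbind, lines)
  widths <- apply(nchar(mat, type = "width"), 2, max)
  body <- apply(mat, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
  structure(paste(trimws(body, "right"), collapse = "\n"), class = "mc_table")
}

#' @export
print.mc_table <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}

#' Reproduce the simulation-study tables
#'
#' Runs the full scenario grid and renders the univariable-MR and MVMR
#' tables. With `supplementary = TRUE` the null-exposure
#' (`beta_x1_y = 0`), null-covariate (`beta_x2_y = 0`) and
#' opposite-direction (`beta_x2_y = -0.8`) variants of each scenario are
#' added.
#'
#' @param seed Master seed; scenario `i` (in run order) uses master seed
#'   `(seed + 1000003 * i) mod (2^31 - 1)`.
#' @param n_reps Replications per scenario (the reduced profile of 200 by
#'   default; the full study profile used 1000).
#' @param n Per-sample size.
#' @param scenarios Scenarios to run.
#' @param schemes Adjustment schemes.
#' @param supplementary Add the null / opposite-direction variants?
#' @param out_dir Optional directory: writes `table_mr.txt`,
#'   `table_mvmr.txt`, `summaries.tsv` and a seed/parameter provenance
#'   header `run_info.tsv`.
#' @param quiet Suppress progress messages?
#' @return List with `results` (named `mc_result` list), `summaries`
#'   (row-bound), `table_mr`, `table_mvmr`.
#' @export
reproduce_tables <- function(seed = 1L, n_reps = 200L, n = 1e5,
                             scenarios = c("confounded", "correlated", "mediated"),
                             schemes = .SCHEMES, supplementary = FALSE,
                             out_dir = NULL, quiet = FALSE) {
  runs <- lapply(scenarios, function(s) list(scenario = s, overrides = list(),
                                             label = s))
  if (supplementary) {
    for (s in scenarios) {
      runs <- c(runs, list(
        list(scenario = s, overrides = list(beta_x1_y = 0),
             label = paste0(s, "_null_x1")),
        list(scenario = s, overrides = list(beta_x2_y = 0),
             label = paste0(s, "_null_x2")),
        list(scenario = s, overrides = list(beta_x2_y = -0.8),
             label = paste0(s, "_opposite"))
      ))
    }
  }
  results <- list()
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    master <- as.integer((as.double(seed) + 1000003 * i) %% 2147483647)
    cfg <- scenario_config(run$scenario, n = n, n_reps = n_reps,
                           seed = master, schemes = schemes,
                           overrides = run$overrides)
    if (!quiet) message("running ", run$label, " (master seed ", master, ")")
    res <- run_scenario(cfg, quiet = quiet)
    res$label <- run$label
    res$summaries$scenario <- run$label
    results[[run$label]] <- res
  }
  summaries <- do.call(rbind, lapply(results, `[[`, "summaries"))
  rownames(summaries) <- NULL
  main <- summaries[summaries$scenario %in% scenarios, ]
  tab_mr <- render_table(main, "mr")
  tab_mvmr <- render_table(main, "mvmr")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(unclass(tab_mr), file.path(out_dir, "table_mr.txt"))
    writeLines(unclass(tab_mvmr), file.path(out_dir, "table_mvmr.txt"))
    write.table(summaries, file.path(out_dir, "summaries.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    info <- data.frame(
      key = c("seed", "n_reps", "n", "scenarios", "schemes", "supplementary",
              "package_version"),
      value = c(seed, n_reps, format(n, scientific = FALSE),
                paste(scenarios, collapse = ","),
                paste(schemes, collapse = ","), supplementary,
                as.character(utils::packageVersion("covadjMR")))
    )
    write.table(info, file.path(out_dir, "run_info.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(results = results, summaries = summaries,
       table_mr = tab_mr, table_mvmr = tab_mvmr)
}
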