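# Individual-level simulation under an mr_dgp structural model.

#' Draw per-SNP effect sizes for one replication
#'
#' Effects of the G1 SNPs on X1 and of the G2 SNPs on X2 are drawn from
#' normal distributions with the model's `snp_effect_mean` and
#' `snp_effect_sd`. The effect vector is treated as part of the stochastic
#' design and redrawn each replication; pass the result to
#' [simulate_sample()] (for both samples of a two-sample design) to hold it
#' fixed.
#'
#' @param model An `mr_dgp` object.
#' @return List with numeric vectors `g1` and `g2`.
#' @export
draw_snp_effects <- function(model) {
  stopifnot(inherits(model, "mr_dgp"))
  g1 <- rnorm(model$n_snps_g1, model$snp_effect_mean[["g1"]],
              model$snp_effect_sd[["g1"]])
  g2 <- rnorm(model$n_snps_g2, model$snp_effect_mean[["g2"]],
              model$snp_effect_sd[["g2"]])
  if (isTRUE(model$positive_effects)) {
    g1 <- abs(g1)
    g2 <- abs(g2)
  }
  list(g1 = g1, g2 = g2)
}

#' Simulate an individual-level sample from a structural model
#'
#' Generates genotypes as independent Binomial(2, MAF) dosages and the
#' traits in the topological order of the scenario DAG with independent
#' normal residuals. The random draws happen in a fixed order (per-SNP MAF
#' if a range was requested, SNP effects if not supplied, genotypes,
#' confounder, then the x1 / x2 / y residuals), so a given
#' `(model, n, seed)` always reproduces the same sample.
#'
#' @param model An `mr_dgp` object from [build_model()].
#' @param n Sample size (>= 1).
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @param effects Optional effect list from [draw_snp_effects()]; supply the
#'   same list to two calls to emulate a two-sample design drawn from one
#'   population.
#' @param buffer Optional pre-allocated integer matrix of dimension
#'   `n x 250` that is filled in place with the dosages and becomes the
#'   returned sample's genotype matrix. Used by the Monte Carlo driver to
#'   recycle the two large dosage matrices across replications; note that
#'   any earlier sample built on the same buffer is invalidated.
#' @return An object of class `mr_sample`: genotype matrix (`n` x 250 allele
#'   dosages in 0/1/2, columns named `snp_001`, ...), trait vectors `x1`,
#'   `x2`, `y`, the confounder `u`, the index sets `g1_index` / `g2_index`,
#'   the true per-SNP effects, and the generating model.
#' @examples
#' m <- build_model("correlated")
#' s <- simulate_sample(m, n = 2000, seed = 1)
#' cor(s$x1, s$x2)
#' @export
simulate_sample <- function(model, n, seed = NULL, effects = NULL,
                            buffer = NULL) {
  stopifnot(inherits(model, "mr_dgp"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a single count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  L <- model$n_snps_g1 + model$n_snps_g2
  maf <- if (length(model$maf) == 2L) {
    runif(L, min(model$maf), max(model$maf))
  } else {
    rep(model$maf, L)
  }
  if (is.null(effects)) effects <- draw_snp_effects(model)
  stopifnot(length(effects$g1) == model$n_snps_g1,
            length(effects$g2) == model$n_snps_g2)

  g1_index <- seq_len(model$n_snps_g1)
  g2_index <- model$n_snps_g1 + seq_len(model$n_snps_g2)
  eff <- matrix(0, L, 2)
  eff[g1_index, 1] <- effects$g1
  eff[g2_index, 2] <- effects$g2

  if (is.null(buffer)) {
    G <- matrix(NA_integer_, n, L)
  } else {
    stopifnot(is.matrix(buffer), is.integer(buffer),
              nrow(buffer) == n, ncol(buffer) == L)
    G <- buffer
  }
  scores <- matrix(0, n, 2)
  cpp_sim_geno_fill(G, maf, eff, scores)
  if (is.null(colnames(G))) colnames(G) <- sprintf("snp_%03d", seq_len(L))

  u <- rnorm(n)
  e1 <- rnorm(n, sd = model$sigma_x1)
  e2 <- rnorm(n, sd = model$sigma_x2)
  ey <- rnorm(n, sd = model$sigma_y)

  if (model$scenario == "confounded") {
    x2 <- scores[, 2] + model$u_x2 * u + e2
    x1 <- model$beta_x2_x1 * x2 + scores[, 1] + model$u_x1 * u + e1
  } else if (model$scenario == "mediated") {
    x1 <- scores[, 1] + model$u_x1 * u + e1
    x2 <- model$beta_x1_x2 * x1 + scores[, 2] + model$u_x2 * u + e2
  } else {
    x1 <- scores[, 1] + model$u_x1 * u + e1
    x2 <- scores[, 2] + model$u_x2 * u + e2
  }
  y <- model$beta_x1_y * x1 + model$beta_x2_y * x2 + model$u_y * u + ey

  structure(
    list(genotypes = G, x1 = x1, x2 = x2, y = y, u = u,
         g1_index = g1_index, g2_index = g2_index,
         effects = effects, maf = maf, n = n, model = model,
         .cache = new.env(parent = emptyenv())),
    class = "mr_sample"
  )
}

#' @export
print.mr_sample <- function(x, ...) {
  cat(sprintf("Simulated sample: n = %d, %d SNPs (%s scenario)\n",
              x$n, ncol(x$genotypes), x$model$scenario))
  cat(sprintf("  cor(x1, x2) = %.3f, var(x1) = %.3f, var(x2) = %.3f\n",
              cor(x$x1, x$x2), stats::var(x$x1), stats::var(x$x2)))
  invisible(x)
}

#' Write the per-SNP simulation truth to a TSV file
#'
#' One row per SNP: identifier, SNP set, MAF and the true direct effects on
#' x1 and x2.
#'
#' @param sample An `mr_sample` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sample_truth <- function(sample, path) {
  stopifnot(inherits(sample, "mr_sample"))
  L <- ncol(sample$genotypes)
  truth <- data.frame(
    snp_id = colnames(sample$genotypes),
    set = ifelse(seq_len(L) %in% sample$g1_index, "g1", "g2"),
    maf = sample$maf,
    effect_x1 = replace(numeric(L), sample$g1_index, sample$effects$g1),
    effect_x2 = replace(numeric(L), sample$g2_index, sample$effects$g2)
  )
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
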