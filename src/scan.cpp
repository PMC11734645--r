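#include <Rcpp.h>
using namespace Rcpp;

// Dosage simulation and per-SNP sufficient statistics.
//
// These two kernels are the only compiled code in the package: a Monte
// Carlo replication touches 2 x (100,000 x 250) dosage matrices, and doing
// the generation and the column-wise accumulation in C++ keeps one
// replication around a second.  All statistical logic stays in R.

// Draw biallelic dosages g ~ Binomial(2, maf_j) into a pre-allocated n x L
// matrix, one column per SNP, and accumulate the genetic scores
// score[, c] += g_j * eff[j, c] in the same pass.  Uses R's RNG (one
// uniform per dosage against the cumulative genotype probabilities), so
// set.seed() in R makes the draw reproducible.  Filling a caller-owned
// buffer lets the Monte Carlo driver recycle the two large dosage matrices
// across replications instead of paying a fresh allocation each time.
// [[Rcpp::export]]
void cpp_sim_geno_fill(IntegerMatrix G, NumericVector maf,
                       NumericMatrix eff, NumericMatrix score) {
  int n = G.nrow(), L = G.ncol(), k = eff.ncol();
  if (maf.size() != L) stop("maf must have one entry per SNP");
  if (eff.nrow() != L) stop("effect matrix must have one row per SNP");
  if (score.nrow() != n || score.ncol() != k) stop("bad score dimensions");
  std::fill(score.begin(), score.end(), 0.0);
  for (int j = 0; j < L; ++j) {
    double q = 1.0 - maf[j];
    double p0 = q * q;                    // P(g = 0)
    double p01 = p0 + 2.0 * maf[j] * q;   // P(g <= 1)
    IntegerMatrix::Column col = G(_, j);
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      col[i] = (u > p0) + (u > p01);
    }
    for (int c = 0; c < k; ++c) {
      double e = eff(j, c);
      if (e == 0.0) continue;
      NumericMatrix::Column s = score(_, c);
      for (int i = 0; i < n; ++i) s[i] += e * col[i];
    }
  }
}

// Per-SNP sufficient statistics against a small matrix of traits:
// sum(g), sum(g^2) and cross[j, c] = sum(g_j * M[, c]).  Together with the
// trait-level sums these determine every single-SNP regression (with or
// without one covariate) in closed form.
// [[Rcpp::export]]
List cpp_scan_stats(IntegerMatrix G, NumericMatrix M) {
  int n = G.nrow(), L = G.ncol(), k = M.ncol();
  if (M.nrow() != n) stop("genotype and trait matrices disagree on n");
  NumericVector sg(L), sgg(L);
  NumericMatrix cross(L, k);
  for (int j = 0; j < L; ++j) {
    IntegerMatrix::Column g = G(_, j);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = g[i];
      s += v;
      s2 += v * v;
    }
    sg[j] = s;
    sgg[j] = s2;
    for (int c = 0; c < k; ++c) {
      NumericMatrix::Column m = M(_, c);
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += g[i] * m[i];
      cross(j, c) = acc;
    }
  }
  return List::create(_["sum_g"] = sg, _["sum_gg"] = sgg, _["cross"] = cross);
}
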