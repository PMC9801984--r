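// Pairwise linkage-disequilibrium accumulators.
//
// r2 is the squared Pearson correlation of diploid dosage vectors, i.e.
// the squared Burrows composite correlation with observed-variance
// normalisation, valid for unphased genotypes.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Same-chromosome pairs binned by recombination fraction.
//
// geno: sites x individuals integer dosage matrix (one chromosome).
// pos: site positions in bp.  Physical distance is converted to Morgans
// (morgan_per_bp) and to recombination fraction with Haldane's map
// c = (1 - exp(-2d))/2.  Pairs with c > hc are discarded; bins are
// equal-width in c on (0, hc].
// weights: sites x R matrix of non-negative resampling weights (R may be
// 0).  A pair contributes w_i * w_j to replicate r.
// Returns per-bin sums and counts for the base data and each replicate.
// [[Rcpp::export]]
List cpp_ld_bins(IntegerMatrix geno, NumericVector pos, double morgan_per_bp,
                 double hc, int nbins, NumericMatrix weights) {
  const int S = geno.nrow();      // sites
  const int n = geno.ncol();      // individuals
  const int R = weights.ncol();
  if (R > 0 && weights.nrow() != S) stop("weights must have one row per site");

  // per-site moments
  std::vector<double> mean(S), inv_sd(S);
  std::vector<bool> poly(S);
  for (int s = 0; s < S; ++s) {
    double sum = 0, sum2 = 0;
    for (int i = 0; i < n; ++i) {
      double x = geno(s, i);
      sum += x; sum2 += x * x;
    }
    double m = sum / n, v = sum2 / n - m * m;
    mean[s] = m;
    poly[s] = v > 0;
    inv_sd[s] = poly[s] ? 1.0 / std::sqrt(v) : 0.0;
  }

  NumericVector bin_sum(nbins), bin_cnt(nbins), bin_csum(nbins);
  NumericMatrix rep_sum(nbins, R), rep_cnt(nbins, R);

  // max physical distance with c <= hc (Haldane inverse)
  double dmax_m = -0.5 * std::log(1.0 - 2.0 * hc);
  double dmax_bp = dmax_m / morgan_per_bp;

  for (int a = 0; a < S; ++a) {
    if (!poly[a]) continue;
    for (int b2 = a + 1; b2 < S; ++b2) {
      double d_bp = pos[b2] - pos[a];
      if (d_bp > dmax_bp) break;  // pos sorted ascending
      if (!poly[b2]) continue;
      double c = 0.5 * (1.0 - std::exp(-2.0 * d_bp * morgan_per_bp));
      if (c <= 0 || c > hc) continue;
      int bin = (int)(c / hc * nbins);
      if (bin >= nbins) bin = nbins - 1;
      double sxy = 0;
      for (int i = 0; i < n; ++i) sxy += (double)geno(a, i) * geno(b2, i);
      double cov = sxy / n - mean[a] * mean[b2];
      double r = cov * inv_sd[a] * inv_sd[b2];
      double r2 = r * r;
      bin_sum[bin] += r2; bin_cnt[bin] += 1; bin_csum[bin] += c;
      for (int r_i = 0; r_i < R; ++r_i) {
        double w = weights(a, r_i) * weights(b2, r_i);
        if (w > 0) {
          rep_sum(bin, r_i) += w * r2;
          rep_cnt(bin, r_i) += w;
        }
      }
    }
  }
  return List::create(_["sum"] = bin_sum, _["count"] = bin_cnt,
                      _["csum"] = bin_csum,
                      _["rep_sum"] = rep_sum, _["rep_count"] = rep_cnt);
}

// Unlinked-pair mean r2 with per-site (delete-one-locus jackknife)
// accumulators.  Pairs are formed between sites on different chromosomes
// (or all distinct pairs when same_chrom is allowed, with c assumed 0.5).
// [[Rcpp::export]]
List cpp_unlinked_r2(IntegerMatrix geno, IntegerVector chrom,
                     bool exclude_same_chrom) {
  const int S = geno.nrow();
  const int n = geno.ncol();
  std::vector<double> mean(S), inv_sd(S);
  std::vector<bool> poly(S);
  for (int s = 0; s < S; ++s) {
    double sum = 0, sum2 = 0;
    for (int i = 0; i < n; ++i) {
      double x = geno(s, i);
      sum += x; sum2 += x * x;
    }
    double m = sum / n, v = sum2 / n - m * m;
    mean[s] = m; poly[s] = v > 0;
    inv_sd[s] = poly[s] ? 1.0 / std::sqrt(v) : 0.0;
  }
  double tot = 0; double cnt = 0;
  NumericVector site_sum(S), site_cnt(S);
  for (int a = 0; a < S; ++a) {
    if (!poly[a]) continue;
    for (int b = a + 1; b < S; ++b) {
      if (!poly[b]) continue;
      if (exclude_same_chrom && chrom[a] == chrom[b]) continue;
      double sxy = 0;
      for (int i = 0; i < n; ++i) sxy += (double)geno(a, i) * geno(b, i);
      double cov = sxy / n - mean[a] * mean[b];
      double r = cov * inv_sd[a] * inv_sd[b];
      double r2 = r * r;
      tot += r2; cnt += 1;
      site_sum[a] += r2; site_cnt[a] += 1;
      site_sum[b] += r2; site_cnt[b] += 1;
    }
  }
  return List::create(_["total"] = tot, _["count"] = cnt,
                      _["site_sum"] = site_sum, _["site_count"] = site_cnt);
}
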