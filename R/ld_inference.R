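# Linkage-disequilibrium effective-size estimators.
#
# (a) ld_ne_point: single-sample estimator from mean r2 across unlinked
#     (between-chromosome) SNP pairs, with the published random-mating
#     sample-size bias corrections and a delete-one-locus jackknife CI.
#     Applied per timepoint; temporal comparison uses two such estimates.
# (b) ld_trajectory: recombination-binned mean r2 across same-chromosome
#     pairs (uniform 1 cM/Mb map, Haldane correction, pairs with c <= hc),
#     inverted bin-by-bin via E[r2] ~ 1/(3 + 4Nc) + 1/S and read out at
#     generation t = 1/(2c), with SNP-resampling confidence intervals.

#' Squared Burrows composite correlation of two dosage vectors
#'
#' The composite measure for unphased diploid genotypes: the squared
#' Pearson correlation of the dosage vectors (Burrows' composite
#' disequilibrium normalised by the observed one-locus variances).
#' Symmetric in its arguments and invariant to allele relabelling.
#'
#' @param dosages_a,dosages_b Integer dosage vectors (0/1/2), equal length.
#' @return r-squared in `[0, 1]`.
#' @export
burrows_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b))
  if (stats::var(dosages_a) == 0 || stats::var(dosages_b) == 0) {
    stop("monomorphic locus")
  }
  stats::cor(dosages_a, dosages_b)^2
}

# Expected sample r2 under linkage equilibrium and the Ne inversion, for
# the random-mating/unphased case.  Two regimes by sample size, following
# the published weighted regressions.
ld_sample_correction <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

ld_ne_from_r2prime <- function(r2p, S) {
  if (!is.finite(r2p) || r2p <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2p
    if (disc < 0) disc <- 0
    (1 / 3 + sqrt(disc)) / (2 * r2p)
  } else {
    disc <- 0.308^2 - 2.08 * r2p
    if (disc < 0) disc <- 0
    (0.308 + sqrt(disc)) / (2 * r2p)
  }
}

#' Single-sample LD estimate of Ne from unlinked SNP pairs
#'
#' Computes the mean squared dosage correlation across SNP pairs on
#' different chromosomes (honouring the unlinked assumption; same-
#' chromosome pairs can be allowed via `exclude_same_chromosome = FALSE`,
#' in which case all pairs are treated as unlinked), subtracts the
#' random-mating sample-size expectation, and inverts the drift
#' expectation for Ne.  A corrected mean r2 <= 0 yields an infinite
#' estimate.  The 95% CI comes from a delete-one-locus jackknife on the
#' mean r2, mapped through the same inversion.
#'
#' @param genotypes Sites x individuals dosage matrix.
#' @param chrom Chromosome index per site.
#' @param maf Minor-allele-frequency cutoff (sites below are dropped).
#' @param exclude_same_chromosome Use only between-chromosome pairs.
#' @return A `ne_estimate`: `point`, `ci_low`, `ci_high` (possibly `Inf`),
#'   `S`, `n_pairs`, `n_loci`, `r2_mean`, `r2_prime`, `flags`.
#' @export
ld_ne_point <- function(genotypes, chrom, maf = 0.05,
                        exclude_same_chromosome = TRUE) {
  S <- ncol(genotypes)
  p <- rowSums(genotypes) / (2 * S)
  keep <- pmin(p, 1 - p) >= maf & p > 0 & p < 1
  genotypes <- genotypes[keep, , drop = FALSE]
  chrom <- chrom[keep]
  if (nrow(genotypes) < 2L) {
    return(structure(list(point = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, S = S, n_pairs = 0L,
                          n_loci = nrow(genotypes), r2_mean = NA_real_,
                          r2_prime = NA_real_, flags = "too_few_loci"),
                     class = "ne_estimate"))
  }
  acc <- cpp_unlinked_r2(genotypes, as.integer(chrom),
                         exclude_same_chromosome)
  if (acc$count == 0) {
    return(structure(list(point = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, S = S, n_pairs = 0L,
                          n_loci = nrow(genotypes), r2_mean = NA_real_,
                          r2_prime = NA_real_, flags = "no_pairs"),
                     class = "ne_estimate"))
  }
  r2_mean <- acc$total / acc$count
  corr <- ld_sample_correction(S)
  r2p <- r2_mean - corr
  point <- ld_ne_from_r2prime(r2p, S)
  # delete-one-locus jackknife on the mean r2
  jk <- (acc$total - acc$site_sum) / (acc$count - acc$site_count)
  jk <- jk[acc$site_count > 0 & is.finite(jk)]
  J <- length(jk)
  if (J >= 2) {
    se <- sqrt((J - 1) / J * sum((jk - mean(jk))^2))
    r2_lo <- r2_mean - 1.96 * se
    r2_hi <- r2_mean + 1.96 * se
    ci_low <- ld_ne_from_r2prime(r2_hi - corr, S)
    ci_high <- ld_ne_from_r2prime(r2_lo - corr, S)
  } else {
    ci_low <- ci_high <- NA_real_
  }
  flags <- character(0)
  if (!is.finite(point)) flags <- c(flags, "infinite")
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 S = S, n_pairs = acc$count, n_loci = nrow(genotypes),
                 r2_mean = r2_mean, r2_prime = r2p,
                 flags = if (length(flags)) flags else "ok"),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat("Ne =", format(x$point, digits = 4), "(95% CI",
      format(x$ci_low, digits = 4), "-", format(x$ci_high, digits = 4),
      "), S =", x$S, ",", x$n_pairs, "pairs\n")
  invisible(x)
}

#' Bin same-chromosome SNP pairs by recombination fraction
#'
#' Pairs of polymorphic sites on the same chromosome are mapped to
#' recombination fraction with a uniform genetic map (`map_rate` Morgans
#' per bp, default 1 cM/Mb) and Haldane's function
#' `c = (1 - exp(-2d))/2`; pairs with `c > hc` are discarded and the rest
#' accumulate mean r2 in `n_bins` equal-width bins on (0, hc].  Optionally
#' subsamples each chromosome to at most `max_snps_per_chrom` SNPs
#' (seed-deterministic) and accumulates `resamples` SNP-resampling
#' replicates for confidence intervals (resample size `resample_size`;
#' drawn with replacement when it is not smaller than the number of
#' available SNPs).
#'
#' @param variants A `varianttable`.
#' @param timepoint Sampling time whose genotypes are used (default 0).
#' @param maf Minor-allele-frequency cutoff applied before binning.  The
#'   per-bin Sved inversion assumes moderate allele frequencies; pairs
#'   involving rare alleles depress the mean squared correlation in a
#'   distance-dependent way and bias the inverted sizes upward.
#' @param map_rate Morgans per bp.
#' @param hc Maximum recombination fraction.
#' @param n_bins Number of bins.
#' @param max_snps_per_chrom SNP cap per chromosome.
#' @param resamples Number of SNP-resampling replicates (0 = none).
#' @param resample_size SNPs per replicate.
#' @param seed RNG seed.
#' @return A `binldstats`: data.frame `bins` (c_mid, mean_r2, n_pairs),
#'   resampling matrices, and `S` (diploid sample size).
#' @export
bin_pairs <- function(variants, timepoint = 0, maf = 0.05,
                      map_rate = 1e-8, hc = 0.05,
                      n_bins = 400L, max_snps_per_chrom = 50000L,
                      resamples = 0L, resample_size = 50000L, seed = 1L) {
  geno <- genotypes_at(variants, timepoint)
  S <- ncol(geno)
  set.seed(seed)
  p <- rowSums(geno) / (2 * S)
  keep <- which(pmin(p, 1 - p) >= max(maf, 1e-12) & p > 0 & p < 1)
  # seed-deterministic per-chromosome cap
  keep_by_chrom <- split(keep, variants$chrom[keep])
  keep <- sort(unlist(lapply(keep_by_chrom, function(ix) {
    if (length(ix) > max_snps_per_chrom) {
      sort(resample(ix, max_snps_per_chrom))
    } else ix
  }), use.names = FALSE))
  n_snp <- length(keep)
  if (n_snp < 2L) stop("fewer than two polymorphic SNPs")
  # resampling weights: multiplicity of each SNP in each replicate
  W_all <- if (resamples > 0L) {
    replace <- resample_size >= n_snp
    vapply(seq_len(resamples), function(r) {
      draw <- sample.int(n_snp, min(resample_size, n_snp),
                         replace = replace)
      tabulate(draw, nbins = n_snp)
    }, numeric(n_snp))
  } else matrix(0, nrow = n_snp, ncol = 0L)

  bsum <- numeric(n_bins); bcnt <- numeric(n_bins); bcsum <- numeric(n_bins)
  rsum <- matrix(0, n_bins, resamples); rcnt <- matrix(0, n_bins, resamples)
  for (ch in sort(unique(variants$chrom[keep]))) {
    sel <- keep[variants$chrom[keep] == ch]
    o <- order(variants$pos[sel]); sel <- sel[o]
    res <- cpp_ld_bins(geno[sel, , drop = FALSE], variants$pos[sel],
                       map_rate, hc, as.integer(n_bins),
                       W_all[match(sel, keep), , drop = FALSE])
    bsum <- bsum + res$sum; bcnt <- bcnt + res$count
    bcsum <- bcsum + res$csum
    if (resamples > 0L) {
      rsum <- rsum + res$rep_sum; rcnt <- rcnt + res$rep_count
    }
  }
  bins <- data.frame(
    bin = seq_len(n_bins),
    c_mid = ifelse(bcnt > 0, bcsum / bcnt,
                   (seq_len(n_bins) - 0.5) * hc / n_bins),
    mean_r2 = ifelse(bcnt > 0, bsum / bcnt, NA_real_),
    n_pairs = bcnt)
  structure(list(bins = bins, rep_sum = rsum, rep_cnt = rcnt, S = S,
                 hc = hc, n_bins = n_bins, n_snp = n_snp),
            class = "binldstats")
}

# Invert one set of per-bin mean r2 into a size-by-generation trajectory.
ld_bins_to_traj <- function(c_mid, mean_r2, n_pairs, S, eps = 1e-6,
                            smooth_window = 15L) {
  ok <- n_pairs > 0 & !is.na(mean_r2)
  r2c <- mean_r2 - 1 / S
  ok <- ok & r2c > eps
  if (sum(ok) < 2L) return(NULL)
  c_ok <- c_mid[ok]
  ne <- (1 / r2c[ok] - 3) / (4 * c_ok)
  t_gen <- 1 / (2 * c_ok)
  o <- order(t_gen)
  ne <- ne[o]; t_gen <- t_gen[o]
  if (length(ne) >= smooth_window) {
    ne <- stats::runmed(ne, k = smooth_window, endrule = "median")
  }
  data.frame(t_gen = t_gen, ne = pmax(ne, 1))
}

traj_read_at <- function(traj, t_gen) {
  traj$ne[which.min(abs(traj$t_gen - t_gen))]
}

#' LD trajectory of recent effective size with resampling CIs
#'
#' Converts binned mean r2 into a per-generation size trajectory: each
#' bin's sample-size-corrected r2 (`mean r2 - 1/S`, floored at `eps`) is
#' inverted through `E[r2] = 1/(3 + 4 N c)` and assigned to generation
#' `t = 1/(2c)`; the trajectory is smoothed with a running median.
#' Contemporary size is read at the youngest resolvable generation
#' (`t = 1/(2 hc)`, i.e. 10 generations at hc = 0.05) and historic size at
#' `120 / gen_time` generations.  95% CIs are the 2.5/97.5 percentiles of
#' the same readouts across the SNP-resampling replicates accumulated by
#' [bin_pairs()].
#'
#' @param binstats A `binldstats` from [bin_pairs()].
#' @param gen_time Generation time in years.
#' @param eps Floor for corrected r2; bins below are dropped.
#' @param smooth_window Running-median window (bins).
#' @return A `ne_trajectory`: `trajectory` data.frame, `Ne_C`, `Ne_H`
#'   (each a `ne_estimate`-like list with point and CI), `n_resamples`.
#' @export
ld_trajectory <- function(binstats, gen_time = 1, eps = 1e-6,
                          smooth_window = 15L) {
  stopifnot(inherits(binstats, "binldstats"))
  b <- binstats$bins
  traj <- ld_bins_to_traj(b$c_mid, b$mean_r2, b$n_pairs, binstats$S, eps,
                          smooth_window)
  if (is.null(traj) || nrow(traj) < 10L) {
    return(structure(list(trajectory = traj, Ne_C = NULL, Ne_H = NULL,
                          n_resamples = 0L, flags = "too_few_bins"),
                     class = "ne_trajectory"))
  }
  t_young <- 1 / (2 * binstats$hc)
  t_hist <- 120 / gen_time
  ne_c <- traj_read_at(traj, t_young)
  ne_h <- traj_read_at(traj, t_hist)
  R <- ncol(binstats$rep_sum)
  reps_c <- reps_h <- numeric(0)
  if (R > 0) {
    for (r in seq_len(R)) {
      m <- ifelse(binstats$rep_cnt[, r] > 0,
                  binstats$rep_sum[, r] / binstats$rep_cnt[, r], NA_real_)
      tr <- ld_bins_to_traj(b$c_mid, m, binstats$rep_cnt[, r], binstats$S,
                            eps, smooth_window)
      if (is.null(tr)) next
      reps_c <- c(reps_c, traj_read_at(tr, t_young))
      reps_h <- c(reps_h, traj_read_at(tr, t_hist))
    }
  }
  ci <- function(point, reps) {
    if (length(reps) >= 3) {
      q <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
      list(point = point, ci_low = q[1], ci_high = q[2])
    } else {
      list(point = point, ci_low = point, ci_high = point)
    }
  }
  structure(list(trajectory = traj, Ne_C = ci(ne_c, reps_c),
                 Ne_H = ci(ne_h, reps_h),
                 n_resamples = length(reps_c), flags = "ok"),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  if (identical(x$flags, "ok")) {
    cat("LD trajectory:", nrow(x$trajectory), "bins; Ne_C =",
        format(x$Ne_C$point, digits = 4), "[",
        format(x$Ne_C$ci_low, digits = 4), ",",
        format(x$Ne_C$ci_high, digits = 4), "]; Ne_H =",
        format(x$Ne_H$point, digits = 4), "[",
        format(x$Ne_H$ci_low, digits = 4), ",",
        format(x$Ne_H$ci_high, digits = 4), "]\n")
  } else cat("LD trajectory:", x$flags, "\n")
  invisible(x)
}
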