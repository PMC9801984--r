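# LD-based effective-size estimators.

test_that("burrows_r2 matches longhand composite arithmetic", {
  # 6-individual toy, computed by hand from the covariance definition:
  # r = cov(X, Y) / sqrt(var(X) var(Y)) on dosages
  x <- c(0L, 1L, 2L, 1L, 0L, 2L)
  y <- c(0L, 1L, 1L, 1L, 0L, 2L)
  n <- 6
  cxy <- sum(x * y) / n - mean(x) * mean(y)
  vx <- sum(x^2) / n - mean(x)^2
  vy <- sum(y^2) / n - mean(y)^2
  expect_equal(burrows_r2(x, y), cxy^2 / (vx * vy))
  expect_equal(burrows_r2(x, y), burrows_r2(y, x))       # symmetric
  expect_equal(burrows_r2(x, x), 1)                      # identical
  expect_equal(burrows_r2(2L - x, y), burrows_r2(x, y))  # allele swap
  expect_error(burrows_r2(rep(1L, 6), y), "monomorphic")
})

test_that("r2 of independent loci is 1/S-scale noise (permutation oracle)", {
  set.seed(33)
  S <- 50
  x <- sample(0:2, S, replace = TRUE)
  r2s <- replicate(400, burrows_r2(x, sample(x)))
  expect_equal(mean(r2s), 1 / (S - 1), tolerance = 0.2)
})

test_that("ld_ne_point handles corrected r2 <= 0 and degenerate input", {
  # two independent loci with tiny empirical correlation: corrected
  # r2 below the sampling expectation yields an infinite estimate
  set.seed(4)
  g <- matrix(sample(0:2, 2 * 400, replace = TRUE), nrow = 2)
  est <- ld_ne_point(g, chrom = c(1, 2), maf = 0.05)
  if (est$r2_prime <= 0) expect_equal(est$point, Inf)
  # fewer than two polymorphic loci is flagged
  g1 <- matrix(c(rep(1L, 10), rep(0L, 10)), nrow = 2, byrow = TRUE)
  est1 <- ld_ne_point(g1, chrom = c(1, 2))
  expect_true(est1$flags == "too_few_loci")
  # same-chromosome pairs excluded by default: no pairs -> flagged
  g2 <- rbind(sample(0:2, 40, TRUE), sample(0:2, 40, TRUE))
  est2 <- ld_ne_point(g2, chrom = c(1, 1), maf = 0)
  expect_true(est2$flags == "no_pairs")
  est3 <- ld_ne_point(g2, chrom = c(1, 1), maf = 0,
                      exclude_same_chromosome = FALSE)
  expect_equal(est3$n_pairs, 1)
})

test_that("ld_ne_point is invariant to sample column order", {
  d <- cached("ld_rad_ne200", {
    scen <- g1_scenario(Ne = 200, duration = 100L)
    ped <- simulate_pedigree(scen, seed = 5, checkpoints = c(50L))
    samples <- data.frame(id = ped$checkpoints[["0"]][1:100], time_ybp = 0L)
    loci <- rad_loci(20, 1e6, 100, locus_len = 500, seed = 9)
    v <- simulate_variants(ped, samples, loci, seed = 13,
                           linked_gens = 200)
    genotypes_at(v, 0)
  })
  g <- d
  chrom <- rep(1:20, length.out = nrow(g))  # synthetic chromosome labels
  e1 <- ld_ne_point(g, chrom)
  set.seed(1)
  e2 <- ld_ne_point(g[, sample(ncol(g))], chrom)
  expect_equal(e1$r2_mean, e2$r2_mean)
  expect_equal(e1$point, e2$point)
})

test_that("unlinked mean r2 tracks 1/(3Ne) + 1/S across replicates", {
  # Ne = 200, S = 100: drift plus sampling expectation ~ 1/(3*200) + 1/S.
  # Averaged over replicate simulations; within 15%.
  r2s <- sapply(1:6, function(i) {
    scen <- g1_scenario(Ne = 200, duration = 100L)
    ped <- simulate_pedigree(scen, seed = 600 + i, checkpoints = c(50L))
    samples <- data.frame(id = ped$checkpoints[["0"]][1:100],
                          time_ybp = 0L)
    loci <- rad_loci(20, 1e6, 100, locus_len = 500, seed = 700 + i)
    v <- simulate_variants(ped, samples, loci, seed = 800 + i,
                           linked_gens = 100)
    est <- ld_ne_point(genotypes_at(v, 0), v$chrom, maf = 0.05)
    est$r2_mean
  })
  expected <- 1 / (3 * 200) + 1 / 99
  expect_equal(mean(r2s), expected, tolerance = 0.15)
})

test_that("bin_pairs applies Haldane mapping and the hc cutoff", {
  # Haldane arithmetic: 1 Mb at 1 cM/Mb -> d = 0.01 M, c ~ 0.00990
  d <- 0.01
  expect_equal((1 - exp(-2 * d)) / 2, 0.00990, tolerance = 1e-3)
  v <- cached("tiny_wgs",
              sim_dataset(Ne = 200, n = 20, n_chrom = 2, chrom_len = 2e6,
                          window = 2000, duration = 60L, seed = 99,
                          linked_gens = 200))$variants
  bins <- bin_pairs(v, 0, maf = 0.05, n_bins = 50, resamples = 3, seed = 2)
  b <- bins$bins
  expect_true(all(b$c_mid[b$n_pairs > 0] <= 0.05))
  expect_equal(nrow(b), 50L)
  # deterministic given the seed
  bins2 <- bin_pairs(v, 0, maf = 0.05, n_bins = 50, resamples = 3, seed = 2)
  expect_identical(bins$bins, bins2$bins)
  expect_identical(bins$rep_sum, bins2$rep_sum)
})

test_that("binned means match a plain-R pair loop (oracle)", {
  v <- cached("tiny_wgs",
              sim_dataset(Ne = 200, n = 20, n_chrom = 2, chrom_len = 2e6,
                          window = 2000, duration = 60L, seed = 99,
                          linked_gens = 200))$variants
  bins <- bin_pairs(v, 0, maf = 0.1, n_bins = 20, seed = 3)
  g <- genotypes_at(v, 0)
  p <- rowSums(g) / (2 * ncol(g))
  keep <- which(pmin(p, 1 - p) >= 0.1)
  sums <- numeric(20); cnts <- numeric(20)
  for (a in keep) for (b in keep) {
    if (b <= a || v$chrom[a] != v$chrom[b]) next
    dd <- abs(v$pos[b] - v$pos[a]) * 1e-8
    cc <- (1 - exp(-2 * dd)) / 2
    if (cc <= 0 || cc > 0.05) next
    bin <- min(floor(cc / 0.05 * 20) + 1, 20)
    sums[bin] <- sums[bin] + burrows_r2(g[a, ], g[b, ])
    cnts[bin] <- cnts[bin] + 1
  }
  expect_equal(bins$bins$n_pairs, cnts)
  got <- bins$bins$mean_r2[cnts > 0]
  expect_equal(got, (sums / cnts)[cnts > 0], tolerance = 1e-12)
})

test_that("ld_trajectory degenerates gracefully and collapses CIs", {
  v <- cached("tiny_wgs",
              sim_dataset(Ne = 200, n = 20, n_chrom = 2, chrom_len = 2e6,
                          window = 2000, duration = 60L, seed = 99,
                          linked_gens = 200))$variants
  b1 <- bin_pairs(v, 0, maf = 0.05, resamples = 1, seed = 7)
  tr <- ld_trajectory(b1)
  if (identical(tr$flags, "ok")) {
    # a single resample cannot support percentile CIs: they collapse
    expect_equal(tr$Ne_C$ci_low, tr$Ne_C$point)
    expect_equal(tr$Ne_C$ci_high, tr$Ne_C$point)
  }
  # too few usable bins is flagged, not an error
  fake <- structure(list(
    bins = data.frame(bin = 1:5, c_mid = seq(0.01, 0.05, 0.01),
                      mean_r2 = rep(1e-9, 5), n_pairs = rep(2, 5)),
    rep_sum = matrix(0, 5, 0), rep_cnt = matrix(0, 5, 0),
    S = 50, hc = 0.05, n_bins = 5L, n_snp = 10L),
    class = "binldstats")
  expect_equal(ld_trajectory(fake)$flags, "too_few_bins")
})
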