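# Shared simulation helpers.  Expensive shared objects are memoised in
# `.sim_cache` so multiple test files can reuse them within one run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

g1_scenario <- function(Ne = 1000, lambda = 1, T_dec = NA, duration = 220L,
                        ancestral = NULL) {
  demographic_scenario(life_history("G1"),
                       size_trajectory(Ne, lambda, T_dec, duration),
                       ancestral)
}

# One simulated dataset: pedigree + genotypes for contemporary (or
# scheme-drawn) samples.
sim_dataset <- function(lambda = 1, T_dec = NA, Ne = 1000, n = 100,
                        scheme = "contemporary", type = c("WGS", "RAD"),
                        n_chrom = 4L, chrom_len = 1.5e7,
                        loci_per_chrom = 2000L, window = 5000,
                        duration = 220L, seed = 1L, linked_gens = 2000) {
  type <- match.arg(type)
  scen <- g1_scenario(Ne, lambda, T_dec, duration)
  ped <- simulate_pedigree(scen, seed = derive_seed(seed, "ped"))
  samples <- draw_samples(ped, sampling_scheme(scheme, n),
                          seed = derive_seed(seed, "draw"))
  loci <- if (type == "WGS") {
    wgs_loci(n_chrom, chrom_len, window)
  } else {
    rad_loci(n_chrom, chrom_len, loci_per_chrom,
             seed = derive_seed(seed, "loci"))
  }
  v <- simulate_variants(ped, samples, loci,
                         seed = derive_seed(seed, "var"),
                         linked_gens = linked_gens)
  list(variants = v, scenario = scen, pedigree = ped, samples = samples)
}

lean_opt <- function() optimizer_config(n_starts = 2L, maxit = 50L)

# tighter settings for noise-free MLE recovery checks
strong_opt <- function() optimizer_config(n_starts = 3L, maxit = 200L,
                                          factr = 1e7)

aic_detects_decline <- function(fit) {
  fit$best$model %in% c("M2_recent", "M4_both") &&
    fit$best$Ne_C_hat < fit$best$Ne_H_hat
}

# brute-force folded SFS (independent oracle for folded_sfs)
brute_folded_sfs <- function(geno, L, timepoint = 0) {
  n <- 2L * ncol(geno)
  counts <- numeric(floor(n / 2))
  for (s in seq_len(nrow(geno))) {
    dc <- sum(geno[s, ])
    m <- min(dc, n - dc)
    if (m >= 1) counts[m] <- counts[m] + 1
  }
  folded_sfs_obj(counts, n, L, timepoint)
}
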