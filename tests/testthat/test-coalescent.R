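# Coalescent completion and genotype generation.

# TMRCA of each locus from a recapitated forest (generations; pedigree
# coalescences are converted from years via the generation time).
locus_tmrca <- function(forest) {
  gt <- forest$gen_time
  n_loc <- nrow(forest$loci)
  out <- rep(NA_real_, n_loc)
  ped_t <- tapply(forest$edges$year, forest$edges$locus, max) / gt
  out[as.integer(names(ped_t)) + 1L] <- ped_t
  if (length(forest$recap$locus)) {
    rec_t <- tapply(forest$recap$time_gen, forest$recap$locus, max)
    out[as.integer(names(rec_t)) + 1L] <- rec_t
  }
  out
}

test_that("pairwise TMRCA matches the coalescent expectation (MC oracle)", {
  # 2 haplotypes (one diploid), constant Ne = 100, short pedigree epoch:
  # E[TMRCA] = 2 Ne generations.  Loci on separate chromosomes are
  # nearly independent replicates.
  scen <- g1_scenario(Ne = 100, duration = 20L)
  ped <- simulate_pedigree(scen, seed = 31, checkpoints = c(10L))
  samples <- data.frame(id = ped$checkpoints[["0"]][1], time_ybp = 0L)
  tm <- unlist(lapply(1:25, function(ch) {
    spec <- chromosome_spec(ch, 1e6, 1e-8)
    loci <- data.frame(chrom = ch, start = seq(0, 9.5e5, by = 2e4),
                       length = 100)
    f <- trace_pedigree_ancestry(ped, samples, loci, spec,
                                 seed = 400 + ch)
    f <- recapitate(f, scen, seed = 500 + ch, linked_gens = 0)
    locus_tmrca(f)
  }))
  expect_gte(length(tm), 1000)
  se <- sd(tm) / sqrt(length(tm) / 3)  # discount for residual correlation
  expect_lt(abs(mean(tm) - 200), 3 * se + 10)
})

test_that("recapitation honours an ancestral size change (stochastic order)", {
  # 10x ancestral expansion (small ancestral size) at 500 generations
  # shortens deep coalescence times relative to the constant-size case
  scen <- g1_scenario(Ne = 1000, duration = 10L)
  small_anc <- structure(list(kind = "expansion", factor = 10,
                              time_gen = 500L, Ne_A = 100),
                         class = "ancestralchange")
  scen_exp <- scen; scen_exp$ancestral <- small_anc
  ped <- simulate_pedigree(scen, seed = 8, checkpoints = c(5L))
  samples <- data.frame(id = ped$checkpoints[["0"]][1:2], time_ybp = 0L)
  spec <- chromosome_spec(1, 1e6, 1e-8)
  loci <- data.frame(chrom = 1, start = seq(0, 9.9e5, by = 5e3),
                     length = 100)
  f0 <- trace_pedigree_ancestry(ped, samples, loci, spec, seed = 1)
  t_const <- locus_tmrca(recapitate(f0, scen, seed = 2, linked_gens = 0))
  t_exp <- locus_tmrca(recapitate(f0, scen_exp, seed = 2, linked_gens = 0))
  expect_lt(mean(t_exp), mean(t_const))
  # deep times under the expansion are compressed toward 500 + small tail
  expect_lt(mean(t_exp[t_exp > 500]), mean(t_const[t_const > 500]))
})

test_that("mutation count scales linearly in mu and mu = 0 gives no sites", {
  scen <- g1_scenario(Ne = 200, duration = 40L)
  ped <- simulate_pedigree(scen, seed = 13, checkpoints = c(20L))
  samples <- data.frame(id = ped$checkpoints[["0"]][1:10], time_ybp = 0L)
  spec <- chromosome_spec(1, 2e6, 1e-8)
  loci <- data.frame(chrom = 1, start = seq(0, 1.99e6, by = 4e3),
                     length = 2000)
  attr(loci, "L") <- sum(loci$length)
  f <- trace_pedigree_ancestry(ped, samples, loci, spec, seed = 3)
  f <- recapitate(f, scen, seed = 4, linked_gens = 0)
  v0 <- drop_mutations(f, 0, seed = 5)
  expect_equal(length(v0$pos), 0L)
  s1 <- length(drop_mutations(f, 1e-8, seed = 5)$pos)
  s2 <- length(drop_mutations(f, 2e-8, seed = 6)$pos)
  # doubling mu doubles the expected count (same forest): Poisson z-test
  expect_lt(abs(s2 - 2 * s1) / sqrt(s2 + 4 * s1), 4)
})

test_that("positions are unique, increasing within chromosomes, inside loci", {
  d <- cached("tiny_wgs",
              sim_dataset(Ne = 200, n = 20, n_chrom = 2, chrom_len = 2e6,
                          window = 2000, duration = 60L, seed = 99,
                          linked_gens = 200))
  v <- d$variants
  for (ch in unique(v$chrom)) {
    p <- v$pos[v$chrom == ch]
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p < 2e6))
  }
  # dosages are 0/1/2 and every site segregates
  expect_true(all(v$geno %in% 0:2))
  dc <- rowSums(v$geno)
  expect_true(all(dc > 0 & dc < 2 * nrow(v$samples)))
})

test_that("genotypes_at validates samples and keeps column order stable", {
  d <- cached("tiny_wgs",
              sim_dataset(Ne = 200, n = 20, n_chrom = 2, chrom_len = 2e6,
                          window = 2000, duration = 60L, seed = 99,
                          linked_gens = 200))
  v <- d$variants
  g <- genotypes_at(v, 0)
  expect_equal(dim(g), c(length(v$pos), 20L))
  expect_identical(colnames(g), v$samples$name)
  expect_error(genotypes_at(v, 0, sample_ids = -5), "unknown sample id")
  expect_equal(ncol(genotypes_at(v, 30)), 0L)  # no samples at 30 ybp
  sub <- genotypes_at(v, 0, sample_ids = v$samples$id[3:5])
  expect_equal(ncol(sub), 3L)
  expect_identical(sub, g[, 3:5, drop = FALSE])
})

test_that("each locus forms one connected, fully coalesced genealogy", {
  scen <- g1_scenario(Ne = 100, duration = 30L)
  ped <- simulate_pedigree(scen, seed = 21, checkpoints = c(15L))
  samples <- data.frame(id = ped$checkpoints[["0"]][1:6], time_ybp = 0L)
  spec <- chromosome_spec(1, 1e6, 1e-8)
  loci <- data.frame(chrom = 1, start = seq(0, 9e5, by = 1e5), length = 1e3)
  f <- recapitate(trace_pedigree_ancestry(ped, samples, loci, spec, 3),
                  scen, seed = 4, linked_gens = 100)
  for (l in seq_len(nrow(loci)) - 1L) {
    child <- c(f$edges$child[f$edges$locus == l & f$edges$parent >= 0],
               f$recap$child[f$recap$locus == l])
    parent <- c(f$edges$parent[f$edges$locus == l & f$edges$parent >= 0],
                f$recap$parent[f$recap$locus == l])
    nodes <- unique(c(child, parent))
    # binary tree over all 12 leaves: one root, n_leaves - 1 internals
    expect_equal(length(setdiff(parent, child)), 1L)
    expect_equal(sum(!nodes %in% child), 1L)
    expect_true(all(0:11 %in% child))
    expect_equal(length(nodes), 2L * 12L - 1L)
  }
})

test_that("full and linked-extension recapitation agree marginally", {
  # the linked Wright-Fisher extension must not change single-locus
  # summaries: compare Watterson's estimator across the two settings
  scen <- g1_scenario(Ne = 200, duration = 40L)
  ped <- simulate_pedigree(scen, seed = 55, checkpoints = c(20L))
  samples <- data.frame(id = ped$checkpoints[["0"]][1:15], time_ybp = 0L)
  loci <- wgs_loci(n_chrom = 2, chrom_len = 2e6, window = 2000)
  s_lk <- length(simulate_variants(ped, samples, loci, seed = 1,
                                   linked_gens = 2000)$pos)
  s_no <- length(simulate_variants(ped, samples, loci, seed = 2,
                                   linked_gens = 0)$pos)
  # same expectation; allow generous Poisson-scale slack
  expect_lt(abs(s_lk - s_no) / sqrt(s_lk + s_no), 5)
})
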