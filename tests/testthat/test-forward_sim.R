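# Forward-time pedigree simulation and segment-mosaic transmission.

test_that("stable G1 pedigree has exact yearly cohorts and checkpoints", {
  scen <- g1_scenario(Ne = 100, duration = 60L)
  ped <- simulate_pedigree(scen, seed = 11, checkpoint_n = 30L,
                           checkpoints = c(30L, 20L))
  cohort_sizes <- table(ped$birth[ped$mother != 0L])
  expect_true(all(cohort_sizes == 100L))
  expect_equal(lengths(ped$checkpoints[c("30", "20")]),
               c("30" = 30L, "20" = 30L))
  expect_equal(length(ped$checkpoints[["0"]]), 100L)  # all at 0 ybp
  # fixed seed reproduces the pedigree bit-exactly
  ped2 <- simulate_pedigree(scen, seed = 11, checkpoint_n = 30L,
                            checkpoints = c(30L, 20L))
  expect_identical(ped[c("id", "sex", "birth", "mother", "father",
                         "checkpoints")],
                   ped2[c("id", "sex", "birth", "mother", "father",
                          "checkpoints")])
})

test_that("declining G1 pedigree follows the trajectory and records breeders", {
  scen <- g1_scenario(Ne = 200, lambda = 0.95, T_dec = 20, duration = 40L)
  ped <- simulate_pedigree(scen, seed = 3, checkpoints = c(30L))
  for (y in c(0, 10, 20, 30)) {
    expect_equal(sum(ped$birth == y & ped$mother != 0L),
                 trajectory_size(scen$trajectory, y))
  }
  br <- ped$breeders
  expect_true(all(br$females + br$males > 0))
  rd <- realized_demography(ped)
  expect_equal(rd$mean_parental_age, 1)  # annual semelparity
})

test_that("extinction of one sex aborts with a diagnostic", {
  scen <- demographic_scenario(life_history("G1"),
                               size_trajectory(2, 1, NA, 50L))
  # with N = 2 per cohort a single-sex cohort occurs almost surely
  expect_error(simulate_pedigree(scen, seed = 1), "extinction")
})

test_that("G1 reproductive success matches the ideal-population moments", {
  # mean 2 within 1% and variance within 10% over >= 100 replicate years
  scen <- g1_scenario(Ne = 1000, duration = 120L)
  ped <- simulate_pedigree(scen, seed = 2024, checkpoints = c(30L))
  rd <- realized_demography(ped, years_ybp = 0:99)
  expect_equal(rd$offspring_mean, 2, tolerance = 0.01)
  expect_equal(rd$offspring_variance, 2, tolerance = 0.1)
})

test_that("stable G2 pedigree meets its calibration targets", {
  scen <- demographic_scenario(life_history("G2"),
                               size_trajectory(1000, 1, NA, 220L))
  ped <- cached("g2_ped_1000", simulate_pedigree(scen, seed = 77))
  rd <- realized_demography(ped, years_ybp = 0:99)
  expect_equal(rd$mean_parental_age, 3, tolerance = 0.05)
  # E[N_B] = N_O within 5% (long-run average)
  nb <- ped$breeders$females + ped$breeders$males
  expect_equal(mean(nb[ped$breeders$ybp <= 100]), 1000, tolerance = 0.05)
  expect_equal(rd$sex_ratio, 0.5, tolerance = 0.03)
})

test_that("pedigree export writes the documented table", {
  scen <- g1_scenario(Ne = 50, duration = 10L)
  ped <- simulate_pedigree(scen, seed = 2, checkpoints = c(5L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(ped, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("id", "sex", "birth_year", "mother", "father"))
  expect_equal(nrow(tab), length(ped$id))
  expect_setequal(unique(tab$sex), c("F", "M"))
  expect_true(all(tab$mother[tab$birth_year == 10] == 0))
})

test_that("transmit_gamete respects its contract", {
  spec <- chromosome_spec(1, 3e7, 1e-8)
  h1 <- founder_mosaic(1L, 3e7); h2 <- founder_mosaic(2L, 3e7)
  # r = 0: whole parental haplotype, fair-coin choice
  spec0 <- chromosome_spec(1, 3e7, 0)
  set.seed(5)
  picks <- replicate(200, transmit_gamete(h1, h2, spec0)[1, "founder"])
  expect_setequal(unique(picks), c(1, 2))
  expect_gt(mean(picks == 1), 0.35); expect_lt(mean(picks == 1), 0.65)
  # crossover count is Poisson(rL): mean ~0.3 for r=1e-8, L=3e7
  set.seed(6)
  segs <- replicate(600, nrow(transmit_gamete(h1, h2, spec)))
  expect_equal(mean(segs - 1), 0.3, tolerance = 0.25)
  # gametes tile [0, L) and are in canonical (merged) form
  set.seed(7)
  for (i in 1:50) {
    g <- transmit_gamete(h1, h2, spec)
    expect_equal(g[1, "start"], 0, ignore_attr = TRUE)
    expect_equal(g[nrow(g), "end"], 3e7, ignore_attr = TRUE)
    if (nrow(g) > 1) {
      expect_equal(g[-1, "start"], g[-nrow(g), "end"], ignore_attr = TRUE)
      expect_true(all(g[-1, "founder"] != g[-nrow(g), "founder"]))
    }
  }
})

test_that("simulate_chromosome reuses the pedigree with independent meioses", {
  scen <- g1_scenario(Ne = 30, duration = 12L)
  ped <- simulate_pedigree(scen, seed = 9, checkpoints = c(6L))
  spec <- chromosome_spec(1, 3e7, 5e-8)
  c1 <- simulate_chromosome(ped, spec, seed = 101)
  c2 <- simulate_chromosome(ped, spec, seed = 202)
  # same samples, different breakpoints
  expect_identical(names(c1$mosaics), names(c2$mosaics))
  expect_false(identical(c1$mosaics, c2$mosaics))
  # every haplotype tiles [0, L)
  for (m in c1$mosaics) for (h in m) {
    expect_equal(sum(h[, "end"] - h[, "start"]), 3e7)
  }
  expect_true(all(c1$founders_used <= c1$n_founder_haps))
})

test_that("founder-segment counts grow with pedigree depth (toy oracle)", {
  # 3-generation chain: depth-d descendants of founders accumulate about
  # 1 + d*r*L expected crossover-induced segments; compare the simulated
  # mean against a direct Monte-Carlo of repeated transmit_gamete calls.
  spec <- chromosome_spec(1, 3e7, 2e-8)  # rL = 0.6 per meiosis
  set.seed(42)
  depth_mean <- function(d, reps = 300) {
    mean(replicate(reps, {
      h <- founder_mosaic(1L, 3e7); h2 <- founder_mosaic(2L, 3e7)
      for (i in seq_len(d)) {
        g <- transmit_gamete(h, h2, spec)
        h <- g
        h2 <- founder_mosaic(100L + i, 3e7)
      }
      nrow(h)
    }))
  }
  m1 <- depth_mean(1); m3 <- depth_mean(3)
  expect_gt(m3, m1)
  # depth 1: k ~ Poisson(rL) breakpoints alternate between two distinct
  # founder haplotypes, so the gamete has exactly k + 1 segments
  expect_equal(m1, 1 + 0.6, tolerance = 0.15)
})
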