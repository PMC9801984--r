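# Folded SFS computation, singleton injection, and the expected-SFS engine.

test_that("folded_sfs bins minor-allele counts correctly", {
  # all-zero dosages: no segregating bins
  z <- matrix(0L, nrow = 5, ncol = 4)
  expect_equal(folded_sfs(z, L = 1e4)$counts, rep(0, 4))
  # 2 diploids (n = 4), one site with dosages (1, 0): bin 1
  m <- matrix(c(1L, 0L), nrow = 1)
  expect_equal(folded_sfs(m, L = 100)$counts, c(1, 0))
  # brute-force oracle on random toy matrices
  set.seed(14)
  for (rep in 1:5) {
    g <- matrix(sample(0:2, 5 * 6, replace = TRUE), nrow = 5)
    expect_equal(folded_sfs(g, L = 1e3)$counts,
                 brute_folded_sfs(g, 1e3)$counts)
  }
  expect_error(folded_sfs(matrix(NA_integer_, 1, 2), 10), "missing")
})

test_that("inject_singletons adds exactly the requested mass", {
  s <- folded_sfs_obj(c(100, 50, 25), n = 6, L = 1.5e6)
  expect_equal(inject_singletons(s, 0)$counts, s$counts)
  s2 <- inject_singletons(s, 1e-3)
  expect_equal(s2$counts[1], 100 + 1500)       # round(1e-3 * 1.5e6)
  expect_equal(s2$counts[-1], s$counts[-1])
  expect_equal(sum(s2$counts) - sum(s$counts), 1500)  # conservation
  set.seed(1)
  s3 <- inject_singletons(s, 1e-3, mode = "stochastic")
  expect_gt(s3$counts[1], 100)  # Poisson draw around 1500
  expect_lt(abs(s3$counts[1] - 100 - 1500), 4 * sqrt(1500))
})

test_that("dataset-level injection targets the requested timepoints", {
  sl <- list(folded_sfs_obj(c(10, 5), 4, 1e5, timepoint = 0),
             folded_sfs_obj(c(20, 8), 4, 1e5, timepoint = 120))
  hist <- inject_dataset_singletons(sl, 1e-3)
  expect_equal(hist[[1]]$counts, c(10, 5))          # contemporary untouched
  expect_equal(hist[[2]]$counts[1], 20 + 100)
  cont <- inject_dataset_singletons(sl, 1e-3, timepoints = 0)
  expect_equal(cont[[1]]$counts[1], 110)
  expect_equal(cont[[2]]$counts, c(20, 8))
  all_tp <- inject_dataset_singletons(sl, 1e-3, timepoints = "all")
  expect_equal(sapply(all_tp, function(s) s$counts[1]), c(110, 120))
})

test_that("expected folded SFS matches the constant-size closed form", {
  N <- 1000; mu <- 1e-8; L <- 7.5e6
  for (n in c(2, 10, 41, 400)) {
    m <- demography_model("M1_constant", list(N_constant = N))
    ex <- expected_folded_sfs(m, n, L, mu)
    i <- seq_len(floor(n / 2))
    theory <- 4 * N * mu * L * (1 / i + ifelse(n - i != i, 1 / (n - i), 0))
    expect_equal(ex$counts, theory, tolerance = 1e-10)
  }
  # n = 2: single bin equal to 4 N mu L
  m <- demography_model("M1_constant", list(N_constant = N))
  expect_equal(expected_folded_sfs(m, 2, L, mu)$counts, 4 * N * mu * L,
               tolerance = 1e-10)
})

test_that("weight recursion agrees with the independent ODE integrator", {
  # dual-route check on a non-trivial (10x step change) history
  n <- 40
  tb <- c(0, 500); Ns <- c(1000, 10000)
  sk <- declinesim:::cpp_esfs_sk(n, tb, Ns)
  pnk <- function(n, k, i) exp(lchoose(n - i - 1, k - 2) -
                                 lchoose(n - 1, k - 1))
  xi_ode <- sapply(1:(n - 1), function(i) {
    sum(sapply(2:n, function(k) k * pnk(n, k, i) * sk[k - 1]))
  })
  W <- declinesim:::pk_weights(n)
  Fj <- declinesim:::esfs_Fj(n, tb, Ns)
  expect_equal(as.vector(W %*% Fj), xi_ode, tolerance = 1e-4)
})

test_that("folding symmetry and mu-L homogeneity hold", {
  m <- demography_model("M2_recent",
                        list(N_contemp = 300, N_historic = 2000, T_rc = 60))
  n <- 30; L <- 1e6; mu <- 1e-8
  ep <- declinesim:::model_epochs(m, 0, 1, 256)
  xi <- declinesim:::expected_unfolded_sfs_counts(n, L, mu, ep)
  folded <- expected_folded_sfs(m, n, L, mu, grid_points = 256)$counts
  i <- seq_len(n / 2)
  expect_equal(folded, xi[i] + ifelse(n - i != i, xi[n - i], 0),
               tolerance = 1e-8)
  # homogeneous of degree 1 in mu * L
  f2 <- expected_folded_sfs(m, n, 2 * L, mu, grid_points = 256)$counts
  f3 <- expected_folded_sfs(m, n, L, 2 * mu, grid_points = 256)$counts
  expect_equal(f2, 2 * folded, tolerance = 1e-10)
  expect_equal(f3, 2 * folded, tolerance = 1e-10)
})

test_that("a recent decline depresses the rare-allele share", {
  n <- 100; L <- 1e7; mu <- 1e-8
  dec <- demography_model("M2_recent",
                          list(N_contemp = 300, N_historic = 1000,
                               T_rc = 30))
  con <- demography_model("M1_constant", list(N_constant = 300))
  f_dec <- expected_folded_sfs(dec, n, L, mu)$counts
  f_con <- expected_folded_sfs(con, n, L, mu)$counts
  expect_lt(f_dec[1] / sum(f_dec), f_con[1] / sum(f_con))
})

test_that("expected SFS matches Monte-Carlo simulated spectra (3 SE)", {
  # simulator-vs-engine cross-validation at n = 20, constant Ne = 200
  d <- cached("tiny_wgs",
              sim_dataset(Ne = 200, n = 20, n_chrom = 2, chrom_len = 2e6,
                          window = 2000, duration = 60L, seed = 99,
                          linked_gens = 200))
  reps <- lapply(1:8, function(i) {
    v <- sim_dataset(Ne = 200, n = 20, n_chrom = 2, chrom_len = 2e6,
                     window = 2000, duration = 60L, seed = 1000 + i,
                     linked_gens = 0)$variants
    dataset_sfs(v)[[1]]$counts
  })
  obs <- Reduce(`+`, reps) / length(reps)
  m <- demography_model("M1_constant", list(N_constant = 200))
  ex <- expected_folded_sfs(m, 40, 4e6, 1e-8)$counts
  # aggregate into coarse classes to stabilise the comparison
  cls <- list(1, 2:3, 4:8, 9:20)
  for (cl in cls) {
    o <- sum(obs[cl]); e <- sum(ex[cl])
    se <- sqrt(e / length(reps))
    expect_lt(abs(o - e), 3 * se + 0.02 * e)
  }
})

test_that("folded-SFS text round-trips", {
  s1 <- folded_sfs_obj(c(10, 5, 2), 6, 1e5, timepoint = 0)
  s2 <- folded_sfs_obj(c(7, 3, 1, 0, 0), 10, 2e5, timepoint = 120)
  path <- withr::local_tempfile(fileext = ".sfs")
  write_sfs(list(s1, s2), path)
  back <- read_sfs(path)
  expect_equal(back[[1]]$counts, s1$counts)
  expect_equal(back[[2]]$counts, s2$counts)
  expect_equal(back[[2]]$timepoint, 120)
  expect_equal(back[[2]]$n, 10L)
  expect_equal(back[[2]]$L, 2e5)
  expect_equal(sum(back[[1]]$counts), 17)  # sums preserved
})
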