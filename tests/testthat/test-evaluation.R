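# Decline-detection criteria, power, MAPE, and aggregation.

rec <- function(...) inference_record(...)

test_that("decline_detected implements both pathways", {
  # AIC pathway
  expect_true(decline_detected(rec("s", "sfs", "aic", "contemporary", 200,
                                   "RAD2000", 300, 1000, 300, 1000,
                                   best_model = "M2_recent")))
  expect_false(decline_detected(rec("s", "sfs", "aic", "contemporary", 200,
                                    "RAD2000", 300, 1000, 1200, 1000,
                                    best_model = "M2_recent")))
  expect_false(decline_detected(rec("s", "sfs", "aic", "contemporary", 200,
                                    "RAD2000", 300, 1000, 500, 500,
                                    best_model = "M1_constant")))
  # CI pathway: disjoint CIs detect
  r_ci <- rec("s", "ld_traj", "ci", "contemporary", 100, "WGS",
              300, 1000, 300, 1000, Ne_C_lo = 100, Ne_C_hi = 400,
              Ne_H_lo = 500, Ne_H_hi = 1500)
  expect_true(decline_detected(r_ci))
  # overlapping CIs do not
  r_ov <- rec("s", "ld_traj", "ci", "contemporary", 100, "WGS",
              300, 1000, 600, 900, Ne_C_lo = 400, Ne_C_hi = 800,
              Ne_H_lo = 700, Ne_H_hi = 1200)
  expect_false(decline_detected(r_ov))
  expect_true(stable_correct(r_ov))
  # boundary tie counts as NOT detected (strict inequality)
  r_tie <- rec("s", "ld_traj", "ci", "contemporary", 100, "WGS",
               300, 1000, 300, 1000, Ne_C_lo = 100, Ne_C_hi = 500,
               Ne_H_lo = 500, Ne_H_hi = 1500)
  expect_false(decline_detected(r_tie))
  # infinite estimates never detect
  r_inf <- rec("s", "ld_point", "ci", "two_sample", 50, "RAD400",
               300, 1000, Inf, 1000, Ne_C_lo = 100, Ne_C_hi = Inf,
               Ne_H_lo = 500, Ne_H_hi = 1500)
  expect_false(decline_detected(r_inf))
  # missing CIs on the CI pathway are an error
  r_na <- rec("s", "ld_traj", "ci", "contemporary", 100, "WGS",
              300, 1000, 300, 1000)
  expect_error(decline_detected(r_na), "CI")
})

test_that("power_of counts correct calls for each truth", {
  base <- do.call(rbind, lapply(1:5, function(i) {
    rec("dec", "sfs", "aic", "contemporary", 200, "RAD2000", 300, 1000,
        300, 1000,
        best_model = if (i <= 4) "M2_recent" else "M1_constant")
  }))
  expect_equal(power_of(base), 0.8)
  const <- do.call(rbind, lapply(1:3, function(i) {
    rec("con", "sfs", "aic", "contemporary", 200, "RAD2000", 1000, 1000,
        900, 1000, best_model = "M1_constant", declining_truth = FALSE)
  }))
  expect_equal(power_of(const), 1.0)
  mixed <- rbind(base[1, ], const[1, ])
  expect_error(power_of(mixed), "mix")
  expect_error(power_of(base[0, ]), "empty")
})

test_that("mape and log10_ratio follow their definitions", {
  r1 <- rec("s", "m", "aic", "c", 100, "WGS", 100, 100, 150, 100,
            best_model = "M2_recent")
  expect_equal(mape(r1, "Ne_C"), 50)
  expect_equal(mape(r1, "Ne_H"), 0)
  r2 <- rec("s", "m", "aic", "c", 100, "WGS", 100, 100, 110, 100,
            best_model = "M2_recent")
  two <- rbind(r1, r2)
  expect_equal(mape(two, "Ne_C"), 30)          # mean of 50% and 10%
  expect_equal(mape(two[2:1, ], "Ne_C"), 30)   # permutation-invariant
  expect_gte(mape(two, "Ne_C"), 0)
  expect_equal(log10_ratio(r1, "Ne_C"), log10(1.5))
  expect_equal(log10_ratio(r1, "Ne_H"), 0)
  r10 <- rec("s", "m", "aic", "c", 100, "WGS", 100, 100, 1000, 100,
             best_model = "M2_recent")
  expect_equal(log10_ratio(r10, "Ne_C"), 1)
  # antisymmetry under swapping inferred and simulated
  r_swap <- rec("s", "m", "aic", "c", 100, "WGS", 1000, 100, 100, 100,
                best_model = "M2_recent")
  expect_equal(log10_ratio(r_swap, "Ne_C"), -log10_ratio(r10, "Ne_C"))
  r_inf <- rec("s", "m", "ci", "c", 100, "WGS", 100, 100, Inf, 100,
               Ne_C_lo = 1, Ne_C_hi = Inf, Ne_H_lo = 1, Ne_H_hi = 200)
  expect_true(is.na(log10_ratio(r_inf, "Ne_C")))
  expect_equal(attr(log10_ratio(r_inf, "Ne_C"), "flag"),
               "infinite_estimate")
})

test_that("aggregate_report applies the published subset and exclusions", {
  scenarios <- enumerate_scenarios(study_grid_config())
  agg <- scenarios$scenario_id[
    scenarios$ancestral == "none" &
      (scenarios$lambda == 1 |
         (scenarios$lambda == 0.95 & scenarios$T_dec == 30) |
         (scenarios$lambda == 0.99 & scenarios$T_dec == 120))]
  expect_equal(length(agg), 6L)  # 3 trajectories x 2 initial sizes
  records <- do.call(rbind, lapply(scenarios$scenario_id, function(sid) {
    rbind(rec(sid, "sfs", "aic", "contemporary", 200, "RAD2000",
              300, 1000, 400, 1100, best_model = "M2_recent"),
          rec(sid, "ld_point", "ci", "two_sample", 50, "RAD2000",
              300, 1000, Inf, 900, Ne_C_lo = 1, Ne_C_hi = Inf,
              Ne_H_lo = 500, Ne_H_hi = 1200))
  }))
  rep1 <- aggregate_report(records, scenarios)
  # ld_point at n = 50 excluded from MAPE entirely
  expect_false("ld_point" %in% rep1$mape$method)
  expect_true(all(rep1$power$power >= 0 & rep1$power$power <= 1))
  # infinite estimates are counted
  inf_ld <- rep1$infinite_counts[rep1$infinite_counts$method == "ld_point", ]
  expect_true(all(inf_ld$n_infinite == inf_ld$n))
  # regeneration is byte-identical
  rep2 <- aggregate_report(records, scenarios)
  expect_identical(rep1, rep2)
})
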