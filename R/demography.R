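#' Life-history schedules for the forward simulator
#'
#' Two life histories are supported.  `G1` is an annual, semelparous
#' organism: every individual breeds at age one and dies immediately
#' afterwards, so the generation time is exactly one year.  `G2` has
#' overlapping generations: age at first breeding is one year, maximum age
#' is eight years, and an age-specific survival schedule is calibrated so
#' that in a stable population (i) the expected number of breeding-age
#' individuals equals the yearly offspring number and (ii) the mean age of
#' a breeding individual -- and hence the mean generation time -- is about
#' three years.
#'
#' The `G2` schedule is not hard-coded: it is solved at construction time
#' from the two calibration constraints.  Survival is modelled with a
#' first-year (juvenile) survival probability `s1` and a constant adult
#' annual survival `sa` for ages 1..7; survival beyond the maximum age is
#' zero.  In a stable age structure the breeding-age classes a = 1..8 have
#' relative abundance `s1 * sa^(a-1)`, so the constraints are
#' `s1 * sum(sa^(a-1)) = 1` and `sum(a * sa^(a-1)) / sum(sa^(a-1)) = 3`.
#'
#' @param id `"G1"` or `"G2"`.
#' @param target_generation_time Mean breeder age the `G2` schedule is
#'   calibrated to, in years.  Ignored for `G1`.
#' @return An object of class `lifehistory` with fields `id`,
#'   `age_first_breeding`, `max_age`, `survival` (per-age survival
#'   probabilities, index a = survival from age a-1 to age a),
#'   `expected_generation_time`.
#' @examples
#' lh <- life_history("G2")
#' lh$expected_generation_time  # ~3
#' @export
life_history <- function(id = c("G1", "G2"), target_generation_time = 3) {
  id <- match.arg(id)
  if (id == "G1") {
    obj <- list(
      id = "G1", age_first_breeding = 1L, max_age = 1L,
      survival = c(1, 0),  # survive birth year to breed at age 1, then die
      expected_generation_time = 1
    )
  } else {
    max_age <- 8L
    ages <- seq_len(max_age)
    mean_age <- function(sa) {
      w <- sa^(ages - 1)
      sum(ages * w) / sum(w)
    }
    sa <- stats::uniroot(function(s) mean_age(s) - target_generation_time,
                         c(1e-6, 1 - 1e-9), tol = 1e-12)$root
    s1 <- 1 / sum(sa^(ages - 1))
    stopifnot(s1 > 0, s1 <= 1)
    obj <- list(
      id = "G2", age_first_breeding = 1L, max_age = max_age,
      survival = c(s1, rep(sa, max_age - 1L), 0),
      expected_generation_time = mean_age(sa)
    )
  }
  structure(obj, class = "lifehistory")
}

#' Recent population-size trajectory
#'
#' The number of offspring produced each year (`N_O`, which doubles as the
#' effective size under the simulator's random-mating rule) is constant at
#' `Ne_H` until the decline onset `T_dec` years before present and then
#' declines exponentially at per-year rate `lambda`, reaching
#' `Ne_H * lambda^T_dec` at the present.
#'
#' @param Ne_H Initial (historic) size, a positive integer.
#' @param lambda Per-year size multiplier in (0, 1]; 1 means stable.
#' @param T_dec Years before present at which the decline starts, or `NA`
#'   for a stable trajectory.
#' @param duration Total forward-simulated span in years (default 220).
#' @return Object of class `sizetrajectory`.
#' @export
size_trajectory <- function(Ne_H, lambda = 1, T_dec = NA, duration = 220L) {
  stopifnot(Ne_H >= 2, duration >= 1)
  if (!(lambda > 0 && lambda <= 1)) stop("lambda must be in (0, 1]")
  if (!is.na(T_dec)) stopifnot(T_dec >= 0, T_dec <= duration)
  if (lambda == 1) T_dec <- NA
  structure(list(Ne_H = as.integer(Ne_H), lambda = lambda,
                 T_dec = if (is.na(T_dec)) NA_integer_ else as.integer(T_dec),
                 duration = as.integer(duration)),
            class = "sizetrajectory")
}

#' Population size at a given time
#'
#' Deterministic size of a [size_trajectory()] at `t` years before present:
#' `Ne_H` for `t >= T_dec`, `round(Ne_H * lambda^(T_dec - t))` afterwards,
#' floored at 2 so the forward simulator always has at least one potential
#' breeder of each sex.
#'
#' @param trajectory A `sizetrajectory`.
#' @param t Years before present (vectorised); must lie in `[0, duration]`.
#' @return Integer vector of population sizes.
#' @export
trajectory_size <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "sizetrajectory"))
  if (any(t < 0 | t > trajectory$duration)) {
    stop("t outside [0, duration]")
  }
  if (is.na(trajectory$T_dec) || trajectory$lambda == 1) {
    return(rep(trajectory$Ne_H, length(t)))
  }
  size <- ifelse(t >= trajectory$T_dec,
                 trajectory$Ne_H,
                 round(trajectory$Ne_H * trajectory$lambda^(trajectory$T_dec - t)))
  as.integer(pmax(size, 2))
}

#' Contemporary-to-historic size ratio under exponential decline
#'
#' Returns `lambda^T`, the ratio of contemporary to historic size after `T`
#' years of exponential decline at per-year rate `lambda`.  `gen_time` is
#' only used to report the number of elapsed generations in the attribute
#' `generations`.
#'
#' @param lambda Per-year multiplier in (0, 1].
#' @param T_years Years of decline (>= 0).
#' @param gen_time Generation time in years.
#' @return Numeric ratio with attribute `generations = T_years / gen_time`.
#' @examples
#' round(decline_ratio(0.99, 30), 2)   # 0.74
#' round(decline_ratio(0.95, 30), 2)   # 0.21
#' @export
decline_ratio <- function(lambda, T_years, gen_time = 1) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  stopifnot(all(T_years >= 0))
  structure(lambda^T_years, generations = T_years / gen_time)
}

#' Ancestral (pre-simulation) size change
#'
#' A single instantaneous 10-fold size change at 10,000 generations before
#' present.  Labels follow the backward-time reading: an "expansion" means
#' the population expanded towards the present, i.e. the ancestral size was
#' `Ne_H / factor`; a "bottleneck" means the ancestral size was
#' `Ne_H * factor`.  Both directions are supported and unambiguously
#' identified by `Ne_A / Ne_H`.
#'
#' @param kind `"none"`, `"expansion"`, or `"bottleneck"`.
#' @param Ne_H Historic size the forward simulation starts from.
#' @param factor Fold change (default 10).
#' @param time_gen Generations before present of the change (default 10000).
#' @return Object of class `ancestralchange` with `Ne_A` filled in.
#' @export
ancestral_change <- function(kind = c("none", "expansion", "bottleneck"),
                             Ne_H, factor = 10, time_gen = 10000L) {
  kind <- match.arg(kind)
  Ne_A <- switch(kind,
                 none = as.numeric(Ne_H),
                 expansion = Ne_H / factor,
                 bottleneck = Ne_H * factor)
  if (Ne_A < 2) stop("ancestral size below 2")
  structure(list(kind = kind, factor = factor, time_gen = as.integer(time_gen),
                 Ne_A = Ne_A),
            class = "ancestralchange")
}

#' Demographic scenario: life history + recent trajectory + ancestral change
#'
#' Bundles the ground truth for one simulation.  Per the study design,
#' ancestral size changes are only allowed together with `Ne_H = 10000`,
#' life history `G1`, and a recent trajectory that is stable, a fast
#' decline from 30 ybp (`lambda = 0.95`), or a slow decline from 120 ybp
#' (`lambda = 0.99`).
#'
#' @param life_history A [life_history()] object.
#' @param trajectory A [size_trajectory()] object.
#' @param ancestral An [ancestral_change()] object (default: none).
#' @param mutation_rate Per-bp per-generation mutation rate.
#' @param recombination_rate Per-bp per-generation recombination rate.
#' @return Object of class `demographicscenario`.
#' @export
demographic_scenario <- function(life_history, trajectory,
                                 ancestral = NULL,
                                 mutation_rate = 1e-8,
                                 recombination_rate = 1e-8) {
  stopifnot(inherits(life_history, "lifehistory"),
            inherits(trajectory, "sizetrajectory"))
  if (is.null(ancestral)) ancestral <- ancestral_change("none", trajectory$Ne_H)
  stopifnot(inherits(ancestral, "ancestralchange"))
  if (ancestral$kind != "none") {
    ok_traj <- is_stable(trajectory) ||
      (trajectory$lambda == 0.95 && identical(trajectory$T_dec, 30L)) ||
      (trajectory$lambda == 0.99 && identical(trajectory$T_dec, 120L))
    if (!(trajectory$Ne_H == 10000L && life_history$id == "G1" && ok_traj)) {
      stop("ancestral changes require Ne_H = 10000, G1, and a stable, ",
           "fast-30, or slow-120 recent trajectory")
    }
  }
  structure(list(life_history = life_history, trajectory = trajectory,
                 ancestral = ancestral, mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate),
            class = "demographicscenario")
}

is_stable <- function(trajectory) {
  trajectory$lambda == 1 || is.na(trajectory$T_dec)
}

#' True effective sizes of a scenario at the evaluation time points
#'
#' @param scenario A [demographic_scenario()].
#' @return Named numeric vector with `Ne_C` (size at 0 ybp) and `Ne_H`
#'   (size at 120 ybp).
#' @export
scenario_truth <- function(scenario) {
  c(Ne_C = as.numeric(trajectory_size(scenario$trajectory, 0)),
    Ne_H = as.numeric(trajectory_size(scenario$trajectory, 120)))
}

# Stable polynomial string hash mod the Mersenne prime 2^31 - 1, giving a
# positive R integer.  Used to derive per-entry RNG seeds that are
# reproducible and independent of enumeration order.  Exact in double
# precision: h < 2^31, so h * 131 + b < 2^39 << 2^53.
hash32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

derive_seed <- function(master_seed, ...) {
  key <- paste(c(master_seed, ...), collapse = "|")
  hash32(key)
}

#' Default full-study factor grid
#'
#' The published factor grid: 18 demographic scenarios (2 historic sizes
#' crossed with a stable trajectory, four `lambda = 0.99` declines starting
#' 120/90/60/30 ybp and one `lambda = 0.95` decline starting 30 ybp, plus
#' ancestral expansions and bottlenecks crossed with three recent
#' trajectories at `Ne_H = 10000`), 5 replicates, 3 temporal sampling
#' schemes, whole-genome data at n = 20/50/100 and two RAD-like data types
#' at n = 50/100/200: 2430 dataset specifications in total.
#'
#' @param replicates Replicate simulations per scenario.
#' @param master_seed Master seed all per-entry seeds are derived from.
#' @return A config list consumable by [enumerate_study_grid()].
#' @export
study_grid_config <- function(replicates = 5L, master_seed = 20220914L) {
  list(
    life_history = "G1",
    Ne_H = c(1000L, 10000L),
    recent = list(
      list(lambda = 1.00, T_dec = NA),
      list(lambda = 0.99, T_dec = 120L),
      list(lambda = 0.99, T_dec = 90L),
      list(lambda = 0.99, T_dec = 60L),
      list(lambda = 0.99, T_dec = 30L),
      list(lambda = 0.95, T_dec = 30L)
    ),
    ancestral = c("expansion", "bottleneck"),
    ancestral_recent = list(               # recent trajectories crossed with
      list(lambda = 1.00, T_dec = NA),     # ancestral changes (Ne_H = 10000)
      list(lambda = 0.95, T_dec = 30L),
      list(lambda = 0.99, T_dec = 120L)
    ),
    replicates = as.integer(replicates),
    schemes = c("contemporary", "two_sample", "serial"),
    sample_sizes = list(WGS = c(20L, 50L, 100L),
                        RAD400 = c(50L, 100L, 200L),
                        RAD2000 = c(50L, 100L, 200L)),
    data_types = c("WGS", "RAD400", "RAD2000"),
    master_seed = as.integer(master_seed)
  )
}

#' Enumerate the demographic scenarios of a study config
#'
#' @param config A config list as from [study_grid_config()].
#' @return A data.frame with one row per scenario: `scenario_id`,
#'   `life_history`, `Ne_H`, `lambda`, `T_dec`, `ancestral`.
#' @export
enumerate_scenarios <- function(config) {
  rows <- list()
  for (ne in config$Ne_H) for (rc in config$recent) {
    rows[[length(rows) + 1L]] <- data.frame(
      life_history = config$life_history, Ne_H = ne,
      lambda = rc$lambda,
      T_dec = if (is.null(rc$T_dec) || is.na(rc$T_dec)) NA_integer_ else rc$T_dec,
      ancestral = "none", stringsAsFactors = FALSE)
  }
  for (anc in config$ancestral) for (rc in config$ancestral_recent) {
    rows[[length(rows) + 1L]] <- data.frame(
      life_history = config$life_history, Ne_H = max(config$Ne_H),
      lambda = rc$lambda,
      T_dec = if (is.null(rc$T_dec) || is.na(rc$T_dec)) NA_integer_ else rc$T_dec,
      ancestral = anc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$scenario_id <- sprintf(
    "%s_N%d_l%s_T%s_%s", out$life_history, out$Ne_H,
    sub("\\.", "p", formatC(out$lambda, format = "f", digits = 2)),
    ifelse(is.na(out$T_dec), "none", out$T_dec), out$ancestral)
  out[, c("scenario_id", "life_history", "Ne_H", "lambda", "T_dec", "ancestral")]
}

#' Enumerate the full study grid of dataset specifications
#'
#' Crosses scenarios, replicates, sampling schemes, data types and the
#' per-data-type sample sizes; every entry carries a unique RNG seed
#' derived from the master seed and a stable hash of the entry tuple, so
#' enumeration is deterministic and order-stable.
#'
#' @param config A config list as from [study_grid_config()].
#' @return A data.frame with one row per dataset spec.
#' @export
enumerate_study_grid <- function(config) {
  known_schemes <- c("contemporary", "two_sample", "serial")
  known_types <- c("WGS", "RAD400", "RAD2000")
  if (!all(config$schemes %in% known_schemes)) {
    stop("unknown scheme: ",
         paste(setdiff(config$schemes, known_schemes), collapse = ", "))
  }
  if (!all(config$data_types %in% known_types)) {
    stop("unknown data type: ",
         paste(setdiff(config$data_types, known_types), collapse = ", "))
  }
  sc <- enumerate_scenarios(config)
  entries <- list()
  for (i in seq_len(nrow(sc))) for (rep_i in seq_len(config$replicates)) {
    for (scheme in config$schemes) for (dt in config$data_types) {
      sizes <- config$sample_sizes[[dt]]
      if (is.null(sizes)) stop("no sample sizes for data type ", dt)
      for (n in sizes) {
        entries[[length(entries) + 1L]] <- data.frame(
          scenario_id = sc$scenario_id[i], replicate = rep_i,
          scheme = scheme, data_type = dt, n_total = n,
          stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, entries)
  grid$seed <- vapply(seq_len(nrow(grid)), function(j) {
    derive_seed(config$master_seed, grid$scenario_id[j], grid$replicate[j],
                grid$scheme[j], grid$data_type[j], grid$n_total[j])
  }, integer(1))
  grid
}

#' Build the scenario object for one row of the scenario table
#'
#' @param row One row of [enumerate_scenarios()] output (or a list with the
#'   same fields).
#' @param duration Forward-simulated years.
#' @return A [demographic_scenario()].
#' @export
scenario_from_row <- function(row, duration = 220L) {
  lh <- life_history(row$life_history)
  traj <- size_trajectory(row$Ne_H, row$lambda,
                          if (is.na(row$T_dec)) NA else row$T_dec, duration)
  anc <- ancestral_change(row$ancestral, row$Ne_H)
  demographic_scenario(lh, traj, anc)
}
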