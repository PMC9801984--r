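# Forward-time individual-based simulation of the pedigree.
#
# Population size is regulated by the number of offspring N_O produced each
# year; each offspring draws one female and one male parent uniformly with
# replacement from the breeding-age pool, giving approximately Poisson
# reproductive success (mean 2, variance ~2) so that N_O tracks Ne.

resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Chromosome specification
#'
#' @param index Chromosome index (1-based).
#' @param length_bp Chromosome length in base pairs (default 30 Mb).
#' @param recombination_rate Per-bp per-generation crossover rate.
#' @return Object of class `chromspec`.
#' @export
chromosome_spec <- function(index = 1L, length_bp = 3e7,
                            recombination_rate = 1e-8) {
  stopifnot(length_bp > 0, recombination_rate >= 0)
  structure(list(index = as.integer(index), length_bp = length_bp,
                 recombination_rate = recombination_rate),
            class = "chromspec")
}

#' Simulate the pedigree of a demographic scenario
#'
#' Runs the forward-time individual-based model for
#' `scenario$trajectory$duration` yearly steps.  Sex is assigned with
#' probability 1/2.  Under `G1` every individual breeds at age one and then
#' dies; under `G2` the age-specific survival schedule is applied first and
#' the year's offspring are then recruited from all breeding-age
#' individuals.  Individuals alive at the checkpoint years (120, 90, 60,
#' 30 ybp) are sampled (200 per checkpoint, or all if fewer) and all
#' individuals alive at 0 ybp are recorded.
#'
#' @param scenario A [demographic_scenario()].
#' @param seed Integer RNG seed.
#' @param checkpoint_n Individuals recorded per historical checkpoint.
#' @param checkpoints Years before present at which samples are recorded.
#' @return Object of class `pedigree`: parallel vectors `id`, `sex`
#'   (0 = female, 1 = male), `birth` (ybp), `mother`, `father`
#'   (0 = founder), plus `checkpoints` (named list of id vectors),
#'   `breeders` (per-year breeding-age counts by sex) and the scenario.
#' @export
simulate_pedigree <- function(scenario, seed = 1L, checkpoint_n = 200L,
                              checkpoints = c(120L, 90L, 60L, 30L)) {
  stopifnot(inherits(scenario, "demographicscenario"))
  set.seed(seed)
  lh <- scenario$life_history
  traj <- scenario$trajectory
  dur <- traj$duration

  sex_l <- list(); birth_l <- list(); mo_l <- list(); fa_l <- list()
  next_id <- 1L
  new_cohort <- function(n, ybp, mothers, fathers) {
    ids <- seq.int(next_id, length.out = n)
    sex_l[[length(sex_l) + 1L]] <<- as.integer(stats::runif(n) < 0.5)
    birth_l[[length(birth_l) + 1L]] <<- rep.int(as.integer(ybp), n)
    mo_l[[length(mo_l) + 1L]] <<- mothers
    fa_l[[length(fa_l) + 1L]] <<- fathers
    next_id <<- next_id + n
    ids
  }
  last_sex <- function() sex_l[[length(sex_l)]]

  cp_years <- sort(unique(as.integer(checkpoints)), decreasing = TRUE)
  cp_ids <- stats::setNames(vector("list", length(cp_years) + 1L),
                            c(as.character(cp_years), "0"))
  breeders_f <- integer(dur); breeders_m <- integer(dur)

  if (lh$id == "G1") {
    cohort_ids <- new_cohort(traj$Ne_H, dur, rep(0L, traj$Ne_H),
                             rep(0L, traj$Ne_H))
    cohort_sex <- last_sex()
    for (y in seq.int(dur - 1L, 0L)) {
      n_o <- trajectory_size(traj, y)
      fem <- cohort_ids[cohort_sex == 0L]
      mal <- cohort_ids[cohort_sex == 1L]
      if (length(fem) == 0L || length(mal) == 0L) {
        stop("pedigree extinction: no breeding-age ",
             if (length(fem) == 0L) "females" else "males",
             " in year ", y, " ybp")
      }
      breeders_f[y + 1L] <- length(fem); breeders_m[y + 1L] <- length(mal)
      mothers <- resample(fem, n_o, replace = TRUE)
      fathers <- resample(mal, n_o, replace = TRUE)
      cohort_ids <- new_cohort(n_o, y, mothers, fathers)
      cohort_sex <- last_sex()
      if (y %in% cp_years) {
        cp_ids[[as.character(y)]] <-
          sort(resample(cohort_ids, min(checkpoint_n, length(cohort_ids))))
      } else if (y == 0L) {
        cp_ids[["0"]] <- cohort_ids
      }
    }
  } else {
    # G2: initialise a stable age structure at the start year.  Breeding
    # pool of ~Ne_H individuals with ages ~ stable distribution, plus a
    # newborn cohort of size N_O.
    sa_w <- cumprod(lh$survival[-1])[seq_len(lh$max_age - 1L)]
    age_w <- c(1, sa_w)                      # relative abundance of ages 1..8
    n_b <- traj$Ne_H
    init_ages <- sample(seq_len(lh$max_age), n_b, replace = TRUE,
                        prob = age_w / sum(age_w))
    pool_ids <- new_cohort(n_b, dur, rep(0L, n_b), rep(0L, n_b))
    pool_sex <- last_sex()
    pool_age <- init_ages
    nb_ids <- new_cohort(traj$Ne_H, dur, rep(0L, traj$Ne_H),
                         rep(0L, traj$Ne_H))
    alive_ids <- c(pool_ids, nb_ids)
    alive_sex <- c(pool_sex, last_sex())
    alive_age <- c(pool_age, rep(0L, traj$Ne_H))
    for (y in seq.int(dur - 1L, 0L)) {
      n_o <- trajectory_size(traj, y)
      surv_p <- lh$survival[pmin(alive_age + 1L, length(lh$survival))]
      keep <- stats::runif(length(alive_ids)) < surv_p
      alive_ids <- alive_ids[keep]
      alive_sex <- alive_sex[keep]
      alive_age <- alive_age[keep] + 1L
      br <- alive_age >= lh$age_first_breeding
      fem <- alive_ids[br & alive_sex == 0L]
      mal <- alive_ids[br & alive_sex == 1L]
      if (length(fem) == 0L || length(mal) == 0L) {
        stop("pedigree extinction: no breeding-age ",
             if (length(fem) == 0L) "females" else "males",
             " in year ", y, " ybp")
      }
      breeders_f[y + 1L] <- length(fem); breeders_m[y + 1L] <- length(mal)
      mothers <- resample(fem, n_o, replace = TRUE)
      fathers <- resample(mal, n_o, replace = TRUE)
      nb <- new_cohort(n_o, y, mothers, fathers)
      alive_ids <- c(alive_ids, nb)
      alive_sex <- c(alive_sex, last_sex())
      alive_age <- c(alive_age, rep(0L, n_o))
      if (y %in% cp_years) {
        cp_ids[[as.character(y)]] <-
          sort(resample(alive_ids, min(checkpoint_n, length(alive_ids))))
      } else if (y == 0L) {
        cp_ids[["0"]] <- sort(alive_ids)
      }
    }
  }

  structure(list(
    id = seq_len(next_id - 1L),
    sex = unlist(sex_l), birth = unlist(birth_l),
    mother = unlist(mo_l), father = unlist(fa_l),
    checkpoints = cp_ids,
    breeders = data.frame(ybp = seq.int(0L, dur - 1L),
                          females = breeders_f, males = breeders_m),
    scenario = scenario, seed = as.integer(seed)
  ), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", length(x$id), "individuals,",
      x$scenario$life_history$id, "life history, Ne_H =",
      x$scenario$trajectory$Ne_H, "\n")
  invisible(x)
}

#' Realized demographic summaries of a pedigree
#'
#' Per-year breeding-age counts by sex, the mean parental age (mother and
#' father ages pooled) and the variance of per-parent offspring counts
#' (zero-offspring breeders included), used by the calibration checks.
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param years_ybp Restrict offspring cohorts to these years (default all
#'   non-founder cohorts).
#' @return List with `breeders` (data.frame), `mean_parental_age`,
#'   `offspring_variance`, `offspring_mean`, `sex_ratio` (proportion
#'   female over all individuals).
#' @export
realized_demography <- function(pedigree, years_ybp = NULL) {
  stopifnot(inherits(pedigree, "pedigree"))
  nonf <- pedigree$mother != 0L
  if (!is.null(years_ybp)) nonf <- nonf & pedigree$birth %in% years_ybp
  kid_birth <- pedigree$birth[nonf]
  mo <- pedigree$mother[nonf]; fa <- pedigree$father[nonf]
  age_mo <- pedigree$birth[mo] - kid_birth
  age_fa <- pedigree$birth[fa] - kid_birth
  # offspring counts per breeder-year: tabulate parent assignments; zero
  # counts come from breeders that were alive but drew no offspring.
  counts <- tabulate(c(mo, fa), nbins = length(pedigree$id))
  # restrict to individuals that were ever breeding-age in the window:
  # approximate the breeder pool by parents' cohorts (exact for G1).
  cohort_years <- unique(kid_birth)
  n_breeders <- sum(pedigree$breeders$females[pedigree$breeders$ybp %in% cohort_years],
                    pedigree$breeders$males[pedigree$breeders$ybp %in% cohort_years])
  n_off <- 2L * length(mo)
  offspring_mean <- n_off / n_breeders
  # variance over the realized multinomial assignment, including zeros
  parents_seen <- counts[counts > 0L]
  n_zero <- n_breeders - length(parents_seen)
  all_counts <- c(parents_seen, rep.int(0L, max(n_zero, 0L)))
  list(
    breeders = pedigree$breeders,
    mean_parental_age = mean(c(age_mo, age_fa)),
    offspring_mean = offspring_mean,
    offspring_variance = stats::var(all_counts),
    sex_ratio = mean(pedigree$sex == 0L)
  )
}

#' Export a pedigree as a tab-separated table
#'
#' Columns: `id`, `sex` (`F`/`M`), `birth_year` (ybp), `mother`, `father`
#' (0 for founders).
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  stopifnot(inherits(pedigree, "pedigree"))
  utils::write.table(
    data.frame(id = pedigree$id, sex = c("F", "M")[pedigree$sex + 1L],
               birth_year = pedigree$birth, mother = pedigree$mother,
               father = pedigree$father),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- segment mosaics (reference-scale forward transmission) ----

#' Create a founder segment mosaic
#'
#' @param founder_hap Integer founder haplotype id.
#' @param length_bp Chromosome length.
#' @return A one-row mosaic matrix with columns `start`, `end`, `founder`
#'   (0-based half-open interval).
#' @export
founder_mosaic <- function(founder_hap, length_bp) {
  matrix(c(0, length_bp, founder_hap), nrow = 1,
         dimnames = list(NULL, c("start", "end", "founder")))
}

merge_mosaic <- function(m) {
  if (nrow(m) <= 1L) return(m)
  keep <- c(TRUE, m[-1L, "founder"] != m[-nrow(m), "founder"])
  if (all(keep)) return(m)
  idx <- which(keep)
  out <- m[idx, , drop = FALSE]
  out[, "end"] <- m[c(idx[-1L] - 1L, nrow(m)), "end"]
  out
}

slice_mosaic <- function(m, from, to) {
  sel <- m[, "end"] > from & m[, "start"] < to
  s <- m[sel, , drop = FALSE]
  s[1L, "start"] <- max(s[1L, "start"], from)
  s[nrow(s), "end"] <- min(s[nrow(s), "end"], to)
  s
}

#' Transmit one gamete through meiosis
#'
#' Crossover count is Poisson with mean `recombination_rate * length_bp`;
#' breakpoints are uniform integers in (0, L) (continuous uniforms floored,
#' collisions resampled); the gamete alternates between the two parental
#' haplotypes starting from a fair-coin choice.  Adjacent segments with the
#' same founder id are merged, so output is in canonical form and tiles
#' `[0, L)` exactly.
#'
#' @param hap1,hap2 Parental haplotype mosaics (matrices as from
#'   [founder_mosaic()]).
#' @param spec A [chromosome_spec()].
#' @return A haploid mosaic matrix.
#' @export
transmit_gamete <- function(hap1, hap2, spec) {
  L <- spec$length_bp
  k <- stats::rpois(1L, spec$recombination_rate * L)
  first <- sample.int(2L, 1L)
  if (k == 0L) return(if (first == 1L) hap1 else hap2)
  bp <- unique(floor(stats::runif(k, 1, L)))
  while (length(bp) < k) bp <- unique(c(bp, floor(stats::runif(k - length(bp), 1, L))))
  bp <- sort(bp)
  bounds <- c(0, bp, L)
  pieces <- vector("list", length(bounds) - 1L)
  for (i in seq_along(pieces)) {
    src <- if ((i + first) %% 2L == 0L) hap1 else hap2
    pieces[[i]] <- slice_mosaic(src, bounds[i], bounds[i + 1L])
  }
  merge_mosaic(do.call(rbind, pieces))
}

#' Simulate one chromosome's segment mosaics over a fixed pedigree
#'
#' Reference-scale forward transmission: every individual receives one
#' gamete from each parent via [transmit_gamete()]; founders get fresh
#' founder haplotypes covering `[0, L)`.  The same pedigree can be reused
#' across chromosomes with independent recombination randomness.  Intended
#' for toy-scale pedigrees (everything is kept in memory); the production
#' dataset path uses the equivalent backward-in-time tracer in
#' [simulate_variants()].
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param spec A [chromosome_spec()].
#' @param seed RNG seed.
#' @param sample_ids Individuals whose mosaics to return (default: all
#'   checkpoint samples).
#' @return List with `mosaics` (per sample id, a list of two haplotype
#'   mosaics), `founders_used` (founder haplotype ids with surviving
#'   ancestry in the returned samples) and `n_founder_haps`.
#' @export
simulate_chromosome <- function(pedigree, spec, seed = 1L,
                                sample_ids = NULL) {
  stopifnot(inherits(pedigree, "pedigree"))
  set.seed(seed)
  if (is.null(sample_ids)) sample_ids <- unique(unlist(pedigree$checkpoints))
  n <- length(pedigree$id)
  haps <- vector("list", n)
  ord <- order(pedigree$birth, decreasing = TRUE)  # oldest first
  founder_next <- 1L
  L <- spec$length_bp
  for (i in ord) {
    if (pedigree$mother[i] == 0L) {
      haps[[i]] <- list(founder_mosaic(founder_next, L),
                        founder_mosaic(founder_next + 1L, L))
      founder_next <- founder_next + 2L
    } else {
      mo <- haps[[pedigree$mother[i]]]
      fa <- haps[[pedigree$father[i]]]
      haps[[i]] <- list(transmit_gamete(mo[[1L]], mo[[2L]], spec),
                        transmit_gamete(fa[[1L]], fa[[2L]], spec))
    }
  }
  mosaics <- stats::setNames(haps[sample_ids], sample_ids)
  founders_used <- sort(unique(unlist(
    lapply(mosaics, function(h) c(h[[1L]][, "founder"], h[[2L]][, "founder"])))))
  list(mosaics = mosaics, founders_used = founders_used,
       n_founder_haps = founder_next - 1L)
}
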