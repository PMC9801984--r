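# Pipeline orchestration: simulate -> datasets -> infer -> evaluate, with
# a JSON config, derived seeding, stage skipping, and a run manifest.

pipeline_defaults <- function() {
  list(
    duration = 220L,
    n_chrom = 25L, chrom_len = 3e7, wgs_window = 5000,
    mutation_rate = 1e-8, recombination_rate = 1e-8,
    checkpoint_n = 200L,
    sfs_optimizer = optimizer_config(),
    ld = list(hc = 0.05, n_bins = 400L, max_snps_per_chrom = 50000L,
              resamples = 40L, resample_size = 50000L, maf_point = 0.05)
  )
}

#' Read and normalise a pipeline configuration
#'
#' Configurations are JSON documents (or R lists) with the keys of
#' [study_grid_config()] plus optional genome/runtime overrides
#' (`n_chrom`, `chrom_len`, `wgs_window`, `duration`, `checkpoint_n`,
#' `rad_loci_per_chrom`).  Missing keys fall back to package defaults.
#'
#' @param config Path to a JSON file, or a list.
#' @return Normalised config list.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- c(study_grid_config(), pipeline_defaults())
  # keys present in the user config replace defaults wholesale (no
  # recursive merging: a 1-entry scenario list means 1 scenario)
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  if (is.null(cfg$recent) || !is.list(cfg$recent[[1]])) {
    # allow a simplified single-trajectory spec: lambda + T_dec scalars
    if (!is.null(config$lambda)) {
      cfg$recent <- list(list(lambda = config$lambda,
                              T_dec = config$T_dec))
    }
  }
  cfg
}

rad_count <- function(data_type) {
  switch(data_type, RAD400 = 400L, RAD2000 = 2000L,
         stop("not a RAD data type: ", data_type))
}

dataset_loci <- function(cfg, data_type, seed) {
  if (data_type == "WGS") {
    wgs_loci(cfg$n_chrom, cfg$chrom_len, cfg$wgs_window)
  } else {
    rad_loci(cfg$n_chrom, cfg$chrom_len, rad_count(data_type),
             seed = seed)
  }
}

#' Run inference methods on one simulated dataset
#'
#' Applies the method set appropriate to the dataset's scheme and data
#' type: the SFS composite-likelihood fitter (all schemes and types), the
#' unlinked-pair LD estimator (two-sample RAD data: one estimate per
#' timepoint, CIs compared across time), and the binned-LD trajectory
#' (contemporary WGS data).
#'
#' @param variants A `varianttable`.
#' @param scenario The generating [demographic_scenario()] (for truth).
#' @param scheme_kind,data_type,scenario_id,n_total Record metadata.
#' @param methods Subset of `c("sfs", "ld_point", "ld_traj")`.
#' @param cfg Pipeline config (for estimator settings).
#' @param seed RNG seed.
#' @return Records data.frame (one row per method).
#' @export
infer_dataset <- function(variants, scenario, scheme_kind, data_type,
                          scenario_id, n_total,
                          methods = c("sfs", "ld_point", "ld_traj"),
                          cfg = read_config(list()), seed = 1L) {
  truth <- scenario_truth(scenario)
  gt <- scenario$life_history$expected_generation_time
  recs <- list()
  if ("sfs" %in% methods) {
    sfs <- dataset_sfs(variants)
    fit <- fit_sfs_models(sfs, scenario$mutation_rate, gt,
                          config = cfg$sfs_optimizer,
                          seed = derive_seed(seed, "sfs"))
    recs[["sfs"]] <- inference_record(
      scenario_id, "sfs", "aic", scheme_kind, n_total, data_type,
      truth["Ne_C"], truth["Ne_H"], fit$best$Ne_C_hat, fit$best$Ne_H_hat,
      best_model = fit$best$model)
  }
  if ("ld_point" %in% methods &&
      all(c(0, 120) %in% variants$samples$time_ybp)) {
    est <- lapply(c(0, 120), function(tp) {
      ld_ne_point(genotypes_at(variants, tp), variants$chrom,
                  maf = cfg$ld$maf_point)
    })
    recs[["ld_point"]] <- inference_record(
      scenario_id, "ld_point", "ci", scheme_kind, n_total, data_type,
      truth["Ne_C"], truth["Ne_H"],
      est[[1]]$point, est[[2]]$point,
      Ne_C_lo = est[[1]]$ci_low, Ne_C_hi = est[[1]]$ci_high,
      Ne_H_lo = est[[2]]$ci_low, Ne_H_hi = est[[2]]$ci_high,
      flags = paste(est[[1]]$flags, est[[2]]$flags, sep = ";"))
  }
  if ("ld_traj" %in% methods && 0 %in% variants$samples$time_ybp) {
    bins <- bin_pairs(variants, 0,
                      map_rate = scenario$recombination_rate,
                      hc = cfg$ld$hc, n_bins = cfg$ld$n_bins,
                      max_snps_per_chrom = cfg$ld$max_snps_per_chrom,
                      resamples = cfg$ld$resamples,
                      resample_size = cfg$ld$resample_size,
                      seed = derive_seed(seed, "ldtraj"))
    tr <- ld_trajectory(bins, gen_time = gt)
    if (identical(tr$flags, "ok")) {
      recs[["ld_traj"]] <- inference_record(
        scenario_id, "ld_traj", "ci", scheme_kind, n_total, data_type,
        truth["Ne_C"], truth["Ne_H"],
        tr$Ne_C$point, tr$Ne_H$point,
        Ne_C_lo = tr$Ne_C$ci_low, Ne_C_hi = tr$Ne_C$ci_high,
        Ne_H_lo = tr$Ne_H$ci_low, Ne_H_hi = tr$Ne_H$ci_high)
    } else {
      recs[["ld_traj"]] <- inference_record(
        scenario_id, "ld_traj", "ci", scheme_kind, n_total, data_type,
        truth["Ne_C"], truth["Ne_H"], NA_real_, NA_real_,
        Ne_C_lo = NA, Ne_C_hi = NA, Ne_H_lo = NA, Ne_H_hi = NA,
        flags = tr$flags)
    }
  }
  do.call(rbind, recs)
}

#' Run the simulation/inference pipeline
#'
#' Executes the requested stages over the study grid of `config`, writing
#' all artifacts under `out_dir`: pedigrees (`pedigrees/`), datasets as
#' VCF plus folded-SFS text (`datasets/`), inference records
#' (`records.csv`) and evaluation tables (`evaluation/`).  Completed
#' stages are skipped on re-runs unless `force`; all randomness derives
#' from the config's `master_seed`, so identical configs reproduce
#' identical artifacts.
#'
#' @param config Config list or JSON path (see [read_config()]).
#' @param stages Subset of `c("simulate", "datasets", "infer",
#'   "evaluate")`.
#' @param out_dir Run directory.
#' @param force Recompute existing artifacts.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, stages = c("simulate", "datasets",
                                            "infer", "evaluate"),
                         out_dir = "declinesim_run", force = FALSE) {
  cfg <- read_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenarios <- enumerate_scenarios(cfg)
  grid <- enumerate_study_grid(cfg)
  manifest <- list(
    package_version = as.character(utils::packageVersion("declinesim")),
    config_hash = hash32(jsonlite::toJSON(cfg, auto_unbox = TRUE)),
    master_seed = cfg$master_seed,
    n_scenarios = nrow(scenarios), n_datasets = nrow(grid),
    stages_run = stages, artifacts = list())

  ped_dir <- file.path(out_dir, "pedigrees")
  ds_dir <- file.path(out_dir, "datasets")
  ped_path <- function(sid, rep) {
    file.path(ped_dir, sprintf("%s_rep%d.rds", sid, rep))
  }
  load_pedigree <- function(sid, rep) readRDS(ped_path(sid, rep))

  if ("simulate" %in% stages) {
    dir.create(ped_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(scenarios))) {
      for (rep_i in seq_len(cfg$replicates)) {
        pth <- ped_path(scenarios$scenario_id[i], rep_i)
        if (file.exists(pth) && !force) next
        scen <- scenario_from_row(scenarios[i, ], cfg$duration)
        ped <- simulate_pedigree(
          scen, seed = derive_seed(cfg$master_seed, "ped",
                                   scenarios$scenario_id[i], rep_i),
          checkpoint_n = cfg$checkpoint_n)
        saveRDS(ped, pth)
      }
    }
    manifest$artifacts$pedigrees <- ped_dir
  }

  if ("datasets" %in% stages) {
    dir.create(ds_dir, showWarnings = FALSE)
    for (j in seq_len(nrow(grid))) {
      g <- grid[j, ]
      stem <- file.path(ds_dir, sprintf("%s_rep%d_%s_%s_n%d",
                                        g$scenario_id, g$replicate,
                                        g$scheme, g$data_type, g$n_total))
      if (file.exists(paste0(stem, ".vcf")) && !force) next
      ped <- load_pedigree(g$scenario_id, g$replicate)
      samples <- draw_samples(ped, sampling_scheme(g$scheme, g$n_total),
                              seed = derive_seed(g$seed, "draw"))
      loci <- dataset_loci(cfg, g$data_type, derive_seed(g$seed, "loci"))
      v <- simulate_variants(ped, samples, loci,
                             seed = derive_seed(g$seed, "var"))
      write_vcf(v, paste0(stem, ".vcf"), cfg$chrom_len)
      write_sfs(dataset_sfs(v), paste0(stem, ".sfs"))
    }
    manifest$artifacts$datasets <- ds_dir
  }

  rec_path <- file.path(out_dir, "records.csv")
  if ("infer" %in% stages && (!file.exists(rec_path) || force)) {
    all_recs <- list()
    for (j in seq_len(nrow(grid))) {
      g <- grid[j, ]
      stem <- file.path(ds_dir, sprintf("%s_rep%d_%s_%s_n%d",
                                        g$scenario_id, g$replicate,
                                        g$scheme, g$data_type, g$n_total))
      v <- read_vcf(paste0(stem, ".vcf"))
      scen <- scenario_from_row(
        scenarios[scenarios$scenario_id == g$scenario_id, ][1, ],
        cfg$duration)
      methods <- c("sfs",
                   if (g$data_type != "WGS" && g$scheme == "two_sample")
                     "ld_point",
                   if (g$data_type == "WGS" && g$scheme == "contemporary")
                     "ld_traj")
      all_recs[[j]] <- infer_dataset(v, scen, g$scheme, g$data_type,
                                     g$scenario_id, g$n_total, methods,
                                     cfg, seed = derive_seed(g$seed, "inf"))
    }
    utils::write.csv(do.call(rbind, all_recs), rec_path,
                     row.names = FALSE)
    manifest$artifacts$records <- rec_path
  }

  if ("evaluate" %in% stages) {
    ev_dir <- file.path(out_dir, "evaluation")
    dir.create(ev_dir, showWarnings = FALSE)
    records <- utils::read.csv(rec_path, stringsAsFactors = FALSE)
    rep_tabs <- aggregate_report(records, scenarios)
    for (nm in names(rep_tabs)) {
      utils::write.csv(rep_tabs[[nm]],
                       file.path(ev_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    manifest$artifacts$evaluation <- ev_dir
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a miniature fixture dataset on disk
#'
#' Presets: `constant_tiny` (stable Ne = 200), `decline_tiny`
#' (lambda = 0.9 from 20 ybp) and `ancestral_tiny` (stable with a 10x
#' ancestral bottleneck), each with 2 chromosomes of 2 Mb, 60 forward
#' years and n = 20 contemporary samples.  Small enough for unit tests.
#'
#' @param preset Fixture preset name.
#' @param dir Output directory.
#' @param seed RNG seed.
#' @return List with the `varianttable`, scenario, and file paths.
#' @export
make_fixture <- function(preset = c("constant_tiny", "decline_tiny",
                                    "ancestral_tiny"),
                         dir = tempfile("fixture"), seed = 1L) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  duration <- 60L
  lh <- life_history("G1")
  traj <- switch(preset,
    constant_tiny = size_trajectory(200, 1, NA, duration),
    decline_tiny = size_trajectory(200, 0.9, 20, duration),
    ancestral_tiny = size_trajectory(200, 1, NA, duration))
  anc <- if (preset == "ancestral_tiny") {
    structure(list(kind = "bottleneck", factor = 10, time_gen = 500L,
                   Ne_A = 2000), class = "ancestralchange")
  } else NULL
  scen <- if (is.null(anc)) demographic_scenario(lh, traj) else
    structure(list(life_history = lh, trajectory = traj, ancestral = anc,
                   mutation_rate = 1e-8, recombination_rate = 1e-8),
              class = "demographicscenario")
  ped <- simulate_pedigree(scen, seed = derive_seed(seed, preset, "ped"),
                           checkpoint_n = 50L,
                           checkpoints = c(30L, 20L, 10L))
  samples <- data.frame(id = resample(ped$checkpoints[["0"]], 20L),
                        time_ybp = 0L)
  loci <- wgs_loci(n_chrom = 2L, chrom_len = 2e6, window = 2000)
  v <- simulate_variants(ped, samples, loci,
                         seed = derive_seed(seed, preset, "var"))
  vcf <- file.path(dir, paste0(preset, ".vcf"))
  sfs <- file.path(dir, paste0(preset, ".sfs"))
  write_vcf(v, vcf, 2e6)
  write_sfs(dataset_sfs(v), sfs)
  list(variants = v, scenario = scen, pedigree = ped,
       paths = c(vcf = vcf, sfs = sfs))
}
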