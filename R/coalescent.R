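# Coalescent completion of pedigree ancestry and genotype generation.
#
# The production dataset path traces sampled haplotypes backward through
# the fixed pedigree (exact conditional gene dropping at a set of point
# loci; see src/ancestry.cpp), completes the open founder lineages with a
# single-locus coalescent under the ancestral size history, and drops
# infinite-sites mutations on the resulting forest.

#' Define a whole-genome locus tiling
#'
#' Whole-genome sequence is represented as a contiguous tiling of short
#' windows; within-window recombination is ignored (a 5 kb window spans
#' 5e-5 Morgans at 1 cM/Mb) while between-window linkage through the
#' pedigree is exact.  Total site count L equals the full genome length.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param window Window (point-locus) size in bp.
#' @return A `lociset`: data.frame with `chrom`, `start`, `length`, and
#'   attributes `L` (total bp) and `chrom_len`.
#' @export
wgs_loci <- function(n_chrom = 25L, chrom_len = 3e7, window = 5000) {
  n_win <- floor(chrom_len / window)
  starts <- (seq_len(n_win) - 1) * window
  out <- data.frame(
    chrom = rep(seq_len(n_chrom), each = n_win),
    start = rep(starts, n_chrom),
    length = window)
  structure(out, L = n_chrom * n_win * window, chrom_len = chrom_len,
            data_type = "WGS", class = c("lociset", "data.frame"))
}

#' Define random RAD-like loci
#'
#' Places `loci_per_chrom` non-overlapping 150 bp windows uniformly at
#' random on each chromosome.  Total site count L is 150 times the total
#' locus count.
#'
#' @param n_chrom,chrom_len Genome shape.
#' @param loci_per_chrom RAD loci per chromosome (400 or 2000 in the study
#'   grid).
#' @param locus_len Locus length in bp.
#' @param seed RNG seed for placement.
#' @return A `lociset` (see [wgs_loci()]).
#' @export
rad_loci <- function(n_chrom = 25L, chrom_len = 3e7, loci_per_chrom = 400L,
                     locus_len = 150, seed = 1L) {
  if (loci_per_chrom * locus_len > chrom_len) {
    stop("cannot place ", loci_per_chrom, " non-overlapping loci of ",
         locus_len, " bp on a ", chrom_len, " bp chromosome")
  }
  set.seed(seed)
  rows <- lapply(seq_len(n_chrom), function(ch) {
    if (loci_per_chrom == 0L) {
      return(data.frame(chrom = integer(), start = numeric(),
                        length = numeric()))
    }
    # uniform non-overlapping placement: sort draws in the reduced space,
    # then re-inflate by the cumulative locus length
    gap_space <- chrom_len - loci_per_chrom * locus_len
    starts <- sort(stats::runif(loci_per_chrom, 0, gap_space)) +
      (seq_len(loci_per_chrom) - 1) * locus_len
    data.frame(chrom = ch, start = floor(starts), length = locus_len)
  })
  out <- do.call(rbind, rows)
  structure(out, L = nrow(out) * locus_len, chrom_len = chrom_len,
            data_type = "RAD", class = c("lociset", "data.frame"))
}

#' Trace sampled haplotypes backward through the pedigree
#'
#' Exact pedigree-conditioned gene dropping for one chromosome: every
#' sampled haplotype is traced back through its carrier's parents, with a
#' shared per-meiosis crossover pattern (Poisson number of breakpoints,
#' uniform positions) deciding which parental haplotype each locus is
#' copied from.  Lineages of the same locus meeting in the same haplotype
#' coalesce.  The result records all pedigree-epoch coalescences (edges
#' with meiosis counts, i.e. branch lengths in generations) and the open
#' lineages that reached founder haplotypes.
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param samples data.frame with columns `id` (pedigree individual ids)
#'   and `time_ybp`; row order defines leaf order (sample i owns leaf
#'   haplotypes 2i-1 and 2i, 1-based).
#' @param loci A `lociset` restricted to one chromosome, or any data.frame
#'   with `start` and `length` columns.
#' @param spec A [chromosome_spec()].
#' @param seed RNG seed.
#' @return An `ancestryforest` for one chromosome.
#' @export
trace_pedigree_ancestry <- function(pedigree, samples, loci, spec, seed = 1L) {
  stopifnot(inherits(pedigree, "pedigree"), is.data.frame(samples))
  if (!all(samples$id %in% pedigree$id)) stop("unknown sample id")
  set.seed(seed)
  mid <- loci$start + loci$length / 2
  tr <- cpp_trace_ancestry(pedigree$mother, pedigree$father, pedigree$birth,
                           as.integer(samples$id), as.numeric(mid),
                           spec$length_bp, spec$recombination_rate,
                           pedigree$scenario$trajectory$duration)
  ord <- order(tr$open_locus, tr$open_node)
  structure(list(
    edges = list(child = tr$edge_child, parent = tr$edge_parent,
                 meioses = tr$edge_meioses, locus = tr$edge_locus,
                 year = tr$edge_year),
    open = list(locus = tr$open_locus[ord], node = tr$open_node[ord],
                hap = tr$open_hap[ord]),
    recap = NULL,
    n_leaves = tr$n_leaves, next_node = tr$next_node,
    loci = loci, spec = spec, samples = samples,
    gen_time = pedigree$scenario$life_history$expected_generation_time,
    duration = pedigree$scenario$trajectory$duration
  ), class = "ancestryforest")
}

#' Complete open founder lineages with a coalescent process
#'
#' Completes the genealogy of the open founder lineages in two stages.
#' First, an optional linked backward Wright-Fisher extension: lineages
#' are propagated through a virtual random-mating diploid population of
#' size `Ne_H` until `linked_gens` generations before present (or the
#' ancestral change point if earlier), preserving between-locus linkage --
#' this carries the long-range LD signal that the binned-LD estimator
#' reads back to its stated 2000-generation horizon.  Second, a
#' single-locus Kingman coalescent finishes each locus independently
#' under the ancestral size history (`Ne_H` until the change point,
#' `Ne_A` earlier), whose marginal tree distribution is identical to the
#' linked process.  Time is measured in generations
#' (`years / generation time`); the discrete life history is not modelled
#' backward.
#'
#' @param forest An `ancestryforest` from [trace_pedigree_ancestry()].
#' @param scenario The [demographic_scenario()] (supplies `Ne_H`, the
#'   ancestral change, and the generation time).
#' @param seed RNG seed.
#' @param linked_gens Horizon (generations before present) of the linked
#'   extension.  0 skips it, which leaves all marginal (single-locus)
#'   summaries such as the SFS unaffected but omits pre-pedigree LD.
#' @return The forest with `recap` edges filled in (fully coalesced).
#' @export
recapitate <- function(forest, scenario, seed = 1L, linked_gens = 2000) {
  stopifnot(inherits(forest, "ancestryforest"))
  set.seed(seed)
  gt <- scenario$life_history$expected_generation_time
  g0 <- forest$duration / gt
  anc <- scenario$ancestral
  ne_h <- scenario$trajectory$Ne_H
  ne_a <- if (anc$kind == "none") ne_h else anc$Ne_A
  gens_virtual <- max(0, round(min(linked_gens, anc$time_gen) - g0))
  open <- forest$open
  if (gens_virtual > 0 && length(open$node) > 0) {
    mid <- forest$loci$start + forest$loci$length / 2
    vx <- cpp_virtual_ancestry(open$locus, open$node, open$hap,
                               forest$next_node, as.numeric(mid),
                               forest$spec$length_bp,
                               forest$spec$recombination_rate,
                               ne_h, as.integer(gens_virtual))
    forest$edges <- list(
      child = c(forest$edges$child, vx$edge_child),
      parent = c(forest$edges$parent, vx$edge_parent),
      meioses = c(forest$edges$meioses, vx$edge_meioses),
      locus = c(forest$edges$locus, vx$edge_locus),
      year = c(forest$edges$year,
               as.integer(round(forest$duration + vx$edge_gen * gt))))
    forest$next_node <- vx$next_node
    ord <- order(vx$open_locus, vx$open_node)
    open <- list(locus = vx$open_locus[ord], node = vx$open_node[ord])
  }
  rc <- cpp_recapitate(open$locus, open$node, forest$next_node,
                       g0 + gens_virtual, ne_h, ne_a,
                       as.numeric(anc$time_gen))
  forest$recap <- list(child = rc$child, parent = rc$parent,
                       length_gen = rc$length_gen, locus = rc$locus,
                       time_gen = rc$time_gen)
  forest$next_node <- rc$next_node
  forest
}

#' Drop infinite-sites mutations on a completed ancestry forest
#'
#' Pedigree-epoch branches carry one Bernoulli mutation trial per meiosis
#' (probability `mu * locus length`); coalescent-epoch branches carry
#' Poisson(`mu * locus length * branch generations`) mutations.  Each
#' mutation gets a unique integer position inside its locus; sites
#' monomorphic across all sampled haplotypes are not emitted.
#'
#' @param forest A recapitated `ancestryforest`.
#' @param mu Per-bp per-generation mutation rate.
#' @param seed RNG seed.
#' @return A `varianttable` for the forest's chromosome: `chrom`, `pos`,
#'   `geno` (sites x individuals dosage matrix), `samples`, `L`.
#' @export
drop_mutations <- function(forest, mu = 1e-8, seed = 1L) {
  stopifnot(inherits(forest, "ancestryforest"))
  if (is.null(forest$recap)) stop("forest must be recapitated first")
  set.seed(seed)
  dm <- cpp_drop_mutations(
    forest$edges$child, forest$edges$parent, forest$edges$meioses,
    forest$edges$locus, forest$recap$child, forest$recap$parent,
    forest$recap$length_gen, forest$recap$locus,
    forest$n_leaves, forest$next_node,
    as.numeric(forest$loci$start), as.numeric(forest$loci$length), mu)
  n_ind <- nrow(forest$samples)
  n_sites <- length(dm$site_pos)
  geno <- matrix(0L, nrow = n_sites, ncol = n_ind)
  if (n_sites > 0) {
    site_of_carrier <- rep.int(seq_len(n_sites), diff(dm$carrier_offsets))
    ind_of_carrier <- dm$carriers %/% 2L + 1L
    idx <- (ind_of_carrier - 1L) * n_sites + site_of_carrier
    add <- tabulate(idx, nbins = n_sites * n_ind)
    geno <- matrix(as.integer(add), nrow = n_sites, ncol = n_ind)
    ord <- order(dm$site_pos)
    geno <- geno[ord, , drop = FALSE]
    dm$site_pos <- dm$site_pos[ord]
  }
  new_varianttable(chrom = rep.int(forest$spec$index, n_sites),
                   pos = dm$site_pos, geno = geno,
                   samples = forest$samples, L = attr(forest$loci, "L"))
}

new_varianttable <- function(chrom, pos, geno, samples, L) {
  samples$name <- sprintf("t%d_ind%03d", samples$time_ybp,
                          seq_len(nrow(samples)))
  structure(list(chrom = as.integer(chrom), pos = as.numeric(pos),
                 geno = geno, samples = samples, L = as.numeric(L)),
            class = "varianttable")
}

#' @export
print.varianttable <- function(x, ...) {
  cat("varianttable:", length(x$pos), "segregating sites,",
      nrow(x$samples), "diploid samples, L =", format(x$L, big.mark = ","),
      "bp\n")
  invisible(x)
}

#' Simulate genotypes for sampled individuals across the genome
#'
#' Runs [trace_pedigree_ancestry()], [recapitate()] and [drop_mutations()]
#' chromosome by chromosome over a locus set and concatenates the
#' per-chromosome variant tables.  The same pedigree is reused for every
#' chromosome with independent meiosis randomness.
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param samples data.frame(`id`, `time_ybp`).
#' @param loci A `lociset` covering all chromosomes.
#' @param seed Master seed; per-chromosome, per-stage seeds are derived.
#' @param linked_gens Linked-ancestry horizon passed to [recapitate()].
#'   The default (2000 generations) matches the binned-LD estimator's
#'   trajectory span; SFS-only analyses may use 0 (marginal distributions
#'   are unchanged).
#' @return A `varianttable`.
#' @export
simulate_variants <- function(pedigree, samples, loci, seed = 1L,
                              linked_gens = 2000) {
  scen <- pedigree$scenario
  chroms <- sort(unique(loci$chrom))
  parts <- vector("list", length(chroms))
  for (i in seq_along(parts)) {
    ch <- chroms[i]
    spec <- chromosome_spec(ch, attr(loci, "chrom_len"),
                            scen$recombination_rate)
    lc <- loci[loci$chrom == ch, , drop = FALSE]
    attr(lc, "L") <- sum(lc$length)
    forest <- trace_pedigree_ancestry(pedigree, samples, lc, spec,
                                      derive_seed(seed, "trace", ch))
    forest <- recapitate(forest, scen, derive_seed(seed, "recap", ch),
                         linked_gens = linked_gens)
    parts[[i]] <- drop_mutations(forest, scen$mutation_rate,
                                 derive_seed(seed, "mut", ch))
  }
  new_varianttable(
    chrom = unlist(lapply(parts, `[[`, "chrom")),
    pos = unlist(lapply(parts, `[[`, "pos")),
    geno = do.call(rbind, lapply(parts, `[[`, "geno")),
    samples = samples, L = attr(loci, "L"))
}

#' Extract the diploid dosage matrix for one timepoint
#'
#' Returns the sites x samples matrix of derived-allele dosages (0/1/2)
#' for the requested samples at one sampling time.  All sites in the table
#' are returned; sites fixed among the requested samples are retained here
#' and excluded later by [folded_sfs()].
#'
#' @param variants A `varianttable`.
#' @param timepoint Sampling time in ybp.
#' @param sample_ids Optional subset of pedigree individual ids (default:
#'   all samples at `timepoint`).
#' @return Integer matrix (sites x individuals) with column names.
#' @export
genotypes_at <- function(variants, timepoint, sample_ids = NULL) {
  stopifnot(inherits(variants, "varianttable"))
  keep <- variants$samples$time_ybp == timepoint
  if (!is.null(sample_ids)) {
    if (!all(sample_ids %in% variants$samples$id[keep])) {
      stop("unknown sample id for timepoint ", timepoint)
    }
    keep <- keep & variants$samples$id %in% sample_ids
  }
  m <- variants$geno[, keep, drop = FALSE]
  colnames(m) <- variants$samples$name[keep]
  m
}
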