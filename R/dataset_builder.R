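# Building analysis-ready datasets: temporal sampling schemes, data types,
# MAF filtering, and export.

#' Temporal sampling scheme
#'
#' `contemporary`: all n at 0 ybp.  `two_sample`: n/2 at 0 and n/2 at 120
#' ybp.  `serial`: n/5 at each of 0/30/60/90/120 ybp.
#'
#' @param kind Scheme kind.
#' @param n_total Total sample size (must split evenly).
#' @return A `samplingscheme` with an `allocation` (timepoint -> count).
#' @export
sampling_scheme <- function(kind = c("contemporary", "two_sample", "serial"),
                            n_total) {
  kind <- match.arg(kind)
  alloc <- switch(kind,
    contemporary = c("0" = n_total),
    two_sample = {
      if (n_total %% 2 != 0) stop("two_sample requires even n_total")
      c("0" = n_total / 2, "120" = n_total / 2)
    },
    serial = {
      if (n_total %% 5 != 0) stop("serial requires n_total divisible by 5")
      stats::setNames(rep(n_total / 5, 5), c("0", "30", "60", "90", "120"))
    })
  structure(list(kind = kind, n_total = as.integer(n_total),
                 allocation = alloc),
            class = "samplingscheme")
}

#' Draw sample individuals from pedigree checkpoints
#'
#' Uniform draws without replacement within each timepoint's recorded
#' checkpoint individuals; timepoints use different individuals by
#' construction.
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param scheme A [sampling_scheme()].
#' @param seed RNG seed.
#' @return data.frame(`id`, `time_ybp`) in timepoint-major order
#'   (0 ybp first).
#' @export
draw_samples <- function(pedigree, scheme, seed = 1L) {
  stopifnot(inherits(pedigree, "pedigree"),
            inherits(scheme, "samplingscheme"))
  set.seed(seed)
  rows <- lapply(names(scheme$allocation), function(tp) {
    want <- scheme$allocation[[tp]]
    pool <- pedigree$checkpoints[[tp]]
    if (is.null(pool) || length(pool) < want) {
      stop("checkpoint ", tp, " ybp holds ", length(pool),
           " recorded individuals; ", want, " requested")
    }
    data.frame(id = sort(resample(pool, want)),
               time_ybp = as.integer(tp))
  })
  do.call(rbind, rows)
}

#' Restrict a variant table to RAD-like loci
#'
#' Pure row filter: keeps only SNPs falling inside the windows of a RAD
#' locus set (windows shared across timepoints), and resets `L` to the
#' summed window length.
#'
#' @param variants A `varianttable` (e.g. whole-genome).
#' @param rad A `lociset` from [rad_loci()].
#' @return The filtered `varianttable` with window coordinates attached as
#'   attribute `windows`.
#' @export
rad_subset <- function(variants, rad) {
  stopifnot(inherits(variants, "varianttable"))
  keep <- logical(length(variants$pos))
  for (ch in unique(rad$chrom)) {
    w <- rad[rad$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    on_ch <- which(variants$chrom == ch)
    if (!length(on_ch)) next
    iv <- findInterval(variants$pos[on_ch], w$start)
    inside <- iv >= 1 & variants$pos[on_ch] < w$start[pmax(iv, 1)] +
      w$length[pmax(iv, 1)]
    keep[on_ch[inside]] <- TRUE
  }
  out <- new_varianttable(variants$chrom[keep], variants$pos[keep],
                          variants$geno[keep, , drop = FALSE],
                          variants$samples, attr(rad, "L"))
  attr(out, "windows") <- rad
  out
}

#' Apply a dataset-wide minor-allele-frequency filter
#'
#' Sites whose minor-allele frequency, pooled over all samples and
#' timepoints, is below `threshold` are removed; the total site count `L`
#' is unchanged (filtering mimics post-hoc SNP filtering, not a change in
#' sequencing effort).  Idempotent.
#'
#' @param variants A `varianttable`.
#' @param threshold Frequency in `[0, 0.5]`.
#' @return The filtered `varianttable`.
#' @export
apply_maf_filter <- function(variants, threshold) {
  stopifnot(inherits(variants, "varianttable"),
            threshold >= 0, threshold <= 0.5)
  if (threshold == 0) return(variants)
  n_hap <- 2 * nrow(variants$samples)
  p <- rowSums(variants$geno) / n_hap
  keep <- pmin(p, 1 - p) >= threshold
  out <- new_varianttable(variants$chrom[keep], variants$pos[keep],
                          variants$geno[keep, , drop = FALSE],
                          variants$samples, variants$L)
  attr(out, "windows") <- attr(variants, "windows")
  out
}

#' Per-timepoint folded SFS of a dataset
#'
#' @param variants A `varianttable`.
#' @return List of `foldedsfs`, one per sampling time present.
#' @export
dataset_sfs <- function(variants) {
  tps <- sort(unique(variants$samples$time_ybp))
  lapply(tps, function(tp) {
    folded_sfs(genotypes_at(variants, tp), variants$L, tp)
  })
}

# ---- VCF v4.2 export / import ----

#' Write a variant table as a minimal VCF v4.2 file
#'
#' Diploid unphased GT fields; REF/ALT are placeholder alleles (`A`/`T`)
#' since the simulation is infinite-sites; contig headers cover all
#' chromosomes present; sample names encode the sampling time
#' (`t120_ind007`).  Deterministic ordering (chromosome, then position).
#'
#' @param variants A `varianttable`.
#' @param path Output file path.
#' @param contig_length Declared contig length.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contig_length = 3e7) {
  stopifnot(inherits(variants, "varianttable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=declinesim",
    sprintf("##simulated_total_sites=%.0f", variants$L),
    sprintf("##contig=<ID=%d,length=%.0f>",
            sort(unique(variants$chrom)), contig_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", variants$samples$name), collapse = "\t")),
    con)
  if (length(variants$pos)) {
    o <- order(variants$chrom, variants$pos)
    gt <- c("0/0", "0/1", "1/1")[variants$geno[o, , drop = FALSE] + 1L]
    gt <- matrix(gt, nrow = length(o))
    body <- paste(variants$chrom[o], sprintf("%.0f", variants$pos[o] + 1),
                  ".", "A", "T", ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' Minimal parser for the subset of VCF v4.2 this package writes
#' (bi-allelic sites, GT-only FORMAT).  Sampling times are recovered from
#' the sample names.
#'
#' @param path VCF file path.
#' @return A `varianttable` (`samples$id` is the column index, as pedigree
#'   ids are not stored in VCF).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  L <- NA_real_
  lsite <- grep("^##simulated_total_sites=", lines, value = TRUE)
  if (length(lsite)) L <- as.numeric(sub(".*=", "", lsite[1]))
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header in ", path)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  snames <- cols[-(1:9)]
  time_ybp <- as.integer(sub("^t(\\d+)_.*$", "\\1", snames))
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    chrom <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    pos <- vapply(parts, function(p) as.numeric(p[2]) - 1, numeric(1))
    geno <- t(vapply(parts, function(p) {
      g <- p[-(1:9)]
      as.integer(substr(g, 1, 1)) + as.integer(substr(g, 3, 3))
    }, integer(length(snames))))
    if (length(snames) == 1L) geno <- matrix(geno, ncol = 1L)
  } else {
    chrom <- integer(0); pos <- numeric(0)
    geno <- matrix(integer(0), nrow = 0, ncol = length(snames))
  }
  new_varianttable(chrom, pos, geno,
                   data.frame(id = seq_along(snames), time_ybp = time_ybp),
                   L)
}
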