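# Folded site-frequency-spectrum computation and expectation.

#' Construct a folded SFS object
#'
#' @param counts Per-bin counts for minor-allele counts 1..floor(n/2).
#' @param n Number of sampled haplotypes.
#' @param L Total sites (bp), including monomorphic sites.
#' @param timepoint Sampling time in ybp.
#' @return A `foldedsfs` object.
#' @export
folded_sfs_obj <- function(counts, n, L, timepoint = 0) {
  stopifnot(length(counts) == floor(n / 2), all(counts >= 0))
  if (sum(counts) > L) stop("segregating sites exceed L")
  structure(list(timepoint = timepoint, n = as.integer(n), L = as.numeric(L),
                 counts = as.numeric(counts)),
            class = "foldedsfs")
}

#' @export
print.foldedsfs <- function(x, ...) {
  cat("folded SFS: t =", x$timepoint, "ybp, n =", x$n, "haplotypes,",
      sum(x$counts), "segregating sites, L =", format(x$L, big.mark = ","),
      "\n")
  invisible(x)
}

#' Folded SFS of a diploid dosage matrix
#'
#' Bin i counts the sites whose minor-allele count equals i among the
#' `2 * ncol(genotypes)` sampled haplotypes; sites monomorphic within the
#' sample are excluded from the bins (they contribute to the monomorphic
#' class `L - sum(counts)`).
#'
#' @param genotypes Sites x individuals dosage matrix (0/1/2, no missing).
#' @param L Total sites in bp.
#' @param timepoint Sampling time in ybp.
#' @return A `foldedsfs`.
#' @export
folded_sfs <- function(genotypes, L, timepoint = 0) {
  if (any(is.na(genotypes))) stop("missing genotypes not supported")
  n <- 2L * ncol(genotypes)
  dc <- rowSums(genotypes)
  if (any(dc > n)) stop("dosages exceed haplotype count")
  minor <- pmin(dc, n - dc)
  minor <- minor[minor > 0]
  folded_sfs_obj(tabulate(minor, nbins = floor(n / 2)), n, L, timepoint)
}

#' Inject singleton genotyping errors into a folded SFS
#'
#' Models per-site genotyping error as extra singleton sites: bin 1 is
#' incremented by `round(rate * L)` (deterministic mode, the default, for
#' reproducible bias experiments) or by a Poisson draw with that mean
#' (stochastic mode); all other bins are unchanged.
#'
#' @param sfs A `foldedsfs`.
#' @param rate Singletons per site (e.g. 1e-3, 1e-4, 1e-5).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @return The modified `foldedsfs`.
#' @export
inject_singletons <- function(sfs, rate,
                              mode = c("deterministic", "stochastic")) {
  stopifnot(inherits(sfs, "foldedsfs"), rate >= 0)
  mode <- match.arg(mode)
  extra <- if (mode == "deterministic") round(rate * sfs$L) else
    stats::rpois(1L, rate * sfs$L)
  sfs$counts[1] <- sfs$counts[1] + extra
  sfs
}

#' Inject singletons into selected timepoints of a dataset's SFS list
#'
#' Genotyping errors are more likely in historical samples, so the default
#' targets the historical timepoints only; pass `timepoints = 0` for the
#' contemporary-only experiment, or an explicit vector of times.
#'
#' @param sfs_list List of `foldedsfs` objects (one per timepoint).
#' @param rate Singletons per site.
#' @param timepoints `"historical"` (every timepoint except 0 ybp),
#'   `"all"`, or a numeric vector of times in ybp.
#' @param mode Passed to [inject_singletons()].
#' @return The modified list.
#' @export
inject_dataset_singletons <- function(sfs_list, rate,
                                      timepoints = "historical",
                                      mode = "deterministic") {
  hit <- function(tp) {
    if (identical(timepoints, "historical")) tp != 0
    else if (identical(timepoints, "all")) TRUE
    else tp %in% timepoints
  }
  lapply(sfs_list, function(s) {
    if (hit(s$timepoint)) inject_singletons(s, rate, mode) else s
  })
}

# ---- expected folded SFS under a parametric size history ----

# Stable weights W[i, j] such that E[xi_i] = mu * L * sum_j W[i,j] F_j,
# where F_j = int_0^inf exp(-b_j tau(t)) dt, tau(t) = int_0^t ds / (2N(s)),
# b_j = j(j-1)/2.  The classical spectral coefficients for P[A(t) = k]
# suffer catastrophic cancellation for n beyond ~50; this three-term
# recursion in j is numerically stable for n in the thousands.
# Verified against the independent lineage-count ODE integrator
# (cpp_esfs_sk) in the test suite.
pk_weight_cache <- new.env(parent = emptyenv())

pk_weights <- function(n) {
  key <- as.character(n)
  if (!is.null(pk_weight_cache[[key]])) return(pk_weight_cache[[key]])
  i <- seq_len(n - 1)
  W <- matrix(0, nrow = n - 1, ncol = n - 1)  # columns j = 2..n
  W[, 1] <- 6 / (n + 1)
  if (n >= 3) W[, 2] <- 30 * (n - 2 * i) / ((n + 1) * (n + 2))
  if (n >= 4) {
    for (j in 2:(n - 2)) {
      a <- -((1 + j) * (3 + 2 * j) * (n - j)) /
        ((2 * j - 1) * j * (n + j + 1))
      b <- ((3 + 2 * j) * (n - 2 * i)) / (j * (n + j + 1))
      W[, j + 1] <- a * W[, j - 1] + b * W[, j]
    }
  }
  pk_weight_cache[[key]] <- W
  W
}

# F_j for a piecewise-constant diploid size history.
# t_bounds: epoch starts in generations (t_bounds[1] = 0, increasing);
# N_epoch: size per epoch, last epoch extends to infinity.
esfs_Fj <- function(n, t_bounds, N_epoch) {
  b <- seq(2, n) * (seq(2, n) - 1) / 2
  J <- length(N_epoch)
  dtau <- diff(t_bounds) / (2 * N_epoch[-J])
  tau <- c(0, cumsum(dtau))                      # length J
  E <- exp(-outer(b, tau))                       # (n-1) x J
  if (J > 1) {
    body <- (E[, -J, drop = FALSE] - E[, -1, drop = FALSE]) %*%
      (2 * N_epoch[-J]) / b
  } else {
    body <- 0
  }
  tail <- E[, J] * 2 * N_epoch[J] / b
  as.vector(body) + tail
}

#' Expected folded SFS under a demographic model
#'
#' Computes the expected per-bin site counts for a sample of `n`
#' haplotypes taken `sample_time` years before present from a population
#' whose size follows `model` (see [demography_model()]).  The history is
#' truncated at the sampling time.  The size function is discretised onto
#' a log-spaced grid of at least `grid_points` epochs spanning 1e-2 to 1e6
#' generations; expectations use the stable weight recursion with exact
#' per-epoch integrals, so the only numerical error is the grid
#' discretisation of exponential-change segments.
#'
#' @param model A `demographymodel`.
#' @param n Haplotypes sampled.
#' @param L Total sites (bp).
#' @param mu Per-bp per-generation mutation rate.
#' @param sample_time Sampling time, ybp.
#' @param gen_time Generation time in years.
#' @param grid_points Epochs in the discretisation grid.
#' @return A real-valued `foldedsfs`.
#' @export
expected_folded_sfs <- function(model, n, L, mu, sample_time = 0,
                                gen_time = 1, grid_points = 512) {
  stopifnot(n >= 2)
  ep <- model_epochs(model, sample_time, gen_time, grid_points)
  xi <- expected_unfolded_sfs_counts(n, L, mu, ep)
  nb <- floor(n / 2)
  i <- seq_len(nb)
  folded <- xi[i] + ifelse(n - i != i, xi[n - i], 0)
  out <- folded_sfs_obj(rep(0, nb), n, L, sample_time)
  out$counts <- folded
  out
}

expected_unfolded_sfs_counts <- function(n, L, mu, epochs) {
  W <- pk_weights(n)
  Fj <- esfs_Fj(n, epochs$t_bounds, epochs$N)
  xi <- mu * L * as.vector(W %*% Fj)
  pmax(xi, 0)
}

# ---- folded-SFS text format ----
# One line per timepoint: timepoint n L count_1 ... count_floor(n/2),
# whitespace-separated, '#' comments allowed.

#' Write folded SFS objects to a text file
#'
#' @param sfs_list A `foldedsfs` or list of them.
#' @param path Output file.
#' @export
write_sfs <- function(sfs_list, path) {
  if (inherits(sfs_list, "foldedsfs")) sfs_list <- list(sfs_list)
  lines <- vapply(sfs_list, function(s) {
    paste(c(s$timepoint, s$n, format(s$L, scientific = FALSE),
            format(s$counts, scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c("# timepoint\tn\tL\tcounts[1..n/2]", lines), path)
  invisible(path)
}

#' Read folded SFS objects from a text file
#'
#' @param path File written by [write_sfs()].
#' @return List of `foldedsfs` objects.
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(lines, function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    folded_sfs_obj(v[-(1:3)], v[2], v[3], v[1])
  })
}
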