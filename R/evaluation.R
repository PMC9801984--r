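# Evaluation layer: decline-detection criteria, power, MAPE, log-ratio
# bias, and the aggregation rules used for summary tables.

#' Construct an inference record
#'
#' One record per (dataset, method): the scenario truth, the method's
#' point estimates of contemporary and historic size, and either an
#' AIC-classification payload (`best_model`) or 95% CIs, depending on the
#' method's pathway.
#'
#' @param scenario_id Scenario label.
#' @param method Method label (e.g. `"sfs"`, `"ld_point"`, `"ld_traj"`).
#' @param pathway `"aic"` or `"ci"` (decline-detection pathway).
#' @param scheme,n_total,data_type Design factors.
#' @param true_Ne_C,true_Ne_H Simulated truth.
#' @param Ne_C_hat,Ne_H_hat Point estimates (may be `Inf`).
#' @param best_model Winning model id (AIC pathway).
#' @param Ne_C_lo,Ne_C_hi,Ne_H_lo,Ne_H_hi 95% CIs (CI pathway).
#' @param declining_truth Is the simulated scenario a decline?
#' @param flags Free-form status flags.
#' @return A one-row data.frame.
#' @export
inference_record <- function(scenario_id, method, pathway, scheme, n_total,
                             data_type, true_Ne_C, true_Ne_H,
                             Ne_C_hat, Ne_H_hat, best_model = NA_character_,
                             Ne_C_lo = NA_real_, Ne_C_hi = NA_real_,
                             Ne_H_lo = NA_real_, Ne_H_hi = NA_real_,
                             declining_truth = true_Ne_C < true_Ne_H,
                             flags = "ok") {
  stopifnot(pathway %in% c("aic", "ci"))
  data.frame(scenario_id = scenario_id, method = method, pathway = pathway,
             scheme = scheme, n_total = n_total, data_type = data_type,
             true_Ne_C = true_Ne_C, true_Ne_H = true_Ne_H,
             Ne_C_hat = Ne_C_hat, Ne_H_hat = Ne_H_hat,
             best_model = best_model, Ne_C_lo = Ne_C_lo,
             Ne_C_hi = Ne_C_hi, Ne_H_lo = Ne_H_lo, Ne_H_hi = Ne_H_hi,
             declining_truth = declining_truth, flags = flags,
             stringsAsFactors = FALSE)
}

recent_change_models <- c("M2_recent", "M4_both")

#' Was a decline detected?
#'
#' AIC pathway: a model including a recent change won model selection AND
#' the contemporary estimate is below the historic one.  CI pathway: the
#' upper 95% CI of the contemporary estimate lies strictly below the lower
#' 95% CI of the historic estimate; infinite estimates are never counted
#' as detections, and a boundary tie counts as not detected.
#'
#' @param record A one-row record from [inference_record()].
#' @return Logical.
#' @export
decline_detected <- function(record) {
  record <- as.list(record)
  if (record$pathway == "aic") {
    return(record$best_model %in% recent_change_models &&
             is.finite(record$Ne_C_hat) && is.finite(record$Ne_H_hat) &&
             record$Ne_C_hat < record$Ne_H_hat)
  }
  if (is.na(record$Ne_C_hi) || is.na(record$Ne_H_lo)) {
    stop("CI pathway requires CIs on both estimates")
  }
  if (!is.finite(record$Ne_C_hat) || !is.finite(record$Ne_H_hat)) {
    return(FALSE)
  }
  is.finite(record$Ne_C_hi) && record$Ne_C_hi < record$Ne_H_lo
}

#' Was a constant-size history correctly inferred?
#'
#' AIC pathway: a model with constant recent size (M1 or M3) won model
#' selection.  CI pathway: the two 95% CIs overlap.
#'
#' @param record A one-row record.
#' @return Logical.
#' @export
stable_correct <- function(record) {
  record <- as.list(record)
  if (record$pathway == "aic") {
    return(!(record$best_model %in% recent_change_models))
  }
  if (is.na(record$Ne_C_hi) || is.na(record$Ne_H_lo)) {
    stop("CI pathway requires CIs on both estimates")
  }
  # overlap of [C_lo, C_hi] and [H_lo, H_hi]
  !(record$Ne_C_hi < record$Ne_H_lo || record$Ne_H_hi < record$Ne_C_lo)
}

#' Fraction of records with the correct call
#'
#' For declining truth, the fraction with a detected decline; for constant
#' truth, the fraction called stable.  All records must share the same
#' truth.
#'
#' @param records Records data.frame (rows from [inference_record()]).
#' @return Fraction in `[0, 1]`.
#' @export
power_of <- function(records) {
  if (nrow(records) == 0L) stop("empty cell: power undefined")
  if (length(unique(records$declining_truth)) != 1L) {
    stop("records mix declining and constant truths")
  }
  calls <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, , drop = FALSE]
    if (r$declining_truth) decline_detected(r) else stable_correct(r)
  }, logical(1))
  mean(calls)
}

#' Mean absolute percentage error
#'
#' `(100/n) * sum(|inferred_i - simulated_i| / simulated_i)` over records;
#' infinite or flagged estimates must be excluded upstream.
#'
#' @param records Records data.frame.
#' @param target `"Ne_H"` or `"Ne_C"`.
#' @return Percent error (scalar).
#' @export
mape <- function(records, target = c("Ne_H", "Ne_C")) {
  target <- match.arg(target)
  inferred <- records[[paste0(target, "_hat")]]
  simulated <- records[[paste0("true_", target)]]
  keep <- is.finite(inferred) & is.finite(simulated)
  inferred <- inferred[keep]; simulated <- simulated[keep]
  if (length(inferred) == 0L) stop("no finite records for MAPE")
  if (any(simulated <= 0)) stop("simulated values must be positive")
  100 / length(inferred) * sum(abs(inferred - simulated) / simulated)
}

#' Log10 ratio of inferred to simulated size
#'
#' @param record A one-row record.
#' @param target `"Ne_H"` or `"Ne_C"`.
#' @return `log10(inferred / simulated)`; `NA` with a flag for infinite
#'   estimates.
#' @export
log10_ratio <- function(record, target = c("Ne_H", "Ne_C")) {
  target <- match.arg(target)
  record <- as.list(record)
  inferred <- record[[paste0(target, "_hat")]]
  simulated <- record[[paste0("true_", target)]]
  if (!is.finite(inferred)) {
    return(structure(NA_real_, flag = "infinite_estimate"))
  }
  stopifnot(inferred > 0, simulated > 0)
  log10(inferred / simulated)
}

#' Aggregated power / error / bias report
#'
#' Power is tabulated per scenario x method x scheme x size x data type.
#' MAPE follows the published aggregation subset: constant-size, fast
#' decline from 30 ybp (lambda 0.95) and slow decline from 120 ybp
#' (lambda 0.99) scenarios, generation time 1, both initial sizes; WGS and
#' the 50k-RAD data type are aggregated separately; unlinked-pair LD
#' records at n = 50 are excluded (they return many infinite estimates);
#' infinite estimates are counted per cell.
#'
#' @param records Records data.frame.
#' @param scenarios Scenario table (from [enumerate_scenarios()]) used to
#'   identify the aggregation subset.
#' @param mape_exclude_method Method label excluded from MAPE at n = 50.
#' @return List of data.frames: `power`, `mape`, `infinite_counts`.
#' @export
aggregate_report <- function(records, scenarios,
                             mape_exclude_method = "ld_point") {
  power_tab <- do.call(rbind, lapply(
    split(records, records[, c("scenario_id", "method", "scheme",
                               "n_total", "data_type")], drop = TRUE),
    function(cell) {
      data.frame(scenario_id = cell$scenario_id[1], method = cell$method[1],
                 scheme = cell$scheme[1], n_total = cell$n_total[1],
                 data_type = cell$data_type[1], n = nrow(cell),
                 power = power_of(cell), stringsAsFactors = FALSE)
    }))
  rownames(power_tab) <- NULL

  agg_ids <- scenarios$scenario_id[
    scenarios$life_history == "G1" & scenarios$ancestral == "none" &
      (scenarios$lambda == 1 |
         (scenarios$lambda == 0.95 & scenarios$T_dec == 30) |
         (scenarios$lambda == 0.99 & scenarios$T_dec == 120))]
  sub <- records[records$scenario_id %in% agg_ids, , drop = FALSE]
  sub <- sub[!(sub$method == mape_exclude_method & sub$n_total == 50), ,
             drop = FALSE]
  mape_tab <- do.call(rbind, lapply(
    split(sub, sub[, c("method", "data_type")], drop = TRUE),
    function(cell) {
      fin_c <- is.finite(cell$Ne_C_hat); fin_h <- is.finite(cell$Ne_H_hat)
      data.frame(
        method = cell$method[1], data_type = cell$data_type[1],
        n = nrow(cell),
        mape_Ne_H = if (any(fin_h)) mape(cell[fin_h, ], "Ne_H") else NA_real_,
        mape_Ne_C = if (any(fin_c)) mape(cell[fin_c, ], "Ne_C") else NA_real_,
        stringsAsFactors = FALSE)
    }))
  rownames(mape_tab) <- NULL

  inf_tab <- do.call(rbind, lapply(
    split(records, records[, c("method", "scheme", "n_total", "data_type")],
          drop = TRUE),
    function(cell) {
      data.frame(method = cell$method[1], scheme = cell$scheme[1],
                 n_total = cell$n_total[1], data_type = cell$data_type[1],
                 n = nrow(cell),
                 n_infinite = sum(!is.finite(cell$Ne_C_hat) |
                                    !is.finite(cell$Ne_H_hat)),
                 stringsAsFactors = FALSE)
    }))
  rownames(inf_tab) <- NULL
  list(power = power_tab, mape = mape_tab, infinite_counts = inf_tab)
}
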