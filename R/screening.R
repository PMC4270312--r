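# Vehicle normalization, replicate aggregation, hit calling at the
# normalized-ER-calcium < 0.9 rule, and plate QC against positive controls.

#' Normalize well readouts to the DMSO vehicle mean
#'
#' `normalized_value = well readout / mean(vehicle well readouts)`, so the
#' vehicle wells' normalized values average exactly 1 by construction. The
#' same normalizer serves the calcium readout ("normalized ER calcium"), TMRM
#' intensities and ELISA levels (all reported relative to DMSO = 1).
#'
#' @param summaries data.frame with one row per well, containing `address`
#'   and the readout column; typically rbind-ed [summarize_well()] rows.
#' @param layout a [plate_layout()].
#' @param value_col name of the readout column (default `"mean_peak"`).
#' @return `plate_result` data.frame: layout columns + readout +
#'   `normalized_value` (+ `n_cells`/`n_responsive`/`valid` when present).
#' @export
normalize_to_vehicle <- function(summaries, layout, value_col = "mean_peak") {
  stopifnot(inherits(layout, "plate_layout"))
  if (!value_col %in% names(summaries)) {
    stop_fs("summaries lack a '%s' column", value_col)
  }
  merged <- merge(layout$wells, summaries, by = "address", sort = FALSE)
  if (!"valid" %in% names(merged)) merged$valid <- is.finite(merged[[value_col]])
  veh <- merged$role == "vehicle" & merged$valid
  if (!any(veh)) stop_fs("no valid vehicle wells on the plate")
  veh_mean <- mean(merged[[value_col]][veh])
  if (!is.finite(veh_mean) || veh_mean <= 0) {
    stop_fs("vehicle mean readout must be positive, got %g", veh_mean)
  }
  merged$normalized_value <- merged[[value_col]] / veh_mean
  class(merged) <- c("plate_result", "data.frame")
  attr(merged, "vehicle_mean") <- veh_mean
  attr(merged, "value_col") <- value_col
  merged
}

#' Aggregate replicate wells per compound
#'
#' Wells flagged invalid, and wells whose responsive-cell fraction falls below
#' `min_responsive_frac` (the toxicity-interference proxy: compounds toxic to
#' the cells leave too few responders to measure calcium release), are dropped
#' and counted; a compound whose wells were dropped for low responsiveness is
#' annotated `toxicity_interference` and, with no valid well left, not scored.
#'
#' @param plate a `plate_result` from [normalize_to_vehicle()].
#' @param min_responsive_frac well-exclusion threshold on
#'   `n_responsive/n_cells` (used only when those columns are present).
#' @return data.frame per test compound: `compound_id, norm_mean, norm_sd,
#'   n_wells, n_dropped, toxicity_interference`.
#' @export
aggregate_replicates <- function(plate, min_responsive_frac = 0.2) {
  stopifnot(inherits(plate, "plate_result"))
  tst <- plate[plate$role == "test", , drop = FALSE]
  if (nrow(tst) == 0L) stop_fs("plate has no test wells")
  ok <- tst$valid
  tox_well <- rep(FALSE, nrow(tst))
  if (all(c("n_responsive", "n_cells") %in% names(tst))) {
    tox_well <- tst$n_responsive / tst$n_cells < min_responsive_frac
    ok <- ok & !tox_well
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(tst)), tst$compound_id), function(i) {
    vals <- tst$normalized_value[i][ok[i]]
    data.frame(
      compound_id = tst$compound_id[i[1]],
      norm_mean = if (length(vals)) mean(vals) else NA_real_,
      norm_sd = if (length(vals) >= 2L) stats::sd(vals) else NA_real_,
      n_wells = length(vals),
      n_dropped = sum(!ok[i]),
      toxicity_interference = any(tox_well[i]) && length(vals) == 0L,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Call active compounds
#'
#' A compound is active iff its replicate-mean normalized value is strictly
#' below the threshold (default 0.9: "normalized ER calcium < 0.9").
#' Unscored compounds (no valid wells) get `NA`.
#'
#' @param per_compound table from [aggregate_replicates()].
#' @param threshold hit threshold on the normalized value.
#' @return the input table with an `active` logical column.
#' @export
call_hits <- function(per_compound, threshold = 0.9) {
  if (nrow(per_compound) == 0L) stop_fs("empty compound table")
  per_compound$active <- ifelse(is.na(per_compound$norm_mean), NA,
                                per_compound$norm_mean < threshold)
  per_compound
}

#' Plate QC from positive-control wells
#'
#' Each positive control (SERCA/ER-calcium blockers dispensed on every plate)
#' must itself read below the hit threshold; the plate passes iff all do.
#'
#' @param plate a `plate_result`.
#' @param threshold normalized-value pass threshold (default 0.9).
#' @return list of class `qc_report`: `controls` data.frame
#'   (`compound_id, normalized_value, pass`), `plate_pass`, `reason`.
#' @export
qc_plate <- function(plate, threshold = 0.9) {
  stopifnot(inherits(plate, "plate_result"))
  pc <- plate[plate$role == "positive_control" & plate$valid, , drop = FALSE]
  if (nrow(pc) == 0L) {
    return(structure(list(controls = data.frame(), plate_pass = FALSE,
                          reason = "no positive-control wells"),
                     class = "qc_report"))
  }
  per <- vapply(split(pc$normalized_value, pc$compound_id), mean, 1.0)
  controls <- data.frame(compound_id = names(per), normalized_value = unname(per),
                         pass = unname(per) < threshold, stringsAsFactors = FALSE)
  structure(list(controls = controls, plate_pass = all(controls$pass),
                 reason = if (all(controls$pass)) "all positive controls pass"
                          else paste("failing controls:",
                                     paste(controls$compound_id[!controls$pass],
                                           collapse = ", "))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> plate %s: %s\n",
              if (x$plate_pass) "PASS" else "FAIL", x$reason))
  if (nrow(x$controls)) print(x$controls, row.names = FALSE)
  invisible(x)
}

#' Per-compound Dunnett statistics against the vehicle wells
#'
#' Forms one group per test compound (its replicate wells' normalized values)
#' plus the vehicle group, and runs [anova_dunnett()] with vehicle as control.
#'
#' @param plate a `plate_result`.
#' @param compounds optional subset of compound ids.
#' @param ... passed to [anova_dunnett()].
#' @return a `dunnett_result`.
#' @export
plate_dunnett <- function(plate, compounds = NULL, ...) {
  stopifnot(inherits(plate, "plate_result"))
  veh <- plate$normalized_value[plate$role == "vehicle" & plate$valid]
  tst <- plate[plate$role == "test" & plate$valid, , drop = FALSE]
  if (!is.null(compounds)) tst <- tst[tst$compound_id %in% compounds, , drop = FALSE]
  groups <- c(list(vehicle = veh), split(tst$normalized_value, tst$compound_id))
  anova_dunnett(groups, control = "vehicle", ...)
}
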