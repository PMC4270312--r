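# Sandwich-ELISA calibration and back-calculation: standards are fit with a
# 4PL curve and unknown samples are inverted through it.

ELISA_ANALYTES <- c("Abeta38", "Abeta40", "Abeta42", "sAPPalpha", "sAPPbeta")

#' Fit an ELISA calibration curve from standards
#'
#' @param standard_concs known standard concentrations (>= 6 levels).
#' @param signals measured signals, one per standard well; replicates allowed
#'   (same concentration repeated).
#' @param analyte one of `r paste(ELISA_ANALYTES, collapse = ", ")`.
#' @return object of class `elisa_calibration`: `analyte`, `curve`
#'   (a [four_pl()]), `range` (lowest/highest standard), `span_warning`.
#' @export
elisa_calibration <- function(standard_concs, signals,
                              analyte = c("Abeta38", "Abeta40", "Abeta42",
                                          "sAPPalpha", "sAPPbeta")) {
  analyte <- match.arg(analyte)
  if (length(unique(standard_concs)) < 6L) {
    stop_fs("calibration needs >= 6 distinct standards")
  }
  if (diff(range(signals)) == 0) stop_fs("all standards read identically")
  fit <- fit_4pl(standard_concs, signals)
  if (isTRUE(fit$degenerate)) stop_fs("degenerate calibration fit (flat standards)")
  span <- log10(max(standard_concs) / min(standard_concs))
  structure(list(analyte = analyte, curve = fit$params, fit = fit,
                 range = range(standard_concs),
                 span_warning = span < 3),
            class = "elisa_calibration")
}

#' Back-calculate sample concentrations through a calibration curve
#'
#' Replicate signals are averaged per sample, then inverted through the 4PL
#' calibration. Samples outside the invertible signal range or outside the
#' standard concentration range are flagged, never silently clipped.
#'
#' @param calib an [elisa_calibration()].
#' @param signals data.frame with `sample_id` and `signal` columns (one row
#'   per replicate well), e.g. the `type == "sample"` rows of
#'   [simulate_elisa_plate()] output.
#' @return data.frame `sample_id, mean_signal, n_replicates, conc, flag`
#'   (flag: `"ok"`, `"below_range"`, `"above_range"`, `"not_invertible"`).
#' @export
quantify_samples <- function(calib, signals) {
  stopifnot(inherits(calib, "elisa_calibration"))
  if (!all(c("sample_id", "signal") %in% names(signals))) {
    stop_fs("signals need sample_id and signal columns")
  }
  sp <- split(signals$signal, signals$sample_id)
  cv <- calib$curve
  lo <- min(cv$bottom, cv$top); hi <- max(cv$bottom, cv$top)
  out <- do.call(rbind, lapply(names(sp), function(id) {
    m <- mean(sp[[id]])
    if (m <= lo || m >= hi) {
      return(data.frame(sample_id = id, mean_signal = m,
                        n_replicates = length(sp[[id]]), conc = NA_real_,
                        flag = "not_invertible", stringsAsFactors = FALSE))
    }
    conc <- invert_4pl(cv, m)
    flag <- if (conc < calib$range[1]) "below_range"
            else if (conc > calib$range[2]) "above_range" else "ok"
    data.frame(sample_id = id, mean_signal = m,
               n_replicates = length(sp[[id]]), conc = conc, flag = flag,
               stringsAsFactors = FALSE)
  }))
  # preserve first-appearance order of samples
  out[match(unique(signals$sample_id), out$sample_id), , drop = FALSE]
}
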