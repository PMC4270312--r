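# Per-cell YFP/CFP ratio traces, delta-F/F0 normalization, peak amplitude,
# responder filtering and well summaries.

#' Extract a per-cell YFP/CFP ratio trace from an image stack
#'
#' For each frame the ratio is mean(YFP pixels of the cell) / mean(CFP pixels
#' of the cell), using a fixed label image (segmentation is performed once on
#' the reference frame and reused across the short time-lapse).
#'
#' Segmentation masks dilate cells by roughly the smoothing radius, so a thin
#' rim of background pixels is usually included; with `background = "field"`
#' the per-frame, per-channel mean of the unlabeled (label 0) pixels is
#' subtracted before ratioing, which removes the resulting ratio bias.
#'
#' @param stack list with `cfp` and `yfp` arrays (`H x W x n_frames`).
#' @param labels cell label matrix.
#' @param cell_id label of the cell to extract.
#' @param background `"none"`, `"field"` (estimate from unlabeled pixels), or
#'   a numeric length-2 vector `c(cfp, yfp)` of fixed background levels.
#' @return numeric ratio series (one value per frame).
#' @export
extract_ratio_trace <- function(stack, labels, cell_id, background = "none") {
  sel <- labels == cell_id
  if (!any(sel)) stop_fs("cell %s not present in label image", cell_id)
  n_frames <- dim(stack$cfp)[3]
  idx <- which(sel)
  npix <- length(idx)
  HW <- prod(dim(labels))
  bg_idx <- if (identical(background, "field")) which(labels == 0) else integer(0)
  vapply(seq_len(n_frames), function(f) {
    off <- (f - 1L) * HW
    bg <- if (identical(background, "field")) {
      c(mean(stack$cfp[bg_idx + off]), mean(stack$yfp[bg_idx + off]))
    } else if (is.numeric(background)) {
      rep_len(background, 2L)
    } else {
      c(0, 0)
    }
    cfp_mean <- sum(stack$cfp[idx + off]) / npix - bg[1]
    if (cfp_mean <= 0) {
      stop_fs("cell %s has nonpositive CFP mean at frame %d", cell_id, f)
    }
    (sum(stack$yfp[idx + off]) / npix - bg[2]) / cfp_mean
  }, 1.0)
}

#' Normalize a ratio trace to delta-F/F0
#'
#' `dff(t) = (F(t) - F0)/F0` with `F0` the mean of all pre-dispense frames
#' (the time points preceding agonist application). The peak amplitude is the
#' maximum dff over the frames at/after the dispense index.
#'
#' @param ratio numeric ratio series.
#' @param schedule an [acq_schedule()] (supplies the dispense index).
#' @param threshold responder threshold on the peak (see
#'   [classify_responsive()]).
#' @param cell_id optional identifier carried through.
#' @return object of class `calcium_trace`: `ratio`, `f0`, `dff`,
#'   `peak_amplitude`, `responsive`, `cell_id`.
#' @export
compute_dff <- function(ratio, schedule = default_schedule(), threshold = 0.1,
                        cell_id = NA_integer_) {
  di <- schedule$dispense_index
  if (length(ratio) != length(schedule$timestamps)) {
    stop_fs("trace length (%d) does not match schedule (%d frames)",
            length(ratio), length(schedule$timestamps))
  }
  f0 <- mean(ratio[seq_len(di - 1L)])
  if (!is.finite(f0) || f0 <= 0) stop_fs("baseline F0 must be positive")
  dff <- (ratio - f0) / f0
  peak <- max(dff[seq(di, length(ratio))])
  structure(list(cell_id = cell_id, ratio = ratio, f0 = f0, dff = dff,
                 peak_amplitude = peak,
                 responsive = classify_responsive(peak, threshold)),
            class = "calcium_trace")
}

#' Peak amplitude of a calcium trace
#' @param trace a `calcium_trace` from [compute_dff()].
#' @return maximum post-dispense delta-F/F0.
#' @export
peak_amplitude <- function(trace) {
  stopifnot(inherits(trace, "calcium_trace"))
  trace$peak_amplitude
}

#' Responder classification
#'
#' A cell is responsive iff its peak delta-F/F0 reaches the threshold
#' (inclusive boundary). The threshold is assay-defined; default 0.1.
#'
#' @param peak peak delta-F/F0.
#' @param threshold nonnegative responder threshold.
#' @return logical.
#' @export
classify_responsive <- function(peak, threshold = 0.1) {
  if (threshold < 0) stop_fs("responder threshold must be >= 0")
  peak >= threshold
}

#' Summarize a well from its per-cell traces
#'
#' The well readout is the mean peak amplitude over responsive cells only;
#' wells with zero responsive cells are flagged invalid and excluded
#' downstream.
#'
#' @param traces list of `calcium_trace` objects, or a numeric matrix of
#'   ratio series (cells x frames) which is first normalized per
#'   [compute_dff()].
#' @param schedule an [acq_schedule()] (used for the matrix input form).
#' @param threshold responder threshold.
#' @param address well address label.
#' @return one-row data.frame: `address, n_cells, n_responsive, mean_peak,
#'   sd_peak, valid`.
#' @export
summarize_well <- function(traces, schedule = default_schedule(),
                           threshold = 0.1, address = NA_character_) {
  if (is.matrix(traces)) {
    traces <- lapply(seq_len(nrow(traces)), function(i) {
      compute_dff(traces[i, ], schedule, threshold, cell_id = i)
    })
  }
  if (length(traces) == 0L) stop_fs("no traces to summarize")
  peaks <- vapply(traces, peak_amplitude, 1.0)
  resp <- vapply(traces, function(t) t$responsive, TRUE)
  n_resp <- sum(resp)
  if (n_resp == 0L) warn_fs("well %s has no responsive cells", address)
  data.frame(
    address = address,
    n_cells = length(traces),
    n_responsive = n_resp,
    mean_peak = if (n_resp >= 1L) mean(peaks[resp]) else NA_real_,
    sd_peak = if (n_resp >= 2L) stats::sd(peaks[resp]) else NA_real_,
    valid = n_resp >= 1L,
    stringsAsFactors = FALSE
  )
}

#' Export per-cell traces as a tidy table
#'
#' @param traces list of `calcium_trace` objects.
#' @param schedule an [acq_schedule()].
#' @param address well address written into the table.
#' @return data.frame `well, cell_id, t_s, ratio, dff`.
#' @export
trace_table <- function(traces, schedule = default_schedule(),
                        address = NA_character_) {
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(well = address, cell_id = tr$cell_id,
               t_s = schedule$timestamps, ratio = tr$ratio, dff = tr$dff,
               stringsAsFactors = FALSE)
  }))
}
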