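# Nuclei detection on the far-red channel, nuclei-seeded cell boundary
# growing on the cytoplasmic (CFP+YFP) signal, edge-cell exclusion, and
# field-level intensity quantification for the TMRM assay.

#' Detect nuclei in a far-red nuclear-dye frame
#'
#' Gaussian smoothing, thresholding (Otsu by default, so detection is
#' invariant under uniform intensity scaling), connected components, and a
#' distance-transform watershed split of fused nuclei: within each component,
#' pixels at >= `marker_frac` of the component's peak chamfer distance form
#' markers, and components with more than one marker are re-partitioned by
#' seeded growing.
#'
#' @param nuclear_frame 2-D nonnegative intensity matrix.
#' @param min_area minimum nucleus area in pixels.
#' @param threshold `"otsu"` or a numeric intensity cutoff.
#' @param sigma smoothing sd in pixels.
#' @param marker_frac distance fraction defining split markers.
#' @return integer label matrix with attribute `provenance = "nuclei"`.
#' @export
detect_nuclei <- function(nuclear_frame, min_area = 30L, threshold = "otsu",
                          sigma = 2, marker_frac = 0.8) {
  if (!is.matrix(nuclear_frame) || any(nuclear_frame < 0)) {
    stop_fs("nuclear frame must be a nonnegative 2-D matrix")
  }
  if (max(nuclear_frame) == 0) {
    lab <- matrix(0L, nrow(nuclear_frame), ncol(nuclear_frame))
    attr(lab, "provenance") <- "nuclei"
    return(lab)
  }
  sm <- gaussian_blur(nuclear_frame, sigma)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(sm) else as.numeric(threshold)
  mask <- sm > thr
  comp <- label_components(mask)
  if (max(comp) > 0) {
    dist <- chamfer_distance(mask)
    compmax <- vapply(seq_len(max(comp)), function(i) max(dist[comp == i]), 1.0)
    marker_mask <- mask & dist >= marker_frac * compmax[pmax(comp, 1L)] & comp > 0
    markers <- label_components(marker_mask)
    # only re-partition components holding more than one marker
    n_markers <- vapply(seq_len(max(comp)), function(i) {
      length(setdiff(unique(markers[comp == i]), 0L))
    }, 1L)
    if (any(n_markers > 1L)) {
      grown <- grow_labels(markers, mask)
      keep1 <- comp > 0 & n_markers[pmax(comp, 1L)] <= 1L
      grown[keep1] <- max(markers) + comp[keep1]  # untouched components keep one label
      comp <- relabel_contiguous(grown)
    }
  }
  if (max(comp) > 0) {
    areas <- tabulate(comp[comp > 0], max(comp))
    drop <- which(areas < min_area)
    if (length(drop)) comp[comp %in% drop] <- 0L
    comp <- relabel_contiguous(comp)
  }
  attr(comp, "provenance") <- "nuclei"
  comp
}

#' Grow single-cell boundaries from nucleus seeds
#'
#' The cytoplasmic frame (typically CFP+YFP of the first pre-stimulus frame)
#' is smoothed and thresholded into a foreground mask; cell labels are grown
#' from the nucleus seeds by synchronous region growing restricted to that
#' mask, so cells partition the foreground and each retained cell contains
#' exactly one nucleus. Nuclei whose pixels fall entirely outside the
#' foreground are dropped with a warning.
#'
#' @param cyto_frame 2-D intensity matrix.
#' @param nuclei nucleus label matrix from [detect_nuclei()].
#' @param threshold `"otsu"` or numeric cutoff for the foreground mask.
#' @param sigma smoothing sd in pixels.
#' @param min_area minimum cell area in pixels.
#' @return list: `labels` (cell label matrix, provenance `"cells"`) and
#'   `cells` (data.frame `cell_id, nucleus_id, area_px, centroid_y,
#'   centroid_x, edge`; centroids 0-based (row, col)).
#' @export
grow_cell_boundaries <- function(cyto_frame, nuclei, threshold = "otsu",
                                 sigma = 2, min_area = 1L) {
  if (max(nuclei) == 0) stop_fs("no nuclei to seed cell growing")
  sm <- gaussian_blur(cyto_frame, sigma)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(sm) else as.numeric(threshold)
  mask <- sm > thr
  in_fg <- vapply(seq_len(max(nuclei)), function(i) any(mask[nuclei == i]), TRUE)
  seeds <- nuclei
  if (!all(in_fg)) {
    warn_fs("dropping %d nucleus/nuclei outside the cytoplasmic foreground",
            sum(!in_fg))
    seeds[seeds %in% which(!in_fg)] <- 0L
  }
  if (max(seeds) == 0) stop_fs("all nuclei fall outside the cytoplasmic foreground")
  lab <- grow_labels(seeds, mask)
  areas <- tabulate(lab[lab > 0], max(lab))
  small <- which(areas > 0 & areas < min_area)
  if (length(small)) lab[lab %in% small] <- 0L

  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  H <- nrow(lab); W <- ncol(lab)
  border_ids <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  rows <- row(lab)[lab > 0]; cols <- col(lab)[lab > 0]; labv <- lab[lab > 0]
  cells <- data.frame(
    cell_id = seq_along(ids),
    nucleus_id = ids,
    area_px = as.integer(tabulate(labv, max(ids))[ids]),
    centroid_y = as.numeric(tapply(rows, labv, mean)[as.character(ids)]) - 1,
    centroid_x = as.numeric(tapply(cols, labv, mean)[as.character(ids)]) - 1,
    edge = ids %in% border_ids
  )
  out <- relabel_contiguous(lab)
  attr(out, "provenance") <- "cells"
  list(labels = out, cells = cells)
}

#' Exclude cells touching the image border
#'
#' Any cell with at least one pixel on the outermost rows/columns is removed
#' (strict rule). The `edge` flag is set on all records; excluded records are
#' attached as the `"excluded"` attribute of the returned table.
#'
#' @param cells cell table from [grow_cell_boundaries()].
#' @param labels matching cell label matrix.
#' @return retained cell records (possibly zero rows, with a warning).
#' @export
exclude_edge_cells <- function(cells, labels) {
  H <- nrow(labels); W <- ncol(labels)
  border_ids <- setdiff(unique(c(labels[1, ], labels[H, ], labels[, 1], labels[, W])), 0L)
  cells$edge <- cells$cell_id %in% border_ids
  kept <- cells[!cells$edge, , drop = FALSE]
  if (nrow(kept) == 0L) warn_fs("all cells touch the image border")
  attr(kept, "excluded") <- cells[cells$edge, , drop = FALSE]
  kept
}

#' Field-level mean intensity (TMRM quantification)
#'
#' Mean of (optionally background-subtracted) pixel intensities of a whole
#' frame; mitochondrial membrane potential is quantified without segmentation.
#'
#' @param frame 2-D intensity matrix.
#' @param background `"none"` (default, plain mean) or `"percentile"`.
#' @param percentile background percentile when subtracting (default 0.05).
#' @return scalar mean intensity in the frame's arbitrary units.
#' @export
mean_field_intensity <- function(frame, background = c("none", "percentile"),
                                 percentile = 0.05) {
  background <- match.arg(background)
  if (!is.matrix(frame)) stop_fs("frame must be a 2-D matrix")
  bg <- switch(background,
    none = 0,
    percentile = stats::quantile(frame, percentile, names = FALSE))
  mean(frame - bg)
}
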