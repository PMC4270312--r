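# Shared fixtures, all built in code at test time.

# simple 5-frame schedule: 3 pre-stimulus frames, dispense at frame 4
tiny_schedule <- function() acq_schedule(c(0, 1, 2, 3, 4), dispense_index = 4L)

# draw a set of disks into a blank image; centers = matrix(row, col), one
# radius per disk
disk_image <- function(h, w, centers, radius, value = 100) {
  img <- matrix(0, h, w)
  rr <- row(img); cc <- col(img)
  radius <- rep_len(radius, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    img[(rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius[i]^2] <- value
  }
  img
}

# small rendered field with ground truth, noiseless by default
small_field <- function(n_cells = 8, seed = 5, noise_cv = 0, cell_cv = 0,
                        fraction_edge = 0.25, fraction_nonresponsive = 0,
                        height = 96, width = 96, amplitude = 1.2,
                        schedule = default_schedule()) {
  spec <- field_spec(height = height, width = width, n_cells = n_cells,
                     fraction_edge = fraction_edge,
                     fraction_nonresponsive = fraction_nonresponsive)
  tw <- simulate_well_traces(n_cells, amplitude, schedule,
                             fraction_nonresponsive = fraction_nonresponsive,
                             cell_cv = cell_cv, noise_cv = noise_cv, seed = seed)
  rf <- render_field(spec, tw$traces, seed = seed, truth_peaks = tw$true_peaks)
  c(rf, list(traces = tw$traces, true_peaks = tw$true_peaks, spec = spec))
}

# per-true-cell Jaccard of a predicted segmentation against ground truth
truth_jaccard <- function(pred_labels, truth_labels, ids) {
  vapply(ids, function(i) {
    tm <- truth_labels == i
    labs <- pred_labels[tm]
    labs <- labs[labs > 0]
    if (!length(labs)) return(0)
    pl <- as.integer(names(which.max(table(labs))))
    pm <- pred_labels == pl
    sum(tm & pm) / sum(tm | pm)
  }, 1.0)
}

# a minimal valid plate map data.frame for layout tests
tiny_wells <- function() {
  data.frame(
    address = c("A1", "A2", "A3", "A4", "B1", "B2"),
    role = c("vehicle", "vehicle", "test", "test", "positive_control", "untreated"),
    compound_id = c(NA, NA, "cpdX", "cpdX", "TP", NA),
    concentration = c(NA, NA, 1e-5, 1e-5, 1e-6, NA),
    replicate_group = c("veh", "veh", "cpdX", "cpdX", "TP", "untr"),
    stringsAsFactors = FALSE
  )
}
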