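test_that("detect_nuclei labels separated disks and degenerate inputs", {
  centers <- cbind(c(20, 20, 60, 60, 40), c(20, 60, 20, 60, 40))
  img <- disk_image(80, 80, centers, radius = 7)
  lab <- detect_nuclei(img, min_area = 20)
  expect_equal(max(lab), 5L)
  expect_equal(attr(lab, "provenance"), "nuclei")

  expect_equal(max(detect_nuclei(matrix(0, 40, 40))), 0L)

  # min_area filtering removes specks
  img2 <- disk_image(80, 80, rbind(c(40, 40), c(10, 70)), radius = c(8, 2))
  expect_equal(max(detect_nuclei(img2, min_area = 30)), 1L)
})

test_that("fused nuclei are split by the distance-transform watershed", {
  r <- 8
  img <- disk_image(64, 64, rbind(c(28, 32), c(28 + 1.8 * r, 32)), radius = r)
  lab <- detect_nuclei(img, min_area = 20)
  expect_equal(max(lab), 2L)
  # a single disk of the same radius is not over-split
  expect_equal(max(detect_nuclei(disk_image(64, 64, cbind(32, 32), r),
                                 min_area = 20)), 1L)
})

test_that("detect_nuclei with Otsu is invariant under intensity scaling", {
  f <- small_field(n_cells = 10, seed = 7, fraction_edge = 0)
  base <- detect_nuclei(f$stack$nuclear)
  for (k in c(0.5, 3, 40)) {
    scaled <- detect_nuclei(f$stack$nuclear * k)
    expect_identical(scaled == 0, base == 0)
    expect_equal(max(scaled), max(base))
  }
})

test_that("grow_cell_boundaries partitions the foreground, one nucleus per cell", {
  f <- small_field(n_cells = 10, seed = 7, fraction_edge = 0)
  nuc <- detect_nuclei(f$stack$nuclear)
  cyto <- f$stack$cfp[, , 1] + f$stack$yfp[, , 1]
  seg <- grow_cell_boundaries(cyto, nuc)
  expect_equal(nrow(seg$cells), max(nuc))
  # cell_id <-> nucleus_id bijection
  expect_false(anyDuplicated(seg$cells$nucleus_id) > 0)
  # every cell contains exactly its own nucleus
  for (i in seg$cells$cell_id) {
    nid <- seg$cells$nucleus_id[seg$cells$cell_id == i]
    expect_true(all(seg$labels[nuc == nid] == i))
  }
  # labels are a partition: max one label per pixel by construction; check
  # they cover the thresholded foreground
  sm <- gaussian_blur(cyto, 2)
  mask <- sm > otsu_threshold(sm)
  expect_true(all(seg$labels[mask] > 0))

  expect_error(grow_cell_boundaries(cyto, matrix(0L, nrow(cyto), ncol(cyto))),
               "no nuclei")
})

test_that("segmentation recovers synthetic ground truth (50-cell field)", {
  s <- default_schedule()
  spec <- field_spec(height = 256, width = 256, n_cells = 50,
                     fraction_edge = 0.1, fraction_nonresponsive = 0)
  tw <- simulate_well_traces(50, 1.2, s, noise_cv = 0.02, seed = 21)
  rf <- render_field(spec, tw$traces, seed = 21, truth_peaks = tw$true_peaks)
  nuc <- detect_nuclei(rf$stack$nuclear)
  expect_equal(max(nuc), 50L)  # recall and precision 1 on non-touching cells
  seg <- grow_cell_boundaries(rf$stack$cfp[, , 1] + rf$stack$yfp[, , 1], nuc)
  jac <- truth_jaccard(seg$labels, rf$truth$cell_labels, 1:50)
  expect_gte(median(jac), 0.8)
})

test_that("edge exclusion removes exactly the border-touching cells", {
  f <- small_field(n_cells = 12, seed = 13, fraction_edge = 0.25)
  nuc <- detect_nuclei(f$stack$nuclear)
  seg <- grow_cell_boundaries(f$stack$cfp[, , 1] + f$stack$yfp[, , 1], nuc)
  kept <- exclude_edge_cells(seg$cells, seg$labels)
  lab <- seg$labels
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  expect_true(all(!kept$cell_id %in% border))
  excl <- attr(kept, "excluded")
  expect_setequal(excl$cell_id, setdiff(border, 0))
  expect_true(all(excl$edge))

  # all cells on the border: empty result plus warning
  one <- matrix(1L, 10, 10)
  cells <- data.frame(cell_id = 1L, nucleus_id = 1L, area_px = 100L,
                      centroid_y = 4.5, centroid_x = 4.5, edge = FALSE)
  expect_warning(kept0 <- exclude_edge_cells(cells, one), "border")
  expect_equal(nrow(kept0), 0L)
})

test_that("mean_field_intensity is linear and tracks intensity scaling", {
  img <- matrix(7, 50, 50)
  expect_equal(mean_field_intensity(img), 7)
  expect_equal(mean_field_intensity(img + 3), 10)

  set.seed(1)
  tmrm <- matrix(rexp(2500, 1 / 50), 50, 50)
  ratio <- mean_field_intensity(tmrm * 1.6) / mean_field_intensity(tmrm)
  expect_equal(ratio, 1.6, tolerance = 1e-9)

  # percentile background subtraction
  expect_equal(mean_field_intensity(img, "percentile"), 0)
})
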