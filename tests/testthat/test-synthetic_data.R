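test_that("simulate_transient honors the rescaling contract", {
  s <- default_schedule()
  # null stimulus: constant baseline
  p0 <- transient_params(baseline_ratio = 1.5, peak_dff = 0, noise_cv = 0)
  expect_equal(simulate_transient(p0, s), rep(1.5, 13))

  # noiseless peak delta-F/F0 equals A exactly, for several amplitudes
  for (A in c(0.2, 0.8, 1.3)) {
    p <- transient_params(peak_dff = A, noise_cv = 0)
    tr <- simulate_transient(p, s)
    dff <- (tr - mean(tr[1:3])) / mean(tr[1:3])
    expect_equal(max(dff[4:13]), A, tolerance = 1e-12)
  }

  # determinism under a fixed seed
  pn <- transient_params(peak_dff = 0.8, noise_cv = 0.05)
  expect_identical(simulate_transient(pn, s, seed = 42),
                   simulate_transient(pn, s, seed = 42))
  expect_false(identical(simulate_transient(pn, s, seed = 42),
                         simulate_transient(pn, s, seed = 43)))

  expect_error(transient_params(peak_dff = -0.1), ">= 0")
  expect_error(transient_params(rise_tau = 5, decay_tau = 4), "decay_tau")
})

test_that("render_field satisfies the ratiometric rendering contract", {
  f <- small_field(n_cells = 8, seed = 5)
  truth <- f$truth

  # one ground-truth record per rendered cell; nuclei strictly inside cells
  expect_equal(nrow(truth$cells), 8L)
  expect_true(all(truth$nucleus_labels[truth$nucleus_labels > 0] ==
                  truth$cell_labels[truth$nucleus_labels > 0]))

  # per-cell YFP+CFP pixel sum is frame-constant (ratiometric redistribution)
  for (i in c(1, 4, 8)) {
    sel <- truth$cell_labels == i
    sums <- vapply(seq_len(dim(f$stack$cfp)[3]), function(fr) {
      mean(f$stack$cfp[, , fr][sel] + f$stack$yfp[, , fr][sel])
    }, 1.0)
    expect_lt(diff(range(sums)), 1e-6)
  }

  # background-subtracted pixel-mean YFP/CFP reproduces the input trace
  # exactly (noise off)
  r <- extract_ratio_trace(f$stack, truth$cell_labels, 3, background = "field")
  expect_equal(r, f$traces[3, ], tolerance = 1e-9)

  # requested fraction of edge cells is rendered on the border
  expect_equal(sum(truth$cells$edge), round(0.25 * 8))

  # nuclear channel nonzero only in nuclei
  expect_true(all(f$stack$nuclear[truth$nucleus_labels == 0] == 0))
})

test_that("render_field degenerate and determinism cases", {
  spec0 <- field_spec(n_cells = 0)
  out <- render_field(spec0, matrix(numeric(0), 0, 13), seed = 1)
  expect_equal(nrow(out$truth$cells), 0L)
  expect_true(all(out$truth$cell_labels == 0))

  f1 <- small_field(seed = 9)
  f2 <- small_field(seed = 9)
  expect_identical(f1$stack, f2$stack)

  # overcrowding fails after bounded retries
  spec <- field_spec(height = 40, width = 40, n_cells = 30)
  traces <- matrix(1.5, 30, 13)
  expect_error(render_field(spec, traces, seed = 1), "non-overlapping")
})

test_that("simulate_screen_plate wires scalings by role", {
  lay <- make_screen_layout(n_compounds = 2, n_replicates = 2,
                            compound_ids = c("a", "b"))
  sim <- simulate_screen_plate(lay, c(a = 0.7, b = 1.0), genotype_factor = 1.5,
                               base_amplitude = 0.8, noise_cv = 0, cell_cv = 0,
                               spec = field_spec(n_cells = 10,
                                                 fraction_nonresponsive = 0),
                               seed = 3)
  tr <- sim$truth
  expect_equal(tr$scaling[tr$role == "vehicle"], rep(1, 8))
  expect_equal(unique(tr$scaling[tr$compound_id %in% "a"]), 0.7)
  expect_equal(unique(tr$amplitude[tr$compound_id %in% "a"]), 0.8 * 1.5 * 0.7)
  expect_equal(tr$scaling[tr$compound_id %in% "TP"], rep(0.15, 2))

  # true well peak ratio equals the scaling with noise off
  pk_a <- mean(sim$wells[[tr$address[tr$compound_id %in% "a"][1]]]$true_peaks)
  pk_v <- mean(sim$wells[[tr$address[tr$role == "vehicle"][1]]]$true_peaks)
  expect_equal(pk_a / pk_v, 0.7, tolerance = 1e-12)

  expect_error(simulate_screen_plate(lay, c(a = 0.7), seed = 1), "no effect")

  sim2 <- simulate_screen_plate(lay, c(a = 0.7, b = 1.0), noise_cv = 0,
                                cell_cv = 0,
                                spec = field_spec(n_cells = 10,
                                                  fraction_nonresponsive = 0),
                                seed = 3)
  expect_identical(sim$wells[["A1"]]$traces, sim2$wells[["A1"]]$traces)
})

test_that("simulate_dose_table follows the 4PL ground truth", {
  p <- four_pl(bottom = 1, top = 2, ec50 = 5e-6, hill = 1.2)
  tab <- simulate_dose_table(p, c(1e-7, 1e-6, 5e-6, 1e-4), n_replicates = 8,
                             noise_cv = 0, seed = 1)
  expect_equal(sum(tab$conc == 5e-6), 8L)  # 8 rows per concentration
  expect_equal(unique(tab$response[tab$conc == 5e-6]), 1.5)  # midpoint at EC50
  # asymptotes
  expect_equal(unname(predict_4pl(p, 0)), 1)
  expect_equal(unname(predict_4pl(p, 1e6)), 2, tolerance = 1e-6)
  expect_error(simulate_dose_table(p, c(0, 1e-6), seed = 1), "positive")
})

test_that("simulate_elisa_plate is the exact forward of the calibration", {
  calib <- four_pl(bottom = 40, top = 25000, ec50 = 300, hill = 1.1)
  stds <- 300 * 4^seq(-4, 4)
  truth <- c(s1 = 120, s2 = 900, s3 = 2500)
  plate <- simulate_elisa_plate(calib, stds, truth, noise_cv = 0,
                                n_replicates = 2, seed = 1)
  expect_equal(sum(plate$sample_id == "s1"), 2L)  # duplicate wells per sample
  cal <- elisa_calibration(plate$conc[plate$type == "standard"],
                           plate$signal[plate$type == "standard"], "Abeta40")
  q <- quantify_samples(cal, plate[plate$type == "sample", ])
  expect_equal(q$conc, unname(truth[q$sample_id]), tolerance = 1e-3)
  expect_lt(max(abs(q$conc / truth[q$sample_id] - 1)), 1e-3)

  # all-zero samples read at the bottom asymptote
  plate0 <- simulate_elisa_plate(calib, stds, c(z = 0), noise_cv = 0, seed = 1)
  expect_equal(unique(plate0$signal[plate0$sample_id == "z"]), 40)

  expect_error(simulate_elisa_plate(calib, numeric(0), truth, seed = 1),
               "standards")
})
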