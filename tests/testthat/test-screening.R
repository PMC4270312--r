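mk_summaries <- function(lay, values) {
  data.frame(address = lay$wells$address,
             mean_peak = values,
             n_cells = 50L, n_responsive = 45L, valid = TRUE,
             stringsAsFactors = FALSE)
}

test_that("normalize_to_vehicle divides by the vehicle mean", {
  w <- tiny_wells()
  lay <- plate_layout("p", 384, w)
  sums <- mk_summaries(lay, c(0.5, 0.5, 0.45, 0.47, 0.1, 0.5))
  plate <- normalize_to_vehicle(sums, lay)
  expect_equal(plate$normalized_value[plate$address == "A3"], 0.9)
  # vehicle wells average exactly 1 by construction
  expect_identical(mean(plate$normalized_value[plate$role == "vehicle"]), 1)

  # errors
  w2 <- w; w2$role[w2$role == "vehicle"] <- "untreated"
  w2$replicate_group[1:2] <- "untr"
  lay2 <- plate_layout("p", 384, w2)
  expect_error(normalize_to_vehicle(mk_summaries(lay2, rep(1, 6)), lay2),
               "no valid vehicle")
  expect_error(normalize_to_vehicle(mk_summaries(lay, rep(0, 6)), lay),
               "positive")
})

test_that("aggregate_replicates pools replicate wells and drops invalid ones", {
  lay <- make_screen_layout(n_compounds = 1, n_replicates = 4,
                            compound_ids = "cpd")
  vals <- rep(1, nrow(lay$wells))
  vals[lay$wells$role == "test"] <- c(0.88, 0.92, 0.90, 0.86)
  sums <- mk_summaries(lay, vals)
  plate <- normalize_to_vehicle(sums, lay)
  agg <- aggregate_replicates(plate)
  expect_equal(agg$norm_mean, 0.89)
  expect_equal(agg$n_wells, 4L)

  # permuting well order leaves the result unchanged
  perm <- sample(nrow(sums))
  agg2 <- aggregate_replicates(normalize_to_vehicle(sums[perm, ], lay))
  expect_equal(agg2$norm_mean, agg$norm_mean)
  expect_equal(agg2$norm_sd, agg$norm_sd)

  # only one valid well: mean over it, sd undefined
  sums$valid[lay$wells$role == "test"][1:3] <- FALSE
  agg3 <- aggregate_replicates(normalize_to_vehicle(sums, lay))
  expect_equal(agg3$n_wells, 1L)
  expect_true(is.na(agg3$norm_sd))

  # toxicity-interference proxy: too few responsive cells
  sums <- mk_summaries(lay, vals)
  idx <- which(lay$wells$role == "test")
  sums$n_responsive[idx] <- 5L  # 5/50 < 0.2
  agg4 <- aggregate_replicates(normalize_to_vehicle(sums, lay))
  expect_true(agg4$toxicity_interference)
  expect_true(is.na(agg4$norm_mean))
  expect_true(is.na(call_hits(agg4)$active))
})

test_that("call_hits applies the strict < 0.9 rule", {
  tab <- data.frame(compound_id = c("a", "b", "c"),
                    norm_mean = c(0.89, 0.90, 1.2),
                    norm_sd = 0.01, n_wells = 4L, n_dropped = 0L,
                    toxicity_interference = FALSE)
  hits <- call_hits(tab)
  expect_identical(hits$active, c(TRUE, FALSE, FALSE))  # 0.90 is inactive
  expect_error(call_hits(tab[0, ]), "empty")
})

test_that("hit calls are invariant under uniform readout scaling (property)", {
  lay <- make_screen_layout(n_compounds = 5, n_replicates = 4)
  set.seed(8)
  vals <- runif(nrow(lay$wells), 0.3, 1.2)
  base <- call_hits(aggregate_replicates(
    normalize_to_vehicle(mk_summaries(lay, vals), lay)))
  for (k in c(0.01, 3, 1e4)) {
    scaled <- call_hits(aggregate_replicates(
      normalize_to_vehicle(mk_summaries(lay, vals * k), lay)))
    expect_identical(scaled$active, base$active)
  }
})

test_that("plate QC requires all positive controls below threshold", {
  lay <- make_screen_layout(n_compounds = 1, n_replicates = 4)
  vals <- rep(1, nrow(lay$wells))
  vals[lay$wells$compound_id %in% "TP"] <- 0.15
  vals[lay$wells$compound_id %in% "CPA"] <- 0.2
  vals[lay$wells$compound_id %in% "TMB-8"] <- 0.4
  vals[lay$wells$compound_id %in% "Bepridil"] <- 0.5
  plate <- normalize_to_vehicle(mk_summaries(lay, vals), lay)
  qc <- qc_plate(plate)
  expect_true(qc$plate_pass)
  expect_equal(sort(qc$controls$compound_id),
               sort(c("TP", "CPA", "TMB-8", "Bepridil")))

  vals[lay$wells$compound_id %in% "Bepridil"] <- 0.95
  qc2 <- qc_plate(normalize_to_vehicle(mk_summaries(lay, vals), lay))
  expect_false(qc2$plate_pass)
  expect_match(qc2$reason, "Bepridil")

  # no control wells at all
  w <- tiny_wells()[c(1, 2, 3, 4), ]
  lay3 <- plate_layout("p", 384, w)
  qc3 <- qc_plate(normalize_to_vehicle(mk_summaries(lay3, c(1, 1, 0.5, 0.5)),
                                       lay3))
  expect_false(qc3$plate_pass)
  expect_match(qc3$reason, "no positive-control")
})

test_that("star annotation matches the caption convention", {
  expect_identical(star_annotation(c(0.04, 0.20, 0.0005, 0.009)),
                   c("*", "n.s.", "***", "**"))
  expect_error(star_annotation(1.2), "\\[0, 1\\]")
  expect_error(star_annotation(-0.1), "\\[0, 1\\]")
})
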