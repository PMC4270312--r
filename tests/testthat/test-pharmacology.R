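test_that("4PL evaluation and inversion are exact inverses", {
  p <- four_pl(bottom = 1, top = 2, ec50 = 4.84e-6, hill = 1.3)
  expect_equal(unname(predict_4pl(p, 4.84e-6)), 1.5)   # midpoint at EC50
  expect_equal(unname(predict_4pl(p, 0)), 1)           # c -> 0 asymptote
  expect_equal(unname(invert_4pl(p, 1.5)), 4.84e-6)

  set.seed(3)
  cs <- 10^runif(20, -8, -4)
  expect_equal(invert_4pl(p, predict_4pl(p, cs)), cs, tolerance = 1e-9)

  # decreasing curve: hill sign flip mirrors direction
  pd <- four_pl(bottom = 1, top = 2, ec50 = 4.84e-6, hill = -1.3)
  expect_equal(unname(predict_4pl(pd, 0)), 2)
  expect_equal(predict_4pl(pd, cs) - 1, 2 - predict_4pl(p, cs), tolerance = 1e-12)

  expect_error(invert_4pl(p, 2), "asymptote")
  expect_error(invert_4pl(p, 0.5), "asymptote")
  expect_error(four_pl(1, 1, 1e-6, 1), "bottom != top")
  expect_error(four_pl(1, 2, -1, 1), "ec50")
  expect_error(four_pl(1, 2, 1e-6, 0), "hill")
})

test_that("fit_4pl recovers generating parameters on noiseless data", {
  for (truth in list(four_pl(1, 2, 4.84e-6, 1),
                     four_pl(0.2, 1.1, 2e-6, 1.7),
                     four_pl(0.5, 5, 8e-6, -1.2))) {  # decreasing curve
    tab <- simulate_dose_table(truth, 10^seq(-7, log10(3e-5), length.out = 6),
                               n_replicates = 8, noise_cv = 0, seed = 1)
    fit <- fit_4pl(tab$conc, tab$response)
    expect_false(fit$degenerate)
    expect_equal(fit$params$ec50, truth$ec50, tolerance = 1e-6)
    expect_equal(fit$params$hill, truth$hill, tolerance = 1e-6)
    expect_equal(fit$params$bottom, truth$bottom, tolerance = 1e-6)
    expect_equal(fit$params$top, truth$top, tolerance = 1e-6)
  }
})

test_that("flat data yield a degenerate fit, short designs an error", {
  cs <- 10^seq(-7, -4, length.out = 6)
  fit <- fit_4pl(cs, rep(1.3, 6))
  expect_true(fit$degenerate)
  expect_null(fit$params)

  # range below 3x replicate noise is also degenerate
  set.seed(2)
  tab <- simulate_dose_table(four_pl(1, 1.01, 5e-6, 1), cs, 8, noise_cv = 0.1,
                             seed = 7)
  expect_true(fit_4pl(tab$conc, tab$response)$degenerate)

  expect_error(fit_4pl(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})

test_that("EC50 estimator has small median bias at assay noise (simulation)", {
  # bias benchmark on a design that identifies the parameter: six
  # concentrations log-symmetric around the EC50 (100x either side). On the
  # narrow 0.1-30 uM assay design the top plateau is unobserved and both
  # bias and spread inflate (see the acceptance suite and decisions ledger).
  truth <- gea133_tmrm_4pl()
  cs <- truth$ec50 * 10^seq(-2, 2, length.out = 6)
  errs <- vapply(1:100, function(seed) {
    tab <- simulate_dose_table(truth, cs, n_replicates = 8, noise_cv = 0.1,
                               seed = seed)
    fit <- fit_4pl(tab$conc, tab$response, direction = "up")
    fit$params$ec50 / truth$ec50 - 1
  }, 1.0)
  expect_lt(abs(median(errs)), 0.02)
})

test_that("ELISA calibration validates its standards", {
  expect_error(elisa_calibration(c(1, 2, 3), c(1, 2, 3), "Abeta40"),
               "6 distinct")
  expect_error(elisa_calibration(1:6 * 10, rep(5, 6), "Abeta40"),
               "identically")
  # narrow span attaches a warning flag
  cal <- elisa_calibration(seq(100, 200, length.out = 7),
                           predict_4pl(four_pl(10, 1e4, 150, 1),
                                       seq(100, 200, length.out = 7)),
                           "Abeta42")
  expect_true(cal$span_warning)
})

test_that("quantify_samples averages replicates and flags range violations", {
  truth <- four_pl(50, 2e4, 400, 1.1)
  stds <- 400 * 4^seq(-3, 3)
  cal <- elisa_calibration(stds, predict_4pl(truth, stds), "Abeta40")

  # duplicate replicates [s, s] quantify identically to a single s
  s1 <- predict_4pl(truth, 900)
  q2 <- quantify_samples(cal, data.frame(sample_id = "a", signal = c(s1, s1)))
  q1 <- quantify_samples(cal, data.frame(sample_id = "a", signal = s1))
  expect_equal(q2$conc, q1$conc)
  expect_equal(q2$conc, 900, tolerance = 1e-4)

  # above the top standard: flagged, not clipped
  hi <- predict_4pl(truth, max(stds) * 5)
  qh <- quantify_samples(cal, data.frame(sample_id = "hot", signal = hi))
  expect_equal(qh$flag, "above_range")
  expect_false(is.na(qh$conc))

  # signal beyond the fitted top: not invertible
  qn <- quantify_samples(cal, data.frame(sample_id = "x", signal = 1e9))
  expect_equal(qn$flag, "not_invertible")
  expect_true(is.na(qn$conc))
})

test_that("build_profile normalizes to the in-context vehicle", {
  tab_app <- data.frame(
    sample_id = rep(c("DMSO", "cpd"), 3),
    analyte = rep(c("Abeta38", "Abeta40", "Abeta42"), each = 2),
    conc = c(400, 200, 900, 450, 120, 60))
  profs <- build_profile(list(app = tab_app), vehicle_id = "DMSO")
  expect_equal(unname(profs$DMSO$app), rep(1, 3))       # vehicle maps to 1
  expect_equal(unname(profs$DMSO$ratio_42_40[["app"]]), 1)
  expect_equal(unname(profs$cpd$app[["Abeta42"]]), 0.5)
  # 42 and 40 both halved: ratio 1
  expect_equal(unname(profs$cpd$ratio_42_40[["app"]]), 1)

  # 42 halved, 40 unchanged: ratio 0.5
  tab2 <- tab_app
  tab2$conc[tab2$analyte == "Abeta40" & tab2$sample_id == "cpd"] <- 900
  profs2 <- build_profile(list(app = tab2), "DMSO")
  expect_equal(unname(profs2$cpd$ratio_42_40[["app"]]), 0.5)

  expect_error(build_profile(list(app = tab_app), vehicle_id = "nope"),
               "vehicle")
})

test_that("normalized ratio equals the raw concentration ratio (property)", {
  set.seed(6)
  for (i in 1:10) {
    conc <- runif(6, 10, 1000)
    tab <- data.frame(
      sample_id = rep(c("DMSO", "cpd"), 3),
      analyte = rep(c("Abeta38", "Abeta40", "Abeta42"), each = 2),
      conc = conc)
    pr <- build_profile(list(app = tab), "DMSO")$cpd
    raw_ratio <- (conc[6] / conc[4]) / (conc[5] / conc[3])
    expect_equal(unname(pr$ratio_42_40[["app"]]), raw_ratio, tolerance = 1e-12)
  }
})

test_that("mechanism truth table", {
  ab <- function(x38, x40, x42) c(Abeta38 = x38, Abeta40 = x40, Abeta42 = x42)
  dapt <- secretase_profile(ab(0.2, 0.2, 0.2), c99 = ab(0.2, 0.2, 0.2))
  expect_equal(classify_mechanism(dapt)$class, "gamma_inhibitor")

  sulindac <- secretase_profile(ab(1.6, 1.0, 0.5))
  expect_equal(classify_mechanism(sulindac)$class, "gamma_modulator")

  bepridil <- secretase_profile(ab(0.9, 0.8, 1.4), c99 = ab(0.9, 0.8, 1.4))
  expect_equal(classify_mechanism(bepridil)$class, "inverse_gamma_modulator")

  gea <- secretase_profile(ab(0.5, 0.5, 0.5), c99 = ab(1, 1, 1),
                           sapp = c(sAPPalpha = 1, sAPPbeta = 0.5))
  expect_equal(classify_mechanism(gea)$class, "beta_cleavage_reduction")
  # sAPP evidence alone suffices when the C99 context is missing
  gea2 <- secretase_profile(ab(0.5, 0.5, 0.5),
                            sapp = c(sAPPalpha = 1, sAPPbeta = 0.5))
  expect_equal(classify_mechanism(gea2)$class, "beta_cleavage_reduction")

  none <- secretase_profile(ab(1, 1, 1))
  expect_equal(classify_mechanism(none)$class, "no_effect")

  expect_error(classify_mechanism(list()), "secretase_profile")
})

test_that("classifier is total and order-invariant (property)", {
  set.seed(7)
  for (i in 1:40) {
    lv <- function(n) exp(rnorm(n, 0, 0.5))
    app <- setNames(lv(3), c("Abeta38", "Abeta40", "Abeta42"))
    cls <- classify_mechanism(secretase_profile(app))$class
    expect_true(cls %in% c("gamma_inhibitor", "gamma_modulator",
                           "inverse_gamma_modulator", "beta_cleavage_reduction",
                           "no_effect", "unclassified"))
    shuffled <- app[sample(3)]
    expect_equal(classify_mechanism(secretase_profile(shuffled))$class, cls)
  }
})

test_that("SAR grouping follows the substituent-class rules", {
  cmp <- rbind(
    compound_record("g133", "cyano", "benzylpiperidinyl", "synthesized"),
    compound_record("c1", "nitro", "phenethylpiperidinyl", "commercial"),
    compound_record("c2", "hydrogen", "benzylpiperidinyl", "synthesized"),
    compound_record("c3", "nitro", "aliphatic", "commercial"))
  res <- data.frame(compound_id = c("g133", "c1", "c2", "c3"),
                    assay = "calcium", value = c(0.7, 0.72, 0.98, 0.97))
  tab <- sar_summary(cmp, res)
  pick <- function(r1, r2) tab[tab$r1_class == r1 & tab$r2_class == r2, ]
  expect_equal(pick("cyano", "benzylpiperidinyl")$expected, "expected-active")
  expect_equal(pick("nitro", "phenethylpiperidinyl")$expected, "expected-active")
  expect_equal(pick("hydrogen", "benzylpiperidinyl")$expected, "expected-inactive")
  expect_equal(pick("nitro", "aliphatic")$expected, "expected-inactive")
  expect_equal(pick("cyano", "benzylpiperidinyl")$mean_calcium, 0.7)

  # unannotated compounds fall under "other"
  cmp2 <- cmp
  cmp2$r1_class[1] <- NA
  tab2 <- sar_summary(cmp2)
  expect_true("other" %in% tab2$r1_class)

  expect_equal(nrow(sar_summary(cmp[0, ])), 0L)
})
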