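# Secretase mechanism-of-action profiling: vehicle-normalized Abeta and sAPP
# levels across cell contexts, Abeta42/40 ratios, and rule-based
# classification (gamma-inhibitor / GSM / inverse GSM / beta-cleavage
# reduction), plus substituent-class SAR summaries.

MECHANISM_CLASSES <- c("gamma_inhibitor", "gamma_modulator",
                       "inverse_gamma_modulator", "beta_cleavage_reduction",
                       "no_effect", "unclassified")

#' Construct a secretase profile from vehicle-normalized levels
#'
#' Levels are relative to the DMSO vehicle (= 1) in each cell context:
#' `app` for APP-overexpressing cells (full processing), `c99` for cells
#' expressing the beta-cleaved C99 stub (gamma-cleavage in isolation), `sapp`
#' for soluble APP ectodomains from wild-type cells.
#'
#' @param app named vector with `Abeta38`, `Abeta40`, `Abeta42` levels.
#' @param c99 optional named vector, same analytes, C99-cell context.
#' @param sapp optional named vector with `sAPPalpha`, `sAPPbeta`.
#' @param stars optional named character vector of significance stars.
#' @return object of class `secretase_profile` with per-context
#'   `ratio_42_40 = Abeta42/Abeta40`.
#' @export
secretase_profile <- function(app, c99 = NULL, sapp = NULL, stars = NULL) {
  check_levels <- function(x, what) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop_fs("%s levels must be positive and finite", what)
    }
    x
  }
  if (is.null(app) || !all(c("Abeta40", "Abeta42") %in% names(app))) {
    stop_fs("profile needs at least Abeta40 and Abeta42 in the APP context")
  }
  app <- check_levels(app, "APP-context")
  if (!is.null(c99)) c99 <- check_levels(c99, "C99-context")
  if (!is.null(sapp)) sapp <- check_levels(sapp, "sAPP")
  ratio <- c(app = unname(app["Abeta42"] / app["Abeta40"]),
             c99 = if (!is.null(c99) && all(c("Abeta40", "Abeta42") %in% names(c99)))
               unname(c99["Abeta42"] / c99["Abeta40"]) else NA_real_)
  structure(list(app = app, c99 = c99, sapp = sapp,
                 ratio_42_40 = ratio, stars = stars,
                 partial = is.null(c99) || is.null(sapp)),
            class = "secretase_profile")
}

#' @export
print.secretase_profile <- function(x, ...) {
  fmt <- function(v) paste(sprintf("%s=%.2f", names(v), v), collapse = " ")
  cat("<secretase_profile>\n  APP:", fmt(x$app),
      sprintf(" ratio42/40=%.2f\n", x$ratio_42_40[["app"]]))
  if (!is.null(x$c99)) cat("  C99:", fmt(x$c99),
                           sprintf(" ratio42/40=%.2f\n", x$ratio_42_40[["c99"]]))
  if (!is.null(x$sapp)) cat("  sAPP:", fmt(x$sapp), "\n")
  invisible(x)
}

#' Build secretase profiles from quantified ELISA tables
#'
#' Each context's analyte concentrations are divided by the vehicle mean in
#' the same context (DMSO = 1); the Abeta42/40 ratio is computed after
#' normalization (the vehicle scale cancels, so it equals the raw ratio
#' relative to the vehicle's raw ratio).
#'
#' @param contexts named list (`app`, optionally `c99`, `sapp`) of
#'   data.frames with columns `sample_id, analyte, conc` — e.g. stacked
#'   [quantify_samples()] outputs, one row per sample x analyte.
#' @param vehicle_id sample id of the DMSO vehicle, present in every context.
#' @return named list of [secretase_profile()] objects, one per sample
#'   (vehicle included; its levels are all exactly 1).
#' @export
build_profile <- function(contexts, vehicle_id = "DMSO") {
  if (is.null(contexts$app)) stop_fs("an 'app' context table is required")
  norm_ctx <- function(tab) {
    if (is.null(tab)) return(NULL)
    out <- lapply(split(tab, tab$analyte), function(a) {
      veh <- a$conc[a$sample_id == vehicle_id]
      if (length(veh) == 0L) stop_fs("vehicle '%s' missing for analyte %s",
                                     vehicle_id, a$analyte[1])
      stats::setNames(a$conc / mean(veh), a$sample_id)
    })
    out
  }
  ctx <- lapply(contexts, norm_ctx)
  samples <- unique(contexts$app$sample_id)
  profiles <- lapply(samples, function(s) {
    lv <- function(cx, analytes) {
      if (is.null(cx)) return(NULL)
      v <- vapply(analytes, function(a) {
        if (!is.null(cx[[a]]) && s %in% names(cx[[a]])) cx[[a]][[s]] else NA_real_
      }, 1.0)
      v <- v[is.finite(v)]
      if (length(v)) v else NULL
    }
    secretase_profile(
      app = lv(ctx$app, c("Abeta38", "Abeta40", "Abeta42")),
      c99 = lv(ctx$c99, c("Abeta38", "Abeta40", "Abeta42")),
      sapp = lv(ctx$sapp, c("sAPPalpha", "sAPPbeta")))
  })
  stats::setNames(profiles, samples)
}

#' Classify the mechanism of action of a secretase profile
#'
#' Rule-based, first match wins, with "down" = level < `down_threshold`,
#' "up" = level > `up_threshold`, "unchanged" = inside the band:
#' \enumerate{
#'   \item gamma_inhibitor — every Abeta species down in the APP context and
#'     (C99 data present and) down in the C99 context: total gamma-cleavage
#'     block.
#'   \item gamma_modulator — Abeta42 down, Abeta38 up, Abeta42/40 ratio down:
#'     cleavage shifted towards shorter species.
#'   \item inverse_gamma_modulator — Abeta42/40 ratio up (C99 context when
#'     available, else APP).
#'   \item beta_cleavage_reduction — Abeta down in the APP context with the
#'     ratio unchanged, while gamma-cleavage itself is intact: C99-context
#'     levels unchanged (when measured) and/or sAPPbeta down with sAPPalpha
#'     unchanged. At least one of the two lines of evidence must be present.
#'   \item no_effect — every measured entry inside the band.
#'   \item unclassified — anything else.
#' }
#'
#' @param profile a [secretase_profile()].
#' @param down_threshold,up_threshold banding thresholds (defaults 0.8 and
#'   1.25, symmetric on the log scale).
#' @return list of class `mechanism_class`: `class` (one of
#'   `r paste(MECHANISM_CLASSES, collapse = ", ")`) and `rationale`.
#' @export
classify_mechanism <- function(profile, down_threshold = 0.8,
                               up_threshold = 1.25) {
  stopifnot(inherits(profile, "secretase_profile"))
  dn <- function(x) is.finite(x) & x < down_threshold
  up <- function(x) is.finite(x) & x > up_threshold
  flat <- function(x) is.finite(x) & x >= down_threshold & x <= up_threshold
  app <- profile$app; c99 <- profile$c99; sapp <- profile$sapp
  ratio <- profile$ratio_42_40
  ratio_eff <- if (is.finite(ratio[["c99"]])) ratio[["c99"]] else ratio[["app"]]

  res <- if (all(dn(app)) && !is.null(c99) && all(dn(c99))) {
    list("gamma_inhibitor",
         "all Abeta species reduced in both APP and C99 contexts")
  } else if (dn(app[["Abeta42"]]) && "Abeta38" %in% names(app) &&
             up(app[["Abeta38"]]) && dn(ratio[["app"]])) {
    list("gamma_modulator",
         "Abeta42 down, Abeta38 up, Abeta42/40 ratio down")
  } else if (up(ratio_eff)) {
    list("inverse_gamma_modulator", "Abeta42/40 ratio increased")
  } else if (all(dn(app)) && flat(ratio[["app"]]) &&
             ((!is.null(c99) && all(flat(c99))) ||
              (!is.null(sapp) && all(c("sAPPalpha", "sAPPbeta") %in% names(sapp)) &&
               dn(sapp[["sAPPbeta"]]) && flat(sapp[["sAPPalpha"]])))) {
    list("beta_cleavage_reduction",
         "Abeta down with unchanged ratio and intact gamma-cleavage (C99 unchanged and/or sAPPbeta selectively reduced)")
  } else if (all(flat(c(app, c99, sapp, ratio_eff)))) {
    list("no_effect", "all measured entries inside the unchanged band")
  } else {
    list("unclassified", "pattern matches no rule")
  }
  structure(list(class = res[[1]], rationale = res[[2]],
                 down_threshold = down_threshold, up_threshold = up_threshold),
            class = "mechanism_class")
}

#' @export
print.mechanism_class <- function(x, ...) {
  cat(sprintf("<mechanism_class> %s (%s)\n", x$class, x$rationale))
  invisible(x)
}

R1_CLASSES <- c("nitro", "halogen", "trifluoromethyl", "cyano", "hydrogen", "other")
R2_CLASSES <- c("aliphatic", "benzylpiperidinyl", "phenethylpiperidinyl", "other")
EWG_R1 <- c("nitro", "halogen", "trifluoromethyl", "cyano")
AROMATIC_R2 <- c("benzylpiperidinyl", "phenethylpiperidinyl")

#' Construct a compound annotation record
#'
#' @param compound_id unique compound identifier.
#' @param r1_class substituent class at the R1 position.
#' @param r2_class substituent class at the R2 position.
#' @param source provenance of the compound.
#' @return one-row data.frame.
#' @export
compound_record <- function(compound_id,
                            r1_class = c("other", "nitro", "halogen",
                                         "trifluoromethyl", "cyano", "hydrogen"),
                            r2_class = c("other", "aliphatic",
                                         "benzylpiperidinyl", "phenethylpiperidinyl"),
                            source = c("library", "commercial", "synthesized")) {
  data.frame(compound_id = compound_id, r1_class = match.arg(r1_class),
             r2_class = match.arg(r2_class), source = match.arg(source),
             stringsAsFactors = FALSE)
}

#' Structure-activity summary by substituent class
#'
#' Groups compounds by their (R1, R2) substituent classes, reports per-group
#' mean measured activity for every assay supplied, and attaches the
#' qualitative expectation: electron-withdrawing R1 (nitro, halogen,
#' trifluoromethyl, cyano) combined with an aromatic-bearing piperidinyl R2
#' maintains activity; hydrogen at R1 or an aliphatic R2 diminishes it.
#'
#' @param compounds data.frame of [compound_record()] rows; unannotated
#'   compounds (classes missing/NA) are grouped under `"other"`.
#' @param results optional data.frame `compound_id, assay, value` of measured
#'   activities to average per group.
#' @return data.frame `r1_class, r2_class, n_compounds, expected` plus one
#'   `mean_<assay>` column per assay.
#' @export
sar_summary <- function(compounds, results = NULL) {
  if (is.null(compounds) || nrow(compounds) == 0L) {
    return(data.frame(r1_class = character(), r2_class = character(),
                      n_compounds = integer(), expected = character(),
                      stringsAsFactors = FALSE))
  }
  fix <- function(x, valid) ifelse(is.na(x) | !x %in% valid, "other", x)
  compounds$r1_class <- fix(compounds$r1_class, R1_CLASSES)
  compounds$r2_class <- fix(compounds$r2_class, R2_CLASSES)
  key <- interaction(compounds$r1_class, compounds$r2_class, drop = TRUE)
  out <- do.call(rbind, lapply(split(compounds, key), function(g) {
    r1 <- g$r1_class[1]; r2 <- g$r2_class[1]
    expected <- if (r1 == "hydrogen" || r2 == "aliphatic") {
      "expected-inactive"
    } else if (r1 %in% EWG_R1 && r2 %in% AROMATIC_R2) {
      "expected-active"
    } else {
      "unclassified"
    }
    row <- data.frame(r1_class = r1, r2_class = r2, n_compounds = nrow(g),
                      expected = expected, stringsAsFactors = FALSE)
    if (!is.null(results)) {
      sub <- results[results$compound_id %in% g$compound_id, , drop = FALSE]
      for (a in unique(results$assay)) {
        row[[paste0("mean_", a)]] <-
          if (any(sub$assay == a)) mean(sub$value[sub$assay == a]) else NA_real_
      }
    }
    row
  }))
  rownames(out) <- NULL
  out
}
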