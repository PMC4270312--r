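# Orchestration: configuration, plate-layout generation, the end-to-end
# simulate -> quantify -> screen -> fit -> classify pipeline, and report
# rendering.

#' Generate a screening plate layout
#'
#' Lays out `n_compounds` test compounds at `n_replicates` wells each,
#' vehicle (DMSO) wells, untreated wells and the four standard
#' positive-control compounds, row-major on a 96- or 384-well plate.
#'
#' @param n_compounds number of test compounds.
#' @param n_replicates wells per compound (assay standard: 4).
#' @param n_vehicle,n_untreated numbers of control wells.
#' @param controls positive-control compound ids (2 wells each).
#' @param concentration test concentration in molar (assay standard: 10 uM).
#' @param format plate format (96 or 384).
#' @param plate_id plate identifier.
#' @param compound_ids optional explicit compound ids.
#' @return a [plate_layout()].
#' @export
make_screen_layout <- function(n_compounds, n_replicates = 4L, n_vehicle = 8L,
                               n_untreated = 4L,
                               controls = names(positive_control_presets()),
                               concentration = 1e-5, format = 384L,
                               plate_id = "plate01", compound_ids = NULL) {
  if (is.null(compound_ids)) {
    compound_ids <- sprintf("cpd_%03d", seq_len(n_compounds))
  }
  dims <- plate_dims(format)
  rows <- data.frame(
    role = c(rep("vehicle", n_vehicle), rep("untreated", n_untreated),
             rep("positive_control", 2L * length(controls)),
             rep("test", n_compounds * n_replicates)),
    compound_id = c(rep(NA_character_, n_vehicle + n_untreated),
                    rep(controls, each = 2L),
                    rep(compound_ids, each = n_replicates)),
    stringsAsFactors = FALSE)
  if (nrow(rows) > dims["rows"] * dims["cols"]) {
    stop_fs("layout needs %d wells but the %d-well plate has %d",
            nrow(rows), format, dims["rows"] * dims["cols"])
  }
  idx <- seq_len(nrow(rows)) - 1L
  rows$address <- paste0(LETTERS[idx %/% dims["cols"] + 1L],
                         idx %% dims["cols"] + 1L)
  rows$concentration <- ifelse(rows$role %in% c("test", "positive_control"),
                               concentration, NA_real_)
  rows$replicate_group <- ifelse(is.na(rows$compound_id), rows$role,
                                 rows$compound_id)
  plate_layout(plate_id, format, rows)
}

#' Build a run configuration
#'
#' All tunable analysis parameters in one serializable object; a run is
#' reproducible from (config, seed).
#'
#' @param seed integer seed for every stochastic stage.
#' @param n_compounds,n_replicates plate design.
#' @param active_compounds indices (into the compound list) simulated with
#'   `active_scaling`; all others are inert (scaling 1).
#' @param active_scaling true multiplicative peak scaling of actives.
#' @param genotype_factor mutant-vs-wild-type peak enhancement.
#' @param base_amplitude wild-type well-level peak delta-F/F0.
#' @param n_cells cells per well.
#' @param noise_cv,cell_cv,fraction_nonresponsive noise model.
#' @param responder_theta responder threshold on peak delta-F/F0.
#' @param hit_threshold hit threshold on normalized ER calcium.
#' @param down_threshold,up_threshold mechanism banding thresholds.
#' @param min_responsive_frac toxicity-interference well exclusion.
#' @param render render image stacks and run segmentation (slow) instead of
#'   the trace-level fast path.
#' @param schedule an [acq_schedule()].
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_compounds = 24L, n_replicates = 4L,
                       active_compounds = seq_len(max(1L, n_compounds %/% 3L)),
                       active_scaling = 0.7, genotype_factor = 1.5,
                       base_amplitude = 0.8, n_cells = 60L,
                       noise_cv = 0.02, cell_cv = 0.2,
                       fraction_nonresponsive = 0.1,
                       responder_theta = 0.1, hit_threshold = 0.9,
                       down_threshold = 0.8, up_threshold = 1.25,
                       min_responsive_frac = 0.2, render = FALSE,
                       schedule = default_schedule()) {
  structure(as.list(environment()), class = "run_config")
}

#' Serialize / restore a run configuration (JSON)
#' @param config a [run_config()].
#' @param path JSON path.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$schedule <- list(timestamps = x$schedule$timestamps,
                     dispense_index = x$schedule$dispense_index)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$schedule <- acq_schedule(x$schedule$timestamps, x$schedule$dispense_index)
  x$active_compounds <- as.integer(x$active_compounds)
  do.call(run_config, x)
}

# reference secretase fingerprints used for the mechanism section of the
# demo pipeline; synthetic constructions mirroring the canonical controls
synthetic_mechanism_presets <- function() {
  list(
    DAPT_like = list(app = c(Abeta38 = 0.2, Abeta40 = 0.2, Abeta42 = 0.2),
                     c99 = c(Abeta38 = 0.2, Abeta40 = 0.2, Abeta42 = 0.2)),
    sulindac_like = list(app = c(Abeta38 = 1.6, Abeta40 = 1.0, Abeta42 = 0.5)),
    bepridil_like = list(app = c(Abeta38 = 0.9, Abeta40 = 0.8, Abeta42 = 1.4),
                         c99 = c(Abeta38 = 0.9, Abeta40 = 0.8, Abeta42 = 1.4)),
    gea133_like = list(app = c(Abeta38 = 0.5, Abeta40 = 0.5, Abeta42 = 0.5),
                       c99 = c(Abeta38 = 1.0, Abeta40 = 1.0, Abeta42 = 1.0),
                       sapp = c(sAPPalpha = 1.0, sAPPbeta = 0.5)),
    vehicle_like = list(app = c(Abeta38 = 1.0, Abeta40 = 1.0, Abeta42 = 1.0)))
}

#' Run the full screening pipeline
#'
#' simulate plate -> (optionally render + segment) -> quantify calcium ->
#' normalize/aggregate/call hits -> QC -> Dunnett statistics -> TMRM
#' dose-response fit -> ELISA quantification + mechanism classification ->
#' SAR summary, with a reproducibility manifest.
#'
#' @param config a [run_config()].
#' @return list of class `report_bundle` with elements `hit_table`, `plate`,
#'   `qc`, `stats`, `dose_fit`, `mechanisms`, `sar`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cpds <- sprintf("cpd_%03d", seq_len(config$n_compounds))
  effects <- stats::setNames(rep(1, config$n_compounds), cpds)
  effects[config$active_compounds] <- config$active_scaling
  layout <- make_screen_layout(config$n_compounds, config$n_replicates,
                               compound_ids = cpds)
  fspec <- field_spec(n_cells = config$n_cells,
                      fraction_nonresponsive = config$fraction_nonresponsive)
  sim <- simulate_screen_plate(
    layout, effects, genotype_factor = config$genotype_factor,
    base_amplitude = config$base_amplitude, schedule = config$schedule,
    spec = fspec, noise_cv = config$noise_cv, cell_cv = config$cell_cv,
    seed = config$seed, render = config$render)

  summaries <- do.call(rbind, lapply(names(sim$wells), function(addr) {
    w <- sim$wells[[addr]]
    if (config$render) {
      nuclei <- detect_nuclei(w$stack$nuclear)
      cyto <- w$stack$cfp[, , 1] + w$stack$yfp[, , 1]
      seg <- grow_cell_boundaries(cyto, nuclei)
      kept <- exclude_edge_cells(seg$cells, seg$labels)
      if (nrow(kept) == 0L) {
        return(data.frame(address = addr, n_cells = 0L, n_responsive = 0L,
                          mean_peak = NA_real_, sd_peak = NA_real_,
                          valid = FALSE, stringsAsFactors = FALSE))
      }
      traces <- lapply(kept$cell_id, function(id) {
        compute_dff(extract_ratio_trace(w$stack, seg$labels, id,
                                        background = "field"),
                    config$schedule, config$responder_theta, cell_id = id)
      })
      summarize_well(traces, config$schedule, config$responder_theta, addr)
    } else {
      summarize_well(w$traces, config$schedule, config$responder_theta, addr)
    }
  }))

  plate <- normalize_to_vehicle(summaries, layout)
  per_compound <- aggregate_replicates(plate, config$min_responsive_frac)
  hits <- call_hits(per_compound, config$hit_threshold)
  qc <- qc_plate(plate, config$hit_threshold)
  stats_res <- plate_dunnett(plate)
  hits$stars <- stats_res$comparisons$star[
    match(hits$compound_id, stats_res$comparisons$group)]

  dose_tab <- simulate_dose_table(
    gea133_tmrm_4pl(), concentrations = 10^seq(log10(1e-7), log10(3e-5), length.out = 6),
    n_replicates = 8L, noise_cv = 0.05, seed = child_seed(config$seed, 101L),
    compound_id = "gea_133")
  dose_fit <- fit_4pl(dose_tab$conc, dose_tab$response, direction = "up")

  mech_presets <- synthetic_mechanism_presets()
  calib <- four_pl(bottom = 50, top = 30000, ec50 = 500, hill = 1.1)
  standards <- 500 * 4^seq(-4, 4)
  mechanisms <- lapply(names(mech_presets), function(nm) {
    pr <- mech_presets[[nm]]
    base <- c(Abeta38 = 400, Abeta40 = 900, Abeta42 = 120,
              sAPPalpha = 600, sAPPbeta = 700)
    ctx_tables <- lapply(pr, function(levels) {
      analytes <- names(levels)
      truth <- c(stats::setNames(base[analytes], analytes))
      samples <- c(stats::setNames(truth * levels, analytes))
      do.call(rbind, lapply(analytes, function(a) {
        plate_tab <- simulate_elisa_plate(
          calib, standards,
          c(DMSO = unname(truth[a]), cpd = unname(samples[a])),
          noise_cv = 0.02, seed = child_seed(config$seed, 200L + nchar(nm)))
        cal <- elisa_calibration(
          plate_tab$conc[plate_tab$type == "standard"],
          plate_tab$signal[plate_tab$type == "standard"],
          analyte = if (a %in% ELISA_ANALYTES) a else "Abeta40")
        q <- quantify_samples(cal, plate_tab[plate_tab$type == "sample", ])
        data.frame(sample_id = q$sample_id, analyte = a, conc = q$conc,
                   stringsAsFactors = FALSE)
      }))
    })
    profs <- build_profile(ctx_tables, vehicle_id = "DMSO")
    cls <- classify_mechanism(profs[["cpd"]], config$down_threshold,
                              config$up_threshold)
    list(name = nm, profile = profs[["cpd"]], classification = cls)
  })
  names(mechanisms) <- names(mech_presets)

  sar_compounds <- do.call(rbind, list(
    compound_record("gea_133", "cyano", "benzylpiperidinyl", "synthesized"),
    compound_record("cpd_5781464", "nitro", "benzylpiperidinyl", "commercial"),
    compound_record("cpd_5781441", "nitro", "phenethylpiperidinyl", "commercial"),
    compound_record("cpd_h", "hydrogen", "benzylpiperidinyl", "synthesized"),
    compound_record("cpd_ali", "nitro", "aliphatic", "commercial")))
  sar <- sar_summary(sar_compounds)

  cfg_path <- tempfile(fileext = ".json")
  save_config(config, cfg_path)
  manifest <- list(
    package = "fretscreen",
    version = as.character(utils::packageVersion("fretscreen")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_wells = nrow(layout$wells))
  unlink(cfg_path)

  structure(list(hit_table = hits, plate = plate, qc = qc, stats = stats_res,
                 dose_fit = dose_fit, dose_table = dose_tab,
                 mechanisms = mechanisms, sar = sar, layout = layout,
                 truth = sim$truth, manifest = manifest),
            class = "report_bundle")
}

#' Render a report bundle as markdown
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @return character vector of markdown lines (also usable via
#'   `writeLines`).
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  fmt_tab <- function(df, digits = 4) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, digits))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i) {
        paste0("| ", paste(vapply(df[i, ], function(v) {
          if (is.na(v)) "NA" else as.character(v)
        }, ""), collapse = " | "), " |")
      }, ""))
  }
  n_active <- sum(bundle$hit_table$active, na.rm = TRUE)
  lines <- c(
    "# FRET calcium screening report",
    "",
    sprintf("Seed %s, config hash `%s`, package %s %s.",
            bundle$manifest$seed, bundle$manifest$config_hash,
            bundle$manifest$package, bundle$manifest$version),
    "",
    "## Plate QC",
    "",
    if (!bundle$qc$plate_pass) "**WARNING: plate QC FAILED**" else
      "Plate QC passed (all positive controls below threshold).",
    sprintf("Reason: %s", bundle$qc$reason),
    "",
    if (nrow(bundle$qc$controls)) fmt_tab(bundle$qc$controls) else NULL,
    "",
    "## Hit calling (normalized ER calcium < 0.9)",
    "",
    if (n_active == 0L) "Zero active compounds." else
      sprintf("%d active compound(s).", n_active),
    "",
    fmt_tab(bundle$hit_table),
    "",
    "Stars: n.s., non-significant; *P<0.05, **P<0.01, ***P<0.001",
    "(Dunnett vs vehicle).",
    "",
    "## TMRM dose-response",
    "",
    if (isTRUE(bundle$dose_fit$degenerate)) "Degenerate fit (flat data)." else
      sprintf("Fitted EC50 = %.2f uM (hill %.2f, bottom %.2f, top %.2f).",
              bundle$dose_fit$params$ec50 * 1e6, bundle$dose_fit$params$hill,
              bundle$dose_fit$params$bottom, bundle$dose_fit$params$top),
    "",
    "## Mechanism classification",
    "",
    fmt_tab(data.frame(
      compound = names(bundle$mechanisms),
      class = vapply(bundle$mechanisms, function(m) m$classification$class, ""),
      rationale = vapply(bundle$mechanisms, function(m) m$classification$rationale, ""))),
    "",
    "## SAR by substituent class",
    "",
    fmt_tab(bundle$sar))
  lines[!is.na(lines)]
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d compounds, %d active, QC %s\n",
              nrow(x$hit_table), sum(x$hit_table$active, na.rm = TRUE),
              if (x$qc$plate_pass) "pass" else "FAIL"))
  invisible(x)
}
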