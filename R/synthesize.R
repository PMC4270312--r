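# Ground-truthed synthetic inputs: calcium transients, rendered image fields,
# whole screening plates, dose-response tables and ELISA plates.
#
# All generators are pure functions of (parameters, seed).

#' Parameters of a synthetic carbachol-evoked calcium transient
#'
#' @param baseline_ratio pre-stimulus YFP/CFP ratio R0 (> 0).
#' @param peak_dff true peak delta-F/F0 amplitude A (>= 0; 0 = nonresponder).
#' @param rise_tau,decay_tau rise and decay time constants in seconds;
#'   `decay_tau > rise_tau > 0`.
#' @param noise_cv coefficient of variation of multiplicative Gaussian noise.
#' @return object of class `transient_params`.
#' @export
transient_params <- function(baseline_ratio = 1.5, peak_dff = 0.8,
                             rise_tau = 0.5, decay_tau = 4, noise_cv = 0) {
  if (baseline_ratio <= 0) stop_fs("baseline_ratio must be > 0")
  if (peak_dff < 0) stop_fs("peak amplitude must be >= 0")
  if (!(decay_tau > rise_tau && rise_tau > 0)) {
    stop_fs("need decay_tau > rise_tau > 0")
  }
  if (noise_cv < 0) stop_fs("noise_cv must be >= 0")
  structure(list(baseline_ratio = baseline_ratio, peak_dff = peak_dff,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 noise_cv = noise_cv),
            class = "transient_params")
}

#' Simulate one YFP/CFP ratio trace
#'
#' Pre-stimulus frames sit at the baseline ratio R0. From the dispense time
#' (the last pre-stimulus timestamp) the noiseless trace follows
#' `R0 * (1 + A * g(t)/max(g))` with `g(t) = (1 - exp(-(t-td)/rise)) *
#' exp(-(t-td)/decay)`, the maximum taken over the post-dispense frames, so
#' the noiseless peak delta-F/F0 equals A exactly. Multiplicative Gaussian
#' noise with CV `noise_cv` is applied to every frame.
#'
#' @param params a [transient_params()].
#' @param schedule an [acq_schedule()].
#' @param seed integer seed.
#' @return numeric ratio series, one value per frame.
#' @export
simulate_transient <- function(params, schedule = default_schedule(), seed = 1L) {
  stopifnot(inherits(params, "transient_params"), inherits(schedule, "acq_schedule"))
  ts <- schedule$timestamps
  di <- schedule$dispense_index
  td <- ts[di - 1L]
  r <- rep(params$baseline_ratio, length(ts))
  if (params$peak_dff > 0) {
    post <- seq(di, length(ts))
    dt <- ts[post] - td
    g <- (1 - exp(-dt / params$rise_tau)) * exp(-dt / params$decay_tau)
    r[post] <- params$baseline_ratio * (1 + params$peak_dff * g / max(g))
  }
  if (params$noise_cv > 0) {
    r <- with_seed(seed, r * (1 + stats::rnorm(length(r), 0, params$noise_cv)))
  }
  r
}

#' Geometry and intensity specification for a rendered imaging field
#'
#' @param height,width field size in pixels.
#' @param n_cells number of cells to place.
#' @param cell_radius range (min, max) of cell disk radii in pixels.
#' @param nucleus_radius range of nucleus radii; must stay below the cell radius.
#' @param fraction_nonresponsive fraction of cells simulated with zero peak.
#' @param fraction_edge fraction of cells intersecting the image border.
#' @param cell_intensity per-pixel CFP+YFP signal sum inside a cell (a.u.).
#' @param nuclear_intensity nuclear-dye per-pixel intensity inside nuclei.
#' @param background background level outside cells in the FRET channels.
#' @param background_noise Gaussian sd added to every pixel when > 0.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(height = 128L, width = 128L, n_cells = 20L,
                       cell_radius = c(8, 11), nucleus_radius = c(3, 4),
                       fraction_nonresponsive = 0.1, fraction_edge = 0.1,
                       cell_intensity = 200, nuclear_intensity = 150,
                       background = 5, background_noise = 0) {
  if (max(nucleus_radius) >= min(cell_radius)) {
    stop_fs("nucleus radius must be smaller than cell radius")
  }
  if (fraction_nonresponsive < 0 || fraction_nonresponsive > 1 ||
      fraction_edge < 0 || fraction_edge > 1) {
    stop_fs("fractions must lie in [0, 1]")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 cell_radius = cell_radius, nucleus_radius = nucleus_radius,
                 fraction_nonresponsive = fraction_nonresponsive,
                 fraction_edge = fraction_edge,
                 cell_intensity = cell_intensity,
                 nuclear_intensity = nuclear_intensity,
                 background = background, background_noise = background_noise),
            class = "field_spec")
}

# Rejection-sample non-overlapping disk centers; a share of cells is forced
# onto the border. Returns data.frame(center_row, center_col, radius, edge).
place_cells <- function(spec, radii, max_tries = 500L) {
  n <- spec$n_cells
  n_edge <- round(spec$fraction_edge * n)
  rows <- cols <- numeric(0); edge <- logical(0); rad <- numeric(0)
  for (i in seq_len(n)) {
    r <- radii[i]
    want_edge <- i <= n_edge
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (want_edge) {
        side <- sample.int(4L, 1L)
        off <- stats::runif(1, 1, r - 1)  # center within r of the border
        cr <- switch(side, off, spec$height - off + 1,
                     stats::runif(1, r + 2, spec$height - r - 1),
                     stats::runif(1, r + 2, spec$height - r - 1))
        cc <- switch(side, stats::runif(1, r + 2, spec$width - r - 1),
                     stats::runif(1, r + 2, spec$width - r - 1),
                     off, spec$width - off + 1)
      } else {
        cr <- stats::runif(1, r + 2, spec$height - r - 1)
        cc <- stats::runif(1, r + 2, spec$width - r - 1)
      }
      if (length(rows) == 0L ||
          all(sqrt((rows - cr)^2 + (cols - cc)^2) > rad + r + 2)) {
        rows <- c(rows, cr); cols <- c(cols, cc)
        rad <- c(rad, r); edge <- c(edge, want_edge)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop_fs("could not place %d non-overlapping cells in a %dx%d field",
              n, spec$height, spec$width)
    }
  }
  data.frame(center_row = rows, center_col = cols, radius = rad, edge = edge)
}

#' Render a multi-channel time-lapse field from per-cell ratio traces
#'
#' Produces a CFP stack, a YFP stack (both `height x width x n_frames`) and a
#' single nuclear-dye frame. Inside a cell the two FRET channels redistribute
#' a frame-constant per-pixel sum `S` so that `YFP/CFP` equals the cell's
#' ratio at that frame: `CFP = S/(1+r)`, `YFP = S*r/(1+r)`. A uniform
#' background level is added to every pixel of both FRET channels (as in a
#' real camera image), so with noise off the background-subtracted pixel-mean
#' ratio of a cell reproduces its trace exactly — for any segmentation mask
#' overlapping the cell, since background pixels cancel under subtraction.
#' The nuclear channel is nonzero only in nuclei (plus noise, when enabled).
#'
#' @param spec a [field_spec()].
#' @param traces matrix `n_cells x n_frames` of YFP/CFP ratios (rows = cells),
#'   or a list of equal-length numeric vectors.
#' @param seed integer seed (placement geometry and pixel noise).
#' @param truth_peaks optional numeric vector of true peak amplitudes to carry
#'   into the ground truth; `NA` if omitted.
#' @return list with `stack` (list: `cfp`, `yfp` arrays; `nuclear` matrix) and
#'   `truth` (list: `cells` data.frame, `cell_labels`, `nucleus_labels`).
#' @export
render_field <- function(spec, traces, seed = 1L, truth_peaks = NULL) {
  stopifnot(inherits(spec, "field_spec"))
  if (is.list(traces) && !is.matrix(traces)) {
    traces <- do.call(rbind, traces)
  }
  if (spec$n_cells == 0L) {
    n_frames <- if (is.matrix(traces)) ncol(traces) else 1L
    empty <- array(spec$background, dim = c(spec$height, spec$width, n_frames))
    return(list(
      stack = list(cfp = empty, yfp = empty,
                   nuclear = matrix(0, spec$height, spec$width)),
      truth = list(cells = data.frame(),
                   cell_labels = matrix(0L, spec$height, spec$width),
                   nucleus_labels = matrix(0L, spec$height, spec$width))))
  }
  if (!is.matrix(traces) || nrow(traces) != spec$n_cells) {
    stop_fs("need one ratio trace per cell (%d)", spec$n_cells)
  }
  n_frames <- ncol(traces)

  with_seed(seed, {
    radii <- stats::runif(spec$n_cells, spec$cell_radius[1], spec$cell_radius[2])
    nradii <- stats::runif(spec$n_cells, spec$nucleus_radius[1], spec$nucleus_radius[2])
    cells <- place_cells(spec, radii)
    cells$nucleus_radius <- nradii
    cells$cell_id <- seq_len(spec$n_cells)

    H <- spec$height; W <- spec$width
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    cell_labels <- matrix(0L, H, W)
    nucleus_labels <- matrix(0L, H, W)
    for (i in seq_len(spec$n_cells)) {
      d2 <- (rr - cells$center_row[i])^2 + (cc - cells$center_col[i])^2
      cell_labels[d2 <= cells$radius[i]^2] <- i
      nucleus_labels[d2 <= cells$nucleus_radius[i]^2] <- i
    }
    # recompute the edge flag from rendered pixels (authoritative)
    border <- cell_labels
    border[2:(H - 1L), 2:(W - 1L)] <- 0L
    cells$edge <- cells$cell_id %in% setdiff(unique(as.vector(border)), 0L)

    inside <- cell_labels > 0L
    S <- spec$cell_intensity
    cfp <- array(0, dim = c(H, W, n_frames))
    yfp <- array(0, dim = c(H, W, n_frames))
    for (f in seq_len(n_frames)) {
      r_at <- traces[cell_labels[inside], f]
      cf <- matrix(spec$background, H, W)
      yf <- matrix(spec$background, H, W)
      cf[inside] <- cf[inside] + S / (1 + r_at)
      yf[inside] <- yf[inside] + S * r_at / (1 + r_at)
      cfp[, , f] <- cf
      yfp[, , f] <- yf
    }
    nuclear <- matrix(0, H, W)
    nuclear[nucleus_labels > 0L] <- spec$nuclear_intensity
    if (spec$background_noise > 0) {
      cfp <- cfp + stats::rnorm(length(cfp), 0, spec$background_noise)
      yfp <- yfp + stats::rnorm(length(yfp), 0, spec$background_noise)
      nuclear <- nuclear + abs(stats::rnorm(length(nuclear), 0, spec$background_noise))
    }
    cells$true_peak_dff <- if (is.null(truth_peaks)) NA_real_ else truth_peaks
    cells$responsive <- if (is.null(truth_peaks)) NA else truth_peaks > 0
    list(stack = list(cfp = cfp, yfp = yfp, nuclear = nuclear),
         truth = list(cells = cells, cell_labels = cell_labels,
                      nucleus_labels = nucleus_labels))
  })
}

#' Default peak-scaling presets for the plate positive controls
#'
#' Thapsigargin, cyclopiazonic acid, TMB-8 and Bepridil all lower ER calcium
#' release; the scalings are package defaults, configurable per call.
#' @return named numeric vector of multiplicative peak scalings.
#' @export
positive_control_presets <- function() {
  c(TP = 0.15, CPA = 0.2, `TMB-8` = 0.4, Bepridil = 0.5)
}

#' Simulate per-cell calcium traces for one well
#'
#' Per-cell true amplitudes are `A_well` jittered by a lognormal cell-to-cell
#' factor (CV `cell_cv`); a `fraction_nonresponsive` share of cells gets
#' amplitude 0.
#'
#' @param n_cells cells in the well.
#' @param amplitude well-level true peak delta-F/F0.
#' @param schedule an [acq_schedule()].
#' @param baseline_ratio baseline YFP/CFP ratio.
#' @param fraction_nonresponsive share of zero-amplitude cells.
#' @param cell_cv lognormal CV of per-cell amplitude heterogeneity.
#' @param noise_cv frame-level multiplicative noise CV.
#' @param seed integer seed.
#' @return list: `traces` (matrix cells x frames), `true_peaks`, `responsive`.
#' @export
simulate_well_traces <- function(n_cells, amplitude, schedule = default_schedule(),
                                 baseline_ratio = 1.5,
                                 fraction_nonresponsive = 0.1,
                                 cell_cv = 0.2, noise_cv = 0.02, seed = 1L) {
  with_seed(seed, {
    nonresp <- stats::runif(n_cells) < fraction_nonresponsive
    jitter <- if (cell_cv > 0) {
      sl <- sqrt(log(1 + cell_cv^2))
      exp(stats::rnorm(n_cells, -sl^2 / 2, sl))
    } else {
      rep(1, n_cells)
    }
    peaks <- ifelse(nonresp, 0, amplitude * jitter)
    seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
    traces <- t(vapply(seq_len(n_cells), function(i) {
      simulate_transient(
        transient_params(baseline_ratio = baseline_ratio, peak_dff = peaks[i],
                         noise_cv = noise_cv),
        schedule, seed = seeds[i])
    }, numeric(length(schedule$timestamps))))
    list(traces = traces, true_peaks = peaks, responsive = !nonresp)
  })
}

#' Simulate a whole screening plate
#'
#' Vehicle and untreated wells get peak scaling 1; positive-control wells use
#' their presets; test wells take their scaling from `effects`. The well
#' amplitude is `base_amplitude * genotype_factor * scaling`, the mutant
#' genotype enhancement defaulting to 1.5 over wild type.
#'
#' @param layout a [plate_layout()].
#' @param effects named numeric vector/list mapping compound_id to peak
#'   scaling in (0, 1]. Every test compound must be present.
#' @param genotype_factor mutant-vs-wild-type peak enhancement factor.
#' @param base_amplitude wild-type well-level peak delta-F/F0.
#' @param control_presets named scalings for positive-control compounds.
#' @param schedule an [acq_schedule()].
#' @param spec a [field_spec()]; its `fraction_nonresponsive` is used for the
#'   trace simulation too.
#' @param noise_cv,cell_cv noise parameters, see [simulate_well_traces()].
#' @param seed integer seed.
#' @param render if `TRUE` each well is rendered to an image stack; if
#'   `FALSE` only per-cell traces are produced (fast path for large plates).
#' @return list with `wells` (named by address: `traces`, `true_peaks`,
#'   `scaling`, `amplitude`, and when rendered `stack` + `truth`) and
#'   `truth` data.frame (one row per well).
#' @export
simulate_screen_plate <- function(layout, effects, genotype_factor = 1.5,
                                  base_amplitude = 0.8,
                                  control_presets = positive_control_presets(),
                                  schedule = default_schedule(),
                                  spec = field_spec(),
                                  noise_cv = 0.02, cell_cv = 0.2,
                                  seed = 1L, render = FALSE) {
  stopifnot(inherits(layout, "plate_layout"))
  effects <- unlist(effects)
  wl <- layout$wells
  test_cpds <- unique(wl$compound_id[wl$role == "test"])
  missing <- setdiff(test_cpds, names(effects))
  if (length(missing)) {
    stop_fs("no effect specified for compound(s): %s", paste(missing, collapse = ", "))
  }
  scaling <- vapply(seq_len(nrow(wl)), function(i) {
    switch(wl$role[i],
      vehicle = , untreated = 1,
      positive_control = {
        s <- control_presets[[wl$compound_id[i]]]
        if (is.null(s)) stop_fs("no preset for positive control %s", wl$compound_id[i])
        s
      },
      test = effects[[wl$compound_id[i]]])
  }, 1.0)
  amplitude <- base_amplitude * genotype_factor * scaling

  wells <- vector("list", nrow(wl))
  names(wells) <- wl$address
  for (i in seq_len(nrow(wl))) {
    ws <- child_seed(seed, i)
    tr <- simulate_well_traces(
      n_cells = spec$n_cells, amplitude = amplitude[i], schedule = schedule,
      fraction_nonresponsive = spec$fraction_nonresponsive,
      cell_cv = cell_cv, noise_cv = noise_cv, seed = ws)
    w <- list(traces = tr$traces, true_peaks = tr$true_peaks,
              scaling = scaling[i], amplitude = amplitude[i])
    if (render) {
      rf <- render_field(spec, tr$traces, seed = child_seed(ws, 1L),
                         truth_peaks = tr$true_peaks)
      w$stack <- rf$stack
      w$truth <- rf$truth
    }
    wells[[i]] <- w
  }
  truth <- data.frame(address = wl$address, role = wl$role,
                      compound_id = wl$compound_id,
                      scaling = scaling, amplitude = amplitude,
                      stringsAsFactors = FALSE)
  list(wells = wells, truth = truth)
}

#' Simulate a dose-response table from a 4PL ground truth
#'
#' @param fpl a [four_pl()] (concentration unit = molar).
#' @param concentrations positive molar concentrations.
#' @param n_replicates replicate measurements per concentration.
#' @param noise_cv multiplicative Gaussian noise CV.
#' @param seed integer seed.
#' @param compound_id label written into the table.
#' @return data.frame `compound_id, conc, conc_uM, replicate, response`.
#' @export
simulate_dose_table <- function(fpl, concentrations, n_replicates = 8L,
                                noise_cv = 0, seed = 1L,
                                compound_id = "compound") {
  stopifnot(inherits(fpl, "four_pl"))
  if (any(concentrations <= 0)) stop_fs("concentrations must be positive")
  tab <- expand.grid(replicate = seq_len(n_replicates), conc = concentrations)
  mu <- predict_4pl(fpl, tab$conc)
  resp <- if (noise_cv > 0) {
    with_seed(seed, mu * (1 + stats::rnorm(length(mu), 0, noise_cv)))
  } else {
    mu
  }
  data.frame(compound_id = compound_id, conc = tab$conc,
             conc_uM = tab$conc * 1e6, replicate = tab$replicate,
             response = resp, stringsAsFactors = FALSE)
}

#' Simulate an ELISA plate (calibration standards + unknown samples)
#'
#' @param calib a [four_pl()] mapping concentration to signal.
#' @param standard_concs concentrations of the calibration standards (molar or
#'   pg/ml; any unit, consistently).
#' @param sample_concs named numeric vector of true sample concentrations.
#' @param noise_cv multiplicative noise CV on all signals.
#' @param n_replicates wells per sample/standard (assay default 2).
#' @param seed integer seed.
#' @return data.frame `sample_id, type, conc, replicate, signal` (conc is NA
#'   for unknowns).
#' @export
simulate_elisa_plate <- function(calib, standard_concs, sample_concs,
                                 noise_cv = 0, n_replicates = 2L, seed = 1L) {
  stopifnot(inherits(calib, "four_pl"))
  if (length(standard_concs) == 0L) stop_fs("no calibration standards")
  if (length(sample_concs)) {
    pos <- sample_concs[sample_concs > 0]
    if (length(pos) &&
        (min(pos) < min(standard_concs) || max(pos) > max(standard_concs))) {
      warn_fs("sample concentrations fall outside the standard range")
    }
  }
  ids <- c(sprintf("std_%02d", seq_along(standard_concs)), names(sample_concs))
  conc <- c(standard_concs, unname(sample_concs))
  type <- rep(c("standard", "sample"), c(length(standard_concs), length(sample_concs)))
  tab <- expand.grid(replicate = seq_len(n_replicates), idx = seq_along(ids))
  mu <- predict_4pl(calib, conc[tab$idx])
  sig <- if (noise_cv > 0) {
    with_seed(seed, mu * (1 + stats::rnorm(length(mu), 0, noise_cv)))
  } else {
    mu
  }
  data.frame(sample_id = ids[tab$idx], type = type[tab$idx],
             conc = ifelse(type[tab$idx] == "standard", conc[tab$idx], NA_real_),
             replicate = tab$replicate, signal = sig, stringsAsFactors = FALSE)
}

#' TMRM dose-response preset for the lead derivative gea_133
#'
#' Relative TMRM intensity vs concentration: bottom 1 (vehicle level), top 2,
#' Hill slope 1, half-maximal concentration 4.84 uM.
#' @return a [four_pl()] with molar EC50.
#' @export
gea133_tmrm_4pl <- function() four_pl(bottom = 1, top = 2, ec50 = 4.84e-6, hill = 1)
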