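# Plate layouts, well specs, acquisition schedules and result serialization.

WELL_ROLES <- c("test", "vehicle", "positive_control", "untreated")

plate_dims <- function(format) {
  switch(as.character(format),
    "96"  = c(rows = 8L, cols = 12L),
    "384" = c(rows = 16L, cols = 24L),
    stop_fs("plate format must be 96 or 384, got %s", format)
  )
}

#' Parse microtiter well addresses ("A1" .. "P24")
#'
#' @param address character vector of addresses, row letter + 1-based column.
#' @return data.frame with `row` (integer), `col` (integer).
#' @export
parse_address <- function(address) {
  ok <- grepl("^[A-Pa-p][0-9]{1,2}$", address)
  if (!all(ok)) stop_fs("malformed well address: %s", paste(address[!ok], collapse = ", "))
  row <- match(toupper(substr(address, 1, 1)), LETTERS)
  col <- as.integer(sub("^[A-Pa-p]", "", address))
  data.frame(row = row, col = col)
}

#' Construct and validate a plate layout
#'
#' A layout ties well addresses to experimental roles (test, vehicle,
#' positive_control, untreated), compounds, concentrations (stored in molar)
#' and replicate groups.
#'
#' @param plate_id character plate identifier.
#' @param format well count, 96 or 384.
#' @param wells data.frame with columns `address`, `role`, `compound_id`,
#'   `concentration` (molar; `NA` for compound-free wells), `replicate_group`.
#' @return object of class `plate_layout`.
#' @export
plate_layout <- function(plate_id, format, wells) {
  format <- as.integer(format)
  dims <- plate_dims(format)
  req <- c("address", "role", "compound_id", "concentration", "replicate_group")
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols)) {
    stop_fs("plate map missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(wells) == 0L) stop_fs("no wells in plate map")
  if (anyDuplicated(wells$address)) {
    stop_fs("duplicate well address: %s",
            paste(unique(wells$address[duplicated(wells$address)]), collapse = ", "))
  }
  rc <- parse_address(wells$address)
  if (any(rc$row > dims["rows"] | rc$col > dims["cols"] | rc$col < 1L)) {
    stop_fs("well address outside a %d-well plate", format)
  }
  bad_role <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad_role)) stop_fs("unknown well role: %s", paste(bad_role, collapse = ", "))
  wells$compound_id <- as.character(wells$compound_id)
  wells$compound_id[!nzchar(wells$compound_id) | is.na(wells$compound_id)] <- NA_character_
  if (!is.numeric(wells$concentration)) stop_fs("malformed concentration column")
  veh <- wells$role %in% c("vehicle", "untreated")
  if (any(veh & !is.na(wells$compound_id))) {
    stop_fs("vehicle/untreated wells must not carry a compound_id")
  }
  tst <- wells$role == "test"
  if (any(tst & is.na(wells$compound_id))) stop_fs("test wells must carry a compound_id")
  if (any(tst & (is.na(wells$concentration) | wells$concentration <= 0))) {
    stop_fs("test wells must have concentration > 0")
  }
  # each replicate group maps to a single compound + concentration
  grp <- wells[tst, c("replicate_group", "compound_id", "concentration")]
  if (nrow(grp)) {
    per <- unique(grp)
    if (anyDuplicated(per$replicate_group)) {
      stop_fs("replicate group references more than one compound/concentration")
    }
  }
  structure(
    list(plate_id = as.character(plate_id), format = format,
         wells = wells[, req], dims = dims),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %s (%d-well), %d wells: %s\n",
              x$plate_id, x$format, nrow(x$wells),
              paste(sprintf("%s=%d", names(table(x$wells$role)),
                            as.integer(table(x$wells$role))), collapse = ", ")))
  invisible(x)
}

#' Read a plate map CSV
#'
#' Expected columns: `address,role,compound_id,concentration_uM,replicate_group`.
#' Concentrations are given in micromolar in the file and stored in molar.
#'
#' @param path CSV file path.
#' @param plate_id plate identifier; defaults to the file stem.
#' @param format 96 or 384; default inferred (384 unless all wells fit 96).
#' @return a [plate_layout()].
#' @export
load_plate_map <- function(path, plate_id = NULL,
                           format = NULL) {
  if (!file.exists(path)) stop_fs("plate map not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(concentration_uM = "character"))
  req <- c("address", "role", "compound_id", "concentration_uM", "replicate_group")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop_fs("plate map missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop_fs("no wells in plate map")
  conc_chr <- trimws(raw$concentration_uM)
  conc_uM <- suppressWarnings(as.numeric(conc_chr))
  bad <- nzchar(conc_chr) & is.na(conc_uM)
  if (any(bad)) stop_fs("malformed concentration: %s", paste(conc_chr[bad], collapse = ", "))
  if (is.null(format)) {
    rc <- parse_address(raw$address)
    format <- if (all(rc$row <= 8L & rc$col <= 12L)) 96L else 384L
  }
  wells <- data.frame(
    address = raw$address, role = raw$role, compound_id = raw$compound_id,
    concentration = conc_uM * 1e-6, replicate_group = as.character(raw$replicate_group),
    stringsAsFactors = FALSE
  )
  plate_layout(plate_id %||% sub("\\.[Cc][Ss][Vv]$", "", basename(path)), format, wells)
}

#' Write a plate map CSV (inverse of [load_plate_map()])
#' @param layout a `plate_layout`.
#' @param path output CSV path.
#' @export
save_plate_map <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  out <- layout$wells
  out$concentration_uM <- out$concentration * 1e6
  out$concentration <- NULL
  utils::write.csv(out[, c("address", "role", "compound_id",
                           "concentration_uM", "replicate_group")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct an acquisition schedule for time-lapse calcium imaging
#'
#' @param timestamps frame times in seconds, strictly increasing, starting at 0.
#' @param dispense_index 1-based index of the first frame acquired after
#'   agonist dispensing (frames `1:(dispense_index-1)` are pre-stimulus).
#' @return object of class `acq_schedule` with `total_duration` in seconds.
#' @export
acq_schedule <- function(timestamps, dispense_index) {
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  if (n < 2L) stop_fs("schedule needs at least 2 frames")
  if (timestamps[1] != 0) stop_fs("schedule must start at t = 0")
  if (any(diff(timestamps) <= 0)) stop_fs("timestamps must be strictly increasing")
  dispense_index <- as.integer(dispense_index)
  if (dispense_index < 2L || dispense_index > n) {
    stop_fs("dispense_index must leave >= 1 pre-stimulus frame and point into the series")
  }
  structure(
    list(timestamps = timestamps, dispense_index = dispense_index,
         total_duration = timestamps[n] - timestamps[1]),
    class = "acq_schedule"
  )
}

#' Default carbachol-stimulus acquisition schedule
#'
#' Pre-stimulus frames every 2.5 s for 5 s (t = 0, 2.5, 5), then after CCh
#' dispensing at 1 s resolution for 5 s (6..10 s) and at 2.5 s resolution for
#' 12.5 s (12.5..22.5 s): 13 frames, 3 pre-stimulus, 22.5 s first-to-last.
#'
#' @return an [acq_schedule()].
#' @export
default_schedule <- function() {
  acq_schedule(c(0, 2.5, 5, 6, 7, 8, 9, 10, 12.5, 15, 17.5, 20, 22.5),
               dispense_index = 4L)
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf("<acq_schedule> %d frames, %d pre-stimulus, %.1f s\n",
              length(x$timestamps), x$dispense_index - 1L, x$total_duration))
  invisible(x)
}

#' Serialize result tables (CSV) or nested profiles (JSON)
#'
#' Tabular results (data.frames) go to CSV; nested lists (e.g. secretase
#' profiles) go to JSON. Reading back with [read_results()] reproduces values
#' to better than 1e-9 relative.
#'
#' @param records non-empty data.frame or list.
#' @param path output path; extension `.csv` or `.json` selects the format.
#' @export
write_results <- function(records, path) {
  if (is.data.frame(records)) {
    if (nrow(records) == 0L) stop_fs("refusing to write an empty result table")
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::write_json(records, path, digits = NA, dataframe = "rows", na = "null")
    } else {
      utils::write.csv(format(records, digits = 17, trim = TRUE, scientific = NA),
                       path, row.names = FALSE, na = "")
    }
  } else if (is.list(records)) {
    if (length(records) == 0L) stop_fs("refusing to write an empty result object")
    jsonlite::write_json(records, path, digits = NA, auto_unbox = TRUE, na = "null")
  } else {
    stop_fs("records must be a data.frame or a list")
  }
  invisible(path)
}

#' Read back results written by [write_results()]
#' @param path CSV or JSON path.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_fs("results file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
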