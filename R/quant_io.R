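#' Column dialect for fragment-ion reports
#'
#' DIA extraction tools export fragment-level reports with vendor-specific
#' headers. A dialect maps the semantic column names this package uses to the
#' header names found in a given file. The default maps every semantic name
#' to itself, which is the layout [write_fragment_report()] and the
#' simulators produce; override individual entries for other exports, e.g.
#' `karma_dialect(protein_id = "PG.ProteinAccessions")`.
#'
#' @param ... Named overrides, `semantic_name = "file column name"`.
#' @return Named list mapping semantic names to file column names.
#' @export
karma_dialect <- function(...) {
  default <- list(
    bait_id = "bait_id",
    condition = "condition",
    replicate = "replicate",
    time_min = "time_min",
    protein_id = "protein_id",
    is_proteotypic = "is_proteotypic",
    precursor_id = "precursor_id",
    fragment_series = "fragment_series",
    fragment_index = "fragment_index",
    fragment_charge = "fragment_charge",
    channel = "channel",
    intensity = "intensity",
    excluded_flag = "excluded_flag",
    lysine_count = "lysine_count",
    missed_cleavages = "missed_cleavages"
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(default))
  if (length(bad)) {
    abort(paste0("unknown dialect field(s): ", paste(bad, collapse = ", ")),
          class = "karma_value_error")
  }
  modifyList(default, dots)
}

#' Read a fragment-ion quantification report
#'
#' Reads a long-format delimited report (one row per fragment ion x channel x
#' sample) into the tibble of fragment records consumed by the quantification
#' functions. Intensities that are empty or `NA` are normalized to 0; the
#' package-wide convention is that "detected" means intensity > 0.
#'
#' Time-0 samples (collected immediately before labeling onset) are read and
#' kept; downstream presence filtering and RMSE computation ignore them.
#'
#' @param path Path to a TSV (default) or CSV file with a header row.
#' @param dialect Column mapping from [karma_dialect()].
#' @param delim Field delimiter; `NULL` guesses from the file extension
#'   (`.csv` means comma, anything else tab).
#' @return Tibble with one row per input row and the semantic column names;
#'   attribute `n_rejected` (always reported, rows are never silently
#'   dropped — malformed values raise errors instead).
#' @export
read_fragment_report <- function(path, dialect = karma_dialect(), delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "karma_io_error")
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(unlist(dialect), names(raw))
  if (length(missing_cols)) {
    abort(
      paste0("fragment report is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "karma_format_error"
    )
  }
  x <- raw[, unlist(dialect)]
  names(x) <- names(dialect)

  parse_num <- function(v, col) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad)) {
      abort(paste0("unreadable number in column '", col, "' at data row ", bad[1],
                   ": '", v[bad[1]], "'"),
            class = "karma_value_error")
    }
    out
  }
  parse_int <- function(v, col) {
    out <- parse_num(v, col)
    as.integer(round(out))
  }
  parse_bool <- function(v, col) {
    lo <- tolower(trimws(v))
    out <- rep(NA, length(v))
    out[lo %in% c("true", "t", "1", "yes")] <- TRUE
    out[lo %in% c("false", "f", "0", "no")] <- FALSE
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      abort(paste0("unreadable logical in column '", col, "' at data row ", bad[1]),
            class = "karma_value_error")
    }
    out
  }

  chan <- tolower(trimws(x$channel))
  bad_chan <- which(!chan %in% c("light", "heavy"))
  if (length(bad_chan)) {
    abort(paste0("unknown channel label '", x$channel[bad_chan[1]],
                 "' at data row ", bad_chan[1], " (expected 'light' or 'heavy')"),
          class = "karma_value_error")
  }
  cond <- tolower(trimws(x$condition))
  bad_cond <- which(!cond %in% c("treated", "control", "none"))
  if (length(bad_cond)) {
    abort(paste0("unknown condition label '", x$condition[bad_cond[1]],
                 "' at data row ", bad_cond[1]),
          class = "karma_value_error")
  }

  out <- tibble(
    bait_id = x$bait_id,
    condition = cond,
    replicate = parse_int(x$replicate, "replicate"),
    time_min = parse_num(x$time_min, "time_min"),
    protein_id = x$protein_id,
    is_proteotypic = parse_bool(x$is_proteotypic, "is_proteotypic"),
    precursor_id = x$precursor_id,
    fragment_series = tolower(trimws(x$fragment_series)),
    fragment_index = parse_int(x$fragment_index, "fragment_index"),
    fragment_charge = parse_int(x$fragment_charge, "fragment_charge"),
    channel = chan,
    intensity = parse_num(x$intensity, "intensity"),
    excluded_flag = parse_bool(x$excluded_flag, "excluded_flag"),
    lysine_count = parse_int(x$lysine_count, "lysine_count"),
    missed_cleavages = parse_int(x$missed_cleavages, "missed_cleavages")
  )
  # empty / NA intensity means "not detected"; normalize to the 0 convention
  out$intensity[is.na(out$intensity)] <- 0
  if (any(out$intensity < 0)) {
    abort(paste0("negative intensity at data row ", which(out$intensity < 0)[1]),
          class = "karma_value_error")
  }
  if (any(out$replicate < 1, na.rm = TRUE)) {
    abort("replicate numbers must be >= 1", class = "karma_value_error")
  }
  attr(out, "n_rejected") <- 0L
  out
}

#' Write a result table as delimited text
#'
#' Writes any uniform-schema table (fragment records, labeling profiles,
#' fit results) as TSV/CSV with full numeric precision, so that a write/read
#' round trip reproduces doubles to better than 1e-12 relative error and
#' integers bitwise.
#'
#' @param rows Data frame to write.
#' @param path Output path; `.csv` extension selects comma delimiting.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(rows, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
write_fragment_report <- function(rows, path) write_table(rows, path)

#' Read and write run configuration
#'
#' Run configuration (filter policies, tier maps, simulation design, seed) is
#' stored as YAML. [karma_config()] builds a complete configuration with
#' documented defaults; values supplied by the user override defaults.
#'
#' @param ... Named overrides of the default configuration entries.
#' @return Nested list with class `karma_config`.
#' @export
karma_config <- function(...) {
  default <- list(
    seed = 1L,
    min_reps_per_timepoint = 2L,       # presence policy (relaxed variant: 1)
    discard_fraction = 0.5,            # RMSE pruning share
    detection_threshold = 0,           # intensity > threshold counts as detected
    aggregation = "sum_all",           # or "top3"
    doubling_time_min = 120,
    tier_map = list(),                 # bait_id -> early / intermediate / late
    simulate = list(
      time_grid_min = c(0, 30, 60, 90),
      replicates = 3L,
      n_proteins_per_class = 4L,
      n_precursors = 5L,
      n_fragments = 6L,
      noise_sigma = 0.2,
      missing_rate = 0.05,
      early_late_factor = 5,
      mixing_fraction = 1
    )
  )
  cfg <- modifyList(default, list(...))
  if (cfg$discard_fraction < 0 || cfg$discard_fraction >= 1) {
    abort("discard_fraction must lie in [0, 1)", class = "karma_value_error")
  }
  if (cfg$min_reps_per_timepoint < 0) {
    abort("min_reps_per_timepoint must be >= 0", class = "karma_value_error")
  }
  structure(cfg, class = "karma_config")
}

#' @rdname karma_config
#' @param path Path of a YAML configuration file.
#' @export
read_config <- function(path) {
  do.call(karma_config, yaml::read_yaml(path))
}

#' @rdname karma_config
#' @param config A `karma_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
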