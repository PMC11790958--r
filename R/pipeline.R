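#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the standard
#' analysis: disc median radius 2 px, white top-hat radius 10 px (display
#' only), 11-px summation band, 9-px Loop window, Savitzky-Golay order
#' 2 / 50-point window, 5-s linear fit window, 1000-s acquisition span and
#' the 48.5 kbp lambda-DNA substrate.  Unknown keys are rejected.
#'
#' @param ... overrides for any default (see Details in the package
#'   vignette for units and rationale).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    median_radius = 2,          # px, frame smoothing before summation
    tophat_radius = 10,         # px, display/background subtraction
    quantify_tophat_radius = NULL,  # top-hat before quantification (off)
    kymo_background = "offband",    # constant-background removal per frame
    band_half_width = 5,        # 11-px band
    axis_col = NULL,            # NULL = auto (max-intensity column)
    min_prominence = 0.05,      # fraction of line total
    search_range = 10,          # px, linking
    link_memory = 3,            # frames bridged
    min_track_length = 10,      # frames
    loop_halfwidth = 4,         # 9-px Loop window
    sg_order = 2, sg_window = 50,
    fit_window_s = 5,
    monotone_drop_tol = 0.5,    # kbp
    acquisition_span = 1000,    # s
    total_dna = 48.5,           # kbp
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop_loopx(paste0("unknown configuration key(s): ",
                        paste(bad, collapse = ", ")), "loopx_bad_config")
    defaults <- modifyList(defaults, over, keep.null = TRUE)
  }
  structure(defaults, class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration (YAML or JSON)
#'
#' Serialisation round-trips losslessly; unknown keys in a file are
#' rejected on read.
#'
#' @param config a [pipeline_config()].
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       null = "null", digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the loop-extrusion pipeline end to end
#'
#' For every input tether (a simulation config or a TIFF movie) the
#' pipeline builds the kymograph, detects and links the loop punctum,
#' partitions each line into Up/Loop/Down, converts intensity fractions
#' to DNA amounts, and fits the extrusion rate on the monotone window.
#' The run is deterministic given the config seed and emits a
#' machine-readable manifest (package version, config hash, seed).
#'
#' @param config a [pipeline_config()].
#' @param inputs list of [tether_sim_config()] objects, or a character
#'   vector of multi-page TIFF paths.
#' @param output_dir optional directory; when given, per-tether results
#'   (`tether_results.csv`), the experiment summary (`summary.json`) and
#'   the run manifest (`manifest.json`) are written there.
#' @return list with `tethers` (per-tether data frame: `tether`, `looped`,
#'   `rate_kbp_s`, `excluded`), `summary` (a `looping_summary`), `rates`
#'   (numeric vector of accepted rates), and `manifest`.
#' @export
run_pipeline <- function(config, inputs, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(inputs) == 0)
    stop_loopx("no input tethers supplied", "loopx_bad_config")
  is_paths <- is.character(inputs)
  n <- length(inputs)
  rows <- vector("list", n)
  rates <- numeric(0)
  for (i in seq_len(n)) {
    series <- if (is_paths) read_movie_tiff(inputs[i]) else {
      stopifnot(inherits(inputs[[i]], "tether_sim_config"))
      simulate_tether_movie(inputs[[i]])$series
    }
    q <- tryCatch(quantify_tether(series, config), loopx_error = function(e) {
      stop_loopx(sprintf("stage 'quantify' failed on tether %d: %s",
                         i, conditionMessage(e)), "loopx_stage_error")
    })
    rate <- NA_real_; excluded <- NA_character_
    if (!is.null(q$dna)) {
      re <- estimate_loop_rate(q$dna, config)
      if (inherits(re, "rate_estimate")) {
        rate <- re$k; rates <- c(rates, re$k)
      } else excluded <- re$reason
    }
    rows[[i]] <- data.frame(tether = i, looped = q$looped,
                            rate_kbp_s = rate, excluded = excluded,
                            stringsAsFactors = FALSE)
  }
  tethers <- do.call(rbind, rows)
  summary <- fraction_looped(tethers$looped, experiment_id = "run",
                             acquisition_span = config$acquisition_span)
  manifest <- list(package = "loopx",
                   version = as.character(utils::packageVersion("loopx")),
                   config_hash = config_hash(config),
                   seed = config$seed, n_tethers = n)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tethers, file.path(output_dir, "tether_results.csv"),
              row.names = FALSE)
    jsonlite::write_json(unclass(summary),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tethers = tethers, summary = summary, rates = rates,
       manifest = manifest)
}

#' Validate a pipeline output file against its published schema
#'
#' Schemas live in `inst/schema/` and list the required columns (CSV) or
#' fields (JSON) of each pipeline output.
#'
#' @param path output file.
#' @param schema schema name (`"tether_results"`, `"summary"`,
#'   `"manifest"`).
#' @return `TRUE` invisibly; errors describe what is missing.
#' @export
validate_output <- function(path, schema) {
  sfile <- system.file("schema", paste0(schema, ".json"), package = "loopx")
  if (sfile == "")
    stop_loopx(sprintf("unknown schema '%s'", schema), "loopx_bad_config")
  sc <- jsonlite::read_json(sfile, simplifyVector = TRUE)
  if (identical(sc$type, "csv")) {
    d <- read.csv(path, nrows = 1)
    missing <- setdiff(sc$required_columns, names(d))
    if (length(missing))
      stop_loopx(sprintf("%s: missing column(s) %s", path,
                         paste(missing, collapse = ", ")),
                 "loopx_schema_violation")
  } else {
    d <- jsonlite::read_json(path)
    missing <- setdiff(sc$required_fields, names(d))
    if (length(missing))
      stop_loopx(sprintf("%s: missing field(s) %s", path,
                         paste(missing, collapse = ", ")),
                 "loopx_schema_violation")
  }
  invisible(TRUE)
}
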