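# File I/O: delimited curve tables, YAML configuration, run manifests.
# Curve files are UTF-8 CSV with a mandatory header: dephasing curves use
# columns (t1_us, intensity), recovery series (delay_s, intensity).

#' Read a dephasing or recovery curve from CSV
#'
#' Validates the header, numeric content, sign and ordering of the time axis;
#' malformed rows are reported with their file line number (header = line 1).
#'
#' @param path CSV file path.
#' @param type `"dephasing"` (columns `t1_us,intensity`) or `"recovery"`
#'   (columns `delay_s,intensity`); `"auto"` (default) decides from the
#'   header.
#' @return a [dephasing_curve()] or [recovery_curve()].
#' @export
read_curve_csv <- function(path, type = c("auto", "dephasing", "recovery")) {
  type <- match.arg(type)
  if (!file.exists(path))
    stop("parse error: file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (type == "auto") {
    type <- if ("t1_us" %in% names(raw)) "dephasing"
            else if ("delay_s" %in% names(raw)) "recovery"
            else stop("parse error: header must contain t1_us or delay_s",
                      call. = FALSE)
  }
  tcol <- if (type == "dephasing") "t1_us" else "delay_s"
  missing_cols <- setdiff(c(tcol, "intensity"), names(raw))
  if (length(missing_cols))
    stop("parse error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0L)
    stop("empty-curve error: file has a header but no data rows",
         call. = FALSE)
  tv <- suppressWarnings(as.numeric(raw[[tcol]]))
  iv <- suppressWarnings(as.numeric(raw$intensity))
  bad <- which(!is.finite(tv) | !is.finite(iv))
  if (length(bad))
    stop("parse error: non-numeric cell at line ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  neg <- which(tv < 0)
  if (length(neg))
    stop("parse error: negative time at line ",
         paste(neg + 1L, collapse = ", "), call. = FALSE)
  if (is.unsorted(tv, strictly = FALSE))
    stop("parse error: time column is not sorted (first offence at line ",
         which(diff(tv) < 0)[1L] + 2L, ")", call. = FALSE)
  if (type == "dephasing") dephasing_curve(tv, iv) else recovery_curve(tv, iv)
}

#' Write a curve to CSV
#'
#' @param curve a [dephasing_curve()] or [recovery_curve()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_curve_csv <- function(curve, path) {
  df <- as.data.frame(curve)[, if (inherits(curve, "dephasing_curve"))
    c("t1_us", "intensity") else c("delay_s", "intensity")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

CONFIG_KEYS <- c(spinning_freq_khz = "spinning_freq_khz",
                 kappa = "kappa",
                 n_powder = "n_powder",
                 r_ch_angstrom = "r_ch",
                 hch_angle_deg = "hch_angle",
                 n_t1_points = "n_t1_points")

#' Load an experiment configuration from YAML
#'
#' Recognized keys: `spinning_freq_khz`, `kappa`, `n_powder`,
#' `r_ch_angstrom`, `hch_angle_deg`, `n_t1_points`. Missing keys take the
#' package defaults (7.813 kHz spinning, kappa = 1/sqrt(3), r = 1.09
#' Angstrom); unknown keys are rejected; out-of-range values raise a
#' configuration error naming the offending keys.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return an [experiment_config()].
#' @export
load_config <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("configuration error: file not found: ", path, call. = FALSE)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    unknown <- setdiff(names(vals), names(CONFIG_KEYS))
    if (length(unknown))
      stop("configuration error: unknown key(s) ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- stats::setNames(vals, CONFIG_KEYS[names(vals)])
  do.call(experiment_config, args)
}

#' Write an experiment configuration to YAML
#'
#' @param config an [experiment_config()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(list(spinning_freq_khz = config$spinning_freq_khz,
                        kappa = config$kappa,
                        n_powder = config$n_powder,
                        r_ch_angstrom = config$r_ch,
                        hch_angle_deg = config$hch_angle,
                        n_t1_points = config$n_t1_points),
                   path)
  invisible(path)
}

#' Run manifest for reproducible pipelines
#'
#' Records the command, configuration digest, input-file digests, seed, tool
#' version and a timestamp, so that a deterministic command re-run with an
#' identical manifest reproduces its outputs.
#'
#' @param command character description of the command being run.
#' @param inputs character vector of input file paths (digested with MD5).
#' @param config_path optional configuration file path (digested too).
#' @param seed optional integer seed used by the run.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(command, inputs = character(), config_path = NULL,
                         seed = NULL) {
  digest_of <- function(p) unname(tools::md5sum(p))
  structure(list(
    command = command,
    config = if (!is.null(config_path))
      list(path = config_path, md5 = digest_of(config_path)) else NULL,
    inputs = if (length(inputs))
      data.frame(path = inputs, md5 = vapply(inputs, digest_of, character(1)))
    else NULL,
    seed = seed,
    tool = "wallscrew",
    version = as.character(utils::packageVersion("wallscrew")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
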