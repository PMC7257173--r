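TRANSITION_COLS <- c("sample_id", "batch", "injection_index", "protein",
                     "peptide", "charge", "label", "fragment_ion", "area")

#' Read a long-format transition report
#'
#' Reads a Skyline-style transition report export: one row per product-ion
#' peak area per injection, with columns `sample_id`, `batch`,
#' `injection_index`, `protein`, `peptide`, `charge`, `label`
#' (light/heavy/reference), `fragment_ion`, `area`. Lines starting with `#`
#' are treated as comments. A missing required column is fatal (named in the
#' error); rows whose `area` is not a number are dropped, reported via a
#' message, and returned in the `"rejected"` attribute so nothing is lost
#' silently.
#'
#' @param path CSV file path.
#' @return Tibble of typed transition records.
#' @export
read_transition_report <- function(path) {
  raw <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  required_columns(raw, TRANSITION_COLS)
  area <- suppressWarnings(as.numeric(raw$area))
  bad <- is.na(area) & !is.na(raw$area) & nzchar(raw$area)
  bad <- bad | is.na(raw$area)
  rejected <- raw[bad, ]
  out <- raw[!bad, ]
  out$area <- area[!bad]
  out$injection_index <- as.integer(out$injection_index)
  out$charge <- as.integer(out$charge)
  if (nrow(rejected)) {
    message(nrow(rejected), " row(s) rejected (non-numeric or missing area)")
    attr(out, "rejected") <- rejected
  }
  out
}

#' Write a transition report (or any pipeline stage table) as CSV
#'
#' Writes the table with a `#`-prefixed provenance header (package version,
#' seed, configuration hash) so every output file records how it was made.
#' [read_transition_report()] and [read_prm_csv()] skip such headers.
#'
#' @param x Data frame to write.
#' @param path Output CSV path.
#' @param seed Seed to record in the header (optional).
#' @param config_hash Configuration hash to record (optional; see
#'   [pipeline_config()]).
#' @return `path`, invisibly.
#' @export
write_prm_csv <- function(x, path, seed = NULL, config_hash = NULL) {
  hdr <- paste0("# csfprm ", as.character(packageVersion("csfprm")),
                if (!is.null(seed)) paste0(" | seed=", seed),
                if (!is.null(config_hash)) paste0(" | config=", config_hash))
  writeLines(hdr, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE, na = "",
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_prm_csv
#' @export
write_transition_report <- function(x, path, seed = NULL,
                                    config_hash = NULL) {
  required_columns(x, TRANSITION_COLS)
  write_prm_csv(x[TRANSITION_COLS], path, seed = seed,
                config_hash = config_hash)
}

#' @rdname read_transition_report
#' @export
read_prm_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read per-injection sample metadata
#'
#' Expects columns `sample_id`, `group`, `age`, `sex`, `batch`,
#' `injection_index`; immunoassay columns (`abeta42`, `ttau`, `ptau`,
#' `platform`) are optional. An `is_gis` column is derived from `group ==
#' "GIS"` when absent.
#'
#' @param path CSV file path.
#' @return Tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  meta <- read_prm_csv(path)
  required_columns(meta, c("sample_id", "group", "batch", "injection_index"))
  if (!"is_gis" %in% names(meta)) meta$is_gis <- meta$group == "GIS"
  meta
}

#' Write a simulated study to disk
#'
#' Emits the transition report CSV, the metadata CSV and the ground-truth
#' parameters as JSON into `dir`.
#'
#' @param study A `prm_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "prm_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_transition_report(study$transitions,
                          file.path(dir, "transitions.csv"),
                          seed = study$seed)
  write_prm_csv(study$metadata, file.path(dir, "metadata.csv"),
                seed = study$seed)
  truth <- study$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
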