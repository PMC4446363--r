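#' Load and validate a run configuration
#'
#' Reads a YAML file with up to three sections — `photosynthesis`,
#' `management`, `growth` — whose keys are the arguments of
#' [photosynthesis_params()], [management_params()] and [growth_params()].
#' Missing keys take the standard defaults (a = 0.75, n_addmax = 0.6,
#' vcmax/jmax = 55/110, sla_max = 0.048, IC = 13, alpha = 0.2, ...);
#' unknown sections or keys are rejected; every value is validated against
#' the parameter invariants by the constructors. An empty (or missing
#' `path = NULL`) configuration yields the full defaults.
#'
#' @param path YAML file path, or NULL for defaults
#' @return list with validated elements `pp`, `mp`, `gp`
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("photosynthesis", "management", "growth")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  build <- function(section, constructor) {
    args <- cfg[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(constructor)))
    if (length(bad)) {
      stop("unknown key(s) in '", section, "': ",
           paste(bad, collapse = ", "))
    }
    do.call(constructor, args)
  }
  list(pp = build("photosynthesis", photosynthesis_params),
       mp = build("management", management_params),
       gp = build("growth", growth_params))
}

#' Write gridded or tabular results to disk
#'
#' Tables (data.frames) are written as CSV; per-cell annual fields given as
#' matrices are flattened to long-format CSV (`year`, `cell`, `value`). A
#' units string, when supplied, is recorded in a `#`-prefixed header line so
#' files stay self-describing.
#'
#' @param results named list of data.frames and/or matrices
#' @param dir output directory (created if needed)
#' @param units optional named character vector of unit strings
#' @return invisibly, the paths written
#' @export
write_outputs <- function(results, dir, units = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.matrix(x)) {
      x <- data.frame(year = rep(seq_len(nrow(x)), ncol(x)),
                      cell = rep(seq_len(ncol(x)), each = nrow(x)),
                      value = as.vector(x))
    }
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    if (!is.null(units) && nm %in% names(units)) {
      writeLines(paste0("# units: ", units[[nm]]), con)
    }
    utils::write.csv(x, con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a table written by [write_outputs()]
#'
#' @param path CSV path
#' @return data.frame (the units header line, if any, is skipped)
#' @export
read_output <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Record a reproducible run manifest
#'
#' @param config the configuration list used (from [load_config()])
#' @param seed integer seed of the run
#' @param outputs character vector of output paths
#' @param path where to write the JSON manifest
#' @return the manifest list, invisibly
#' @export
run_manifest <- function(config, seed, outputs, path) {
  manifest <- list(
    package = "grassim",
    version = as.character(utils::packageVersion("grassim")),
    seed = seed,
    config = lapply(config, unclass),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
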