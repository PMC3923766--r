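# Config, manifest and deterministic tabular writers.

.config_defaults <- list(mode = "symmetric", topology = "well_mixed", seed = 0L)
.config_keys <- c("n", "epsilon", "p", "delta", "mode", "topology", "seed")

#' Load a flat JSON model configuration
#'
#' Reads a flat JSON object with keys \code{n, epsilon, p, delta, mode,
#' topology, seed} (the last three optional: defaults \code{symmetric},
#' \code{well_mixed}, \code{0}). Unknown keys are an error.
#'
#' @param path path to the JSON file.
#' @return Named list of the seven fields, defaults applied; validate it with
#'   [validate_params()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a flat JSON object", call. = FALSE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown key(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  required <- c("n", "epsilon", "p", "delta")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.config_defaults, raw)
  cfg[.config_keys]
}

.num_fmt <- function(x) formatC(x, digits = 10, format = "g")

#' Write a trajectory as CSV
#'
#' Columns: \code{t}, \code{mean_damage}, \code{f0}, then one column per
#' recorded increment bin. Numeric cells use 10 significant digits so output
#' is byte-identical for identical data.
#'
#' @param trajectory a \code{"damage_trajectory"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  s <- trajectory$summary
  df <- s
  if (!is.null(trajectory$hist)) df <- cbind(df, as.data.frame(trajectory$hist))
  lines <- c(paste(colnames(df), collapse = ","),
             if (nrow(df)) apply(df, 1, function(r)
               paste(.num_fmt(as.numeric(r)), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a kymograph as a tab-separated matrix
#'
#' One row per recorded time unit, one column per cell index.
#'
#' @param kymograph numeric matrix (time units x cells).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_kymograph <- function(kymograph, path) {
  stopifnot(is.matrix(kymograph))
  lines <- apply(kymograph, 1, function(r) paste(.num_fmt(r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a sweep table as CSV
#'
#' @param sweep data.frame from [sweep_fragility_mutation()],
#'   [sweep_system_size()] or [median_collapse_time()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  cols <- colnames(sweep)
  fmt_cell <- function(x) {
    if (is.numeric(x)) .num_fmt(x) else as.character(x)
  }
  body <- if (nrow(sweep)) {
    mat <- vapply(cols, function(cn) fmt_cell(sweep[[cn]]), character(nrow(sweep)))
    if (nrow(sweep) == 1L) mat <- matrix(mat, nrow = 1)
    apply(mat, 1, paste, collapse = ",")
  } else character(0)
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of the effective configuration, command, seed, package version,
#' timestamp and output paths — sufficient to regenerate any output exactly on
#' the same platform.
#'
#' @param params a [damage_model()] or config list.
#' @param command command name (e.g. \code{"simulate"}).
#' @param outputs character vector of output paths.
#' @param path manifest path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(params, command, outputs, path) {
  cfg <- if (inherits(params, "damage_model")) {
    list(n = params$N, epsilon = params$epsilon, p = params$p,
         delta = params$delta, mode = params$mode, topology = params$topology,
         seed = params$seed)
  } else params
  manifest <- list(command = command, config = cfg,
                   package_version = as.character(utils::packageVersion("segsim")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
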