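# Configuration, serialization and run manifests tying the stages into a
# reproducible pipeline. Configs are flat `key: value` files (YAML syntax)
# mirroring the sim_params() field names; omitted keys fall back to the
# wild-type defaults, and `variant: uniform` switches to the ase1-null
# preset (R = 34, its catastrophe-clock parameters) unless overridden.

#' Load a simulation configuration file
#'
#' Reads a flat key-value file (YAML syntax) whose keys mirror the
#' [sim_params()] arguments, validates every entry, and returns the fully
#' resolved parameter set. An empty file yields the wild-type defaults;
#' `variant: uniform` applies the ase1-null preset as a whole (uniform
#' rescue, `R = 34` um/min, its catastrophe-clock fit), with explicit keys
#' taking precedence. Unknown keys fail with a message naming the key.
#'
#' @param path path to the config file.
#' @return A `sim_params` object with attribute `config` (the raw
#'   key-value list read from disk).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a flat key-value mapping")
  allowed <- names(formals(sim_params))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  p <- if (identical(raw$variant, "uniform"))
    do.call(sim_params_ase1, raw[setdiff(names(raw), "variant")])
  else
    do.call(sim_params, raw)
  attr(p, "config") <- raw
  p
}

#' Write and read event logs
#'
#' Event logs use the CSV schema
#' `kind,t_min,mt_id,pos_signed_um,spindle_length_um` and round-trip
#' exactly through [read_event_log()].
#'
#' @param events event data frame from a `spindle_trajectory` (columns
#'   `kind`, `t`, `mt_id`, `pos_signed`, `S`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  num <- function(x) sprintf("%.17g", x)  # survives the round trip exactly
  out <- data.frame(kind = events$kind, t_min = num(events$t),
                    mt_id = events$mt_id,
                    pos_signed_um = num(events$pos_signed),
                    spindle_length_um = num(events$S))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(kind = d$kind, t = d$t_min, mt_id = d$mt_id,
             pos_signed = d$pos_signed_um, S = d$spindle_length_um)
}

#' Write and read trajectory series
#'
#' Trajectory series use the CSV schema
#' `t_min,spindle_length_um,polymer_um,n_mts_left,n_mts_right`.
#'
#' @param series series data frame from a `spindle_trajectory` (columns
#'   `t`, `S`, `polymer`, `n_left`, `n_right`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_series <- function(series, path) {
  num <- function(x) sprintf("%.17g", x)
  out <- data.frame(t_min = num(series$t), spindle_length_um = num(series$S),
                    polymer_um = num(series$polymer),
                    n_mts_left = series$n_left,
                    n_mts_right = series$n_right)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_series
#' @export
read_trajectory_series <- function(path) {
  d <- utils::read.csv(path)
  data.frame(t = d$t_min, S = d$spindle_length_um, polymer = d$polymer_um,
             n_left = d$n_mts_left, n_right = d$n_mts_right)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run or ensemble: the resolved
#' parameter set, the master seed, the package version and a hash of the
#' parameters. JSON, human-readable.
#'
#' @param params a `sim_params` object.
#' @param seed master seed.
#' @param path output JSON path.
#' @param extra optional named list appended verbatim.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, seed, path, extra = list()) {
  pl <- unclass(params)
  attr(pl, "config") <- NULL
  manifest <- c(list(
    package = "anaphaseB",
    version = as.character(utils::packageVersion("anaphaseB")),
    seed = seed,
    params = pl,
    params_hash = params_hash(params)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# order-stable hash of the parameter values (no digest dependency)
params_hash <- function(params) {
  pl <- unclass(params)
  attr(pl, "config") <- NULL
  pl <- pl[order(names(pl))]
  txt <- paste(names(pl), vapply(pl, function(v) format(v, digits = 17), ""),
               sep = "=", collapse = ";")
  # polynomial rolling hash over the UTF-8 bytes (exact in doubles)
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
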