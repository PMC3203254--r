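# Configuration parsing, deterministic output writing, and run manifests.

.CONFIG_BLOCKS <- c("rates", "diffusivities", "geometry", "initial",
                    "scales", "units", "solver")

#' Parse a structured model configuration file
#'
#' Reads a JSON configuration with blocks `rates`, `diffusivities`,
#' `geometry`, `initial`, optional `scales`, `units` and `solver` (grid and
#' time-stepping settings), validates it and returns typed objects.
#'
#' @param path path to the JSON file.
#' @param strict reject unknown keys (default); otherwise warn.
#' @return List with `params` (an [rta_params()]) and `settings` (an
#'   [rd_settings()], or `NULL` when no `solver` block is present).
#' @export
parse_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), .CONFIG_BLOCKS)
  if (length(unknown)) {
    msg <- paste("unknown config key(s):", paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  known <- list(rates = c("k1", "k_m1", "k2", "k_m2", "k3"),
                diffusivities = c("kappa_T", "kappa_A", "kappa_C"),
                geometry = c("rho_c", "rho_e", "r0"),
                initial = c("uT0", "uA0", "uC0"),
                scales = c("u_star", "tau_star", "l"),
                solver = c("N", "dt", "scheme", "nonlinear_tol", "max_inner"))
  for (blk in intersect(names(known), names(cfg))) {
    extra <- setdiff(names(cfg[[blk]]), known[[blk]])
    if (length(extra)) {
      msg <- sprintf("unknown key(s) in '%s': %s", blk,
                     paste(extra, collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    num <- setdiff(known[[blk]], "scheme")
    for (key in intersect(num, names(cfg[[blk]]))) {
      v <- cfg[[blk]][[key]]
      if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
        stop(sprintf("config field %s$%s is not a finite number", blk, key),
             call. = FALSE)
      }
    }
  }
  params <- rta_params(
    rates = cfg$rates, diffusivities = cfg$diffusivities,
    geometry = cfg$geometry, initial = cfg$initial,
    scales = cfg$scales,
    units = if (is.null(cfg$units)) "nondimensional" else cfg$units
  )
  settings <- if (!is.null(cfg$solver)) do.call(rd_settings, cfg$solver)
  list(params = params, settings = settings)
}

#' Write a time series or curve as plain CSV
#'
#' Full double precision (values survive a read/parse round trip), LF line
#' endings, header row.
#'
#' @param x a data.frame (e.g. a `wms_trajectory` or `protection_curve`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  x <- as.data.frame(x)
  header <- paste(names(x), collapse = ",")
  if (nrow(x)) {
    cells <- vapply(x, function(col) sprintf("%.17g", as.numeric(col)),
                    character(nrow(x)))
    if (nrow(x) == 1L) cells <- matrix(cells, nrow = 1L)
    body <- apply(cells, 1L, paste, collapse = ",")
  } else body <- character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Write radial snapshots in long format
#'
#' @param sol an `rta_pde` solution.
#' @param path output CSV path with columns `t`, `rho`, `uT`, `uA`, `uC`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(sol, path) {
  stopifnot(inherits(sol, "rta_pde"))
  rows <- do.call(rbind, lapply(sol$snapshots, function(s) {
    data.frame(t = s$t, rho = sol$grid$rho, uT = s$uT, uA = s$uA, uC = s$uC)
  }))
  write_timeseries(rows, path)
}

#' Content hash of a parameter/settings combination
#'
#' MD5 of the canonical (name-sorted) JSON serialization; changes iff a
#' semantically meaningful field changes.
#'
#' @param params an [rta_params()] object.
#' @param settings optional [rd_settings()].
#' @return Hex digest string.
#' @export
config_hash <- function(params, settings = NULL) {
  canon <- function(x) {
    if (is.list(x)) lapply(x[order(names(x))], canon) else x
  }
  obj <- canon(list(params = unclass(params),
                    settings = if (!is.null(settings)) unclass(settings)))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Machine-readable run manifest
#'
#' @param params an [rta_params()] object.
#' @param settings optional [rd_settings()].
#' @param convergence optional convergence certificate (e.g. the result of
#'   [grid_convergence_study()]).
#' @param wall_time optional elapsed seconds.
#' @return List with the full parameter echo, settings, config hash,
#'   package version and optional convergence certificate.
#' @export
run_manifest <- function(params, settings = NULL, convergence = NULL,
                         wall_time = NULL) {
  list(tool = "rta",
       version = as.character(utils::packageVersion("rta")),
       config_hash = config_hash(params, settings),
       params = unclass(params),
       settings = if (!is.null(settings)) unclass(settings),
       convergence = convergence,
       wall_time = wall_time)
}

#' Write a manifest as JSON
#'
#' @param manifest a [run_manifest()] list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}
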