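# Parameter containers, validation, and (non)dimensionalization.
#
# All model code operates on the nondimensional parameter set; dimensional
# input is converted once on entry via nondimensionalize() and can be
# recovered exactly via redimensionalize().

# number of molecules per cm^3 in a 1 M solution (Avogadro / 1000)
.PER_CM3_PER_MOLAR <- 6.02214076e23 / 1000

#' Receptor-toxin-antibody model parameters
#'
#' Construct the full parameter set of the RTA model: mass-action rate
#' constants, species diffusivities, spherical-shell geometry, and
#' initial/outer-boundary concentrations.  Parameters are nondimensional by
#' default; dimensional sets (with `scales` and a `units` flag) can be
#' converted with [nondimensionalize()].
#'
#' @param rates named list with `k1`, `k_m1` (forward/reverse toxin-antibody
#'   rates), `k2`, `k_m2` (forward/reverse toxin-receptor rates) and `k3`
#'   (internalization rate of receptor-bound toxin).  All must be >= 0.
#' @param diffusivities named list with `kappa_T`, `kappa_A`, `kappa_C`, the
#'   diffusivities of toxin, antibody and toxin-antibody complex (all > 0).
#' @param geometry named list with `rho_c` (cell radius), `rho_e` (outer
#'   compartment radius, > `rho_c`) and `r0` (surface receptor
#'   concentration, > 0).
#' @param initial named list with `uT0`, `uA0` (initial and outer-boundary
#'   toxin/antibody concentrations) and optionally `uC0` (initial complex
#'   concentration, 0 by default and fixed to 0 at the outer boundary).
#' @param scales optional named list with `u_star` (concentration scale,
#'   cm^-3), `tau_star` (time scale, s) and `l` (length scale, cm); required
#'   for dimensional round trips.
#' @param units one of `"nondimensional"`, `"molar"` (second-order rates in
#'   M^-1 s^-1, concentrations in M) or `"number_density"` (rates in
#'   cm^3 s^-1, concentrations in cm^-3).
#' @param check if `TRUE` (default), stop when [validate_params()] reports
#'   violations.
#' @return An object of class `rta_params`.
#' @seealso [default_params()] for the canonical parameter set,
#'   [derived_constants()] for the equilibrium and geometry constants.
#' @export
rta_params <- function(rates, diffusivities, geometry, initial,
                       scales = NULL, units = "nondimensional",
                       check = TRUE) {
  units <- match.arg(units, c("nondimensional", "molar", "number_density"))
  need <- function(x, keys, what) {
    miss <- setdiff(keys, names(x))
    if (length(miss)) {
      stop(sprintf("missing %s field(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    lapply(x[keys], as.numeric)
  }
  if (is.null(initial$uC0)) initial$uC0 <- 0
  p <- structure(list(
    rates = need(rates, c("k1", "k_m1", "k2", "k_m2", "k3"), "rates"),
    diff  = need(diffusivities, c("kappa_T", "kappa_A", "kappa_C"),
                 "diffusivities"),
    geom  = need(geometry, c("rho_c", "rho_e", "r0"), "geometry"),
    ib    = need(initial, c("uT0", "uA0", "uC0"), "initial"),
    scales = if (!is.null(scales)) {
      need(scales, c("u_star", "tau_star", "l"), "scales")
    },
    units = units
  ), class = "rta_params")
  if (check) {
    bad <- validate_params(p)
    if (length(bad)) {
      stop("invalid parameters:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
    }
  }
  p
}

#' Validate an RTA parameter set
#'
#' Checks every invariant of the parameter container and returns the
#' violations as data rather than raising a condition, so callers can report
#' all problems at once.
#'
#' @param p an `rta_params` object (or a compatible plain list).
#' @return Character vector of violation messages; empty when the set is
#'   valid.  Each entry names the offending field.
#' @export
validate_params <- function(p) {
  bad <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  for (nm in names(p$rates)) {
    chk(is.finite(p$rates[[nm]]) && p$rates[[nm]] >= 0,
        sprintf("rates$%s must be finite and >= 0", nm))
  }
  for (nm in names(p$diff)) {
    chk(is.finite(p$diff[[nm]]) && p$diff[[nm]] > 0,
        sprintf("diff$%s must be finite and > 0", nm))
  }
  chk(is.finite(p$geom$rho_c) && p$geom$rho_c > 0, "geom$rho_c must be > 0")
  chk(is.finite(p$geom$rho_e) && p$geom$rho_e > p$geom$rho_c,
      "geom$rho_e must exceed rho_c")
  chk(is.finite(p$geom$r0) && p$geom$r0 > 0, "geom$r0 must be > 0")
  chk(is.finite(p$ib$uT0) && p$ib$uT0 >= 0, "ib$uT0 must be >= 0")
  chk(is.finite(p$ib$uA0) && p$ib$uA0 >= 0, "ib$uA0 must be >= 0")
  chk(is.finite(p$ib$uC0) && identical(p$ib$uC0, 0) || isTRUE(p$ib$uC0 == 0),
      "ib$uC0 must be 0 (complex absent initially and at the outer boundary)")
  if (!is.null(p$scales)) {
    for (nm in names(p$scales)) {
      chk(is.finite(p$scales[[nm]]) && p$scales[[nm]] > 0,
          sprintf("scales$%s must be > 0", nm))
    }
  }
  bad
}

#' Canonical nondimensional parameter sets
#'
#' The default parameter set used throughout: association/dissociation rates
#' representative of a high-affinity neutralizing antibody and a cell-surface
#' receptor, equal small-molecule-scale diffusivities for all species, a cell
#' of nondimensional radius 0.1 inside a compartment of radius 2, surface
#' receptor concentration 2.115e-3, and outer concentrations uT0 = 0.5
#' (toxin), uA0 = 1 (antibody).
#'
#' @param preset `"standard"` (the default set), `"low_toxin"` (uT0 = 0.1) or
#'   `"large_compartment"` (rho_e = 5).
#' @return An `rta_params` object (nondimensional, with the concentration,
#'   time and length scales attached for dimensional round trips).
#' @export
default_params <- function(preset = c("standard", "low_toxin",
                                      "large_compartment")) {
  preset <- match.arg(preset)
  p <- rta_params(
    rates = list(k1 = 1.3e-2, k_m1 = 1.4e-4,
                 k2 = 1.25e-2, k_m2 = 5.2e-4, k3 = 3.3e-5),
    diffusivities = list(kappa_T = 1e-2, kappa_A = 1e-2, kappa_C = 1e-2),
    geometry = list(rho_c = 0.1, rho_e = 2, r0 = 2.115e-3),
    initial = list(uT0 = 0.5, uA0 = 1, uC0 = 0),
    scales = list(u_star = 6.02e13, tau_star = 1, l = 1e-2),
    units = "nondimensional"
  )
  if (preset == "low_toxin") p$ib$uT0 <- 0.1
  if (preset == "large_compartment") p$geom$rho_e <- 5
  p
}

#' Nondimensionalize a dimensional parameter set
#'
#' Applies the scaling k1_bar = tau_star u_star k1, k2_bar = tau_star u_star
#' k2 (second-order rates), k_bar = tau_star k (first-order rates),
#' kappa_bar = tau_star kappa / l^2, lengths divided by l, concentrations by
#' u_star, and the surface receptor concentration by l u_star.  Molar input
#' is first converted to the cm^-3 number-density convention with Avogadro's
#' number.
#'
#' @param p an `rta_params` object with `units` `"molar"` or
#'   `"number_density"` and `scales` present.
#' @return The nondimensional `rta_params` (scales retained).
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "rta_params"))
  if (p$units == "nondimensional") {
    stop("parameters are already nondimensional", call. = FALSE)
  }
  if (is.null(p$scales)) {
    stop("scales (u_star, tau_star, l) are required to nondimensionalize",
         call. = FALSE)
  }
  s <- p$scales
  # bimolecular rates and concentrations to number-density units first
  conv_k2nd <- if (p$units == "molar") 1 / .PER_CM3_PER_MOLAR else 1
  conv_conc <- if (p$units == "molar") .PER_CM3_PER_MOLAR else 1
  q <- p
  q$rates$k1   <- s$tau_star * s$u_star * p$rates$k1 * conv_k2nd
  q$rates$k2   <- s$tau_star * s$u_star * p$rates$k2 * conv_k2nd
  q$rates$k_m1 <- s$tau_star * p$rates$k_m1
  q$rates$k_m2 <- s$tau_star * p$rates$k_m2
  q$rates$k3   <- s$tau_star * p$rates$k3
  for (nm in names(q$diff)) q$diff[[nm]] <- s$tau_star * p$diff[[nm]] / s$l^2
  q$geom$rho_c <- p$geom$rho_c / s$l
  q$geom$rho_e <- p$geom$rho_e / s$l
  q$geom$r0    <- p$geom$r0 / (s$l * s$u_star)   # surface concentration, cm^-2
  for (nm in names(q$ib)) q$ib[[nm]] <- p$ib[[nm]] * conv_conc / s$u_star
  q$units <- "nondimensional"
  q
}

#' Restore dimensional units
#'
#' Exact inverse of [nondimensionalize()] with the same scales.
#'
#' @param p a nondimensional `rta_params` with `scales` present.
#' @param units target unit convention, `"number_density"` (default) or
#'   `"molar"`.
#' @return Dimensional `rta_params`.
#' @export
redimensionalize <- function(p, units = c("number_density", "molar")) {
  stopifnot(inherits(p, "rta_params"))
  units <- match.arg(units)
  if (p$units != "nondimensional") {
    stop("parameters are not nondimensional", call. = FALSE)
  }
  if (is.null(p$scales)) stop("scales are required", call. = FALSE)
  s <- p$scales
  conv_k2nd <- if (units == "molar") 1 / .PER_CM3_PER_MOLAR else 1
  conv_conc <- if (units == "molar") .PER_CM3_PER_MOLAR else 1
  q <- p
  q$rates$k1   <- p$rates$k1 / (s$tau_star * s$u_star * conv_k2nd)
  q$rates$k2   <- p$rates$k2 / (s$tau_star * s$u_star * conv_k2nd)
  q$rates$k_m1 <- p$rates$k_m1 / s$tau_star
  q$rates$k_m2 <- p$rates$k_m2 / s$tau_star
  q$rates$k3   <- p$rates$k3 / s$tau_star
  for (nm in names(q$diff)) q$diff[[nm]] <- p$diff[[nm]] * s$l^2 / s$tau_star
  q$geom$rho_c <- p$geom$rho_c * s$l
  q$geom$rho_e <- p$geom$rho_e * s$l
  q$geom$r0    <- p$geom$r0 * s$l * s$u_star
  for (nm in names(q$ib)) q$ib[[nm]] <- p$ib[[nm]] * s$u_star / conv_conc
  q$units <- units
  q
}

#' Derived equilibrium and geometry constants
#'
#' Computes the constants used by the steady-state and transport analyses:
#' the dissociation constants `K1 = k_m1/k1` (toxin-antibody) and
#' `K2 = k_m2/k2` (toxin-receptor), their ratio `eps = K2/K1`, the
#' internalization ratio `b = k3/k2`, the surface-to-volume factor
#' `k4 = 3 rho_c^2 / (rho_e^3 - rho_c^3)` of the spherical shell, the
#' receptor capacity `R0 = r0 k4`, and the receptor partition coefficient
#' `K_star = R0 / (R0 + K1)`.
#'
#' @param p an `rta_params` object.
#' @return An object of class `rta_derived` (a named list).  When `k1` or
#'   `k2` is zero the affected ratios are `NA` and a warning names them.
#' @export
derived_constants <- function(p) {
  stopifnot(inherits(p, "rta_params"))
  r <- p$rates; g <- p$geom
  undef <- character()
  K1 <- if (r$k1 > 0) r$k_m1 / r$k1 else { undef <- c(undef, "K1"); NA_real_ }
  K2 <- if (r$k2 > 0) r$k_m2 / r$k2 else { undef <- c(undef, "K2"); NA_real_ }
  b  <- if (r$k2 > 0) r$k3 / r$k2 else { undef <- c(undef, "b"); NA_real_ }
  eps <- if (!is.na(K1) && !is.na(K2) && K1 > 0) K2 / K1 else {
    undef <- c(undef, "eps"); NA_real_
  }
  k4 <- 3 * g$rho_c^2 / (g$rho_e^3 - g$rho_c^3)
  R0 <- g$r0 * k4
  K_star <- if (!is.na(K1)) R0 / (R0 + K1) else {
    undef <- c(undef, "K_star"); NA_real_
  }
  if (length(undef)) {
    warning("undefined ratio(s) (zero forward rate): ",
            paste(undef, collapse = ", "), call. = FALSE)
  }
  structure(list(K1 = K1, K2 = K2, eps = eps, b = b, k4 = k4, R0 = R0,
                 K_star = K_star, undefined = undef),
            class = "rta_derived")
}

#' @export
print.rta_params <- function(x, ...) {
  cat("RTA model parameters (", x$units, ")\n", sep = "")
  fmt <- function(v) paste(sprintf("%s = %g", names(v), unlist(v)),
                           collapse = ", ")
  cat("  rates:         ", fmt(x$rates), "\n")
  cat("  diffusivities: ", fmt(x$diff), "\n")
  cat("  geometry:      ", fmt(x$geom), "\n")
  cat("  initial/outer: ", fmt(x$ib), "\n")
  if (!is.null(x$scales)) cat("  scales:        ", fmt(x$scales), "\n")
  invisible(x)
}

#' @export
print.rta_derived <- function(x, ...) {
  cat("Derived constants:\n")
  for (nm in c("K1", "K2", "eps", "b", "k4", "R0", "K_star")) {
    cat(sprintf("  %-6s = %g\n", nm, x[[nm]]))
  }
  invisible(x)
}
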