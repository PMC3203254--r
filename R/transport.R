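# Closed-form transport diagnostics: steady-state flux and conductance,
# bioavailability number, asymptotic protection factor, effective (mean)
# diffusivity, and the compartment-size <-> cell-density relation.

#' Steady-state toxin conductance and flux
#'
#' The steady flux of toxin toward the cell is `J = uT_outer / Lambda` with
#' the series resistance `Lambda = 1/(k3 K_star) + rho_c / kappa_star`:
#' internalization conductance `k3 K_star` in series with diffusive
#' conductance `kappa_star / rho_c`.
#'
#' @param d an `rta_derived` object (supplies `K_star`).
#' @param geom geometry list with `rho_c`.
#' @param kappa_star effective toxin diffusivity (> 0); see
#'   [mean_diffusivity()].
#' @param k3 internalization rate.
#' @param uT_outer toxin concentration at the outer boundary.
#' @return List with `Lambda` and `J`.  When `k3 K_star = 0` the resistance
#'   is infinite and `J = 0` (returned as `Inf`/`0`, not an overflow).
#' @export
conductance <- function(d, geom, kappa_star, k3, uT_outer) {
  stopifnot(kappa_star > 0, k3 >= 0)
  g <- k3 * d$K_star
  if (g == 0) return(list(Lambda = Inf, J = 0))
  Lambda <- 1 / g + geom$rho_c / kappa_star
  list(Lambda = Lambda, J = uT_outer / Lambda)
}

#' Bioavailability number
#'
#' `L = K_star k3 rho_c / kappa_star`, the ratio of internalization to
#' diffusive conductance.  Uptake is internalization-controlled for
#' `L << 1` and diffusion-controlled for `L >> 1`; the classification
#' thresholds 0.1 and 10 are a reporting convention.
#'
#' @inheritParams conductance
#' @return List with `L` and a `regime` tag
#'   (`"internalization-controlled"`, `"mixed"` or `"diffusion-controlled"`).
#' @export
bioavailability <- function(d, geom, kappa_star, k3) {
  stopifnot(kappa_star > 0)
  L <- d$K_star * k3 * geom$rho_c / kappa_star
  regime <- if (L < 0.1) "internalization-controlled"
            else if (L > 10) "diffusion-controlled" else "mixed"
  list(L = L, regime = regime)
}

#' Long-time asymptote of the protection factor
#'
#' `psi(t) ~ psi_star exp(gamma t)` with
#' `psi_star = (1 + L0) / (1 + L0 / p)`, where `L0 = K_star k3 rho_c /
#' kappa_T` is the antibody-free bioavailability number and
#' `p = kappa_star / kappa_T >= 1` the effective-diffusivity ratio.
#' For `L0 >> 1` (diffusion control) `psi_star -> p`; for `L0 << 1`
#' (kinetic control) `psi_star -> 1`.  `gamma = 0` corresponds to constant
#' toxin influx (no depletion) and a flat asymptote.
#'
#' @param L0 antibody-free bioavailability number (>= 0).
#' @param p_ratio effective-diffusivity ratio `kappa_star / kappa_T`
#'   (>= 1).
#' @param gamma depletion-rate difference `1/tau_d - 1/tau_d0` (default 0).
#' @param t times at which to evaluate the asymptote (default 0, i.e. just
#'   the prefactor).
#' @return List with `psi_star` and `psi` (the values
#'   `psi_star * exp(gamma t)`).
#' @export
psi_asymptote <- function(L0, p_ratio, gamma = 0, t = 0) {
  stopifnot(L0 >= 0, p_ratio >= 1)
  psi_star <- (1 + L0) / (1 + L0 / p_ratio)
  list(psi_star = psi_star, psi = psi_star * exp(gamma * t))
}

#' Effective (mean) toxin diffusivity under fast complexation
#'
#' When toxin-antibody complexation is fast relative to diffusion (labile
#' complex), free and complexed toxin diffuse as one pool with the
#' concentration-weighted mean diffusivity
#' `kappa_star = (uT kappa_T + uC kappa_C) / (uT + uC)`.  The antibody
#' diffusivity does not enter.
#'
#' @param uT,uC free-toxin and complex concentrations (`uT + uC > 0`).
#' @param kappa_T,kappa_C toxin and complex diffusivities.
#' @return The mean diffusivity `kappa_star`.
#' @export
mean_diffusivity <- function(uT, uC, kappa_T, kappa_C) {
  if (any(uT + uC <= 0)) {
    stop("uT + uC must be positive", call. = FALSE)
  }
  (uT * kappa_T + uC * kappa_C) / (uT + uC)
}

#' Compartment radius from cell packing density (and inverse)
#'
#' In a uniform cell culture of number density `n`, each cell occupies a
#' compartment of radius `rho_e = (3 / (4 pi n))^(1/3)`.
#'
#' @param n cell number density (> 0).
#' @return `rho_e`.
#' @export
compartment_from_density <- function(n) {
  stopifnot(all(n > 0))
  (3 / (4 * pi * n))^(1 / 3)
}

#' @rdname compartment_from_density
#' @param rho_e compartment radius (> 0).
#' @return `density_from_compartment`: the cell density `n = 3/(4 pi rho_e^3)`.
#' @export
density_from_compartment <- function(rho_e) {
  stopifnot(all(rho_e > 0))
  3 / (4 * pi * rho_e^3)
}

#' Depletion rate from a bulk-toxin decay series
#'
#' Exponential depletion `uT(t) = uT(0) exp(-t/tau_d)` is fitted by least
#' squares on the log scale; the paired antibody/no-antibody rates give
#' `gamma = 1/tau_d - 1/tau_d0`.
#'
#' @param t times (strictly increasing).
#' @param uT positive bulk toxin concentrations at `t`.
#' @return List with `inv_tau_d` (the fitted `1/tau_d`), `uT0_fit` and
#'   `reliable` (`FALSE`, with a warning and `inv_tau_d = 0`, when the
#'   series does not decay).
#' @export
fit_depletion_rate <- function(t, uT) {
  stopifnot(length(t) == length(uT), all(uT > 0),
            !is.unsorted(t, strictly = TRUE))
  fit <- stats::lm(log(uT) ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    warning("series does not decay: no depletion, rate set to 0",
            call. = FALSE)
    return(list(inv_tau_d = 0, uT0_fit = uT[1], reliable = FALSE))
  }
  list(inv_tau_d = -slope, uT0_fit = exp(unname(stats::coef(fit)[1])),
       reliable = TRUE)
}

#' @rdname fit_depletion_rate
#' @param uT_with,uT_without paired bulk-toxin series with and without
#'   antibody, at the same `t`.
#' @return `gamma_from_decay`: list with `gamma`, `inv_tau_d`,
#'   `inv_tau_d0` and `reliable`.
#' @export
gamma_from_decay <- function(t, uT_with, uT_without) {
  fa <- fit_depletion_rate(t, uT_with)
  f0 <- fit_depletion_rate(t, uT_without)
  list(gamma = fa$inv_tau_d - f0$inv_tau_d,
       inv_tau_d = fa$inv_tau_d, inv_tau_d0 = f0$inv_tau_d,
       reliable = fa$reliable && f0$reliable)
}

#' Full transport-regime diagnostics
#'
#' Convenience wrapper assembling the closed-form diagnostics for a
#' parameter set: conductance and flux, bioavailability number and regime,
#' effective-diffusivity ratio and the asymptotic protection-factor
#' prefactor.
#'
#' @param p an [rta_params()] object.
#' @param kappa_star effective toxin diffusivity; defaults to `kappa_T`
#'   (no labile-complex enhancement).
#' @param gamma depletion-rate difference (default 0: no depletion).
#' @return Object of class `transport_diagnostics`.
#' @export
transport_diagnostics <- function(p, kappa_star = p$diff$kappa_T, gamma = 0) {
  stopifnot(inherits(p, "rta_params"))
  d <- derived_constants(p)
  cond <- conductance(d, p$geom, kappa_star, p$rates$k3, p$ib$uT0)
  bio <- bioavailability(d, p$geom, kappa_star, p$rates$k3)
  p_ratio <- max(1, kappa_star / p$diff$kappa_T)
  L0 <- d$K_star * p$rates$k3 * p$geom$rho_c / p$diff$kappa_T
  asym <- psi_asymptote(L0, p_ratio, gamma)
  structure(list(Lambda = cond$Lambda, J = cond$J,
                 kappa_star = kappa_star, p_ratio = p_ratio,
                 L = bio$L, regime = bio$regime, L0 = L0,
                 psi_star = asym$psi_star, gamma = gamma,
                 K_star = d$K_star),
            class = "transport_diagnostics")
}

#' @export
print.transport_diagnostics <- function(x, ...) {
  cat("Transport diagnostics:\n")
  cat(sprintf("  conductance Lambda = %g, steady flux J = %g\n", x$Lambda, x$J))
  cat(sprintf("  kappa_star = %g (p = kappa_star/kappa_T = %g)\n",
              x$kappa_star, x$p_ratio))
  cat(sprintf("  bioavailability L = %g [%s], L0 = %g\n", x$L, x$regime, x$L0))
  cat(sprintf("  asymptotic protection prefactor psi_star = %g (gamma = %g)\n",
              x$psi_star, x$gamma))
  invisible(x)
}
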