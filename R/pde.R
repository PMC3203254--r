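# Reaction-diffusion model on the spherical shell [rho_c, rho_e]: R-side
# surface over the compiled implicit finite-difference stepper.

#' Uniform radial grid on the extracellular shell
#'
#' @param geom geometry list with `rho_c` and `rho_e` (e.g. `p$geom`).
#' @param N number of nodes (>= 3), endpoints included.
#' @return Object of class `radial_grid`: list with `rho` (node
#'   coordinates), `N` and spacing `h`.
#' @export
build_grid <- function(geom, N) {
  N <- as.integer(N)
  if (N < 3) stop("N must be at least 3", call. = FALSE)
  stopifnot(geom$rho_e > geom$rho_c)
  rho <- seq(geom$rho_c, geom$rho_e, length.out = N)
  structure(list(rho = rho, N = N, h = rho[2] - rho[1]),
            class = "radial_grid")
}

#' Solver settings for the reaction-diffusion model
#'
#' @param N grid nodes (default 401, suited to `rho_e = 2`; use ~981 for
#'   `rho_e = 5` to keep the same spacing).
#' @param dt time step (default 0.5).
#' @param scheme `"backward_euler"` (fully implicit, default) or
#'   `"crank_nicolson"` (second order in time).
#' @param nonlinear_tol fixed-point tolerance for the reaction/wall coupling
#'   within each step (default 1e-12).
#' @param max_inner maximum inner iterations per step.
#' @return List of class `rd_settings`.
#' @export
rd_settings <- function(N = 401L, dt = 0.5,
                        scheme = c("backward_euler", "crank_nicolson"),
                        nonlinear_tol = 1e-12, max_inner = 50L) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0, nonlinear_tol > 0, N >= 3)
  structure(list(N = as.integer(N), dt = dt, scheme = scheme,
                 nonlinear_tol = nonlinear_tol,
                 max_inner = as.integer(max_inner)),
            class = "rd_settings")
}

#' Pointwise mass-action reaction terms
#'
#' Complexation source terms at the grid nodes: toxin and antibody are
#' consumed and complex produced at rate `k1 uT uA - k_m1 uC`, so the
#' sources satisfy `source(uT) + source(uC) = 0` and
#' `source(uA) + source(uC) = 0` exactly.
#'
#' @param uT,uA,uC concentration vectors (same length).
#' @param p an [rta_params()] object.
#' @return List with components `uT`, `uA`, `uC` of per-node sources.
#' @export
reaction_terms <- function(uT, uA, uC, p) {
  cx <- p$rates$k1 * uT * uA - p$rates$k_m1 * uC
  list(uT = -cx, uA = -cx, uC = cx)
}

#' Reactive wall flux and occupancy rate at the cell surface
#'
#' Net receptor binding rate `s = k2 (1 - theta) uT - k_m2 theta`; the toxin
#' gradient at the wall satisfies `kappa_T duT/drho = r0 s` (positive `s`
#' draws toxin toward the cell), and the occupancy evolves as
#' `dtheta/dt = s - k3 theta`.
#'
#' @param uT_wall toxin concentration at the cell-surface node.
#' @param theta occupied-receptor fraction in `[0, 1]`.
#' @param p an [rta_params()] object.
#' @return List with `binding_rate` (`s`), `wall_gradient`
#'   (`duT/drho` at `rho_c`) and `theta_rate`.
#' @export
surface_flux <- function(uT_wall, theta, p) {
  stopifnot(theta >= 0, theta <= 1)
  s <- p$rates$k2 * (1 - theta) * uT_wall - p$rates$k_m2 * theta
  list(binding_rate = s,
       wall_gradient = p$geom$r0 * s / p$diff$kappa_T,
       theta_rate = s - p$rates$k3 * theta)
}

.rd_pars <- function(p, uA0 = NULL) {
  list(k1 = p$rates$k1, k_m1 = p$rates$k_m1, k2 = p$rates$k2,
       k_m2 = p$rates$k_m2, k3 = p$rates$k3, r0 = p$geom$r0,
       kappa_T = p$diff$kappa_T, kappa_A = p$diff$kappa_A,
       kappa_C = p$diff$kappa_C,
       uT_outer = p$ib$uT0,
       uA_outer = if (is.null(uA0)) p$ib$uA0 else uA0)
}

.scheme_weight <- function(settings) {
  if (settings$scheme == "crank_nicolson") 0.5 else 1.0
}

#' Initial field state on a radial grid
#'
#' Homogeneous initial data: toxin and antibody at their outer-boundary
#' concentrations everywhere, no complex, no occupied receptors.
#'
#' @param p an [rta_params()] object.
#' @param grid a [build_grid()] result.
#' @param uA0 optional antibody override.
#' @return Object of class `rta_fields`.
#' @export
rd_fields <- function(p, grid, uA0 = NULL) {
  if (is.null(uA0)) uA0 <- p$ib$uA0
  structure(list(uT = rep(p$ib$uT0, grid$N), uA = rep(uA0, grid$N),
                 uC = rep(0, grid$N), theta = 0, t = 0,
                 grid = grid, uA0 = uA0),
            class = "rta_fields")
}

#' Advance the reaction-diffusion state by one implicit step
#'
#' Single step of the implicit scheme: diffusion treated implicitly
#' (tridiagonal solves per species), the nonlinear complexation terms and the
#' wall occupancy coupling resolved by fixed-point iteration to
#' `nonlinear_tol`.  Boundary conditions are enforced exactly each step.
#'
#' @param fields an `rta_fields` state (see [rd_fields()]).
#' @param dt time step.
#' @param p an [rta_params()] object.
#' @param settings an [rd_settings()] object (its `dt`/`N` are ignored in
#'   favour of `dt` and the grid in `fields`).
#' @return Updated `rta_fields` at `t + dt`.
#' @export
rd_advance <- function(fields, dt, p, settings = rd_settings()) {
  res <- rd_integrate_cpp(fields$uT, fields$uA, fields$uC, fields$theta,
                          fields$grid$rho, .rd_pars(p, fields$uA0),
                          dt, 1L, .scheme_weight(settings),
                          settings$nonlinear_tol, settings$max_inner,
                          FALSE, 0)
  if (res$failed) {
    stop(sprintf("inner iteration did not converge within %d iterations at t = %g",
                 settings$max_inner, fields$t + dt), call. = FALSE)
  }
  fields$uT <- res$uT; fields$uA <- res$uA; fields$uC <- res$uC
  fields$theta <- res$theta
  fields$t <- fields$t + dt
  fields
}

#' Simulate the reaction-diffusion model
#'
#' Integrates the coupled toxin/antibody/complex diffusion-reaction system
#' with the surface occupancy equation from homogeneous initial data to
#' `t_end`, recording the occupancy (and wall toxin concentration) at every
#' accepted step and full radial profiles at `record_times`.
#'
#' @param p an [rta_params()] object.
#' @param settings an [rd_settings()] object.
#' @param t_end final time (>= 0).
#' @param record_times snapshot times (snapped to the nearest step);
#'   defaults to `c(0, t_end)`.
#' @param uA0 optional antibody override (paired protection runs).
#' @param detect_steady stop early once the maximum field change per unit
#'   time falls below `steady_tol`.
#' @param steady_tol steady-state detection threshold (default 1e-10).
#' @return Object of class `rta_pde`: list with the grid, `theta_series` and
#'   `uT_wall_series` (per accepted step, times in `step_times`), radial
#'   `snapshots`, the settings and parameters, and the `steady` flag.
#' @export
simulate_rd <- function(p, settings = rd_settings(), t_end,
                        record_times = NULL, uA0 = NULL,
                        detect_steady = TRUE, steady_tol = 1e-10) {
  stopifnot(inherits(p, "rta_params"), t_end >= 0)
  grid <- build_grid(p$geom, settings$N)
  f <- rd_fields(p, grid, uA0)
  snap <- function(f) list(t = f$t, uT = f$uT, uA = f$uA, uC = f$uC,
                           theta = f$theta)
  if (is.null(record_times)) record_times <- c(0, t_end)
  rec_steps <- sort(unique(pmin(round(record_times / settings$dt),
                                round(t_end / settings$dt))))
  n_total <- round(t_end / settings$dt)
  snapshots <- list()
  if (0 %in% rec_steps) snapshots <- list(snap(f))
  theta_series <- numeric(0)
  wall_series <- numeric(0)
  pars <- .rd_pars(p, uA0)
  w <- .scheme_weight(settings)
  done <- 0L
  steady <- FALSE
  bounds <- sort(unique(c(rec_steps[rec_steps > 0], n_total)))
  for (upto in bounds) {
    n_seg <- upto - done
    if (n_seg <= 0) next
    res <- rd_integrate_cpp(f$uT, f$uA, f$uC, f$theta, grid$rho, pars,
                            settings$dt, n_seg, w,
                            settings$nonlinear_tol, settings$max_inner,
                            detect_steady, steady_tol)
    if (res$failed) {
      stop(sprintf("inner iteration did not converge within %d iterations at t = %g",
                   settings$max_inner, (done + res$steps_done + 1) * settings$dt),
           call. = FALSE)
    }
    f$uT <- res$uT; f$uA <- res$uA; f$uC <- res$uC; f$theta <- res$theta
    done <- done + res$steps_done
    f$t <- done * settings$dt
    theta_series <- c(theta_series, res$theta_series)
    wall_series <- c(wall_series, res$uT_wall_series)
    if (upto %in% rec_steps || res$steady) snapshots <- c(snapshots, list(snap(f)))
    if (res$steady) { steady <- TRUE; break }
  }
  structure(list(grid = grid, params = p, settings = settings,
                 uA0 = if (is.null(uA0)) p$ib$uA0 else uA0,
                 step_times = settings$dt * seq_len(done),
                 theta_series = theta_series,
                 uT_wall_series = wall_series,
                 snapshots = snapshots, t_end = f$t,
                 steady = steady),
            class = "rta_pde")
}

#' Protection factor time course from paired simulations
#'
#' The antibody protection factor is the ratio of the occupied-receptor
#' fraction with antibody present to that without; on a spherically
#' symmetric cell the surface integrals reduce to `psi(t) =
#' theta_A(t) / theta_0(t)`.  At `t = 0` both occupancies vanish and `psi`
#' is defined as 1 by continuity.
#'
#' @param sol_with a `rta_pde` run with antibody (`uA0 > 0`).
#' @param sol_without the paired run with `uA0 = 0` (identical grid,
#'   settings and all other parameters).
#' @return Object of class `protection_curve`: data.frame with columns `t`,
#'   `theta_A`, `theta_0`, `psi`.
#' @export
psi_timecourse <- function(sol_with, sol_without) {
  stopifnot(inherits(sol_with, "rta_pde"), inherits(sol_without, "rta_pde"))
  same <- isTRUE(all.equal(sol_with$grid$rho, sol_without$grid$rho)) &&
    identical(sol_with$settings, sol_without$settings) &&
    isTRUE(all.equal(sol_with$params$rates, sol_without$params$rates)) &&
    isTRUE(all.equal(sol_with$params$diff, sol_without$params$diff))
  if (!same) stop("paired runs must share grid, settings and parameters",
                  call. = FALSE)
  n <- min(length(sol_with$theta_series), length(sol_without$theta_series))
  out <- data.frame(
    t = c(0, sol_with$step_times[seq_len(n)]),
    theta_A = c(0, sol_with$theta_series[seq_len(n)]),
    theta_0 = c(0, sol_without$theta_series[seq_len(n)])
  )
  out$psi <- c(1, out$theta_A[-1] / out$theta_0[-1])
  structure(out, estimator = "theta ratio (reaction-diffusion model)",
            class = c("protection_curve", "data.frame"))
}

#' Saturation protection factor from the reaction-diffusion model
#'
#' Two long-time estimators from paired (antibody / no-antibody) runs:
#' \describe{
#'   \item{`psi5`}{direct occupancy ratio `theta_A(t_theta) /
#'     theta_0(t_theta)` (default horizon 1e4).}
#'   \item{`psi1`}{the wall toxin concentration at `t_wall` (default 1e3) is
#'     mapped through the saturation isotherm `theta_sat(u) = u / (u + K2 +
#'     b)` and the ratio taken.}
#' }
#'
#' @param p an [rta_params()] object.
#' @param settings an [rd_settings()] object.
#' @param variant `"psi5"` or `"psi1"`.
#' @param t_theta horizon for the occupancy ratio (default 1e4).
#' @param t_wall sampling time for the wall concentration (default 1e3).
#' @param sols optional precomputed list `list(with = , without = )` of
#'   `rta_pde` runs covering the needed horizon.
#' @return The scalar saturation estimate.
#' @export
psi_sat_pde <- function(p, settings = rd_settings(),
                        variant = c("psi5", "psi1"),
                        t_theta = 1e4, t_wall = 1e3, sols = NULL) {
  variant <- match.arg(variant)
  t_need <- if (variant == "psi5") t_theta else t_wall
  if (is.null(sols)) {
    sols <- list(
      with = simulate_rd(p, settings, t_need, detect_steady = FALSE),
      without = simulate_rd(p, settings, t_need, uA0 = 0,
                            detect_steady = FALSE)
    )
  }
  idx <- round(t_need / settings$dt)
  stopifnot(idx >= 1, idx <= length(sols$with$theta_series),
            idx <= length(sols$without$theta_series))
  if (variant == "psi5") {
    num <- sols$with$theta_series[idx]
    den <- sols$without$theta_series[idx]
  } else {
    d <- derived_constants(p)
    iso <- function(u) u / (u + d$K2 + d$b)
    num <- iso(sols$with$uT_wall_series[idx])
    den <- iso(sols$without$uT_wall_series[idx])
  }
  if (den == 0) stop("zero denominator: no receptor occupancy without antibody",
                     call. = FALSE)
  num / den
}

#' Grid-convergence study for the saturation protection factor
#'
#' Recomputes the occupancy-ratio estimator under successive grid/time-step
#' refinements and reports the successive changes; used to certify that the
#' discretization error is below the reporting tolerance.
#'
#' @param p an [rta_params()] object.
#' @param settings_list list of [rd_settings()] (>= 2), coarse to fine.
#' @param t_end horizon for the estimator (default 1e4).
#' @return data.frame with columns `N`, `dt`, `psi5` and `change`
#'   (absolute difference from the previous row; `NA` for the first).
#' @export
grid_convergence_study <- function(p, settings_list, t_end = 1e4) {
  stopifnot(length(settings_list) >= 2)
  psi <- vapply(settings_list, function(s) {
    psi_sat_pde(p, s, variant = "psi5", t_theta = t_end)
  }, numeric(1))
  data.frame(
    N = vapply(settings_list, `[[`, integer(1), "N"),
    dt = vapply(settings_list, `[[`, numeric(1), "dt"),
    psi5 = psi,
    change = c(NA_real_, abs(diff(psi)))
  )
}

#' @export
print.rta_pde <- function(x, ...) {
  cat(sprintf("RTA reaction-diffusion solution: N = %d nodes on [%g, %g], dt = %g\n",
              x$grid$N, x$grid$rho[1], x$grid$rho[x$grid$N], x$settings$dt))
  cat(sprintf("  integrated to t = %g (%d steps, %s)%s\n", x$t_end,
              length(x$theta_series), x$settings$scheme,
              if (x$steady) " [steady state detected]" else ""))
  cat(sprintf("  uA0 = %g, final theta = %.6g, wall uT = %.6g\n",
              x$uA0, utils::tail(x$theta_series, 1),
              utils::tail(x$uT_wall_series, 1)))
  invisible(x)
}

#' @export
print.protection_curve <- function(x, ...) {
  cat(sprintf("Protection curve psi(t): %d points on [%g, %g]\n",
              nrow(x), x$t[1], x$t[nrow(x)]))
  cat(sprintf("  estimator: %s\n", attr(x, "estimator")))
  cat(sprintf("  final psi = %.6g, min psi = %.6g at t = %g\n",
              x$psi[nrow(x)], min(x$psi), x$t[which.min(x$psi)]))
  invisible(x)
}

#' @export
plot.protection_curve <- function(x, ...) {
  graphics::plot(x$t, x$psi, type = "l", xlab = "time",
                 ylab = expression(psi(t)), ...)
  invisible(x)
}
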