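# Well-mixed-solution (WMS) reduction: mass-action ODEs for bulk toxin,
# antibody and complex with surface receptors on a single embedded cell,
# no influx across the outer boundary (species deplete), and first-order
# internalization of receptor-bound toxin.

#' Right-hand side of the WMS ODE system
#'
#' The bulk concentrations evolve by toxin-antibody mass action and by net
#' binding to the cell-surface receptors (scaled by the surface-to-volume
#' factor `k4` and receptor concentration `r0`); the occupied-receptor
#' fraction `theta` evolves by binding, unbinding and internalization:
#' \deqn{\dot u_T = -k_1 u_T u_A + k_{-1} u_C - k_4 r_0 (k_2(1-\theta)u_T - k_{-2}\theta)}
#' \deqn{\dot\theta = k_2(1-\theta)u_T - k_{-2}\theta - k_3\theta}
#' \deqn{\dot u_A = -k_1 u_T u_A + k_{-1} u_C, \quad \dot u_C = +k_1 u_T u_A - k_{-1} u_C}
#'
#' @param state named numeric vector with `uT`, `uA`, `uC`, `theta`.
#' @param p an [rta_params()] object.
#' @return Named numeric vector of time derivatives, same order as `state`.
#' @export
wms_rhs <- function(state, p) {
  r <- p$rates
  k4 <- 3 * p$geom$rho_c^2 / (p$geom$rho_e^3 - p$geom$rho_c^3)
  uT <- state[["uT"]]; uA <- state[["uA"]]
  uC <- state[["uC"]]; th <- state[["theta"]]
  complexation <- r$k1 * uT * uA - r$k_m1 * uC
  binding <- r$k2 * (1 - th) * uT - r$k_m2 * th
  c(uT = -complexation - k4 * p$geom$r0 * binding,
    uA = -complexation,
    uC = complexation,
    theta = binding - r$k3 * th)
}

#' Integrate the WMS model
#'
#' Stiff-capable implicit integration (lsoda) of the four-variable WMS system
#' from the initial state `(uT0, uA0, 0, 0)`.
#'
#' @param p an [rta_params()] object.
#' @param t_end final time (> 0).
#' @param out_times output times within `[0, t_end]`; defaults to 201
#'   points spanning the interval.
#' @param uA0 optional override of the antibody concentration (used for the
#'   paired antibody/no-antibody runs behind the protection factor).
#' @param rtol,atol solver tolerances.
#' @return A `wms_trajectory`: a data.frame with columns `t`, `uT`, `uA`,
#'   `uC`, `theta` and the parameters and tolerances as attributes.
#' @export
integrate_wms <- function(p, t_end, out_times = NULL, uA0 = NULL,
                          rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "rta_params"), t_end > 0)
  if (!is.null(uA0)) p$ib$uA0 <- uA0
  if (is.null(out_times)) out_times <- seq(0, t_end, length.out = 201L)
  stopifnot(all(out_times >= 0), all(out_times <= t_end),
            !is.unsorted(out_times, strictly = TRUE))
  if (out_times[1] > 0) out_times <- c(0, out_times)
  y0 <- c(uT = p$ib$uT0, uA = p$ib$uA0, uC = 0, theta = 0)
  sol <- deSolve::lsoda(
    y = y0, times = out_times,
    func = function(t, y, parms) list(wms_rhs(y, parms)),
    parms = p, rtol = rtol, atol = atol, maxsteps = 1e6
  )
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("WMS integration failed near t = %g", utils::tail(sol[, 1], 1)),
         call. = FALSE)
  }
  out <- as.data.frame(unclass(sol))
  names(out)[1] <- "t"
  structure(out, params = p, rtol = rtol, atol = atol,
            class = c("wms_trajectory", "data.frame"))
}

#' Steady-state receptor occupancy of the WMS model
#'
#' Solves the closed steady-state equation (internalization switched off,
#' `k3 = 0`):
#' \deqn{(1-\theta)\left(u_T^0 - R_0\theta - \frac{\varepsilon u_A^0 \theta}{1+(\varepsilon-1)\theta}\right) = K_2\theta}
#' for the physically admissible root `theta` in `[0, 1]` by bracketed
#' root-finding.
#'
#' @param p an [rta_params()] object (its `k3` is ignored: the equation is
#'   the zero-internalization steady state).
#' @param uA0 antibody concentration; defaults to the value in `p`.
#' @param tol root tolerance (default 1e-12).
#' @return The root `theta_sat` in `[0, 1]`.
#' @export
steady_state_theta <- function(p, uA0 = p$ib$uA0, tol = 1e-12) {
  stopifnot(inherits(p, "rta_params"), uA0 >= 0)
  d <- derived_constants(p)
  uT0 <- p$ib$uT0
  if (uT0 == 0) return(0)
  g <- function(th) {
    (1 - th) * (uT0 - d$R0 * th -
                d$eps * uA0 * th / (1 + (d$eps - 1) * th)) - d$K2 * th
  }
  if (g(0) <= 0) return(0)
  if (g(1) >= 0) return(1)
  stats::uniroot(g, c(0, 1), tol = tol)$root
}

#' Closed-form occupancy quadratic of the WMS steady state
#'
#' Approximate closed form for the saturation occupancy when the receptor
#' capacity is negligible relative to the antibody buffering
#' (`R0 / (eps uA0) << 1`):
#' \deqn{F(x, y) = \frac{q_1 - \sqrt{q_1^2 - 4 q_2 y}}{2 q_2}}
#' with \eqn{q_1 = K_2 + \varepsilon x - (\varepsilon - 2) y} and
#' \eqn{q_2 = q_1 - (\varepsilon K_2 + y)}; `x` is the antibody and `y` the
#' toxin concentration.  The minus branch is the physical root.
#'
#' @param x antibody concentration.
#' @param y toxin concentration.
#' @param d an `rta_derived` object (see [derived_constants()]).
#' @return The value `F(x, y)`.
#' @export
closed_form_F <- function(x, y, d) {
  q1 <- d$K2 + d$eps * x - (d$eps - 2) * y
  q2 <- q1 - (d$eps * d$K2 + y)
  disc <- q1^2 - 4 * q2 * y
  if (q2 == 0) {
    stop(sprintf("degenerate quadratic (q2 = 0) at x = %g, y = %g", x, y),
         call. = FALSE)
  }
  if (disc < 0) {
    stop(sprintf("negative discriminant (%g) at x = %g, y = %g", disc, x, y),
         call. = FALSE)
  }
  (q1 - sqrt(disc)) / (2 * q2)
}

#' WMS saturation protection factor
#'
#' The protection factor is the ratio of occupied receptors with antibody
#' present to occupied receptors without antibody.  Three estimators of its
#' saturation (long-time) value are available:
#' \describe{
#'   \item{`root`}{ratio of steady-state occupancies from
#'     [steady_state_theta()] (zero internalization).}
#'   \item{`closed_form`}{ratio of the closed-form roots
#'     `F(uA0, uT0) / F(0, uT0)` (see [closed_form_F()]).}
#'   \item{`long_time`}{ratio of `theta(t_long)` from paired
#'     [integrate_wms()] runs with and without antibody; the only estimator
#'     valid with internalization (`k3 > 0`).}
#' }
#'
#' @param p an [rta_params()] object.
#' @param method one of `"root"`, `"closed_form"`, `"long_time"`.
#' @param t_long horizon for the `long_time` method (default 1e4).
#' @return The scalar saturation protection factor.
#' @export
psi_sat_wms <- function(p, method = c("root", "closed_form", "long_time"),
                        t_long = 1e4) {
  stopifnot(inherits(p, "rta_params"))
  method <- match.arg(method)
  if (p$ib$uT0 == 0) {
    stop("uT0 = 0: no receptor occupancy, protection factor undefined",
         call. = FALSE)
  }
  if (p$ib$uA0 == 0) return(1)
  if (method != "long_time" && p$rates$k3 > 0) {
    warning("steady-state estimators assume k3 = 0; ",
            "falling back to the long-time estimator", call. = FALSE)
    method <- "long_time"
  }
  switch(method,
    root = steady_state_theta(p) / steady_state_theta(p, uA0 = 0),
    closed_form = {
      d <- derived_constants(p)
      closed_form_F(p$ib$uA0, p$ib$uT0, d) / closed_form_F(0, p$ib$uT0, d)
    },
    long_time = {
      tt <- c(0, t_long)
      thA <- utils::tail(integrate_wms(p, t_long, tt)$theta, 1)
      th0 <- utils::tail(integrate_wms(p, t_long, tt, uA0 = 0)$theta, 1)
      thA / th0
    }
  )
}

#' Conservation-law residuals of a WMS trajectory
#'
#' The WMS system conserves total antibody exactly (`uA + uC = uA0`); with
#' internalization switched off it also conserves total toxin
#' (`uT + uC + k4 r0 theta = uT0`).  With `k3 > 0` the toxin residual equals
#' the cumulative internalized amount and grows monotonically.
#'
#' @param traj a `wms_trajectory` from [integrate_wms()].
#' @param p parameters; defaults to those stored in `traj`.
#' @return data.frame with columns `t`, `antibody` (|uA + uC - uA0|) and
#'   `toxin` (|uT + uC + k4 r0 theta - uT0|).
#' @export
conservation_residuals <- function(traj, p = attr(traj, "params")) {
  stopifnot(inherits(traj, "wms_trajectory"))
  k4 <- 3 * p$geom$rho_c^2 / (p$geom$rho_e^3 - p$geom$rho_c^3)
  uA0 <- traj$uA[1] + traj$uC[1]
  data.frame(
    t = traj$t,
    antibody = abs(traj$uA + traj$uC - uA0),
    toxin = abs(traj$uT + traj$uC + k4 * p$geom$r0 * traj$theta - p$ib$uT0)
  )
}

#' @export
print.wms_trajectory <- function(x, ...) {
  cat(sprintf("WMS trajectory: %d output times on [%g, %g]\n",
              nrow(x), x$t[1], x$t[nrow(x)]))
  cat(sprintf("  final state: uT = %.6g, uA = %.6g, uC = %.6g, theta = %.6g\n",
              x$uT[nrow(x)], x$uA[nrow(x)], x$uC[nrow(x)], x$theta[nrow(x)]))
  invisible(x)
}

#' @export
plot.wms_trajectory <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$uT, x$uA, x$uC, x$theta), type = "l",
                    lty = 1, col = c("firebrick", "steelblue", "darkgreen",
                                     "black"),
                    xlab = "time", ylab = "concentration / occupancy", ...)
  graphics::legend("topright", c("uT", "uA", "uC", "theta"), lty = 1,
                   col = c("firebrick", "steelblue", "darkgreen", "black"),
                   bty = "n")
  invisible(x)
}
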