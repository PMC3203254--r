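# Well-mixed ODE model: right-hand side, integration, steady states and
# the saturation estimators.

test_that("rhs preserves complex/antibody antisymmetry and initial rates", {
  p <- default_params()
  s0 <- c(uT = 0.5, uA = 1, uC = 0, theta = 0)
  d <- wms_rhs(s0, p)
  expect_equal(d[["uA"]], -p$rates$k1 * 0.5 * 1)
  expect_equal(d[["uC"]], -d[["uA"]])
  # occupancy growth with free receptors only
  d2 <- wms_rhs(c(uT = 0.5, uA = 0, uC = 0, theta = 0), p)
  expect_equal(d2[["theta"]], 6.25e-3)
  # uA + uC invariant holds for arbitrary states
  set.seed(11)
  for (i in 1:25) {
    s <- c(uT = runif(1), uA = runif(1), uC = runif(1), theta = runif(1))
    dv <- wms_rhs(s, p)
    expect_identical(dv[["uA"]] + dv[["uC"]], 0)
  }
})

test_that("trajectories satisfy the conservation laws", {
  p <- params_with(k3 = 0)
  traj <- integrate_wms(p, 1e4)
  res <- conservation_residuals(traj)
  expect_lt(max(res$antibody), 1e-9)
  expect_lt(max(res$toxin), 1e-8)
  expect_equal(unlist(traj[1, c("uT", "uA", "uC", "theta")]),
               c(uT = 0.5, uA = 1, uC = 0, theta = 0))
  # with internalization the toxin deficit grows monotonically
  trj <- integrate_wms(default_params(), 1e4)
  resk <- conservation_residuals(trj)
  expect_lt(max(resk$antibody), 1e-9)
  expect_true(all(diff(resk$toxin) > -1e-12))
  # cumulative internalized amount ~ k4 r0 k3 * integral(theta): small but
  # clearly above solver noise
  expect_gt(max(resk$toxin), 1e-8)
})

test_that("occupancy and concentrations stay in their physical ranges", {
  traj <- integrate_wms(default_params(), 1e4)
  expect_true(all(traj$theta >= 0 & traj$theta <= 1))
  expect_true(all(traj$uT >= -1e-12 & traj$uA >= -1e-12 & traj$uC >= -1e-12))
})

test_that("no antibody means no complex, and short-time occupancy is linear", {
  p <- params_with(uA0 = 0)
  traj <- integrate_wms(p, 100)
  expect_true(all(traj$uA == 0))
  expect_true(all(abs(traj$uC) < 1e-14))
  th1 <- integrate_wms(p, 1, out_times = c(0, 1))$theta[2]
  expect_equal(th1, 6.25e-3, tolerance = 5e-3)
})

test_that("steady-state occupancy matches an independent bisection oracle", {
  p <- params_with(k3 = 0)
  d <- derived_constants(p)
  # frozen oracle values (200-step bisection on the occupancy equation)
  expect_equal(steady_state_theta(p, uA0 = 0), 0.9231895080, tolerance = 1e-9)
  expect_equal(steady_state_theta(p, uA0 = 1), 0.1989688509, tolerance = 1e-9)
  # and against the oracle recomputed here for other antibody levels
  for (uA0 in c(0.25, 2, 5)) {
    expect_equal(steady_state_theta(p, uA0 = uA0),
                 bisect_theta_sat(0.5, uA0, d$K2, d$eps, d$R0),
                 tolerance = 1e-9)
  }
  expect_equal(steady_state_theta(params_with(uT0 = 0)), 0)
})

test_that("steady-state occupancy decreases with antibody concentration", {
  p <- params_with(k3 = 0)
  th <- vapply(c(0, 0.5, 1, 2, 4, 8), function(a) steady_state_theta(p, a),
               numeric(1))
  expect_true(all(diff(th) < 0))
})

test_that("closed-form root agrees with a polyroot oracle and edge cases", {
  d <- derived_constants(default_params())
  # frozen values from the quadratic solved independently with polyroot
  expect_equal(closed_form_F(0, 0.5, d), 0.9231905465, tolerance = 1e-9)
  expect_equal(closed_form_F(1, 0.5, d), 0.1989698175, tolerance = 1e-9)
  expect_equal(closed_form_F(1, 0, d), 0)
  for (x in c(0.3, 1.5)) {
    for (y in c(0.1, 0.5)) {
      q1 <- d$K2 + d$eps * x - (d$eps - 2) * y
      q2 <- q1 - (d$eps * d$K2 + y)
      roots <- Re(polyroot(c(y, -q1, q2)))
      expect_equal(closed_form_F(x, y, d),
                   roots[roots >= 0 & roots <= 1][1], tolerance = 1e-9)
    }
  }
})

test_that("the three saturation estimators agree pairwise across rate combinations", {
  rows <- list(c(0.013, 0.0125), c(0.013, 0.025), c(0.013, 0.05),
               c(0.13, 0.0125))
  for (kk in rows) {
    p <- params_with(k1 = kk[1], k2 = kk[2], k3 = 0)
    psi2 <- psi_sat_wms(p, "root")
    psi3 <- psi_sat_wms(p, "closed_form")
    psi4 <- psi_sat_wms(p, "long_time")
    # the finite-horizon estimator sits up to ~5e-4 above the true steady
    # state at t = 1e4 on the slowest-converging row
    expect_lt(abs(psi2 - psi3), 5e-4)
    expect_lt(abs(psi2 - psi4), 6e-4)
    expect_lt(abs(psi3 - psi4), 6e-4)
  }
})

test_that("long-time occupancy converges to the steady state", {
  p <- params_with(k3 = 0)
  th1 <- utils::tail(integrate_wms(p, 1e4, c(0, 1e4))$theta, 1)
  th2 <- utils::tail(integrate_wms(p, 2e4, c(0, 2e4))$theta, 1)
  th_sat <- steady_state_theta(p)
  expect_lt(abs(th2 - th1), 5e-4)
  expect_lt(abs(th2 - th_sat), abs(th1 - th_sat))  # monotone approach
  expect_lt(abs(th2 - th_sat), 1e-3)
})

test_that("degenerate protection requests are handled explicitly", {
  expect_equal(psi_sat_wms(params_with(uA0 = 0), "root"), 1)
  expect_error(psi_sat_wms(params_with(uT0 = 0)), "uT0")
  # internalization routes steady-state estimators to the long-time path
  expect_warning(psi <- psi_sat_wms(default_params(), "root"), "k3")
  expect_equal(psi, psi_sat_wms(default_params(), "long_time"))
})
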