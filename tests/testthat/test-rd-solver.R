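# Reaction-diffusion solver: grid, boundary handling, step mechanics and
# physical invariants.  Runs here use reduced grids/horizons; the published
# table values are exercised in the acceptance suite.

test_that("radial grid spans the shell uniformly", {
  g <- build_grid(list(rho_c = 0.1, rho_e = 2), 3)
  expect_equal(g$rho, c(0.1, 1.05, 2.0))
  g2 <- build_grid(list(rho_c = 0.1, rho_e = 5), 491)
  expect_equal(g2$h, 0.01)
  expect_equal(range(g2$rho), c(0.1, 5))
  expect_error(build_grid(list(rho_c = 0.1, rho_e = 2), 2), "at least 3")
})

test_that("reaction terms are mass-action with exact antisymmetry", {
  p <- default_params()
  src <- reaction_terms(0.5, 1, 0, p)
  expect_equal(src$uT, -6.5e-3)
  # detailed balance at complexation equilibrium
  uT <- 0.3; uA <- 0.7
  uC <- p$rates$k1 * uT * uA / p$rates$k_m1
  eq <- reaction_terms(uT, uA, uC, p)
  expect_equal(eq$uT, 0)
  set.seed(21)
  for (i in 1:20) {
    s <- reaction_terms(runif(5), runif(5), runif(5), p)
    expect_identical(s$uT + s$uC, rep(0, 5))
    expect_identical(s$uA + s$uC, rep(0, 5))
  }
})

test_that("surface flux implements the reactive wall condition", {
  p <- default_params()
  # binding equilibrium: zero net rate, zero wall gradient
  uT <- 0.4
  th_eq <- p$rates$k2 * uT / (p$rates$k2 * uT + p$rates$k_m2)
  eq <- surface_flux(uT, th_eq, p)
  expect_equal(eq$binding_rate, 0, tolerance = 1e-15)
  expect_equal(eq$wall_gradient, 0, tolerance = 1e-12)
  # fresh surface
  f0 <- surface_flux(0.5, 0, p)
  expect_equal(f0$binding_rate, 6.25e-3)
  expect_equal(f0$theta_rate, 6.25e-3)
  expect_gt(f0$wall_gradient, 0)   # toxin drawn toward the cell
  # saturated surface releasing toxin
  f1 <- surface_flux(0, 1, p)
  expect_equal(f1$binding_rate, -p$rates$k_m2)
  expect_lt(f1$wall_gradient, 0)
})

test_that("one implicit step keeps the outer boundary exactly Dirichlet", {
  p <- default_params()
  g <- build_grid(p$geom, 51)
  f <- rd_fields(p, g)
  f1 <- rd_advance(f, 0.5, p)
  N <- g$N
  expect_identical(f1$uT[N], p$ib$uT0)
  expect_identical(f1$uA[N], p$ib$uA0)
  expect_identical(f1$uC[N], 0)
  expect_gt(f1$theta, 0)
  expect_lt(f1$uT[1], p$ib$uT0)    # wall depletion from receptor binding
})

test_that("without antibody the antibody/complex subsystem stays zero", {
  p <- default_params()
  sol <- simulate_rd(p, rd_settings(N = 51, dt = 1), 200, uA0 = 0,
                     detect_steady = FALSE)
  last <- sol$snapshots[[length(sol$snapshots)]]
  expect_identical(max(abs(last$uA)), 0)
  expect_identical(max(abs(last$uC)), 0)
})

test_that("simulation is deterministic and t_end = 0 is the initial state", {
  p <- default_params()
  st <- rd_settings(N = 51, dt = 1)
  a <- simulate_rd(p, st, 50, detect_steady = FALSE)
  b <- simulate_rd(p, st, 50, detect_steady = FALSE)
  expect_identical(a$theta_series, b$theta_series)
  expect_identical(a$snapshots, b$snapshots)
  z <- simulate_rd(p, st, 0)
  expect_length(z$snapshots, 1)
  expect_length(z$theta_series, 0)
  expect_equal(z$snapshots[[1]]$t, 0)
})

test_that("fields stay nonnegative and occupancy within [0, 1]", {
  p <- params_with(kappa_T = 1e-3)
  sol <- simulate_rd(p, rd_settings(N = 101, dt = 1), 2000,
                     record_times = c(0, 500, 2000), detect_steady = FALSE)
  expect_true(all(sol$theta_series >= 0 & sol$theta_series <= 1))
  for (s in sol$snapshots) {
    expect_gt(min(s$uT, s$uA, s$uC), -1e-10)
  }
})

test_that("large diffusivities reduce to the analytic surface kinetics", {
  p <- params_with(kappa_T = 1e3, kappa_A = 1e3, kappa_C = 1e3)
  st <- rd_settings(N = 101, dt = 0.25, scheme = "crank_nicolson")
  sol <- simulate_rd(p, st, 600, uA0 = 0, detect_steady = FALSE)
  lam <- p$rates$k2 * p$ib$uT0 + p$rates$k_m2 + p$rates$k3
  th_inf <- p$rates$k2 * p$ib$uT0 / lam
  analytic <- th_inf * (1 - exp(-lam * sol$step_times))
  expect_lt(max(abs(sol$theta_series - analytic)), 1e-3)
  last <- sol$snapshots[[length(sol$snapshots)]]
  expect_lt(diff(range(last$uT)), 1e-4)   # fields effectively uniform
})

test_that("protection curve is the occupancy ratio with psi(0) = 1", {
  p <- default_params()
  st <- rd_settings(N = 51, dt = 1)
  sA <- simulate_rd(p, st, 100, detect_steady = FALSE)
  s0 <- simulate_rd(p, st, 100, uA0 = 0, detect_steady = FALSE)
  pc <- psi_timecourse(sA, s0)
  expect_equal(pc$psi[1], 1)
  expect_equal(pc$psi[-1], pc$theta_A[-1] / pc$theta_0[-1])
  expect_true(all(pc$psi >= 0))
  # identical runs give psi identically 1
  id <- psi_timecourse(sA, sA)
  expect_identical(unique(id$psi), 1)
  # mismatched settings are rejected
  sB <- simulate_rd(p, rd_settings(N = 41, dt = 1), 100, uA0 = 0,
                    detect_steady = FALSE)
  expect_error(psi_timecourse(sA, sB), "paired runs")
})

test_that("steady internalization flux balances the outer diffusive influx", {
  p <- default_params()
  sol <- simulate_rd(p, rd_settings(N = 201, dt = 1), 2e4, uA0 = 0,
                     detect_steady = FALSE)
  s <- sol$snapshots[[length(sol$snapshots)]]
  rho <- sol$grid$rho; h <- sol$grid$h; N <- sol$grid$N
  grad_out <- (3 * s$uT[N] - 4 * s$uT[N - 1] + s$uT[N - 2]) / (2 * h)
  influx <- p$diff$kappa_T * rho[N]^2 * grad_out
  internalized <- p$geom$r0 * p$rates$k3 * s$theta * rho[1]^2
  expect_equal(influx, internalized, tolerance = 0.01)
})

test_that("steady-state detection stops the run early", {
  p <- params_with(kappa_T = 1e3, kappa_A = 1e3, kappa_C = 1e3)
  sol <- simulate_rd(p, rd_settings(N = 51, dt = 1), 6000, uA0 = 0,
                     detect_steady = TRUE)
  expect_true(sol$steady)
  expect_lt(sol$t_end, 6000)
})

test_that("identical refinement settings give zero change", {
  p <- default_params()
  st <- rd_settings(N = 51, dt = 2)
  cs <- grid_convergence_study(p, list(st, st), t_end = 100)
  expect_identical(cs$change[2], 0)
})
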