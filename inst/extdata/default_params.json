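{
  "rates": {"k1": 1.3e-2, "k_m1": 1.4e-4, "k2": 1.25e-2, "k_m2": 5.2e-4, "k3": 3.3e-5},
  "diffusivities": {"kappa_T": 1.0e-2, "kappa_A": 1.0e-2, "kappa_C": 1.0e-2},
  "geometry": {"rho_c": 0.1, "rho_e": 2.0, "r0": 2.115e-3},
  "initial": {"uT0": 0.5, "uA0": 1.0, "uC0": 0.0},
  "scales": {"u_star": 6.02e13, "tau_star": 1.0, "l": 1.0e-2},
  "units": "nondimensional",
  "solver": {"N": 401, "dt": 0.5, "scheme": "backward_euler", "nonlinear_tol": 1.0e-12, "max_inner": 50}
}
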