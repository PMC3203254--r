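# Shared helpers: parameter overrides by field name and an independent
# bisection oracle for the steady-state occupancy equation.

params_with <- function(..., base = default_params()) {
  mods <- list(...)
  p <- base
  blocks <- list(rates = names(p$rates), diff = names(p$diff),
                 geom = names(p$geom), ib = names(p$ib))
  for (nm in names(mods)) {
    hit <- FALSE
    for (blk in names(blocks)) {
      if (nm %in% blocks[[blk]]) { p[[blk]][[nm]] <- mods[[nm]]; hit <- TRUE }
    }
    if (!hit) stop("unknown parameter field: ", nm)
  }
  p
}

# Bisection on the steady-state occupancy equation, written independently of
# steady_state_theta (no uniroot, no shared code path).
bisect_theta_sat <- function(uT0, uA0, K2, eps, R0, iters = 200) {
  g <- function(th) {
    (1 - th) * (uT0 - R0 * th - eps * uA0 * th / (1 + (eps - 1) * th)) -
      K2 * th
  }
  lo <- 0; hi <- 1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
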