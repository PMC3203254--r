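# Published reference saturation values used for regression reporting.

# WMS estimators across four (k1, k2) rate combinations; psi4 columns are the
# long-time ODE estimates at t = 1e4 without and with internalization.
.REF_WMS <- data.frame(
  k1 = c(0.013, 0.013, 0.013, 0.13),
  k2 = c(0.0125, 0.025, 0.05, 0.0125),
  psi2 = c(0.215524, 0.345686, 0.508760, 0.027219),
  psi3 = c(0.215524, 0.345708, 0.508754, 0.027220),
  psi4_k3_off = c(0.216026, 0.345903, 0.508767, 0.027426),
  psi4_k3_on = c(0.206474, 0.332632, 0.493704, 0.025913)
)

# Reaction-diffusion estimators: psi1 (wall-concentration isotherm at t = 1e3)
# and psi5 (occupancy ratio at t = 1e4) across toxin- and antibody-diffusivity
# sweeps.
.REF_PDE <- data.frame(
  kappa_T = c(1e-2, 5e-3, 1e-3, 1e-4, 1e-3, 1e-3, 1e-3, 1e-3),
  kappa_A = c(1e-2, 1e-2, 1e-2, 1e-2, 1e-1, 1e-2, 1e-3, 1e-4),
  psi1 = c(0.9339, 0.8433, 0.1480, 0.0047, 0.1342, 0.1480, 0.3729, 0.9801),
  psi5 = c(0.9339, 0.8433, 0.1483, 0.0034, 0.1345, 0.1483, 0.3726, 0.9801)
)

#' Recompute the saturation-estimator comparison tables
#'
#' Recomputes every saturation estimate of the protection factor with the
#' shipped default parameters and compares it side by side with the stored
#' published reference values.
#'
#' For `model = "wms"` the four (k1, k2) rate combinations are evaluated
#' with the steady-state root (`psi2`), the closed form (`psi3`) and the
#' long-time ODE ratio at t = 1e4 without and with internalization
#' (`psi4`).  For `model = "pde"` the eight diffusivity combinations are
#' evaluated with the wall-isotherm estimator (`psi1`, t = 1e3) and the
#' occupancy ratio (`psi5`, t = 1e4) from paired reaction-diffusion runs.
#'
#' @param model `"wms"` or `"pde"`.
#' @param settings [rd_settings()] for the `"pde"` table.
#' @param tol verdict tolerance on |computed - reference|; defaults to
#'   5e-4 for `"wms"` and 0.01 for `"pde"`.
#' @return data.frame with columns `estimator`, the varied parameters,
#'   `computed`, `reference`, `abs_diff`, `pass`.
#' @export
psi_saturation_report <- function(model = c("wms", "pde"),
                                  settings = rd_settings(), tol = NULL) {
  model <- match.arg(model)
  p0 <- default_params()
  if (model == "wms") {
    if (is.null(tol)) tol <- 5e-4
    out <- do.call(rbind, lapply(seq_len(nrow(.REF_WMS)), function(i) {
      ref <- .REF_WMS[i, ]
      p <- p0
      p$rates$k1 <- ref$k1
      p$rates$k2 <- ref$k2
      p_off <- p; p_off$rates$k3 <- 0
      comp <- c(psi2 = psi_sat_wms(p_off, "root"),
                psi3 = psi_sat_wms(p_off, "closed_form"),
                psi4_k3_off = psi_sat_wms(p_off, "long_time"),
                psi4_k3_on = psi_sat_wms(p, "long_time"))
      data.frame(estimator = names(comp), k1 = ref$k1, k2 = ref$k2,
                 computed = unname(comp),
                 reference = unlist(ref[names(comp)], use.names = FALSE))
    }))
  } else {
    if (is.null(tol)) tol <- 0.01
    out <- do.call(rbind, lapply(seq_len(nrow(.REF_PDE)), function(i) {
      ref <- .REF_PDE[i, ]
      p <- p0
      p$diff$kappa_T <- ref$kappa_T
      p$diff$kappa_A <- ref$kappa_A
      sols <- list(
        with = simulate_rd(p, settings, 1e4, detect_steady = FALSE),
        without = simulate_rd(p, settings, 1e4, uA0 = 0,
                              detect_steady = FALSE)
      )
      comp <- c(psi1 = psi_sat_pde(p, settings, "psi1", sols = sols),
                psi5 = psi_sat_pde(p, settings, "psi5", sols = sols))
      data.frame(estimator = names(comp),
                 kappa_T = ref$kappa_T, kappa_A = ref$kappa_A,
                 computed = unname(comp),
                 reference = unlist(ref[names(comp)], use.names = FALSE))
    }))
  }
  out$abs_diff <- abs(out$computed - out$reference)
  out$pass <- out$abs_diff <= tol
  rownames(out) <- NULL
  out
}
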