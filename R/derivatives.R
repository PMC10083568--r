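#' CHIP partition fraction
#'
#' Fraction of CHIP activity directed at misfolded protein rather than at
#' HSPA1A, under a quasi-steady-state competition with affinity bias
#' `a_chip` for misfolded clients: `phi = a_chip * M / (a_chip * M + H)`.
#' By convention the fraction is 0 when both concentrations are zero.
#' The fraction is monotone increasing in `M`, decreasing in `H`, and lies
#' in [0, 1]; a high misfolded-protein load therefore shuts down
#' CHIP-mediated chaperone turnover while boosting MFP clearance.
#'
#' @param M misfolded-protein concentration (vectorised).
#' @param H free HSPA1A concentration.
#' @param a_chip affinity bias, > 1.
#' @return Numeric vector of partition fractions in [0, 1].
#' @export
chip_partition <- function(M, H, a_chip) {
  den <- a_chip * M + H
  ifelse(den <= 0, 0, a_chip * M / den)
}

#' Time derivatives of the titration model
#'
#' Evaluates the right-hand side of the delay system at one time point.
#' Seven processes are represented: basal (stress-amplified) misfolding,
#' chaperone-catalysed refolding, delayed HSF1-driven HSPA1A synthesis,
#' CHIP-mediated degradation of misfolded protein and of HSPA1A
#' (partitioned by [chip_partition()]), HSF1 inactivation by association
#' with HSPA1A, and MFP-driven release of HSF1 from the complex. HSF1 is
#' conserved by construction: `dF = -dHF` exactly.
#'
#' @param state current [hsr_state()].
#' @param state_delayed state at `t - tau` (only its `F` component is used).
#' @param params an [hsr_params()] object.
#' @param stress_on logical; is the stress window active?
#' @param titrate_C logical; if `TRUE`, CHIP relaxes towards `H / r_HC`
#'   (the equilibration mode), otherwise `dC = 0`.
#' @param eta relaxation rate of the CHIP titration (1/min).
#' @return Named numeric vector of derivatives `(H, HF, F, M, C)`.
#' @export
#' @examples
#' p <- hsr_params()
#' st <- hsr_state(H = 1, HF = 0.95, F = 0.05, M = 0.05, C = 0.2)
#' hsr_derivatives(st, st, p, stress_on = FALSE)
hsr_derivatives <- function(state, state_delayed = state, params,
                            stress_on = FALSE, titrate_C = FALSE,
                            eta = 0.05) {
  if (any(unclass(state) < 0) || any(unclass(state_delayed) < 0))
    stop("negative input concentration")
  H <- state[["H"]]; HF <- state[["HF"]]; F <- state[["F"]]
  M <- state[["M"]]; C <- state[["C"]]
  Fd <- state_delayed[["F"]]
  phi <- chip_partition(M, H, params$a_chip)
  syn <- if (Fd > 0) params$k * Fd / (params$Kd + Fd) else 0
  gen <- params$k1 * if (isTRUE(stress_on)) params$s else 1
  assoc <- params$k6 * H * F
  rel <- params$k7 * M * HF
  dM <- gen - params$k2 * H * M - params$k4 * C * phi * M
  dHF <- assoc - rel
  dH <- syn - params$k5 * C * (1 - phi) * H - assoc + rel
  dC <- if (titrate_C) eta * (H / params$r_HC - C) else 0
  out <- c(H = dH, HF = dHF, F = -dHF, M = dM, C = dC)
  if (!all(is.finite(out))) stop("non-finite rate")
  out
}

as_state_vector <- function(state) {
  as.numeric(unclass(state)[c("H", "HF", "F", "M", "C")])
}

par_vector <- function(params, eta = 0.05) {
  c(params$k, params$Kd, params$k2, params$k4, params$k5, params$k7,
    params$k1, params$k6, params$a_chip, params$r_HC, eta)
}
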