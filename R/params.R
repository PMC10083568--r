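#' Parameters of the HSPA1A titration model
#'
#' Constructs the full parameter set of the HSF1--HSPA1A--CHIP--MFP titration
#' model. Concentrations are dimensionless, normalised so that the prestress
#' equilibrium free-HSPA1A concentration is 1; time is in minutes.
#'
#' The free (fitted) parameters are `k`, `Kd`, `k2`, `k4`, `k5` and `k7`.
#' The remaining parameters are fixed from theory, data, or literature:
#' `k1` (basal misfolding), `k6` (HSF1 inactivation), `tau` (synthesis
#' delay), `F_tot` (total HSF1 pool), `r_HC` (prestress HSPA1A:CHIP ratio),
#' `a_chip` (CHIP affinity bias for misfolded protein over HSPA1A) and `s`
#' (stress multiplier on the misfolding rate during the stress window).
#'
#' The shipped defaults are the package's baseline parameter set, calibrated
#' once so that the equilibrated model reproduces the experimentally anchored
#' behaviours of the early-passage stress response (see the methods
#' vignette): prestress equilibrium at H = 1 with M = 0.05, an HSPA1A
#' half-life of 100 min when synthesis is switched off, and a 10.3-h period
#' of proteotoxic stress under the standard 120-min stress protocol.
#'
#' @param k maximal HSPA1A synthesis rate (concentration/min).
#' @param Kd half-saturation constant of active-HSF1-driven synthesis.
#' @param k2 chaperone-mediated refolding rate constant (1/(conc min)).
#' @param k4 CHIP-mediated MFP degradation rate constant (1/(conc min)).
#' @param k5 CHIP-mediated HSPA1A degradation rate constant (1/(conc min)).
#' @param k7 MFP-driven HSF1-release rate constant (1/(conc min)).
#' @param k1 basal misfolding rate (concentration/min).
#' @param k6 HSPA1A-HSF1 association rate constant (1/(conc min)).
#' @param tau synthesis delay between HSF1 activation and protein
#'   appearance (min).
#' @param F_tot total HSF1 pool (conserved).
#' @param r_HC prestress HSPA1A:CHIP concentration ratio.
#' @param a_chip CHIP affinity bias for MFP over HSPA1A (> 1).
#' @param s stress multiplier applied to the misfolding rate (>= 1).
#' @return An object of class `hsr_params` (a named list).
#' @seealso [hsr_model()], [hsr_derivatives()], [write_params_yaml()]
#' @export
#' @examples
#' p <- hsr_params()
#' p$k5
hsr_params <- function(k = .hsr_defaults[["k"]],
                       Kd = .hsr_defaults[["Kd"]],
                       k2 = .hsr_defaults[["k2"]],
                       k4 = .hsr_defaults[["k4"]],
                       k5 = .hsr_defaults[["k5"]],
                       k7 = .hsr_defaults[["k7"]],
                       k1 = .hsr_defaults[["k1"]],
                       k6 = .hsr_defaults[["k6"]],
                       tau = .hsr_defaults[["tau"]],
                       F_tot = .hsr_defaults[["F_tot"]],
                       r_HC = .hsr_defaults[["r_HC"]],
                       a_chip = .hsr_defaults[["a_chip"]],
                       s = .hsr_defaults[["s"]]) {
  p <- list(k = k, Kd = Kd, k2 = k2, k4 = k4, k5 = k5, k7 = k7,
            k1 = k1, k6 = k6, tau = tau, F_tot = F_tot, r_HC = r_HC,
            a_chip = a_chip, s = s)
  validate_hsr_params(p)
  structure(p, class = "hsr_params")
}

#' @export
print.hsr_params <- function(x, ...) {
  cat("HSR titration model parameters\n")
  cat("  fitted: ", paste(sprintf("%s=%.4g", hsr_free_params(),
                                  unlist(x[hsr_free_params()])),
                          collapse = ", "), "\n")
  fixed <- setdiff(names(x), hsr_free_params())
  cat("  fixed:  ", paste(sprintf("%s=%.4g", fixed, unlist(x[fixed])),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Names of the free (fitted) model parameters
#' @return Character vector of the six optimised parameter names.
#' @export
hsr_free_params <- function() c("k", "Kd", "k2", "k4", "k5", "k7")

validate_hsr_params <- function(p) {
  need <- c("k", "Kd", "k2", "k4", "k5", "k7", "k1", "k6", "tau",
            "F_tot", "r_HC", "a_chip", "s")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  vals <- unlist(p[need])
  if (!all(is.finite(vals))) stop("all parameters must be finite")
  # k and k1 may be zero (synthesis switch-off / no-misfolding experiments)
  pos <- c("Kd", "k2", "k4", "k5", "k7", "k6", "tau", "F_tot", "r_HC")
  if (any(vals[pos] <= 0))
    stop("parameters ", paste(pos[vals[pos] <= 0], collapse = ", "),
         " must be strictly positive")
  if (p$k < 0 || p$k1 < 0) stop("k and k1 must be non-negative")
  if (p$a_chip <= 1) stop("a_chip must exceed 1")
  if (p$s < 1) stop("s must be >= 1")
  invisible(TRUE)
}

#' Read or write model parameters as a flat YAML mapping
#'
#' Parameters serialise to a flat mapping keyed by symbol name. Unknown keys
#' in a file are rejected so that typos cannot silently fall back to
#' defaults; absent keys take the package defaults.
#'
#' @param path file path.
#' @param params an [hsr_params()] object.
#' @return `read_params_yaml()` returns an `hsr_params` object;
#'   `write_params_yaml()` returns `path` invisibly.
#' @export
read_params_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(hsr_params))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  do.call(hsr_params, x)
}

#' @rdname read_params_yaml
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "hsr_params"))
  yaml::write_yaml(lapply(unclass(params), as.numeric), path,
                   precision = 15)
  invisible(path)
}

#' Construct a model state
#'
#' A model state holds the concentrations of the five tracked species:
#' free HSPA1A (`H`), the HSPA1A.HSF1 complex (`HF`, the inactive-HSF1
#' reservoir), free/active HSF1 (`F`), misfolded protein (`M`) and the CHIP
#' pool (`C`). All concentrations are non-negative and `F + HF` equals the
#' conserved total HSF1 pool.
#'
#' @param H,HF,F,M,C species concentrations.
#' @return A named numeric vector of class `hsr_state`.
#' @export
hsr_state <- function(H, HF, F, M, C) {
  x <- c(H = unname(H), HF = unname(HF), F = unname(F), M = unname(M),
         C = unname(C))
  if (!all(is.finite(x))) stop("state must be finite")
  if (any(x < 0)) stop("state concentrations must be non-negative")
  structure(x, class = "hsr_state")
}

#' @export
print.hsr_state <- function(x, ...) {
  cat("HSR model state:\n")
  print(round(unclass(x), 6))
  invisible(x)
}
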