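#' Convert a log2 fold-change to a linear multiplier
#'
#' @param log2fc finite numeric (vectorised).
#' @return `2^log2fc`.
#' @export
#' @examples
#' log2fc_to_factor(-0.7799)  # prestress CHIP scaling in senescent cells
#' log2fc_to_factor(-0.4873)  # maximal-synthesis scaling
log2fc_to_factor <- function(log2fc) {
  if (!all(is.finite(log2fc))) stop("log2fc must be finite")
  2^log2fc
}

#' Senescence perturbation of the fitted model
#'
#' Applies the measured late-passage (LP) alterations to an early-passage
#' (EP) model: the prestress CHIP pool is multiplied by
#' `2^log2fc_chip` (loss of CHIP) and the maximal HSPA1A synthesis rate `k`
#' by `2^log2fc_k` (loss of ribosomal/translational capacity). CHIP is held
#' fixed at its scaled value (not re-titrated); the remaining species are
#' then re-relaxed to the LP model's own prestress steady state before any
#' stress protocol is applied.
#'
#' @param model an equilibrated EP [hsr_model()].
#' @param log2fc_chip log2 fold-change of prestress CHIP (LP vs EP).
#' @param log2fc_k log2 fold-change of the maximal synthesis rate.
#' @return An `hsr_model` for the LP condition whose `equilibrium` is the
#'   LP prestress steady state (with the scaled, fixed CHIP pool).
#' @export
#' @examples
#' ep <- hsr_model()
#' lp <- apply_senescence(ep)
apply_senescence <- function(model, log2fc_chip = -0.7799,
                             log2fc_k = -0.4873) {
  stopifnot(inherits(model, "hsr_model"))
  if (is.null(model$equilibrium))
    stop("model must be equilibrated before perturbation")
  p <- model$params
  p$k <- p$k * log2fc_to_factor(log2fc_k)
  class(p) <- "hsr_params"
  C_lp <- model$equilibrium[["C"]] * log2fc_to_factor(log2fc_chip)
  eq_lp <- steady_state_fixed_C(p, C_lp, model$equilibrium)
  structure(list(params = p, equilibrium = eq_lp, tol = model$tol,
                 perturbation = list(log2fc_chip = log2fc_chip,
                                     log2fc_k = log2fc_k)),
            class = "hsr_model")
}

# Steady state of the 4-species system with the CHIP pool held fixed.
# Long relaxation integration followed by a damped Newton polish.
steady_state_fixed_C <- function(params, C, init) {
  p1 <- params; p1$s <- 1
  y <- as_state_vector(init)
  y[5] <- C
  h <- 0.1
  for (chunk in 1:8) {
    n <- round(5000 / h)
    out <- hsr_integrate_cpp(y, par_vector(p1), 0, n, h,
                             lag_steps = max(1L, round(params$tau / h)),
                             stress_start_idx = -1L, stress_end_idx = -1L,
                             s = 1, F_hist = y[3], stride = n,
                             titrate = FALSE)
    y_new <- as.numeric(out[nrow(out), 2:6])
    conv <- max(abs(y_new - y)) < 1e-8
    y <- y_new
    if (conv) break
  }
  g <- function(x) {
    st <- hsr_state(H = x[1], HF = params$F_tot - x[3], F = x[3],
                    M = x[2], C = C)
    hsr_derivatives(st, st, p1, stress_on = FALSE)[c("M", "H", "HF")]
  }
  x <- c(y[1], y[4], y[3])
  for (it in 1:100) {
    fx <- g(x)
    if (max(abs(fx)) < 1e-14) break
    J <- matrix(0, 3, 3)
    for (j in 1:3) {
      dx <- max(1e-8, 1e-8 * abs(x[j]))
      xp <- x; xp[j] <- x[j] + dx
      J[, j] <- (g(xp) - fx) / dx
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (all(xn > 0) && xn[3] < params$F_tot &&
          sum(g(xn)^2) <= sum(fx^2)) break
      lam <- lam / 2
      if (lam < 1e-6) { xn <- x; break }
    }
    if (identical(xn, x)) break
    x <- xn
  }
  hsr_state(H = x[1], HF = params$F_tot - x[3], F = x[3], M = x[2], C = C)
}

#' Misfolded-protein burden metrics of a trajectory
#'
#' Quantifies the proteotoxic load of a stress simulation: the period of
#' proteotoxic stress (time from stress onset until misfolded protein
#' returns within a tolerance band of its prestress equilibrium, located
#' by bisection on the dense output) and the area under the MFP excursion
#' above baseline (trapezoidal rule), plus the HSPA1A peak and its timing.
#'
#' @param traj an `hsr_trajectory` covering stress onset through recovery.
#' @param baseline_M prestress equilibrium MFP level of the condition.
#' @param tol_fraction return-to-baseline band: M is "recovered" once below
#'   `baseline_M * (1 + tol_fraction)`.
#' @return A list of class `hsr_burden`: `stress_period_h`, `mfp_auc`
#'   (concentration x hours), `peak_H`, `time_to_peak_h`, and `censored`
#'   (`TRUE` if M never returns within the window; `stress_period_h` is
#'   then a lower bound).
#' @export
mfp_burden <- function(traj, baseline_M, tol_fraction = 0.05) {
  stopifnot(is.data.frame(traj), baseline_M >= 0, tol_fraction >= 0)
  post <- traj[traj$time >= 0, ]
  thr <- baseline_M * (1 + tol_fraction)
  above <- post$M > thr
  censored <- FALSE
  if (!any(above)) {
    period <- 0
  } else {
    last <- max(which(above))
    if (last == nrow(post)) {
      censored <- TRUE
      period <- post$time[last] / 60
      warning("M never returned within tolerance; stress period is a ",
              "lower bound")
    } else {
      # bisection (linear root) between the last sample above and the next
      t1 <- post$time[last]; t2 <- post$time[last + 1]
      m1 <- post$M[last]; m2 <- post$M[last + 1]
      period <- (t1 + (thr - m1) * (t2 - t1) / (m2 - m1)) / 60
    }
  }
  ex <- pmax(post$M - baseline_M, 0)
  auc <- sum(diff(post$time) * (utils::head(ex, -1) +
                                  utils::tail(ex, -1)) / 2) / 60
  ipk <- which.max(post$H)
  structure(list(stress_period_h = period, mfp_auc = auc,
                 peak_H = post$H[ipk], time_to_peak_h = post$time[ipk] / 60,
                 censored = censored),
            class = "hsr_burden")
}

#' @export
print.hsr_burden <- function(x, ...) {
  cat(sprintf("MFP burden: stress period %.2f h%s, AUC %.4g conc*h\n",
              x$stress_period_h, if (x$censored) " (censored)" else "",
              x$mfp_auc))
  cat(sprintf("HSPA1A peak %.3f at %.2f h after stress onset\n",
              x$peak_H, x$time_to_peak_h))
  invisible(x)
}

#' Compare EP and LP misfolded-protein burden
#'
#' Runs the same stress protocol on an early-passage model and its
#' senescence-perturbed counterpart and reports burden metrics per
#' condition plus their ratios. Each condition is scored against its own
#' prestress baseline.
#'
#' @param ep_model an equilibrated EP [hsr_model()].
#' @param protocol a [stress_protocol()].
#' @param log2fc_chip,log2fc_k the senescence perturbation.
#' @param tol_fraction return-to-baseline band for [mfp_burden()].
#' @param ... passed to [integrate_hsr()].
#' @return List with elements `EP`, `LP` (each an `hsr_burden`) and
#'   `ratio` (LP/EP stress period and MFP AUC).
#' @export
senescence_burden <- function(ep_model, protocol = stress_protocol(),
                              log2fc_chip = -0.7799, log2fc_k = -0.4873,
                              tol_fraction = 0.05, ...) {
  lp_model <- apply_senescence(ep_model, log2fc_chip, log2fc_k)
  ep_tr <- simulate(ep_model, protocol = protocol, ...)
  lp_tr <- simulate(lp_model, protocol = protocol, ...)
  ep_b <- mfp_burden(ep_tr, ep_model$equilibrium[["M"]], tol_fraction)
  lp_b <- mfp_burden(lp_tr, lp_model$equilibrium[["M"]], tol_fraction)
  list(EP = ep_b, LP = lp_b,
       ratio = list(
         stress_period = lp_b$stress_period_h / ep_b$stress_period_h,
         mfp_auc = lp_b$mfp_auc / ep_b$mfp_auc))
}
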