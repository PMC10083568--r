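#' Stress protocol description
#'
#' The standard in-silico experiment: record an equilibrated baseline for
#' `pre_roll` minutes, amplify the misfolding rate by `s` for
#' `stress_duration` minutes (default 120, mirroring a 2-h heat shock),
#' then follow recovery. The default recovery window is 24 h.
#'
#' @param pre_roll minutes of equilibrated baseline recorded before stress
#'   onset (stress onset is time 0).
#' @param stress_duration minutes of stress.
#' @param recovery_duration minutes of recovery after stress end.
#' @param s stress multiplier on the misfolding rate; `NULL` uses the
#'   model's parameter value.
#' @return An object of class `stress_protocol`.
#' @export
stress_protocol <- function(pre_roll = 120, stress_duration = 120,
                            recovery_duration = 1440, s = NULL) {
  stopifnot(pre_roll >= 0, stress_duration >= 0, recovery_duration >= 0)
  if (!is.null(s)) stopifnot(s >= 1)
  structure(list(pre_roll = pre_roll, stress_duration = stress_duration,
                 recovery_duration = recovery_duration, s = s),
            class = "stress_protocol")
}

#' Titration model object
#'
#' Bundles a parameter set with its prestress equilibrium. The equilibrium
#' is found by CHIP titration (see [hsr_equilibrate()]); simulation,
#' half-life and senescence analyses all start from it.
#'
#' @param params an [hsr_params()] object.
#' @param equilibrate logical; compute the prestress equilibrium now.
#' @param tol equilibration tolerance on the derivative magnitudes.
#' @return An object of class `hsr_model` with elements `params` and
#'   `equilibrium`.
#' @export
#' @examples
#' m <- hsr_model()
#' m$equilibrium
hsr_model <- function(params = hsr_params(), equilibrate = TRUE,
                      tol = 1e-9) {
  stopifnot(inherits(params, "hsr_params"))
  eq <- if (equilibrate) hsr_equilibrate(params, tol = tol) else NULL
  structure(list(params = params, equilibrium = eq, tol = tol),
            class = "hsr_model")
}

#' @export
print.hsr_model <- function(x, ...) {
  cat("HSR titration model\n")
  print(x$params)
  if (!is.null(x$equilibrium)) {
    cat("prestress equilibrium (CHIP titrated to H/r_HC):\n")
    print(round(unclass(x$equilibrium), 6))
  }
  invisible(x)
}

#' @export
coef.hsr_model <- function(object, ...) unlist(unclass(object$params))

#' Find the prestress equilibrium by CHIP titration
#'
#' CHIP is adjusted against HSPA1A at every time point (relaxing towards
#' `H / r_HC`) while the system is integrated to a stable steady state;
#' the result is then polished by a damped Newton iteration on the reduced
#' steady-state system (with `C = H / r_HC` and `HF = F_tot - F`
#' substituted). Stability is verified through the eigenvalues of a
#' numerically differenced Jacobian.
#'
#' @param params an [hsr_params()] object.
#' @param tol tolerance: every derivative magnitude at the returned state is
#'   below `tol`, and `|C - H / r_HC| < tol`.
#' @param max_time maximum relaxation time (min) before giving up.
#' @return An [hsr_state()] at equilibrium.
#' @export
hsr_equilibrate <- function(params, tol = 1e-9, max_time = 2e5) {
  stopifnot(tol > 0)
  p1 <- params; p1$s <- 1
  y <- c(1, params$F_tot / 2, params$F_tot / 2, 0.05, 1 / params$r_HC)
  h <- 0.1
  t_done <- 0
  repeat {
    chunk <- 5000
    n <- round(chunk / h)
    out <- hsr_integrate_cpp(y, par_vector(p1), 0, n, h,
                             lag_steps = max(1L, round(params$tau / h)),
                             stress_start_idx = -1L, stress_end_idx = -1L,
                             s = 1, F_hist = y[3], stride = n, titrate = TRUE)
    y_new <- as.numeric(out[nrow(out), 2:6])
    t_done <- t_done + chunk
    drift <- max(abs(y_new - y))
    y <- y_new
    if (drift < 1e-7 || t_done >= max_time) break
  }
  polished <- tryCatch(newton_equilibrium(p1, y), error = function(e) NULL)
  if (!is.null(polished)) y <- polished
  st <- hsr_state(H = y[1], HF = y[2], F = y[3], M = y[4], C = y[5])
  dv <- hsr_derivatives(st, st, p1, stress_on = FALSE)
  resid <- max(abs(dv[c("H", "HF", "F", "M")]))
  if (resid >= tol || abs(st[["C"]] - st[["H"]] / params$r_HC) >= tol) {
    cond <- structure(class = c("hsr_nonconvergence", "error", "condition"),
                      list(message = sprintf(
                        "equilibration did not converge (residual %.3g)",
                        resid), call = sys.call(-1), residual = resid))
    stop(cond)
  }
  ev <- eigen(equilibrium_jacobian(p1, st), only.values = TRUE)$values
  if (any(Re(ev) > 1e-8))
    warning("equilibrium may be unstable (positive Jacobian eigenvalue)")
  st
}

# Newton polish on the reduced system: unknowns (H, M, F) with
# C = H/r_HC and HF = F_tot - F substituted. Damped steps, positivity kept.
newton_equilibrium <- function(params, y0) {
  g <- function(x) {
    st <- c(H = x[1], HF = params$F_tot - x[3], F = x[3], M = x[2],
            C = x[1] / params$r_HC)
    phi <- chip_partition(st[["M"]], st[["H"]], params$a_chip)
    syn <- params$k * st[["F"]] / (params$Kd + st[["F"]])
    c(params$k1 - params$k2 * st[["H"]] * st[["M"]] -
        params$k4 * st[["C"]] * phi * st[["M"]],
      syn - params$k5 * st[["C"]] * (1 - phi) * st[["H"]],
      params$k6 * st[["H"]] * st[["F"]] - params$k7 * st[["M"]] * st[["HF"]])
  }
  x <- c(y0[1], y0[4], y0[3])
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
  c(x[1], params$F_tot - x[3], x[3], x[2], x[1] / params$r_HC)
}

# Jacobian of the 4-species system (C fixed) by central differences.
equilibrium_jacobian <- function(params, st) {
  f <- function(v) {
    s <- hsr_state(H = v[1], HF = v[2], F = v[3], M = v[4], C = st[["C"]])
    hsr_derivatives(s, s, params, stress_on = FALSE)[c("H", "HF", "F", "M")]
  }
  v0 <- unclass(st)[c("H", "HF", "F", "M")]
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    dv <- max(1e-6, 1e-6 * abs(v0[j]))
    vp <- v0; vp[j] <- v0[j] + dv
    vm <- v0; vm[j] <- max(0, v0[j] - dv)
    J[, j] <- (f(vp) - f(vm)) / (vp[j] - vm[j])
  }
  J
}

#' Integrate the delay system through a stress protocol
#'
#' Runs the fixed-step RK4 method-of-steps integrator (compiled) from an
#' equilibrated state through a [stress_protocol()]. CHIP is held constant
#' at its (possibly perturbed) prestress value; history before the start of
#' the run is the constant equilibrium state. Alternatively
#' `method = "dede"` uses the adaptive [deSolve::dede()] solver, which
#' serves as an independent cross-check of the fixed-step scheme.
#'
#' @param params an [hsr_params()] object.
#' @param initial an equilibrated [hsr_state()].
#' @param protocol a [stress_protocol()].
#' @param h integration step (min); internally adjusted so that the delay
#'   is an exact multiple of the step.
#' @param sample_dt output sampling interval (min).
#' @param method `"rk4"` (fixed-step method of steps) or `"dede"`.
#' @param atol,rtol tolerances for the `"dede"` method.
#' @return An object of class `hsr_trajectory`: a data frame with columns
#'   `time` (min; 0 = stress onset), `H`, `HF`, `F`, `M`, `C`,
#'   `stress_on`, carrying the parameters, protocol and solver settings as
#'   attributes.
#' @export
integrate_hsr <- function(params, initial, protocol = stress_protocol(),
                          h = 0.01, sample_dt = 1, method = c("rk4", "dede"),
                          atol = 1e-9, rtol = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(params, "hsr_params"), inherits(initial, "hsr_state"))
  s <- if (is.null(protocol$s)) params$s else protocol$s
  t0 <- -protocol$pre_roll
  t_end <- protocol$stress_duration + protocol$recovery_duration
  if (method == "rk4") {
    h <- params$tau / max(1, round(params$tau / h))
    n_steps <- ceiling((t_end - t0) / h - 1e-9)
    stride <- max(1L, round(sample_dt / h))
    out <- hsr_integrate_cpp(as_state_vector(initial), par_vector(params),
                             t0, as.integer(n_steps), h,
                             lag_steps = as.integer(round(params$tau / h)),
                             stress_start_idx = as.integer(round(-t0 / h)),
                             stress_end_idx = as.integer(
                               round((protocol$stress_duration - t0) / h)),
                             s = s, F_hist = initial[["F"]],
                             stride = as.integer(stride), titrate = FALSE)
    df <- as.data.frame(out)
  } else {
    df <- integrate_dede(params, initial, protocol, s, t0, t_end,
                         sample_dt, atol, rtol)
  }
  structure(df, class = c("hsr_trajectory", "data.frame"),
            params = params, protocol = protocol,
            solver = list(method = method, h = h, sample_dt = sample_dt,
                          atol = atol, rtol = rtol, s = s))
}

integrate_dede <- function(params, initial, protocol, s, t0, t_end,
                           sample_dt, atol, rtol) {
  params$s <- s
  y0 <- as_state_vector(initial)
  Feq <- initial[["F"]]
  rhs <- function(t, y, p) {
    Fd <- if (t - params$tau < t0) Feq else deSolve::lagvalue(t - params$tau, 3)
    st <- hsr_state(H = max(y[1], 0), HF = max(y[2], 0), F = max(y[3], 0),
                    M = max(y[4], 0), C = max(y[5], 0))
    del <- st; del[["F"]] <- max(Fd, 0)
    on <- t >= 0 && t < protocol$stress_duration
    list(as.numeric(hsr_derivatives(st, del, params, stress_on = on)))
  }
  times <- seq(t0, t_end, by = sample_dt)
  out <- deSolve::dede(y0, times, function(t, y, parms) rhs(t, y, parms),
                       parms = NULL, atol = atol, rtol = rtol,
                       control = list(mxhist = 1e5))
  df <- as.data.frame(out)
  names(df) <- c("time", "H", "HF", "F", "M", "C")
  df$stress_on <- as.numeric(df$time >= 0 & df$time < protocol$stress_duration)
  df
}

#' Simulate the model through a stress protocol
#'
#' `simulate()` on an [hsr_model()] integrates the delay system from the
#' stored prestress equilibrium through the given protocol.
#'
#' @param object an [hsr_model()].
#' @param nsim number of trajectories (the model is deterministic; values
#'   above 1 return a list of identical runs).
#' @param seed ignored (deterministic model); kept for generic consistency.
#' @param protocol a [stress_protocol()].
#' @param ... passed to [integrate_hsr()].
#' @return An `hsr_trajectory` (or list of them if `nsim > 1`).
#' @export
simulate.hsr_model <- function(object, nsim = 1, seed = NULL,
                               protocol = stress_protocol(), ...) {
  if (is.null(object$equilibrium))
    stop("model has no equilibrium; construct with equilibrate = TRUE")
  one <- function() integrate_hsr(object$params, object$equilibrium,
                                  protocol, ...)
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @export
plot.hsr_trajectory <- function(x, species = c("H", "F", "M"), ...) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  th <- x$time / 60
  graphics::matplot(th, as.matrix(x[, species, drop = FALSE]), type = "l",
                    lty = 1, xlab = "time since stress onset (h)",
                    ylab = "relative concentration", ...)
  win <- range(th[x$stress_on > 0])
  if (all(is.finite(win)))
    graphics::abline(v = win, col = "grey60", lty = 3)
  graphics::legend("topright", legend = species, col = seq_along(species),
                   lty = 1, bty = "n")
  invisible(x)
}

#' HSPA1A half-life after synthesis switch-off
#'
#' Sets the maximal synthesis rate `k` to zero at time 0 (from the
#' prestress equilibrium) and returns the first time at which free HSPA1A
#' falls to half its equilibrium value, located by bracketing on the dense
#' output followed by local interpolation.
#'
#' @param model an [hsr_model()].
#' @param horizon maximum time (min) to search.
#' @param h integration step (min).
#' @return Half-life in minutes, or `NA` (with a warning) if the level
#'   never halves within the horizon.
#' @export
#' @examples
#' half_life(hsr_model())
half_life <- function(model, horizon = 2000, h = 0.05) {
  stopifnot(inherits(model, "hsr_model"))
  p0 <- model$params
  p0$k <- 0
  proto <- stress_protocol(pre_roll = 0, stress_duration = 0,
                           recovery_duration = horizon, s = 1)
  tr <- integrate_hsr(p0, model$equilibrium, proto, h = h,
                      sample_dt = max(h, 0.25))
  target <- model$equilibrium[["H"]] / 2
  below <- which(tr$H <= target)
  if (!length(below)) {
    warning("HSPA1A never halved within the horizon")
    return(NA_real_)
  }
  i <- below[1]
  if (i == 1) return(tr$time[1])
  t1 <- tr$time[i - 1]; t2 <- tr$time[i]
  h1 <- tr$H[i - 1]; h2 <- tr$H[i]
  t1 + (target - h1) * (t2 - t1) / (h2 - h1)
}

#' Parameter sensitivity sweep
#'
#' Re-runs the standard stress protocol with one parameter scaled by each
#' of a set of factors, re-equilibrating per factor, and tabulates summary
#' metrics of the response (peak HSPA1A, time to peak, misfolded-protein
#' persistence and area under the MFP excursion).
#'
#' @param model an [hsr_model()].
#' @param param name of an [hsr_params()] field.
#' @param factors positive multipliers applied to the parameter.
#' @param protocol a [stress_protocol()].
#' @param ... passed to [integrate_hsr()].
#' @return Data frame with one row per factor; failed runs carry `NA`
#'   metrics and the error message.
#' @export
sensitivity_sweep <- function(model, param, factors,
                              protocol = stress_protocol(), ...) {
  stopifnot(param %in% names(model$params), all(factors > 0))
  rows <- lapply(factors, function(f) {
    res <- tryCatch({
      p <- model$params
      p[[param]] <- p[[param]] * f
      class(p) <- "hsr_params"
      validate_hsr_params(p)
      eq <- hsr_equilibrate(p, tol = model$tol)
      tr <- integrate_hsr(p, eq, protocol, ...)
      b <- mfp_burden(tr, baseline_M = eq[["M"]])
      data.frame(factor = f, peak_H = b$peak_H,
                 time_to_peak_h = b$time_to_peak_h,
                 stress_period_h = b$stress_period_h,
                 mfp_auc = b$mfp_auc, error = NA_character_)
    }, error = function(e) {
      data.frame(factor = f, peak_H = NA_real_, time_to_peak_h = NA_real_,
                 stress_period_h = NA_real_, mfp_auc = NA_real_,
                 error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "param") <- param
  out
}

#' Write or read a trajectory as CSV (with optional provenance sidecar)
#'
#' @param traj an `hsr_trajectory`.
#' @param path CSV path.
#' @param provenance optional YAML path; receives parameters, protocol and
#'   solver settings.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a data frame.
#' @export
write_trajectory_csv <- function(traj, path, provenance = NULL) {
  utils::write.csv(as.data.frame(traj)[, c("time", "H", "HF", "F", "M",
                                           "C", "stress_on")],
                   path, row.names = FALSE)
  if (!is.null(provenance)) {
    yaml::write_yaml(list(
      params = lapply(unclass(attr(traj, "params")), as.numeric),
      protocol = lapply(unclass(attr(traj, "protocol")),
                        function(x) if (is.null(x)) NA else as.numeric(x)),
      solver = attr(traj, "solver")), provenance, precision = 15)
  }
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path)
}
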