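#' Fit the free model parameters to an HSPA1A time course
#'
#' Optimises the six free parameters (`k`, `Kd`, `k2`, `k4`, `k5`, `k7`)
#' against a relative HSPA1A protein time course (prestress mean normalised
#' to 1), by a two-stage search: a coarse scan over orders of magnitude per
#' free parameter (a seeded random sample of the factorial grid, plus any
#' explicitly supplied candidates and the starting values), followed by
#' derivative-free Nelder-Mead refinement in log-parameter space from the
#' best coarse points. Every candidate is re-equilibrated so that its own
#' prestress level defines the normalisation, and scored by mean squared
#' difference between the simulated relative HSPA1A curve and the
#' replicate-mean data at the observed times. The search is deterministic
#' for a given `seed`.
#'
#' @param data a time-course data frame with columns `time_min` (relative
#'   to stress onset; negative = prestress), `replicate` and `value`
#'   (relative level). Extra columns (`condition`, `analyte`) are ignored.
#' @param params0 starting [hsr_params()]; fixed parameters are taken from
#'   here.
#' @param grid named list (per free parameter) of candidate values spanning
#'   the orders of magnitude to scan; `NULL` skips the coarse stage and
#'   refines from `params0` only. `"default"` scans
#'   `params0 * 10^(-2:2)` per parameter.
#' @param n_grid number of factorial-grid combinations sampled.
#' @param candidates optional data frame of explicit free-parameter
#'   combinations (one row per candidate) always scored in the coarse
#'   stage, e.g. externally proposed starting points.
#' @param free subset of [hsr_free_params()] to optimise; the rest stay at
#'   `params0`. Useful when external information fixes some rates, and for
#'   recovery experiments on identifiable subsets.
#' @param n_local number of best coarse points refined locally.
#' @param protocol the [stress_protocol()] the data were collected under.
#' @param h integration step used during fitting (min).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param seed integer seed for the coarse-stage sampling.
#' @return An object of class `hsr_fit` with elements `params` (full
#'   parameter set at the optimum), `loss`, `starts` (per-start records),
#'   `data`, `seed`. Methods: `coef()`, `print()`, `summary()`, `plot()`,
#'   `predict()`, `residuals()`.
#' @export
hsr_fit <- function(data, params0 = hsr_params(), grid = "default",
                    n_grid = 150, n_local = 3, candidates = NULL,
                    free = hsr_free_params(),
                    protocol = stress_protocol(), h = 0.5, maxit = 400,
                    seed = 1) {
  stopifnot(all(c("time_min", "value") %in% names(data)),
            all(free %in% hsr_free_params()))
  agg <- stats::aggregate(value ~ time_min, data = data, FUN = mean)
  agg <- agg[order(agg$time_min), ]
  obs_t <- agg$time_min
  obs_v <- agg$value
  objective <- function(logpar) {
    p <- params0
    p[free] <- as.list(exp(logpar))
    class(p) <- "hsr_params"
    tryCatch({
      validate_hsr_params(p)
      eq <- hsr_equilibrate(p, tol = 1e-7)
      tr <- integrate_hsr(p, eq, protocol, h = h, sample_dt = 1)
      mod <- stats::approx(tr$time, tr$H / eq[["H"]], xout = obs_t)$y
      mean((mod - obs_v)^2)
    }, error = function(e) Inf)
  }
  set.seed(seed)
  start0 <- log(unlist(params0[free]))
  cand <- list(start0)
  if (identical(grid, "default"))
    grid <- lapply(params0[free], function(v) v * 10^(-2:2))
  if (!is.null(grid)) {
    stopifnot(setequal(names(grid), free))
    for (i in seq_len(n_grid))
      cand[[length(cand) + 1]] <-
        log(vapply(grid[free], function(v) sample(v, 1), numeric(1)))
  }
  if (!is.null(candidates)) {
    stopifnot(all(free %in% names(candidates)))
    for (i in seq_len(nrow(candidates)))
      cand[[length(cand) + 1]] <- log(unlist(candidates[i, free]))
  }
  scores <- vapply(cand, objective, numeric(1))
  if (all(!is.finite(scores))) {
    cond <- structure(class = c("hsr_fit_failure", "error", "condition"),
                      list(message = "all starts failed integration",
                           call = sys.call(-1)))
    stop(cond)
  }
  ord <- order(scores)
  starts <- ord[seq_len(min(n_local, sum(is.finite(scores))))]
  records <- list()
  best_par <- cand[[ord[1]]]
  best_loss <- scores[ord[1]]
  for (i in starts) {
    opt <- stats::optim(cand[[i]], objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    records[[length(records) + 1]] <-
      data.frame(start = i, start_loss = scores[i], final_loss = opt$value,
                 convergence = opt$convergence)
    if (opt$value < best_loss) {
      best_loss <- opt$value
      best_par <- opt$par
    }
  }
  pfit <- params0
  pfit[free] <- as.list(exp(best_par))
  class(pfit) <- "hsr_params"
  flat <- vapply(free, function(nm) {
    up <- best_par; up[nm] <- up[nm] + log(1.05)
    dn <- best_par; dn[nm] <- dn[nm] - log(1.05)
    abs(objective(up) - best_loss) + abs(objective(dn) - best_loss) <
      1e-12 * max(best_loss, 1e-12)
  }, logical(1))
  structure(list(params = pfit, loss = best_loss,
                 starts = do.call(rbind, records),
                 free = free, flat_directions = free[flat],
                 data = data, protocol = protocol, h = h, seed = seed),
            class = "hsr_fit")
}

#' @export
coef.hsr_fit <- function(object, ...) unlist(object$params[object$free])

#' @export
print.hsr_fit <- function(x, ...) {
  cat("HSR titration model fit\n")
  cat("  loss (MSE):", format(x$loss, digits = 6), "\n")
  cat("  fitted parameters:\n")
  print(round(coef(x), 6))
  if (length(x$flat_directions))
    cat("  note: objective locally flat in:",
        paste(x$flat_directions, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hsr_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, rmse = sqrt(mean(res^2)),
                 n_obs = length(res)), class = "summary.hsr_fit")
}

#' @export
print.summary.hsr_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RMSE %.4g over %d mean observations\n", x$rmse, x$n_obs))
  invisible(x)
}

#' @export
predict.hsr_fit <- function(object, times = NULL, ...) {
  eq <- hsr_equilibrate(object$params, tol = 1e-7)
  tr <- integrate_hsr(object$params, eq, object$protocol, h = object$h,
                      sample_dt = 1)
  if (is.null(times)) times <- sort(unique(object$data$time_min))
  data.frame(time_min = times,
             value = stats::approx(tr$time, tr$H / eq[["H"]],
                                   xout = times)$y)
}

#' @export
residuals.hsr_fit <- function(object, ...) {
  agg <- stats::aggregate(value ~ time_min, data = object$data, FUN = mean)
  pred <- predict(object, times = agg$time_min)
  agg$value - pred$value
}

#' @export
plot.hsr_fit <- function(x, ...) {
  agg <- stats::aggregate(value ~ time_min, data = x$data, FUN = mean)
  pred <- predict(x, times = seq(min(agg$time_min), max(agg$time_min),
                                 by = 10))
  graphics::plot(agg$time_min / 60, agg$value,
                 xlab = "time since stress onset (h)",
                 ylab = "relative HSPA1A", ...)
  graphics::lines(pred$time_min / 60, pred$value, col = 2)
  graphics::legend("topright", c("data (replicate mean)", "model"),
                   pch = c(1, NA), lty = c(NA, 1), col = c(1, 2),
                   bty = "n")
  invisible(x)
}

#' Scale modelled active HSF1 onto a transcript curve
#'
#' Modelled active HSF1 tracks the transcriptional programme; a single
#' least-squares scalar maps it onto measured transcript levels:
#' `alpha = sum(F * mRNA) / sum(F^2)`, with the resulting R-squared as the
#' goodness of fit.
#'
#' @param model_F numeric vector of modelled active-HSF1 values.
#' @param transcript numeric vector of transcript levels at the same times.
#' @return List with `alpha` and `r_squared`.
#' @export
#' @examples
#' hsf1_transcript_scale(c(1, 2, 3), 3.7 * c(1, 2, 3))
hsf1_transcript_scale <- function(model_F, transcript) {
  stopifnot(length(model_F) == length(transcript))
  ss <- sum(model_F^2)
  if (ss == 0) {
    cond <- structure(class = c("hsr_undefined_scale", "error", "condition"),
                      list(message = "model series is identically zero",
                           call = sys.call(-1)))
    stop(cond)
  }
  alpha <- sum(model_F * transcript) / ss
  resid <- transcript - alpha * model_F
  sst <- sum((transcript - mean(transcript))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(resid^2) / sst
  list(alpha = alpha, r_squared = r2)
}

#' Write a fit result to YAML
#'
#' Serialises the fitted parameter values, loss, free-parameter set, any
#' flat (locally non-identifiable) directions, and the seed.
#'
#' @param fit an `hsr_fit` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_yaml <- function(fit, path) {
  stopifnot(inherits(fit, "hsr_fit"))
  yaml::write_yaml(list(
    params = lapply(unclass(fit$params), as.numeric),
    free = fit$free,
    loss = as.numeric(fit$loss),
    flat_directions = fit$flat_directions,
    seed = fit$seed), path, precision = 15)
  invisible(path)
}
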