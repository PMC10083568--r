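#' Module-level response test on a fold-change table
#'
#' Tests, per chaperome module, whether the module's proteins changed in
#' abundance. To avoid pseudo-replication the observational unit is the
#' replicate (donor): per replicate, the module mean log2 fold-change is
#' computed over the module's proteins, and the module is tested by a
#' one-way ANOVA of those per-donor means against zero (equivalently the
#' one-sample F/t test at a single group). Modules with fewer than
#' `min_proteins` scored proteins are excluded with a warning.
#'
#' @param table data frame with columns `protein`, `group` (module label)
#'   and replicate columns `rep1`, `rep2`, ... of log2 fold-changes.
#' @param min_proteins minimum proteins per tested module.
#' @return Data frame: `group`, `n_proteins`, `n_replicates`,
#'   `mean_log2fc`, `p_value`.
#' @export
module_response_test <- function(table, min_proteins = 3) {
  repcols <- grep("^rep", names(table), value = TRUE)
  stopifnot("group" %in% names(table), length(repcols) >= 2)
  groups <- unique(table$group)
  out <- lapply(groups, function(g) {
    sub <- table[table$group == g, repcols, drop = FALSE]
    if (nrow(sub) < min_proteins) {
      warning("module '", g, "' has fewer than ", min_proteins,
              " proteins; excluded")
      return(NULL)
    }
    donor_means <- colMeans(as.matrix(sub))
    p <- if (stats::sd(donor_means) == 0) {
      if (mean(donor_means) == 0) 1 else 0
    } else stats::t.test(donor_means, mu = 0)$p.value
    data.frame(group = g, n_proteins = nrow(sub),
               n_replicates = length(donor_means),
               mean_log2fc = mean(donor_means),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Distribution shift of a protein subset against the background
#'
#' Compares the log2 fold-change distribution of a subset (e.g. ribosomal
#' proteins) with the background (e.g. whole proteome). Gaussian curves
#' are fitted to each distribution by moment matching (the fitted maximum
#' is the sample mean); significance is a two-tailed Welch t test. Proteins
#' are summarised by their replicate-mean fold-change first. By default the
#' subset is removed from the background before testing.
#'
#' @param table fold-change table as in [module_response_test()].
#' @param subset_groups group labels forming the subset.
#' @param background_groups group labels forming the background; `NULL`
#'   means all other groups.
#' @param exclude_subset drop subset proteins from the background.
#' @return List of class `subset_shift`: `mu_subset`, `sd_subset`,
#'   `mu_background`, `sd_background`, `mean_difference`, `p_value`,
#'   `n_subset`, `n_background`.
#' @export
subset_shift_test <- function(table, subset_groups,
                              background_groups = NULL,
                              exclude_subset = TRUE) {
  repcols <- grep("^rep", names(table), value = TRUE)
  vals <- rowMeans(as.matrix(table[, repcols, drop = FALSE]))
  in_sub <- table$group %in% subset_groups
  in_bg <- if (is.null(background_groups)) !in_sub
           else table$group %in% background_groups
  if (exclude_subset) in_bg <- in_bg & !in_sub
  x <- vals[in_sub]; y <- vals[in_bg]
  if (length(x) < 10)
    warning("subset has fewer than 10 proteins; test still computed")
  tt <- stats::t.test(x, y)
  structure(list(mu_subset = mean(x), sd_subset = stats::sd(x),
                 mu_background = mean(y), sd_background = stats::sd(y),
                 mean_difference = mean(x) - mean(y),
                 p_value = tt$p.value,
                 n_subset = length(x), n_background = length(y)),
            class = "subset_shift")
}

#' @export
print.subset_shift <- function(x, ...) {
  cat(sprintf("subset mean %.4f (sd %.3f, n=%d) vs background %.4f (sd %.3f, n=%d)\n",
              x$mu_subset, x$sd_subset, x$n_subset,
              x$mu_background, x$sd_background, x$n_background))
  cat(sprintf("mean difference %.4f, two-tailed t-test p = %.3g\n",
              x$mean_difference, x$p_value))
  invisible(x)
}

#' Shift in tagged-peptide fold-changes under stress
#'
#' Distribution summary and Wilcoxon signed-rank test of paired per-peptide
#' log2 fold-changes against the zero-shift null, with the standard
#' zero-exclusion rule. A paired two-tailed t test is reported alongside
#' (the non-parametric test is primary).
#'
#' @param values numeric vector of per-peptide log2 fold-changes (already
#'   paired differences against the control state).
#' @return List of class `peptide_shift`: `median`, `iqr`, `n`,
#'   `n_nonzero`, `p_wilcoxon`, `p_ttest`, `degenerate` (all differences
#'   zero).
#' @export
tagged_peptide_shift <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  nz <- values[values != 0]
  if (!length(nz)) {
    return(structure(list(median = 0, iqr = 0, n = length(values),
                          n_nonzero = 0L, p_wilcoxon = 1, p_ttest = 1,
                          degenerate = TRUE), class = "peptide_shift"))
  }
  w <- stats::wilcox.test(nz, mu = 0, exact = length(nz) <= 50,
                          correct = TRUE)
  tt <- stats::t.test(values, mu = 0)
  structure(list(median = stats::median(values),
                 iqr = stats::IQR(values), n = length(values),
                 n_nonzero = length(nz), p_wilcoxon = w$p.value,
                 p_ttest = tt$p.value, degenerate = FALSE),
            class = "peptide_shift")
}

#' @export
print.peptide_shift <- function(x, ...) {
  cat(sprintf("median %.4f, IQR %.4f (n = %d, %d non-zero)\n",
              x$median, x$iqr, x$n, x$n_nonzero))
  cat(sprintf("Wilcoxon signed-rank p = %.3g; paired t-test p = %.3g\n",
              x$p_wilcoxon, x$p_ttest))
  invisible(x)
}

#' Recovery time of a stress-perturbed time course
#'
#' The recovery time (RT) is the first post-stress time at which the
#' series becomes statistically indistinguishable from its prestress
#' baseline and remains so for all later sampled times. Each time point is
#' compared with the pooled baseline replicates by a one-way ANOVA
#' (two-group F test); no multiplicity correction is applied, matching
#' per-timepoint testing practice. Single-replicate series fall back to a
#' threshold-crossing rule with a warning.
#'
#' @param tc time-course data frame with columns `time_min`, `replicate`,
#'   `value`.
#' @param baseline_window numeric length-2: time window (min) defining the
#'   prestress baseline (inclusive).
#' @param alpha significance level; p >= alpha counts as "returned".
#' @param tol relative tolerance for the single-replicate fallback.
#' @return List of class `recovery_time`: `rt_h` (hours since stress
#'   onset), `censored` (`TRUE` if the series never settles back;
#'   `rt_h` is then a lower bound equal to the last sampled time),
#'   `per_time` (data frame of per-timepoint p-values).
#' @export
recovery_time <- function(tc, baseline_window = c(-Inf, 0), alpha = 0.05,
                          tol = 0.05) {
  stopifnot(all(c("time_min", "value") %in% names(tc)))
  if (!"replicate" %in% names(tc)) tc$replicate <- 1L
  base <- tc$value[tc$time_min >= baseline_window[1] &
                     tc$time_min <= baseline_window[2]]
  if (!length(base)) stop("no baseline observations in the window")
  post <- tc[tc$time_min > baseline_window[2], , drop = FALSE]
  times <- sort(unique(post$time_min))
  n_rep <- min(table(post$time_min))
  if (n_rep < 2 || length(base) < 2) {
    warning("fewer than 2 replicates; falling back to threshold crossing")
    mu <- mean(base)
    means <- vapply(times, function(t0)
      mean(post$value[post$time_min == t0]), numeric(1))
    ok <- abs(means - mu) <= tol * abs(mu)
    pt <- data.frame(time_min = times, p_value = NA_real_, settled = ok)
  } else {
    pv <- vapply(times, function(t0) {
      y <- c(base, post$value[post$time_min == t0])
      g <- factor(c(rep("base", length(base)),
                    rep("t", sum(post$time_min == t0))))
      stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1]
    }, numeric(1))
    pt <- data.frame(time_min = times, p_value = pv, settled = pv >= alpha)
  }
  settled_from <- rev(cumprod(rev(pt$settled))) > 0
  if (all(pt$settled)) {
    rt <- 0           # never left baseline
    censored <- FALSE
  } else if (any(settled_from)) {
    rt <- times[which(settled_from)[1]] / 60
    censored <- FALSE
  } else {
    rt <- max(times) / 60
    censored <- TRUE
  }
  structure(list(rt_h = rt, censored = censored, per_time = pt,
                 alpha = alpha), class = "recovery_time")
}

#' @export
print.recovery_time <- function(x, ...) {
  cat(sprintf("recovery time: %.2f h%s (alpha = %g)\n", x$rt_h,
              if (x$censored) " (right-censored lower bound)" else "",
              x$alpha))
  invisible(x)
}
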