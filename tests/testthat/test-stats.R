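test_that("module response test: null input gives zero means, nothing called", {
  tab <- data.frame(protein = sprintf("P%02d", 1:12),
                    group = rep(c("HSP70", "HSP90", "CCT"), each = 4),
                    rep1 = 0, rep2 = 0, rep3 = 0, rep4 = 0)
  res <- module_response_test(tab)
  expect_equal(res$mean_log2fc, rep(0, 3))
  expect_true(all(res$p_value == 1))
})

test_that("module response test excludes undersized modules with a warning", {
  tab <- data.frame(protein = c("A", "B", "C", "D", "E"),
                    group = c(rep("big", 4), "tiny"),
                    rep1 = rnorm(5), rep2 = rnorm(5), rep3 = rnorm(5))
  expect_warning(res <- module_response_test(tab), "tiny")
  expect_equal(res$group, "big")
})

test_that("module response test type-I error is calibrated (scaled null)", {
  set.seed(101)
  n_sim <- 300
  hits <- 0
  for (i in seq_len(n_sim)) {
    tab <- data.frame(protein = sprintf("P%02d", 1:20), group = "HSP70",
                      matrix(rnorm(20 * 4, 0, 0.3), 20, 4,
                             dimnames = list(NULL, paste0("rep", 1:4))))
    hits <- hits + (module_response_test(tab)$p_value < 0.05)
  }
  expect_gt(hits / n_sim, 0.02)
  expect_lt(hits / n_sim, 0.08)
})

test_that("a planted module effect is detected with high power", {
  set.seed(202)
  detected <- vapply(1:100, function(i) {
    n <- 50
    grp <- c(rep("HSP70", 20), rep("other", 30))
    eff <- ifelse(grp == "HSP70", 0.4, 0)
    tab <- data.frame(protein = sprintf("P%02d", 1:n), group = grp,
                      matrix(rnorm(n * 4, eff, 0.2), n, 4,
                             dimnames = list(NULL, paste0("rep", 1:4))))
    res <- module_response_test(tab)
    res$p_value[res$group == "HSP70"] < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("subset shift test: null behaviour and moment-matched fits", {
  set.seed(7)
  tab <- data.frame(protein = sprintf("P%04d", 1:1000),
                    group = rep(c("ribosome", "proteome"), each = 500),
                    rep1 = rnorm(1000, 0, 0.3), rep2 = rnorm(1000, 0, 0.3))
  res <- subset_shift_test(tab, "ribosome")
  expect_lt(abs(res$mean_difference), 0.05)
  vals <- rowMeans(tab[tab$group == "ribosome", c("rep1", "rep2")])
  expect_equal(res$mu_subset, mean(vals), tolerance = 1e-6)
  expect_equal(res$sd_subset, sd(vals), tolerance = 1e-6)
})

test_that("subset shift test recovers the planted ribosomal suppression", {
  cfg <- synth_config(seed = 33)
  tab <- synth_foldchange_table(cfg)
  res <- subset_shift_test(tab, "ribosome")
  expect_lt(abs(res$mu_subset - (-0.4873)), 0.03)
  expect_lt(res$p_value, 1e-4)
})

test_that("signed-rank p-values match exact enumeration for small n", {
  set.seed(5)
  for (n in c(6, 9, 12)) {
    for (rep in 1:3) {
      x <- round(rnorm(n, 0.3, 1), 3)
      x <- x[x != 0]
      while (anyDuplicated(abs(x)) || length(x) < n) {
        x <- round(rnorm(n, 0.3, 1), 3); x <- x[x != 0]
      }
      res <- tagged_peptide_shift(x)
      expect_equal(res$p_wilcoxon, enum_signed_rank_p(x), tolerance = 1e-10)
    }
  }
})

test_that("signed-rank test degenerate and strong-shift contracts", {
  res0 <- tagged_peptide_shift(rep(0, 20))
  expect_true(res0$degenerate)
  expect_equal(res0$p_wilcoxon, 1)
  set.seed(8)
  shifted <- 0.5 + rnorm(359, 0, 0.05)
  res <- tagged_peptide_shift(shifted)
  expect_lt(res$p_wilcoxon, 1e-4)
  expect_equal(res$n, 359)
  sym <- c(-(1:10), 1:10) / 10 + rnorm(20, 0, 1e-4)
  expect_gt(tagged_peptide_shift(sym)$p_wilcoxon, 0.05)
})

test_that("recovery time: flat, generator-crossing and censored series", {
  set.seed(12)
  times <- c(-60, -30, seq(0, 1440, by = 60))
  flat <- do.call(rbind, lapply(1:3, function(r)
    data.frame(time_min = times, replicate = r,
               value = 1 + rnorm(length(times), 0, 0.01))))
  expect_equal(recovery_time(flat, baseline_window = c(-60, 0))$rt_h, 0)

  # peak at +1 h, exponential return crossing baseline noise floor ~4 h
  curve_mean <- function(t) {
    peak <- 3; tp <- 180
    ifelse(t <= 0, 1,
           ifelse(t <= tp, 1 + (peak - 1) * t / tp,
                  1 + (peak - 1) * exp(-(t - tp) / 12)))
  }
  tc <- do.call(rbind, lapply(1:4, function(r)
    data.frame(time_min = times, replicate = r,
               value = curve_mean(times) * rlnorm(length(times), 0, 0.02))))
  rt <- recovery_time(tc, baseline_window = c(-60, 0))
  expect_false(rt$censored)
  expect_gt(rt$rt_h, 2.5)
  expect_lt(rt$rt_h, 6.5)
  # invariant to uniform rescaling
  tc2 <- tc
  tc2$value <- tc2$value * 37
  expect_equal(recovery_time(tc2, baseline_window = c(-60, 0))$rt_h, rt$rt_h)

  mono <- do.call(rbind, lapply(1:3, function(r)
    data.frame(time_min = times, replicate = r,
               value = 1 + (times > 0) * (1 + times / 100) +
                 rnorm(length(times), 0, 0.01))))
  rtm <- recovery_time(mono, baseline_window = c(-60, 0))
  expect_true(rtm$censored)
  expect_equal(rtm$rt_h, max(times) / 60)
})

test_that("single-replicate series falls back to threshold crossing", {
  times <- c(-60, 0, 60, 120, 180)
  tc <- data.frame(time_min = times, replicate = 1,
                   value = c(1, 1, 2, 1.5, 1.01))
  expect_warning(rt <- recovery_time(tc, baseline_window = c(-60, 0)),
                 "threshold")
  expect_equal(rt$rt_h, 3)
})
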