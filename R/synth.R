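#' Configuration of the synthetic-data generators
#'
#' Groups the parameters of the three generators: immunofluorescence-like
#' time courses, module-structured fold-change tables, and planted-partition
#' PPI benchmark graphs. The time-course defaults emulate the measured
#' HSPA1A dynamics: baseline 1, rise during the 2-h stress, peak 4 h into
#' recovery at twice baseline, exponential-like return, with the
#' late-passage variant delayed by ~1 h and peaking at 63% of the
#' early-passage maximum; replicate noise is multiplicative lognormal.
#' Fold-change tables have Gaussian replicate noise around per-module
#' effects and include a designated ribosome subset whose default planted
#' shift is -0.4873 (the measured ribosomal-protein mean). Graphs are
#' planted-partition samples with weights in the high-confidence band.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param baseline prestress level of the time course.
#' @param rise_lag_min delay from stress onset to the start of the rise
#'   (EP); the LP rise is delayed by `lp_extra_lag_min` more.
#' @param peak_time_min time of the noiseless peak, from stress onset
#'   (default 360 = 4 h into recovery after a 120-min stress).
#' @param peak_fold peak/baseline ratio of the EP curve.
#' @param lp_peak_ratio LP peak amplitude relative to EP (0.63).
#' @param lp_extra_lag_min extra onset delay of the LP curve (min).
#' @param decay_constant_min time constant of the post-peak return (min).
#' @param noise_cv coefficient of variation of the lognormal replicate
#'   noise.
#' @param n_replicates replicates per time point.
#' @param times_min sampling times (min, stress onset = 0).
#' @param n_proteins,module_sizes,module_effects,fc_sd,fc_replicates
#'   fold-change table shape: total proteins, named module sizes, named
#'   per-module effects (unnamed modules get 0), replicate noise sd,
#'   replicate count. Proteins beyond the named modules form the
#'   background group `"proteome"`.
#' @param ribosome_size,ribosome_effect size and planted mean shift of the
#'   designated `"ribosome"` subset.
#' @param n_blocks,block_size,p_in,p_out,weight_band planted-partition
#'   graph shape: number of blocks, nodes per block, within- and
#'   between-block edge probabilities, and the weight band edges are
#'   drawn from.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         baseline = 1, rise_lag_min = 30,
                         peak_time_min = 360, peak_fold = 2,
                         lp_peak_ratio = 0.63, lp_extra_lag_min = 60,
                         decay_constant_min = 480,
                         noise_cv = 0.05, n_replicates = 3,
                         times_min = c(-60, 0, 60, 120, 180, 240, 300,
                                       360, 480, 600, 840, 1080, 1560),
                         n_proteins = 400,
                         module_sizes = c(HSP70 = 20, HSP90 = 15,
                                          CCT = 10, ER = 15, OSR = 5),
                         module_effects = c(HSP70 = 0),
                         fc_sd = 0.2, fc_replicates = 4,
                         ribosome_size = 77, ribosome_effect = -0.4873,
                         n_blocks = 5, block_size = 30,
                         p_in = 0.6, p_out = 0.02,
                         weight_band = c(0.90, 1.00)) {
  cfg <- list(seed = seed, baseline = baseline,
              rise_lag_min = rise_lag_min, peak_time_min = peak_time_min,
              peak_fold = peak_fold, lp_peak_ratio = lp_peak_ratio,
              lp_extra_lag_min = lp_extra_lag_min,
              decay_constant_min = decay_constant_min,
              noise_cv = noise_cv, n_replicates = n_replicates,
              times_min = times_min, n_proteins = n_proteins,
              module_sizes = module_sizes, module_effects = module_effects,
              fc_sd = fc_sd, fc_replicates = fc_replicates,
              ribosome_size = ribosome_size,
              ribosome_effect = ribosome_effect,
              n_blocks = n_blocks, block_size = block_size,
              p_in = p_in, p_out = p_out, weight_band = weight_band)
  stopifnot(cfg$noise_cv >= 0, cfg$fc_sd >= 0, cfg$n_replicates >= 1,
            cfg$p_in >= 0, cfg$p_in <= 1, cfg$p_out >= 0, cfg$p_out <= 1,
            cfg$p_in > cfg$p_out,
            sum(cfg$module_sizes) + cfg$ribosome_size <= cfg$n_proteins)
  structure(cfg, class = "synth_config")
}

# Noiseless response shape: flat baseline, then a gamma-like pulse
# (continuous, peaking exactly at peak time, exponential-like tail).
synth_curve <- function(t, baseline, onset, peak_time, amplitude,
                        decay_constant) {
  shape <- rep(0, length(t))
  up <- t > onset
  x <- (t[up] - onset) / (peak_time - onset)
  p <- max(1.5, (peak_time - onset) / decay_constant * 4)
  shape[up] <- x^p * exp(p * (1 - x))
  baseline + amplitude * shape
}

#' Generate an immunofluorescence-like HSPA1A time course
#'
#' @param cfg a [synth_config()].
#' @param condition `"EP"` or `"LP"`.
#' @param analyte analyte label recorded in the output.
#' @return Data frame with columns `time_min`, `condition`, `replicate`,
#'   `analyte`, `value`. Deterministic per `cfg$seed`.
#' @export
#' @examples
#' tc <- synth_timecourse(synth_config(seed = 7), "EP")
#' head(tc)
synth_timecourse <- function(cfg, condition = c("EP", "LP"),
                             analyte = "HSPA1A_protein") {
  condition <- match.arg(condition)
  set.seed(cfg$seed + ifelse(condition == "EP", 0L, 1000L))
  onset <- cfg$rise_lag_min +
    if (condition == "LP") cfg$lp_extra_lag_min else 0
  amp <- cfg$baseline * (cfg$peak_fold - 1) *
    if (condition == "LP") cfg$lp_peak_ratio else 1
  peak_t <- cfg$peak_time_min +
    if (condition == "LP") cfg$lp_extra_lag_min else 0
  mu <- synth_curve(cfg$times_min, cfg$baseline, onset, peak_t, amp,
                    cfg$decay_constant_min)
  rows <- expand.grid(time_min = cfg$times_min,
                      replicate = seq_len(cfg$n_replicates))
  mu_all <- mu[match(rows$time_min, cfg$times_min)]
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- stats::rlnorm(nrow(rows), -sdlog^2 / 2, sdlog)
  } else noise <- 1
  data.frame(time_min = rows$time_min, condition = condition,
             replicate = rows$replicate, analyte = analyte,
             value = mu_all * noise, stringsAsFactors = FALSE)
}

#' Generate a module-structured fold-change table
#'
#' Per-protein true effect equals its module's effect (0 for the
#' background `"proteome"` group); replicate values add Gaussian noise.
#' Includes the designated `"ribosome"` subset for shift testing.
#'
#' @param cfg a [synth_config()].
#' @return Data frame: `protein`, `group`, `contrast`, `rep1..repN`, plus
#'   attribute `true_effects` (named per group).
#' @export
synth_foldchange_table <- function(cfg) {
  set.seed(cfg$seed + 2000L)
  sizes <- c(cfg$module_sizes, ribosome = cfg$ribosome_size)
  n_bg <- cfg$n_proteins - sum(sizes)
  groups <- c(rep(names(sizes), sizes), rep("proteome", n_bg))
  effects <- stats::setNames(rep(0, length(sizes) + 1),
                             c(names(sizes), "proteome"))
  effects[names(cfg$module_effects)] <- cfg$module_effects
  effects["ribosome"] <- cfg$ribosome_effect
  prot <- sprintf("P%04d", seq_along(groups))
  reps <- matrix(stats::rnorm(length(groups) * cfg$fc_replicates,
                              mean = effects[groups], sd = cfg$fc_sd),
                 nrow = length(groups))
  colnames(reps) <- paste0("rep", seq_len(cfg$fc_replicates))
  out <- data.frame(protein = prot, group = groups, contrast = "LP/EP",
                    reps, stringsAsFactors = FALSE)
  attr(out, "true_effects") <- effects
  out
}

#' Generate a planted-partition weighted PPI benchmark graph
#'
#' Within-block pairs are connected with probability `p_in`, between-block
#' pairs with `p_out`; edge weights are uniform in the configured
#' high-confidence band.
#'
#' @param cfg a [synth_config()].
#' @return List with `edges` (data frame: `protein1`, `protein2`,
#'   `combined_score`) and `labels` (named integer vector of planted block
#'   memberships).
#' @export
synth_ppi_graph <- function(cfg) {
  set.seed(cfg$seed + 3000L)
  n <- cfg$n_blocks * cfg$block_size
  block <- rep(seq_len(cfg$n_blocks), each = cfg$block_size)
  name <- sprintf("N%03d", seq_len(n))
  pairs <- utils::combn(n, 2)
  same <- block[pairs[1, ]] == block[pairs[2, ]]
  prob <- ifelse(same, cfg$p_in, cfg$p_out)
  keep <- stats::runif(ncol(pairs)) < prob
  w <- stats::runif(sum(keep), cfg$weight_band[1], cfg$weight_band[2])
  edges <- data.frame(protein1 = name[pairs[1, keep]],
                      protein2 = name[pairs[2, keep]],
                      combined_score = w, stringsAsFactors = FALSE)
  list(edges = edges, labels = stats::setNames(block, name))
}

#' Write a time course / fold-change table in the package CSV dialects
#'
#' `write_timecourse_csv()` and `write_foldchange_csv()` write the exact
#' dialects that [hsr_fit()], [module_response_test()] and friends read;
#' `write_edges_tsv()` writes the STRING-style edge list consumed by
#' [read_chaperome_graph()].
#'
#' @param x the object to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
write_foldchange_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
write_edges_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) utils::read.csv(path)

#' @rdname write_timecourse_csv
#' @export
read_foldchange_csv <- function(path) utils::read.csv(path)
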