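# Shared fixtures built in code.

# Random non-negative model states for property-style loops.
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    hsr_state(H = runif(1, 0, 5), HF = runif(1, 0, 0.1),
              F = runif(1, 0, 0.1), M = runif(1, 0, 10),
              C = runif(1, 0, 1))
  })
}

# A well-conditioned, non-stiff parameter set for fitting experiments:
# moderate stress, all six free parameters visibly shaping the observable
# HSPA1A curve. Not the calibrated baseline.
fit_test_params <- function() {
  hsr_params(k = 0.02, Kd = 0.02, k2 = 0.004, k4 = 0.02, k5 = 0.06,
             k7 = 1, k1 = 3e-4, k6 = 1, tau = 180, F_tot = 1,
             r_HC = 5, a_chip = 10, s = 20)
}

# Short protocol to keep integration cheap in unit tests.
short_protocol <- function(s = NULL)
  stress_protocol(pre_roll = 30, stress_duration = 120,
                  recovery_duration = 720, s = s)

# Exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# assignments (no ties, no zeros). Independent oracle for small n.
enum_signed_rank_p <- function(x) {
  stopifnot(all(x != 0), !anyDuplicated(abs(x)))
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}
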