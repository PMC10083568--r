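# Baseline (calibrated) parameter set. Concentrations are normalised so the
# prestress equilibrium has H = 1; time is in minutes. k5 is calibrated to
# the 100-min synthesis-switch-off half-life and s to the 10.3-h period of
# proteotoxic stress under the standard 120-min stress protocol; k and k1
# pin the prestress equilibrium at H = 1 with the baseline misfolded
# fraction. See the methods vignette for the calibration priorities and
# the provenance of each value.
.hsr_defaults <- list(
  k      = 0.0140879114826,
  Kd     = 8.20173462e-05,
  k2     = 0.004540854025,
  k4     = 0.03678401302,
  k5     = 0.0508821810096,
  k7     = 0.3432771518,
  k1     = 0.0001412485717,
  k6     = 14.85070692,
  tau    = 180,
  F_tot  = 0.192925914,
  r_HC   = 5,
  a_chip = 14.1018763,
  s      = 81094.5455
)
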