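# Independent oracles: plain-arithmetic evaluations of the diagnostic
# equations, written without the package's unit plumbing so that tests
# compare two separate code paths.

# Table-2 constants, spelled out locally on purpose.
.ORC <- list(
  beta_loglin = -0.1345, alpha_T = 0.1, beta_T = 1.1e-6, D_T = 2.75,
  K41 = 2e10, K42 = 2e8, alpha_31 = 0.026, beta_31 = 8e-6,
  K_M1 = 5e-7, K30 = 2e9, TBG = 3e-7, TBPA = 4.5e-6
)

# GD by direct arithmetic, everything in mol/L / mol/s
oracle_gd <- function(ft4_pmol, ft3_pmol, tbg = .ORC$TBG) {
  ft4 <- ft4_pmol * 1e-12
  ft3 <- ft3_pmol * 1e-12
  gd <- .ORC$beta_31 * (.ORC$K_M1 + ft4) * (1 + .ORC$K30 * tbg) * ft3 /
    (.ORC$alpha_31 * ft4)
  gd * 1e9  # nmol/s
}

# GT by direct arithmetic
oracle_gt <- function(tsh, ft4_pmol, tbg = .ORC$TBG, tbpa = .ORC$TBPA) {
  ft4 <- ft4_pmol * 1e-12
  gt <- .ORC$beta_T * (.ORC$D_T + tsh) * (1 + .ORC$K41 * tbg + .ORC$K42 * tbpa) *
    ft4 / (.ORC$alpha_T * tsh)
  gt * 1e12  # pmol/s
}

# forward thyroid transfer (inverse of oracle_gt), by direct arithmetic
oracle_thyroid_ft4 <- function(tsh, gt_pmol, tbg = .ORC$TBG, tbpa = .ORC$TBPA) {
  .ORC$alpha_T * gt_pmol * tsh /
    (.ORC$beta_T * (.ORC$D_T + tsh) * (1 + .ORC$K41 * tbg + .ORC$K42 * tbpa))
}

# forward peripheral transfer (inverse of oracle_gd)
oracle_peripheral_ft3 <- function(ft4_pmol, gd_nmol, tbg = .ORC$TBG) {
  ft4 <- ft4_pmol * 1e-12
  ft3 <- .ORC$alpha_31 * (gd_nmol * 1e-9) * ft4 /
    (.ORC$beta_31 * (.ORC$K_M1 + ft4) * (1 + .ORC$K30 * tbg))
  ft3 * 1e12
}

# a flat series with one exponentially decaying pulse, for detector tests
single_pulse_series <- function(onset_s = 7200, amp = 0.8, baseline = 1,
                                halflife_min = 50, hours = 6, dt = 60) {
  t_s <- seq(0, hours * 3600, by = dt)
  tsh <- rep(baseline, length(t_s))
  idx <- t_s >= onset_s
  tsh[idx] <- tsh[idx] + amp * exp(-log(2) / (halflife_min * 60) *
                                     (t_s[idx] - onset_s))
  tibble::tibble(t_s = t_s, tsh = tsh)
}
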