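# shared helpers: small bundles and normalized-curve plumbing

# reduce a bundle beam to a normalized RL curve (entrance-calibrated)
norm_curve_for <- function(bundle, nm) {
  b <- bundle$beams[[nm]]
  meas <- reduce_bundle(bundle, nm)
  mu <- relative_efficiency(
    meas$delta_rl[1], b$reference$entrance_dose * b$reference$dose[1],
    bundle$cal)
  list(norm = normalized_rl_curve(mu, meas, b$reference), mu = mu,
       meas = meas)
}

# proton-only ground truth (exact-inversion recovery studies)
proton_truth <- function(kB = 3106, rl0 = 1.0246) {
  birks_set(list(birks_params("H-1", kB, rl0, c(3, 45))))
}

# a tiny rectangular-pulse trace
pulse_trace <- function(n_win, h, b, n_bg = 25) {
  counts <- c(rep(b, n_bg), rep(b + h, n_win), rep(b, n_bg))
  rl_trace(counts, window = c(n_bg + 1, n_bg + n_win),
           pre_background = c(1, n_bg),
           post_background = c(n_bg + n_win + 1, 2 * n_bg + n_win))
}

# published-table fixture, split per (beam, depth) row group
fixture_rows <- function() {
  tab <- load_fluence_tables()
  split(tab, interaction(tab$beam, tab$depth_mm, drop = TRUE))
}
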