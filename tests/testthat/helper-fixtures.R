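# Shared fixtures, generated in code.

# Single-Gaussian R-wave template (one lead carries everything) for
# analytically tractable synthesis tests.
single_r_template <- function(a = 1, b = 0.1, theta = 0) {
  waves <- data.frame(
    lead = c(1L, 2L, 3L),
    wave = "R",
    a = c(a, 0, 0),
    b = b,
    theta = theta
  )
  bounds <- data.frame(wave = c("P", "QRS", "T"),
                       onset = c(-1.7, -0.45, 0.9),
                       offset = c(-0.9, 0.45, 2.2))
  vcg_template(waves, bounds)
}

zero_template <- function() {
  tpl <- vcg_template_preset("typical")
  tpl$waves$a <- 0
  tpl
}

# A clean 4-channel record of identical beats at a constant rate.
constant_beat_record <- function(n_beats = 40, rr = 0.5, fs = 500,
                                 template = vcg_template_preset("typical"),
                                 projection = NULL, seed = 1) {
  vcg <- synthesize_vcg(template, rep(rr, n_beats), fs = fs)
  project_to_abdominal_leads(vcg, projection = projection, seed = seed)
}

expect_tbl_names <- function(x, names) {
  expect_true(all(names %in% colnames(x)))
}
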