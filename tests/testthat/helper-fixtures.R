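# Shared fixtures: the published reference cubic and a noiseless point set
# sampled from it (least squares through >= 4 distinct points of a cubic
# reproduces it exactly, so these points are also an oracle for the fit).

printed_curve <- function() {
  calibration_curve(1685, -187.9, 1006, -2.328, od_domain = c(0, 0.65))
}

printed_coefs <- c(a = 1685, b = -187.9, c = 1006, d = -2.328)

noiseless_points <- function(n = 10, od_range = c(0.05, 0.60)) {
  nod <- seq(od_range[1], od_range[2], length.out = n)
  tibble::tibble(nod = nod, dose_cGy = od_to_dose(printed_curve(), nod))
}

# the ten-dose calibration schedule (cGy)
calibration_doses <- c(seq(50, 450, by = 50), 800)
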