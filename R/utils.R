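# round half away from zero, the convention used in the summary tables
# (base round() is half-to-even: round(-8.25, 1) would give -8.2)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# log-spaced concentration grid (mol/L)
log_grid <- function(min, max, points) {
  if (!(min > 0) || !(max > min)) stop("need 0 < min < max")
  if (points < 2) stop("need at least 2 grid points")
  10^seq(log10(min), log10(max), length.out = points)
}
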