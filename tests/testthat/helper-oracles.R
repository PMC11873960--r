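# Independent oracles used across the suite.  Each re-derives its
# quantity from first principles without calling the package's own
# solver/fitting code paths.

# scalar mass-balance residual, written out independently
oracle_balance <- function(o, o_total, probe, comp, ns_sites, ns_kd,
                           kd, n) {
  h <- o^n / (kd^n + o^n)
  ns <- if (ns_sites > 0) ns_sites * o / (ns_kd + o) else 0
  o + 2 * (probe + comp) * h + ns - o_total
}

# exhaustive bisection on [0, o_total]; 200 halvings pin the root to
# machine precision
oracle_bisect_speciation <- function(o_total, probe, comp = 0,
                                     ns_sites = 0, ns_kd = 1,
                                     kd, n = 2, iters = 200) {
  lo <- 0; hi <- o_total
  flo <- oracle_balance(lo, o_total, probe, comp, ns_sites, ns_kd, kd, n)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    fm <- oracle_balance(mid, o_total, probe, comp, ns_sites, ns_kd, kd, n)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# closed-form simple linear regression (normal equations)
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

# closed-form intersection of two log10-linear lines
oracle_crossover <- function(int_a, slope_a, int_b, slope_b) {
  10^((int_b - int_a) / (slope_a - slope_b))
}

# random valid binding setup for property sweeps
random_speciation_case <- function() {
  kd <- 10^runif(1, -9.5, -6)
  probe <- 10^runif(1, -9.5, -7)
  comp <- if (runif(1) < 0.4) 10^runif(1, -8, -5) else 0
  has_ns <- runif(1) < 0.4
  ns_bp <- if (has_ns) 10^runif(1, -4, -2) else 0
  ns_kd <- if (has_ns) 10^runif(1, -7, -5) else NA_real_
  o_total <- 10^runif(1, -9, -5.5)
  list(kd = kd, probe = probe, comp = comp, ns_bp = ns_bp,
       ns_kd = ns_kd, o_total = o_total,
       conditions = assay_conditions(probe_total = probe,
                                     competitor_total = comp,
                                     ns_bp_total = ns_bp,
                                     ns_site_size = 14,
                                     ns_kd = ns_kd, na_conc = 0.15),
       params = binding_parameters(kd = kd, phi = 1e4,
                                   r_specific = 0.08))
}

# standard 16-point synthetic design spanning 1 nM - 10 uM
mc_generator_spec <- function(kd, phi, seed,
                              noise_sd = 0.002, n_replicates = 3L) {
  generator_spec(truth = binding_parameters(kd = kd, phi = phi,
                                            r_specific = 0.08),
                 conditions = assay_conditions(probe_total = 5e-9,
                                               na_conc = 0.15),
                 design = list(min = 1e-9, max = 1e-5, points = 16,
                               spacing = "log"),
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 seed = seed)
}

default_fit_init <- function() {
  binding_parameters(kd = 1e-8, phi = 1e3, r_specific = 0.06)
}
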