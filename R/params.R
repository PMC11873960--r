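#' Binding-model parameters
#'
#' Bundle of parameters for the saturable-plus-excess anisotropy model.
#' The saturable component is a Hill isotherm with half-saturation
#' constant \code{kd} and coefficient \code{n_hill} (2 for the
#' cooperative 2:1 dimer on a palindromic site); the excess (secondary
#' complex) component contributes \code{phi} times the free titrant
#' concentration to the observed anisotropy.
#'
#' \code{kd} is the Hill half-saturation constant in mol/L, the form in
#' which salt-dependence tables report affinities.  The macroscopic 2:1
#' dissociation constant (units M^2) is \code{kd^2}; see
#' \code{\link{kd_macroscopic}}.
#'
#' @param kd half-saturation constant (mol/L); must be positive.
#' @param n_hill Hill coefficient (dimensionless, >= 1); default 2.
#' @param phi excess-binding coefficient (1/(mol/L), >= 0).
#' @param r_unbound anisotropy of the unbound probe (0 for
#'   baseline-subtracted data).
#' @param r_specific anisotropy of the specifically bound probe; must be
#'   >= \code{r_unbound}.
#' @return An object of class \code{"binding_parameters"}.
#' @examples
#' binding_parameters(kd = 3.8e-9, phi = 2.6e4, r_specific = 0.08)
#' @export
binding_parameters <- function(kd, n_hill = 2, phi = 0,
                               r_unbound = 0, r_specific = 0.08) {
  stopifnot(is.numeric(kd), length(kd) == 1L,
            is.numeric(n_hill), length(n_hill) == 1L,
            is.numeric(phi), length(phi) == 1L,
            is.numeric(r_unbound), length(r_unbound) == 1L,
            is.numeric(r_specific), length(r_specific) == 1L)
  if (!is.finite(kd) || kd <= 0) stop("'kd' must be finite and > 0")
  if (!is.finite(n_hill) || n_hill < 1) stop("'n_hill' must be >= 1")
  if (!is.finite(phi) || phi < 0) stop("'phi' must be >= 0")
  if (!is.finite(r_unbound) || !is.finite(r_specific))
    stop("anisotropy endpoints must be finite")
  if (r_specific < r_unbound)
    stop("'r_specific' must be >= 'r_unbound'")
  structure(list(kd = kd, n_hill = n_hill, phi = phi,
                 r_unbound = r_unbound, r_specific = r_specific),
            class = "binding_parameters")
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat("Binding parameters (Hill + excess-binding model)\n")
  cat(sprintf("  kd         : %.4g M   (macroscopic K_D = kd^2 = %.4g M^2)\n",
              x$kd, x$kd^2))
  cat(sprintf("  n_hill     : %g\n", x$n_hill))
  cat(sprintf("  phi        : %.4g 1/M\n", x$phi))
  cat(sprintf("  r_unbound  : %.4g\n  r_specific : %.4g\n",
              x$r_unbound, x$r_specific))
  invisible(x)
}

#' Macroscopic 2:1 dissociation constant
#'
#' Maps the Hill half-saturation constant of a 2:1 complex to the
#' macroscopic dissociation constant of the overall reaction
#' 2 O + S = S.O2, i.e. \code{kd^n_hill} (M^2 for \code{n_hill = 2}).
#'
#' @param params a \code{\link{binding_parameters}} object.
#' @return Macroscopic dissociation constant (M^\code{n_hill}).
#' @export
kd_macroscopic <- function(params) {
  stopifnot(inherits(params, "binding_parameters"))
  params$kd^params$n_hill
}

#' Assay conditions for one titration
#'
#' Solution context in which a titration was (or is to be) measured:
#' labeled-probe concentration, unlabeled competitor carrying the same
#' site, nonspecific lattice DNA, and ionic conditions.  The nonspecific
#' lattice is modeled as independent non-overlapping sites of
#' \code{ns_site_size} base pairs, so the site concentration is
#' \code{ns_bp_total / ns_site_size}.
#'
#' @param probe_total labeled-probe site concentration (mol/L).
#' @param competitor_total unlabeled cognate-site concentration (mol/L).
#' @param ns_bp_total nonspecific DNA in base pairs (mol/L bp).
#' @param ns_site_size base pairs occluded per bound dimer on the
#'   nonspecific lattice (default 14, the dimer footprint on a
#'   MORE-length duplex).
#' @param ns_kd nonspecific dissociation constant per lattice site
#'   (mol/L); required whenever \code{ns_bp_total > 0}.
#' @param na_conc Na+ concentration (mol/L).
#' @param temperature temperature in K (default 298.15).
#' @return An object of class \code{"assay_conditions"}.
#' @examples
#' # 5 nM probe at 0.15 M Na+ with an excess of poly[d(I-C)]
#' assay_conditions(probe_total = 5e-9, ns_bp_total = 7e-3,
#'                  ns_kd = 1e-6, na_conc = 0.15)
#' @export
assay_conditions <- function(probe_total, competitor_total = 0,
                             ns_bp_total = 0, ns_site_size = 14,
                             ns_kd = NA_real_, na_conc = 0.15,
                             temperature = 298.15) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L)
      stop(sprintf("'%s' must be a single number", nm))
    x
  }
  probe_total <- num1(probe_total, "probe_total")
  competitor_total <- num1(competitor_total, "competitor_total")
  ns_bp_total <- num1(ns_bp_total, "ns_bp_total")
  ns_site_size <- num1(ns_site_size, "ns_site_size")
  na_conc <- num1(na_conc, "na_conc")
  temperature <- num1(temperature, "temperature")
  if (probe_total < 0 || competitor_total < 0 || ns_bp_total < 0)
    stop("concentrations must be >= 0")
  if (ns_site_size < 1) stop("'ns_site_size' must be >= 1")
  if (!is.finite(na_conc) || na_conc <= 0) stop("'na_conc' must be > 0")
  if (temperature <= 0) stop("'temperature' must be > 0 K")
  if (ns_bp_total > 0 && (!is.finite(ns_kd) || ns_kd <= 0))
    stop("'ns_kd' must be supplied (> 0) when 'ns_bp_total' > 0")
  structure(list(probe_total = probe_total,
                 competitor_total = competitor_total,
                 ns_bp_total = ns_bp_total,
                 ns_site_size = ns_site_size,
                 ns_kd = ns_kd,
                 na_conc = na_conc,
                 temperature = temperature),
            class = "assay_conditions")
}

#' @export
print.assay_conditions <- function(x, ...) {
  cat("Assay conditions\n")
  cat(sprintf("  probe_total      : %.4g M\n", x$probe_total))
  cat(sprintf("  competitor_total : %.4g M\n", x$competitor_total))
  cat(sprintf("  ns_bp_total      : %.4g M bp (site size %g bp -> %.4g M sites)\n",
              x$ns_bp_total, x$ns_site_size, ns_site_conc(x)))
  if (x$ns_bp_total > 0)
    cat(sprintf("  ns_kd            : %.4g M\n", x$ns_kd))
  cat(sprintf("  na_conc          : %.4g M\n", x$na_conc))
  cat(sprintf("  temperature      : %.2f K\n", x$temperature))
  invisible(x)
}

# concentration of independent nonspecific lattice sites (mol/L)
ns_site_conc <- function(conditions) {
  conditions$ns_bp_total / conditions$ns_site_size
}

#' Titration curve container
#'
#' An ordered set of (total titrant, anisotropy) observations measured
#' under a single set of assay conditions.
#'
#' @param o_total total titrant concentrations (mol/L), strictly
#'   increasing and >= 0.
#' @param anisotropy observed anisotropies (one per concentration).
#' @param sd replicate standard deviations (optional; \code{NA} allowed).
#' @param n_rep replicate counts (recycled; default 1).
#' @param conditions an \code{\link{assay_conditions}} object, or
#'   \code{NULL} if the curve is free-standing.
#' @return An object of class \code{"titration_curve"}: a data frame with
#'   columns \code{o_total}, \code{anisotropy}, \code{sd}, \code{n_rep}
#'   and the conditions attached as an attribute.
#' @export
titration_curve <- function(o_total, anisotropy, sd = NULL, n_rep = 1L,
                            conditions = NULL) {
  o_total <- as.numeric(o_total)
  anisotropy <- as.numeric(anisotropy)
  if (length(o_total) != length(anisotropy))
    stop("'o_total' and 'anisotropy' must have equal length")
  if (any(!is.finite(o_total)) || any(o_total < 0))
    stop("'o_total' must be finite and >= 0")
  if (any(diff(o_total) <= 0))
    stop("'o_total' must be strictly increasing")
  if (is.null(sd)) sd <- rep(NA_real_, length(o_total))
  sd <- rep_len(as.numeric(sd), length(o_total))
  n_rep <- rep_len(as.integer(n_rep), length(o_total))
  if (!is.null(conditions) && !inherits(conditions, "assay_conditions"))
    stop("'conditions' must be an assay_conditions object or NULL")
  out <- data.frame(o_total = o_total, anisotropy = anisotropy,
                    sd = sd, n_rep = n_rep)
  class(out) <- c("titration_curve", "data.frame")
  attr(out, "conditions") <- conditions
  out
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve: %d points, o_total %.3g to %.3g M\n",
              nrow(x), min(x$o_total), max(x$o_total)))
  print.data.frame(x, ...)
  invisible(x)
}

# a curve must hold at least this many points to be fitted
MIN_FIT_POINTS <- 6L
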