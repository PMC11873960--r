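#' Salt-dependence series
#'
#' A series of equilibrium quantities (dissociation constants or
#' excess-binding coefficients) measured across Na+ concentrations, the
#' input to linkage regression.
#'
#' @param na_conc Na+ concentrations (mol/L), strictly increasing.
#' @param value measured quantity per salt point: \code{kd} (mol/L) or
#'   \code{phi} (1/M), all > 0.
#' @param sd standard deviations of \code{log10(value)} (optional).
#' @param label series label (e.g. \code{"-poly[d(I-C)]"}).
#' @param quantity \code{"kd"} or \code{"phi"}.
#' @return An object of class \code{"salt_series"} (a data frame with
#'   attributes \code{label} and \code{quantity}).
#' @export
salt_series <- function(na_conc, value, sd = NULL, label = "",
                        quantity = c("kd", "phi")) {
  quantity <- match.arg(quantity)
  na_conc <- as.numeric(na_conc); value <- as.numeric(value)
  if (length(na_conc) != length(value))
    stop("'na_conc' and 'value' must have equal length")
  if (any(!is.finite(na_conc)) || any(na_conc <= 0))
    stop("'na_conc' must be > 0")
  if (length(na_conc) > 1L && any(diff(na_conc) <= 0))
    stop("'na_conc' must be strictly increasing")
  if (any(!is.finite(value)) || any(value <= 0))
    stop("'value' must be > 0 (log-log regression)")
  if (is.null(sd)) sd <- rep(NA_real_, length(value))
  out <- data.frame(na_conc = na_conc, value = value,
                    sd = rep_len(as.numeric(sd), length(value)))
  class(out) <- c("salt_series", "data.frame")
  attr(out, "label") <- label
  attr(out, "quantity") <- quantity
  out
}

#' Log-log salt-dependence (SK) regression
#'
#' Ordinary (or inverse-variance weighted) least squares of
#' \code{log10(value)} on \code{log10(na_conc)}.  The slope is returned
#' in the association-constant sign convention: \code{sk} is the
#' \emph{negative} of the fitted log K_D slope, so net ion release upon
#' binding gives \code{sk < 0}.
#'
#' @param series a \code{\link{salt_series}} of dissociation constants
#'   (>= 3 points).
#' @param weighting \code{"none"} or \code{"inverse-variance"} (uses the
#'   \code{sd} column as standard deviations of \code{log10(value)}).
#' @return A list with \code{sk}, \code{sk_stderr}, \code{intercept}
#'   (fitted \code{log10(value)} at \code{log10(na_conc) = 0}, i.e. 1 M
#'   Na+), \code{slope} (= \code{-sk}, the raw log K_D slope) and the
#'   underlying \code{lm} fit.
#' @examples
#' tbl <- oct2_kd_salt_table()
#' fit_salt_dependence(salt_series(tbl$na_conc, tbl$kd_minus_poly))
#' @export
fit_salt_dependence <- function(series,
                                weighting = c("none", "inverse-variance")) {
  stopifnot(inherits(series, "salt_series"))
  weighting <- match.arg(weighting)
  if (nrow(series) < 3L)
    stop("need at least 3 salt points for regression")
  x <- log10(series$na_conc)
  y <- log10(series$value)
  if (diff(range(x)) == 0) stop("zero variance in 'na_conc'")
  w <- NULL
  if (weighting == "inverse-variance") {
    if (any(!is.finite(series$sd)) || any(series$sd <= 0))
      stop("inverse-variance weighting needs complete positive 'sd'")
    w <- 1 / series$sd^2
  }
  fit <- lm(y ~ x, weights = w)
  # an exact power law has zero residual; the stderr is then 0/0-free
  sm <- suppressWarnings(summary(fit))$coefficients
  list(sk = -unname(coef(fit)[2]),
       sk_stderr = unname(sm[2, 2]),
       intercept = unname(coef(fit)[1]),
       slope = unname(coef(fit)[2]),
       fit = fit)
}

#' Polyelectrolyte counterion-release term
#'
#' Predicted contribution of counterion release from neutralized DNA
#' phosphates to the observed salt slope: \eqn{\Delta m_{PE} = \psi Z},
#' where \eqn{\psi} is the charge screening/condensation parameter of
#' the oligonucleotide (0.88 for polymeric B-DNA; end-effect-corrected
#' values for short duplexes are supplied by the caller) and \eqn{Z} the
#' signed count of phosphate charges contacted by the protein.
#'
#' @param psi screening/condensation parameter, in (0, 1].
#' @param z signed phosphate contact count (negative for anionic
#'   phosphates).
#' @return \code{psi * z}, in ions.
#' @examples
#' counterion_release(0.75, -11)  # -8.25 ions, reported as -8.3
#' @export
counterion_release <- function(psi, z) {
  if (!is.numeric(psi) || length(psi) != 1L || !is.finite(psi) ||
      psi <= 0 || psi > 1)
    stop("'psi' must be in (0, 1]")
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("'z' must be a finite number")
  psi * z
}

#' Non-polyelectrolyte component of the salt slope
#'
#' Remainder of the observed ion release after subtracting the
#' polyelectrolyte prediction: \code{dm_other = sk - dm_pe}.  A positive
#' remainder indicates ion \emph{uptake} from protein-side processes
#' (e.g. loss of salt bridges) that oppose the phosphate counterion
#' release.
#'
#' @param sk observed salt slope (association-constant convention).
#' @param dm_pe polyelectrolyte term from
#'   \code{\link{counterion_release}}.
#' @return \code{sk - dm_pe}, in ions.
#' @examples
#' decompose_ion_release(-6.8, -8.3)  # 1.5 ions of protein-side uptake
#' @export
decompose_ion_release <- function(sk, dm_pe) {
  if (!is.numeric(sk) || !is.finite(sk) || !is.numeric(dm_pe) ||
      !is.finite(dm_pe))
    stop("'sk' and 'dm_pe' must be finite numbers")
  sk - dm_pe
}

#' Crossover salt concentration of two log-log lines
#'
#' Intersection of two fitted salt dependencies
#' \code{log10 K_D = intercept - sk * log10[Na+]}, e.g. the series with
#' and without nonspecific competitor DNA.  Above/below the crossover
#' the competitor's net effect on affinity changes sign.
#'
#' @param line_a,line_b lists with elements \code{sk} and
#'   \code{intercept} as returned by \code{\link{fit_salt_dependence}}.
#' @param range optional numeric(2) joint data range (mol/L); a
#'   crossover outside it triggers an extrapolation warning.
#' @return Crossover Na+ concentration (mol/L).
#' @export
crossover_concentration <- function(line_a, line_b, range = NULL) {
  for (l in list(line_a, line_b))
    if (!all(c("sk", "intercept") %in% names(l)))
      stop("lines must carry 'sk' and 'intercept'")
  dslope <- (-line_a$sk) - (-line_b$sk)
  if (abs(dslope) < 1e-14)
    stop("lines are parallel: no crossover")
  x <- (line_b$intercept - line_a$intercept) / dslope
  na <- 10^x
  if (!is.null(range) && (na < min(range) || na > max(range)))
    warning(sprintf("crossover %.4g M lies outside the data range [%g, %g] M (extrapolation)",
                    na, min(range), max(range)))
  na
}

#' Per-ion polyelectrolyte free energy
#'
#' Free energy of counterion release per mole of ion at the given salt
#' activity: \eqn{\Delta G_{PE} = -\psi R T \ln[Na^+]}, in kJ/(mol ion).
#'
#' @param psi screening/condensation parameter, in (0, 1].
#' @param temperature temperature (K).
#' @param na_conc Na+ concentration (mol/L).
#' @return Free energy in kJ/(mol ion); positive below 1 M salt.
#' @examples
#' deltag_pe(0.75, 298.15, 0.35)  # about 2 kJ/(mol ion)
#' @export
deltag_pe <- function(psi, temperature = 298.15, na_conc) {
  if (!is.numeric(psi) || length(psi) != 1L || !is.finite(psi) ||
      psi <= 0 || psi > 1)
    stop("'psi' must be in (0, 1]")
  if (!is.numeric(temperature) || temperature <= 0)
    stop("'temperature' must be > 0 K")
  if (!is.numeric(na_conc) || any(na_conc <= 0))
    stop("'na_conc' must be > 0")
  -psi * R_GAS * temperature * log(na_conc) / 1000
}

#' Relative change of the excess-binding coefficient across series
#'
#' Percentage change of phi induced by nonspecific competitor DNA at
#' each matched salt concentration:
#' \code{100 * (phi_plus - phi_minus) / phi_minus}.
#'
#' @param series_minus,series_plus \code{\link{salt_series}} of phi
#'   values on identical \code{na_conc} grids (without and with the
#'   competitor).
#' @return Data frame with \code{na_conc} and \code{delta_pct}.
#' @export
phi_change <- function(series_minus, series_plus) {
  stopifnot(inherits(series_minus, "salt_series"),
            inherits(series_plus, "salt_series"))
  if (nrow(series_minus) != nrow(series_plus) ||
      any(abs(series_minus$na_conc - series_plus$na_conc) >
            1e-12 * series_minus$na_conc))
    stop("series must share an identical na_conc grid")
  data.frame(na_conc = series_minus$na_conc,
             delta_pct = 100 * (series_plus$value - series_minus$value) /
               series_minus$value)
}

#' Full linkage analysis of one dissociation-constant salt series
#'
#' Runs the SK regression and the polyelectrolyte decomposition in one
#' step, producing the complete linkage summary for a series.
#'
#' @param series a \code{\link{salt_series}} of dissociation constants.
#' @param psi screening/condensation parameter (default 0.75, the
#'   end-effect-corrected value for a 20 phosphate-pair duplex;
#'   \code{PSI_POLYMER = 0.88} applies to polymeric DNA).
#' @param z signed phosphate contact count (default -11).
#' @param weighting passed to \code{\link{fit_salt_dependence}}.
#' @return An object of class \code{"linkage_result"}: \code{sk},
#'   \code{sk_stderr}, \code{intercept}, \code{dm_pe}, \code{dm_other}
#'   (\code{= sk - dm_pe} exactly), \code{psi}, \code{z}.
#' @examples
#' tbl <- oct2_kd_salt_table()
#' linkage_analysis(salt_series(tbl$na_conc, tbl$kd_minus_poly,
#'                              label = "-poly[d(I-C)]"))
#' @export
linkage_analysis <- function(series, psi = 0.75, z = -11,
                             weighting = c("none", "inverse-variance")) {
  reg <- fit_salt_dependence(series, weighting = match.arg(weighting))
  dm_pe <- counterion_release(psi, z)
  structure(list(label = attr(series, "label"),
                 sk = reg$sk,
                 sk_stderr = reg$sk_stderr,
                 intercept = reg$intercept,
                 dm_pe = dm_pe,
                 dm_other = decompose_ion_release(reg$sk, dm_pe),
                 psi = psi, z = z,
                 n_points = nrow(series)),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("Salt-linkage analysis")
  if (nzchar(x$label)) cat(" [", x$label, "]", sep = "")
  cat("\n")
  cat(sprintf("  SK        : %.2f +/- %.2f  (n = %d)\n",
              x$sk, x$sk_stderr, x$n_points))
  cat(sprintf("  dm_PE     : %.1f ions  (psi = %.2f, Z = %g)\n",
              round_half_up(x$dm_pe, 1), x$psi, x$z))
  cat(sprintf("  dm_other  : %.1f ions\n", round_half_up(x$dm_other, 1)))
  cat(sprintf("  intercept : %.2f (log10 K_D at 1 M Na+)\n", x$intercept))
  invisible(x)
}

#' Reference salt dependence of OCT2/MORE specific affinity
#'
#' Published equilibrium dissociation constants (Hill half-saturation
#' form, mol/L) of the OCT2 DNA-binding domain for the palindromic MORE
#' element across 0.15-0.35 M Na+, with and without an excess (7 mM bp)
#' of the nonspecific competitor poly[d(I-C)].  These serve as inputs to
#' the linkage computations and as realistic ground-truth values for
#' simulations.
#'
#' @return Data frame with columns \code{na_conc}, \code{kd_minus_poly},
#'   \code{kd_plus_poly} (mol/L) and the reported standard deviations of
#'   \code{log10 K_D} (\code{log_sd_minus}, \code{log_sd_plus}).
#' @export
oct2_kd_salt_table <- function() {
  data.frame(
    na_conc       = c(0.15, 0.175, 0.20, 0.25, 0.30, 0.35),
    kd_minus_poly = c(3.8e-9, 9.7e-9, 2.9e-8, 8.8e-8, 5.6e-7, 12e-7),
    kd_plus_poly  = c(5.5e-9, 11e-9, 1.6e-8, 4.1e-8, 0.71e-7, 1.9e-7),
    log_sd_minus  = c(0.35, 0.38, 0.32, 0.20, 0.17, 0.23),
    log_sd_plus   = c(0.10, 0.17, 0.18, 0.14, 0.12, 0.15))
}

#' Reference salt dependence of OCT2 excess loading at the MORE site
#'
#' Published excess-binding (secondary complex) coefficients phi (1/M)
#' of the OCT2 DNA-binding domain on the MORE probe across 0.15-0.35 M
#' Na+, with and without poly[d(I-C)].
#'
#' @return Data frame with columns \code{na_conc},
#'   \code{phi_minus_poly}, \code{phi_plus_poly} (1/M) and their
#'   absolute standard deviations (\code{sd_minus}, \code{sd_plus}).
#' @export
oct2_phi_salt_table <- function() {
  data.frame(
    na_conc        = c(0.15, 0.175, 0.20, 0.25, 0.30, 0.35),
    phi_minus_poly = c(2.6e4, 2.1e4, 1.0e4, 3.8e3, 0.52e3, 0.34e3),
    phi_plus_poly  = c(0.93e4, 0.94e4, 0.92e4, 4.8e3, 1.6e3, 1.2e3),
    sd_minus       = c(0.1e4, 0.1e4, 0.1e4, 1.2e3, 0.07e3, 0.03e3),
    sd_plus        = c(0.09e4, 0.08e4, 0.10e4, 0.6e3, 0.2e3, 0.1e3))
}
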