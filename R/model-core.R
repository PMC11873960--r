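#' Hill fractional saturation
#'
#' Fraction of sites specifically occupied at free titrant concentration
#' \code{o_free}: \eqn{o^{n} / (K_D^{n} + o^{n})}.  With \code{n_hill = 2}
#' this is the saturable component of the cooperative 2:1 dimer isotherm.
#'
#' @param o_free free titrant concentration(s), mol/L, >= 0.
#' @param kd half-saturation constant, mol/L, > 0.
#' @param n_hill Hill coefficient, >= 1.
#' @return Fractional saturation in [0, 1); vectorized over
#'   \code{o_free}.
#' @examples
#' hill_fraction(3.8e-9, kd = 3.8e-9, n_hill = 2)  # 0.5 at o_free = kd
#' @export
hill_fraction <- function(o_free, kd, n_hill = 2) {
  if (any(!is.finite(o_free)) || any(o_free < 0))
    stop("'o_free' must be finite and >= 0")
  if (!is.finite(kd) || kd <= 0) stop("'kd' must be finite and > 0")
  if (!is.finite(n_hill) || n_hill < 1) stop("'n_hill' must be >= 1")
  # (o/kd)^n form avoids overflow for very small kd
  x <- (o_free / kd)^n_hill
  x / (1 + x)
}

# derivative of hill_fraction w.r.t. o_free (used by the Newton polish)
hill_fraction_deriv <- function(o_free, kd, n_hill) {
  x <- (o_free / kd)^n_hill
  ifelse(o_free > 0,
         n_hill * x / (o_free * (1 + x)^2),
         ifelse(n_hill == 1, 1 / kd, 0))
}

# titrant bound at free concentration o (mol/L), and its derivative.
# Specific binding consumes 2 protomers per occupied site (probe and
# competitor share the isotherm); the nonspecific lattice is a Langmuir
# of independent sites.  The optional secondary term crudely books
# phi-type excess protein (phi * o protomer equivalents per occupied
# probe site) for sensitivity analysis.
speciation_bound <- function(o, conditions, params, secondary_depletion) {
  h <- hill_fraction(o, params$kd, params$n_hill)
  b <- 2 * (conditions$probe_total + conditions$competitor_total) * h
  ns <- ns_site_conc(conditions)
  if (ns > 0) b <- b + ns * o / (conditions$ns_kd + o)
  if (secondary_depletion)
    b <- b + conditions$probe_total * h * params$phi * o
  b
}

speciation_bound_deriv <- function(o, conditions, params, secondary_depletion) {
  h <- hill_fraction(o, params$kd, params$n_hill)
  hp <- hill_fraction_deriv(o, params$kd, params$n_hill)
  d <- 2 * (conditions$probe_total + conditions$competitor_total) * hp
  ns <- ns_site_conc(conditions)
  if (ns > 0) d <- d + ns * conditions$ns_kd / (conditions$ns_kd + o)^2
  if (secondary_depletion)
    d <- d + conditions$probe_total * params$phi * (h + o * hp)
  d
}

#' Solve the coupled mass balance of one titration point
#'
#' Finds the unique free titrant concentration \code{o_free} in
#' \code{[0, o_total]} satisfying conservation of titrant,
#' \deqn{O_t = [O] + 2 [P]_{sp} + 2 [C]_{sp} + [O]_{ns},}
#' where specific occupancy of probe and competitor follows the same
#' Hill isotherm and the nonspecific lattice is a Langmuir of
#' independent sites of \code{ns_site_size} bp.  The balance is strictly
#' monotone in \code{o_free}, so the root is bracketed and unique; it is
#' located by Brent's method and polished by Newton steps.
#'
#' @param o_total total titrant concentration (mol/L), >= 0.
#' @param conditions an \code{\link{assay_conditions}} object.
#' @param params a \code{\link{binding_parameters}} object.
#' @param secondary_depletion if \code{TRUE}, titrant held in phi-type
#'   secondary complexes is also booked in the balance (1:1 accounting;
#'   off by default because the probe is nM against a uM-scale titrant,
#'   making the term negligible).
#' @return An object of class \code{"speciation_state"}: a list with
#'   \code{o_free}, \code{p_specific}, \code{p_unbound},
#'   \code{c_specific}, \code{o_ns_bound}, \code{o_total} and the
#'   absolute mass-balance \code{residual} (mol/L).
#' @examples
#' cond <- assay_conditions(probe_total = 5e-9, na_conc = 0.15)
#' pars <- binding_parameters(kd = 3.8e-9, r_specific = 0.08)
#' solve_speciation(1e-8, cond, pars)
#' @export
solve_speciation <- function(o_total, conditions, params,
                             secondary_depletion = FALSE) {
  stopifnot(inherits(conditions, "assay_conditions"),
            inherits(params, "binding_parameters"))
  if (!is.numeric(o_total) || length(o_total) != 1L ||
      !is.finite(o_total) || o_total < 0)
    stop("'o_total' must be a single finite number >= 0")

  if (o_total == 0) {
    return(new_speciation_state(0, conditions, params,
                                secondary_depletion, o_total))
  }

  f <- function(o)
    o + speciation_bound(o, conditions, params, secondary_depletion) - o_total

  # f(0) = -o_total < 0, f(o_total) >= 0: root bracketed in [0, o_total]
  root <- tryCatch(
    uniroot(f, lower = 0, upper = o_total,
            f.lower = -o_total, f.upper = f(o_total),
            tol = .Machine$double.eps * max(o_total, 1))$root,
    error = function(e)
      stop(sprintf(paste0("speciation root finding failed on [0, %.3g]: %s ",
                          "(f(0) = %.3g, f(o_total) = %.3g)"),
                   o_total, conditionMessage(e), f(0), f(o_total)))
  )

  # Newton polish: the Brent tolerance bounds the abscissa, not the
  # residual; a few damped Newton steps drive |f| to rounding level
  o <- root
  for (i in 1:10) {
    fo <- f(o)
    if (fo == 0) break
    dfo <- 1 + speciation_bound_deriv(o, conditions, params,
                                      secondary_depletion)
    step <- fo / dfo
    o_new <- min(max(o - step, 0), o_total)
    if (!is.finite(o_new)) break
    moved <- abs(o_new - o)
    o <- o_new
    # quadratic convergence: stop once the step is at rounding level
    if (moved <= 4 * .Machine$double.eps * max(o, 1e-300)) break
  }

  new_speciation_state(o, conditions, params, secondary_depletion, o_total)
}

new_speciation_state <- function(o_free, conditions, params,
                                 secondary_depletion, o_total) {
  h <- hill_fraction(o_free, params$kd, params$n_hill)
  p_specific <- conditions$probe_total * h
  c_specific <- conditions$competitor_total * h
  ns <- ns_site_conc(conditions)
  o_ns_bound <- if (ns > 0) ns * o_free / (conditions$ns_kd + o_free) else 0
  accounted <- o_free + 2 * p_specific + 2 * c_specific + o_ns_bound
  if (secondary_depletion)
    accounted <- accounted + conditions$probe_total * h * params$phi * o_free
  structure(list(o_free = o_free,
                 p_specific = p_specific,
                 p_unbound = conditions$probe_total - p_specific,
                 c_specific = c_specific,
                 o_ns_bound = o_ns_bound,
                 o_total = o_total,
                 residual = abs(accounted - o_total)),
            class = "speciation_state")
}

#' @export
print.speciation_state <- function(x, ...) {
  cat("Speciation state (mol/L)\n")
  for (nm in c("o_total", "o_free", "p_specific", "p_unbound",
               "c_specific", "o_ns_bound", "residual"))
    cat(sprintf("  %-11s: %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Predicted anisotropy of one solved state
#'
#' Population-weighted anisotropy of the labeled probe plus the linear
#' excess-binding term:
#' \deqn{r = (r_{sp} [P]_{sp} + r_0 [P]_0)/[P]_t + \phi [O].}
#'
#' @param state a \code{\link{solve_speciation}} result.
#' @param params a \code{\link{binding_parameters}} object.
#' @param probe_total total labeled-probe concentration (mol/L), > 0.
#' @return Predicted anisotropy (dimensionless).
#' @export
predict_anisotropy <- function(state, params, probe_total) {
  stopifnot(inherits(state, "speciation_state"),
            inherits(params, "binding_parameters"))
  if (!is.numeric(probe_total) || length(probe_total) != 1L ||
      !is.finite(probe_total) || probe_total <= 0)
    stop("'probe_total' must be a single number > 0")
  (params$r_specific * state$p_specific +
     params$r_unbound * state$p_unbound) / probe_total +
    params$phi * state$o_free
}

#' Forward-simulate a noiseless titration curve
#'
#' Evaluates the full depletion model (speciation solve plus anisotropy
#' observable) on a grid of total titrant concentrations.
#'
#' @param o_grid total titrant concentrations (mol/L), nonnegative and
#'   strictly increasing.
#' @param conditions an \code{\link{assay_conditions}} object.
#' @param params a \code{\link{binding_parameters}} object.
#' @param secondary_depletion passed to \code{\link{solve_speciation}}.
#' @return A \code{\link{titration_curve}} with the noiseless model
#'   anisotropies (\code{sd = NA}).
#' @export
simulate_curve <- function(o_grid, conditions, params,
                           secondary_depletion = FALSE) {
  o_grid <- as.numeric(o_grid)
  if (length(o_grid) == 0L) stop("'o_grid' must be nonempty")
  if (any(!is.finite(o_grid)) || any(o_grid < 0))
    stop("'o_grid' must be finite and >= 0")
  if (length(o_grid) > 1L && any(diff(o_grid) <= 0))
    stop("'o_grid' must be strictly increasing")
  r <- vapply(seq_along(o_grid), function(i) {
    st <- tryCatch(
      solve_speciation(o_grid[i], conditions, params, secondary_depletion),
      error = function(e)
        stop(sprintf("grid index %d (o_total = %.3g M): %s",
                     i, o_grid[i], conditionMessage(e))))
    predict_anisotropy(st, params, conditions$probe_total)
  }, numeric(1))
  titration_curve(o_grid, r, conditions = conditions)
}
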