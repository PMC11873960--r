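#' Fit the depletion-corrected anisotropy model to a titration
#'
#' Weighted nonlinear least squares of the forward model (speciation
#' solve plus anisotropy observable) against a measured titration.
#' \code{kd} and \code{phi} are optimized on a log10 scale internally so
#' positivity is built in.  Five deterministic starting values of
#' \code{kd}, log-spaced across the titrant range of the data, guard
#' against local minima; the start with the lowest residual sum of
#' squares wins (ties broken by the first index).
#'
#' By default \code{r_unbound} is held at 0 (appropriate for
#' baseline-subtracted anisotropies) and \code{n_hill} at 2 (the
#' cooperative dimer model); either can be freed through \code{fixed}.
#'
#' @param curve a \code{\link{titration_curve}} with at least 6 points;
#'   its attached \code{\link{assay_conditions}} are used unless
#'   \code{conditions} is given.
#' @param init a \code{\link{binding_parameters}} object of starting
#'   values.
#' @param fixed character vector naming parameters held at their
#'   \code{init} values; subset of \code{c("kd", "phi", "r_specific",
#'   "r_unbound", "n_hill")}.  Default fixes \code{r_unbound} and
#'   \code{n_hill}.
#' @param weighting \code{"none"} (ordinary least squares) or
#'   \code{"inverse-variance"} (weights \code{1/sd^2} from the curve's
#'   \code{sd} column, which must then be complete and positive).
#' @param conditions optional \code{\link{assay_conditions}} overriding
#'   the curve's own.
#' @param secondary_depletion passed to \code{\link{solve_speciation}}.
#' @param multistart if \code{FALSE}, optimize from \code{init} only
#'   (used for warm-started refits, e.g. in the bootstrap).
#' @return An object of class \code{"fit_result"}: point estimates as a
#'   \code{binding_parameters} object, per-parameter standard errors
#'   (delta method on the internal scale), the covariance matrix of the
#'   free internal parameters, residuals, \code{rss}, a convergence
#'   flag, and the set of fixed parameter names.  Standard errors are
#'   \code{Inf} and \code{converged} is \code{FALSE} when a parameter is
#'   unidentifiable (singular normal equations, e.g. a flat curve).
#' @export
fit_titration <- function(curve, init,
                          fixed = c("r_unbound", "n_hill"),
                          weighting = c("none", "inverse-variance"),
                          conditions = NULL,
                          secondary_depletion = FALSE,
                          multistart = TRUE) {
  stopifnot(inherits(curve, "titration_curve"),
            inherits(init, "binding_parameters"))
  weighting <- match.arg(weighting)
  if (is.null(conditions)) conditions <- attr(curve, "conditions")
  if (is.null(conditions))
    stop("no assay_conditions attached to the curve or supplied")
  if (nrow(curve) < MIN_FIT_POINTS)
    stop(sprintf("need at least %d points to fit, got %d",
                 MIN_FIT_POINTS, nrow(curve)))
  all_names <- c("kd", "phi", "r_specific", "r_unbound", "n_hill")
  if (!all(fixed %in% all_names))
    stop("unknown parameter name(s) in 'fixed'")
  free <- setdiff(all_names, fixed)
  if (length(free) == 0L) stop("no free parameters")
  if (nrow(curve) <= length(free))
    stop("fewer data points than free parameters")

  w <- rep(1, nrow(curve))
  if (weighting == "inverse-variance") {
    if (any(!is.finite(curve$sd)) || any(curve$sd <= 0))
      stop("inverse-variance weighting needs complete positive 'sd'")
    w <- 1 / curve$sd^2
  }
  sw <- sqrt(w)

  # internal scale: log10 for kd and phi, natural for the rest
  to_internal <- function(p) {
    th <- c(kd = log10(p$kd),
            phi = log10(max(p$phi, PHI_FLOOR)),
            r_specific = p$r_specific,
            r_unbound = p$r_unbound,
            n_hill = p$n_hill)
    th[free]
  }
  from_internal <- function(theta) {
    # fixed parameters keep their exact init values (no log round trip)
    val <- list(kd = init$kd, phi = init$phi,
                r_specific = init$r_specific, r_unbound = init$r_unbound,
                n_hill = init$n_hill)
    for (nm in names(theta)) {
      val[[nm]] <- if (nm %in% c("kd", "phi")) 10^theta[[nm]]
                   else theta[[nm]]
    }
    binding_parameters(kd = val$kd,
                       n_hill = max(val$n_hill, 1),
                       phi = max(val$phi, 0),
                       r_unbound = min(val$r_unbound, val$r_specific),
                       r_specific = max(val$r_specific, val$r_unbound))
  }
  resid_fn <- function(theta) {
    p <- from_internal(theta)
    pred <- simulate_curve(curve$o_total, conditions, p,
                           secondary_depletion)$anisotropy
    sw * (curve$anisotropy - pred)
  }

  # deterministic multi-start on kd across the positive titrant range
  starts <- list(to_internal(init))
  if (multistart && "kd" %in% free) {
    opos <- curve$o_total[curve$o_total > 0]
    if (length(opos) >= 2) {
      kd_grid <- 10^seq(log10(min(opos)), log10(max(opos)), length.out = 5)
      starts <- lapply(kd_grid, function(k) {
        th <- to_internal(init); th["kd"] <- log10(k); th
      })
    }
  }

  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    # strict improvement only: ties go to the earliest start
    if (is.null(best) || rss < best$rss)
      best <- list(fit = res, rss = rss, theta = res$par)
  }
  if (is.null(best)) stop("optimization failed from every start")

  theta <- best$theta
  params <- from_internal(theta)
  pred <- simulate_curve(curve$o_total, conditions, params,
                         secondary_depletion)$anisotropy
  residuals <- curve$anisotropy - pred
  rss <- sum(w * residuals^2)
  n <- nrow(curve); p <- length(free)

  J <- jacobian_num(resid_fn, theta)
  JtJ <- crossprod(J)
  sigma2 <- rss / max(n - p, 1)
  cov_ok <- TRUE
  covmat <- tryCatch({
    ev <- eigen(JtJ, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= max(ev) * 1e-12) stop("singular")
    sigma2 * solve(JtJ)
  }, error = function(e) { cov_ok <<- FALSE
    matrix(Inf, p, p, dimnames = list(free, free)) })
  dimnames(covmat) <- list(free, free)

  stderr_int <- sqrt(pmax(diag(covmat), 0))
  # delta method back to natural scale for log-fitted parameters
  stderr <- stderr_int
  for (nm in intersect(c("kd", "phi"), free))
    stderr[nm] <- log(10) * params[[nm]] * stderr_int[nm]

  converged <- best$fit$info %in% 1:3 && cov_ok

  structure(list(params = params,
                 stderr = stderr,
                 stderr_internal = stderr_int,
                 covariance = covmat,
                 residuals = residuals,
                 fitted = pred,
                 weights = w,
                 rss = rss,
                 sigma2 = sigma2,
                 converged = converged,
                 identifiable = cov_ok,
                 n_points = n,
                 free = free,
                 fixed = fixed,
                 info = best$fit$info,
                 message = best$fit$message,
                 curve = curve,
                 conditions = conditions,
                 secondary_depletion = secondary_depletion,
                 weighting = weighting),
            class = "fit_result")
}

# phi values below this (1/M) contribute < 1e-9 anisotropy at 1 uM free
# titrant; used only to keep the log parameterization finite
PHI_FLOOR <- 1e-3

# central-difference Jacobian of a vector-valued function
jacobian_num <- function(fn, theta, rel_h = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- rel_h * max(abs(theta[j]), 1e-4)
    tp <- theta; tp[j] <- theta[j] + h
    tm <- theta; tm[j] <- theta[j] - h
    J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  colnames(J) <- names(theta)
  J
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Titration fit (%d points, weighting = %s)\n",
              x$n_points, x$weighting))
  cat(sprintf("  converged: %s   rss: %.4g\n", x$converged, x$rss))
  est <- c(kd = x$params$kd, phi = x$params$phi,
           r_specific = x$params$r_specific,
           r_unbound = x$params$r_unbound, n_hill = x$params$n_hill)
  for (nm in names(est)) {
    tag <- if (nm %in% x$fixed) "(fixed)" else
      sprintf("+/- %.3g", unname(x$stderr[nm]))
    cat(sprintf("  %-11s: %.4g %s\n", nm, est[[nm]], tag))
  }
  invisible(x)
}

#' Confidence intervals for fitted binding parameters
#'
#' Finite-sample (t-quantile) Wald intervals on the internal fitting
#' scale, back-transformed to the natural scale: intervals for
#' \code{kd} and \code{phi} are symmetric in log10 and therefore
#' asymmetric in concentration, as is conventional for binding
#' constants.
#'
#' @param object a \code{\link{fit_titration}} result.
#' @param parm parameter names (default: all free parameters).
#' @param level confidence level.
#' @param ... unused.
#' @return Matrix with columns \code{lower}, \code{upper} and one row
#'   per requested parameter.
#' @export
confint.fit_result <- function(object, parm = object$free, level = 0.95,
                               ...) {
  stopifnot(all(parm %in% object$free))
  crit <- stats::qt(1 - (1 - level) / 2,
                    max(object$n_points - length(object$free), 1))
  out <- t(vapply(parm, function(nm) {
    se <- object$stderr_internal[nm]
    if (nm %in% c("kd", "phi")) {
      c0 <- log10(object$params[[nm]])
      10^(c0 + c(-1, 1) * crit * se)
    } else {
      object$params[[nm]] + c(-1, 1) * crit * se
    }
  }, numeric(2)))
  colnames(out) <- c("lower", "upper")
  out
}

#' Bootstrap confidence intervals for fitted binding parameters
#'
#' Residual-resampling bootstrap: synthetic curves are built as fitted
#' values plus residuals resampled with replacement, each refit from the
#' original point estimate, and percentile intervals taken over the
#' bootstrap distribution of each free parameter.
#'
#' @param curve the fitted \code{\link{titration_curve}}.
#' @param fit a converged \code{\link{fit_titration}} result.
#' @param n_boot number of bootstrap replicates (>= 200).
#' @param seed integer seed; identical seeds give identical intervals.
#' @param level confidence level (default 0.95).
#' @return A data frame with one row per free parameter: point estimate,
#'   lower and upper percentile bounds, and the bootstrap standard error
#'   of log10 values for \code{kd} and \code{phi} (natural scale for the
#'   anisotropy endpoints).
#' @export
bootstrap_uncertainty <- function(curve, fit, n_boot = 200, seed = 1,
                                  level = 0.95) {
  stopifnot(inherits(curve, "titration_curve"),
            inherits(fit, "fit_result"))
  if (!fit$converged) stop("refusing to bootstrap a non-converged fit")
  if (n_boot < 200) stop("'n_boot' must be >= 200")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  n <- nrow(curve)
  draws <- matrix(NA_real_, n_boot, length(fit$free),
                  dimnames = list(NULL, fit$free))
  for (b in seq_len(n_boot)) {
    r_star <- fit$fitted + sample(fit$residuals, n, replace = TRUE)
    curve_b <- titration_curve(curve$o_total, r_star, sd = curve$sd,
                               n_rep = curve$n_rep,
                               conditions = fit$conditions)
    fb <- tryCatch(
      fit_titration(curve_b, init = fit$params, fixed = fit$fixed,
                    weighting = fit$weighting,
                    conditions = fit$conditions,
                    secondary_depletion = fit$secondary_depletion,
                    multistart = FALSE),
      error = function(e) NULL)
    if (is.null(fb)) next
    draws[b, ] <- vapply(fit$free, function(nm) fb$params[[nm]],
                         numeric(1))
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  if (nrow(draws) < n_boot * 0.5)
    warning("more than half of the bootstrap refits failed")

  a <- (1 - level) / 2
  out <- data.frame(parameter = fit$free,
                    estimate = vapply(fit$free,
                                      function(nm) fit$params[[nm]],
                                      numeric(1)),
                    lower = apply(draws, 2, quantile, probs = a,
                                  names = FALSE),
                    upper = apply(draws, 2, quantile, probs = 1 - a,
                                  names = FALSE),
                    row.names = NULL)
  out$boot_se <- vapply(fit$free, function(nm) {
    v <- draws[, nm]
    if (nm %in% c("kd", "phi")) sd(log10(pmax(v, .Machine$double.xmin)))
    else sd(v)
  }, numeric(1))
  attr(out, "n_boot") <- nrow(draws)
  attr(out, "level") <- level
  out
}
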