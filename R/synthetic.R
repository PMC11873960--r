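#' Specification for synthetic titration generation
#'
#' Ground truth, design and noise model for simulated anisotropy
#' titrations.  The defaults mirror the standard experimental design:
#' a 5 nM labeled probe titrated with two-fold dilutions of protein from
#' 1 uM, three replicates, and homoscedastic Gaussian anisotropy noise.
#'
#' @param truth a \code{\link{binding_parameters}} object (the
#'   generating parameters).
#' @param conditions an \code{\link{assay_conditions}} object.
#' @param design list with \code{min}, \code{max} (mol/L), \code{points}
#'   and \code{spacing} (\code{"log"} or \code{"linear"}).  The default
#'   is the 11-point two-fold dilution series from 1 uM down to ~1 nM.
#' @param noise_sd replicate anisotropy standard deviation (>= 0).
#' @param n_replicates replicates averaged per point (>= 1).
#' @param seed integer seed.
#' @param salt_model optional list \code{(kd_ref, ref_na, sk_true,
#'   jitter_log_sd)} enabling \code{\link{generate_salt_series}}.
#' @return An object of class \code{"generator_spec"}.
#' @export
generator_spec <- function(truth = binding_parameters(kd = 3.8e-9,
                                                      phi = 2.6e4,
                                                      r_specific = 0.08),
                           conditions = assay_conditions(probe_total = 5e-9,
                                                         na_conc = 0.15),
                           design = list(min = 1e-6 / 2^10, max = 1e-6,
                                         points = 11, spacing = "log"),
                           noise_sd = 0.002,
                           n_replicates = 3L,
                           seed = 1L,
                           salt_model = NULL) {
  stopifnot(inherits(truth, "binding_parameters"),
            inherits(conditions, "assay_conditions"))
  if (!all(c("min", "max", "points", "spacing") %in% names(design)))
    stop("'design' must name min, max, points and spacing")
  if (!design$spacing %in% c("log", "linear"))
    stop("'spacing' must be \"log\" or \"linear\"")
  if (!(design$min < design$max) || design$min < 0)
    stop("design requires 0 <= min < max")
  if (design$spacing == "log" && design$min <= 0)
    stop("log spacing requires min > 0")
  if (design$points < 2) stop("need at least 2 design points")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  if (!is.null(salt_model)) {
    if (!all(c("kd_ref", "ref_na", "sk_true") %in% names(salt_model)))
      stop("'salt_model' must name kd_ref, ref_na and sk_true")
    if (is.null(salt_model$jitter_log_sd)) salt_model$jitter_log_sd <- 0
  }
  structure(list(truth = truth, conditions = conditions, design = design,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), salt_model = salt_model),
            class = "generator_spec")
}

design_grid <- function(design) {
  if (design$spacing == "log")
    log_grid(design$min, design$max, design$points)
  else seq(design$min, design$max, length.out = design$points)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a noisy synthetic titration with known truth
#'
#' Forward-simulates the depletion model on the design grid, adds
#' i.i.d. Gaussian replicate noise, and reports per-point replicate
#' means and standard deviations, exactly as a plate-reader series would
#' be summarized.  Identical seeds give identical output.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return A list with \code{curve} (a \code{\link{titration_curve}})
#'   and \code{truth} (the generating parameters, conditions and spec).
#' @export
generate_titration <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  grid <- design_grid(spec$design)
  kd <- spec$truth$kd
  gpos <- grid[grid > 0]
  if (length(gpos) == 0L || !any(gpos >= kd / 10 & gpos <= kd * 10))
    warning(sprintf(paste0("design grid has no point within 10-fold of ",
                           "kd = %.3g M; kd may be unidentifiable"), kd))
  clean <- simulate_curve(grid, spec$conditions, spec$truth)
  noisy <- with_seed(spec$seed, {
    reps <- matrix(rnorm(length(grid) * spec$n_replicates,
                         mean = rep(clean$anisotropy, each = spec$n_replicates),
                         sd = spec$noise_sd),
                   nrow = spec$n_replicates)
    list(mean = colMeans(reps),
         sd = if (spec$n_replicates > 1) apply(reps, 2, sd)
              else rep(NA_real_, length(grid)))
  })
  curve <- titration_curve(grid, noisy$mean, sd = noisy$sd,
                           n_rep = spec$n_replicates,
                           conditions = spec$conditions)
  list(curve = curve,
       truth = list(params = spec$truth, conditions = spec$conditions,
                    noise_sd = spec$noise_sd,
                    n_replicates = spec$n_replicates, seed = spec$seed))
}

#' Generate a synthetic salt series with known SK
#'
#' Draws dissociation constants from the linkage power law
#' \code{kd(na) = kd_ref * (na/ref_na)^(-sk_true)} (association-constant
#' sign convention, so a negative \code{sk_true} makes \code{kd} rise
#' with salt), with optional lognormal jitter of \code{jitter_log_sd}
#' decades.  With zero jitter, \code{\link{fit_salt_dependence}} on the
#' output recovers \code{sk_true} exactly.
#'
#' @param spec a \code{\link{generator_spec}} with \code{salt_model}
#'   set.
#' @param na_grid Na+ concentrations (mol/L), >= 3 points, increasing.
#' @return A list with \code{series} (a \code{\link{salt_series}}) and
#'   \code{truth}.
#' @export
generate_salt_series <- function(spec, na_grid) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(spec$salt_model))
    stop("spec has no 'salt_model'")
  na_grid <- as.numeric(na_grid)
  if (length(na_grid) < 3L)
    stop("'na_grid' must have at least 3 points (regression input)")
  sm <- spec$salt_model
  kd <- sm$kd_ref * (na_grid / sm$ref_na)^(-sm$sk_true)
  if (sm$jitter_log_sd > 0)
    kd <- with_seed(spec$seed,
                    kd * 10^rnorm(length(kd), 0, sm$jitter_log_sd))
  list(series = salt_series(na_grid, kd,
                            sd = rep(sm$jitter_log_sd, length(kd)),
                            label = "synthetic", quantity = "kd"),
       truth = sm)
}

#' Generate a competition titration
#'
#' Same forward model and noise as \code{\link{generate_titration}},
#' with an unlabeled cognate-site competitor added to the mass balance.
#' The competitor shares the probe's binding parameters (it is the
#' unlabeled probe sequence); at saturating competitor the saturable
#' probe signal is abolished and only the baseline and excess-binding
#' terms remain.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @param competitor_total unlabeled cognate-site concentration (mol/L).
#' @return As \code{\link{generate_titration}}.
#' @export
generate_competition_curve <- function(spec, competitor_total) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.numeric(competitor_total) || competitor_total < 0)
    stop("'competitor_total' must be >= 0")
  cond <- spec$conditions
  cond$competitor_total <- competitor_total
  spec$conditions <- cond
  generate_titration(spec)
}
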