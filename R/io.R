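#' Read a titration CSV
#'
#' Expected schema: header \code{o_total_M, anisotropy, sd, n_rep};
#' concentrations in mol/L, decimal points, no thousands separators.
#' \code{sd} and \code{n_rep} may be empty.  Malformed rows are reported
#' with their line numbers.
#'
#' @param path file path.
#' @param conditions optional \code{\link{assay_conditions}} to attach.
#' @return A \code{\link{titration_curve}}.
#' @export
read_titration_csv <- function(path, conditions = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("o_total_M", "anisotropy")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  if (!"n_rep" %in% names(df)) df$n_rep <- 1L
  for (col in c("o_total_M", "anisotropy", "sd", "n_rep")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric '%s' at data row(s) %s (file line %s)",
                   col, paste(bad, collapse = ", "),
                   paste(bad + 1L, collapse = ", ")))
    df[[col]] <- v
  }
  bad <- which(!is.finite(df$o_total_M) | df$o_total_M < 0)
  if (length(bad) > 0)
    stop(sprintf("negative or missing concentration at data row(s) %s (file line %s)",
                 paste(bad, collapse = ", "),
                 paste(bad + 1L, collapse = ", ")))
  if (any(diff(df$o_total_M) <= 0)) {
    i <- which(diff(df$o_total_M) <= 0)[1]
    stop(sprintf("concentrations not strictly increasing at data row %d (file line %d)",
                 i + 1L, i + 2L))
  }
  titration_curve(df$o_total_M, df$anisotropy, sd = df$sd,
                  n_rep = ifelse(is.na(df$n_rep), 1L, df$n_rep),
                  conditions = conditions)
}

#' Write a titration CSV
#'
#' Inverse of \code{\link{read_titration_csv}}; full-precision,
#' deterministic output so identical curves give byte-identical files.
#'
#' @param curve a \code{\link{titration_curve}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  df <- data.frame(o_total_M = format_num(curve$o_total),
                   anisotropy = format_num(curve$anisotropy),
                   sd = format_num(curve$sd),
                   n_rep = curve$n_rep)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

format_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         formatC(x, digits = 17, format = "g"))
}

#' Read salt-series CSV
#'
#' Schema: \code{na_M, value, sd, series_label}; one
#' \code{\link{salt_series}} is returned per distinct label.
#'
#' @param path file path.
#' @param quantity \code{"kd"} or \code{"phi"}.
#' @return A named list of \code{\link{salt_series}} objects.
#' @export
read_salt_series_csv <- function(path, quantity = c("kd", "phi")) {
  quantity <- match.arg(quantity)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("na_M", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  if (!"series_label" %in% names(df)) df$series_label <- ""
  out <- lapply(split(df, df$series_label), function(d) {
    d <- d[order(d$na_M), ]
    salt_series(d$na_M, d$value, sd = d$sd,
                label = d$series_label[1], quantity = quantity)
  })
  out
}

#' Read assay conditions from YAML or JSON
#'
#' Keys must match \code{\link{assay_conditions}} argument names
#' exactly; unknown keys abort (strict schema).  A key
#' \code{ns_poly_dic_units} is additionally accepted and converted to
#' \code{ns_bp_total} at 7.0 mM bp per activity unit.
#'
#' @param path a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return An \code{\link{assay_conditions}} object.
#' @export
read_conditions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
  if (!is.null(cfg$ns_poly_dic_units)) {
    cfg$ns_bp_total <- cfg$ns_poly_dic_units * POLY_DIC_BP_PER_U
    cfg$ns_poly_dic_units <- NULL
  }
  allowed <- names(formals(assay_conditions))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(assay_conditions, cfg)
}

#' Write an analysis report
#'
#' Serializes a fit, linkage result or table to JSON or CSV with
#' deterministic field ordering.  JSON reports carry full-precision
#' values plus a \code{display} block rounded by the table conventions
#' of the field (log values to 2 decimals, ion counts to 1 decimal,
#' half away from zero).
#'
#' @param results a \code{\link{fit_titration}} result, a
#'   \code{\link{linkage_analysis}} result, or a data frame.
#' @param path output path.
#' @param format \code{"json"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(results, "fit_result")) {
    payload <- report_fit(results)
  } else if (inherits(results, "linkage_result")) {
    payload <- report_linkage(results)
  } else if (is.data.frame(results)) {
    payload <- list(table = results)
  } else stop("unsupported results object")

  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    df <- payload_as_table(payload, results)
    write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

report_fit <- function(x) {
  est <- list(kd = x$params$kd, phi = x$params$phi,
              r_specific = x$params$r_specific,
              r_unbound = x$params$r_unbound, n_hill = x$params$n_hill)
  list(type = "titration_fit",
       estimate = est,
       stderr = as.list(x$stderr),
       rss = x$rss,
       converged = x$converged,
       identifiable = x$identifiable,
       n_points = x$n_points,
       free = x$free,
       fixed = x$fixed,
       weighting = x$weighting,
       display = list(log10_kd = round_half_up(log10(est$kd), 2),
                      kd_macroscopic_M2 = est$kd^2))
}

report_linkage <- function(x) {
  list(type = "salt_linkage",
       label = x$label,
       sk = x$sk,
       sk_stderr = x$sk_stderr,
       intercept = x$intercept,
       dm_pe = x$dm_pe,
       dm_other = x$dm_other,
       psi = x$psi,
       z = x$z,
       n_points = x$n_points,
       display = list(sk = round_half_up(x$sk, 1),
                      dm_pe = round_half_up(x$dm_pe, 1),
                      dm_other = round_half_up(x$dm_other, 1),
                      intercept = round_half_up(x$intercept, 2)))
}

payload_as_table <- function(payload, results) {
  if (is.data.frame(results)) return(results)
  if (payload$type == "titration_fit") {
    nm <- names(payload$estimate)
    data.frame(parameter = nm,
               estimate = unlist(payload$estimate, use.names = FALSE),
               stderr = vapply(nm, function(n) {
                 s <- payload$stderr[[n]]
                 if (is.null(s)) NA_real_ else s
               }, numeric(1)),
               fixed = nm %in% payload$fixed)
  } else {
    keep <- c("sk", "sk_stderr", "intercept", "dm_pe", "dm_other",
              "psi", "z")
    data.frame(quantity = keep,
               value = vapply(keep, function(n) payload[[n]], numeric(1)))
  }
}
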