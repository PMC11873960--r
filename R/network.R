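#' Species transition with salt-linked equilibrium constant
#'
#' One reversible reaction of the coupled-equilibrium scheme.  The
#' equilibrium constant obeys the linkage power law
#' \code{k_ref * (na_conc / ref_na)^dm}, so \code{log10 K} is linear in
#' \code{log10 [Na+]} with slope \code{dm} (the net ion stoichiometry:
#' negative for ion release toward the products).
#'
#' Species names recognized in \code{consumed}/\code{produced} are the
#' five macroscopic protein species plus the free DNA sites:
#' \code{free_protein}, \code{specific_dimer} (2 protein : 1 cognate
#' site), \code{secondary_complex} (an oversaturated specific complex
#' carrying one extra protein), \code{nonspecific_complex} (1 protein on
#' 1 lattice site), \code{crosslinked_intermediate} (a specific complex
#' bridged to a lattice site by the extra protein), \code{more_free} and
#' \code{ns_free}.
#'
#' @param consumed,produced named integer vectors of species counts on
#'   each side of the reaction; elements (protein, cognate sites,
#'   lattice sites) must balance.
#' @param k_ref equilibrium constant at the reference salt (units per
#'   the reaction's molecularity), > 0.
#' @param ref_na reference Na+ concentration (mol/L).
#' @param dm net ion stoichiometry of the transition (ions).
#' @param name optional label.
#' @return An object of class \code{"network_transition"}.
#' @examples
#' transition(c(free_protein = 2, more_free = 1),
#'            c(specific_dimer = 1), k_ref = 1.2e15, dm = -6.8)
#' @export
transition <- function(consumed, produced, k_ref, ref_na = 0.2, dm = 0,
                       name = NULL) {
  if (!is.numeric(k_ref) || length(k_ref) != 1L || !is.finite(k_ref) ||
      k_ref <= 0)
    stop("'k_ref' must be > 0")
  if (!is.numeric(ref_na) || ref_na <= 0) stop("'ref_na' must be > 0")
  if (!is.numeric(dm) || !is.finite(dm)) stop("'dm' must be finite")
  chk <- function(v, side) {
    if (length(v) == 0L || is.null(names(v)) || any(!nzchar(names(v))))
      stop(sprintf("'%s' must be a named vector of species counts", side))
    if (any(v <= 0) || any(v != round(v)))
      stop(sprintf("'%s' counts must be positive integers", side))
    v
  }
  consumed <- chk(consumed, "consumed")
  produced <- chk(produced, "produced")
  if (is.null(name))
    name <- paste0(paste(names(consumed), collapse = "+"), " -> ",
                   paste(names(produced), collapse = "+"))
  structure(list(consumed = consumed, produced = produced,
                 k_ref = k_ref, ref_na = ref_na, dm = dm, name = name),
            class = "network_transition")
}

#' Equilibrium constant of a transition at a given salt
#'
#' @param t a \code{\link{transition}}.
#' @param na_conc Na+ concentration(s), mol/L, > 0.
#' @return \code{k_ref * (na_conc/ref_na)^dm}; vectorized over
#'   \code{na_conc}.
#' @export
k_at_salt <- function(t, na_conc) {
  stopifnot(inherits(t, "network_transition"))
  if (any(!is.finite(na_conc)) || any(na_conc <= 0))
    stop("'na_conc' must be > 0")
  t$k_ref * (na_conc / t$ref_na)^t$dm
}

# element composition (protein, cognate sites, lattice sites) of the
# recognized species; frees carry a unit of their own element
network_species_table <- function() {
  m <- rbind(free_protein             = c(1, 0, 0),
             specific_dimer           = c(2, 1, 0),
             secondary_complex        = c(3, 1, 0),
             nonspecific_complex      = c(1, 0, 1),
             crosslinked_intermediate = c(3, 1, 1),
             more_free                = c(0, 1, 0),
             ns_free                  = c(0, 0, 1))
  colnames(m) <- c("protein", "more", "ns")
  m
}

# species whose concentrations are independent unknowns of the solver;
# every other (complex) species is a monomial in these
FREE_SPECIES <- c("free_protein", "more_free", "ns_free")

#' Coupled mass-action equilibrium network
#'
#' Assembles transitions and conserved totals into a solvable network.
#' Construction validates element balance of every transition and
#' thermodynamic cycle consistency: any combination of transitions with
#' zero net stoichiometry must have zero net \code{log K} at the
#' reference salt and zero net \code{dm} (so the constraint holds at
#' every salt).
#'
#' @param transitions list of \code{\link{transition}} objects.
#' @param totals named numeric vector of conserved totals (mol/L):
#'   \code{protein}, \code{more} (cognate sites), \code{ns} (lattice
#'   sites); all >= 0.
#' @return An object of class \code{"equilibrium_network"}.
#' @seealso \code{\link{default_network}} for the standard five-species
#'   parameterization.
#' @export
equilibrium_network <- function(transitions, totals) {
  if (!is.list(transitions) || length(transitions) == 0L ||
      !all(vapply(transitions, inherits, logical(1), "network_transition")))
    stop("'transitions' must be a nonempty list of transition objects")
  comp <- network_species_table()
  need <- c("protein", "more", "ns")
  if (!all(need %in% names(totals)))
    stop("'totals' must name protein, more and ns")
  totals <- unlist(totals)[need]
  if (any(!is.finite(totals)) || any(totals < 0))
    stop("totals must be finite and >= 0")

  ref_na <- transitions[[1]]$ref_na
  if (!all(vapply(transitions, function(t) t$ref_na, numeric(1)) == ref_na))
    stop("all transitions must share one reference salt")

  # net stoichiometry matrix: rows = transitions, cols = species
  nu <- matrix(0, length(transitions), nrow(comp),
               dimnames = list(vapply(transitions, `[[`, character(1),
                                      "name"),
                               rownames(comp)))
  for (i in seq_along(transitions)) {
    t <- transitions[[i]]
    for (nm in names(t$consumed)) {
      if (!nm %in% rownames(comp)) stop("unknown species: ", nm)
      nu[i, nm] <- nu[i, nm] - t$consumed[[nm]]
    }
    for (nm in names(t$produced)) {
      if (!nm %in% rownames(comp)) stop("unknown species: ", nm)
      nu[i, nm] <- nu[i, nm] + t$produced[[nm]]
    }
    bal <- drop(nu[i, , drop = FALSE] %*% comp)
    if (any(abs(bal) > 0))
      stop(sprintf("transition '%s' does not conserve: %s", t$name,
                   paste(need[bal != 0], collapse = ", ")))
  }

  logk <- vapply(transitions, function(t) log(t$k_ref), numeric(1))
  dm <- vapply(transitions, function(t) t$dm, numeric(1))

  # cycle consistency: c' nu = 0 must imply c'.logk = 0 and c'.dm = 0
  sv <- svd(nu, nu = nrow(nu), nv = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < nrow(nu)) {
    cycles <- sv$u[, (rank + 1):nrow(nu), drop = FALSE]
    bad_k <- abs(crossprod(cycles, logk))
    bad_m <- abs(crossprod(cycles, dm))
    if (any(bad_k > 1e-8) || any(bad_m > 1e-8))
      stop(sprintf(paste0("thermodynamically inconsistent cycle: net ",
                          "log K = %.3g, net dm = %.3g around a closed ",
                          "loop (both must be 0)"),
                   max(bad_k), max(bad_m)))
  }

  # formation representation: [s] = exp(g_s + dmf_s*log(na/ref)) *
  # prod(free^a) for every complex species s reachable from the frees
  complex_names <- setdiff(colnames(nu)[colSums(abs(nu)) > 0], FREE_SPECIES)
  A <- nu[, complex_names, drop = FALSE]
  qrA <- qr(A)
  if (qrA$rank < length(complex_names))
    stop("transitions do not determine the formation constants of: ",
         paste(complex_names[-seq_len(qrA$rank)], collapse = ", "))
  g <- qr.coef(qrA, logk)
  dmf <- qr.coef(qrA, dm)

  structure(list(transitions = transitions, totals = totals,
                 ref_na = ref_na, species = comp,
                 complex_names = complex_names,
                 g = g, dm_formation = dmf),
            class = "equilibrium_network")
}

#' @export
print.equilibrium_network <- function(x, ...) {
  cat(sprintf("Equilibrium network: %d transitions, ref salt %.3g M\n",
              length(x$transitions), x$ref_na))
  cat(sprintf("  totals: protein %.3g M, cognate sites %.3g M, lattice sites %.3g M\n",
              x$totals[["protein"]], x$totals[["more"]], x$totals[["ns"]]))
  for (t in x$transitions)
    cat(sprintf("  %-60s K_ref = %.3g, dm = %+.2f\n", t$name, t$k_ref,
                t$dm))
  invisible(x)
}

#' Standard five-species network for OCT2/MORE with nonspecific DNA
#'
#' The default parameterization of the coupled scheme: cooperative
#' specific dimer formation with the experimentally observed salt slope
#' (\code{dm = -6.8}), salt-insensitive loading of one extra protein
#' onto the saturated complex and bridging of a nonspecific site by that
#' extra protein (\code{dm = 0} for both, since neither changes net DNA
#' occupancy), and nonspecific binding that releases more ions than
#' specific binding (\code{dm = -9}).  The release of the lattice site
#' from the bridged intermediate then carries \code{dm = +9} (ion
#' uptake) by cycle closure.  Constants for the transitions involving
#' the secondary and cross-linked species are illustrative: experiments
#' constrain their salt exponents and rank order, not their magnitudes.
#'
#' @param protein_total total protein (mol/L).
#' @param more_total cognate (MORE) site total (mol/L); default 5 nM,
#'   the standard labeled-probe concentration.
#' @param ns_site_total nonspecific lattice-site total (mol/L); default
#'   7 mM bp / 14 bp per site = 0.5 mM sites.
#' @param k_specific specific-dimer formation constant at the reference
#'   salt (1/M^2); default \code{1/kd^2} with \code{kd = 2.9e-8} M, the
#'   measured affinity at 0.20 M Na+.
#' @param k_secondary extra-protein loading constant (1/M).
#' @param k_ns nonspecific site association constant (1/M).
#' @param k_bridge association of a nonspecific complex with a specific
#'   complex into the cross-linked intermediate (1/M).
#' @param dm_specific,dm_ns salt exponents of the two binding steps.
#' @param ref_na reference Na+ concentration (mol/L).
#' @return An \code{\link{equilibrium_network}}.
#' @export
default_network <- function(protein_total = 5e-8,
                            more_total = 5e-9,
                            ns_site_total = 7e-3 / 14,
                            k_specific = 1 / 2.9e-8^2,
                            k_secondary = 3e4,
                            k_ns = 4e3,
                            k_bridge = 1e9,
                            dm_specific = -6.8,
                            dm_ns = -9,
                            ref_na = 0.2) {
  trans <- list(
    transition(c(free_protein = 2, more_free = 1),
               c(specific_dimer = 1),
               k_ref = k_specific, ref_na = ref_na, dm = dm_specific,
               name = "specific dimer formation"),
    transition(c(specific_dimer = 1, free_protein = 1),
               c(secondary_complex = 1),
               k_ref = k_secondary, ref_na = ref_na, dm = 0,
               name = "secondary (oversaturated) loading"),
    transition(c(free_protein = 1, ns_free = 1),
               c(nonspecific_complex = 1),
               k_ref = k_ns, ref_na = ref_na, dm = dm_ns,
               name = "nonspecific site binding"),
    transition(c(specific_dimer = 1, nonspecific_complex = 1),
               c(crosslinked_intermediate = 1),
               k_ref = k_bridge, ref_na = ref_na, dm = 0,
               name = "intersegmental bridge formation"),
    transition(c(crosslinked_intermediate = 1),
               c(secondary_complex = 1, ns_free = 1),
               # cycle closure fixes both the constant and dm = -dm_ns
               k_ref = k_secondary / (k_bridge * k_ns),
               ref_na = ref_na, dm = -dm_ns,
               name = "lattice-site release (ion uptake)"))
  equilibrium_network(trans,
                      totals = c(protein = protein_total,
                                 more = more_total,
                                 ns = ns_site_total))
}

#' Read an equilibrium network from JSON
#'
#' Schema: \code{totals} (object with \code{protein}, \code{more},
#' \code{ns}, mol/L) and \code{transitions}, an array of objects with
#' \code{consumed} and \code{produced} (objects mapping species names
#' to counts), \code{k_ref}, \code{ref_na}, \code{dm} and optional
#' \code{name}.  Validation (element balance, cycle consistency) is the
#' same as for \code{\link{equilibrium_network}}.
#'
#' @param path a \code{.json} file.
#' @return An \code{\link{equilibrium_network}}.
#' @export
read_network_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!all(c("totals", "transitions") %in% names(cfg)))
    stop("network spec must name 'totals' and 'transitions'")
  trans <- lapply(cfg$transitions, function(t) {
    transition(consumed = unlist(t$consumed),
               produced = unlist(t$produced),
               k_ref = t$k_ref,
               ref_na = if (is.null(t$ref_na)) 0.2 else t$ref_na,
               dm = if (is.null(t$dm)) 0 else t$dm,
               name = t$name)
  })
  equilibrium_network(trans, totals = unlist(cfg$totals))
}

#' Solve the coupled equilibria at one salt concentration
#'
#' Newton iteration on the log concentrations of the free species
#' (protein, cognate sites, lattice sites), with every complex species a
#' monomial in the frees through its formation constant.  Working in log
#' space enforces positivity; the Jacobian of the conservation equations
#' is analytic.
#'
#' @param net an \code{\link{equilibrium_network}}.
#' @param na_conc Na+ concentration (mol/L).
#' @param totals optional named vector overriding the network's totals.
#' @param tol relative conservation tolerance (default 1e-12).
#' @return A list with \code{concentrations} (named, mol/L, all species
#'   and frees), \code{residual_rel} (largest relative conservation
#'   violation) and \code{na_conc}.
#' @export
solve_network <- function(net, na_conc, totals = NULL, tol = 1e-12) {
  stopifnot(inherits(net, "equilibrium_network"))
  if (!is.numeric(na_conc) || length(na_conc) != 1L || na_conc <= 0)
    stop("'na_conc' must be a single number > 0")
  tot <- net$totals
  if (!is.null(totals)) tot[names(totals)] <- unlist(totals)
  if (any(tot < 0)) stop("totals must be >= 0")

  comp <- net$species
  cn <- net$complex_names
  # salt-adjusted log formation constants
  gs <- net$g + net$dm_formation * log(na_conc / net$ref_na)
  acomp <- comp[cn, , drop = FALSE]

  elements <- colnames(comp)
  active <- elements[tot > 0]
  conc0 <- setNames(rep(0, nrow(comp)), rownames(comp))
  if (length(active) == 0L)
    return(list(concentrations = conc0, residual_rel = 0,
                na_conc = na_conc))
  # species needing an absent element cannot form
  feasible <- cn[apply(acomp[, setdiff(elements, active), drop = FALSE],
                       1, function(a) all(a == 0))]
  afe <- acomp[feasible, active, drop = FALSE]
  gfe <- gs[feasible]

  free_of <- c(protein = "free_protein", more = "more_free",
               ns = "ns_free")
  lf <- log(tot[active])  # start from all-free
  calc <- function(lf) {
    cc <- exp(gfe + drop(afe %*% lf))
    free <- exp(lf)
    tc <- free + drop(crossprod(afe, cc))  # per active element
    list(cc = cc, free = free, tc = tc)
  }
  fres_at <- function(lf) {
    tc <- calc(lf)$tc
    log(tc / tot[active])
  }
  for (it in 1:300) {
    st <- calc(lf)
    fres <- log(st$tc / tot[active])
    if (!all(is.finite(fres))) stop("network solve left the feasible domain")
    if (max(abs(fres)) < 1e-14) break
    # J[e,e'] = d tc_e / d lf_e' = delta*free + sum_s a_se a_se' c_s
    J <- diag(st$free, nrow = length(lf)) +
      crossprod(afe * st$cc, afe)
    Jlog <- J / st$tc
    step <- tryCatch(solve(Jlog, fres), error = function(e) fres)
    # cap the length, not the components, to keep the Newton direction
    m <- max(abs(step))
    if (m > 5) step <- step * (5 / m)
    # backtracking line search on the residual norm
    f0 <- sum(fres^2)
    t <- 1
    repeat {
      fr_new <- fres_at(lf - t * step)
      if (all(is.finite(fr_new)) && sum(fr_new^2) < f0) break
      t <- t / 2
      if (t < 1e-8) break
    }
    lf <- lf - t * step
  }
  st <- calc(lf)
  res_rel <- max(abs(st$tc - tot[active]) / tot[active])
  if (res_rel > tol)
    stop(sprintf(paste0("network solve did not converge at %.3g M Na+: ",
                        "relative conservation residual %.3g"),
                 na_conc, res_rel))
  conc0[free_of[active]] <- st$free
  conc0[feasible] <- st$cc
  list(concentrations = conc0, residual_rel = res_rel,
       na_conc = na_conc)
}

#' Salt scan of the coupled network
#'
#' Solves the network across a Na+ grid with and without the nonspecific
#' lattice, reporting specific occupancy (fraction of cognate sites
#' carrying the specific dimer in any form), secondary and nonspecific
#' loads, and the crossover salt at which the lattice's effect on
#' specific occupancy changes sign, if one occurs on the grid.
#'
#' @param net an \code{\link{equilibrium_network}}.
#' @param na_grid increasing Na+ concentrations (mol/L).
#' @param with_ns if \code{FALSE} the lattice totals are zeroed in both
#'   branches (the nonspecific load is then identically 0).
#' @return A data frame with one row per salt: \code{na_conc},
#'   \code{occ_specific} / \code{occ_specific_no_ns} (with/without the
#'   lattice), \code{secondary_load}, \code{ns_load} and
#'   \code{delta_occ}; the crossover (linear interpolation of the sign
#'   change of \code{delta_occ}) is attached as attribute
#'   \code{"crossover_na"} (\code{NA} if none).
#' @export
salt_scan <- function(net, na_grid, with_ns = TRUE) {
  stopifnot(inherits(net, "equilibrium_network"))
  na_grid <- as.numeric(na_grid)
  if (length(na_grid) < 2L || any(diff(na_grid) <= 0) ||
      any(na_grid <= 0))
    stop("'na_grid' must be increasing and > 0")
  more_t <- net$totals[["more"]]
  if (more_t <= 0) stop("network has no cognate sites to track")
  ns_t <- if (with_ns) net$totals[["ns"]] else 0

  row1 <- function(na) {
    with_ <- solve_network(net, na, totals = c(ns = ns_t))$concentrations
    none <- solve_network(net, na, totals = c(ns = 0))$concentrations
    occ <- function(cc)
      (cc[["specific_dimer"]] + cc[["secondary_complex"]] +
         cc[["crosslinked_intermediate"]]) / more_t
    c(occ_specific = occ(with_),
      occ_specific_no_ns = occ(none),
      secondary_load = (with_[["secondary_complex"]] +
                          with_[["crosslinked_intermediate"]]) / more_t,
      ns_load = if (ns_t > 0)
        (with_[["nonspecific_complex"]] +
           with_[["crosslinked_intermediate"]]) / ns_t else 0)
  }
  m <- t(vapply(na_grid, row1, numeric(4)))
  out <- data.frame(na_conc = na_grid, m)
  out$delta_occ <- out$occ_specific - out$occ_specific_no_ns

  cross <- NA_real_
  s <- sign(out$delta_occ)
  flip <- which(s[-1] * s[-length(s)] < 0)
  if (length(flip) > 0) {
    i <- flip[1]
    # interpolate the zero of delta_occ in log salt
    x <- log10(na_grid[c(i, i + 1)]); y <- out$delta_occ[c(i, i + 1)]
    cross <- 10^(x[1] - y[1] * diff(x) / diff(y))
  }
  attr(out, "crossover_na") <- cross
  out
}
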