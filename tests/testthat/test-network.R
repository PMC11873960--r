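test_that("k_at_salt implements the linkage power law", {
  t0 <- transition(c(free_protein = 1, ns_free = 1),
                   c(nonspecific_complex = 1), k_ref = 5e3,
                   ref_na = 0.2, dm = 0)
  expect_equal(k_at_salt(t0, 0.02), 5e3)
  t1 <- transition(c(free_protein = 2, more_free = 1),
                   c(specific_dimer = 1), k_ref = 1e15, ref_na = 0.2,
                   dm = -6.8)
  expect_equal(k_at_salt(t1, 2), 1e15 * 10^-6.8)
  t2 <- transition(c(free_protein = 1, ns_free = 1),
                   c(nonspecific_complex = 1), k_ref = 1e4,
                   ref_na = 0.2, dm = 1.5)
  expect_equal(k_at_salt(t2, 0.4), 1e4 * 2^1.5)
  # log10 K linear in log10 na with slope dm
  na <- c(0.1, 0.2, 0.4, 0.8)
  expect_equal(diff(log10(k_at_salt(t1, na))) / diff(log10(na)),
               rep(-6.8, 3))
})

test_that("network assembly rejects element-unbalanced transitions", {
  bad <- transition(c(free_protein = 1), c(specific_dimer = 1),
                    k_ref = 1)
  expect_error(equilibrium_network(list(bad),
                                   totals = c(protein = 1e-6,
                                              more = 1e-9, ns = 0)),
               "conserve")
})

test_that("thermodynamically inconsistent cycles are rejected", {
  mk <- function(k_release, dm_release) {
    list(transition(c(free_protein = 2, more_free = 1),
                    c(specific_dimer = 1), k_ref = 1e15, dm = -6.8),
         transition(c(specific_dimer = 1, free_protein = 1),
                    c(secondary_complex = 1), k_ref = 3e4, dm = 0),
         transition(c(free_protein = 1, ns_free = 1),
                    c(nonspecific_complex = 1), k_ref = 4e3, dm = -9),
         transition(c(specific_dimer = 1, nonspecific_complex = 1),
                    c(crosslinked_intermediate = 1), k_ref = 1e9,
                    dm = 0),
         transition(c(crosslinked_intermediate = 1),
                    c(secondary_complex = 1, ns_free = 1),
                    k_ref = k_release, dm = dm_release))
  }
  totals <- c(protein = 5e-8, more = 5e-9, ns = 5e-4)
  good <- 3e4 / (1e9 * 4e3)
  expect_s3_class(equilibrium_network(mk(good, 9), totals),
                  "equilibrium_network")
  # wrong constant around the loop
  expect_error(equilibrium_network(mk(good * 10, 9), totals),
               "inconsistent cycle")
  # wrong ion stoichiometry around the loop
  expect_error(equilibrium_network(mk(good, 5), totals),
               "inconsistent cycle")
})

test_that("solve_network conserves totals across salts and compositions", {
  net <- default_network()
  for (na in c(0.12, 0.15, 0.2, 0.3, 0.4)) {
    sol <- solve_network(net, na)
    cc <- sol$concentrations
    expect_lte(sol$residual_rel, 1e-10)
    prot <- cc[["free_protein"]] + 2 * cc[["specific_dimer"]] +
      3 * cc[["secondary_complex"]] + cc[["nonspecific_complex"]] +
      3 * cc[["crosslinked_intermediate"]]
    expect_equal(prot, net$totals[["protein"]], tolerance = 1e-10)
    more <- cc[["more_free"]] + cc[["specific_dimer"]] +
      cc[["secondary_complex"]] + cc[["crosslinked_intermediate"]]
    expect_equal(more, net$totals[["more"]], tolerance = 1e-10)
    ns <- cc[["ns_free"]] + cc[["nonspecific_complex"]] +
      cc[["crosslinked_intermediate"]]
    expect_equal(ns, net$totals[["ns"]], tolerance = 1e-10)
    expect_true(all(cc >= 0))
  }
})

test_that("all-zero totals give the empty state", {
  net <- default_network()
  sol <- solve_network(net, 0.2, totals = c(protein = 0, more = 0,
                                            ns = 0))
  expect_true(all(sol$concentrations == 0))
})

test_that("a dimer-only network reduces to the titration mass balance", {
  kd <- 2.9e-8
  net <- equilibrium_network(
    list(transition(c(free_protein = 2, more_free = 1),
                    c(specific_dimer = 1), k_ref = 1 / kd^2,
                    ref_na = 0.2, dm = -6.8)),
    totals = c(protein = 5e-8, more = 5e-9, ns = 0))
  cond <- assay_conditions(probe_total = 5e-9, na_conc = 0.2)
  pars <- binding_parameters(kd = kd, r_specific = 0.08)
  for (ot in c(1e-8, 5e-8, 2e-7)) {
    sol <- solve_network(net, 0.2, totals = c(protein = ot))
    st <- solve_speciation(ot, cond, pars)
    expect_equal(sol$concentrations[["free_protein"]], st$o_free,
                 tolerance = 1e-9)
    expect_equal(sol$concentrations[["specific_dimer"]],
                 st$p_specific, tolerance = 1e-9)
  }
})

test_that("a three-species toy network matches a brute-force grid oracle", {
  # 1e6-point grid minimization of the conservation residual over the
  # two free concentrations (protein, cognate sites)
  net <- equilibrium_network(
    list(transition(c(free_protein = 2, more_free = 1),
                    c(specific_dimer = 1), k_ref = 1e14, dm = 0),
         transition(c(specific_dimer = 1, free_protein = 1),
                    c(secondary_complex = 1), k_ref = 1e5, dm = 0)),
    totals = c(protein = 1e-7, more = 2e-8, ns = 0))
  sol <- solve_network(net, 0.2)

  lo <- 10^seq(log10(1e-7) - 4, log10(1e-7), length.out = 1000)
  ls <- 10^seq(log10(2e-8) - 4, log10(2e-8), length.out = 1000)
  best <- c(Inf, NA, NA)
  for (o in lo) {
    d2 <- 1e14 * o^2 * ls
    d3 <- 1e5 * o * d2
    rp <- abs(o + 2 * d2 + 3 * d3 - 1e-7) / 1e-7
    rs <- abs(ls + d2 + d3 - 2e-8) / 2e-8
    r <- pmax(rp, rs)
    i <- which.min(r)
    if (r[i] < best[1]) best <- c(r[i], o, ls[i])
  }
  # the oracle is grid-limited: agree within one log-grid spacing (~1%)
  expect_equal(sol$concentrations[["free_protein"]], best[2],
               tolerance = 2e-2)
  expect_equal(sol$concentrations[["more_free"]], best[3],
               tolerance = 2e-2)
})

test_that("adding nonspecific sites never increases free protein", {
  net <- default_network()
  for (na in c(0.15, 0.2, 0.3)) {
    f_with <- solve_network(net, na)$concentrations[["free_protein"]]
    f_wo <- solve_network(net, na,
                          totals = c(ns = 0))$concentrations[["free_protein"]]
    expect_lte(f_with, f_wo * (1 + 1e-10))
  }
})

test_that("the default network flips the lattice effect from inhibition to enhancement", {
  net <- default_network()
  scan <- salt_scan(net, 10^seq(log10(0.1), log10(0.4), length.out = 25))
  expect_lt(scan$delta_occ[1], 0)              # low salt: inhibitory
  expect_gt(scan$delta_occ[nrow(scan)], 0)     # high salt: stimulatory
  cross <- attr(scan, "crossover_na")
  expect_true(is.finite(cross))
  expect_gt(cross, 0.1)
  expect_lt(cross, 0.4)
})

test_that("the flip requires salt-linked lattice edges", {
  # with the nonspecific-binding and lattice-release edges stripped of
  # their ion stoichiometry, depletion and bridging scale together at
  # every salt and the lattice effect keeps a single sign
  net <- default_network(dm_ns = 0)
  scan <- salt_scan(net, 10^seq(log10(0.1), log10(0.4), length.out = 25))
  s <- sign(scan$delta_occ[abs(scan$delta_occ) > 1e-12])
  expect_true(all(s == s[1]))
  expect_true(is.na(attr(scan, "crossover_na")))
})

test_that("a JSON network spec reproduces the default scheme", {
  path <- system.file("extdata", "example-network.json",
                      package = "anisobind")
  net <- read_network_json(path)
  ref <- default_network()
  for (na in c(0.15, 0.3)) {
    expect_equal(solve_network(net, na)$concentrations,
                 solve_network(ref, na)$concentrations,
                 tolerance = 1e-6)
  }
  # a cycle-violating edit is rejected at load time
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg$transitions[[5]]$k_ref <- 1e-3
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_network_json(bad), "inconsistent cycle")
})

test_that("with_ns = FALSE zeroes the nonspecific load", {
  net <- default_network()
  scan <- salt_scan(net, c(0.15, 0.2, 0.3), with_ns = FALSE)
  expect_true(all(scan$ns_load == 0))
  expect_equal(scan$occ_specific, scan$occ_specific_no_ns)
})
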