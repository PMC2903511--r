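# Integration engine: oracle equivalence, composition with the tissue
# rate laws, limit behavior, dissipativity and the mass ledger.

test_that("single-state first-order elimination follows exponential decay", {
  body <- tiny_body()
  chem <- chemical_species("X", 100, list(list(compartment = "pool1", scheme = "pool", volume = 1)))
  tr <- list(transport_process("urinary_excretion", "X", source = "pool1", rate = 0.3))
  ex <- list(exposure_profile("X", "oral_bolus", events = list(list(time = 0, amount = 5)),
                              F_abs = 1, target = "pool1"))
  sys <- assemble_system(body, list(chem), transports = tr, exposures = ex)
  res <- simulate_system(sys, 10, report_grid = seq(0, 10, 0.5))
  expect_equal(res$amounts[, 1], 5 * exp(-0.3 * res$time), tolerance = 1e-6)
  # as t -> infinity, excreted -> administered
  res2 <- simulate_system(sys, 100, report_grid = c(0, 100))
  expect_equal(unname(res2$ledger[2, "X|urine"]), 5, tolerance = 1e-6)
})

test_that("random linear fixtures match the matrix-exponential oracle", {
  for (s in 1:5) {
    fix <- generate_linear_fixture(n_states = 3 + s, n_inputs = 2, seed = 100 + s)
    expect_lt(fixture_max_rel_err(fix), 1e-6)
  }
})

test_that("a single perfusion tissue reduces to the perfusion rate law", {
  # assembled 2-state system vs explicit matrix built from the rate-law
  # contract, solved with the matrix exponential
  body <- tiny_body()
  chem <- chemical_species("X", 100, list(list(compartment = "blood", scheme = "blood"),
                                          list(compartment = "liver", scheme = "perfusion", P = 3)))
  sys <- assemble_system(body, list(chem))
  Vb <- 5; Vl <- 2; Q <- 90; P <- 3
  A <- matrix(c(-Q / Vb, Q / Vb,
                Q / (Vl * P), -Q / (Vl * P)), 2, 2)
  y0 <- c(4, 0)
  res <- simulate_system(sys, 3, report_grid = seq(0, 3, 0.25),
                         init = c("X|blood|" = 4))
  for (j in seq_along(res$time)) {
    ref <- drop(as.matrix(Matrix::expm(A * res$time[j])) %*% y0)
    expect_equal(unname(res$amounts[j, c("X|blood|", "X|liver|")]), ref, tolerance = 1e-6)
  }
})

test_that("diffusion-limited solution converges to the perfusion limit as H grows", {
  Q <- 10; VE <- 1; VC <- 4; P <- 2
  mk_body <- function(scheme) {
    comps <- list(compartment("blood", 5, 0, tags = "blood"),
                  if (scheme == "diffusion")
                    compartment("tissue", VE + VC, Q, scheme = "diffusion_limited",
                                subvolumes = c(VE, VC))
                  else compartment("tissue", VE + VC, Q),
                  compartment("bypass", 40, 302))
    body_physiology(comps, cardiac_output = 312, body_mass = 70)
  }
  run_diff <- function(H) {
    chem <- chemical_species("X", 100,
                             list(list(compartment = "blood", scheme = "blood"),
                                  list(compartment = "tissue", scheme = "diffusion", P = P, H = H)))
    sys <- assemble_system(mk_body("diffusion"), list(chem))
    simulate_system(sys, 5, report_grid = seq(0, 5, 0.1), init = c("X|blood|" = 10))
  }
  # perfusion-limited equivalent: whole-tissue volume with effective
  # partition (V_E + V_C P) / (V_E + V_C)
  P_eff <- (VE + VC * P) / (VE + VC)
  chem_p <- chemical_species("X", 100,
                             list(list(compartment = "blood", scheme = "blood"),
                                  list(compartment = "tissue", scheme = "perfusion", P = P_eff)))
  sys_p <- assemble_system(mk_body("perfusion"), list(chem_p))
  ref <- simulate_system(sys_p, 5, report_grid = seq(0, 5, 0.1), init = c("X|blood|" = 10))
  cb_ref <- concentration(ref, "X", "blood")
  sup <- vapply(c(10, 100, 100 * Q), function(H) {
    max(abs(concentration(run_diff(H), "X", "blood") - cb_ref))
  }, numeric(1))
  expect_true(all(diff(sup) < 0))                  # monotone decreasing in H
  expect_lt(sup[3], 0.01 * max(cb_ref))            # < 1% of peak at H = 100 Q
})

test_that("untracked-product metabolism is dissipative and ledgered", {
  body <- tiny_body()
  chem <- chemical_species("X", 100, list(list(compartment = "blood", scheme = "blood"),
                                          list(compartment = "liver", scheme = "perfusion", P = 2)))
  gam <- list(list(tissue = "liver", parent = "X", product = NA, k = 0.4))
  sys <- assemble_system(body, list(chem), reactions = list(gamma = gam))
  res <- simulate_system(sys, 20, report_grid = seq(0, 20, 1), init = c("X|blood|" = 8))
  burden <- body_burden(res, "X")
  expect_true(all(diff(burden) < 0))
  expect_equal(max(res$audit$rel_error), 0, tolerance = 1e-7)
  # everything lost went to the transformation ledger
  expect_equal(unname(res$ledger[nrow(res$ledger), "X|transformed"]), 8 - burden[length(burden)],
               tolerance = 1e-6)
})

test_that("parent-to-metabolite transformation is molar-paired in the ledger", {
  body <- tiny_body()
  par <- chemical_species("P", 100, list(list(compartment = "blood", scheme = "blood")))
  met <- chemical_species("Mt", 80, list(list(compartment = "blood", scheme = "blood")))
  gam <- list(list(tissue = "blood", parent = "P", product = "Mt", k = 0.2))
  sys <- assemble_system(body, list(par, met), reactions = list(gamma = gam))
  res <- simulate_system(sys, 15, report_grid = c(0, 5, 15), init = c("P|blood|" = 3))
  led <- res$ledger[nrow(res$ledger), ]
  expect_gt(led[["P|transformed"]], 0)
  expect_equal(led[["P|transformed"]], -led[["Mt|transformed"]], tolerance = 1e-9)
  expect_true(all(res$audit$ok))
})

test_that("a no-exposure simulation from a zero state stays identically zero", {
  body <- tiny_body()
  chem <- chemical_species("X", 100, list(list(compartment = "blood", scheme = "blood"),
                                          list(compartment = "liver", scheme = "perfusion", P = 2)))
  sys <- assemble_system(body, list(chem))
  res <- simulate_system(sys, 10, report_grid = c(0, 10))
  expect_true(all(res$amounts == 0))
  expect_true(all(res$ledger == 0))
  expect_true(all(res$audit$ok))
})

test_that("unknown references fail assembly with named errors", {
  body <- tiny_body()
  chem <- chemical_species("X", 100, list(list(compartment = "blood", scheme = "blood")))
  expect_error(assemble_system(body, list(chem),
                               reactions = list(gamma = list(
                                 list(tissue = "blood", parent = "Y", product = NA, k = 1)))),
               "not a declared chemical")
  expect_error(assemble_system(body, list(chem),
                               transports = list(transport_process(
                                 "urinary_excretion", "X", source = "nowhere", rate = 1))),
               "unresolved")
  expect_error(assemble_system(body, list(
    chemical_species("X", 100, list(list(compartment = "nosuch", scheme = "perfusion", P = 1))))),
    "not in body")
})
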