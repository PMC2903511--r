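# Tissue-level rate laws, the first-order reaction-network matrix and the
# saturable kinetics primitives.

test_that("perfusion-limited balance: equilibrium, arithmetic, closed-form steady state", {
  expect_equal(perfusion_tissue_rate(C_tissue = 2, C_in = 1, Q = 10, V = 5, P = 2), 0)
  expect_equal(perfusion_tissue_rate(C_tissue = 0, C_in = 1, Q = 10, V = 5, P = 2), 2)

  # constant infusion R0 into blood with urinary clearance CL:
  # steady state C_blood = R0 / CL
  R0 <- 3; CL <- 6
  body <- tiny_body()
  chem <- chemical_species("X", 100, list(list(compartment = "blood", scheme = "blood"),
                                          list(compartment = "liver", scheme = "perfusion", P = 2)))
  tr <- list(transport_process("urinary_excretion", "X", source = "blood", clearance = CL))
  ex <- list(exposure_profile("X", "oral_continuous",
                              events = list(list(start = 0, end = Inf, magnitude = R0)),
                              F_abs = 1, target = "blood"))
  sys <- assemble_system(body, list(chem), transports = tr, exposures = ex)
  res <- simulate_system(sys, 100, report_grid = c(0, 50, 100))
  expect_equal(concentration(res, "X", "blood")[3], R0 / CL, tolerance = 1e-6)
})

test_that("permeation rate: equilibrium, magnitude, antisymmetry, conventions", {
  expect_equal(permeation_rate(C_E = 1, C_C = 2, H = 5, P = 2), 0)
  expect_equal(permeation_rate(C_E = 1, C_C = 0, H = 2, P = 2), 2)
  expect_lt(permeation_rate(C_E = 1, C_C = 4, H = 2, P = 2), 0)
  expect_equal(permeation_rate(C_E = 2, C_C = 1, H = 3, P = 2,
                               convention = "extracellular_partitioned"), 0)
})

test_that("diffusion-limited balances conserve the internal flux and freeze at H = 0", {
  r <- diffusion_tissue_rates(C_E = 1, C_C = 0.2, C_in = 2, Q = 10,
                              V_E = 1, V_C = 4, H = 3, P = 2)
  # total tissue mass rate = Q (C_in - C_E): permeation cancels internally
  expect_equal(r[["dC_E"]] * 1 + r[["dC_C"]] * 4, 10 * (2 - 1))
  r0 <- diffusion_tissue_rates(C_E = 1, C_C = 0.2, C_in = 2, Q = 10,
                               V_E = 1, V_C = 4, H = 0, P = 2)
  expect_equal(r0[["dC_C"]], 0)
})

test_that("gamma matrix follows the net rate-constant convention", {
  G <- build_gamma_matrix(list(list(parent = "A", product = "B", k = 0.5)),
                          species = c("A", "B"))
  expect_equal(unname(G), matrix(c(0.5, -0.5, 0, 0), 2, 2))

  # all-tracked network: every column sums to zero for any concentrations
  G2 <- build_gamma_matrix(list(
    list(parent = "A", product = "B", k = 1),
    list(parent = "B", product = "C", k = 2),
    list(parent = "C", product = "A", k = 0.3)), species = c("A", "B", "C"))
  expect_equal(unname(colSums(G2)), c(0, 0, 0))
  y <- c(0.4, 1.2, 7)
  expect_equal(sum(first_order_metabolic_rates(G2, y)), 0)
  expect_equal(first_order_metabolic_rates(G, c(2, 0)), c(A = 1, B = -1))
  expect_equal(first_order_metabolic_rates(G, c(0, 0)), c(A = 0, B = 0))

  expect_error(build_gamma_matrix(list(list(parent = "Z", product = "B", k = 1)),
                                  species = c("A", "B")), "unknown species")
  expect_error(first_order_metabolic_rates(G, c(1, 2, 3)), "dimension")
})

test_that("decay chain matches the matrix-exponential solution", {
  # A -> B -> C, k1 = 1, k2 = 2, bolus of A: Bateman kinetics
  G <- build_gamma_matrix(list(list(parent = "A", product = "B", k = 1),
                               list(parent = "B", product = "C", k = 2)),
                          species = c("A", "B", "C"))
  y0 <- c(1, 0, 0)
  for (t in c(0.3, 1, 2.5)) {
    oracle <- drop(as.matrix(Matrix::expm(-G * t)) %*% y0)
    bateman <- c(exp(-t), 1 / (2 - 1) * (exp(-t) - exp(-2 * t)),
                 1 - exp(-t) - (exp(-t) - exp(-2 * t)))
    expect_equal(unname(oracle), bateman, tolerance = 1e-12)
  }
})

test_that("saturable kinetics: half-saturation, competitive inhibition, reductions", {
  rxn <- mm_reaction("liver", "i", V_max = 10, K_m = 4)
  expect_equal(mm_metabolic_rate("i", c(i = 4), rxn), 5)

  rxn_i <- mm_reaction("liver", "i", V_max = 10, K_m = 4, competitive = c(k = 2))
  # C_k = I and C_i = K_m: v = Vmax/3
  expect_equal(mm_metabolic_rate("i", c(i = 4, k = 2), rxn_i), 10 / 3)
  # zero inhibitor concentration: plain Michaelis-Menten
  expect_equal(mm_metabolic_rate("i", c(i = 4, k = 0), rxn_i),
               mm_metabolic_rate("i", c(i = 4), rxn))

  # C << K_m: agrees with first-order k = Vmax/(Km V) within 1%
  V_liv <- 2; Ci <- 4e-3
  first_order <- rxn$V_max / (rxn$K_m * V_liv) * Ci * V_liv
  expect_equal(mm_metabolic_rate("i", c(i = Ci), rxn), first_order, tolerance = 0.01)
})

test_that("effective V_max modifiers: identities, clamping, order independence", {
  expect_equal(effective_vmax(7), 7)
  expect_equal(effective_vmax(10, list(list(kind = "noncompetitive", conc = 3, K = 3))), 5)
  expect_equal(effective_vmax(10, list(list(kind = "induction", factor = 0.5))), 15)
  expect_equal(effective_vmax(10, list(list(kind = "interaction", effect = 1.7))), 0)
  mods <- list(list(kind = "noncompetitive", conc = 1, K = 2),
               list(kind = "induction", factor = 0.3),
               list(kind = "interaction", effect = 0.4))
  expect_equal(effective_vmax(10, mods), effective_vmax(10, rev(mods)))
})
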