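# Chemical-specific model builders: structure audits and qualitative
# kinetic behavior of each configured model.

test_that("cadmium network is linear and accumulates without a 30-year plateau", {
  cd <- build_cadmium_model()
  run_cd <- function(ug_day, t_end = 30 * 8766, grid = 30) {
    sys <- assemble_model(cd, exposures = list(dietary_profile(cd, "cadmium", ug_day)))
    simulate_system(sys, t_end, report_grid = seq(0, t_end, length.out = grid))
  }
  r1 <- run_cd(15); r2 <- run_cd(30)
  k1 <- concentration(r1, "cadmium", "kidney")
  k2 <- concentration(r2, "cadmium", "kidney")
  expect_equal(k2[-1] / k1[-1], rep(2, length(k1) - 1), tolerance = 1e-6)
  # kidney burden still rising after 30 years of constant intake
  expect_true(all(diff(k1) > 0))
  expect_true(all(r1$audit$ok))
  # zero intake from a zero state stays zero
  sys0 <- assemble_model(cd, exposures = list())
  r0 <- simulate_system(sys0, 100, report_grid = c(0, 100))
  expect_true(all(r0$amounts == 0))
  # female absorbed fraction is the higher one
  expect_gt(build_cadmium_model(sex = "female")$dose_hooks$cadmium$F_abs,
            cd$dose_hooks$cadmium$F_abs)
})

test_that("arsenic network has the six canonical pathways and no demethylation", {
  as_m <- build_arsenic_model()
  gam <- as_m$reactions$gamma
  mm <- as_m$reactions$mm
  edge <- function(p, q) list(parent = p, product = q)
  edges <- c(lapply(gam, function(g) edge(g$parent, g$product)),
             lapply(mm, function(r) edge(r$substrate, r$product)))
  lab <- vapply(edges, function(e) paste(e$parent, e$product, sep = ">"), character(1))
  # the six metabolic steps
  expect_true(all(c("as5>as3", "as3>mma5", "as3>dma5",
                    "mma5>mma3", "mma3>dma5", "dma5>dma3") %in% lab))
  # oxidation back-reactions for every trivalent species
  expect_true(all(c("as3>as5", "mma3>mma5", "dma3>dma5") %in% lab))
  expect_length(lab, 9)
  # no demethylation: no edge from a methylated to a less-methylated family
  family <- function(x) ifelse(grepl("^as", x), 0L, ifelse(grepl("^mma", x), 1L, 2L))
  for (e in edges) expect_gte(family(e$product), family(e$parent))
  # steps 2 and 5 carry the noncompetitive inhibitors
  by_name <- setNames(mm, vapply(mm, `[[`, character(1), "name"))
  m2 <- by_name[["as3_methylation_mma"]]$modifiers[[1]]
  expect_equal(list(m2$chemical, m2$compartment), list("mma3", "liver"))
  m5 <- by_name[["mma3_methylation_dma"]]$modifiers[[1]]
  expect_equal(list(m5$chemical, m5$compartment), list("as3", "liver"))
})

test_that("arsenic elimination is exclusively urinary and balances intake at steady state", {
  as_m <- build_arsenic_model()
  kinds <- vapply(as_m$transports, `[[`, character(1), "kind")
  expect_true(all(kinds == "urinary_excretion"))
  sys <- assemble_model(as_m, exposures = list(dietary_profile(as_m, "as5", 100)))
  res <- simulate_system(sys, 2000, report_grid = seq(0, 2000, 100))
  n <- nrow(res$ledger)
  urine_cols <- grep("\\|urine$", colnames(res$ledger), value = TRUE)
  rate_out <- sum(res$ledger[n, urine_cols] - res$ledger[n - 1, urine_cols]) /
    (res$time[n] - res$time[n - 1])
  rate_in <- 0.95 * convert_dose(100, "ug/day", 74.92)   # absorbed fraction
  expect_equal(rate_out, rate_in, tolerance = 0.01)
  expect_true(all(res$audit$ok))
})

test_that("stronger noncompetitive inhibition of the first methylation lowers the urinary methylated fraction", {
  frac_methylated <- function(K_nc) {
    m <- build_arsenic_model(params = list(metabolism = list(step2_methylation = list(
      V_max = 30, K_m = 10, K_nc_by_mma3 = K_nc))))
    sys <- assemble_model(m, exposures = list(dietary_profile(m, "as5", 100)))
    res <- simulate_system(sys, 1500, report_grid = c(0, 750, 1500))
    led <- res$ledger[nrow(res$ledger), ]
    meth <- sum(led[paste0(c("mma5", "mma3", "dma5", "dma3"), "|urine")])
    meth / sum(led[paste0(c("as5", "as3", "mma5", "mma3", "dma5", "dma3"), "|urine")])
  }
  f <- vapply(c(20, 4, 0.5), frac_methylated, numeric(1))  # decreasing K_nc = stronger effect
  expect_true(all(diff(f) < 0))
})

test_that("the cortical-shell subsystem conserves mass and has a discrete-Laplacian null state", {
  pb <- build_lead_model(params = list(bone = list(cortical_uptake_k = 0, cortical_return_k = 0,
                                                   trabecular_uptake_k = 0, trabecular_return_k = 0)))
  shells <- grep("bone_cort", pb$bone_states, value = TRUE)
  expect_length(shells, 8)
  sys <- assemble_model(pb, exposures = list())
  lay <- sys$layout
  vols <- lay$volume[match(paste0("lead|", shells, "|"), lay$key)]
  # equal-thickness annuli: volumes proportional to the odd numbers
  expect_equal(vols / vols[1], (2 * (1:8) - 1), tolerance = 1e-12)
  # non-uniform load, blood exchange disabled: total shell mass conserved
  init <- setNames(c(1, rep(0, 7)), paste0("lead|", shells, "|"))
  res <- simulate_system(sys, 5000, report_grid = seq(0, 5000, 500), init = init)
  shell_tot <- rowSums(res$amounts[, paste0("lead|", shells, "|")])
  expect_equal(shell_tot, rep(1, length(shell_tot)), tolerance = 1e-7)
  # uniform concentration: zero net internal flux
  init_u <- setNames(vols / sum(vols), paste0("lead|", shells, "|"))
  res_u <- simulate_system(sys, 1000, report_grid = c(0, 1000), init = init_u)
  expect_equal(res_u$amounts[2, paste0("lead|", shells, "|")],
               res_u$amounts[1, paste0("lead|", shells, "|")], tolerance = 1e-8)
})

test_that("chronic lead exposure puts the body burden predominantly in bone", {
  res <- run_scenario(system.file("extdata", "scenario_lead_chronic.yaml",
                                  package = "pbtkmix"))
  n <- nrow(res$amounts)
  bone <- grepl("bone", res$layout$compartment)
  frac <- sum(res$amounts[n, bone]) / sum(res$amounts[n, ])
  expect_gt(frac, 0.90)
  expect_true(all(res$audit$ok))
})

test_that("hexavalent chromium vanishes from blood quickly while total chromium balances", {
  res <- run_scenario(system.file("extdata", "scenario_chromium_bolus.yaml",
                                  package = "pbtkmix"))
  cr6 <- res$amounts[, "cr6|blood|"]
  peak <- max(cr6)
  t_cr3_scale <- 1 / 0.08                      # Cr(III) elimination timescale (h)
  fast <- res$time[min(which(cr6 < 0.01 * peak & res$time > 0))]
  expect_lt(fast, 0.2 * t_cr3_scale)
  urine3 <- res$ledger[, "cr3|urine"]
  expect_true(all(diff(urine3) >= 0))
  expect_true(all(res$audit$ok))
})

test_that("methylmercury routes: hair is first-order on blood, conservation without demethylation", {
  hg <- build_mehg_model()
  sys <- assemble_model(hg, exposures = list(dietary_profile(hg, "mehg", 40)))
  res <- simulate_system(sys, 2400, report_grid = seq(0, 2400, 24))
  # hair ledger accumulates proportionally to the integrated blood amount
  blood <- res$amounts[, "mehg|blood|"]
  dt <- diff(res$time)
  integ <- cumsum(c(0, (head(blood, -1) + tail(blood, -1)) / 2 * dt))
  hair <- res$ledger[, "mehg|hair"]
  expect_equal(hair, 2e-4 * integ, tolerance = 1e-3)
  # with demethylation off, methylmercury closes without transformation
  hg0 <- build_mehg_model(params = list(demethylation_k = 0))
  sys0 <- assemble_model(hg0, exposures = list(dietary_profile(hg0, "mehg", 40)))
  res0 <- simulate_system(sys0, 1200, report_grid = c(0, 600, 1200))
  led <- res0$ledger[3, ]
  expect_equal(led[["mehg|transformed"]], 0, tolerance = 1e-9)
  expect_true(all(res0$audit$ok))
})

test_that("the pregnancy subsystem lets fetal blood exceed maternal blood", {
  hg <- build_mehg_model(pregnancy = TRUE)
  sys <- assemble_model(hg, exposures = list(dietary_profile(hg, "mehg", 40 * 70)))
  res <- simulate_system(sys, 2592, report_grid = seq(0, 2592, 48))  # 108 days
  cf <- concentration(res, "mehg", "fetal")
  cm <- concentration(res, "mehg", "blood")
  expect_true(any(cf > cm))
  expect_true(all(res$audit$ok))
  # flag without parameters fails
  expect_error(build_mehg_model(pregnancy = TRUE, params = list(pregnancy = NULL)),
               "fetal parameters")
})

test_that("benzene/toluene co-exposure raises benzene through competitive inhibition", {
  steady_liver <- function(model, profs) {
    sys <- assemble_model(model, exposures = profs)
    res <- simulate_system(sys, 300, report_grid = c(0, 150, 300))
    tail(concentration(res, "benzene", "liver"), 1)
  }
  voc <- build_voc_model()
  alone <- steady_liver(voc, list(inhalation_profile(voc, "benzene", 10)))
  both <- steady_liver(voc, list(inhalation_profile(voc, "benzene", 10),
                                 inhalation_profile(voc, "toluene", 20)))
  expect_gt(both, alone)
  # infinite inhibition constants recover single-chemical kinetics
  voc_inf <- build_voc_model(params = list(mutual_inhibition = list(
    I_toluene_on_benzene = 1e12, I_benzene_on_toluene = 1e12)))
  both_inf <- steady_liver(voc_inf, list(inhalation_profile(voc_inf, "benzene", 10),
                                         inhalation_profile(voc_inf, "toluene", 20)))
  expect_equal(both_inf, alone, tolerance = 1e-6)
})

test_that("every builder shares one body and passes a smoke-test audit", {
  body <- reference_adult()
  models <- list(build_cadmium_model(body = body), build_lead_model(body = body),
                 build_chromium_model(body = body), build_mehg_model(body = body),
                 build_arsenic_model(body = body), build_voc_model(body = body))
  for (m in models) expect_equal(m$body$cardiac_output, body$cardiac_output)
  joint <- combine_models_with_hooks(models[-3], name = "smoke")  # chromium dosed separately
  expo <- list(dietary_profile(joint, "cadmium", 15),
               dietary_profile(joint, "lead", 70),
               dietary_profile(joint, "mehg", 40),
               dietary_profile(joint, "as5", 100),
               inhalation_profile(joint, "benzene", 10),
               inhalation_profile(joint, "toluene", 20))
  sys <- assemble_model(joint, exposures = expo)
  res <- simulate_system(sys, 240, report_grid = seq(0, 240, 24))
  expect_true(all(res$audit$ok))
})

test_that("a lead tracer follows stable-lead kinetics independently", {
  pb <- add_lead_tracer(build_lead_model())
  expo <- list(dietary_profile(pb, "lead", 70),
               dietary_profile(pb, "lead204", 17.5))
  sys <- assemble_model(pb, exposures = expo)
  res <- simulate_system(sys, 2496, report_grid = seq(0, 2496, 104))  # 104 days
  # identical kinetics: tracer trajectories are the stable ones scaled by dose
  ratio <- res$amounts[-1, "lead204|plasma|"] / res$amounts[-1, "lead|plasma|"]
  expect_equal(ratio, rep(17.5 / 70, length(ratio)), tolerance = 1e-6)
})
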