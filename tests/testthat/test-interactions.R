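# Mixture-interaction layer: registration, the lagged exposure-response
# effect, nullity and the metal-step response of the case study.

test_that("registering and removing interactions round-trips the system", {
  voc <- build_voc_model(mutual_inhibition = FALSE)
  expo <- list(inhalation_profile(voc, "benzene", 10),
               inhalation_profile(voc, "toluene", 20))
  base <- assemble_model(voc, exposures = expo)
  spec <- interaction_spec("competitive", targets = "benzene_oxidation",
                           chemical = "toluene", I = 7, name = "tol_on_benz")
  with_ia <- register_interaction(base, spec)
  # the competitive term lands in the Eq-5 denominator of the target
  r <- with_ia$mm[[1]]
  expect_equal(r$inh_I, 7)
  expect_equal(with_ia$layout$chemical[r$inh_idx], "toluene")
  restored <- remove_interaction(with_ia, "tol_on_benz")
  expect_equal(restored$M, base$M)
  expect_length(restored$mm[[1]]$inh_idx, 0)
  # registering zero specs leaves trajectories bit-identical
  res_a <- simulate_system(base, 50, report_grid = seq(0, 50, 10))
  res_b <- simulate_system(restored, 50, report_grid = seq(0, 50, 10))
  expect_identical(res_a$amounts, res_b$amounts)
  expect_error(register_interaction(base, interaction_spec(
    "competitive", targets = "nosuch_rxn", chemical = "toluene", I = 7)),
    "no target reaction")
})

test_that("mutual competitive specs produce the two-inhibitor denominator", {
  voc <- build_voc_model(mutual_inhibition = FALSE)
  base <- assemble_model(voc)
  s1 <- interaction_spec("competitive", targets = "benzene_oxidation",
                         chemical = "toluene", I = 7, name = "a")
  s2 <- interaction_spec("competitive", targets = "toluene_oxidation",
                         chemical = "benzene", I = 5, name = "b")
  sys <- register_interaction(register_interaction(base, s1), s2)
  wired <- build_voc_model(mutual_inhibition = TRUE)
  ref <- assemble_model(wired)
  for (i in 1:2) {
    expect_equal(sys$mm[[i]]$inh_I, ref$mm[[i]]$inh_I)
    expect_equal(sys$mm[[i]]$inh_idx, ref$mm[[i]]$inh_idx)
  }
})

test_that("the lagged effect relaxes to the weighted linear response", {
  expect_equal(effect_derivative(E = 0.3, liver_concentrations = c(1, 2),
                                 weights = c(0.1, 0.1), tau = 24),
               (0.3 - 0.3) / 24)
  expect_equal(effect_derivative(0, c(2, 4), c(0.5, 0.25), 10), 0.2)
  expect_error(effect_derivative(0, 1, 1, tau = 0), "tau")
  # equal-contribution weighting: each source contributes E_total / n
  w <- equal_contribution_weights(c(a = 0.01, b = 10), E_total = 0.3)
  expect_equal(unname(w * c(0.01, 10)), c(0.15, 0.15))
})

test_that("with all interaction parameters zero the joint simulation equals the singles", {
  body <- reference_adult()
  models <- list(cadmium = build_cadmium_model(body = body),
                 mehg = build_mehg_model(body = body),
                 lead = build_lead_model(body = body),
                 arsenic = build_arsenic_model(body = body),
                 voc = build_voc_model(mutual_inhibition = FALSE, body = body))
  joint <- combine_models_with_hooks(models, name = "joint")
  profs <- list(cadmium = dietary_profile(joint, "cadmium", 15),
                mehg = dietary_profile(joint, "mehg", 40),
                lead = dietary_profile(joint, "lead", 70),
                arsenic = dietary_profile(joint, "as5", 100),
                benzene = inhalation_profile(joint, "benzene", 10),
                toluene = inhalation_profile(joint, "toluene", 20))
  grid <- seq(0, 240, 24)
  run <- function(model, expos) {
    sys <- assemble_model(model, exposures = expos)
    simulate_system(sys, 240, report_grid = grid, rtol = 1e-11, atol = 1e-16)
  }
  res_joint <- run(joint, unname(profs))
  singles <- list(run(models$cadmium, profs["cadmium"]),
                  run(models$mehg, profs["mehg"]),
                  run(models$lead, profs["lead"]),
                  run(models$arsenic, profs["arsenic"]),
                  run(models$voc, profs[c("benzene", "toluene")]))
  for (s in singles) expect_lt(max_rel_deviation(res_joint, s), 1e-9)
})

test_that("positive interaction weights raise benzene after the metal intake step", {
  mx <- mixture_cached()
  base <- mx$results$base
  v1 <- mx$results$variant_x1
  t <- base$time
  i_step <- which.min(abs(t - mx$config$step_day * 24))
  cb <- concentration(base, "benzene", "liver")
  cv <- concentration(v1, "benzene", "liver")
  # base case: benzene unaffected by the day-500 metal step
  expect_equal(cb[length(cb)], cb[i_step], tolerance = 1e-6)
  # interaction variant: strictly increasing after the step
  post <- cv[t >= mx$config$step_day * 24 + 48]
  expect_true(all(diff(post) > 0) || (tail(post, 1) - post[1]) / post[1] > 0.01)
  expect_gt(tail(cv, 1), cv[i_step])
  # the effect level stays bounded by the running maximum weighted response
  metals <- rbind(cadmium = concentration(v1, "cadmium", "liver"),
                  lead = concentration(v1, "lead", "liver"),
                  mehg = concentration(v1, "mehg", "liver"))
  as_conc <- Reduce(`+`, lapply(c("as5", "as3", "mma5", "mma3", "dma5", "dma3"),
                                function(s) concentration(v1, s, "liver")))
  wsum <- mx$weights[["cadmium"]] * metals["cadmium", ] +
    mx$weights[["lead"]] * metals["lead", ] +
    mx$weights[["mehg"]] * metals["mehg", ] +
    mx$weights[["arsenic_total"]] * as_conc
  expect_lte(max(v1$effects[, 1]), max(wsum) * (1 + 1e-6))
  # interactions modify rates, never the ledgers: both runs conserve mass
  expect_true(all(base$audit$ok))
  expect_true(all(v1$audit$ok))
})

test_that("benzene steady-state increase is monotone in the common weight scale", {
  mx <- mixture_cached()
  base <- mx$results$base
  cfg <- mx$config
  # sweep small weight multipliers on a shorter horizon for speed
  models <- pbtkmix:::mixture_models()
  joint <- combine_models_with_hooks(models, name = "sweep")
  expo <- pbtkmix:::mixture_exposures(joint, cfg)
  sources <- lapply(names(mx$weights)[1:3], function(m)
    list(chemical = m, compartment = "liver", weight = mx$weights[[m]]))
  end_benzene <- vapply(c(0.5, 1, 2), function(mult) {
    spec <- interaction_spec("metal_vmax_modulation",
                             targets = c("benzene_oxidation", "toluene_oxidation"),
                             sources = lapply(sources, function(s) {
                               s$weight <- s$weight * mult; s }),
                             tau = cfg$tau_h, name = "sweep")
    sys <- assemble_model(joint, exposures = expo, interactions = list(spec))
    res <- simulate_system(sys, 2400, report_grid = c(0, 1200, 2400))
    tail(concentration(res, "benzene", "liver"), 1)
  }, numeric(1))
  expect_true(all(diff(end_benzene) > 0))
})
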