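# scenario behaviour on the 2-species toy (cheap) and, where the claim is
# about the study design, the full 6-species toy

test_that("glucose is fully absorbed only when GLUT2 is apical", {
  m <- build_toy_model(small_toy_spec())
  d <- toy_diet(10)
  A <- conversion_factor()
  glc_supply <- d$nutrient_intakes[["glc"]] * A
  na_supply <- d$nutrient_intakes[["na"]] * A
  with_g2 <- glucose_transport_scenario(m, d, apical_glut2 = TRUE)
  without <- glucose_transport_scenario(m, d, apical_glut2 = FALSE)
  expect_equal(with_g2$outputs$max_apical_absorption_glucose, glc_supply,
               tolerance = 1e-8)
  # Na+-limited without apical GLUT2: supply / stoichiometry
  expect_equal(without$outputs$max_apical_absorption_glucose, na_supply / 2,
               tolerance = 1e-8)
  expect_lt(without$outputs$max_apical_absorption_glucose, 0.05 * glc_supply)
  # relaxation property: adding apical GLUT2 can only help
  for (o in names(with_g2$outputs))
    expect_gte(with_g2$outputs[[o]] + 1e-9, without$outputs[[o]])
})

test_that("fructose secretion equals fructose absorption in both settings", {
  m <- build_toy_model(small_toy_spec())
  d <- toy_diet(20)
  for (g2 in c(TRUE, FALSE)) {
    sc <- glucose_transport_scenario(m, d, g2)
    expect_equal(sc$outputs$max_basolateral_secretion_fructose,
                 sc$outputs$max_apical_absorption_fructose,
                 tolerance = 1e-8)
  }
})

test_that("a carbohydrate-free diet supports no glucose absorption", {
  m <- build_toy_model(small_toy_spec())
  d <- diet_composition("nocarb", c(glc = 0, fru = 0, na = 3e-4,
                                    gln = 1e-4),
                        nutrient_class = c(glc = "carbohydrate",
                                           fru = "carbohydrate",
                                           na = "mineral",
                                           gln = "amino_acid"))
  sc <- glucose_transport_scenario(m, d, apical_glut2 = TRUE)
  expect_equal(sc$outputs$max_apical_absorption_glucose, 0)
})

test_that("Na+ titration rises at slope 1/sigma then plateaus; flat with GLUT2", {
  m <- build_toy_model(small_toy_spec())
  d <- toy_diet(10)
  A <- conversion_factor()
  glc_supply <- d$nutrient_intakes[["glc"]] * A
  sc <- sodium_titration_scenario(m, d, apical_glut2 = FALSE)
  v <- sc$curves$objective_values
  na <- sc$curves$parameter_values
  expect_equal(v, pmin(na / 2, glc_supply), tolerance = 1e-6)
  expect_true(all(diff(v) >= -1e-9))
  # the refined Na+ requirement is the stoichiometric one
  expect_equal(sc$outputs$na_required, 2 * glc_supply * 0.999,
               tolerance = 1e-3)
  # dietary Na+ is more than 10-fold short of the requirement
  expect_gt(sc$outputs$na_required_over_dietary, 10)
  flat <- sodium_titration_scenario(m, d, apical_glut2 = TRUE)
  expect_equal(max(flat$curves$objective_values) -
                 min(flat$curves$objective_values), 0, tolerance = 1e-8)
  expect_equal(flat$curves$objective_values[1], glc_supply, tolerance = 1e-8)
})

test_that("gluconeogenic surplus exists, traces to glutamine, needs the pathway", {
  m <- build_toy_model(small_toy_spec())
  d <- toy_diet(10)
  sc <- gluconeogenesis_scenario(m, d, apical_glut2 = TRUE)
  expect_gt(sc$outputs$gluconeogenic_surplus, 0)
  abl <- sc$tables$ablation
  expect_setequal(abl$nutrient, c("gln", "ala", "leu", "lys", "pro"))
  expect_equal(abl$surplus_without[abl$nutrient == "gln"], 0,
               tolerance = 1e-8)
  others <- abl$surplus_without[abl$nutrient != "gln"]
  expect_true(all(abs(others - sc$outputs$gluconeogenic_surplus) < 1e-8))
  # surplus is larger with apical GLUT2 (no Na+-pumping fuel cost)
  sc0 <- gluconeogenesis_scenario(m, d, apical_glut2 = FALSE)
  expect_gt(sc0$outputs$gluconeogenic_surplus, 0)
  expect_gt(sc$outputs$gluconeogenic_surplus,
            sc0$outputs$gluconeogenic_surplus)
  # without the pathway there is no surplus
  m_no <- build_toy_model(small_toy_spec(include_gluconeogenesis = FALSE))
  sc_no <- gluconeogenesis_scenario(m_no, d, apical_glut2 = TRUE)
  expect_equal(sc_no$outputs$gluconeogenic_surplus, 0, tolerance = 1e-8)
  # a diet without amino acids has no surplus either
  d0 <- d
  d0$nutrient_intakes[names(d0$nutrient_class)[
    d0$nutrient_class == "amino_acid"]] <- 0
  sc_d0 <- gluconeogenesis_scenario(m, d0, apical_glut2 = TRUE)
  expect_equal(sc_d0$outputs$gluconeogenic_surplus, 0, tolerance = 1e-8)
})

test_that("chylomicron secretion requires a cholesterol source", {
  m <- build_toy_model(small_toy_spec())
  d <- toy_diet(45)
  none <- chylomicron_oxygen_scenario(m, d, "none")
  expect_equal(none$outputs$max_secretion, 0, tolerance = 1e-9)
  lum <- chylomicron_oxygen_scenario(m, d, "luminal")
  expect_gt(lum$outputs$max_secretion, 0)
  bio <- chylomicron_oxygen_scenario(m, d, "biosynthesis")
  expect_gt(bio$outputs$max_secretion, 0)
  expect_gt(bio$outputs$min_o2_flux, 0)
})

test_that("minimal oxygen equals the hand stoichiometric account", {
  spec <- small_toy_spec()
  m <- build_toy_model(spec)
  d <- toy_diet(30)
  bio <- chylomicron_oxygen_scenario(m, d, "biosynthesis")
  # hand accounting on the toy stoichiometry:
  # particles are limited by dietary TAG; each particle consumes
  # tag_total pooled TAG plus ce_coef acyl chains for cholesteryl esters,
  # the latter freed by hydrolyzing extra TAG (2 FFA per TAG, MAG wasted)
  sp <- spec$fa_species
  prof <- chylomicron_profile(setNames(rep(1 / nrow(sp), nrow(sp)), sp$code))
  asm <- build_chylomicron_assembly(prof, flexible_fa = TRUE)
  cf <- asm$coefficients
  A <- conversion_factor()
  tag_supply <- sum(d$nutrient_intakes[paste0("tag", sp$token)]) * A
  particles <- tag_supply / (cf$tag_total + cf$cholesterol_ester / 2)
  expect_equal(bio$outputs$max_secretion, particles, tolerance = 1e-6)
  # ATP demand per particle: 2 activations x 2 ATP per pooled TAG,
  # (2 ATP activation + declared cholesterol cost) per cholesteryl ester,
  # plus the phospholipid and apoprotein supply costs
  atp_per_particle <- 4 * cf$tag_total +
    cf$cholesterol_ester * (2 + spec$atp_per_cholesterol) +
    cf$phospholipid * spec$atp_per_phospholipid +
    cf$apoprotein * spec$atp_per_apoprotein
  # cheapest ATP: glucose -> 2 pyruvate -> full oxidation;
  # 2 + 10 * P:O ATP per glucose at 5 O2 per glucose
  o2_per_atp <- 5 / (2 + 10 * spec$p_to_o_yield)
  # tolerance covers the stage-2 equality band of the two-stage LP
  expect_equal(bio$outputs$min_o2_flux,
               particles * atp_per_particle * o2_per_atp,
               tolerance = 1e-5)
  # unit conversion back to moles per mouse per day
  expect_equal(bio$outputs$min_o2_mol_per_day,
               bio$outputs$min_o2_flux / A, tolerance = 1e-12)
})

test_that("more oxygen never hurts, and fatter diets need more oxygen", {
  m <- build_toy_model(small_toy_spec())
  d <- toy_diet(20)
  cm <- chylomicron_task_model(m, d, "biosynthesis")
  o2_caps <- c(0, 1e-3, 1e-2, 1)
  sec <- vapply(o2_caps, function(cap) {
    max_flux(set_reaction_bounds(cm, "EX_o2_e", lower = -cap), "EX_cm_e")
  }, numeric(1))
  expect_true(all(diff(sec) >= -1e-9))
  o2_min <- vapply(c(10, 20, 30, 45), function(fat) {
    chylomicron_oxygen_scenario(m, toy_diet(fat),
                                "biosynthesis")$outputs$min_o2_mol_per_day
  }, numeric(1))
  expect_true(all(diff(o2_min) > 0))
})

test_that("scenario outputs scale linearly while no other constraint binds", {
  m <- build_toy_model(small_toy_spec())
  d1 <- toy_diet(20, kcal = 12)
  d2 <- toy_diet(20, kcal = 24)
  s1 <- glucose_transport_scenario(m, d1, TRUE)
  s2 <- glucose_transport_scenario(m, d2, TRUE)
  for (o in names(s1$outputs))
    expect_equal(s2$outputs[[o]], 2 * s1$outputs[[o]], tolerance = 1e-8)
  c1 <- chylomicron_oxygen_scenario(m, d1, "biosynthesis")
  c2 <- chylomicron_oxygen_scenario(m, d2, "biosynthesis")
  expect_equal(c2$outputs$max_secretion, 2 * c1$outputs$max_secretion,
               tolerance = 1e-8)
  expect_equal(c2$outputs$min_o2_flux, 2 * c1$outputs$min_o2_flux,
               tolerance = 1e-6)
})

test_that("missing transporter configuration raises a configuration error", {
  m <- build_toy_model(small_toy_spec(include_apical_glut2 = FALSE))
  d <- toy_diet(10)
  expect_error(glucose_transport_scenario(m, d, apical_glut2 = TRUE),
               "configuration error")
  # absent reaction is fine when the setting does not need it
  sc <- glucose_transport_scenario(m, d, apical_glut2 = FALSE)
  expect_gt(sc$outputs$max_apical_absorption_glucose, 0)
})
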