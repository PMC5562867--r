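test_that("per-species reaction templates give the documented counts", {
  full <- generate_lipid_reactions(fatty_acid_species())
  expect_equal(unname(full$category_counts[c("absorption", "resynthesis",
                                             "cholesteryl_ester")]),
               c(18L, 36L, 6L))
  expect_equal(unname(full$category_counts["hydrolysis"]), 6L)
  one <- generate_lipid_reactions(fatty_acid_species("C16:0"))
  expect_equal(unname(one$category_counts[c("absorption", "resynthesis",
                                            "cholesteryl_ester")]),
               c(3L, 6L, 1L))
  # count law for arbitrary species subsets
  for (n in 2:5) {
    sub <- generate_lipid_reactions(fatty_acid_species()[seq_len(n), ])
    expect_equal(unname(sub$category_counts[c("absorption", "resynthesis",
                                              "cholesteryl_ester")]),
                 c(3L * n, 6L * n, n))
    expect_equal(sum(sub$category_counts), length(sub$reactions))
  }
})

test_that("degenerate and malformed species lists are rejected", {
  expect_error(generate_lipid_reactions(fatty_acid_species()[0, ]),
               "non-empty")
  expect_error(fatty_acid_species(c("C16:0", "C16:0")), "duplicate")
  expect_error(fatty_acid_species("C20:4"), "unknown fatty acid")
})

test_that("generated reactions conserve carbon where formulas are declared", {
  set <- generate_lipid_reactions(fatty_acid_species())
  bal <- carbon_balance(set$reactions, set$metabolites)
  specified <- !is.na(bal$carbon_delta)
  expect_true(all(abs(bal$carbon_delta[specified]) < 1e-9))
  # only the mixed-species pool steps lack a formula
  expect_true(all(grepl("^(MTTP|ACAT)_", bal$reaction[!specified])))
  expect_gt(sum(specified), 50)
})

test_that("assembly coefficients reproduce the component mass fractions", {
  fa <- c("C16:0" = 0.5, "C18:1" = 0.3, "C18:2" = 0.2)
  prof <- chylomicron_profile(fa, c(TAG = 0.95, phospholipid = 0.04,
                                    cholesterol_ester = 0.01, protein = 0))
  asm <- build_chylomicron_assembly(prof, reference_mass = 10000)
  mm <- lipid_molar_masses(fatty_acid_species(names(fa)))
  st <- asm$assembly$stoichiometry
  tag_mass <- sum(vapply(seq_len(nrow(mm)), function(i) {
    tok <- fatty_acid_species(mm$code[i])$token
    -st[[paste0("tag", tok, "[r]")]] * mm$tag[i]
  }, numeric(1)))
  pl_mass <- -st[["pl[r]"]] * attr(mm, "phospholipid")
  ce_mass <- -st[["ce[r]"]] * sum(fa * mm$cholesteryl_ester)
  total <- 10000
  expect_equal(tag_mass / total, 0.95, tolerance = 1e-6)
  expect_equal(pl_mass / total, 0.04, tolerance = 1e-6)
  expect_equal(ce_mass / total, 0.01, tolerance = 1e-6)
  # TAG split follows the FA mole fractions
  coefs <- -unlist(st[paste0("tag", fatty_acid_species(names(fa))$token, "[r]")])
  expect_equal(unname(coefs / sum(coefs)), unname(fa), tolerance = 1e-12)
})

test_that("degenerate profiles behave as expected", {
  all16 <- chylomicron_profile(c("C16:0" = 1))
  asm <- build_chylomicron_assembly(all16)
  tags <- grep("^tag", names(asm$assembly$stoichiometry), value = TRUE)
  expect_equal(tags, "tag160[r]")
  eq <- chylomicron_profile(setNames(rep(1 / 6, 6), fatty_acid_species()$code))
  asm_eq <- build_chylomicron_assembly(eq)
  coefs <- asm_eq$assembly$stoichiometry[paste0("tag",
                                                fatty_acid_species()$token,
                                                "[r]")]
  expect_equal(max(coefs) - min(coefs), 0, tolerance = 1e-12)
  expect_error(chylomicron_profile(c("C16:0" = 0.6, "C18:1" = 0.3)),
               "sum to 1")
  expect_error(chylomicron_profile(c("C16:0" = 1),
                                   c(TAG = 0.95, phospholipid = 0.04,
                                     cholesterol_ester = 0.02, protein = 0)),
               "sum to 1")
})

test_that("chylomicron FA composition follows the diet through the model", {
  # single-species diet: fraction 1 for that species
  spec <- toy_model_spec(fa_species = fatty_acid_species("C18:1"))
  m <- build_toy_model(spec)
  d <- toy_diet(10)
  cm <- chylomicron_task_model(m, d, "biosynthesis")
  sol <- solve_fba(cm, "EX_cm_e", "maximize")
  prof <- chylomicron_fa_composition(sol, cm)
  expect_equal(unname(prof$fa_fractions[["C18:1"]]), 1)
  # zero TAG flux: undefined composition
  none <- chylomicron_task_model(m, d, "none")
  sol0 <- solve_fba(none, "EX_cm_e", "maximize")
  expect_error(chylomicron_fa_composition(sol0, none), "undefined")
})

test_that("with no FA interconversion the output reflects dietary fractions", {
  m <- build_toy_model()
  d <- toy_diet(45)
  prof <- chylomicron_composition_for_diet(m, d)
  sp <- fatty_acid_species()
  tag_in <- d$nutrient_intakes[paste0("tag", sp$token)]
  dietary <- setNames(as.numeric(tag_in / sum(tag_in)), sp$code)
  # small deviation allowed: the cholesteryl ester demand may draw its
  # acyl chains from any species at the optimum
  expect_lt(max(abs(prof$fa_fractions[sp$code] - dietary)), 0.02)
})
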