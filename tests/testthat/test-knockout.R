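make_glucose_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- glucose_task_model(build_toy_model(small_toy_spec()), toy_diet(10))
      cache <<- list(model = m,
                     screen = screen_knockouts(
                       m, list(reaction = "EX_glc_e", direction = "maximize")))
    }
    cache
  }
})

make_chylo_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- chylomicron_task_model(build_toy_model(small_toy_spec()),
                                  toy_diet(10), "biosynthesis")
      cache <<- list(model = m,
                     screen = screen_knockouts(
                       m, list(reaction = "EX_cm_e", direction = "maximize")))
    }
    cache
  }
})

test_that("knockout records partition the screened set and never gain flux", {
  for (sc in list(make_glucose_screen(), make_chylo_screen())) {
    k <- sc$screen
    expect_true(all(k$class %in% c("I", "II", "III")))
    expect_equal(sum(table(k$class)), nrow(k))
    expect_true(all(k$ko_value <= k$baseline + 1e-9))
    expect_true(all(k$reduction_fraction >= 0 & k$reduction_fraction <= 1))
    # exchanges excluded, deterministic model order
    m <- sc$model
    expect_equal(k$reaction_id,
                 m$reactions$id[!m$reactions$is_exchange])
  }
})

test_that("glucose-secretion screen matches the hand-derived class table", {
  k <- make_glucose_screen()$screen
  cls <- setNames(k$class, k$reaction_id)
  # the only complete blockage is the basolateral GLUT2 exporter
  expect_equal(names(cls)[cls == "II"], "GLCGLUT2")
  # removing apical GLUT2 drops absorption to the Na+-limited trickle
  expect_equal(unname(cls["GLUT2A"]), "III")
  # everything else is redundant or below threshold for this task
  expect_true(all(cls[setdiff(names(cls), c("GLCGLUT2", "GLUT2A"))] == "I"))
})

test_that("chylomicron screen finds cholesterol/energy pathways essential", {
  k <- make_chylo_screen()$screen
  cls <- setNames(k$class, k$reaction_id)
  essential <- c("CHOLSYN", "PLSYN", "APOSYN", "CHYLOMGE",
                 "GLYCOLYSIS", "PYRTM", "OXPHOS", "O2TE", "O2TM",
                 "CO2TM", "CO2TE")
  expect_true(all(cls[essential] == "II"))
  # species-resolved lipid ladder: impaired but not blocked (both species
  # carry >5% of dietary TAG in the 2-species toy)
  ladder <- as.vector(outer(c("LIPASE_", "MAGABS_", "FACOA_", "FACOATR_",
                              "MAGTR_", "MGAT_", "DGAT_", "MTTP_"),
                            c("160", "181"), paste0))
  expect_true(all(cls[ladder] == "III"))
  # parallel FFA absorption routes and per-species cholesteryl ester
  # synthases are individually dispensable
  expect_true(all(cls[c("FAABSC_160", "FAABSD_160", "ACAT_160",
                        "ACAT_181")] == "I"))
  expect_true(all(cls[c("SGLT1", "NAKATPASE", "GLUT2A",
                        "GLUCONEOGENESIS")] == "I"))
})

test_that("knockout values equal independent re-optimization after deletion", {
  sc <- make_chylo_screen()
  for (rid in c("LIPASE_160", "CHOLSYN", "FAABSC_181", "MTTP_181")) {
    direct <- max_flux(knock_out(sc$model, rid), "EX_cm_e")
    expect_equal(sc$screen$ko_value[sc$screen$reaction_id == rid], direct,
                 tolerance = 1e-9)
  }
})

test_that("classification is invariant to uniform diet rescaling", {
  m <- build_toy_model(small_toy_spec())
  k1 <- make_glucose_screen()$screen
  d2 <- toy_diet(10, kcal = 24)  # doubles every intake
  m2 <- glucose_task_model(m, d2)
  k2 <- screen_knockouts(m2, list(reaction = "EX_glc_e",
                                  direction = "maximize"))
  expect_equal(k2$class, k1$class)
  expect_equal(k2$baseline, 2 * k1$baseline, tolerance = 1e-8)
})

test_that("a zero-baseline task refuses to screen", {
  m <- chylomicron_task_model(build_toy_model(small_toy_spec()),
                              toy_diet(10), "none")
  expect_error(screen_knockouts(m, list(reaction = "EX_cm_e",
                                        direction = "maximize")),
               "task infeasible before screening")
})

test_that("dietary rescue restores flux lost to a luminal lipase defect", {
  sc <- make_chylo_screen()
  task <- list(reaction = "EX_cm_e", direction = "maximize")
  rec <- sc$screen[sc$screen$reaction_id == "LIPASE_160", ]
  out <- dietary_rescue(sc$model, rec, toy_diet(10), task)
  expect_gt(out$recovered_fraction, rec$ko_value / rec$baseline)
  expect_match(out$best_rescue, "lipid")
  expect_equal(out$class, "III")  # class is never rewritten
  # empty grid: record unchanged
  same <- dietary_rescue(sc$model, rec, toy_diet(10), task,
                         modification_grid = numeric(0))
  expect_equal(same$recovered_fraction, rec$ko_value / rec$baseline)
  expect_true(is.na(same$best_rescue))
})

test_that("rescue is a warned no-op for class I and II records", {
  sc <- make_chylo_screen()
  task <- list(reaction = "EX_cm_e", direction = "maximize")
  rec2 <- sc$screen[sc$screen$reaction_id == "CHOLSYN", ]
  expect_warning(out2 <- dietary_rescue(sc$model, rec2, toy_diet(10), task),
                 "Type III")
  expect_equal(out2$recovered_fraction, 0)
  rec1 <- sc$screen[sc$screen$reaction_id == "SGLT1", ]
  expect_warning(out1 <- dietary_rescue(sc$model, rec1, toy_diet(10), task),
                 "Type III")
  expect_equal(out1$recovered_fraction, 1, tolerance = 1e-9)
})
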