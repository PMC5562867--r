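# The four headline simulation experiments, each a reproducible procedure
# over (model, diet): glucose/fructose transport with and without apical
# GLUT2, sodium titration of glucose absorption, gluconeogenic potential,
# and oxygen-dependent chylomicron secretion.

scenario_result <- function(diet_name, scenario, settings, outputs,
                            curves = NULL, tables = NULL) {
  structure(list(diet_name = diet_name, scenario = scenario,
                 settings = settings, outputs = outputs,
                 curves = curves, tables = tables),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario", x$scenario, "on diet", x$diet_name, "\n")
  for (nm in names(x$outputs))
    cat(" ", nm, "=", format(x$outputs[[nm]]), "\n")
  invisible(x)
}

prepare_diet_model <- function(model, diet, p, config) {
  bounds <- diet_to_bounds(diet, p)
  apply_exchange_bounds(model, bounds, quiet = TRUE)
}

set_apical_glut2 <- function(model, apical_glut2, config) {
  id <- config$transporter_ids$GLUT2_apical
  present <- !is.null(id) && id %in% model$reactions$id
  if (apical_glut2 && !present)
    stop("configuration error: apical GLUT2 reaction ", id,
         " absent from model")
  if (!apical_glut2 && present)
    model <- set_reaction_bounds(model, id, 0, 0)  # zeroed, not removed
  model
}

#' Diet-constrained model states for the two screening tasks
#'
#' `glucose_task_model()` applies the diet bounds and the apical GLUT2
#' setting; `chylomicron_task_model()` applies the diet bounds and wires
#' the cholesterol source (closing both the intracellular supply and the
#' biosynthesis pathway for `"none"`, opening the supply for `"luminal"`,
#' or opening biosynthesis plus basolateral oxygen for `"biosynthesis"`).
#'
#' @param model a `metabolic_model`.
#' @param diet a [diet_composition()].
#' @param apical_glut2 logical.
#' @param cholesterol_source `"none"`, `"luminal"` or `"biosynthesis"`.
#' @param p [body_parameters()].
#' @param config [run_config()].
#' @return a constrained `metabolic_model`.
#' @export
glucose_task_model <- function(model, diet, apical_glut2 = TRUE,
                               p = body_parameters(), config = run_config()) {
  m <- prepare_diet_model(model, diet, p, config)
  set_apical_glut2(m, apical_glut2, config)
}

#' @rdname glucose_task_model
#' @export
chylomicron_task_model <- function(model, diet,
                                   cholesterol_source = c("biosynthesis",
                                                          "none", "luminal"),
                                   p = body_parameters(),
                                   config = run_config()) {
  cholesterol_source <- match.arg(cholesterol_source)
  m <- prepare_diet_model(model, diet, p, config)
  chol_syn <- require_role(m, config, "CHOLSYN")
  chol_sink <- require_role(m, config, "SINK_chol")
  m <- set_reaction_bounds(m, chol_syn, 0, 0)
  m <- set_reaction_bounds(m, chol_sink, 0, 0)
  if (cholesterol_source == "luminal") {
    m <- set_reaction_bounds(m, chol_sink, -1000, 0)
  } else if (cholesterol_source == "biosynthesis") {
    m <- set_reaction_bounds(m, chol_syn, 0, 1000)
    m <- set_reaction_bounds(m, require_role(m, config, "EX_O2"),
                             lower = -1000)
  }
  m
}

#' Chylomicron fatty acid composition under a diet
#'
#' Maximizes chylomicron secretion on the diet-constrained model (with the
#' given cholesterol source) and reads off the realized fatty acid
#' composition of the secreted particles.
#'
#' @inheritParams glucose_task_model
#' @inheritParams chylomicron_task_model
#' @return a `chylomicron_profile`.
#' @export
chylomicron_composition_for_diet <- function(model, diet,
                                             cholesterol_source = "biosynthesis",
                                             p = body_parameters(),
                                             config = run_config()) {
  m <- chylomicron_task_model(model, diet, cholesterol_source, p, config)
  sol <- solve_fba(m, require_role(m, config, "EX_chylomicron"), "maximize")
  chylomicron_fa_composition(sol, m)
}

#' Glucose and fructose transport scenario
#'
#' Maximal apical absorption and maximal basolateral secretion of glucose
#' and fructose under a diet, with apical GLUT2 either active or zeroed.
#' Absorption is measured as the maximal luminal uptake (negated minimal
#' flux of the luminal exchange); secretion as the maximal basolateral
#' exchange flux.
#'
#' @param model a `metabolic_model`.
#' @param diet a [diet_composition()].
#' @param apical_glut2 logical: is GLUT2 present on the apical membrane?
#' @param p [body_parameters()].
#' @param config [run_config()].
#' @return a `scenario_result` with outputs `max_apical_absorption_glucose`,
#'   `max_basolateral_secretion_glucose`, and the fructose counterparts
#'   (mmol gdw^-1 h^-1).
#' @export
glucose_transport_scenario <- function(model, diet, apical_glut2 = TRUE,
                                       p = body_parameters(),
                                       config = run_config()) {
  require_role(model, config, "SGLT1")
  require_role(model, config, "GLUT2_basolateral")
  m <- prepare_diet_model(model, diet, p, config)
  m <- set_apical_glut2(m, apical_glut2, config)
  outputs <- list(
    max_apical_absorption_glucose =
      -min_flux(m, require_role(m, config, "EX_glc_lumen")),
    max_basolateral_secretion_glucose =
      max_flux(m, require_role(m, config, "EX_glc_baso")),
    max_apical_absorption_fructose =
      -min_flux(m, require_role(m, config, "EX_fru_lumen")),
    max_basolateral_secretion_fructose =
      max_flux(m, require_role(m, config, "EX_fru_baso")))
  scenario_result(diet$name, "glucose_transport",
                  list(apical_glut2 = apical_glut2), outputs)
}

#' Sodium titration of glucose absorption
#'
#' Scans luminal Na+ availability and records the maximal apical glucose
#' absorption at each level. Reports the minimal Na+ availability reaching
#' 99.9% of the plateau (refined by bisection between grid points) and its
#' ratio to the dietary Na+ supply.
#'
#' @param model,diet,apical_glut2,p,config as in
#'   [glucose_transport_scenario()].
#' @param na_levels ordered non-negative Na+ availabilities
#'   (mmol gdw^-1 h^-1); default: 13 points from 0 to 1.2x the
#'   stoichiometric requirement for total luminal glucose.
#' @return a `scenario_result`; `curves` holds the titration curve
#'   (parameter values are Na+ availabilities, objective values maximal
#'   glucose absorption), outputs hold `na_required`,
#'   `dietary_na`, `na_required_over_dietary`.
#' @export
sodium_titration_scenario <- function(model, diet, apical_glut2 = FALSE,
                                      na_levels = NULL,
                                      p = body_parameters(),
                                      config = run_config()) {
  m <- prepare_diet_model(model, diet, p, config)
  m <- set_apical_glut2(m, apical_glut2, config)
  ex_na <- require_role(m, config, "EX_Na")
  ex_glc <- require_role(m, config, "EX_glc_lumen")
  dietary_na <- -reaction_bounds(m, ex_na)[1]
  if (is.null(na_levels)) {
    glc_avail <- -reaction_bounds(m, ex_glc)[1]
    sigma_guess <- 2
    na_levels <- seq(0, 1.2 * sigma_guess * glc_avail, length.out = 13)
  }
  absorb_at <- function(na) {
    mm <- set_reaction_bounds(m, ex_na, lower = -na)
    -min_flux(mm, ex_glc)
  }
  scan <- titration_scan(m, ex_na, -na_levels,
                         objective = list(reaction = ex_glc,
                                          direction = "minimize"))
  curve <- structure(list(parameter_name = "luminal Na+ availability",
                          parameter_values = na_levels,
                          objective_values = -scan$objective_values,
                          statuses = scan$statuses),
                     class = "titration_curve")
  vmax <- max(curve$objective_values, na.rm = TRUE)
  target <- 0.999 * vmax
  idx <- which(curve$objective_values >= target)[1]
  na_req <- na_levels[idx]
  if (!is.na(idx) && idx > 1) {    # bisection refine between grid points
    lo <- na_levels[idx - 1]; hi <- na_levels[idx]
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      if (absorb_at(mid) >= target) hi <- mid else lo <- mid
      if (hi - lo < 1e-9 * max(1, hi)) break
    }
    na_req <- hi
  }
  scenario_result(diet$name, "sodium_titration",
                  list(apical_glut2 = apical_glut2),
                  list(max_absorption = vmax,
                       na_required = na_req,
                       dietary_na = dietary_na,
                       na_required_over_dietary =
                         if (dietary_na > 0) na_req / dietary_na else Inf),
                  curves = curve)
}

#' Gluconeogenic potential scenario
#'
#' Compares the maximal basolateral glucose secretion with the maximal
#' luminal absorption; a positive surplus indicates de novo glucose
#' synthesis capacity. Each amino-acid uptake is then ablated one at a
#' time (exhaustive single-nutrient ablation) to trace the surplus to its
#' dietary origin.
#'
#' @param model,diet,apical_glut2,p,config as in
#'   [glucose_transport_scenario()].
#' @return a `scenario_result` with outputs `max_absorption`,
#'   `max_secretion`, `gluconeogenic_surplus`, and `tables$ablation`
#'   (data.frame: nutrient, surplus_without).
#' @export
gluconeogenesis_scenario <- function(model, diet, apical_glut2 = TRUE,
                                     p = body_parameters(),
                                     config = run_config()) {
  m <- prepare_diet_model(model, diet, p, config)
  m <- set_apical_glut2(m, apical_glut2, config)
  ex_in <- require_role(m, config, "EX_glc_lumen")
  ex_out <- require_role(m, config, "EX_glc_baso")
  surplus_of <- function(mm) {
    max_flux(mm, ex_out) - (-min_flux(mm, ex_in))
  }
  max_abs <- -min_flux(m, ex_in)
  max_sec <- max_flux(m, ex_out)
  aa_nutrients <- names(diet$nutrient_class)[diet$nutrient_class == "amino_acid"]
  mapping <- default_nutrient_mapping(diet)
  abl <- data.frame(nutrient = character(0), surplus_without = numeric(0))
  for (nut in aa_nutrients) {
    rid <- mapping[[nut]]
    if (!rid %in% m$reactions$id) next
    abl <- rbind(abl, data.frame(
      nutrient = nut,
      surplus_without = surplus_of(set_reaction_bounds(m, rid, lower = 0))))
  }
  scenario_result(diet$name, "gluconeogenesis",
                  list(apical_glut2 = apical_glut2),
                  list(max_absorption = max_abs, max_secretion = max_sec,
                       gluconeogenic_surplus = max_sec - max_abs),
                  tables = list(ablation = abl))
}

#' Oxygen-dependent chylomicron secretion scenario
#'
#' The diets are cholesterol-free, so chylomicron assembly depends on a
#' cholesterol source. `cholesterol_source = "none"` leaves both the
#' intracellular cholesterol supply and the biosynthesis pathway closed;
#' `"luminal"` opens an intracellular cholesterol supply (mimicking
#' absorbed biliary cholesterol); `"biosynthesis"` opens the endogenous
#' cholesterol biosynthesis pathway together with basolateral oxygen
#' uptake, and additionally reports the minimal oxygen uptake compatible
#' with maximal chylomicron secretion (two-stage optimization), converted
#' to moles per mouse per day through the same dry-mass normalization used
#' for the diet bounds.
#'
#' @param model,diet,p,config as in [glucose_transport_scenario()].
#' @param cholesterol_source `"none"`, `"luminal"` or `"biosynthesis"`.
#' @return a `scenario_result` with outputs `max_secretion` and, for the
#'   biosynthesis source, `min_o2_flux` (mmol gdw^-1 h^-1) and
#'   `min_o2_mol_per_day` (moles mouse^-1 day^-1).
#' @export
chylomicron_oxygen_scenario <- function(model, diet,
                                        cholesterol_source = c("none", "luminal",
                                                               "biosynthesis"),
                                        p = body_parameters(),
                                        config = run_config()) {
  cholesterol_source <- match.arg(cholesterol_source)
  ex_cm <- require_role(model, config, "EX_chylomicron")
  m <- chylomicron_task_model(model, diet, cholesterol_source, p, config)
  outputs <- list()
  if (cholesterol_source %in% c("none", "luminal")) {
    outputs$max_secretion <- max_flux(m, ex_cm)
  } else {
    ex_o2 <- require_role(m, config, "EX_O2")
    # uptake is negative flux, so the *least* oxygen uptake compatible
    # with maximal secretion is found by maximizing the exchange flux
    lex <- lexicographic_optimize(
      m,
      primary = list(reaction = ex_cm, direction = "maximize"),
      secondary = list(reaction = ex_o2, direction = "maximize"))
    if (lex$status != "optimal")
      return(scenario_result(diet$name, "chylomicron_oxygen",
                             list(cholesterol_source = cholesterol_source),
                             list(status = lex$status)))
    o2_flux <- -lex$secondary_value  # uptake is negative flux
    A <- conversion_factor(enterocyte_dry_mass(p), p$hours_per_day)
    outputs$max_secretion <- lex$primary_value
    outputs$min_o2_flux <- o2_flux
    outputs$min_o2_mol_per_day <- o2_flux / A
    attr(outputs, "solution") <- lex
  }
  scenario_result(diet$name, "chylomicron_oxygen",
                  list(cholesterol_source = cholesterol_source), outputs)
}
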