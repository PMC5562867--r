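# Single-reaction deletion screen against a metabolic task, with the
# three-way impact classification:
#   Type I   - deletion leaves the task (essentially) unaffected,
#   Type II  - deletion blocks the task completely,
#   Type III - deletion reduces the task by more than the Type III
#              threshold (default >5%) without blocking it,
# and a dietary-rescue scan for Type III reactions.

classify_knockout <- function(baseline, ko_value, thresholds) {
  reduction <- 1 - ko_value / baseline
  reduction <- min(max(reduction, 0), 1)
  if (ko_value < thresholds$blockage_eps * baseline) "II"
  else if (reduction <= thresholds$type_iii) "I"
  else "III"
}

#' Screen single-reaction knockouts against a task
#'
#' Computes the task optimum once (baseline), then deletes every
#' non-exchange reaction in turn (both bounds zeroed) and re-optimizes.
#' Exchange reactions are excluded by default — deleting a diet input is a
#' diet change, not an enzymopathy — but can be included.
#'
#' @param model a `metabolic_model`, already constrained by the diet (use
#'   [apply_exchange_bounds()]) and any scenario settings.
#' @param task list `(reaction, direction)` defining the metabolic task,
#'   e.g. basolateral glucose secretion or chylomicron secretion.
#' @param include_exchanges also screen exchange reactions.
#' @param config [run_config()] supplying the classification thresholds.
#' @return data.frame of class `knockout_screen` with one row per
#'   screened reaction: `reaction_id`, `baseline`, `ko_value`,
#'   `reduction_fraction`, `class` (in deterministic model order).
#' @export
screen_knockouts <- function(model, task, include_exchanges = FALSE,
                             config = run_config()) {
  base_sol <- solve_fba(model, task$reaction, task$direction)
  if (base_sol$status != "optimal" || base_sol$objective_value <= 0)
    stop("task infeasible before screening (baseline ",
         if (base_sol$status == "optimal") base_sol$objective_value
         else base_sol$status, ")")
  baseline <- base_sol$objective_value
  ids <- model$reactions$id
  keep <- if (include_exchanges) rep(TRUE, length(ids)) else
    !model$reactions$is_exchange
  ids <- ids[keep]
  rows <- lapply(ids, function(rid) {
    ko <- knock_out(model, rid)
    sol <- solve_fba(ko, task$reaction, task$direction)
    val <- if (sol$status == "optimal") max(sol$objective_value, 0) else 0
    data.frame(reaction_id = rid, baseline = baseline, ko_value = val,
               reduction_fraction = min(max(1 - val / baseline, 0), 1),
               class = classify_knockout(baseline, val, config$thresholds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("knockout_screen", "data.frame")
  attr(out, "task") <- task
  out
}

#' @export
print.knockout_screen <- function(x, ...) {
  task <- attr(x, "task")
  cat("Knockout screen (", task$direction, " ", task$reaction, "), ",
      nrow(x), " reactions\n", sep = "")
  print(table(x$class))
  invisible(x)
}

#' Dietary rescue scan for an impaired (Type III) reaction
#'
#' For each macronutrient class and each factor of the modification grid,
#' the class's uptake bounds are scaled up and the task re-optimized on
#' the knocked-out model. Nutrients of the scanned class that the diet
#' supplies at zero intake (e.g. pre-hydrolyzed FFA/MAG) are granted the
#' class's mean non-zero intake before scaling, so "feed the
#' pre-hydrolyzed form" interventions are reachable. The modification
#' maximizing the recovered fraction `task_after / baseline` is reported;
#' the record's class is never changed.
#'
#' @param model diet-constrained model (same state used for the screen).
#' @param record one row of a `knockout_screen` (or a list with
#'   `reaction_id`, `baseline`, `class`).
#' @param diet the [diet_composition()] behind the applied bounds (supplies
#'   intakes and nutrient classes).
#' @param task list `(reaction, direction)` — the screened task.
#' @param modification_grid multiplicative uptake factors to scan.
#' @param p,config as elsewhere.
#' @return the record as a one-row data.frame with added columns
#'   `best_rescue` (description or `NA`), `recovered_fraction`, and
#'   attribute `warning` when applied to a class I/II record.
#' @export
dietary_rescue <- function(model, record, diet, task,
                           modification_grid = c(1.5, 2, 5, 10),
                           p = body_parameters(), config = run_config()) {
  rec <- as.data.frame(record, stringsAsFactors = FALSE)
  rec$best_rescue <- NA_character_
  rec$recovered_fraction <- rec$ko_value / rec$baseline
  if (!identical(rec$class, "III")) {
    warning("dietary_rescue applies to Type III records; class ",
            rec$class, " record left unmodified")
    attr(rec, "warning") <- "not_type_iii"
    if (identical(rec$class, "II")) rec$recovered_fraction <- 0
    return(rec)
  }
  if (!length(modification_grid)) return(rec)
  ko <- knock_out(model, rec$reaction_id)
  A <- conversion_factor(enterocyte_dry_mass(p), p$hours_per_day)
  mapping <- default_nutrient_mapping(diet)
  classes <- unique(diet$nutrient_class)
  best <- rec$recovered_fraction
  best_desc <- rec$best_rescue
  for (cl in classes) {
    nuts <- names(diet$nutrient_class)[diet$nutrient_class == cl]
    intakes <- diet$nutrient_intakes[nuts]
    base_level <- if (any(intakes > 0)) mean(intakes[intakes > 0]) else 0
    if (base_level == 0) next
    eff <- ifelse(intakes > 0, intakes, base_level)
    for (s in modification_grid) {
      mm <- ko
      for (i in seq_along(nuts)) {
        rid <- mapping[[nuts[i]]]
        if (!rid %in% mm$reactions$id) next
        mm <- set_reaction_bounds(mm, rid, lower = -eff[[i]] * s * A)
      }
      sol <- solve_fba(mm, task$reaction, task$direction)
      val <- if (sol$status == "optimal") sol$objective_value else 0
      frac <- val / rec$baseline
      if (frac > best + 1e-9) {
        best <- frac
        best_desc <- sprintf("%s uptake x%g", cl, s)
      }
    }
  }
  rec$recovered_fraction <- best
  rec$best_rescue <- best_desc
  rec
}
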