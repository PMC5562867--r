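# Conversion of diet composition (nutrient intakes in mol mouse^-1 day^-1)
# into exchange-reaction lower bounds (mmol gdw^-1 h^-1), normalized to the
# dry mass of the enterocyte population of one mouse.

#' Body parameters for the flux normalization
#'
#' Defaults: small-intestine wet weight 1.094 g of which 76% is water, and
#' enterocytes making up 55.2% of small-intestinal cells; 24 h per day.
#'
#' @param si_wet_weight small intestine wet weight (g).
#' @param water_fraction water fraction of the wet weight (0-1).
#' @param enterocyte_cell_fraction enterocyte fraction of intestinal cells (0-1).
#' @param hours_per_day hours over which the daily intake is spread.
#' @return list of class `body_parameters`.
#' @export
body_parameters <- function(si_wet_weight = 1.094, water_fraction = 0.76,
                            enterocyte_cell_fraction = 0.552,
                            hours_per_day = 24) {
  if (water_fraction < 0 || water_fraction > 1 ||
      enterocyte_cell_fraction < 0 || enterocyte_cell_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (si_wet_weight <= 0 || hours_per_day <= 0)
    stop("weights and times must be positive")
  structure(list(si_wet_weight = si_wet_weight,
                 water_fraction = water_fraction,
                 enterocyte_cell_fraction = enterocyte_cell_fraction,
                 hours_per_day = hours_per_day),
            class = "body_parameters")
}

#' Dry mass of the enterocyte population per mouse
#'
#' `si_wet_weight * (1 - water_fraction) * enterocyte_cell_fraction`;
#' with the default parameters 1.094 g x 0.24 x 0.552 = 0.1449 g.
#'
#' @param p a [body_parameters()] object.
#' @return dry weight in g.
#' @export
enterocyte_dry_mass <- function(p = body_parameters()) {
  p$si_wet_weight * (1 - p$water_fraction) * p$enterocyte_cell_fraction
}

#' Intake-to-flux conversion factor A
#'
#' Converts mol mouse^-1 day^-1 to mmol gdw^-1 h^-1:
#' `A = 1000 / (dry_mass * hours)`; with the study defaults
#' `A = 1000 / (0.1449 * 24) = 287.49`.
#'
#' @param dry_mass enterocyte dry mass (g), see [enterocyte_dry_mass()].
#' @param hours hours per day.
#' @return A in (mmol gdw^-1 h^-1) per (mol mouse^-1 day^-1).
#' @export
conversion_factor <- function(dry_mass = enterocyte_dry_mass(), hours = 24) {
  if (dry_mass <= 0 || hours <= 0) stop("dry_mass and hours must be positive")
  1000 / (dry_mass * hours)
}

#' Diet composition container
#'
#' @param name diet label (e.g. `"45en%"`).
#' @param nutrient_intakes named numeric vector, mol mouse^-1 day^-1.
#' @param energy_fractions named numeric over `c("fat","carbohydrate","protein")`
#'   summing to 1 (tolerance 0.01), or `NULL` when unknown.
#' @param nutrient_class optional named character giving each nutrient's
#'   macronutrient class (`"lipid"`, `"carbohydrate"`, `"amino_acid"`,
#'   `"mineral"`); used by ablation and rescue scans.
#' @return list of class `diet_composition`.
#' @export
diet_composition <- function(name, nutrient_intakes, energy_fractions = NULL,
                             nutrient_class = NULL) {
  if (any(nutrient_intakes < 0)) stop("nutrient intakes must be >= 0")
  if (is.null(names(nutrient_intakes)))
    stop("nutrient_intakes must be named by nutrient token")
  if (!is.null(energy_fractions) &&
      abs(sum(energy_fractions) - 1) > 0.01)
    stop("energy fractions must sum to 1 (within 0.01)")
  structure(list(name = name, nutrient_intakes = nutrient_intakes,
                 energy_fractions = energy_fractions,
                 nutrient_class = nutrient_class),
            class = "diet_composition")
}

#' @export
print.diet_composition <- function(x, ...) {
  cat("Diet", x$name, "-", length(x$nutrient_intakes), "nutrients\n")
  if (!is.null(x$energy_fractions)) {
    ef <- round(100 * x$energy_fractions)
    cat("  energy%:", paste(names(ef), ef, sep = " ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Map a diet to exchange-reaction bounds
#'
#' The (negative) uptake rate of each dietary nutrient becomes the lower
#' bound of its luminal exchange reaction: `lower = -intake * A`. Upper
#' bounds are left untouched, so secretion back into the lumen stays
#' possible. Every nutrient must have an entry in the mapping table;
#' mapped nutrients whose exchange reaction is absent from a model are
#' reported by [apply_exchange_bounds()], never silently dropped.
#'
#' @param diet a [diet_composition()].
#' @param p a [body_parameters()].
#' @param mapping named character: nutrient token -> exchange reaction id.
#'   Defaults to the package convention `EX_<nutrient>_u`.
#' @return list of class `exchange_bound_set` with `bounds` (data.frame:
#'   `nutrient`, `reaction`, `lower`, `upper`), `conversion_factor`, and
#'   `diet_name`.
#' @export
diet_to_bounds <- function(diet, p = body_parameters(),
                           mapping = default_nutrient_mapping(diet)) {
  unmapped <- setdiff(names(diet$nutrient_intakes), names(mapping))
  if (length(unmapped))
    stop("no exchange mapping for nutrient(s): ",
         paste(unmapped, collapse = ", "))
  A <- conversion_factor(enterocyte_dry_mass(p), p$hours_per_day)
  nut <- names(diet$nutrient_intakes)
  bounds <- data.frame(
    nutrient = nut,
    reaction = unname(mapping[nut]),
    lower = -diet$nutrient_intakes * A,
    upper = NA_real_,  # model default retained
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(bounds = bounds, conversion_factor = A,
                 diet_name = diet$name),
            class = "exchange_bound_set")
}

#' Default nutrient -> luminal exchange id mapping
#'
#' @param diet optional diet whose nutrient tokens the mapping should cover.
#' @return named character vector `EX_<nutrient>_u` per nutrient.
#' @export
default_nutrient_mapping <- function(diet = NULL) {
  nut <- if (is.null(diet)) character(0) else names(diet$nutrient_intakes)
  setNames(paste0("EX_", nut, "_u"), nut)
}

#' @export
print.exchange_bound_set <- function(x, ...) {
  cat("Exchange bounds for diet", x$diet_name, "-",
      nrow(x$bounds), "nutrients, A =", format(x$conversion_factor), "\n")
  invisible(x)
}

#' Apply an exchange bound set to a model
#'
#' Sets the lower bound of every mapped exchange reaction present in the
#' model; reactions absent from the model are collected and reported via
#' the `"missing_exchanges"` attribute (and a warning unless `quiet`).
#'
#' @param model a `metabolic_model`.
#' @param bound_set an `exchange_bound_set` from [diet_to_bounds()].
#' @param quiet suppress the missing-exchange warning.
#' @return the constrained model (attribute `missing_exchanges` lists
#'   nutrients whose exchange the model lacks).
#' @export
apply_exchange_bounds <- function(model, bound_set, quiet = FALSE) {
  b <- bound_set$bounds
  present <- b$reaction %in% model$reactions$id
  for (k in which(present)) {
    model <- set_reaction_bounds(model, b$reaction[k], lower = b$lower[k])
  }
  missing <- b$nutrient[!present]
  if (length(missing) && !quiet)
    warning("diet nutrients without a model exchange (left unapplied): ",
            paste(missing, collapse = ", "))
  attr(model, "missing_exchanges") <- missing
  model
}

#' Intakes from feed mass and mass composition (helper path)
#'
#' Converts `g/day` feed and per-nutrient mass fractions plus molar masses
#' into mol mouse^-1 day^-1. The canonical input is the pre-multiplied
#' molar intake table; this helper covers the g/day route.
#'
#' @param feed_g_per_day feed intake (g/day).
#' @param mass_fractions named numeric mass fractions of nutrients.
#' @param molar_masses named numeric g/mol for the same nutrients.
#' @return named numeric intake in mol mouse^-1 day^-1.
#' @export
intakes_from_feed <- function(feed_g_per_day, mass_fractions, molar_masses) {
  stopifnot(all(names(mass_fractions) %in% names(molar_masses)))
  feed_g_per_day * mass_fractions / molar_masses[names(mass_fractions)]
}
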