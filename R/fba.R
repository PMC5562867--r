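# Flux balance analysis: optimize a reaction flux subject to the
# steady-state mass balance S v = 0 and the flux bounds l <= v <= u.
# Only the objective value is contract-guaranteed; individual fluxes are
# solver-dependent under alternate optima and should be interrogated via
# flux_variability() instead.

.fba_tol <- list(feasibility = 1e-9, steady_state = 1e-6, optimality = 1e-8)

fba_lp_parts <- function(model) {
  list(S = as.matrix(build_stoichiometric_matrix(model)),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       ids = model$reactions$id)
}

#' Flux balance analysis
#'
#' @param model a `metabolic_model`.
#' @param objective_reaction reaction id to optimize; defaults to the
#'   model's stored objective.
#' @param direction `"maximize"` or `"minimize"`.
#' @return an `fba_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value`, `fluxes` (named
#'   vector v), `objective_reaction` and `direction`. Non-optimal statuses
#'   are reported, not raised.
#' @examples
#' m <- metabolic_model(
#'   compartments(c("u", "c"), side = c("apical_lumen", "intracellular")),
#'   metabolites(c("a", "a"), c("u", "c")),
#'   list(exchange_reaction("a[u]", lower_bound = -5),
#'        reaction("T_a", c("a[u]" = -1, "a[c]" = 1), 0, 1000),
#'        exchange_reaction("a[c]")))
#' solve_fba(m, "EX_a_c", "maximize")$objective_value  # 5
#' @export
solve_fba <- function(model, objective_reaction = NULL,
                      direction = c("maximize", "minimize")) {
  if (is.null(objective_reaction)) {
    if (is.null(model$objective)) stop("no objective reaction given or stored")
    objective_reaction <- model$objective$reaction
    direction <- model$objective$direction
  }
  direction <- match.arg(direction)
  parts <- fba_lp_parts(model)
  j <- match(objective_reaction, parts$ids)
  if (is.na(j)) stop("unknown objective reaction: ", objective_reaction)
  obj <- numeric(length(parts$ids)); obj[j] <- 1
  res <- solve_lp(obj, parts$S, lb = parts$lb, ub = parts$ub,
                  direction = if (direction == "maximize") "max" else "min")
  fluxes <- if (res$status == "optimal") setNames(res$x, parts$ids) else
    setNames(rep(NA_real_, length(parts$ids)), parts$ids)
  structure(list(status = res$status,
                 objective_value = res$objective,
                 fluxes = fluxes,
                 objective_reaction = objective_reaction,
                 direction = direction),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution (", x$direction, " ", x$objective_reaction, ")\n", sep = "")
  cat("  status:", x$status, "\n")
  if (x$status == "optimal")
    cat("  objective value:", format(x$objective_value), "mmol gdw^-1 h^-1\n")
  invisible(x)
}

#' Maximal / minimal achievable flux through one reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @return optimal flux value (numeric scalar); `NA` if not optimal.
#' @export
max_flux <- function(model, reaction_id) {
  solve_fba(model, reaction_id, "maximize")$objective_value
}

#' @rdname max_flux
#' @export
min_flux <- function(model, reaction_id) {
  solve_fba(model, reaction_id, "minimize")$objective_value
}

#' Flux variability over a set of reactions
#'
#' Optionally at a fixed fraction of a primary objective's optimum.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to scan (default: all).
#' @param objective optional list `(reaction, direction)`; when given, the
#'   objective flux is first optimized and then fixed (within `band`)
#'   before scanning.
#' @param band relative width used to fix the objective.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, reaction_ids = model$reactions$id,
                             objective = NULL, band = 1e-8) {
  if (!is.null(objective)) {
    sol <- solve_fba(model, objective$reaction, objective$direction)
    if (sol$status != "optimal") stop("objective not optimal: ", sol$status)
    eps <- band * max(1, abs(sol$objective_value))
    model <- set_reaction_bounds(model, objective$reaction,
                                 sol$objective_value - eps,
                                 sol$objective_value + eps)
  }
  data.frame(reaction = reaction_ids,
             min = vapply(reaction_ids, function(r) min_flux(model, r), numeric(1)),
             max = vapply(reaction_ids, function(r) max_flux(model, r), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-stage (lexicographic) optimization
#'
#' Stage 1 optimizes the primary objective; stage 2 fixes the primary flux
#' at its optimum (within a band of `1e-8 * max(1, |opt|)` to avoid
#' round-off infeasibility) and optimizes the secondary objective. Used
#' e.g. to find the minimal oxygen uptake compatible with maximal
#' chylomicron secretion.
#'
#' @param model a `metabolic_model`.
#' @param primary,secondary lists `(reaction, direction)` with direction
#'   `"maximize"` or `"minimize"`.
#' @param band relative equality band for fixing the primary optimum.
#' @return the stage-2 `fba_solution`, with extra fields
#'   `primary_value` and `secondary_value`.
#' @export
lexicographic_optimize <- function(model, primary, secondary, band = 1e-8) {
  s1 <- solve_fba(model, primary$reaction, primary$direction)
  if (s1$status != "optimal") return(s1)
  opt <- s1$objective_value
  eps <- band * max(1, abs(opt))
  fixed <- set_reaction_bounds(model, primary$reaction, opt - eps, opt + eps)
  s2 <- solve_fba(fixed, secondary$reaction, secondary$direction)
  s2$primary_value <- opt
  s2$secondary_value <- s2$objective_value
  s2
}

#' Titration scan over an exchange lower bound
#'
#' For each value in `lower_bounds` the exchange reaction's lower bound is
#' set and the objective re-optimized; the model is not modified (the
#' bounds are set on a copy). Non-optimal points are recorded as `NaN`
#' with their status.
#'
#' @param model a `metabolic_model`.
#' @param exchange_reaction exchange reaction id to titrate.
#' @param lower_bounds ordered numeric vector of lower-bound values
#'   (uptake is negative).
#' @param objective list `(reaction, direction)`.
#' @return a `titration_curve`: list with `parameter_name`,
#'   `parameter_values`, `objective_values`, `statuses`.
#' @export
titration_scan <- function(model, exchange_reaction, lower_bounds, objective) {
  if (is.unsorted(lower_bounds) && is.unsorted(rev(lower_bounds)))
    stop("lower_bounds must be ordered")
  vals <- numeric(length(lower_bounds))
  stat <- character(length(lower_bounds))
  for (k in seq_along(lower_bounds)) {
    mk <- set_reaction_bounds(model, exchange_reaction, lower = lower_bounds[k])
    sol <- solve_fba(mk, objective$reaction, objective$direction)
    stat[k] <- sol$status
    vals[k] <- if (sol$status == "optimal") sol$objective_value else NaN
  }
  structure(list(parameter_name = exchange_reaction,
                 parameter_values = lower_bounds,
                 objective_values = vals,
                 statuses = stat),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("Titration of", x$parameter_name, "over", length(x$parameter_values),
      "points\n")
  print(data.frame(bound = x$parameter_values, objective = x$objective_values))
  invisible(x)
}

#' @export
plot.titration_curve <- function(x, xlab = x$parameter_name,
                                 ylab = "objective flux", type = "b", ...) {
  plot(x$parameter_values, x$objective_values, xlab = xlab, ylab = ylab,
       type = type, ...)
  invisible(x)
}

#' Check the steady-state and bound residuals of a solution
#'
#' @param model the model the solution was computed on.
#' @param solution an `fba_solution`.
#' @return list with `steady_state` (max |S v|) and `bound_violation`
#'   (largest bound overshoot).
#' @export
solution_residuals <- function(model, solution) {
  parts <- fba_lp_parts(model)
  v <- solution$fluxes[parts$ids]
  list(steady_state = max(abs(parts$S %*% v)),
       bound_violation = max(0, max(parts$lb - v), max(v - parts$ub)))
}
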