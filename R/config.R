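#' Run configuration
#'
#' Central map of solver settings, transporter/reaction role ids,
#' classification thresholds and the nutrient-to-exchange mapping used by
#' the scenario and knockout drivers. The defaults match the toy
#' enterocyte model; for another model, override the ids.
#'
#' @param solver LP backend token (only `"simplex"` is built in).
#' @param transporter_ids named list mapping roles to reaction ids.
#' @param thresholds list with `type_iii` (relative reduction above which
#'   a knockout is Type III) and `blockage_eps` (relative flux below which
#'   a task counts as completely blocked).
#' @param tolerances numerical tolerances for the LP/FBA layer.
#' @return list of class `run_config`.
#' @export
run_config <- function(solver = "simplex",
                       transporter_ids = list(
                         SGLT1 = "SGLT1",
                         GLUT2_apical = "GLUT2A",
                         GLUT2_basolateral = "GLCGLUT2",
                         GLUT5 = "GLUT5A",
                         GLCGLUT2 = "GLCGLUT2",
                         CHYLOMGE = "CHYLOMGE",
                         EX_Na = "EX_na_u",
                         EX_O2 = "EX_o2_e",
                         EX_glc_lumen = "EX_glc_u",
                         EX_glc_baso = "EX_glc_e",
                         EX_fru_lumen = "EX_fru_u",
                         EX_fru_baso = "EX_fru_e",
                         EX_chylomicron = "EX_cm_e",
                         CHOLSYN = "CHOLSYN",
                         SINK_chol = "SINK_chol_r"),
                       thresholds = list(type_iii = 0.05, blockage_eps = 1e-6),
                       tolerances = list(feasibility = 1e-9,
                                         steady_state = 1e-6,
                                         optimality = 1e-8)) {
  if (thresholds$type_iii <= 0 || thresholds$type_iii >= 1 ||
      thresholds$blockage_eps <= 0 || thresholds$blockage_eps >= 1)
    stop("thresholds must lie in (0, 1)")
  structure(list(solver = solver, transporter_ids = transporter_ids,
                 thresholds = thresholds, tolerances = tolerances),
            class = "run_config")
}

require_role <- function(model, config, role) {
  id <- config$transporter_ids[[role]]
  if (is.null(id))
    stop("configuration error: no reaction id configured for role ", role)
  if (!id %in% model$reactions$id)
    stop("configuration error: reaction ", id, " (role ", role,
         ") absent from model")
  id
}
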