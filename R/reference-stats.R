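#' Published model summary statistics
#'
#' Printed element counts of the human small intestinal epithelial cell
#' reconstruction hs_sIEC611 and the murine enterocyte model mmu_ENT717
#' that this package's pipeline is designed around, as a documented
#' reference for expansion bookkeeping.
#'
#' @return nested list with `hs_sIEC611` and `mmu_ENT717` entries
#'   (reactions, metabolites, genes, intracellular_compartments).
#' @export
published_model_summary <- function() {
  list(hs_sIEC611 = list(reactions = 1282, metabolites = 433, genes = 611,
                         intracellular_compartments = 5),
       mmu_ENT717 = list(reactions = 1830, metabolites = 708, genes = 717,
                         intracellular_compartments = 6))
}

#' Relative expansion of the murine model over its human template
#'
#' @return list with `metabolite_increase_pct` and
#'   `reaction_increase_pct`, recomputed from the printed counts.
#' @export
model_expansion_stats <- function() {
  s <- published_model_summary()
  list(metabolite_increase_pct =
         100 * (s$mmu_ENT717$metabolites - s$hs_sIEC611$metabolites) /
         s$hs_sIEC611$metabolites,
       reaction_increase_pct =
         100 * (s$mmu_ENT717$reactions - s$hs_sIEC611$reactions) /
         s$hs_sIEC611$reactions)
}
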