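# Small hand-auditable fixture networks, built in code at test time.

# linear chain: EX_a_u (uptake) -> transport -> EX_b_e (secretion)
chain_model <- function(uptake_lb = -5) {
  metabolic_model(
    compartments(c("u", "c", "e"),
                 side = c("apical_lumen", "intracellular",
                          "basolateral_extracellular")),
    rbind(metabolites("a", "u"), metabolites("a", "c"),
          metabolites("b", "c"), metabolites("b", "e")),
    list(exchange_reaction("a[u]", uptake_lb, 1000),
         reaction("T_in", c("a[u]" = -1, "a[c]" = 1), 0, 1000),
         reaction("A2B", c("a[c]" = -1, "b[c]" = 1), 0, 1000),
         reaction("T_out", c("b[c]" = -1, "b[e]" = 1), 0, 1000),
         exchange_reaction("b[e]", 0, 1000)))
}

# two parallel capacity-5 routes from a to b, uptake 5
parallel_model <- function(uptake_lb = -5, cap = 5) {
  metabolic_model(
    compartments(c("u", "e"), side = c("apical_lumen",
                                       "basolateral_extracellular")),
    rbind(metabolites("a", "u"), metabolites("b", "e")),
    list(exchange_reaction("a[u]", uptake_lb, 1000),
         reaction("P1", c("a[u]" = -1, "b[e]" = 1), 0, cap),
         reaction("P2", c("a[u]" = -1, "b[e]" = 1), 0, cap),
         exchange_reaction("b[e]", 0, 1000)))
}

# Na+-coupled glucose mini-network (9 reactions): SGLT1 with declared
# stoichiometry, optional apical GLUT2, ATP-driven Na+ export lumped
# without an energy cost (kept tiny for vertex-enumeration oracles)
sglt_mini_model <- function(sigma = 2, apical_glut2 = FALSE,
                            glc_lb = -4, na_lb = -2) {
  rxns <- list(
    exchange_reaction("glc[u]", glc_lb, 1000),
    exchange_reaction("na[u]", na_lb, 1000),
    reaction("SGLT1", setNames(c(-1, -sigma, 1, sigma),
                               c("glc[u]", "na[u]", "glc[c]", "na[c]")),
             0, 1000),
    reaction("GLCGLUT2", c("glc[c]" = -1, "glc[e]" = 1), -1000, 1000),
    reaction("NAEXP", c("na[c]" = -1, "na[e]" = 1), 0, 1000),
    exchange_reaction("glc[e]", 0, 1000),
    exchange_reaction("na[e]", 0, 1000))
  if (apical_glut2)
    rxns <- c(rxns, list(reaction("GLUT2A", c("glc[u]" = -1, "glc[c]" = 1),
                                  -1000, 1000)))
  metabolic_model(
    compartments(c("u", "c", "e"),
                 side = c("apical_lumen", "intracellular",
                          "basolateral_extracellular")),
    rbind(metabolites(c("glc", "na"), "u"), metabolites(c("glc", "na"), "c"),
          metabolites(c("glc", "na"), "e")),
    rxns)
}

# two-species toy (cheaper than the 6-species default) for screens
small_toy_spec <- function(...) {
  toy_model_spec(fa_species = fatty_acid_species(c("C16:0", "C18:1")), ...)
}

toy_diet <- function(fat_en = 10, kcal = 12) {
  build_synthetic_diet(synthetic_diet_spec(fat_en, kcal))
}
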