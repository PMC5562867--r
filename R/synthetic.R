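# Miniature, fully auditable enterocyte model and synthetic study diets.
# The toy network reproduces the wiring that drives the headline
# behaviours of intestinal epithelial metabolism: Na+-coupled glucose
# uptake (SGLT1) with basolateral Na+/K+-ATPase export, facilitated
# apical/basolateral GLUT2 and GLUT5 transport, a lumped
# glycolysis/oxidative-phosphorylation energy backbone with a declared
# P:O yield, glutamine-fed gluconeogenesis, species-resolved lipid
# hydrolysis/absorption/re-esterification, lumped cholesterol biosynthesis
# with a declared ATP cost, and chylomicron assembly/secretion. Every
# optimum is computable by hand from the declared stoichiometry.

#' Specification of the toy enterocyte model
#'
#' @param include_apical_glut2 include the apical GLUT2 transporter.
#' @param na_glucose_stoichiometry Na+ ions co-transported per glucose by
#'   SGLT1 (physiological value 2).
#' @param include_gluconeogenesis include the glutamine-fed
#'   gluconeogenesis lump.
#' @param fa_species fatty acid species table ([fatty_acid_species()]) or
#'   character codes; must be non-empty.
#' @param atp_per_cholesterol ATP cost of the lumped cholesterol
#'   biosynthesis pathway (mol ATP per mol cholesterol).
#' @param p_to_o_yield ATP produced per atom of oxygen reduced (P:O).
#' @param atp_per_phospholipid,atp_per_apoprotein ATP costs of the lumped
#'   phospholipid and apolipoprotein supply reactions.
#' @param seed integer seed (reserved for optional stochastic variants;
#'   the builder itself is deterministic).
#' @return list of class `toy_model_spec`.
#' @export
toy_model_spec <- function(include_apical_glut2 = TRUE,
                           na_glucose_stoichiometry = 2,
                           include_gluconeogenesis = TRUE,
                           fa_species = fatty_acid_species(),
                           atp_per_cholesterol = 100,
                           p_to_o_yield = 2.5,
                           atp_per_phospholipid = 10,
                           atp_per_apoprotein = 100,
                           seed = 1L) {
  if (is.character(fa_species)) fa_species <- fatty_acid_species(fa_species)
  if (nrow(fa_species) == 0)
    stop("toy model spec invalid: chylomicron pathway requires fa_species")
  if (na_glucose_stoichiometry <= 0 || p_to_o_yield <= 0 ||
      atp_per_cholesterol <= 0)
    stop("stoichiometric parameters must be positive")
  structure(list(include_apical_glut2 = include_apical_glut2,
                 na_glucose_stoichiometry = na_glucose_stoichiometry,
                 include_gluconeogenesis = include_gluconeogenesis,
                 fa_species = fa_species,
                 atp_per_cholesterol = atp_per_cholesterol,
                 p_to_o_yield = p_to_o_yield,
                 atp_per_phospholipid = atp_per_phospholipid,
                 atp_per_apoprotein = atp_per_apoprotein,
                 seed = as.integer(seed)),
            class = "toy_model_spec")
}

toy_amino_acids <- function() {
  # reduced casein profile: 5 representative amino acids incl. glutamine
  data.frame(token = c("gln", "ala", "leu", "lys", "pro"),
             formula = c("C5", "C3", "C6", "C6", "C5"),
             stringsAsFactors = FALSE)
}

#' Build the miniature enterocyte model
#'
#' Compartments: apical lumen `u`, cytosol `c`, mitochondrion `m`,
#' endoplasmic reticulum `r`, basolateral extracellular `e`. With the six
#' default fatty acid species the model has ~120 reactions. The default
#' model passes [validate_model()] with no dead ends and no blocked
#' reactions; the luminal exchange bounds are open (+/-1000) until a diet
#' is applied via [apply_exchange_bounds()].
#'
#' @param spec a [toy_model_spec()].
#' @return a `metabolic_model`.
#' @export
build_toy_model <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  sigma <- spec$na_glucose_stoichiometry
  k_atp <- 5 * spec$p_to_o_yield       # ATP per pyruvate through oxphos
  comps <- compartments(
    c("u", "c", "m", "r", "e"),
    c("apical lumen", "cytosol", "mitochondrion",
      "endoplasmic reticulum", "basolateral extracellular"),
    c("apical_lumen", "intracellular", "intracellular", "intracellular",
      "basolateral_extracellular"))

  mets <- rbind(
    metabolites(rep("glc", 3), c("u", "c", "e"), "glucose", "C6"),
    metabolites(rep("fru", 3), c("u", "c", "e"), "fructose", "C6"),
    metabolites(rep("na", 3), c("u", "c", "e"), "sodium", "Na"),
    metabolites("pyr", c("c", "m"), "pyruvate", "C3"),
    metabolites("o2", c("e", "c", "m"), "oxygen", "O2"),
    metabolites("co2", c("m", "c", "e"), "carbon dioxide", "CO2"))

  rxns <- list(
    exchange_reaction("glc[u]", -1000, 1000),
    exchange_reaction("fru[u]", -1000, 1000),
    exchange_reaction("na[u]", -1000, 1000),
    reaction("SGLT1",
             setNames(c(-1, -sigma, 1, sigma),
                      c("glc[u]", "na[u]", "glc[c]", "na[c]")),
             0, 1000, gene_rule = "Slc5a1", subsystem = "carbohydrate transport"),
    reaction("GLUT5A", c("fru[u]" = -1, "fru[c]" = 1), -1000, 1000,
             gene_rule = "Slc2a5", subsystem = "carbohydrate transport"),
    reaction("GLCGLUT2", c("glc[c]" = -1, "glc[e]" = 1), -1000, 1000,
             gene_rule = "Slc2a2", subsystem = "carbohydrate transport"),
    reaction("FRUGLUT5B", c("fru[c]" = -1, "fru[e]" = 1), -1000, 1000,
             gene_rule = "Slc2a5", subsystem = "carbohydrate transport"),
    exchange_reaction("glc[e]", 0, 1000),
    exchange_reaction("fru[e]", 0, 1000),
    reaction("NAKATPASE",
             c("na[c]" = -3, "atp[c]" = -1, "na[e]" = 3, "adp[c]" = 1,
               "pi[c]" = 1),
             0, 1000, gene_rule = "Atp1a1", subsystem = "ion transport"),
    exchange_reaction("na[e]", 0, 1000),
    reaction("GLYCOLYSIS",
             c("glc[c]" = -1, "adp[c]" = -2, "pi[c]" = -2,
               "pyr[c]" = 2, "atp[c]" = 2),
             0, 1000, gene_rule = "Gck and Pfkl and Pkm",
             subsystem = "glycolysis (lumped)"),
    reaction("PYRTM", c("pyr[c]" = -1, "pyr[m]" = 1), 0, 1000,
             gene_rule = "Mpc1 and Mpc2", subsystem = "mitochondrial transport"),
    reaction("OXPHOS",
             setNames(c(-1, -2.5, -k_atp, -k_atp, 3, k_atp),
                      c("pyr[m]", "o2[m]", "adp[c]", "pi[c]", "co2[m]",
                        "atp[c]")),
             0, 1000, gene_rule = "Sdha and Cox4i1 and Atp5f1a",
             subsystem = "TCA cycle and oxidative phosphorylation (lumped)"),
    reaction("O2TE", c("o2[e]" = -1, "o2[c]" = 1), -1000, 1000,
             subsystem = "diffusion"),
    reaction("O2TM", c("o2[c]" = -1, "o2[m]" = 1), -1000, 1000,
             subsystem = "diffusion"),
    exchange_reaction("o2[e]", -1000, 1000),
    reaction("CO2TM", c("co2[m]" = -1, "co2[c]" = 1), -1000, 1000,
             subsystem = "diffusion"),
    reaction("CO2TE", c("co2[c]" = -1, "co2[e]" = 1), -1000, 1000,
             subsystem = "diffusion"),
    exchange_reaction("co2[e]", 0, 1000))

  if (spec$include_apical_glut2) {
    rxns <- c(rxns, list(
      reaction("GLUT2A", c("glc[u]" = -1, "glc[c]" = 1), -1000, 1000,
               gene_rule = "Slc2a2", subsystem = "carbohydrate transport")))
  }

  # amino acid transit (+ gluconeogenesis from glutamine)
  aas <- toy_amino_acids()
  for (i in seq_len(nrow(aas))) {
    a <- aas$token[i]
    mets <- rbind(mets, metabolites(rep(a, 3), c("u", "c", "e"),
                                    a, aas$formula[i]))
    rxns <- c(rxns, list(
      exchange_reaction(met_id(a, "u"), -1000, 1000),
      reaction(paste0("AAABS_", a),
               setNames(c(-1, 1), met_id(c(a, a), c("u", "c"))), 0, 1000,
               gene_rule = "Slc6a19", subsystem = "amino acid transport"),
      reaction(paste0("AAEXP_", a),
               setNames(c(-1, 1), met_id(c(a, a), c("c", "e"))), 0, 1000,
               subsystem = "amino acid transport"),
      exchange_reaction(met_id(a, "e"), 0, 1000)))
  }
  if (spec$include_gluconeogenesis) {
    mets <- rbind(mets, metabolites("nh4", c("c", "e"), "ammonium", "H4N"))
    rxns <- c(rxns, list(
      reaction("GLUCONEOGENESIS",
               c("gln[c]" = -2, "atp[c]" = -3, "glc[c]" = 1, "adp[c]" = 3,
                 "pi[c]" = 3, "nh4[c]" = 4, "co2[c]" = 4),
               0, 1000, gene_rule = "Pck1 and Fbp1 and G6pc",
               subsystem = "gluconeogenesis (lumped)"),
      reaction("NH4TE", c("nh4[c]" = -1, "nh4[e]" = 1), 0, 1000,
               subsystem = "diffusion"),
      exchange_reaction("nh4[e]", 0, 1000)))
  }

  # species-resolved lipid pathways
  lip <- generate_lipid_reactions(spec$fa_species)
  rxns <- c(rxns, lip$reactions)
  mets <- rbind(mets, lip$metabolites[!lip$metabolites$id %in% mets$id, ])
  for (tok in spec$fa_species$token) {
    rxns <- c(rxns, list(
      exchange_reaction(met_id(paste0("tag", tok), "u"), -1000, 1000),
      exchange_reaction(met_id(paste0("mag", tok), "u"), -1000, 1000),
      exchange_reaction(met_id(paste0("ffa", tok), "u"), -1000, 1000)))
  }

  # chylomicron assembly (flexible TAG pool wiring) and its supplies
  n_sp <- nrow(spec$fa_species)
  prof <- chylomicron_profile(
    setNames(rep(1 / n_sp, n_sp), spec$fa_species$code))
  asm <- build_chylomicron_assembly(prof, flexible_fa = TRUE)
  mets <- rbind(mets, asm$metabolites[!asm$metabolites$id %in% mets$id, ])
  rxns <- c(rxns, list(asm$assembly, asm$exchange))
  ac <- spec$atp_per_cholesterol
  ap <- spec$atp_per_phospholipid
  aa_apo <- spec$atp_per_apoprotein
  rxns <- c(rxns, list(
    reaction("CHOLSYN",
             setNames(c(-ac, 1, ac, ac),
                      c("atp[c]", "chol[r]", "adp[c]", "pi[c]")),
             0, 1000, gene_rule = "Hmgcr and Dhcr7",
             subsystem = "cholesterol biosynthesis (lumped)"),
    reaction("PLSYN",
             setNames(c(-ap, 1, ap, ap),
                      c("atp[c]", "pl[r]", "adp[c]", "pi[c]")),
             0, 1000, subsystem = "phospholipid supply (lumped)"),
    reaction("APOSYN",
             setNames(c(-aa_apo, 1, aa_apo, aa_apo),
                      c("atp[c]", "apoprot[r]", "adp[c]", "pi[c]")),
             0, 1000, gene_rule = "Apob",
             subsystem = "apolipoprotein supply (lumped)"),
    exchange_reaction("chol[r]", 0, 0, id = "SINK_chol_r")))

  metabolic_model(comps, mets, rxns,
                  objective = list(reaction = "EX_glc_e",
                                   direction = "maximize"))
}

#' Specification of a synthetic study diet
#'
#' The four study diets derive 10/20/30/45% of energy from fat and a fixed
#' 20% from protein; carbohydrate supplies the remainder. All diets are
#' cholesterol-free (palm/soy oil are the only lipid sources): the soy oil
#' contribution is a constant floor and palm oil is exchanged against
#' starch as the fat content rises.
#'
#' @param fat_en_percent energy% from fat; one of 10, 20, 30, 45 unless
#'   `allow_custom`.
#' @param total_kcal_per_day daily energy intake (kcal); default 12, a
#'   typical adult mouse intake.
#' @param fa_profile optional named mass-fraction vector over FA codes
#'   overriding the palm/soy blend.
#' @param soy_en_percent constant soy oil energy% floor.
#' @param allow_custom permit fat_en_percent outside the study set.
#' @return list of class `synthetic_diet_spec`.
#' @export
synthetic_diet_spec <- function(fat_en_percent,
                                total_kcal_per_day = 12,
                                fa_profile = NULL,
                                soy_en_percent = 3,
                                allow_custom = FALSE) {
  if (!allow_custom && !fat_en_percent %in% c(10, 20, 30, 45))
    stop("fat_en_percent must be one of 10, 20, 30, 45 ",
         "(use allow_custom = TRUE to override)")
  if (fat_en_percent + 20 >= 100) stop("fat + protein energy exceeds 100%")
  if (!is.null(fa_profile) && abs(sum(fa_profile) - 1) > 1e-9)
    stop("fa_profile must sum to 1")
  structure(list(fat_en_percent = fat_en_percent,
                 protein_en_percent = 20,
                 total_kcal_per_day = total_kcal_per_day,
                 fa_profile = fa_profile,
                 soy_en_percent = min(soy_en_percent, fat_en_percent),
                 cholesterol_free = TRUE),
            class = "synthetic_diet_spec")
}

# oil FA mass-fraction profiles (normalized palm / soybean compositions)
.palm_fa <- c("C14:0" = 0.011, "C16:0" = 0.444, "C18:0" = 0.046,
              "C18:1" = 0.392, "C18:2" = 0.102, "C18:3" = 0.005)
.soy_fa <- c("C14:0" = 0.005, "C16:0" = 0.110, "C18:0" = 0.040,
             "C18:1" = 0.230, "C18:2" = 0.540, "C18:3" = 0.075)

# reduced casein-like amino acid mass fractions (18 amino acids)
.casein_aa <- c(ala = 0.031, arg = 0.036, asn = 0.031, asp = 0.062,
                cys = 0.005, gln = 0.082, glu = 0.144, gly = 0.021,
                his = 0.031, ile = 0.051, leu = 0.092, lys = 0.082,
                met = 0.026, phe = 0.051, pro = 0.103, ser = 0.051,
                thr = 0.041, val = 0.060)
.aa_mw <- c(ala = 89.09, arg = 174.20, asn = 132.12, asp = 133.10,
            cys = 121.16, gln = 146.15, glu = 147.13, gly = 75.07,
            his = 155.15, ile = 131.17, leu = 131.17, lys = 146.19,
            met = 149.21, phe = 165.19, pro = 115.13, ser = 105.09,
            thr = 119.12, val = 117.15)

#' Build a synthetic study diet
#'
#' Energy bookkeeping uses the standard 4/4/9 kcal/g densities for
#' carbohydrate/protein/fat. Lipids enter as TAG species (palm/soy FA
#' blend); luminal MAG and FFA exchange entries are present at zero intake
#' (they matter for dietary-rescue scans). Carbohydrate is supplied as
#' glucose plus fructose, with a fixed sucrose contribution (10 energy%)
#' providing the fructose and the starch-derived remainder counted as
#' glucose. Protein is an 18-amino-acid casein-like profile; sodium enters
#' at a fixed 2.5e-5 mol per kcal of feed (3e-4 mol/day at the default
#' intake). Altogether this yields the 39 dietary nutrient exchanges of
#' the study design.
#'
#' @param spec a [synthetic_diet_spec()].
#' @return a [diet_composition()] named `"<fat>en%"`.
#' @export
build_synthetic_diet <- function(spec) {
  stopifnot(inherits(spec, "synthetic_diet_spec"))
  kcal <- spec$total_kcal_per_day
  fat_en <- spec$fat_en_percent / 100
  prot_en <- spec$protein_en_percent / 100
  carb_en <- 1 - fat_en - prot_en

  fat_g <- fat_en * kcal / 9
  soy_g <- spec$soy_en_percent / 100 * kcal / 9
  palm_g <- fat_g - soy_g
  fa_mass <- if (!is.null(spec$fa_profile)) fat_g * spec$fa_profile else
    palm_g * .palm_fa + soy_g * .soy_fa
  sp <- fatty_acid_species(names(fa_mass))
  tag_mol <- setNames(as.numeric(fa_mass) / mw_tag(sp$mw),
                      paste0("tag", sp$token))

  sucrose_en <- min(10, 100 * carb_en) / 100
  suc_mol <- sucrose_en * kcal / 4 / 342.30
  glc_rest_g <- (carb_en - sucrose_en) * kcal / 4
  glucose <- suc_mol + glc_rest_g / 180.16
  fructose <- suc_mol

  prot_g <- prot_en * kcal / 4
  aa_mol <- prot_g * .casein_aa / .aa_mw[names(.casein_aa)]

  intakes <- c(tag_mol,
               setNames(rep(0, nrow(sp)), paste0("mag", sp$token)),
               setNames(rep(0, nrow(sp)), paste0("ffa", sp$token)),
               glc = unname(glucose), fru = unname(fructose),
               aa_mol, na = 2.5e-5 * kcal)  # ~0.25% NaCl in feed mass
  classes <- c(setNames(rep("lipid", 3 * nrow(sp)),
                        c(names(tag_mol), paste0("mag", sp$token),
                          paste0("ffa", sp$token))),
               glc = "carbohydrate", fru = "carbohydrate",
               setNames(rep("amino_acid", length(aa_mol)), names(aa_mol)),
               na = "mineral")
  diet_composition(paste0(spec$fat_en_percent, "en%"), intakes,
                   energy_fractions = c(fat = fat_en, carbohydrate = carb_en,
                                        protein = prot_en),
                   nutrient_class = classes)
}

#' The four study diets
#' @param total_kcal_per_day daily energy intake passed to each diet.
#' @return named list of [diet_composition()] objects
#'   (`10en%` ... `45en%`).
#' @export
study_diets <- function(total_kcal_per_day = 12) {
  fat <- c(10, 20, 30, 45)
  out <- lapply(fat, function(f)
    build_synthetic_diet(synthetic_diet_spec(f, total_kcal_per_day)))
  names(out) <- paste0(fat, "en%")
  out
}
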