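# Fatty-acid-species-resolved lipid pathways. Dietary TAG is broken down
# into individual fatty acid (FA) species with a uniform acyl composition:
# every TAG/DAG/MAG molecule carries three/two/one identical acyl chains.
# This keeps the combinatorics linear in the number of FA species while
# retaining the full dietary FA profile.

#' The six dietary fatty acid species
#'
#' @param codes subset of `c("C14:0","C16:0","C18:0","C18:1","C18:2","C18:3")`.
#' @return data.frame with columns `code`, `token` (id-safe), `name`,
#'   `carbon_count`, `double_bonds`, `mw` (g/mol, free acid).
#' @export
fatty_acid_species <- function(codes = c("C14:0", "C16:0", "C18:0",
                                         "C18:1", "C18:2", "C18:3")) {
  tab <- data.frame(
    code = c("C14:0", "C16:0", "C18:0", "C18:1", "C18:2", "C18:3"),
    token = c("140", "160", "180", "181", "182", "183"),
    name = c("myristic acid", "palmitic acid", "stearic acid",
             "oleic acid", "linoleic acid", "linolenic acid"),
    carbon_count = c(14L, 16L, 18L, 18L, 18L, 18L),
    double_bonds = c(0L, 0L, 0L, 1L, 2L, 3L),
    mw = c(228.37, 256.42, 284.48, 282.46, 280.45, 278.43),
    stringsAsFactors = FALSE)
  if (anyDuplicated(codes)) stop("duplicate fatty acid species codes")
  idx <- match(codes, tab$code)
  if (anyNA(idx)) stop("unknown fatty acid species code(s): ",
                       paste(codes[is.na(idx)], collapse = ", "))
  tab[idx, , drop = FALSE]
}

# ester-bond mass bookkeeping (glycerol 92.09, water 18.02 per bond)
.mw_glycerol <- 92.09
.mw_water <- 18.02
.mw_cholesterol <- 386.65
.mw_phospholipid <- 760    # generic glycerophospholipid
.mw_apoprotein <- 241000   # apolipoprotein B-48 scale

mw_tag <- function(mw_fa) 3 * mw_fa + .mw_glycerol - 3 * .mw_water
mw_dag <- function(mw_fa) 2 * mw_fa + .mw_glycerol - 2 * .mw_water
mw_mag <- function(mw_fa) mw_fa + .mw_glycerol - .mw_water
mw_ce  <- function(mw_fa) mw_fa + .mw_cholesterol - .mw_water

carbon_formula <- function(n) paste0("C", n)

#' Molar masses of the species-resolved lipid classes
#'
#' Ester-bond bookkeeping from the free-acid masses: each esterification
#' to the glycerol (92.09 g/mol) or cholesterol (386.65 g/mol) backbone
#' releases one water (18.02 g/mol). Used to convert chylomicron mass
#' fractions into molar coefficients.
#'
#' @param species [fatty_acid_species()] table.
#' @return data.frame with `code` and `ffa`, `mag`, `dag`, `tag`,
#'   `cholesteryl_ester` molar masses (g/mol); the generic phospholipid
#'   and apolipoprotein masses are attached as attributes.
#' @export
lipid_molar_masses <- function(species = fatty_acid_species()) {
  out <- data.frame(code = species$code, ffa = species$mw,
                    mag = mw_mag(species$mw), dag = mw_dag(species$mw),
                    tag = mw_tag(species$mw),
                    cholesteryl_ester = mw_ce(species$mw),
                    stringsAsFactors = FALSE)
  attr(out, "phospholipid") <- .mw_phospholipid
  attr(out, "apoprotein") <- .mw_apoprotein
  out
}

#' Generate species-resolved lipid absorption and re-synthesis reactions
#'
#' Per fatty acid species the generator emits:
#' \itemize{
#'  \item 1 hydrolysis reaction (luminal lipase): TAG -> MAG + 2 FFA;
#'  \item 3 absorption reactions: carrier-mediated FFA apical transport,
#'    FFA apical diffusion, MAG apical transport;
#'  \item 6 re-synthesis reactions: acyl-CoA activation (2 ATP), acyl-CoA
#'    and MAG transport into the ER, MGAT (MAG + acyl-CoA -> DAG), DGAT
#'    (DAG + acyl-CoA -> TAG), and MTTP-like transfer of ER TAG into the
#'    common chylomicron TAG pool;
#'  \item 1 cholesteryl ester formation (acyl-CoA + cholesterol -> CE).
#' }
#' so six species yield 18 absorption, 36 re-synthesis and 6 cholesteryl
#' ester reactions. The per-species breakdown of the absorption and
#' re-synthesis totals is a documented template (constants below), so the
#' counts are auditable.
#'
#' Compartment tokens: `u` apical lumen, `c` cytosol, `r` endoplasmic
#' reticulum.
#'
#' @param species data.frame from [fatty_acid_species()], or a character
#'   vector of codes.
#' @return a `lipid_reaction_set`: list with `reactions` (list of
#'   `mf_reaction`), `category` (named character by reaction id),
#'   `category_counts`, `metabolites` (data.frame of metabolites the
#'   reactions introduce) and `species`.
#' @export
generate_lipid_reactions <- function(species = fatty_acid_species()) {
  if (is.character(species)) species <- fatty_acid_species(species)
  if (nrow(species) == 0) stop("species list must be non-empty")
  if (anyDuplicated(species$code)) stop("duplicate fatty acid species")
  rxns <- list()
  cat <- character(0)
  mets <- NULL
  add <- function(rx, category) {
    rxns[[length(rxns) + 1L]] <<- rx
    cat[rx$id] <<- category
  }
  for (i in seq_len(nrow(species))) {
    tok <- species$token[i]
    k <- species$carbon_count[i]
    ffa <- paste0("ffa", tok); mag <- paste0("mag", tok)
    dag <- paste0("dag", tok); tag <- paste0("tag", tok)
    facoa <- paste0("facoa", tok)
    sp_mets <- rbind(
      metabolites(tag, "u", paste0("TAG (", species$code[i], ")"), carbon_formula(3 * k + 3)),
      metabolites(mag, "u", paste0("2-MAG (", species$code[i], ")"), carbon_formula(k + 3)),
      metabolites(ffa, "u", paste0("FFA (", species$code[i], ")"), carbon_formula(k)),
      metabolites(ffa, "c", formula = carbon_formula(k)),
      metabolites(mag, "c", formula = carbon_formula(k + 3)),
      metabolites(facoa, "c", paste0("acyl-CoA (", species$code[i], ")"), carbon_formula(k)),
      metabolites(facoa, "r", formula = carbon_formula(k)),
      metabolites(mag, "r", formula = carbon_formula(k + 3)),
      metabolites(dag, "r", paste0("DAG (", species$code[i], ")"), carbon_formula(2 * k + 3)),
      metabolites(tag, "r", formula = carbon_formula(3 * k + 3)))
    mets <- rbind(mets, sp_mets)
    # hydrolysis (luminal lipase)
    add(reaction(paste0("LIPASE_", tok),
                 setNames(c(-1, 1, 2), met_id(c(tag, mag, ffa), "u")),
                 0, 1000, gene_rule = "Pnlip", subsystem = "lipid hydrolysis"),
        "hydrolysis")
    # absorption: carrier, diffusion, MAG transport
    add(reaction(paste0("FAABSC_", tok),
                 setNames(c(-1, 1), c(met_id(ffa, "u"), met_id(ffa, "c"))),
                 0, 1000, gene_rule = "Cd36 or Slc27a4",
                 subsystem = "lipid absorption"), "absorption")
    add(reaction(paste0("FAABSD_", tok),
                 setNames(c(-1, 1), c(met_id(ffa, "u"), met_id(ffa, "c"))),
                 0, 1000, subsystem = "lipid absorption"), "absorption")
    add(reaction(paste0("MAGABS_", tok),
                 setNames(c(-1, 1), c(met_id(mag, "u"), met_id(mag, "c"))),
                 0, 1000, subsystem = "lipid absorption"), "absorption")
    # re-synthesis ladder (6 steps)
    add(reaction(paste0("FACOA_", tok),
                 setNames(c(-1, -2, 1, 2, 2),
                          c(met_id(ffa, "c"), met_id("atp", "c"),
                            met_id(facoa, "c"), met_id("adp", "c"),
                            met_id("pi", "c"))),
                 0, 1000, gene_rule = "Acsl5",
                 subsystem = "lipid re-synthesis"), "resynthesis")
    add(reaction(paste0("FACOATR_", tok),
                 setNames(c(-1, 1), c(met_id(facoa, "c"), met_id(facoa, "r"))),
                 0, 1000, subsystem = "lipid re-synthesis"), "resynthesis")
    add(reaction(paste0("MAGTR_", tok),
                 setNames(c(-1, 1), c(met_id(mag, "c"), met_id(mag, "r"))),
                 0, 1000, subsystem = "lipid re-synthesis"), "resynthesis")
    add(reaction(paste0("MGAT_", tok),
                 setNames(c(-1, -1, 1),
                          c(met_id(mag, "r"), met_id(facoa, "r"), met_id(dag, "r"))),
                 0, 1000, gene_rule = "Mogat2",
                 subsystem = "lipid re-synthesis"), "resynthesis")
    add(reaction(paste0("DGAT_", tok),
                 setNames(c(-1, -1, 1),
                          c(met_id(dag, "r"), met_id(facoa, "r"), met_id(tag, "r"))),
                 0, 1000, gene_rule = "Dgat1 or Dgat2",
                 subsystem = "lipid re-synthesis"), "resynthesis")
    add(reaction(paste0("MTTP_", tok),
                 setNames(c(-1, 1), c(met_id(tag, "r"), met_id("tagcm", "r"))),
                 0, 1000, gene_rule = "Mttp",
                 subsystem = "lipid re-synthesis"), "resynthesis")
    # cholesteryl ester formation
    add(reaction(paste0("ACAT_", tok),
                 setNames(c(-1, -1, 1),
                          c(met_id(facoa, "r"), met_id("chol", "r"), met_id("ce", "r"))),
                 0, 1000, gene_rule = "Soat2",
                 subsystem = "cholesteryl ester"), "cholesteryl_ester")
  }
  shared <- rbind(
    metabolites("tagcm", "r", "chylomicron TAG pool (mixed species)"),
    metabolites("chol", "r", "cholesterol", "C27"),
    metabolites("ce", "r", "cholesteryl ester pool (mixed species)"),
    metabolites("atp", "c", "ATP", "C10"),
    metabolites("adp", "c", "ADP", "C10"),
    metabolites("pi", "c", "orthophosphate", "P"))
  mets <- rbind(mets, shared)
  counts <- vapply(c("hydrolysis", "absorption", "resynthesis",
                     "cholesteryl_ester", "chylomicron"),
                   function(x) sum(cat == x), integer(1))
  structure(list(reactions = rxns, category = cat,
                 category_counts = counts, metabolites = mets,
                 species = species),
            class = "lipid_reaction_set")
}

#' @export
print.lipid_reaction_set <- function(x, ...) {
  cat("Lipid reaction set for", nrow(x$species), "fatty acid species\n")
  print(x$category_counts)
  invisible(x)
}

#' Carbon balance of generated reactions
#'
#' Checks, for every reaction whose metabolites all carry a declared
#' formula, that carbon is conserved. Reactions touching an unformulated
#' pool (e.g. mixed-species TAG) are reported as `NA`.
#'
#' @param reactions list of `mf_reaction`.
#' @param metabolite_table data.frame with `id` and `formula`.
#' @return data.frame with `reaction` and `carbon_delta` (0 = balanced).
#' @export
carbon_balance <- function(reactions, metabolite_table) {
  cnum <- function(f) {
    if (is.na(f)) return(NA_real_)
    m <- regmatches(f, regexec("C([0-9]*)(?![a-z])", f, perl = TRUE))[[1]]
    if (!length(m)) return(0)
    if (m[2] == "") 1 else as.numeric(m[2])
  }
  fmap <- setNames(metabolite_table$formula, metabolite_table$id)
  delta <- vapply(reactions, function(rx) {
    fs <- fmap[names(rx$stoichiometry)]
    if (anyNA(fs)) return(NA_real_)
    sum(rx$stoichiometry * vapply(fs, cnum, numeric(1)))
  }, numeric(1))
  data.frame(reaction = vapply(reactions, `[[`, character(1), "id"),
             carbon_delta = delta, row.names = NULL, stringsAsFactors = FALSE)
}

#' Chylomicron composition profile
#'
#' @param fa_fractions named numeric, mole fractions over FA species codes;
#'   must sum to 1.
#' @param component_mass_fractions named numeric over
#'   `c("TAG","phospholipid","cholesterol_ester","protein")`; must sum
#'   to 1. The printed particle composition (~95% TAG, ~4% phospholipid,
#'   ~1% cholesteryl ester, ~2% protein) slightly overfills the total, so
#'   the default folds the protein contribution into a fixed apolipoprotein
#'   demand instead (`protein = 0` here).
#' @return list of class `chylomicron_profile`.
#' @export
chylomicron_profile <- function(fa_fractions,
                                component_mass_fractions = c(
                                  TAG = 0.95, phospholipid = 0.04,
                                  cholesterol_ester = 0.01, protein = 0)) {
  if (abs(sum(fa_fractions) - 1) > 1e-9)
    stop("fa_fractions must sum to 1")
  if (abs(sum(component_mass_fractions) - 1) > 1e-9)
    stop("component_mass_fractions must sum to 1")
  structure(list(fa_fractions = fa_fractions,
                 component_mass_fractions = component_mass_fractions),
            class = "chylomicron_profile")
}

#' Build the chylomicron assembly/secretion pseudo-reaction (CHYLOMGE)
#'
#' Converts the particle's component mass fractions into molar
#' coefficients per reference particle unit (a pseudo-metabolite of
#' declared molar mass `reference_mass`): each coefficient is
#' `fraction * reference_mass / component_molar_mass`. The reaction
#' consumes ER TAG, phospholipid, cholesteryl ester and an apolipoprotein
#' precursor, and produces one basolateral chylomicron particle; its
#' exchange reaction is returned alongside.
#'
#' Two TAG wirings are supported. With `flexible_fa = FALSE` (the default)
#' the reaction consumes species-specific ER TAG in the profile's
#' `fa_fractions` proportions. With `flexible_fa = TRUE` it consumes the
#' mixed-species chylomicron TAG pool (`tagcm[r]`) fed by the per-species
#' MTTP-like transfer reactions, so the realized FA composition is free to
#' follow the diet; the profile's `fa_fractions` then only set the pool's
#' average molar mass.
#'
#' @param profile a [chylomicron_profile()].
#' @param reference_mass molar mass (g/mol) assigned to one particle unit.
#' @param apoprotein_demand fixed molar coefficient of the apolipoprotein
#'   precursor per particle unit (used when the protein mass fraction is 0).
#' @param flexible_fa see above.
#' @return list of class `chylomicron_assembly` with `assembly`
#'   (`mf_reaction`, id `CHYLOMGE`), `exchange` (`EX_cm_e`),
#'   `metabolites`, and `coefficients`.
#' @export
build_chylomicron_assembly <- function(profile, reference_mass = 10000,
                                       apoprotein_demand = 1e-4,
                                       flexible_fa = FALSE) {
  stopifnot(inherits(profile, "chylomicron_profile"))
  fr <- profile$component_mass_fractions
  fa <- profile$fa_fractions
  sp <- fatty_acid_species(names(fa))
  mw_tag_avg <- sum(fa * mw_tag(sp$mw))
  mw_ce_avg <- sum(fa * mw_ce(sp$mw))
  tag_total <- fr[["TAG"]] * reference_mass / mw_tag_avg
  pl_coef <- fr[["phospholipid"]] * reference_mass / .mw_phospholipid
  ce_coef <- fr[["cholesterol_ester"]] * reference_mass / mw_ce_avg
  apo_coef <- if (fr[["protein"]] > 0)
    fr[["protein"]] * reference_mass / .mw_apoprotein else apoprotein_demand
  st <- c()
  if (flexible_fa) {
    st[met_id("tagcm", "r")] <- -tag_total
  } else {
    st[met_id(paste0("tag", sp$token), "r")] <- -tag_total * as.numeric(fa)
  }
  st[met_id("pl", "r")] <- -pl_coef
  st[met_id("ce", "r")] <- -ce_coef
  st[met_id("apoprot", "r")] <- -apo_coef
  st[met_id("cm", "e")] <- 1
  assembly <- reaction("CHYLOMGE", st, 0, 1000, gene_rule = "Apob and Mttp",
                       subsystem = "chylomicron assembly")
  mets <- rbind(
    metabolites("pl", "r", "phospholipid (generic)"),
    metabolites("apoprot", "r", "apolipoprotein precursor"),
    metabolites("cm", "e", "chylomicron particle"))
  structure(list(assembly = assembly,
                 exchange = exchange_reaction(met_id("cm", "e")),
                 metabolites = mets,
                 coefficients = list(tag_total = unname(tag_total),
                                     phospholipid = unname(pl_coef),
                                     cholesterol_ester = unname(ce_coef),
                                     apoprotein = unname(apo_coef),
                                     reference_mass = reference_mass)),
            class = "chylomicron_assembly")
}

#' Fatty acid composition of secreted chylomicrons
#'
#' Reads, from an optimal FBA solution, the per-species TAG fluxes feeding
#' the chylomicron assembly and normalizes them to mole fractions. Handles
#' both assembly wirings: with a pooled TAG substrate the per-species
#' MTTP-like transfer fluxes are used; with a fixed-profile assembly the
#' assembly's own species-specific TAG coefficients are used.
#'
#' @param solution an optimal `fba_solution`.
#' @param model the `metabolic_model` the solution came from.
#' @param tol total TAG flux below which the composition is undefined.
#' @return a `chylomicron_profile` (component fractions taken from the
#'   assembly coefficients are not recomputed; `fa_fractions` carry the
#'   result).
#' @export
chylomicron_fa_composition <- function(solution, model, tol = 1e-9) {
  if (solution$status != "optimal") stop("solution is not optimal")
  pool_consumers <- vapply(seq_along(model$stoich), function(j) {
    st <- model$stoich[[j]]
    any(names(st) == met_id("tagcm", "r") & st > 0) &&
      any(grepl("^tag[0-9]+\\[r\\]$", names(st)) & st < 0)
  }, logical(1))
  flux_by_species <- c()
  if (any(pool_consumers)) {
    for (j in which(pool_consumers)) {
      st <- model$stoich[[j]]
      tag_met <- names(st)[grepl("^tag[0-9]+\\[r\\]$", names(st)) & st < 0]
      tok <- sub("^tag([0-9]+)\\[r\\]$", "\\1", tag_met)
      v <- solution$fluxes[[model$reactions$id[j]]] * (-st[[tag_met]])
      flux_by_species[tok] <- (if (tok %in% names(flux_by_species))
        flux_by_species[[tok]] else 0) + v
    }
  } else {
    j <- which(vapply(model$stoich, function(st)
      any(grepl("^cm\\[", names(st)) & st > 0) &&
        any(grepl("^tag[0-9]+\\[r\\]$", names(st)) & st < 0), logical(1)))
    if (!length(j)) stop("model has no chylomicron assembly consuming TAG")
    st <- model$stoich[[j[1]]]
    tags <- names(st)[grepl("^tag[0-9]+\\[r\\]$", names(st)) & st < 0]
    v <- solution$fluxes[[model$reactions$id[j[1]]]]
    flux_by_species <- setNames(-as.numeric(st[tags]) * v,
                                sub("^tag([0-9]+)\\[r\\]$", "\\1", tags))
  }
  total <- sum(flux_by_species)
  if (!is.finite(total) || total < tol)
    stop("chylomicron FA composition undefined: zero TAG flux into assembly")
  sp <- fatty_acid_species()
  codes <- sp$code[match(names(flux_by_species), sp$token)]
  chylomicron_profile(setNames(as.numeric(flux_by_species) / total, codes))
}
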