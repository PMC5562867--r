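# SBML Level 3 Version 1 + FBC version 2 reader/writer (the subset used
# by constraint-based models: compartments, species with chemical
# formulas, reactions with flux-bound parameters, gene product
# associations, and the active objective). Identifiers are mapped to SId
# form (`M_<base>_<comp>`, `R_<id>`, `C_<id>`, `G_<gene>`) on write and
# inverted on read.

.sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Write a model as SBML L3V1 + FBC v2
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns, level = "3",
                            version = "1", "xmlns:fbc" = .fbc_ns,
                            "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "true")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments))) {
    xml2::xml_add_child(lc, "compartment",
                        id = paste0("C_", sid(model$compartments$id[i])),
                        name = model$compartments$name[i],
                        constant = "true")
    xml2::xml_set_attr(xml2::xml_children(lc)[[i]], "sboTerm",
                       switch(model$compartments$side[i],
                              intracellular = "SBO:0000290",
                              apical_lumen = "SBO:0000309",
                              basolateral_extracellular = "SBO:0000284"))
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    met <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species",
                              id = paste0("M_", sid(met$base_id), "_",
                                          sid(met$compartment)),
                              name = met$name,
                              compartment = paste0("C_", sid(met$compartment)),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false",
                              constant = "false")
    if (!is.na(met$formula))
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula)
  }
  # flux-bound parameters, one per distinct value
  bvals <- sort(unique(c(model$reactions$lower_bound,
                         model$reactions$upper_bound)))
  bid <- setNames(paste0("FB_", seq_along(bvals)),
                  vapply(bvals, format, character(1), digits = 17))
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_along(bvals)) {
    xml2::xml_add_child(lp, "parameter", id = bid[[k]],
                        value = format(bvals[k], digits = 17),
                        constant = "true")
  }
  genes <- model_genes(model)
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[j, ]
    rn <- xml2::xml_add_child(lr, "reaction",
                              id = paste0("R_", sid(rx$id)),
                              reversible = if (rx$lower_bound < 0) "true" else "false",
                              fast = "false")
    xml2::xml_set_attr(rn, "fbc:lowerFluxBound",
                       bid[[format(rx$lower_bound, digits = 17)]])
    xml2::xml_set_attr(rn, "fbc:upperFluxBound",
                       bid[[format(rx$upper_bound, digits = 17)]])
    if (nzchar(rx$subsystem)) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", rx$subsystem))
    }
    st <- model$stoich[[j]]
    met_ref <- function(met) {
      info <- model$metabolites[match(met, model$metabolites$id), ]
      paste0("M_", sid(info$base_id), "_", sid(info$compartment))
    }
    sub <- st[st < 0]; prod <- st[st > 0]
    if (length(sub)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in seq_along(sub))
        xml2::xml_add_child(lre, "speciesReference",
                            species = met_ref(names(sub)[i]),
                            stoichiometry = format(-sub[[i]], digits = 17),
                            constant = "true")
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in seq_along(prod))
        xml2::xml_add_child(lpr, "speciesReference",
                            species = met_ref(names(prod)[i]),
                            stoichiometry = format(prod[[i]], digits = 17),
                            constant = "true")
    }
    if (nzchar(rx$gene_rule)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      add_assoc <- function(parent, node) {
        if (is.character(node)) {
          xml2::xml_add_child(parent, "fbc:geneProductRef",
                              "fbc:geneProduct" = paste0("G_", sid(node)))
        } else {
          el <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
          for (a in node$args) add_assoc(el, a)
        }
      }
      add_assoc(gpa, parse_gene_rule(rx$gene_rule))
    }
  }
  if (!is.null(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = model$objective$direction)
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sid(model$objective$reaction)),
                        "fbc:coefficient" = "1")
  }
  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sid(g)), "fbc:label" = g)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a model from SBML L3V1 + FBC v2
#'
#' @param path SBML file (the dialect written by [write_model_sbml()] or a
#'   compatible FBC v2 export).
#' @return a `metabolic_model`.
#' @export
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file ", path,
                                           ": ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)  # work with local names; fbc attrs keep prefix
  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  if (!length(comp_nodes)) stop("malformed SBML: no compartments in ", path)
  cid <- sub("^C_", "", xml2::xml_attr(comp_nodes, "id"))
  side <- vapply(xml2::xml_attr(comp_nodes, "sboTerm"), function(s) {
    if (is.na(s)) "intracellular"
    else switch(s, "SBO:0000309" = "apical_lumen",
                "SBO:0000284" = "basolateral_extracellular",
                "intracellular")
  }, character(1))
  comps <- compartments(cid, xml2::xml_attr(comp_nodes, "name"), unname(side))

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- sub("^C_", "", xml2::xml_attr(sp_nodes, "compartment"))
  sp_base <- mapply(function(id, comp)
    sub(paste0("_", comp, "$"), "", sub("^M_", "", id)), sp_id, sp_comp)
  mets <- metabolites(unname(sp_base), sp_comp,
                      name = xml2::xml_attr(sp_nodes, "name"),
                      formula = xml2::xml_attr(sp_nodes, "chemicalFormula"))
  sbml_to_met <- setNames(mets$id, sp_id)

  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                    xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("malformed SBML: no reactions in ", path)
  assoc_to_rule <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(sub("^G_", "", xml2::xml_attr(node, "geneProduct")))
    kids <- vapply(xml2::xml_children(node), assoc_to_rule, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(kids, collapse = op), ")")
  }
  rxns <- lapply(rx_nodes, function(rn) {
    id <- sub("^R_", "", xml2::xml_attr(rn, "id"))
    getrefs <- function(which, sign) {
      refs <- xml2::xml_find_all(rn, paste0("./", which, "/speciesReference"))
      if (!length(refs)) return(numeric(0))
      setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
               unname(sbml_to_met[xml2::xml_attr(refs, "species")]))
    }
    st <- c(getrefs("listOfReactants", -1), getrefs("listOfProducts", 1))
    if (anyNA(names(st)))
      stop("malformed SBML: reaction ", id, " references unknown species")
    lbp <- xml2::xml_attr(rn, "lowerFluxBound")
    ubp <- xml2::xml_attr(rn, "upperFluxBound")
    notes <- xml2::xml_text(xml2::xml_find_first(rn, ".//notes"))
    subsystem <- if (!is.na(notes) && grepl("SUBSYSTEM:", notes))
      trimws(sub(".*SUBSYSTEM:", "", notes)) else ""
    gpa <- xml2::xml_find_first(
      rn, "./*[local-name()='geneProductAssociation']/*")
    rule <- if (inherits(gpa, "xml_node")) assoc_to_rule(gpa) else ""
    rule <- sub("^\\((.*)\\)$", "\\1", rule)
    reaction(id, st,
             lower_bound = pvals[[lbp]], upper_bound = pvals[[ubp]],
             gene_rule = rule, subsystem = subsystem,
             is_exchange = length(st) == 1)
  })
  obj_node <- xml2::xml_find_first(
    doc, ".//*[local-name()='listOfObjectives']/*[local-name()='objective']")
  objective <- NULL
  if (inherits(obj_node, "xml_node")) {
    fo <- xml2::xml_find_first(obj_node,
                               ".//*[local-name()='fluxObjective']")
    objective <- list(reaction = sub("^R_", "",
                                     xml2::xml_attr(fo, "reaction")),
                      direction = xml2::xml_attr(obj_node, "type"))
  }
  metabolic_model(comps, mets, rxns, objective)
}

#' Read a constraint-based model from file
#'
#' Dispatches on format; logs the model's element counts.
#'
#' @param path model file.
#' @param format `"sbml"`, `"tsv"` or `"mat"` (default: from extension).
#' @param quiet suppress the count log message.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "tsv", "mat"),
                       quiet = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = "sbml", sbml = "sbml", tsv = "tsv",
                     mat = "mat",
                     stop("cannot infer model format from extension .", ext))
  }
  if (format == "mat")
    stop("reading COBRA .mat structures is not supported in this build; ",
         "convert to SBML or the TSV dialect first")
  model <- switch(format, sbml = read_model_sbml(path),
                  tsv = read_model_tsv(path))
  if (!quiet)
    message("read model: ", nrow(model$metabolites), " metabolites, ",
            nrow(model$reactions), " reactions, ",
            length(model_genes(model)), " genes")
  model
}
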