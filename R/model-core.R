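#' @importFrom methods as
#' @importFrom stats setNames
NULL

#' Construct a compartment table
#'
#' @param id character vector of short compartment tokens (e.g. `"c"`, `"u"`).
#' @param name human-readable names.
#' @param side one of `"intracellular"`, `"apical_lumen"`,
#'   `"basolateral_extracellular"` per compartment.
#' @return data.frame with columns `id`, `name`, `side`.
#' @export
compartments <- function(id, name = id, side = character(0)) {
  if (length(id)) {
    side <- match.arg(side, c("intracellular", "apical_lumen",
                              "basolateral_extracellular"),
                      several.ok = TRUE)
  }
  if (anyDuplicated(id)) stop("compartment ids must be unique")
  data.frame(id = as.character(id), name = as.character(name),
             side = as.character(side), stringsAsFactors = FALSE)
}

#' Compartment-suffixed metabolite id
#'
#' Ids follow the `base[compartment]` convention of intestinal epithelial
#' cell reconstructions, e.g. `glc[c]` for cytosolic glucose.
#'
#' @param base species token shared across compartments.
#' @param comp compartment id token.
#' @return character id.
#' @export
met_id <- function(base, comp) {
  if (!length(base)) return(character(0))
  paste0(base, "[", comp, "]")
}

#' Construct a metabolite table
#'
#' @param base_id species tokens.
#' @param compartment compartment id per metabolite.
#' @param name optional names (default: base_id).
#' @param formula optional elemental formulas (`NA` for lumped pools).
#' @return data.frame with columns `id`, `base_id`, `compartment`, `name`,
#'   `formula`; `id` is `base_id[compartment]`.
#' @export
metabolites <- function(base_id, compartment, name = base_id, formula = NA_character_) {
  name <- rep_len(as.character(name), length(base_id))
  formula <- rep_len(as.character(formula), length(base_id))
  df <- data.frame(id = met_id(base_id, compartment),
                   base_id = as.character(base_id),
                   compartment = as.character(compartment),
                   name = as.character(name),
                   formula = as.character(formula),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate (base_id, compartment) pairs")
  df
}

#' Construct a reaction
#'
#' Stoichiometric coefficients follow the usual sign convention: negative
#' for consumed metabolites (substrates), positive for produced ones.
#' Exchange reactions are single-metabolite boundary pseudo-reactions
#' (`met <=> nothing`) with uptake represented by negative flux.
#'
#' @param id reaction token.
#' @param stoichiometry named numeric vector, names are metabolite ids.
#' @param lower_bound,upper_bound flux bounds in mmol gdw^-1 h^-1;
#'   defaults are the conventional +/-1000 for reversible reactions.
#' @param gene_rule boolean gene association string (`"and"`/`"or"`,
#'   parentheses); empty string for orphan or diffusion reactions.
#' @param subsystem free-text pathway label.
#' @param is_exchange flag marking boundary pseudo-reactions.
#' @return a list of class `mf_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -1000, upper_bound = 1000,
                     gene_rule = "", subsystem = "", is_exchange = FALSE) {
  if (length(stoichiometry) == 0) stop("reaction ", id, " has empty stoichiometry")
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("reaction ", id, ": stoichiometry must be a named vector")
  if (lower_bound > upper_bound)
    stop("reaction ", id, ": lower_bound exceeds upper_bound")
  if (is_exchange && length(stoichiometry) != 1)
    stop("exchange reaction ", id, " must touch exactly one metabolite")
  structure(list(id = as.character(id),
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gene_rule = as.character(gene_rule),
                 subsystem = as.character(subsystem),
                 is_exchange = isTRUE(is_exchange)),
            class = "mf_reaction")
}

#' Shorthand for an exchange reaction `EX_<base>_<comp>`
#'
#' @param met_id full metabolite id (e.g. `"glc[u]"`).
#' @param lower_bound,upper_bound flux bounds; by convention uptake is a
#'   negative lower bound and secretion a positive upper bound.
#' @param id optional explicit reaction id.
#' @return an `mf_reaction`.
#' @export
exchange_reaction <- function(met_id, lower_bound = 0, upper_bound = 1000,
                              id = NULL) {
  base <- sub("\\[.*", "", met_id)
  comp <- sub(".*\\[(.*)\\]", "\\1", met_id)
  if (is.null(id)) id <- paste0("EX_", base, "_", comp)
  reaction(id, setNames(-1, met_id), lower_bound, upper_bound,
           subsystem = "exchange", is_exchange = TRUE)
}

#' Assemble a compartmentalized constraint-based model
#'
#' Validates the structural invariants: unique ids, all stoichiometry keys
#' resolving to declared metabolites, consistent bounds, single-metabolite
#' exchanges.
#'
#' @param compartments compartment data.frame (see [compartments()]).
#' @param metabolites metabolite data.frame (see [metabolites()]).
#' @param reactions list of `mf_reaction` objects.
#' @param objective list with `reaction` (id) and `direction`
#'   (`"maximize"`/`"minimize"`), or `NULL`.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(compartments, metabolites, reactions,
                            objective = NULL) {
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- ids
  for (i in seq_along(reactions)) {
    unknown <- setdiff(names(stoich[[i]]), metabolites$id)
    if (length(unknown)) {
      stop("reaction ", ids[i], " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  unknown_comp <- setdiff(metabolites$compartment, compartments$id)
  if (length(unknown_comp)) {
    stop("metabolites reference undeclared compartment(s): ",
         paste(unknown_comp, collapse = ", "))
  }
  rxn_df <- data.frame(
    id = ids,
    lower_bound = vapply(reactions, `[[`, numeric(1), "lower_bound"),
    upper_bound = vapply(reactions, `[[`, numeric(1), "upper_bound"),
    gene_rule = vapply(reactions, `[[`, character(1), "gene_rule"),
    subsystem = vapply(reactions, `[[`, character(1), "subsystem"),
    is_exchange = vapply(reactions, `[[`, logical(1), "is_exchange"),
    stringsAsFactors = FALSE)
  if (!is.null(objective)) {
    objective$direction <- match.arg(objective$direction,
                                     c("maximize", "minimize"))
    if (!objective$reaction %in% ids)
      stop("objective reaction not in model: ", objective$reaction)
  }
  structure(list(compartments = compartments,
                 metabolites = metabolites,
                 reactions = rxn_df,
                 stoich = stoich,
                 objective = objective),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Constraint-based metabolic model\n")
  cat("  metabolites:", nrow(x$metabolites),
      " reactions:", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), "exchange )\n")
  cat("  compartments:", paste(x$compartments$id, collapse = ", "), "\n")
  if (!is.null(x$objective))
    cat("  objective:", x$objective$direction, x$objective$reaction, "\n")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  genes <- model_genes(object)
  res <- list(n_metabolites = nrow(object$metabolites),
              n_reactions = nrow(object$reactions),
              n_exchange = sum(object$reactions$is_exchange),
              n_genes = length(genes),
              n_compartments = nrow(object$compartments))
  class(res) <- "summary.metabolic_model"
  res
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat("metabolites:", x$n_metabolites, "\nreactions:", x$n_reactions,
      "(", x$n_exchange, "exchange )\ngenes:", x$n_genes,
      "\ncompartments:", x$n_compartments, "\n")
  invisible(x)
}

#' All gene tokens appearing in the model's gene rules
#' @param model a `metabolic_model`.
#' @return character vector of unique gene tokens.
#' @export
model_genes <- function(model) {
  rules <- model$reactions$gene_rule
  unique(unlist(lapply(rules[nzchar(rules)],
                       function(r) gene_rule_genes(r))))
}

#' Build the stoichiometric matrix S
#'
#' Entry `(i, j)` is the coefficient of metabolite `i` in reaction `j`
#' (positive = produced, negative = consumed); rows and columns follow the
#' model's insertion order.
#'
#' @param model a `metabolic_model`.
#' @return sparse `dgCMatrix` of dimension (metabolites x reactions) with
#'   dimnames.
#' @export
build_stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxns)) {
    st <- model$stoich[[j]]
    idx <- match(names(st), mets)
    if (anyNA(idx)) {
      bad <- names(st)[is.na(idx)]
      stop("reaction ", rxns[j], " references unresolved metabolite(s): ",
           paste(bad, collapse = ", "))
    }
    ii <- c(ii, idx); jj <- c(jj, rep.int(j, length(st))); xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Knock out a reaction
#'
#' Returns a copy of the model in which both flux bounds of the reaction
#' are zero; the input model is left unmodified. This mirrors the standard
#' COBRA-style single-reaction deletion.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id id of the reaction to delete.
#' @return modified copy of the model.
#' @export
knock_out <- function(model, reaction_id) {
  set_reaction_bounds(model, reaction_id, 0, 0)
}

#' Set flux bounds of a reaction (functional update)
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @param lower,upper new bounds; `NA` keeps the current value.
#' @return modified copy of the model.
#' @export
set_reaction_bounds <- function(model, reaction_id, lower = NA, upper = NA) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id)
  if (!is.na(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.na(upper)) model$reactions$upper_bound[i] <- upper
  model
}

#' Get the bounds of a reaction
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @return numeric `c(lower, upper)`.
#' @export
reaction_bounds <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id)
  c(model$reactions$lower_bound[i], model$reactions$upper_bound[i])
}

#' Reconstruct the reaction stoichiometries from a stoichiometric matrix
#'
#' Inverse of [build_stoichiometric_matrix()] for the stoichiometry part:
#' the nonzero pattern of each column, as a named coefficient vector.
#'
#' @param S matrix with metabolite ids as rownames and reaction ids as
#'   colnames.
#' @return named list of named numeric vectors.
#' @export
stoichiometry_from_matrix <- function(S) {
  out <- lapply(seq_len(ncol(S)), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    setNames(as.numeric(col[nz]), rownames(S)[nz])
  })
  names(out) <- colnames(S)
  out
}

#' Structural and flux-consistency validation
#'
#' Reports (a) dead-end metabolites — metabolites that, given reaction
#' reversibilities, can only ever be produced or only ever be consumed;
#' (b) blocked reactions — reactions that cannot carry flux in either
#' direction when all exchange reactions are opened; (c) bound violations
#' (`lower > upper`). A model with empty (a) and (b) has "no holes".
#'
#' @param model a `metabolic_model`.
#' @param open_bound magnitude used to open exchange bounds for the
#'   blocked-reaction check.
#' @param tol flux below which a reaction counts as blocked.
#' @return list of class `model_validation` with elements `dead_ends`,
#'   `blocked`, `bound_violations`, `no_holes`.
#' @export
validate_model <- function(model, open_bound = 1000, tol = 1e-6) {
  rx <- model$reactions
  bound_violations <- rx$id[rx$lower_bound > rx$upper_bound]

  # dead ends from directionality pattern
  can_produce <- setNames(logical(nrow(model$metabolites)), model$metabolites$id)
  can_consume <- can_produce
  for (j in seq_len(nrow(rx))) {
    st <- model$stoich[[j]]
    fwd <- rx$upper_bound[j] > tol
    rev <- rx$lower_bound[j] < -tol
    pos <- names(st)[st > 0]; neg <- names(st)[st < 0]
    if (fwd) { can_produce[pos] <- TRUE; can_consume[neg] <- TRUE }
    if (rev) { can_produce[neg] <- TRUE; can_consume[pos] <- TRUE }
  }
  dead_ends <- names(can_produce)[!(can_produce & can_consume)]

  # blocked reactions under open exchanges
  open <- model
  ex <- which(open$reactions$is_exchange)
  open$reactions$lower_bound[ex] <- -open_bound
  open$reactions$upper_bound[ex] <- open_bound
  S <- as.matrix(build_stoichiometric_matrix(open))
  lb <- open$reactions$lower_bound
  ub <- open$reactions$upper_bound
  blocked <- character(0)
  for (j in seq_len(nrow(rx))) {
    obj <- numeric(nrow(rx)); obj[j] <- 1
    hi <- solve_lp(obj, S, lb = lb, ub = ub, direction = "max")
    span <- if (hi$status == "optimal") abs(hi$objective) else 0
    if (span < tol) {
      lo <- solve_lp(obj, S, lb = lb, ub = ub, direction = "min")
      if (lo$status == "optimal") span <- max(span, abs(lo$objective))
    }
    if (span < tol) blocked <- c(blocked, rx$id[j])
  }
  structure(list(dead_ends = dead_ends, blocked = blocked,
                 bound_violations = bound_violations,
                 no_holes = length(dead_ends) == 0 && length(blocked) == 0),
            class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  cat("Model validation report\n")
  cat("  dead-end metabolites:", length(x$dead_ends), "\n")
  if (length(x$dead_ends)) cat("   ", paste(x$dead_ends, collapse = ", "), "\n")
  cat("  blocked reactions:", length(x$blocked), "\n")
  if (length(x$blocked)) cat("   ", paste(x$blocked, collapse = ", "), "\n")
  cat("  bound violations:", length(x$bound_violations), "\n")
  cat(if (x$no_holes) "  no holes in the network\n" else "  holes present\n")
  invisible(x)
}
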