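# Tab-separated reaction-table dialect: one reaction per row with columns
# id, equation, lower_bound, upper_bound, gene_rule, subsystem.
# Equation strings use "->" (irreversible) or "<=>" (reversible), signed
# by side, e.g. "tag160[u] -> mag160[u] + 2 ffa160[u]".

format_equation <- function(stoich, reversible) {
  side <- function(coefs) {
    if (!length(coefs)) return("")
    paste(vapply(seq_along(coefs), function(i) {
      cf <- abs(coefs[[i]])
      if (abs(cf - 1) < 1e-12) names(coefs)[i]
      else paste(format(cf, digits = 12), names(coefs)[i])
    }, character(1)), collapse = " + ")
  }
  arrow <- if (reversible) "<=>" else "->"
  paste(side(stoich[stoich < 0]), arrow, side(stoich[stoich > 0]))
}

parse_equation <- function(eq, id = "?") {
  reversible <- grepl("<=>", eq, fixed = TRUE)
  parts <- strsplit(eq, if (reversible) "<=>" else "->", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("cannot parse equation of reaction ", id, ": ", eq)
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, " + ", fixed = TRUE)[[1]])
    st <- numeric(0)
    for (tm in terms) {
      m <- regexec("^([0-9.eE+-]+\\s+)?(\\S+)$", tm)[[1]]
      pieces <- regmatches(tm, regexec("^(([0-9][0-9.eE+-]*)\\s+)?(\\S+)$", tm))[[1]]
      if (length(pieces) < 4 || !nzchar(pieces[4]))
        stop("cannot parse term '", tm, "' in reaction ", id)
      cf <- if (nzchar(pieces[3])) as.numeric(pieces[3]) else 1
      st[pieces[4]] <- (if (pieces[4] %in% names(st)) st[[pieces[4]]] else 0) +
        sign * cf
    }
    st
  }
  st <- c(parse_side(parts[1], -1), parse_side(parts[2], 1))
  # merge duplicate metabolites across sides
  tapply_names <- unique(names(st))
  merged <- vapply(tapply_names, function(nm) sum(st[names(st) == nm]),
                   numeric(1))
  list(stoichiometry = merged[merged != 0], reversible = reversible)
}

#' Write a model to the TSV reaction-table dialect
#'
#' Two companion files are written: `<path>` with the reactions and
#' `<path>` with extension replaced by `_metabolites.tsv` carrying the
#' metabolite table (id, base_id, compartment, name, formula) and
#' compartment definitions as a commented header.
#'
#' @param model a `metabolic_model`.
#' @param path output file path for the reaction table.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  rx <- model$reactions
  eq <- vapply(seq_len(nrow(rx)), function(j)
    format_equation(model$stoich[[j]], rx$lower_bound[j] < 0), character(1))
  df <- data.frame(id = rx$id, equation = eq,
                   lower_bound = rx$lower_bound, upper_bound = rx$upper_bound,
                   gene_rule = rx$gene_rule, subsystem = rx$subsystem,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mpath <- sub("\\.[^.]*$", "_metabolites.tsv", path)
  con <- file(mpath, "w")
  on.exit(close(con))
  writeLines(paste0("# compartment\t", model$compartments$id, "\t",
                    model$compartments$name, "\t", model$compartments$side),
             con)
  utils::write.table(model$metabolites, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a model from the TSV reaction-table dialect
#'
#' @param path reaction table written by [write_model_tsv()] (the
#'   companion `_metabolites.tsv` must sit next to it).
#' @param objective optional objective list `(reaction, direction)`.
#' @return a `metabolic_model`.
#' @export
read_model_tsv <- function(path, objective = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("id", "equation", "lower_bound", "upper_bound")
  if (!all(need %in% names(df)))
    stop("malformed reaction table ", path, ": need columns ",
         paste(need, collapse = ", "))
  mpath <- sub("\\.[^.]*$", "_metabolites.tsv", path)
  if (!file.exists(mpath)) stop("metabolite table not found: ", mpath)
  lines <- readLines(mpath)
  comp_lines <- grep("^# compartment\t", lines, value = TRUE)
  comp <- do.call(rbind, strsplit(sub("^# compartment\t", "", comp_lines), "\t"))
  comps <- compartments(comp[, 1], comp[, 2], comp[, 3])
  mets <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
  mets$formula[mets$formula == "NA" | mets$formula == ""] <- NA_character_
  rxns <- lapply(seq_len(nrow(df)), function(j) {
    pe <- parse_equation(df$equation[j], df$id[j])
    reaction(df$id[j], pe$stoichiometry, df$lower_bound[j], df$upper_bound[j],
             gene_rule = if ("gene_rule" %in% names(df) &&
                             !is.na(df$gene_rule[j])) df$gene_rule[j] else "",
             subsystem = if ("subsystem" %in% names(df) &&
                             !is.na(df$subsystem[j])) df$subsystem[j] else "",
             is_exchange = length(pe$stoichiometry) == 1)
  })
  metabolic_model(comps, mets, rxns, objective)
}
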