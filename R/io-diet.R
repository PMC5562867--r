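# Diet tables as CSV (columns: nutrient, intake_mol_per_mouse_per_day,
# optional class) and the nutrient -> exchange mapping as YAML.

#' Write / read a diet composition table
#'
#' @param diet a [diet_composition()].
#' @param path CSV path.
#' @return `path` invisibly (writer); a `diet_composition` (reader).
#' @export
write_diet_csv <- function(diet, path) {
  df <- data.frame(nutrient = names(diet$nutrient_intakes),
                   intake_mol_per_mouse_per_day =
                     unname(diet$nutrient_intakes),
                   stringsAsFactors = FALSE)
  if (!is.null(diet$nutrient_class))
    df$class <- unname(diet$nutrient_class[df$nutrient])
  attrline <- paste0("# diet: ", diet$name)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attrline, con)
  if (!is.null(diet$energy_fractions))
    writeLines(paste0("# energy_fractions: ",
                      paste(names(diet$energy_fractions),
                            diet$energy_fractions,
                            sep = "=", collapse = ",")), con)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diet_csv
#' @param name diet name override (default: from the `# diet:` header or
#'   the file name).
#' @export
read_diet_csv <- function(path, name = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(name)) {
    dl <- grep("^# diet:", hdr, value = TRUE)
    name <- if (length(dl)) trimws(sub("^# diet:", "", dl[1])) else
      tools::file_path_sans_ext(basename(path))
  }
  ef <- NULL
  el <- grep("^# energy_fractions:", hdr, value = TRUE)
  if (length(el)) {
    kv <- strsplit(strsplit(trimws(sub("^# energy_fractions:", "", el[1])),
                            ",")[[1]], "=")
    ef <- setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                   vapply(kv, `[`, character(1), 1))
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE)
  if (!all(c("nutrient", "intake_mol_per_mouse_per_day") %in% names(df)))
    stop("malformed diet table ", path,
         ": need columns nutrient, intake_mol_per_mouse_per_day")
  cls <- if ("class" %in% names(df))
    setNames(df$class, df$nutrient) else NULL
  diet_composition(name,
                   setNames(df$intake_mol_per_mouse_per_day, df$nutrient),
                   energy_fractions = ef, nutrient_class = cls)
}

#' Write / read a nutrient-to-exchange mapping as YAML
#'
#' @param mapping named character vector (nutrient -> exchange id).
#' @param path YAML path.
#' @return `path` invisibly (writer); named character vector (reader).
#' @export
write_nutrient_mapping <- function(mapping, path) {
  yaml::write_yaml(as.list(mapping), path)
  invisible(path)
}

#' @rdname write_nutrient_mapping
#' @export
read_nutrient_mapping <- function(path) {
  m <- yaml::read_yaml(path)
  setNames(vapply(m, as.character, character(1)), names(m))
}
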