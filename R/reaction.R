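#' Parse one reaction-SMILES record
#'
#' Accepts `reactants>>products` or `reactants>agents>products` (the agent
#' field is discarded: the synthesis graph is defined over reactants and
#' products only). Molecules on each side are dot-separated and kept as a
#' multiset - duplicates are allowed and counted.
#'
#' @param line a reaction-SMILES string.
#' @param reaction_id identifier stored on the reaction (defaults to the
#'   input line).
#' @param class_label optional integer reaction-class label.
#' @return a `csgl_reaction` with `reactants` and `products` lists of
#'   [csgl_molecule] objects.
#' @export
parse_reaction <- function(line, reaction_id = NULL, class_label = NULL) {
  stopifnot(is.character(line), length(line) == 1L)
  parts <- strsplit(line, ">", fixed = TRUE)[[1]]
  # strsplit drops trailing empty fields ("A>>" must still have 3 parts)
  n_sep <- nchar(line) - nchar(gsub(">", "", line, fixed = TRUE))
  if (n_sep == 2L) parts <- c(parts, character(3L - length(parts)))
  if (length(parts) != 3L) {
    stop(sprintf("reaction SMILES must have form 'reactants>>products': '%s'", line),
         call. = FALSE)
  }
  sides <- parts[c(1, 3)]
  if (any(!nzchar(trimws(sides)))) {
    stop(sprintf("reaction has an empty side: '%s'", line), call. = FALSE)
  }
  parse_side <- function(s) {
    toks <- strsplit(trimws(s), ".", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) {
      stop(sprintf("reaction has an empty side: '%s'", line), call. = FALSE)
    }
    lapply(toks, parse_molecule)
  }
  structure(
    list(
      reaction_id = if (is.null(reaction_id)) line else as.character(reaction_id),
      reactants = parse_side(sides[1]),
      products = parse_side(sides[2]),
      class_label = if (is.null(class_label) || is.na(class_label)) NULL
                    else as.integer(class_label)
    ),
    class = "csgl_reaction"
  )
}

#' @export
print.csgl_reaction <- function(x, ...) {
  cat(sprintf("<reaction> %s%s\n", reaction_smiles(x),
              if (is.null(x$class_label)) "" else sprintf("  [class %d]", x$class_label)))
  invisible(x)
}

#' Reaction-SMILES string of a parsed reaction (canonical molecule ids)
#'
#' @param rxn a `csgl_reaction`.
#' @return a `reactants>>products` string built from canonical SMILES.
#' @export
reaction_smiles <- function(rxn) {
  paste0(
    paste(vapply(rxn$reactants, function(m) m$canonical_id, character(1)), collapse = "."),
    ">>",
    paste(vapply(rxn$products, function(m) m$canonical_id, character(1)), collapse = ".")
  )
}

# canonical multiset key of one reaction side (sorted canonical ids)
side_key <- function(mols) {
  paste(sort(vapply(mols, function(m) m$canonical_id, character(1))), collapse = ".")
}

#' Read a reaction file
#'
#' Plain text or TSV: column 1 is reaction-SMILES, optional column 2 an
#' integer class label; lines starting with `#` and blank lines are skipped.
#' Parse failures report the file line number.
#'
#' @param path path to the file.
#' @return a list of `csgl_reaction` objects.
#' @export
read_reactions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    label <- if (length(fields) >= 2L && nzchar(fields[2])) as.integer(fields[2]) else NULL
    out[[i]] <- tryCatch(
      parse_reaction(fields[1], reaction_id = sprintf("%s:%d", basename(path), ln),
                     class_label = label),
      error = function(e) {
        stop(sprintf("line %d of '%s': %s", ln, path, conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  out
}

#' Write reactions to the TSV format [read_reactions()] accepts
#'
#' @param reactions list of `csgl_reaction` objects.
#' @param path output path.
#' @export
write_reactions <- function(reactions, path) {
  lines <- vapply(reactions, function(r) {
    if (is.null(r$class_label)) reaction_smiles(r)
    else paste(reaction_smiles(r), r$class_label, sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a molecule property file
#'
#' TSV with header columns `smiles` and `label` (binary 0/1).
#'
#' @param path path to the file.
#' @return a data frame with columns `smiles` and `label`.
#' @export
read_property_data <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("smiles", "label") %in% names(df)))
  df$label <- as.integer(df$label)
  df
}

#' Write a molecule property file
#'
#' @param df data frame with columns `smiles` and `label`.
#' @param path output path.
#' @export
write_property_data <- function(df, path) {
  utils::write.table(df[, c("smiles", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
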