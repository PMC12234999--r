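#' Bond-type vocabularies
#'
#' A bond type is an unordered element pair plus a bond-order tag
#' (`"1"` single, `"2"` double, `"3"` triple, `"ar"` aromatic). The
#' vocabulary fixes which bond types get their own entry in the
#' per-bond-type count vector that parameterizes reaction transformation
#' relations; bonds matching no entry fall into an implicit OTHER bucket
#' that is counted by [count_bonds()] but excluded from the vector.
#'
#' @param entries a data frame with columns `elem_a`, `elem_b`, `order`.
#' @return a `csgl_bond_vocab` object with `entries`, lookup `keys`, `size`.
#' @export
bond_type_vocabulary <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("elem_a", "elem_b", "order") %in% names(entries)))
  entries$order <- as.character(entries$order)
  if (!all(entries$order %in% c("1", "2", "3", "ar"))) {
    stop("bond order tags must be one of '1', '2', '3', 'ar'", call. = FALSE)
  }
  keys <- vapply(seq_len(nrow(entries)), function(i) {
    .bond_key(entries$elem_a[i], entries$elem_b[i], entries$order[i])
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate bond-type entries in vocabulary", call. = FALSE)
  }
  structure(
    list(entries = entries, keys = keys, size = nrow(entries)),
    class = "csgl_bond_vocab"
  )
}

.bond_key <- function(ea, eb, order) {
  pair <- sort(c(ea, eb))
  paste(pair[1], pair[2], order, sep = "|")
}

#' Default 15-entry bond-type vocabulary
#'
#' Common organic bond types: carbon-carbon single/double/triple/aromatic,
#' carbon to O/N/S in their usual orders, N-O and S-O oxidation-state pairs.
#' The list is a configuration default and can be replaced wholesale with
#' [read_bond_vocabulary()].
#'
#' @return a `csgl_bond_vocab` of 15 entries.
#' @export
default_bond_vocabulary <- function() {
  entries <- data.frame(
    elem_a = c("C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C", "N", "N", "S", "S"),
    elem_b = c("C", "C", "C", "C", "O", "O", "N", "N", "N", "N", "S", "O", "O", "O", "O"),
    order  = c("1", "2", "3", "ar", "1", "2", "1", "2", "3", "ar", "1", "1", "2", "1", "2"),
    stringsAsFactors = FALSE
  )
  bond_type_vocabulary(entries)
}

#' Read a bond-type vocabulary from YAML or JSON
#'
#' The file holds a list of `{elem_a, elem_b, order}` entries; the element
#' pair is order-insensitive.
#'
#' @param path path to a `.yml`/`.yaml` or `.json` file.
#' @return a `csgl_bond_vocab`.
#' @export
read_bond_vocabulary <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  entries <- do.call(rbind, lapply(raw, function(e) {
    data.frame(elem_a = as.character(e$elem_a), elem_b = as.character(e$elem_b),
               order = as.character(e$order), stringsAsFactors = FALSE)
  }))
  bond_type_vocabulary(entries)
}

#' @export
print.csgl_bond_vocab <- function(x, ...) {
  cat(sprintf("<bond-type vocabulary> %d entries\n", x$size))
  invisible(x)
}

.as_mol_list <- function(mols) {
  if (is_molecule(mols)) return(list(mols))
  if (is.character(mols)) return(lapply(mols, parse_molecule))
  stopifnot(is.list(mols))
  lapply(mols, function(m) if (is_molecule(m)) m else parse_molecule(m))
}

#' Count bonds in a molecule multiset
#'
#' Total number of heavy-atom bonds summed over all member molecules,
#' counting multiset multiplicity. This is the NB statistic whose
#' reactant-product difference drives the bond-count component of a
#' transformation relation.
#'
#' @param mols a molecule, a list of molecules, or a character vector of
#'   SMILES (duplicates allowed and counted).
#' @return a nonnegative integer.
#' @export
count_bonds <- function(mols) {
  mols <- .as_mol_list(mols)
  sum(vapply(mols, function(m) nrow(m$bonds), integer(1)))
}

#' Count rings in a molecule multiset
#'
#' Sum of SSSR ring counts over member molecules with multiplicity (the NR
#' statistic).
#'
#' @inheritParams count_bonds
#' @return a nonnegative integer.
#' @export
count_rings <- function(mols) {
  mols <- .as_mol_list(mols)
  sum(vapply(mols, function(m) m$ring_count, integer(1)))
}

#' Count bonds per vocabulary bond type
#'
#' Entry j of the result is the number of bonds in the multiset matching
#' vocabulary entry j (the NB_bj statistics). Bonds matching no entry are
#' tallied in an OTHER bucket that is excluded from the returned vector.
#'
#' @inheritParams count_bonds
#' @param vocab a [bond_type_vocabulary()].
#' @return an integer vector of length `vocab$size`, named by bond key.
#' @export
count_bond_types <- function(mols, vocab = default_bond_vocabulary()) {
  stopifnot(inherits(vocab, "csgl_bond_vocab"))
  mols <- .as_mol_list(mols)
  counts <- setNames(integer(vocab$size), vocab$keys)
  for (m in mols) {
    if (nrow(m$bonds) == 0L) next
    keys <- vapply(seq_len(nrow(m$bonds)), function(k) {
      .bond_key(m$atoms$element[m$bonds$a[k]],
                m$atoms$element[m$bonds$b[k]],
                m$bonds$order[k])
    }, character(1))
    tab <- table(keys[keys %in% vocab$keys])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}
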