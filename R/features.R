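#' Atom feature vocabulary
#'
#' Fixes the one-hot buckets used to featurize atoms: formal charge clipped
#' to \[-2, 2\] (5 buckets), element symbols observed in the training corpus
#' plus an UNK bucket, hydrogen count clipped to \[0, 4\] (5 buckets), and a
#' ring-membership flag (2 buckets). Buckets must be built once from the
#' training corpus and reused unchanged at inference.
#'
#' @param elements character vector of element symbols to give dedicated
#'   buckets (an UNK bucket is appended automatically).
#' @return a `csgl_feature_vocab` with a `length` field giving the total
#'   feature dimension.
#' @export
atom_feature_vocabulary <- function(elements = c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")) {
  elements <- sort(unique(as.character(elements)))
  structure(
    list(
      charges = -2:2,
      elements = c(elements, "UNK"),
      hydrogens = 0:4,
      length = 5L + length(elements) + 1L + 5L + 2L
    ),
    class = "csgl_feature_vocab"
  )
}

#' Build the atom feature vocabulary from a molecule corpus
#'
#' @param mols list of molecules (or SMILES) forming the training corpus.
#' @return a `csgl_feature_vocab` whose element buckets are the elements
#'   observed in the corpus.
#' @export
feature_vocabulary_from_molecules <- function(mols) {
  mols <- .as_mol_list(mols)
  elems <- unique(unlist(lapply(mols, function(m) m$atoms$element)))
  atom_feature_vocabulary(elems)
}

#' One-hot feature vector for a single atom
#'
#' Concatenates four one-hot blocks - formal charge, element, hydrogen
#' count, ring membership - so every atom vector has exactly four ones.
#' Out-of-range charges and hydrogen counts are clipped to the nearest
#' bucket; unknown elements map to UNK.
#'
#' @param atom a list or one-row data frame with fields `element`,
#'   `formal_charge`, `num_hydrogens`, `in_ring`.
#' @param vocab an [atom_feature_vocabulary()].
#' @return a binary numeric vector of length `vocab$length`.
#' @export
atom_feature_vector <- function(atom, vocab = atom_feature_vocabulary()) {
  stopifnot(inherits(vocab, "csgl_feature_vocab"))
  v <- numeric(vocab$length)
  off <- 0L
  ch <- max(-2L, min(2L, as.integer(atom$formal_charge)))
  v[off + match(ch, vocab$charges)] <- 1
  off <- off + length(vocab$charges)
  el <- as.character(atom$element)
  idx <- match(el, vocab$elements)
  if (is.na(idx)) idx <- match("UNK", vocab$elements)
  v[off + idx] <- 1
  off <- off + length(vocab$elements)
  h <- max(0L, min(4L, as.integer(atom$num_hydrogens)))
  v[off + match(h, vocab$hydrogens)] <- 1
  off <- off + length(vocab$hydrogens)
  v[off + (if (isTRUE(as.logical(atom$in_ring))) 2L else 1L)] <- 1
  v
}

# feature matrix (n_atoms x feature_dim) for one molecule
atom_feature_matrix <- function(mol, vocab) {
  t(vapply(
    seq_len(nrow(mol$atoms)),
    function(j) atom_feature_vector(mol$atoms[j, , drop = FALSE], vocab),
    numeric(vocab$length)
  ))
}
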