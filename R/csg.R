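#' Transformation features of a reaction
#'
#' Integer deltas between the reactant and product sides: total bond count,
#' SSSR ring count, and per-bond-type counts over a bond-type vocabulary
#' (reactants minus products in every case). These deltas are the
#' coefficients of the learned relation embedding of the reaction; reversing
#' a reaction negates every field, and an identity reaction has all-zero
#' features.
#'
#' @param rxn a `csgl_reaction`.
#' @param vocab a [bond_type_vocabulary()].
#' @return a `csgl_transformation` with fields `delta_bonds`, `delta_rings`,
#'   `delta_bond_types`.
#' @examples
#' tf <- transformation_features(parse_reaction("C=CC=C.C=C>>C1=CCCCC1"))
#' tf$delta_bonds   # -2
#' tf$delta_rings   # -1
#' @export
transformation_features <- function(rxn, vocab = default_bond_vocabulary()) {
  stopifnot(inherits(rxn, "csgl_reaction"))
  structure(
    list(
      delta_bonds = count_bonds(rxn$reactants) - count_bonds(rxn$products),
      delta_rings = count_rings(rxn$reactants) - count_rings(rxn$products),
      delta_bond_types = count_bond_types(rxn$reactants, vocab) -
        count_bond_types(rxn$products, vocab)
    ),
    class = "csgl_transformation"
  )
}

#' @export
print.csgl_transformation <- function(x, ...) {
  nz <- x$delta_bond_types[x$delta_bond_types != 0]
  cat(sprintf("<transformation> d.bonds %+d, d.rings %+d%s\n",
              x$delta_bonds, x$delta_rings,
              if (length(nz)) paste0(", ", paste(sprintf("%s %+d", names(nz), nz),
                                                 collapse = ", "))
              else ""))
  invisible(x)
}

# flat numeric coefficient vector (delta_bonds, delta_rings, per-type deltas)
tf_vector <- function(tf) {
  c(tf$delta_bonds, tf$delta_rings, as.numeric(tf$delta_bond_types))
}

tf_negate <- function(tf) {
  structure(
    list(delta_bonds = -tf$delta_bonds, delta_rings = -tf$delta_rings,
         delta_bond_types = -tf$delta_bond_types),
    class = "csgl_transformation"
  )
}

#' Build a chemical synthesis graph
#'
#' Nodes are the reactant-side and product-side molecule multisets of the
#' corpus, deduplicated corpus-wide by sorted-canonical-SMILES key, so a set
#' appearing as the product of one reaction and the reactant of another is a
#' single node. Each reaction contributes one directed edge from its
#' reactant node to its product node, annotated with
#' [transformation_features()]; duplicate reactions yield parallel edges.
#'
#' @param reactions non-empty list of `csgl_reaction` objects.
#' @param vocab a [bond_type_vocabulary()].
#' @return a `csgl_csg` with `nodes`, `edges`, per-node `adjacency`, and the
#'   vocabulary used.
#' @export
build_csg <- function(reactions, vocab = default_bond_vocabulary()) {
  stopifnot(length(reactions) > 0L)
  key_to_id <- new.env(parent = emptyenv())
  nodes <- list()
  get_node <- function(mols) {
    key <- side_key(mols)
    id <- get0(key, envir = key_to_id, inherits = FALSE)
    if (is.null(id)) {
      id <- length(nodes) + 1L
      nodes[[id]] <<- structure(
        list(node_id = id, member_key = key, members = mols),
        class = "csgl_node"
      )
      assign(key, id, envir = key_to_id)
    }
    id
  }
  edges <- vector("list", length(reactions))
  for (i in seq_along(reactions)) {
    rxn <- reactions[[i]]
    stopifnot(inherits(rxn, "csgl_reaction"))
    edges[[i]] <- list(
      src = get_node(rxn$reactants),
      dst = get_node(rxn$products),
      features = transformation_features(rxn, vocab),
      reaction_id = rxn$reaction_id
    )
  }
  adjacency <- vector("list", length(nodes))
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    adjacency[[e$src]] <- c(adjacency[[e$src]], k)
    if (e$dst != e$src) adjacency[[e$dst]] <- c(adjacency[[e$dst]], k)
  }
  structure(
    list(
      nodes = nodes,
      node_keys = vapply(nodes, function(n) n$member_key, character(1)),
      edges = edges,
      adjacency = adjacency,
      vocab = vocab
    ),
    class = "csgl_csg"
  )
}

#' @export
print.csgl_csg <- function(x, ...) {
  cat(sprintf("<chemical synthesis graph> %d nodes, %d edges\n",
              length(x$nodes), length(x$edges)))
  invisible(x)
}

#' Neighbors of a CSG node
#'
#' Returns successors and predecessors alike; features are always oriented
#' center-to-neighbor, so a predecessor reached against the edge direction
#' carries negated transformation features. This orientation is what the
#' attention propagation consumes.
#'
#' @param csg a `csgl_csg`.
#' @param node_id a node id in the graph.
#' @return a list of `list(node_id, features, edge_id)` entries, one per
#'   incident edge (parallel edges appear separately).
#' @export
csg_neighbors <- function(csg, node_id) {
  if (!is.numeric(node_id) || node_id < 1L || node_id > length(csg$nodes)) {
    stop(sprintf("unknown CSG node id: %s", format(node_id)), call. = FALSE)
  }
  out <- list()
  for (k in csg$adjacency[[node_id]]) {
    e <- csg$edges[[k]]
    if (e$src == node_id) {
      out[[length(out) + 1L]] <- list(node_id = e$dst, features = e$features,
                                      edge_id = k)
    }
    if (e$dst == node_id) {
      out[[length(out) + 1L]] <- list(node_id = e$src,
                                      features = tf_negate(e$features),
                                      edge_id = k)
    }
  }
  out
}

# directed neighbor expansion used by the propagation step:
# every edge s->t yields rows (center=s, nbr=t, +f) and (center=t, nbr=s, -f)
csg_directed_expansion <- function(csg) {
  n_e <- length(csg$edges)
  if (n_e == 0L) {
    return(list(center = integer(), nbr = integer(),
                feat = matrix(0, 0, 2L + csg$vocab$size)))
  }
  center <- integer(2L * n_e)
  nbr <- integer(2L * n_e)
  feat <- matrix(0, 2L * n_e, 2L + csg$vocab$size)
  for (k in seq_len(n_e)) {
    e <- csg$edges[[k]]
    fv <- tf_vector(e$features)
    center[2L * k - 1L] <- e$src; nbr[2L * k - 1L] <- e$dst
    feat[2L * k - 1L, ] <- fv
    center[2L * k] <- e$dst; nbr[2L * k] <- e$src
    feat[2L * k, ] <- -fv
  }
  ord <- order(center)
  list(center = center[ord], nbr = nbr[ord], feat = feat[ord, , drop = FALSE])
}

#' Export a CSG edge list to TSV
#'
#' One row per edge: source key, target key, reaction id, bond delta, ring
#' delta, and the per-type deltas as a comma-separated list. The format
#' round-trips through [import_csg()].
#'
#' @param csg a `csgl_csg`.
#' @param path output path.
#' @export
export_csg <- function(csg, path) {
  rows <- vapply(csg$edges, function(e) {
    paste(csg$node_keys[e$src], csg$node_keys[e$dst], e$reaction_id,
          e$features$delta_bonds, e$features$delta_rings,
          paste(e$features$delta_bond_types, collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(c("# source_key\ttarget_key\treaction_id\tdelta_bonds\tdelta_rings\tdelta_bond_types", rows), path)
}

#' Import a CSG edge list written by [export_csg()]
#'
#' @param path path to the TSV file.
#' @param vocab the bond-type vocabulary the file was written with.
#' @return a `csgl_csg` (node members re-parsed from the multiset keys).
#' @export
import_csg <- function(path, vocab = default_bond_vocabulary()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rxns <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    parse_reaction(paste0(f[1], ">>", f[2]), reaction_id = f[3])
  })
  build_csg(rxns, vocab)
}
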