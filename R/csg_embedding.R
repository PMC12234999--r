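#' Summation readout over member molecule embeddings
#'
#' The READ operator: a node of the synthesis graph (a reactant or product
#' multiset) gets the elementwise sum of its member molecule embeddings as
#' its base (layer-0) embedding.
#'
#' @param member_embs a non-empty list of numeric vectors, or a matrix with
#'   one member embedding per row.
#' @return a numeric vector.
#' @export
read_embedding <- function(member_embs) {
  if (is.matrix(member_embs)) {
    if (nrow(member_embs) == 0L) stop("READ of an empty set", call. = FALSE)
    return(colSums(member_embs))
  }
  if (length(member_embs) == 0L) stop("READ of an empty set", call. = FALSE)
  Reduce(`+`, member_embs)
}

#' Initialize relation parameters
#'
#' One learnable d-vector per transformation coordinate: the bond-count
#' delta, the ring-count delta, and each bond-type delta. Stored as a
#' `(2 + vocab size) x d` matrix whose first two rows are the bond and ring
#' embeddings.
#'
#' @param d embedding dimension.
#' @param vocab a [bond_type_vocabulary()].
#' @return a matrix with rownames `"bond"`, `"ring"`, then the vocabulary
#'   keys.
#' @export
init_relation_params <- function(d, vocab = default_bond_vocabulary()) {
  rel <- glorot(2L + vocab$size, d)
  rownames(rel) <- c("bond", "ring", vocab$keys)
  rel
}

#' Relation embedding of a transformation
#'
#' The transformation relation is linear in its integer delta features:
#' `T = delta_bonds * e_bond + delta_rings * e_ring + sum_j delta_j * e_bj`.
#'
#' @param tf a [transformation_features()] object.
#' @param rel relation parameter matrix from [init_relation_params()].
#' @return a numeric vector of length d.
#' @export
relation_embedding <- function(tf, rel) {
  stopifnot(inherits(tf, "csgl_transformation"))
  v <- tf_vector(tf)
  if (length(v) != nrow(rel)) {
    stop("bond-type vocabulary size does not match relation parameters",
         call. = FALSE)
  }
  as.numeric(v %*% rel)
}

#' Attention weights over a node neighborhood
#'
#' For a center node with embedding `center` and neighbors with embeddings
#' `neighbor_embs` and center-to-neighbor relation embeddings
#' `neighbor_rels`, the weight of neighbor j is the softmax over
#' `W_a . (center * neighbor_j * T_j)` (elementwise products).
#'
#' @param center_emb numeric vector (d).
#' @param neighbor_embs matrix with one neighbor embedding per row, or list
#'   of vectors.
#' @param neighbor_rels matching relation embeddings (matrix or list).
#' @param W_a attention weight vector of length d (or d x 1 matrix).
#' @return numeric vector of nonnegative weights summing to 1 (empty input
#'   yields an empty vector).
#' @export
attention_weights <- function(center_emb, neighbor_embs, neighbor_rels, W_a) {
  if (is.list(neighbor_embs)) neighbor_embs <- do.call(rbind, neighbor_embs)
  if (is.list(neighbor_rels)) neighbor_rels <- do.call(rbind, neighbor_rels)
  if (is.null(neighbor_embs) || nrow(neighbor_embs) == 0L) return(numeric(0))
  stopifnot(nrow(neighbor_embs) == nrow(neighbor_rels))
  logits <- as.numeric(
    (neighbor_embs * matrix(center_emb, nrow(neighbor_embs), length(center_emb),
                            byrow = TRUE) * neighbor_rels) %*% as.numeric(W_a)
  )
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Attention propagation over the synthesis graph
#'
#' Refines READ node embeddings with H rounds of residual neighborhood
#' aggregation: at round h, every node adds the attention-weighted sum of
#' its neighbors' round-(h-1) embeddings, with weights computed by
#' [attention_weights()] from the current embeddings and the edge relation
#' embeddings (orientation-negated when an edge is traversed against its
#' direction). The returned final embedding of a node is the average of its
#' embeddings across rounds 0..H, so `H = 0` returns the READ table
#' unchanged.
#'
#' @param csg a [build_csg()] graph.
#' @param base matrix of layer-0 node embeddings (one row per node, READ
#'   outputs).
#' @param rel relation parameters ([init_relation_params()]).
#' @param W_a list of per-round attention vectors (length-d each), one per
#'   round; its length sets H.
#' @return list with `layers` (list of H+1 matrices) and `final` (their
#'   mean).
#' @export
csgnn_propagate <- function(csg, base, rel, W_a = list()) {
  stopifnot(nrow(base) == length(csg$nodes))
  H <- length(W_a)
  exp_ <- csg_directed_expansion(csg)
  Te <- if (nrow(exp_$feat) > 0L) exp_$feat %*% rel else matrix(0, 0, ncol(base))
  layers <- vector("list", H + 1L)
  layers[[1L]] <- base
  E <- base
  for (h in seq_len(H)) {
    if (length(exp_$center) > 0L) {
      logits <- as.numeric(
        (E[exp_$center, , drop = FALSE] * E[exp_$nbr, , drop = FALSE] * Te) %*%
          as.numeric(W_a[[h]])
      )
      m <- stats::ave(logits, exp_$center, FUN = max)
      el <- exp(logits - m)
      den <- stats::ave(el, exp_$center, FUN = sum)
      pi_ <- el / den
      msg <- rowsum(pi_ * E[exp_$nbr, , drop = FALSE], group = exp_$center)
      agg <- matrix(0, nrow(E), ncol(E))
      agg[as.integer(rownames(msg)), ] <- msg
      E <- E + agg
    }
    layers[[h + 1L]] <- E
  }
  list(layers = layers, final = Reduce(`+`, layers) / (H + 1L))
}

# autodiff version used inside the training loop; `expansion` comes from
# csg_directed_expansion() and `rel_node`/`wa_nodes` are tape nodes
csgnn_ad <- function(tape, base, expansion, rel_node, wa_nodes, n_nodes) {
  H <- length(wa_nodes)
  layers <- list(base)
  E <- base
  if (H > 0L && length(expansion$center) > 0L) {
    Fe <- ad_const(tape, expansion$feat)
    Te <- ad_matmul(Fe, rel_node)
    for (h in seq_len(H)) {
      Ec <- ad_gather(E, expansion$center)
      En <- ad_gather(E, expansion$nbr)
      logits <- ad_matmul(ad_mul(ad_mul(Ec, En), Te), wa_nodes[[h]])
      pi_ <- ad_group_softmax(logits, expansion$center)
      agg <- ad_group_sum(ad_mul(pi_, En), expansion$center, n_nodes)
      E <- ad_add(E, agg)
      layers[[h + 1L]] <- E
    }
  } else if (H > 0L) {
    for (h in seq_len(H)) layers[[h + 1L]] <- E
  }
  final <- layers[[1L]]
  if (H > 0L) {
    for (h in seq_len(H)) final <- ad_add(final, layers[[h + 1L]])
    final <- ad_scale(final, 1 / (H + 1))
  }
  list(layers = layers, final = final)
}
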