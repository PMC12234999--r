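# runs code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Initialize all trainable parameters
#'
#' Glorot-uniform weights and zero biases for the encoder, the relation
#' basis embeddings (one d-vector per transformation coordinate), and one
#' attention vector per propagation round.
#'
#' @param encoder_cfg an [encoder_config()].
#' @param feature_dim atom feature dimension (`vocab$length`).
#' @param bond_vocab a [bond_type_vocabulary()].
#' @param csgnn_layers number of propagation rounds H (0 disables).
#' @param seed integer seed.
#' @return named list of parameter matrices (`rel`, `wa_<h>`, encoder
#'   weights).
#' @export
init_model_params <- function(encoder_cfg, feature_dim,
                              bond_vocab = default_bond_vocabulary(),
                              csgnn_layers = 1L, seed = 0L) {
  with_seed(seed, {
    p <- init_encoder_params(encoder_cfg, feature_dim)
    p$rel <- init_relation_params(encoder_cfg$hidden_dim, bond_vocab)
    for (h in seq_len(csgnn_layers)) {
      p[[sprintf("wa_%d", h)]] <- glorot(encoder_cfg$hidden_dim, 1)
    }
    p
  })
}

adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# one full forward pass: encode every molecule, read out and propagate node
# embeddings, and evaluate the margin loss on the minibatch `idx`
.forward_loss <- function(params, blob, encoder_cfg, H, idx, margin, lambda,
                          trainable = TRUE) {
  tape <- ad_tape()
  Pn <- .params_to_nodes(tape, params, trainable = trainable)
  enc <- encode_batch_ad(tape, Pn, blob$batch, encoder_cfg)
  base <- ad_matmul(ad_const(tape, blob$S_node), enc$pooled)
  wa_nodes <- lapply(seq_len(H), function(h) Pn[[sprintf("wa_%d", h)]])
  prop <- csgnn_ad(tape, base, blob$expansion, Pn$rel, wa_nodes,
                   nrow(blob$S_node))
  Rn <- ad_gather(prop$final, blob$rxn_src[idx])
  Pp <- ad_gather(prop$final, blob$rxn_dst[idx])
  Tn <- ad_matmul(ad_const(tape, blob$F_rxn[idx, , drop = FALSE]), Pn$rel)
  ml <- margin_loss_ad(ad_add(Rn, Tn), Pp, margin)
  loss <- if (lambda > 0) ad_add(ml$loss, l2_penalty_ad(Pn, lambda)) else ml$loss
  list(loss = loss, pos = ml$pos, neg = ml$neg, param_nodes = Pn,
       node_final = prop$final, pooled = enc$pooled)
}

# static per-corpus structures shared by every training step
.training_blob <- function(reactions, csg, feature_vocab) {
  mol_ids <- character(0)
  mols <- list()
  for (nd in csg$nodes) {
    for (m in nd$members) {
      if (!m$canonical_id %in% mol_ids) {
        mol_ids <- c(mol_ids, m$canonical_id)
        mols[[length(mols) + 1L]] <- m
      }
    }
  }
  n_nodes <- length(csg$nodes)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_len(n_nodes)) {
    tab <- table(vapply(csg$nodes[[k]]$members, function(m) m$canonical_id,
                        character(1)))
    ii <- c(ii, rep(k, length(tab)))
    jj <- c(jj, match(names(tab), mol_ids))
    xx <- c(xx, as.numeric(tab))
  }
  S_node <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(n_nodes, length(mols)))
  list(
    mols = mols, mol_ids = mol_ids,
    batch = mol_batch(mols, feature_vocab),
    S_node = S_node,
    expansion = csg_directed_expansion(csg),
    rxn_src = vapply(csg$edges, function(e) e$src, integer(1)),
    rxn_dst = vapply(csg$edges, function(e) e$dst, integer(1)),
    F_rxn = do.call(rbind, lapply(csg$edges, function(e) tf_vector(e$features)))
  )
}

#' Train a synthesis-graph embedding model
#'
#' Builds the chemical synthesis graph of the training reactions, then
#' optimizes the molecule encoder, relation embeddings, and attention
#' parameters with Adam on the margin-based translational loss: for each
#' minibatch, all molecules are encoded, node embeddings are read out and
#' refined by `csgnn_layers` rounds of attention propagation over the full
#' graph, and the loss contrasts each reaction's matched product against
#' every unmatched product in the batch.
#'
#' @param reactions non-empty list of `csgl_reaction` objects (at least 2).
#' @param encoder_cfg an [encoder_config()].
#' @param train_cfg a [train_config()].
#' @param with_csgnn if `FALSE`, trains the propagation-free variant used
#'   for transfer to classification and property tasks (node embeddings are
#'   plain READ sums).
#' @param csgnn_layers propagation rounds H when `with_csgnn` (default 1).
#' @param bond_vocab a [bond_type_vocabulary()].
#' @param verbose print per-epoch loss.
#' @return a `csgl_model` holding trained parameters, vocabularies, the
#'   training graph with cached node embeddings, and the per-epoch loss
#'   history.
#' @export
train_model <- function(reactions,
                        encoder_cfg = encoder_config(),
                        train_cfg = train_config(),
                        with_csgnn = TRUE,
                        csgnn_layers = 1L,
                        bond_vocab = default_bond_vocabulary(),
                        verbose = FALSE) {
  if (length(reactions) < 2L) {
    stop("training needs at least two reactions", call. = FALSE)
  }
  H <- if (with_csgnn) as.integer(csgnn_layers) else 0L
  csg <- build_csg(reactions, bond_vocab)
  all_mols <- unlist(lapply(csg$nodes, function(n) n$members), recursive = FALSE)
  feature_vocab <- feature_vocabulary_from_molecules(all_mols)
  blob <- .training_blob(reactions, csg, feature_vocab)
  params <- init_model_params(encoder_cfg, feature_vocab$length, bond_vocab,
                              csgnn_layers = H, seed = train_cfg$seed)
  state <- adam_init(params)
  n_rxn <- length(reactions)
  history <- data.frame(epoch = integer(0), positive = numeric(0),
                        negative = numeric(0), loss = numeric(0))

  with_seed(train_cfg$seed + 1L, {
    for (epoch in seq_len(train_cfg$epochs)) {
      perm <- sample.int(n_rxn)
      starts <- seq(1L, n_rxn, by = train_cfg$batch_size)
      ep_pos <- ep_neg <- ep_loss <- numeric(0)
      for (s in starts) {
        idx <- perm[s:min(s + train_cfg$batch_size - 1L, n_rxn)]
        fw <- .forward_loss(params, blob, encoder_cfg, H, idx,
                            train_cfg$margin, train_cfg$l2_lambda)
        Pn <- fw$param_nodes; ml <- fw; loss <- fw$loss
        if (!is.finite(loss$val)) {
          stop(sprintf(
            "non-finite loss at epoch %d (positive %.4g, negative %.4g); try a smaller learning rate",
            epoch, ml$pos, ml$neg
          ), call. = FALSE)
        }
        ad_backward(loss)
        upd <- adam_step(params, lapply(Pn, ad_grad), state,
                         train_cfg$learning_rate)
        params <- upd$params
        state <- upd$state
        ep_pos <- c(ep_pos, ml$pos); ep_neg <- c(ep_neg, ml$neg)
        ep_loss <- c(ep_loss, loss$val)
      }
      history[epoch, ] <- list(epoch, mean(ep_pos), mean(ep_neg), mean(ep_loss))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f (pos %.4f, neg %.4f)",
                        epoch, mean(ep_loss), mean(ep_pos), mean(ep_neg)))
      }
    }
  })

  # cache final node and molecule embeddings with the trained weights
  pooled <- encode_molecules(blob$mols, params, encoder_cfg, feature_vocab)
  base <- as.matrix(blob$S_node %*% pooled)
  wa <- lapply(seq_len(H), function(h) params[[sprintf("wa_%d", h)]])
  prop <- csgnn_propagate(csg, base, params$rel, wa)

  structure(
    list(
      params = params, encoder_cfg = encoder_cfg, train_cfg = train_cfg,
      feature_vocab = feature_vocab, bond_vocab = bond_vocab,
      csg = csg, with_csgnn = with_csgnn, csgnn_layers = H,
      history = history,
      mol_ids = blob$mol_ids, mol_embeddings = pooled,
      node_base = base, node_embeddings = prop$final
    ),
    class = "csgl_model"
  )
}

#' @export
print.csgl_model <- function(x, ...) {
  cat(sprintf(
    "<csgl model> %s encoder, d=%d, %s pooling, %s; %d molecules, %d CSG nodes\n",
    x$encoder_cfg$gnn_type, x$encoder_cfg$hidden_dim, x$encoder_cfg$pooling,
    if (x$with_csgnn) sprintf("%d propagation round(s)", x$csgnn_layers)
    else "no propagation (READ only)",
    length(x$mol_ids), length(x$csg$nodes)
  ))
  invisible(x)
}

# molecule embeddings under a trained model, reusing the training cache
model_encode <- function(model, mols) {
  mols <- .as_mol_list(mols)
  ids <- vapply(mols, function(m) m$canonical_id, character(1))
  hit <- match(ids, model$mol_ids)
  out <- matrix(0, length(mols), model$encoder_cfg$hidden_dim)
  if (any(!is.na(hit))) {
    out[!is.na(hit), ] <- model$mol_embeddings[hit[!is.na(hit)], , drop = FALSE]
  }
  if (any(is.na(hit))) {
    out[is.na(hit), ] <- encode_molecules(mols[is.na(hit)], model$params,
                                          model$encoder_cfg, model$feature_vocab)
  }
  out
}

# embedding of one molecule multiset: cached propagated embedding when the
# set is a training-graph node, otherwise its READ sum (propagation needs
# graph context that unseen nodes do not have)
side_embedding <- function(model, mols) {
  key <- side_key(.as_mol_list(mols))
  i <- match(key, model$csg$node_keys)
  if (!is.na(i)) {
    model$node_embeddings[i, ]
  } else {
    read_embedding(model_encode(model, mols))
  }
}

#' Embed the two sides and the relation of a reaction
#'
#' Returns the reactant-node embedding, the product-node embedding, and the
#' relation embedding of the transformation. Sides present in the training
#' graph use their cached propagated embeddings; unseen sides fall back to
#' their READ sums.
#'
#' @param rxn a `csgl_reaction`.
#' @param model a trained `csgl_model`.
#' @return list with numeric vectors `R`, `T`, `P`.
#' @export
embed_reaction_sides <- function(rxn, model) {
  stopifnot(inherits(model, "csgl_model"))
  tf <- transformation_features(rxn, model$bond_vocab)
  list(
    R = side_embedding(model, rxn$reactants),
    T = relation_embedding(tf, model$params$rel),
    P = side_embedding(model, rxn$products)
  )
}

#' Save / load a trained model
#'
#' Serializes the full model (weights, vocabularies, training graph and
#' cached embeddings). Loading verifies the object is a model whose weights
#' match its stored vocabularies and fails loudly otherwise.
#'
#' @param model a `csgl_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "csgl_model"))
  saveRDS(model, path)
}

#' @rdname save_model
#' @return `load_model` returns the `csgl_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "csgl_model")) {
    stop("file does not contain a csgl model", call. = FALSE)
  }
  if (nrow(model$params$proj_W) != model$feature_vocab$length ||
      nrow(model$params$rel) != 2L + model$bond_vocab$size) {
    stop("model weights do not match stored vocabularies", call. = FALSE)
  }
  model
}

#' Write the per-epoch training log as TSV
#'
#' @param model a trained `csgl_model`.
#' @param path output path.
#' @export
write_training_log <- function(model, path) {
  utils::write.table(model$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
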