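#' Molecule encoder configuration
#'
#' Controls the message-passing architecture that maps a molecular graph to a
#' fixed-dimension embedding: a linear projection of the one-hot atom
#' features followed by `num_layers` GNN layers and a pooling readout. ReLU
#' is applied after the projection and after every GNN layer except the
#' last.
#'
#' @param gnn_type one of `"GCN"`, `"GAT"`, `"SAGE"`, `"TAG"`.
#' @param num_layers number of message-passing layers (default 2).
#' @param hidden_dim embedding dimension d.
#' @param pooling one of `"sum"`, `"avg"`, `"max"`, `"attention"`,
#'   `"sortpool"`, `"set2set"`. All except sortpool are permutation
#'   invariant; sortpool sorts atoms by their last embedding channel before a
#'   flattened linear readout.
#' @param sortpool_k number of retained sorted atoms for sortpool
#'   (zero-padded).
#' @param set2set_steps LSTM processing steps for set2set.
#' @param tag_hops adjacency powers used by each TAG layer.
#' @return an `csgl_encoder_config`.
#' @export
encoder_config <- function(gnn_type = c("GCN", "GAT", "SAGE", "TAG"),
                           num_layers = 2L,
                           hidden_dim = 64L,
                           pooling = c("sum", "avg", "max", "attention",
                                       "sortpool", "set2set"),
                           sortpool_k = 10L,
                           set2set_steps = 3L,
                           tag_hops = 2L) {
  gnn_type <- match.arg(gnn_type)
  pooling <- match.arg(pooling)
  stopifnot(num_layers >= 1L, hidden_dim >= 1L)
  structure(
    list(gnn_type = gnn_type, num_layers = as.integer(num_layers),
         hidden_dim = as.integer(hidden_dim), pooling = pooling,
         sortpool_k = as.integer(sortpool_k),
         set2set_steps = as.integer(set2set_steps),
         tag_hops = as.integer(tag_hops)),
    class = "csgl_encoder_config"
  )
}

# --- batched molecular graphs ---------------------------------------------
# All molecules of a corpus are packed into one block-diagonal graph: a
# single feature matrix, a global edge list, and sparse pooling/propagation
# operators, so one matrix pass encodes every molecule at once.

mol_batch <- function(mols, feature_vocab) {
  mols <- .as_mol_list(mols)
  n_mols <- length(mols)
  counts <- vapply(mols, function(m) nrow(m$atoms), integer(1))
  offsets <- cumsum(c(0L, counts[-n_mols]))
  n_atoms <- sum(counts)

  X <- matrix(0, n_atoms, feature_vocab$length)
  src <- integer(0); dst <- integer(0)
  for (i in seq_len(n_mols)) {
    m <- mols[[i]]
    X[offsets[i] + seq_len(counts[i]), ] <- atom_feature_matrix(m, feature_vocab)
    if (nrow(m$bonds) > 0L) {
      a <- m$bonds$a + offsets[i]
      b <- m$bonds$b + offsets[i]
      src <- c(src, a, b)
      dst <- c(dst, b, a)
    }
  }
  mol_index <- rep(seq_len(n_mols), counts)

  # symmetric-normalized adjacency with self loops (GCN / TAG operator)
  A_hat <- Matrix::sparseMatrix(
    i = c(src, seq_len(n_atoms)), j = c(dst, seq_len(n_atoms)),
    x = 1, dims = c(n_atoms, n_atoms)
  )
  dis <- 1 / sqrt(Matrix::rowSums(A_hat))
  A_hat <- Matrix::Diagonal(x = dis) %*% A_hat %*% Matrix::Diagonal(x = dis)

  # row-normalized neighbor averaging without self loops (SAGE operator)
  A_mean <- NULL
  if (length(src) > 0L) {
    A_nb <- Matrix::sparseMatrix(i = src, j = dst, x = 1,
                                 dims = c(n_atoms, n_atoms))
    deg <- Matrix::rowSums(A_nb)
    deg[deg == 0] <- 1
    A_mean <- Matrix::Diagonal(x = 1 / deg) %*% A_nb
  } else {
    A_mean <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                   dims = c(n_atoms, n_atoms))
  }

  S_sum <- Matrix::sparseMatrix(i = mol_index, j = seq_len(n_atoms), x = 1,
                                dims = c(n_mols, n_atoms))
  S_avg <- Matrix::Diagonal(x = 1 / counts) %*% S_sum

  list(
    mols = mols, n_mols = n_mols, n_atoms = n_atoms, counts = counts,
    X = X, mol_index = mol_index,
    gat_src = c(src, seq_len(n_atoms)), gat_dst = c(dst, seq_len(n_atoms)),
    A_hat = A_hat, A_mean = A_mean, S_sum = S_sum, S_avg = S_avg
  )
}

# --- parameter initialization ---------------------------------------------

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_encoder_params <- function(cfg, feature_dim) {
  d <- cfg$hidden_dim
  p <- list(proj_W = glorot(feature_dim, d), proj_b = matrix(0, 1, d))
  for (l in seq_len(cfg$num_layers)) {
    nm <- function(s) sprintf("%s_%d", s, l)
    if (cfg$gnn_type == "GCN") {
      p[[nm("gcn_W")]] <- glorot(d, d)
      p[[nm("gcn_b")]] <- matrix(0, 1, d)
    } else if (cfg$gnn_type == "SAGE") {
      p[[nm("sage_Wself")]] <- glorot(d, d)
      p[[nm("sage_Wnbr")]] <- glorot(d, d)
      p[[nm("sage_b")]] <- matrix(0, 1, d)
    } else if (cfg$gnn_type == "TAG") {
      for (k in 0:cfg$tag_hops) p[[sprintf("tag_W_%d_%d", l, k)]] <- glorot(d, d)
      p[[nm("tag_b")]] <- matrix(0, 1, d)
    } else if (cfg$gnn_type == "GAT") {
      p[[nm("gat_W")]] <- glorot(d, d)
      p[[nm("gat_asrc")]] <- glorot(d, 1)
      p[[nm("gat_adst")]] <- glorot(d, 1)
      p[[nm("gat_b")]] <- matrix(0, 1, d)
    }
  }
  if (cfg$pooling == "attention") {
    p$att_U <- glorot(d, d)
    p$att_b <- matrix(0, 1, d)
    p$att_u <- glorot(d, 1)
  } else if (cfg$pooling == "sortpool") {
    p$sp_W <- glorot(cfg$sortpool_k * d, d)
    p$sp_b <- matrix(0, 1, d)
  } else if (cfg$pooling == "set2set") {
    p$s2s_W <- glorot(2 * d, 4 * d)
    p$s2s_U <- glorot(d, 4 * d)
    p$s2s_b <- matrix(0, 1, 4 * d)
    p$s2s_out <- glorot(2 * d, d)
  }
  p
}

# --- forward pass (autodiff nodes in, autodiff nodes out) ------------------

encoder_layers_ad <- function(tape, P, batch, cfg) {
  X <- ad_const(tape, batch$X)
  H <- ad_relu(ad_add(ad_matmul(X, P$proj_W), P$proj_b))
  layers <- list(H)
  for (l in seq_len(cfg$num_layers)) {
    nm <- function(s) sprintf("%s_%d", s, l)
    Z <- switch(cfg$gnn_type,
      GCN = {
        AH <- ad_matmul(ad_const(tape, batch$A_hat), H)
        ad_add(ad_matmul(AH, P[[nm("gcn_W")]]), P[[nm("gcn_b")]])
      },
      SAGE = {
        NH <- ad_matmul(ad_const(tape, batch$A_mean), H)
        ad_add(
          ad_add(ad_matmul(H, P[[nm("sage_Wself")]]),
                 ad_matmul(NH, P[[nm("sage_Wnbr")]])),
          P[[nm("sage_b")]]
        )
      },
      TAG = {
        Pk <- H
        acc <- ad_matmul(Pk, P[[sprintf("tag_W_%d_0", l)]])
        for (k in seq_len(cfg$tag_hops)) {
          Pk <- ad_matmul(ad_const(tape, batch$A_hat), Pk)
          acc <- ad_add(acc, ad_matmul(Pk, P[[sprintf("tag_W_%d_%d", l, k)]]))
        }
        ad_add(acc, P[[nm("tag_b")]])
      },
      GAT = {
        HW <- ad_matmul(H, P[[nm("gat_W")]])
        Hs <- ad_gather(HW, batch$gat_src)
        Hd <- ad_gather(HW, batch$gat_dst)
        logit <- ad_leakyrelu(
          ad_add(ad_matmul(Hs, P[[nm("gat_asrc")]]),
                 ad_matmul(Hd, P[[nm("gat_adst")]])),
          alpha = 0.2
        )
        alpha <- ad_group_softmax(logit, batch$gat_dst)
        msg <- ad_mul(alpha, Hs)
        ad_add(ad_group_sum(msg, batch$gat_dst, batch$n_atoms), P[[nm("gat_b")]])
      }
    )
    H <- if (l < cfg$num_layers) ad_relu(Z) else Z
    layers[[l + 1L]] <- H
  }
  layers
}

pool_ad <- function(tape, P, H, batch, cfg) {
  switch(cfg$pooling,
    sum = ad_matmul(ad_const(tape, batch$S_sum), H),
    avg = ad_matmul(ad_const(tape, batch$S_avg), H),
    max = ad_group_max(H, batch$mol_index, batch$n_mols),
    attention = {
      s <- ad_matmul(ad_tanh_(ad_add(ad_matmul(H, P$att_U), P$att_b)), P$att_u)
      w <- ad_group_softmax(s, batch$mol_index)
      ad_matmul(ad_const(tape, batch$S_sum), ad_mul(w, H))
    },
    sortpool = {
      # sort atoms within each molecule by the last embedding channel
      # (descending); keep k rows, zero-padding short molecules
      k <- cfg$sortpool_k
      key <- H$val[, ncol(H$val)]
      pad_row <- batch$n_atoms + 1L
      idx <- unlist(lapply(seq_len(batch$n_mols), function(i) {
        rows <- which(batch$mol_index == i)
        rows <- rows[order(key[rows], decreasing = TRUE)]
        c(rows[seq_len(min(k, length(rows)))],
          rep(pad_row, max(0L, k - length(rows))))
      }))
      Hpad <- ad_vcat2(H, ad_const(tape, matrix(0, 1, ncol(H$val))))
      flat <- ad_blockflat(ad_gather(Hpad, idx), k)
      ad_add(ad_matmul(flat, P$sp_W), P$sp_b)
    },
    set2set = {
      d <- cfg$hidden_dim
      n <- batch$n_mols
      qstar <- ad_const(tape, matrix(0, n, 2 * d))
      hprev <- ad_const(tape, matrix(0, n, d))
      cprev <- ad_const(tape, matrix(0, n, d))
      for (t in seq_len(cfg$set2set_steps)) {
        gates <- ad_add(ad_add(ad_matmul(qstar, P$s2s_W),
                               ad_matmul(hprev, P$s2s_U)), P$s2s_b)
        ig <- ad_sigmoid(ad_slice_cols(gates, seq_len(d)))
        fg <- ad_sigmoid(ad_slice_cols(gates, d + seq_len(d)))
        og <- ad_sigmoid(ad_slice_cols(gates, 2 * d + seq_len(d)))
        gg <- ad_tanh_(ad_slice_cols(gates, 3 * d + seq_len(d)))
        cprev <- ad_add(ad_mul(fg, cprev), ad_mul(ig, gg))
        hprev <- ad_mul(og, ad_tanh_(cprev))
        q_at <- ad_gather(hprev, batch$mol_index)
        e <- ad_rowsums(ad_mul(q_at, H))
        a <- ad_group_softmax(e, batch$mol_index)
        r <- ad_matmul(ad_const(tape, batch$S_sum), ad_mul(a, H))
        qstar <- ad_cbind2(hprev, r)
      }
      ad_matmul(qstar, P$s2s_out)
    }
  )
}

encode_batch_ad <- function(tape, P, batch, cfg) {
  layers <- encoder_layers_ad(tape, P, batch, cfg)
  pooled <- pool_ad(tape, P, layers[[length(layers)]], batch, cfg)
  list(layers = layers, pooled = pooled)
}

# --- plain-matrix user-facing wrappers ------------------------------------

.params_to_nodes <- function(tape, params, trainable = FALSE) {
  lapply(params, function(w) if (trainable) ad_param(tape, w) else ad_const(tape, w))
}

#' Per-atom embeddings of one molecule
#'
#' Runs the message-passing layers and returns the layer-indexed atom
#' embedding matrices: element `[[1]]` is the linear projection of the atom
#' features (layer 0), element `[[L+1]]` the final layer.
#'
#' @param mol a molecule (or SMILES string).
#' @param params encoder weights from [init_model_params()] or a trained
#'   model's `$params`.
#' @param cfg the [encoder_config()] the weights were created for.
#' @param feature_vocab the [atom_feature_vocabulary()] used at training.
#' @return list of `num_layers + 1` matrices, each `n_atoms x hidden_dim`.
#' @export
encode_atoms <- function(mol, params, cfg, feature_vocab) {
  batch <- mol_batch(list(mol), feature_vocab)
  if (ncol(params$proj_W) != cfg$hidden_dim ||
      nrow(params$proj_W) != feature_vocab$length) {
    stop("encoder weights do not match configuration/vocabulary", call. = FALSE)
  }
  tape <- ad_tape()
  P <- .params_to_nodes(tape, params)
  lapply(encoder_layers_ad(tape, P, batch, cfg), ad_value)
}

#' Pool atom embeddings into a molecule embedding
#'
#' @param atom_embs a matrix of atom embeddings (final layer).
#' @param method pooling tag (see [encoder_config()]).
#' @param params pooling parameters (needed for attention, sortpool,
#'   set2set).
#' @param cfg an [encoder_config()] (for sortpool/set2set sizes).
#' @return a numeric vector of length `hidden_dim`.
#' @export
pool_atoms <- function(atom_embs, method = "sum", params = NULL, cfg = NULL) {
  if (!method %in% c("sum", "avg", "max", "attention", "sortpool", "set2set")) {
    stop(sprintf("unknown pooling method '%s'", method), call. = FALSE)
  }
  n <- nrow(atom_embs)
  if (method == "sum") return(colSums(atom_embs))
  if (method == "avg") return(colMeans(atom_embs))
  if (method == "max") return(apply(atom_embs, 2, max))
  stopifnot(!is.null(params), !is.null(cfg))
  tape <- ad_tape()
  P <- .params_to_nodes(tape, params)
  fake_batch <- list(
    n_mols = 1L, n_atoms = n, mol_index = rep(1L, n),
    S_sum = Matrix::sparseMatrix(i = rep(1L, n), j = seq_len(n), x = 1,
                                 dims = c(1L, n)),
    S_avg = Matrix::sparseMatrix(i = rep(1L, n), j = seq_len(n), x = 1 / n,
                                 dims = c(1L, n))
  )
  cfg2 <- cfg; cfg2$pooling <- method
  as.numeric(ad_value(pool_ad(tape, P, ad_const(tape, atom_embs), fake_batch, cfg2)))
}

#' Encode molecules into embeddings
#'
#' Composition of [encode_atoms()] and [pool_atoms()], vectorized over a
#' list of molecules.
#'
#' @param mols a molecule, list of molecules, or character vector of SMILES.
#' @param params encoder weights.
#' @param cfg the [encoder_config()].
#' @param feature_vocab the atom feature vocabulary.
#' @return a `length(mols) x hidden_dim` embedding matrix.
#' @export
encode_molecules <- function(mols, params, cfg, feature_vocab) {
  batch <- mol_batch(mols, feature_vocab)
  tape <- ad_tape()
  P <- .params_to_nodes(tape, params)
  ad_value(encode_batch_ad(tape, P, batch, cfg)$pooled)
}
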