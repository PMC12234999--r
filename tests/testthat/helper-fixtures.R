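# shared fixtures, built once per test run and memoized

.fx <- new.env(parent = emptyenv())

fx_corpus <- function() {
  if (is.null(.fx$corpus)) {
    .fx$corpus <- synthetic_corpus(n_molecules = 40L, n_reactions = 40L, seed = 11L)
  }
  .fx$corpus
}

fx_csg <- function() {
  if (is.null(.fx$csg)) .fx$csg <- build_csg(fx_corpus()$reactions)
  .fx$csg
}

# a small trained model shared by ranking/feature tests
fx_model <- function() {
  if (is.null(.fx$model)) {
    .fx$model <- train_model(
      fx_corpus()$reactions,
      encoder_config(hidden_dim = 16L),
      train_config(epochs = 8L, seed = 2L),
      with_csgnn = TRUE, csgnn_layers = 1L
    )
  }
  .fx$model
}

side_key_of <- function(...) csgl:::side_key(lapply(c(...), parse_molecule))
with_seed_local <- function(seed, code) csgl:::with_seed(seed, code)
tf_vec_of <- function(tf) csgl:::tf_vector(tf)

# reorder a molecule's atoms by `perm`, remapping bonds accordingly
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  out <- mol
  out$atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$bonds$a <- inv[mol$bonds$a]
  out$bonds$b <- inv[mol$bonds$b]
  out
}

# hand-made transformation-features object for basis/linearity tests
make_tf <- function(delta_bonds, delta_rings, delta_bond_types) {
  structure(
    list(delta_bonds = delta_bonds, delta_rings = delta_rings,
         delta_bond_types = delta_bond_types),
    class = "csgl_transformation"
  )
}

# independent nested-loop evaluation of the attention propagation, built
# from the exported per-node primitives (csg_neighbors, attention_weights,
# relation_embedding); used as the oracle for the vectorized implementation
oracle_propagate <- function(csg, base, rel, wa) {
  H <- length(wa)
  layers <- list(base)
  E <- base
  for (h in seq_len(H)) {
    En <- E
    for (v in seq_along(csg$nodes)) {
      nbs <- csg_neighbors(csg, v)
      if (length(nbs) == 0) next
      nb_emb <- do.call(rbind, lapply(nbs, function(x) E[x$node_id, ]))
      nb_rel <- do.call(rbind, lapply(nbs, function(x) {
        relation_embedding(x$features, rel)
      }))
      w <- attention_weights(E[v, ], nb_emb, nb_rel, wa[[h]])
      En[v, ] <- E[v, ] + colSums(w * nb_emb)
    }
    E <- En
    layers[[h + 1]] <- E
  }
  Reduce(`+`, layers) / (H + 1)
}

# central finite differences of f at params, a few coordinates per array
fd_grads <- function(f, params, coords_per_param = 3L, h = 1e-5, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (nm in names(params)) {
    n <- length(params[[nm]])
    cs <- sample(n, min(coords_per_param, n))
    g <- numeric(length(cs))
    for (k in seq_along(cs)) {
      p1 <- params; p1[[nm]][cs[k]] <- p1[[nm]][cs[k]] + h
      p2 <- params; p2[[nm]][cs[k]] <- p2[[nm]][cs[k]] - h
      g[k] <- (f(p1) - f(p2)) / (2 * h)
    }
    out[[nm]] <- list(coords = cs, grad = g)
  }
  out
}
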