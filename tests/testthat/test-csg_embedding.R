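test_that("READ is a summation readout", {
  v1 <- c(1, 2, 3); v2 <- c(-1, 0, 1)
  expect_equal(read_embedding(list(v1)), v1)
  expect_equal(read_embedding(list(v1, v2)), read_embedding(list(v2, v1)))
  expect_equal(read_embedding(list(v1, -v1)), c(0, 0, 0))
  expect_equal(read_embedding(rbind(v1, v2)), v1 + v2)
  expect_error(read_embedding(list()), "empty set")
})

test_that("relation embeddings are linear in the delta features", {
  vocab <- default_bond_vocabulary()
  rel <- with_seed_local(3, init_relation_params(6L, vocab))
  zero <- make_tf(0L, 0L, setNames(integer(vocab$size), vocab$keys))
  expect_equal(relation_embedding(zero, rel), rep(0, 6))

  bond1 <- make_tf(1L, 0L, setNames(integer(vocab$size), vocab$keys))
  expect_equal(relation_embedding(bond1, rel), unname(rel["bond", ]))
  ring1 <- make_tf(0L, 1L, setNames(integer(vocab$size), vocab$keys))
  expect_equal(relation_embedding(ring1, rel), unname(rel["ring", ]))

  set.seed(4)
  for (i in 1:10) {
    d1 <- make_tf(sample(-3:3, 1), sample(-2:2, 1),
                  setNames(sample(-2:2, vocab$size, replace = TRUE), vocab$keys))
    d2 <- make_tf(sample(-3:3, 1), sample(-2:2, 1),
                  setNames(sample(-2:2, vocab$size, replace = TRUE), vocab$keys))
    a <- sample(-3:3, 1); b <- sample(-3:3, 1)
    combo <- make_tf(a * d1$delta_bonds + b * d2$delta_bonds,
                     a * d1$delta_rings + b * d2$delta_rings,
                     a * d1$delta_bond_types + b * d2$delta_bond_types)
    expect_equal(relation_embedding(combo, rel),
                 a * relation_embedding(d1, rel) + b * relation_embedding(d2, rel),
                 tolerance = 1e-10)
  }
  expect_error(relation_embedding(zero, rel[1:5, ]), "vocabulary size")
})

test_that("attention weights are a softmax over the neighborhood", {
  d <- 5L
  set.seed(8)
  W_a <- rnorm(d)
  center <- rnorm(d)
  expect_equal(attention_weights(center, matrix(rnorm(d), 1), matrix(rnorm(d), 1), W_a), 1)
  nb <- matrix(rnorm(d), 1)[c(1, 1), ]
  rl <- matrix(rnorm(d), 1)[c(1, 1), ]
  expect_equal(attention_weights(center, nb, rl, W_a), c(0.5, 0.5))
  for (k in c(2, 5, 9)) {
    w <- attention_weights(center, matrix(rnorm(k * d), k), matrix(rnorm(k * d), k), W_a)
    expect_equal(sum(w), 1, tolerance = 1e-6)
    expect_true(all(w >= 0))
  }
  expect_length(attention_weights(center, matrix(0, 0, d), matrix(0, 0, d), W_a), 0L)
})

test_that("zero propagation rounds return the READ table bit-identically", {
  csg <- fx_csg()
  set.seed(1)
  base <- matrix(rnorm(length(csg$nodes) * 6), ncol = 6)
  rel <- init_relation_params(6L, csg$vocab)
  out <- csgnn_propagate(csg, base, rel, W_a = list())
  expect_identical(out$final, base)
  expect_identical(out$layers[[1]], base)
})

test_that("a single edge propagates with weight one (hand evaluation)", {
  csg <- build_csg(list(parse_reaction("CCO>>CC=O")))
  set.seed(2)
  d <- 4L
  base <- matrix(rnorm(2 * d), 2, d)
  rel <- init_relation_params(d, csg$vocab)
  wa <- list(matrix(rnorm(d), d, 1))
  out <- csgnn_propagate(csg, base, rel, wa)
  # each node has exactly one neighbor, so the attention weight is 1 and
  # final = (layer0 + (layer0 + neighbor0)) / 2
  expect_equal(out$final[1, ], (base[1, ] + (base[1, ] + base[2, ])) / 2)
  expect_equal(out$final[2, ], (base[2, ] + (base[2, ] + base[1, ])) / 2)
})

test_that("vectorized propagation matches a nested-loop evaluation", {
  # small graphs including shared nodes, parallel edges, and 2-hop paths
  rxn_sets <- list(
    c("CCO>>CC=O", "CC=O.O>>CCO"),
    c("CCO>>CC=O", "CCCO>>CC=O", "CC=O.O>>CCO", "CCN>>CC=O"),
    c("CCO>>CC=O", "CCO>>CC=O", "CC(=O)O.OCC>>CC(=O)OCC.O")
  )
  for (rs in rxn_sets) {
    csg <- build_csg(lapply(rs, parse_reaction))
    expect_lte(length(csg$nodes), 6L)
    d <- 5L
    set.seed(7)
    base <- matrix(rnorm(length(csg$nodes) * d), ncol = d)
    rel <- init_relation_params(d, csg$vocab)
    for (H in 1:2) {
      wa <- lapply(seq_len(H), function(h) matrix(rnorm(d), d, 1))
      fast <- csgnn_propagate(csg, base, rel, wa)$final
      slow <- oracle_propagate(csg, base, rel, wa)
      expect_equal(fast, slow, tolerance = 1e-5)
    }
  }
})

test_that("the training-path propagation agrees with the public one", {
  corp <- fx_corpus()
  csg <- build_csg(corp$reactions)
  all_mols <- unlist(lapply(csg$nodes, function(n) n$members), recursive = FALSE)
  fv <- feature_vocabulary_from_molecules(all_mols)
  blob <- csgl:::.training_blob(corp$reactions, csg, fv)
  cfg <- encoder_config(hidden_dim = 8L)
  params <- init_model_params(cfg, fv$length, csgnn_layers = 2L, seed = 3L)
  fw <- csgl:::.forward_loss(params, blob, cfg, 2L, 1:5, margin = 4, lambda = 0,
                             trainable = FALSE)
  pooled <- csgl:::ad_value(fw$pooled)
  base <- as.matrix(blob$S_node %*% pooled)
  wa <- list(params$wa_1, params$wa_2)
  plain <- csgnn_propagate(csg, base, params$rel, wa)$final
  expect_equal(csgl:::ad_value(fw$node_final), plain, tolerance = 1e-10)
})

test_that("reaction-side embeddings fall back to READ for unseen sides", {
  model <- fx_model()
  seen <- fx_corpus()$reactions[[1]]
  s <- embed_reaction_sides(seen, model)
  i <- match(csgl:::side_key(seen$reactants), model$csg$node_keys)
  expect_equal(s$R, model$node_embeddings[i, ])
  expect_equal(s$T, relation_embedding(
    transformation_features(seen, model$bond_vocab), model$params$rel))

  unseen <- parse_reaction("NCCCCCCCCO>>NCCCCCCCC=O")
  u <- embed_reaction_sides(unseen, model)
  expect_true(is.na(match(csgl:::side_key(unseen$reactants), model$csg$node_keys)))
  direct <- read_embedding(encode_molecules(unseen$reactants, model$params,
                                            model$encoder_cfg, model$feature_vocab))
  expect_equal(u$R, direct)
  # identity reaction on one unseen molecule: zero relation, zero residual
  idrxn <- parse_reaction("NCCCCCCCCO>>NCCCCCCCCO")
  id_ <- embed_reaction_sides(idrxn, model)
  expect_equal(id_$T, rep(0, model$encoder_cfg$hidden_dim))
  expect_equal(translation_distance(id_$R, id_$T, id_$P), 0)
})
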