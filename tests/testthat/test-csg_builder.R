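test_that("transformation features realize the worked deltas", {
  tf0 <- transformation_features(parse_reaction("CCO>>CCO"))
  expect_equal(tf0$delta_bonds, 0L)
  expect_equal(tf0$delta_rings, 0L)
  expect_true(all(tf0$delta_bond_types == 0L))

  ester <- transformation_features(parse_reaction("CC(=O)O.OCC>>CC(=O)OCC.O"))
  expect_equal(ester$delta_bonds, 0L)
  expect_equal(ester$delta_rings, 0L)

  da <- transformation_features(parse_reaction("C=CC=C.C=C>>C1=CCCCC1"))
  expect_equal(da$delta_bonds, -2L)
  expect_equal(da$delta_rings, -1L)
  expect_equal(unname(da$delta_bond_types["C|C|2"]), 2L)
})

test_that("reversing a reaction negates every transformation field", {
  for (rxn in fx_corpus()$reactions[seq(1, 40, by = 3)]) {
    rev_rxn <- rxn
    rev_rxn$reactants <- rxn$products
    rev_rxn$products <- rxn$reactants
    tf <- transformation_features(rxn)
    tr <- transformation_features(rev_rxn)
    expect_equal(tr$delta_bonds, -tf$delta_bonds)
    expect_equal(tr$delta_rings, -tf$delta_rings)
    expect_equal(tr$delta_bond_types, -tf$delta_bond_types)
  }
})

test_that("the synthesis graph deduplicates molecule-set nodes corpus-wide", {
  rxns <- lapply(c("CCO>>CC=O", "CCCO>>CC=O", "CC=O.O>>CCO"), parse_reaction)
  csg <- build_csg(rxns)
  # distinct sides: {CCO}, {CC=O}, {CCCO}, {CC=O, O} - the aldehyde node is
  # shared by two reactions and {CCO} is both a reactant and a product
  expect_equal(length(csg$nodes), 4L)
  expect_equal(length(csg$edges), 3L)
  keys <- csg$node_keys
  aldehyde <- match(side_key_of("CC=O"), keys)
  expect_false(is.na(aldehyde))
  expect_equal(length(csg$adjacency[[aldehyde]]), 2L)

  # disjoint reactions give 2n nodes, n edges
  dis <- lapply(c("CCO>>CC=O", "CCC>>C=CC"), parse_reaction)
  g2 <- build_csg(dis)
  expect_equal(length(g2$nodes), 4L)
  expect_equal(length(g2$edges), 2L)
})

test_that("node count never exceeds twice the reaction count", {
  csg <- fx_csg()
  n <- length(fx_corpus()$reactions)
  expect_lte(length(csg$nodes), 2L * n)
  expect_equal(length(csg$edges), n)
})

test_that("rebuilding from a shuffled corpus yields an isomorphic graph", {
  rxns <- fx_corpus()$reactions
  csg1 <- build_csg(rxns)
  csg2 <- build_csg(rev(rxns))
  expect_setequal(csg1$node_keys, csg2$node_keys)
  sig <- function(csg) {
    sort(vapply(csg$edges, function(e) {
      paste(csg$node_keys[e$src], csg$node_keys[e$dst],
            paste(tf_vec_of(e$features), collapse = ","), sep = " -> ")
    }, character(1)))
  }
  expect_identical(sig(csg1), sig(csg2))
})

test_that("neighbors are returned in both directions with oriented features", {
  rxns <- lapply(c("CCO>>CC=O", "CC=O.O>>CCO"), parse_reaction)
  csg <- build_csg(rxns)
  a <- match(side_key_of("CCO"), csg$node_keys)
  nb <- csg_neighbors(csg, a)
  expect_length(nb, 2L)  # one out-edge, one in-edge (product of reaction 2)
  # the same physical edge seen from both ends carries negated features
  e1 <- csg$edges[[1]]
  fwd <- Filter(function(x) x$edge_id == 1L, csg_neighbors(csg, e1$src))[[1]]
  bwd <- Filter(function(x) x$edge_id == 1L, csg_neighbors(csg, e1$dst))[[1]]
  expect_equal(tf_vec_of(fwd$features), -tf_vec_of(bwd$features))
  expect_equal(tf_vec_of(fwd$features), tf_vec_of(e1$features))
  expect_error(csg_neighbors(csg, 99L), "unknown CSG node")

  # incident-edge count equals adjacency-based degree for every node
  big <- fx_csg()
  for (id in seq(1, length(big$nodes), by = 7)) {
    expect_length(csg_neighbors(big, id), length(big$adjacency[[id]]))
  }
})

test_that("duplicate reactions keep parallel edges", {
  rxns <- lapply(c("CCO>>CC=O", "CCO>>CC=O"), parse_reaction)
  csg <- build_csg(rxns)
  expect_equal(length(csg$nodes), 2L)
  expect_equal(length(csg$edges), 2L)
  expect_length(csg_neighbors(csg, 1L), 2L)
})

test_that("edge lists round-trip through the TSV export", {
  csg <- fx_csg()
  path <- withr::local_tempfile(fileext = ".tsv")
  export_csg(csg, path)
  back <- import_csg(path)
  expect_setequal(back$node_keys, csg$node_keys)
  expect_equal(length(back$edges), length(csg$edges))
  f1 <- do.call(rbind, lapply(csg$edges, function(e) tf_vec_of(e$features)))
  f2 <- do.call(rbind, lapply(back$edges, function(e) tf_vec_of(e$features)))
  expect_equal(f2[order(f2[, 1], f2[, 2]), ], f1[order(f1[, 1], f1[, 2]), ],
               ignore_attr = TRUE)
})
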