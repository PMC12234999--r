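test_that("dataset splitting is a reproducible 80/10/10 partition", {
  items <- as.list(seq_len(100))
  sp <- split_dataset(items, seed = 3)
  expect_equal(lengths(list(sp$train, sp$valid, sp$test)), c(80L, 10L, 10L))
  expect_setequal(unlist(c(sp$train, sp$valid, sp$test)), 1:100)
  sp2 <- split_dataset(items, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(items, seed = 4)))
  # rounding goes toward the training part
  sp3 <- split_dataset(as.list(1:19), seed = 0)
  expect_equal(lengths(list(sp3$train, sp3$valid, sp3$test)), c(17L, 1L, 1L))
  expect_error(split_dataset(as.list(1:9)), "at least 10")
})

test_that("ranking metric arithmetic matches the definitions", {
  m <- csgl:::ranking_metrics(c(1L, 2L, 4L))
  expect_equal(m$mrr, (1 + 1 / 2 + 1 / 4) / 3)
  expect_equal(m$hit1, 1 / 3)
  expect_equal(m$hit3, 2 / 3)
  expect_equal(m$hit5, 1)
  all1 <- csgl:::ranking_metrics(rep(1L, 7))
  expect_equal(all1$mrr, 1)
  expect_equal(c(all1$hit1, all1$hit3, all1$hit5), c(1, 1, 1))
})

test_that("rank_products agrees with an exhaustive distance-sort oracle", {
  model <- fx_model()
  rxns <- fx_corpus()$reactions
  pool <- lapply(rxns, `[[`, "products")
  keys <- vapply(pool, csgl:::side_key, character(1))
  pool <- pool[!duplicated(keys)]
  for (q in rxns[seq(1, 40, by = 5)]) {
    r <- rank_products(q, pool, model)
    # oracle: score every candidate with the exported primitives and sort
    sides <- embed_reaction_sides(q, model)
    scores <- vapply(pool, function(p) {
      match_score(sides$R, sides$T, csgl:::side_embedding(model, p))
    }, numeric(1))
    truth <- match(csgl:::side_key(q$products), vapply(pool, csgl:::side_key, character(1)))
    oracle <- 1L + sum(scores[-truth] >= scores[truth])
    expect_equal(r, oracle)
  }
  expect_equal(rank_products(rxns[[1]], list(rxns[[1]]$products), model), 1L)
  expect_error(rank_products(rxns[[1]], list(rxns[[2]]$products), model),
               "not among the candidates")
})

test_that("evaluation metrics respect their ordering invariants", {
  model <- fx_model()
  test_rxns <- fx_corpus()$reactions[31:40]
  ev <- evaluate_product_prediction(test_rxns, model)
  expect_true(all(ev$ranks >= 1L & ev$ranks <= ev$n_candidates))
  expect_lte(ev$hit1, ev$mrr)
  expect_lte(ev$mrr, 1)
  expect_lte(ev$hit1, ev$hit3)
  expect_lte(ev$hit3, ev$hit5)
})

test_that("reaction features concatenate the two READ sums", {
  model <- fx_model()
  rxn <- fx_corpus()$reactions[[3]]
  f <- reaction_feature(rxn, model)
  d <- model$encoder_cfg$hidden_dim
  expect_length(f, 2L * d)
  swapped <- rxn
  swapped$reactants <- rxn$products
  swapped$products <- rxn$reactants
  g <- reaction_feature(swapped, model)
  expect_equal(g, c(f[(d + 1):(2 * d)], f[1:d]))
  expect_identical(f, reaction_feature(rxn, model))
})

test_that("classification reports sane metrics and rejects single classes", {
  model <- fx_model()
  rxns <- fx_corpus()$reactions
  sp <- split_dataset(rxns, seed = 1)
  cl <- classify_reactions(c(sp$train, sp$valid), sp$test, model,
                           hidden = 8L, maxit = 60L)
  for (v in c(cl$accuracy, cl$macro_precision, cl$macro_recall)) {
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_length(cl$predicted, length(sp$test))
  single <- Filter(function(r) r$class_label == 1L, rxns)
  expect_error(classify_reactions(single, sp$test, model), "single class")
})

test_that("property AUC is high for real labels and null for permuted ones", {
  model <- fx_model()
  # a pool large enough that the 10% test split supports an AUC estimate
  mols <- generate_molecules(150, max_heavy_atoms = 14, seed = 21)
  pd <- generate_property_dataset(mols, noise = 0, seed = 0)
  # noise-free labels equal the predicate values
  expect_equal(pd$label, attr(pd, "clean_label"))
  expect_equal(pd$label,
               vapply(mols, function(m) as.integer(m$ring_count > 0), integer(1)))

  res <- predict_properties(pd, model, seed = 0)
  expect_gte(res$auc, 0); expect_lte(res$auc, 1)

  # permutation null: AUC concentrates near 1/2
  set.seed(5)
  null_auc <- replicate(20, {
    pd2 <- pd
    pd2$label <- sample(pd2$label)
    tryCatch(predict_properties(pd2, model, seed = 0)$auc, error = function(e) NA)
  })
  expect_lt(abs(mean(null_auc, na.rm = TRUE) - 0.5), 0.1)
})

test_that("property labels respect noise and balance contracts", {
  mols <- fx_corpus()$molecules
  pd <- generate_property_dataset(mols, noise = 0.5, seed = 2)
  expect_false(all(pd$label == attr(pd, "clean_label")))
  expect_error(
    generate_property_dataset(mols, rule = function(m) FALSE),
    "unbalanced"
  )
  bz <- generate_property_dataset(list(parse_molecule("c1ccccc1"), parse_molecule("CCO")),
                                  noise = 0)
  expect_equal(bz$label, c(1L, 0L))
})
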