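test_that("parse_molecule extracts the heavy-atom graph", {
  w <- parse_molecule("O")
  expect_equal(nrow(w$atoms), 1L)
  expect_equal(nrow(w$bonds), 0L)
  expect_equal(w$ring_count, 0L)
  expect_equal(w$atoms$num_hydrogens, 2L)

  e <- parse_molecule("CCO")
  expect_equal(nrow(e$atoms), 3L)
  expect_equal(nrow(e$bonds), 2L)
  expect_equal(e$ring_count, 0L)

  bz <- parse_molecule("c1ccccc1")
  expect_equal(nrow(bz$atoms), 6L)
  expect_equal(nrow(bz$bonds), 6L)
  expect_equal(bz$ring_count, 1L)
  expect_true(all(bz$bonds$order == "ar"))
  expect_true(all(bz$atoms$in_ring))
  expect_true(all(bz$atoms$num_hydrogens == 1L))
})

test_that("kekule and aromatic notations agree; unparsable input errors", {
  expect_equal(parse_molecule("C1=CC=CC=C1")$canonical_id,
               parse_molecule("c1ccccc1")$canonical_id)
  expect_error(parse_molecule("qq"), "unparsable SMILES.*qq")
  expect_error(parse_molecule(""), "empty SMILES")
  expect_error(parse_molecule("c1ccccc"), "unparsable")
})

test_that("per-atom attributes match toolkit reference values", {
  # hydrogen counts, charges and ring flags cross-checked against RDKit
  pyr <- parse_molecule("c1ccncc1")
  expect_equal(pyr$atoms$num_hydrogens[pyr$atoms$element == "N"], 0L)
  thio <- parse_molecule("c1ccsc1")
  expect_equal(thio$atoms$num_hydrogens[thio$atoms$element == "S"], 0L)
  fur <- parse_molecule("c1ccoc1")
  expect_equal(fur$atoms$num_hydrogens[fur$atoms$element == "O"], 0L)
  pyrrole <- parse_molecule("c1cc[nH]c1")
  expect_equal(pyrrole$atoms$num_hydrogens[pyrrole$atoms$element == "N"], 1L)
  tol <- parse_molecule("Cc1ccccc1")
  expect_setequal(tol$atoms$num_hydrogens[tol$atoms$element == "C"],
                  c(3L, 0L, 1L))
  nb <- parse_molecule("O=[N+]([O-])c1ccccc1")
  expect_equal(sort(nb$atoms$formal_charge), c(-1L, rep(0L, 7), 1L))
  amm <- parse_molecule("[NH4+]")
  expect_equal(amm$atoms$formal_charge, 1L)
  expect_equal(amm$atoms$num_hydrogens, 4L)
})

test_that("the biphenyl bridge is a single bond, not aromatic", {
  bp <- parse_molecule("c1ccccc1c1ccccc1")
  expect_equal(sum(bp$bonds$order == "ar"), 12L)
  expect_equal(sum(bp$bonds$order == "1"), 1L)
  expect_equal(bp$ring_count, 2L)
})

test_that("canonical ids are stable fixed points", {
  corp <- fx_corpus()
  for (m in corp$molecules[seq(1, 40, by = 4)]) {
    expect_identical(parse_molecule(m$canonical_id)$canonical_id, m$canonical_id)
  }
  # same molecule written differently maps to one id
  expect_identical(parse_molecule("OCC")$canonical_id,
                   parse_molecule("C(O)C")$canonical_id)
})

test_that("atom feature vectors are four concatenated one-hot blocks", {
  vocab <- atom_feature_vocabulary(c("C", "N", "O"))
  v <- atom_feature_vector(
    list(element = "C", formal_charge = 0L, num_hydrogens = 3L, in_ring = FALSE),
    vocab
  )
  expect_equal(length(v), vocab$length)
  expect_equal(sum(v), 4)
  expect_true(all(v %in% c(0, 1)))
  # block positions: charge 0 at slot 3, element C first, H=3 at 4th H slot
  expect_equal(which(v == 1), c(3L, 5L + 1L, 5L + 4L + 4L, 5L + 4L + 5L + 1L))

  v2 <- atom_feature_vector(
    list(element = "C", formal_charge = 0L, num_hydrogens = 3L, in_ring = FALSE),
    vocab
  )
  expect_identical(v, v2)

  # out-of-vocabulary element and clipped attributes still give 4 ones
  v3 <- atom_feature_vector(
    list(element = "Se", formal_charge = -5L, num_hydrogens = 9L, in_ring = TRUE),
    vocab
  )
  expect_equal(sum(v3), 4)
  expect_equal(v3[5L + match("UNK", vocab$elements)], 1)
})

test_that("reactions parse with multiset sides and discard agents", {
  r <- parse_reaction("CCO>>CCO")
  expect_length(r$reactants, 1L)
  expect_length(r$products, 1L)
  expect_identical(r$reactants[[1]]$canonical_id, r$products[[1]]$canonical_id)

  r2 <- parse_reaction("CC(=O)O.OCC>>CC(=O)OCC.O")
  expect_length(r2$reactants, 2L)
  expect_length(r2$products, 2L)

  r3 <- parse_reaction("CC(=O)O.OCC>[Na+]>CC(=O)OCC.O")
  expect_length(r3$reactants, 2L)
  expect_length(r3$products, 2L)

  # duplicates are kept as a multiset
  r4 <- parse_reaction("CC=O.CC=O>>CC(O)CC=O")
  expect_length(r4$reactants, 2L)

  expect_error(parse_reaction("CCO>>"), "empty side")
  expect_error(parse_reaction("CCO"), "reactants>>products")
  expect_error(parse_reaction(">>CCO"), "empty side")
})

test_that("reaction files round-trip with labels and skip comments", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header comment", "CCO>>CC=O\t4", "", "CC(=O)O.OCC>>CC(=O)OCC.O\t1"),
             path)
  rxns <- read_reactions(path)
  expect_length(rxns, 2L)
  expect_equal(rxns[[1]]$class_label, 4L)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_reactions(rxns, path2)
  again <- read_reactions(path2)
  expect_identical(vapply(again, reaction_smiles, character(1)),
                   vapply(rxns, reaction_smiles, character(1)))
  writeLines("CCO>>", path)
  expect_error(read_reactions(path), "line 1")
})

test_that("counting statistics match enumerated examples", {
  expect_equal(count_bonds("O"), 0L)
  expect_equal(count_bonds(c("CC(=O)O", "OCC")), 5L)
  expect_equal(count_bonds(c("C=CC=C", "C=C")), 4L)
  expect_equal(count_rings("CCO"), 0L)
  expect_equal(count_rings("c1ccccc1"), 1L)
  expect_equal(count_rings("c1ccc2ccccc2c1"), 2L)

  v <- count_bond_types("CCO")
  expect_equal(unname(v[c("C|C|1", "C|O|1")]), c(1L, 1L))
  expect_equal(sum(v), 2L)
  expect_true(all(count_bond_types("O") == 0L))
})

test_that("counts are additive and bond types partition the bonds", {
  mols <- lapply(fx_corpus()$molecules[1:12], function(m) m$canonical_id)
  a <- mols[1:5]; b <- mols[6:12]
  expect_equal(count_bonds(c(a, b)), count_bonds(a) + count_bonds(b))
  expect_equal(count_rings(c(a, b)), count_rings(a) + count_rings(b))
  expect_equal(count_bond_types(c(a, b)),
               count_bond_types(a) + count_bond_types(b))
  for (m in mols) {
    v <- count_bond_types(m)
    expect_true(all(v >= 0L))
    expect_lte(sum(v), count_bonds(m))
  }
  # duplicated member counts twice
  expect_equal(count_bonds(c("CCO", "CCO")), 2L * count_bonds("CCO"))
})

test_that("bond-type vocabularies validate and load from YAML and JSON", {
  vb <- default_bond_vocabulary()
  expect_equal(vb$size, 15L)
  expect_error(
    bond_type_vocabulary(data.frame(elem_a = c("C", "C"), elem_b = c("O", "O"),
                                    order = c("1", "1"))),
    "duplicate"
  )
  # element pair is order-insensitive
  expect_error(
    bond_type_vocabulary(data.frame(elem_a = c("C", "O"), elem_b = c("O", "C"),
                                    order = c("1", "1"))),
    "duplicate"
  )
  ypath <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(list(elem_a = "C", elem_b = "C", order = "1"),
                        list(elem_a = "C", elem_b = "O", order = "2")), ypath)
  vy <- read_bond_vocabulary(ypath)
  expect_equal(vy$size, 2L)
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(elem_a = "C", elem_b = "C", order = "1")),
                       jpath, auto_unbox = TRUE)
  expect_equal(read_bond_vocabulary(jpath)$size, 1L)
  expect_equal(unname(count_bond_types("CCO", vy)["C|C|1"]), 1L)
})
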