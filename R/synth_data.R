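# Synthetic molecule and reaction corpora with known structure.
#
# Molecules are assembled from a small fragment grammar (alkyl chains with
# optional branches and carbocyclic or aromatic rings, terminated by a
# functional-group suffix), so every template knows where its reactive
# position sits. Reaction templates are string-level graph edits over that
# grammar; atom bookkeeping is approximate in the same way real patent
# reaction records are (small by-products such as water or HCl are kept,
# mechanisms are not modeled).

.fam_suffix <- c(
  alkane = "", alcohol = "O", acid = "C(=O)O", amine = "N",
  chloride = "Cl", diene = "C=CC=C", alkene = "C=C"
)

.random_stem <- function(max_atoms) {
  core <- paste(rep("C", sample.int(6L, 1L)), collapse = "")
  ring <- if (stats::runif(1) < 0.35) {
    sample(c("c1ccccc1", "C1CCCCC1", "C1CCCC1", "C1CC1", "C1CCCCCC1"), 1L)
  } else ""
  branch <- if (stats::runif(1) < 0.3) {
    sample(c("C(C)", "C(CC)", "C(C)(C)"), 1L)
  } else ""
  stem <- paste0(ring, branch, core)
  n_heavy <- nchar(gsub("[^Cc]", "", stem))
  if (n_heavy > max_atoms) stem <- substr(stem, 1, 0) # force retry
  stem
}

#' Generate a pool of synthetic molecules
#'
#' Builds `n` distinct valid molecules by random assembly of a fragment
#' grammar: an alkyl stem (chain, optional branch, optional five/six-ring or
#' benzene prefix) terminated by a functional-group suffix cycled over
#' alkanes, alcohols, carboxylic acids, amines, alkyl chlorides, conjugated
#' dienes, and terminal alkenes. The generating family and stem are attached
#' as attributes so reaction templates can edit the molecules.
#'
#' @param n number of molecules.
#' @param max_heavy_atoms cap on heavy atoms per molecule.
#' @param seed integer seed (the output is a pure function of it).
#' @return list of `n` distinct [csgl_molecule] objects.
#' @export
generate_molecules <- function(n, max_heavy_atoms = 12L, seed = 0L) {
  stopifnot(n >= 1L)
  families <- rep(names(.fam_suffix), length.out = n)
  with_seed(seed, {
    seen <- character(0)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      fam <- families[i]
      budget <- max_heavy_atoms - nchar(gsub("[^CcNO]", "", .fam_suffix[[fam]]))
      for (try in seq_len(500L)) {
        stem <- .random_stem(budget)
        if (!nzchar(stem)) next
        smi <- paste0(stem, .fam_suffix[[fam]])
        mol <- tryCatch(parse_molecule(smi), error = function(e) NULL)
        if (is.null(mol) || mol$canonical_id %in% seen) next
        attr(mol, "family") <- fam
        attr(mol, "stem") <- stem
        seen <- c(seen, mol$canonical_id)
        out[[i]] <- mol
        break
      }
      if (is.null(out[[i]])) {
        stop(sprintf("could not generate a distinct molecule for family '%s'", fam),
             call. = FALSE)
      }
    }
    out
  })
}

#' Reaction templates of the synthetic corpus
#'
#' Five string-level graph-edit rules over the fragment grammar, each with
#' the sign pattern its transformation features must realize (0 means
#' exactly zero, -1 strictly negative):
#' esterification (condensation losing water), Diels-Alder ring closure,
#' halide substitution by an amine, alcohol-to-carbonyl oxidation, and
#' ester hydrolysis (the reverse of esterification, which shares its nodes
#' with the forward reaction and gives the synthesis graph 2-hop
#' structure).
#'
#' @return named list of template objects with fields `template_id`,
#'   `name`, `families`, `sign` and a `build(stems)` closure returning the
#'   reactant and product SMILES.
#' @export
reaction_templates <- function() {
  tpl <- function(id, name, families, sign_bonds, sign_rings, build) {
    structure(
      list(template_id = id, name = name, families = families,
           sign = c(bonds = sign_bonds, rings = sign_rings), build = build),
      class = "csgl_template"
    )
  }
  list(
    esterification = tpl(
      1L, "esterification", c("acid", "alcohol"), 0L, 0L,
      function(st) list(
        reactants = c(paste0(st[1], "C(=O)O"), paste0(st[2], "O")),
        products = c(paste0(st[1], "C(=O)O", st[2]), "O")
      )
    ),
    diels_alder = tpl(
      2L, "diels_alder", c("diene", "alkene"), -1L, -1L,
      function(st) list(
        reactants = c(paste0(st[1], "C=CC=C"), paste0(st[2], "C=C")),
        # ring closure uses digit 9 so stems carrying their own ring
        # (digit 1) can be substituted without digit collision
        products = paste0("C9(", st[1], ")C=CCCC9", st[2])
      )
    ),
    substitution = tpl(
      3L, "substitution", c("chloride", "amine"), 0L, 0L,
      function(st) list(
        reactants = c(paste0(st[1], "Cl"), paste0(st[2], "N")),
        products = c(paste0(st[2], "N", st[1]), "Cl")
      )
    ),
    oxidation = tpl(
      4L, "oxidation", "alcohol", 0L, 0L,
      function(st) list(
        reactants = paste0(st[1], "O"),
        products = paste0(st[1], "=O")
      )
    ),
    hydrolysis = tpl(
      5L, "hydrolysis", c("acid", "alcohol"), 0L, 0L,
      function(st) list(
        reactants = c(paste0(st[1], "C(=O)O", st[2]), "O"),
        products = c(paste0(st[1], "C(=O)O"), paste0(st[2], "O"))
      )
    )
  )
}

# alcohols whose hydroxyl carbon keeps a hydrogen after oxidation
.primary_like <- function(mol) {
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != "1") next
    ia <- b$a[k]; ib <- b$b[k]
    for (pair in list(c(ia, ib), c(ib, ia))) {
      o <- pair[1]; cc <- pair[2]
      if (mol$atoms$element[o] == "O" && mol$atoms$num_hydrogens[o] >= 1L &&
          mol$atoms$element[cc] == "C" && !mol$atoms$aromatic[cc] &&
          mol$atoms$num_hydrogens[cc] >= 2L) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Generate a labeled synthetic reaction corpus
#'
#' Cycles over the reaction templates, sampling compatible molecules from
#' the pool and instantiating each template's graph edit; the class label of
#' every reaction is its template id. Hydrolysis reactions reverse
#' previously generated esterifications, so their reactant/product sets
#' coincide with existing nodes and the synthesis graph contains shared
#' nodes (degree 2 or more) and nodes with both incoming and outgoing
#' edges. Each realized reaction is checked against its template's
#' transformation sign pattern.
#'
#' @param mols molecule pool from [generate_molecules()] (the family/stem
#'   attributes are required).
#' @param templates templates from [reaction_templates()].
#' @param n number of reactions.
#' @param seed integer seed.
#' @return list of `n` labeled `csgl_reaction` objects.
#' @export
generate_reactions <- function(mols, templates = reaction_templates(), n,
                               seed = 0L) {
  stopifnot(length(templates) >= 1L, n >= 1L)
  stems <- lapply(mols, attr, "stem")
  fams <- vapply(mols, function(m) {
    f <- attr(m, "family")
    if (is.null(f)) NA_character_ else f
  }, character(1))
  usable <- !vapply(stems, is.null, logical(1)) & !is.na(fams)
  pool <- function(fam, extra = NULL) {
    ok <- usable & fams == fam
    if (!is.null(extra)) ok <- ok & vapply(mols, extra, logical(1))
    which(ok)
  }
  pools <- list(
    acid = pool("acid"), alcohol = pool("alcohol"),
    amine = pool("amine"), chloride = pool("chloride"),
    diene = pool("diene"), alkene = pool("alkene"),
    primary_alcohol = pool("alcohol", .primary_like)
  )
  needed <- unique(unlist(lapply(templates, `[[`, "families")))
  for (fam in needed) {
    key <- if (fam == "alcohol") "alcohol" else fam
    if (length(pools[[key]]) == 0L) {
      stop(sprintf("insufficient compatible molecules: no '%s' in the pool", fam),
           call. = FALSE)
    }
  }
  if (length(pools$primary_alcohol) == 0L) {
    stop("insufficient compatible molecules: no oxidizable alcohol in the pool",
         call. = FALSE)
  }

  with_seed(seed, {
    ester_log <- list()
    out <- vector("list", n)
    tpl_seq <- rep(seq_along(templates), length.out = n)
    for (k in seq_len(n)) {
      tp <- templates[[tpl_seq[k]]]
      st <- switch(tp$name,
        esterification = {
          pair <- c(sample(pools$acid, 1L), sample(pools$alcohol, 1L))
          ester_log[[length(ester_log) + 1L]] <-
            c(stems[[pair[1]]], stems[[pair[2]]])
          c(stems[[pair[1]]], stems[[pair[2]]])
        },
        diels_alder = c(stems[[sample(pools$diene, 1L)]],
                        stems[[sample(pools$alkene, 1L)]]),
        substitution = c(stems[[sample(pools$chloride, 1L)]],
                         stems[[sample(pools$amine, 1L)]]),
        oxidation = stems[[sample(pools$primary_alcohol, 1L)]],
        hydrolysis = {
          if (length(ester_log) > 0L) {
            ester_log[[sample.int(length(ester_log), 1L)]]
          } else {
            c(stems[[sample(pools$acid, 1L)]], stems[[sample(pools$alcohol, 1L)]])
          }
        }
      )
      sides <- tp$build(st)
      rxn <- parse_reaction(
        paste0(paste(sides$reactants, collapse = "."), ">>",
               paste(sides$products, collapse = ".")),
        reaction_id = sprintf("synth-%05d", k),
        class_label = tp$template_id
      )
      tf <- transformation_features(rxn)
      ok <- function(delta, sgn) {
        if (sgn == 0L) delta == 0L else sign(delta) == sgn
      }
      if (!ok(tf$delta_bonds, tp$sign[["bonds"]]) ||
          !ok(tf$delta_rings, tp$sign[["rings"]])) {
        stop(sprintf(
          "template '%s' realized deltas (%d, %d) violating its sign pattern",
          tp$name, tf$delta_bonds, tf$delta_rings
        ), call. = FALSE)
      }
      out[[k]] <- rxn
    }
    out
  })
}

#' Generate a binary molecular property dataset
#'
#' Labels each molecule by a structural predicate (default: contains a
#' ring), then flips a small fraction of labels as noise. Errors if the
#' clean labels are outside the 20-80% balance band, in which case the
#' caller should supply a differently composed pool.
#'
#' @param mols list of molecules.
#' @param rule predicate `function(mol) -> logical` (default ring
#'   presence).
#' @param noise label flip probability (default 0.05).
#' @param seed integer seed (controls the flips).
#' @return data frame with columns `smiles`, `label`; the pre-noise labels
#'   are attached as attribute `clean_label`.
#' @export
generate_property_dataset <- function(mols, rule = NULL, noise = 0.05,
                                      seed = 0L) {
  mols <- .as_mol_list(mols)
  if (is.null(rule)) rule <- function(m) m$ring_count > 0L
  clean <- vapply(mols, function(m) as.integer(isTRUE(rule(m))), integer(1))
  bal <- mean(clean)
  if (bal < 0.2 || bal > 0.8) {
    stop(sprintf(
      "property labels unbalanced (positive rate %.2f); supply a pool with balance in [0.2, 0.8]",
      bal
    ), call. = FALSE)
  }
  flips <- with_seed(seed, stats::runif(length(mols)) < noise)
  df <- data.frame(
    smiles = vapply(mols, function(m) m$canonical_id, character(1)),
    label = ifelse(flips, 1L - clean, clean),
    stringsAsFactors = FALSE
  )
  attr(df, "clean_label") <- clean
  df
}

#' Default synthetic study corpus
#'
#' The fixture used throughout the test suite and examples: 120 molecules,
#' 300 reactions over the 5 templates, seed-determined.
#'
#' @param n_molecules,n_reactions,max_heavy_atoms,seed generation settings.
#' @return list with `molecules`, `reactions`, `templates`.
#' @export
synthetic_corpus <- function(n_molecules = 120L, n_reactions = 300L,
                             max_heavy_atoms = 12L, seed = 0L) {
  mols <- generate_molecules(n_molecules, max_heavy_atoms, seed = seed)
  templates <- reaction_templates()
  reactions <- generate_reactions(mols, templates, n_reactions, seed = seed + 1L)
  list(molecules = mols, reactions = reactions, templates = templates)
}
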