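#' Split a dataset into train/validation/test parts
#'
#' Random partition with the given fractions (default 80/10/10). The
#' validation and test sizes are floored, so rounding remainders go to the
#' training part; the split is a partition and is reproducible by seed.
#'
#' @param items a list or vector of at least 10 items.
#' @param fractions length-3 nonnegative fractions summing to 1.
#' @param seed integer seed.
#' @return list with elements `train`, `valid`, `test`.
#' @export
split_dataset <- function(items, fractions = c(0.8, 0.1, 0.1), seed = 0L) {
  n <- length(items)
  if (n < 10L) stop("need at least 10 items to split", call. = FALSE)
  stopifnot(length(fractions) == 3L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  n_valid <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  perm <- with_seed(seed, sample.int(n))
  test_idx <- perm[seq_len(n_test)]
  valid_idx <- perm[n_test + seq_len(n_valid)]
  train_idx <- perm[-seq_len(n_test + n_valid)]
  list(train = items[sort(train_idx)], valid = items[sort(valid_idx)],
       test = items[sort(test_idx)])
}

# local molecule-embedding memo so evaluation encodes each molecule once
.side_embedder <- function(model, reactions, candidate_sides = list()) {
  sides <- c(lapply(reactions, `[[`, "reactants"),
             lapply(reactions, `[[`, "products"), candidate_sides)
  mols <- unlist(sides, recursive = FALSE)
  ids <- vapply(mols, function(m) m$canonical_id, character(1))
  keep <- !duplicated(ids)
  embs <- model_encode(model, mols[keep])
  lookup <- stats::setNames(seq_len(sum(keep)), ids[keep])
  function(side_mols) {
    key <- side_key(side_mols)
    i <- match(key, model$csg$node_keys)
    if (!is.na(i)) return(model$node_embeddings[i, ])
    rows <- lookup[vapply(side_mols, function(m) m$canonical_id, character(1))]
    read_embedding(embs[rows, , drop = FALSE])
  }
}

.rank_one <- function(q_emb, t_emb, cand_embs, true_idx) {
  scores <- vapply(seq_len(nrow(cand_embs)), function(j) {
    -sqrt(sum((q_emb + t_emb - cand_embs[j, ])^2))
  }, numeric(1))
  s_true <- scores[true_idx]
  # pessimistic tie-breaking: equal-scoring distractors precede the truth
  1L + sum(scores[-true_idx] >= s_true)
}

#' Rank the true product among candidate product sets
#'
#' Candidates are scored by [match_score()] against the query's reactant and
#' relation embeddings; identical candidate sets are collapsed by their
#' canonical multiset key. Ties are broken pessimistically (equal-scoring
#' distractors are placed before the true product).
#'
#' @param query a `csgl_reaction` whose product side must appear among the
#'   candidates.
#' @param candidates list of product sets: each a list of molecules or a
#'   character vector of SMILES.
#' @param model a trained `csgl_model`.
#' @return the 1-based rank of the true product.
#' @export
rank_products <- function(query, candidates, model) {
  cand_mols <- lapply(candidates, .as_mol_list)
  keys <- vapply(cand_mols, side_key, character(1))
  cand_mols <- cand_mols[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  true_idx <- match(side_key(query$products), keys)
  if (is.na(true_idx)) {
    stop("true product set is not among the candidates", call. = FALSE)
  }
  emb <- .side_embedder(model, list(query), cand_mols)
  sides <- embed_reaction_sides(query, model)
  cand_embs <- do.call(rbind, lapply(cand_mols, emb))
  .rank_one(sides$R, sides$T, cand_embs, true_idx)
}

ranking_metrics <- function(ranks) {
  list(
    ranks = ranks,
    mrr = mean(1 / ranks),
    hit1 = mean(ranks <= 1),
    hit3 = mean(ranks <= 3),
    hit5 = mean(ranks <= 5)
  )
}

#' Product-prediction evaluation (MRR, Hit@K)
#'
#' The candidate pool is the set of distinct product sides occurring in the
#' test reactions (deduplicated by canonical multiset key). Each test
#' reaction queries the pool with its reactant and relation embeddings, and
#' the rank of its true product feeds mean reciprocal rank and Hit@{1,3,5}.
#'
#' @param test_reactions list of `csgl_reaction` objects.
#' @param model a trained `csgl_model`.
#' @return a `csgl_ranking` with fields `ranks`, `mrr`, `hit1`, `hit3`,
#'   `hit5`, `n_candidates`.
#' @export
evaluate_product_prediction <- function(test_reactions, model) {
  stopifnot(length(test_reactions) >= 1L)
  prod_sides <- lapply(test_reactions, `[[`, "products")
  keys <- vapply(prod_sides, side_key, character(1))
  pool <- prod_sides[!duplicated(keys)]
  pool_keys <- keys[!duplicated(keys)]
  emb <- .side_embedder(model, test_reactions, pool)
  cand_embs <- do.call(rbind, lapply(pool, emb))
  ranks <- vapply(seq_along(test_reactions), function(i) {
    rxn <- test_reactions[[i]]
    tf <- transformation_features(rxn, model$bond_vocab)
    q <- emb(rxn$reactants)
    t_ <- relation_embedding(tf, model$params$rel)
    .rank_one(q, t_, cand_embs, match(keys[i], pool_keys))
  }, integer(1))
  out <- ranking_metrics(ranks)
  out$n_candidates <- length(pool)
  structure(out, class = "csgl_ranking")
}

#' @export
print.csgl_ranking <- function(x, ...) {
  cat(sprintf(
    "<ranking> %d queries, %d candidates | MRR %.4f  Hit@1 %.4f  Hit@3 %.4f  Hit@5 %.4f\n",
    length(x$ranks), x$n_candidates, x$mrr, x$hit1, x$hit3, x$hit5
  ))
  invisible(x)
}

#' Concatenated reaction feature for classification
#'
#' The READ sum of the reactant embeddings concatenated with the READ sum of
#' the product embeddings (2d dimensions). Intended for models trained
#' without propagation, whose node embeddings transfer across corpora.
#'
#' @param rxn a `csgl_reaction`.
#' @param model a trained `csgl_model`.
#' @return numeric vector of length `2 * hidden_dim`.
#' @export
reaction_feature <- function(rxn, model) {
  c(read_embedding(model_encode(model, rxn$reactants)),
    read_embedding(model_encode(model, rxn$products)))
}

.reaction_feature_matrix <- function(reactions, model) {
  mols <- unlist(c(lapply(reactions, `[[`, "reactants"),
                   lapply(reactions, `[[`, "products")), recursive = FALSE)
  ids <- vapply(mols, function(m) m$canonical_id, character(1))
  keep <- !duplicated(ids)
  embs <- model_encode(model, mols[keep])
  lookup <- stats::setNames(seq_len(sum(keep)), ids[keep])
  side_read <- function(side) {
    rows <- lookup[vapply(side, function(m) m$canonical_id, character(1))]
    read_embedding(embs[rows, , drop = FALSE])
  }
  t(vapply(reactions, function(r) {
    c(side_read(r$reactants), side_read(r$products))
  }, numeric(2L * model$encoder_cfg$hidden_dim)))
}

#' Reaction classification on frozen embeddings
#'
#' Fits a single-hidden-layer MLP (softmax output, weight decay) on the
#' concatenated reactant/product features of the training reactions and
#' reports accuracy and macro-averaged precision and recall on the test
#' reactions. Labels come from the reactions' `class_label` fields.
#'
#' @param train_reactions,test_reactions lists of labeled `csgl_reaction`
#'   objects.
#' @param model a trained `csgl_model` (conventionally the propagation-free
#'   variant).
#' @param hidden hidden-layer width. The default 32 keeps the full-batch
#'   BFGS fit of `nnet` fast at typical embedding sizes; widen toward
#'   `2 * hidden_dim` when compute allows.
#' @param decay,maxit `nnet` weight decay and iteration cap.
#' @param seed seed for the MLP initialization.
#' @return list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `predicted`, `truth`.
#' @export
classify_reactions <- function(train_reactions, test_reactions, model,
                               hidden = 32L, decay = 1e-4, maxit = 200L,
                               seed = 0L) {
  get_labels <- function(rxns) {
    labs <- vapply(rxns, function(r) {
      if (is.null(r$class_label)) NA_integer_ else r$class_label
    }, integer(1))
    if (anyNA(labs)) stop("all reactions need class labels", call. = FALSE)
    labs
  }
  y_train <- get_labels(train_reactions)
  y_test <- get_labels(test_reactions)
  if (length(unique(y_train)) < 2L) {
    stop("training reactions contain a single class", call. = FALSE)
  }
  X_train <- .reaction_feature_matrix(train_reactions, model)
  X_test <- .reaction_feature_matrix(test_reactions, model)
  # standardize features for a stable MLP fit
  mu <- colMeans(X_train)
  sdv <- pmax(apply(X_train, 2, stats::sd), 1e-8)
  X_train <- scale(X_train, mu, sdv)
  X_test <- scale(X_test, mu, sdv)
  lev <- sort(unique(c(y_train, y_test)))
  Y <- nnet::class.ind(factor(y_train, levels = lev))
  fit <- with_seed(seed, nnet::nnet(
    x = X_train, y = Y, size = hidden, softmax = TRUE, decay = decay,
    maxit = maxit, MaxNWts = 1e6, trace = FALSE
  ))
  pred <- lev[max.col(predict(fit, X_test))]
  classes <- sort(unique(y_test))
  prec <- vapply(classes, function(cl) {
    denom <- sum(pred == cl)
    if (denom == 0) 0 else sum(pred == cl & y_test == cl) / denom
  }, numeric(1))
  rec <- vapply(classes, function(cl) {
    sum(pred == cl & y_test == cl) / sum(y_test == cl)
  }, numeric(1))
  list(
    accuracy = mean(pred == y_test),
    macro_precision = mean(prec),
    macro_recall = mean(rec),
    predicted = pred, truth = y_test
  )
}

#' Molecular property prediction AUC
#'
#' Embeds each molecule with the trained encoder, fits a ridge-penalized
#' logistic regression on the training split (penalty chosen by
#' deterministic cross-validation; embedding dimension is comparable to the
#' training size, so an unpenalized fit would separate perfectly and emit
#' degenerate probabilities), and reports the area under the ROC curve on
#' the test split.
#'
#' @param data a data frame with columns `smiles` and binary `label` (as
#'   from [generate_property_dataset()] or [read_property_data()]).
#' @param model a trained `csgl_model` (conventionally the propagation-free
#'   variant).
#' @param fractions,seed split specification (see [split_dataset()]).
#' @return list with `auc`, `n_train`, `n_test`.
#' @export
predict_properties <- function(data, model, fractions = c(0.8, 0.1, 0.1),
                               seed = 0L) {
  stopifnot(all(c("smiles", "label") %in% names(data)))
  embs <- model_encode(model, data$smiles)
  idx <- split_dataset(seq_len(nrow(data)), fractions, seed)
  y_train <- data$label[idx$train]
  y_test <- data$label[idx$test]
  if (length(unique(y_test)) < 2L) {
    stop("test split contains a single class; cannot compute AUC", call. = FALSE)
  }
  X_train <- embs[idx$train, , drop = FALSE]
  X_test <- embs[idx$test, , drop = FALSE]
  foldid <- rep_len(1:5, length(y_train))
  fit <- glmnet::cv.glmnet(X_train, y_train, family = "binomial", alpha = 0,
                           foldid = foldid)
  prob <- as.numeric(stats::predict(fit, newx = X_test, s = "lambda.min",
                                    type = "response"))
  roc <- pROC::roc(response = y_test, predictor = prob, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  list(auc = as.numeric(pROC::auc(roc)),
       n_train = length(idx$train), n_test = length(idx$test))
}
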