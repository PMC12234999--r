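#' Training configuration
#'
#' Hyperparameters of the margin-based translational objective and its Adam
#' optimization. The margin defaults to 4, the setting recommended by the
#' sensitivity analysis of the method; the learning rate and embedding size
#' are conventionally searched over `{1e-5, 1e-4, 1e-3, 1e-2}` and
#' `{32, ..., 1024}`.
#'
#' @param margin positive margin gamma of the hinge on negative pairs.
#' @param l2_lambda nonnegative L2 regularization strength on all trainable
#'   parameters.
#' @param learning_rate Adam step size.
#' @param batch_size reactions per minibatch.
#' @param epochs training epochs.
#' @param seed integer seed controlling initialization and batching.
#' @return a `csgl_train_config`.
#' @export
train_config <- function(margin = 4, l2_lambda = 0, learning_rate = 1e-3,
                         batch_size = 32L, epochs = 20L, seed = 0L) {
  stopifnot(margin > 0, l2_lambda >= 0, learning_rate > 0,
            batch_size >= 1L, epochs >= 1L)
  structure(
    list(margin = margin, l2_lambda = l2_lambda,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "csgl_train_config"
  )
}

#' Translational distance of a reaction triple
#'
#' The residual of the chemical-balance constraint `R + T ~ P`: the
#' Euclidean norm of `R + T - P`.
#'
#' @param R,T,P numeric vectors of equal length (reactant, relation, product
#'   embeddings).
#' @return a nonnegative scalar.
#' @export
translation_distance <- function(R, T, P) {
  if (length(R) != length(T) || length(T) != length(P)) {
    stop("embedding dimensions differ", call. = FALSE)
  }
  sqrt(sum((R + T - P)^2))
}

#' Match score of a candidate product
#'
#' The negated translational distance: candidates closer to `R + T` score
#' higher, with 0 the maximum (exact translation).
#'
#' @inheritParams translation_distance
#' @return a nonpositive scalar.
#' @export
match_score <- function(R, T, P) -translation_distance(R, T, P)

#' Margin-based contrastive batch loss
#'
#' Mean positive residual plus mean hinged negative term over all ordered
#' unmatched pairs in the batch:
#' `(1/n) sum_i ||R_i + T_i - P_i|| + (1/(n^2-n)) sum_{i != j} max(gamma -
#' ||R_i + T_i - P_j||, 0)`. A batch of one reaction has no negative term.
#'
#' @param batch list of `list(R, T, P)` triples (numeric vectors).
#' @param margin positive margin gamma.
#' @return a nonnegative scalar.
#' @export
batch_loss <- function(batch, margin = 4) {
  stopifnot(length(batch) >= 1L, margin > 0)
  Rm <- do.call(rbind, lapply(batch, function(x) as.numeric(x$R)))
  Tm <- do.call(rbind, lapply(batch, function(x) as.numeric(x$T)))
  Pm <- do.call(rbind, lapply(batch, function(x) as.numeric(x$P)))
  n <- nrow(Rm)
  Q <- Rm + Tm
  D <- .pairwise_dist(Q, Pm)
  pos <- mean(diag(D))
  if (n == 1L) return(pos)
  off <- D[row(D) != col(D)]
  neg <- sum(pmax(margin - off, 0)) / (n^2 - n)
  pos + neg
}

.pairwise_dist <- function(Q, Pm) {
  cross <- Q %*% t(Pm)
  sq <- matrix(rowSums(Q^2), nrow(Q), nrow(Pm)) +
    matrix(rowSums(Pm^2), nrow(Q), nrow(Pm), byrow = TRUE) - 2 * cross
  sqrt(pmax(sq, 0))
}

#' Total loss with L2 regularization
#'
#' `batch_loss + lambda * ||Theta||_F^2` summed over all trainable
#' parameter arrays.
#'
#' @param batch_loss_value a [batch_loss()] value.
#' @param params list of numeric parameter arrays.
#' @param lambda nonnegative regularization strength.
#' @return a nonnegative scalar.
#' @export
total_loss <- function(batch_loss_value, params, lambda = 0) {
  stopifnot(lambda >= 0)
  batch_loss_value + lambda * sum(vapply(params, function(w) sum(w^2), numeric(1)))
}

# --- autodiff loss used by the training loop ------------------------------
# Q, P: n x d tape nodes (reactant+relation and product embeddings).
# Returns list(loss, pos, neg) where pos/neg are plain numerics for logging.

margin_loss_ad <- function(Q, P, margin) {
  n <- nrow(Q$val)
  sqQ <- ad_rowsums(ad_square(Q))
  sqP <- ad_rowsums(ad_square(P))
  D2 <- ad_add(ad_outer_add(sqQ, sqP), ad_scale(ad_tcrossprod(Q, P), -2))
  # the expansion can go slightly negative by cancellation; clamp before sqrt
  D <- ad_sqrt_(ad_relu(D2), eps = 1e-12)
  eye <- diag(n)
  pos <- ad_scale(ad_sum(ad_mul(D, eye)), 1 / n)
  if (n == 1L) return(list(loss = pos, pos = pos$val, neg = 0))
  hinge <- ad_relu(ad_addc(ad_scale(D, -1), margin))
  neg <- ad_scale(ad_sum(ad_mul(hinge, 1 - eye)), 1 / (n^2 - n))
  list(loss = ad_add(pos, neg), pos = pos$val, neg = neg$val)
}

l2_penalty_ad <- function(param_nodes, lambda) {
  acc <- NULL
  for (p in param_nodes) {
    term <- ad_sum(ad_square(p))
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  ad_scale(acc, lambda)
}
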