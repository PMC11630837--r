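# Residual-like graph convolution fine-tuning on the treat bipartite graph.
#
# Supervision combines two pairwise ranking losses: a binary treat loss
# (positive drug above a sampled non-treating drug) and an effectiveness-
# comparison loss (the more effective treater above the less effective one).
# The two are balanced per step by Bayesian averaging with a position-aware
# weight beta; weights are computed from detached loss values so no gradient
# flows through them.

#' Residual-like GCN forward pass
#'
#' `H^(0) = Z0`; `H^(l) = act(A_hat H^(l-1) W^(l)) + H^(l-1)`. The additive
#' identity path keeps deep stacks from over-smoothing: with all-zero
#' weights the output is exactly `Z0`.
#'
#' @param adjacency a `normalized_adjacency` over the embedding's node set.
#' @param z0 input embedding matrix (node ids as rownames).
#' @param weights list of `d x d` layer weight matrices.
#' @return embedding matrix of the same shape as `z0`.
#' @export
residual_forward <- function(adjacency, z0, weights) {
  residual_fwd(adjacency, z0, weights)$H
}

residual_fwd <- function(adjacency, z0, weights) {
  z0 <- align_features(z0, adjacency$node_order)
  d <- ncol(z0)
  for (w in weights) {
    if (!identical(dim(w), c(d, d))) {
      input_error("residual layer weights must be %d x %d", d, d)
    }
  }
  a_hat <- adjacency$matrix
  hs <- vector("list", length(weights) + 1L); hs[[1L]] <- z0
  pre <- vector("list", length(weights))
  for (l in seq_along(weights)) {
    pre[[l]] <- as.matrix(a_hat %*% hs[[l]]) %*% weights[[l]]
    hs[[l + 1L]] <- relu(pre[[l]]) + hs[[l]]
  }
  out <- hs[[length(hs)]]
  rownames(out) <- adjacency$node_order
  list(H = out, hs = hs, pre = pre)
}

residual_bwd <- function(adjacency, weights, fwd, d_out) {
  a_hat <- adjacency$matrix
  d_w <- vector("list", length(weights))
  dh <- d_out
  for (l in rev(seq_along(weights))) {
    dm <- dh * (fwd$pre[[l]] > 0)
    d_w[[l]] <- crossprod(as.matrix(a_hat %*% fwd$hs[[l]]), dm)
    dh <- as.matrix(a_hat %*% (dm %*% t(weights[[l]]))) + dh
  }
  list(dW = d_w, dz0 = dh)
}

#' Sample binary ranking triples from training treat edges
#'
#' For every training edge (disease u, drug i), draws
#' `negatives_per_positive` drugs j uniformly from the drugs with no
#' training edge to u.
#'
#' @param train a `bipartite_graph` of training treat edges.
#' @param negatives_per_positive positive integer.
#' @param seed integer.
#' @return data.frame with columns `disease`, `pos`, `neg`.
#' @export
sample_binary_triples <- function(train, negatives_per_positive = 1L, seed = 1L) {
  if (negatives_per_positive < 1L) input_error("negatives_per_positive must be >= 1")
  if (nrow(train$edges) == 0L) input_error("no training edges to sample from")
  pos_by_dis <- split(train$edges[, 2L], train$edges[, 1L])
  negs_by_dis <- lapply(pos_by_dis, function(p) setdiff(train$drugs, p))
  starving <- names(negs_by_dis)[lengths(negs_by_dis) == 0L]
  if (length(starving) > 0L) {
    input_error("disease \"%s\" treats every drug; no negative available", starving[[1L]])
  }
  k <- as.integer(negatives_per_positive)
  u <- rep(train$edges[, 1L], each = k)
  i <- rep(train$edges[, 2L], each = k)
  j <- with_seed(seed, vapply(u, function(dis) {
    pool <- negs_by_dis[[dis]]
    pool[[sample.int(length(pool), 1L)]]
  }, character(1L)))
  data.frame(disease = u, pos = i, neg = unname(j))
}

#' Binary treat-relationship ranking loss
#'
#' Sum over triples of `-ln(sigmoid(r_ui - r_uj))` where i treats disease u
#' and j does not; computed in the overflow-safe softplus form.
#'
#' @param triples data.frame with columns `disease`, `pos`, `neg`
#'   (from [sample_binary_triples()]).
#' @param scores disease x drug score matrix with ids as dimnames.
#' @return non-negative scalar.
#' @export
treat_ranking_loss <- function(triples, scores) {
  if (nrow(triples) == 0L) input_error("no binary triples")
  pairwise_rank_loss(triples$disease, triples$pos, triples$neg, scores)
}

#' Effectiveness-comparison ranking loss
#'
#' Sum over comparison triples of `-ln(sigmoid(r_ui - r_uk))` where drug i is
#' the more effective and k the less effective treater of disease u. An
#' empty triple set returns 0 with attribute `usable = FALSE`.
#'
#' @param ecr data.frame with columns `disease_id`, `better_drug_id`,
#'   `worse_drug_id`.
#' @inheritParams treat_ranking_loss
#' @export
ecr_ranking_loss <- function(ecr, scores) {
  if (is.null(ecr) || nrow(ecr) == 0L) {
    return(structure(0, usable = FALSE))
  }
  structure(pairwise_rank_loss(ecr$disease_id, ecr$better_drug_id,
                               ecr$worse_drug_id, scores),
            usable = TRUE)
}

pairwise_rank_loss <- function(u, i, j, scores) {
  iu <- match(u, rownames(scores)); ii <- match(i, colnames(scores))
  ij <- match(j, colnames(scores))
  if (anyNA(iu)) input_error("unknown disease id \"%s\" in triples", u[which(is.na(iu))[1L]])
  if (anyNA(c(ii, ij))) {
    bad <- c(i, j)[which(is.na(c(ii, ij)))[1L]]
    input_error("unknown drug id \"%s\" in triples", bad)
  }
  diff <- scores[cbind(iu, ii)] - scores[cbind(iu, ij)]
  sum(softplus(-diff))
}

#' Bayesian-averaged combination of the two ranking losses
#'
#' With `L_IET = L_I + L_E`, the total objective is
#' `w_I * L_I + w_E * L_E + lambda * ||Theta||^2` where
#' `w_I = L_IET / (L_IET + beta)` and `w_E = beta / (L_IET + beta)`. As beta
#' tends to 0 all weight moves to the binary loss; as beta grows it moves to
#' the effectiveness loss. When `L_IET + beta == 0` the weights default to
#' (0.5, 0.5).
#'
#' @param l_i,l_e non-negative loss values.
#' @param beta non-negative position-aware weight.
#' @param lambda non-negative L2 coefficient.
#' @param theta_sq_norm squared L2 norm of the trainable parameters.
#' @return list with `total`, `w_i`, `w_e`, `l_iet`.
#' @export
bayesian_multiloss <- function(l_i, l_e, beta, lambda = 0, theta_sq_norm = 0) {
  if (beta < 0 || lambda < 0) input_error("beta and lambda must be non-negative")
  if (l_i < 0 || l_e < 0) input_error("loss values must be non-negative")
  l_iet <- l_i + l_e
  if (l_iet + beta == 0) {
    w_i <- 0.5; w_e <- 0.5
  } else {
    w_i <- l_iet / (l_iet + beta)
    w_e <- beta / (l_iet + beta)
  }
  list(total = w_i * l_i + w_e * l_e + lambda * theta_sq_norm,
       w_i = w_i, w_e = w_e, l_iet = l_iet)
}

#' Default fine-tuning configuration
#'
#' @param beta position-aware weight of [bayesian_multiloss()].
#' @param lambda L2 regularization coefficient.
#' @param n_layers residual layers L.
#' @param epochs gradient steps (binary negatives resampled each epoch).
#' @param learning_rate Adam learning rate.
#' @param negatives_per_positive negatives drawn per training edge per epoch.
#' @param weight_override `NULL`, or `c(w_i, w_e)` to pin the loss weights
#'   (ablations use `c(1, 0)` / `c(0, 1)`).
#' @param init_sd standard deviation of the layer-weight initialization.
#'   Exactly zero weights are a valid identity model but the rectifier
#'   gradient at 0 is 0, so training needs `init_sd > 0`.
#' @param seed integer master seed.
#' @param verbose print the loss every 20 epochs.
#' @export
finetune_config <- function(beta = 1.0, lambda = 1e-4, n_layers = 2L,
                            epochs = 200L, learning_rate = 1e-3,
                            negatives_per_positive = 1L,
                            weight_override = NULL, init_sd = 0.01,
                            seed = 1L, verbose = FALSE) {
  if (!is.null(weight_override) &&
      (length(weight_override) != 2L || any(weight_override < 0))) {
    input_error("weight_override must be NULL or two non-negative numbers")
  }
  structure(list(beta = beta, lambda = lambda, n_layers = as.integer(n_layers),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 negatives_per_positive = as.integer(negatives_per_positive),
                 weight_override = weight_override, init_sd = init_sd,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "finetune_config")
}

#' Fine-tune a residual GCN ranking model on training treat edges
#'
#' Builds the propagation operator from the training bipartite graph over
#' the full node set of `z0` (unseen diseases stay as isolated self-loop
#' nodes, so the cold-start setting works unchanged), then trains the
#' residual layer weights with Adam on the Bayesian-averaged total loss.
#' The score of (disease u, drug i) is the inner product of their final
#' embeddings.
#'
#' @param train a `bipartite_graph` of training treat edges.
#' @param ecr data.frame of effectiveness triples used for training
#'   (may be empty / NULL).
#' @param z0 pretrained embedding matrix covering all diseases and drugs.
#' @param config a [finetune_config()].
#' @return object of class `finetune_model` with fields `weights`,
#'   `embeddings` (final node embeddings), `scores` (disease x drug matrix),
#'   `log` (per-epoch data.frame), `config`, `adjacency`.
#' @export
finetune_model <- function(train, ecr, z0, config = finetune_config()) {
  nodes <- rownames(z0)
  need <- unique(c(train$diseases, train$drugs,
                   if (!is.null(ecr) && nrow(ecr) > 0)
                     c(ecr$disease_id, ecr$better_drug_id, ecr$worse_drug_id)))
  missing <- setdiff(need, nodes)
  if (length(missing) > 0L) {
    input_error("z0 does not cover node \"%s\"", missing[[1L]])
  }
  adjacency <- build_normalized_adjacency(train, nodes = nodes)
  d <- ncol(z0)
  weights <- with_seed(derive_seed(config$seed, 0L), lapply(
    seq_len(config$n_layers),
    function(l) matrix(stats::rnorm(d * d, sd = config$init_sd), d, d)))
  opt <- adam_init(weights)
  dis_ids <- train$diseases; drug_ids <- train$drugs
  has_ecr <- !is.null(ecr) && nrow(ecr) > 0L
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    fwd <- residual_fwd(adjacency, z0, weights)
    e_mat <- fwd$H
    scores <- e_mat[dis_ids, , drop = FALSE] %*% t(e_mat[drug_ids, , drop = FALSE])
    triples <- sample_binary_triples(train, config$negatives_per_positive,
                                     derive_seed(config$seed, epoch))
    gi <- pairwise_loss_grad(triples$disease, triples$pos, triples$neg,
                             e_mat, scores)
    if (has_ecr) {
      ge <- pairwise_loss_grad(ecr$disease_id, ecr$better_drug_id,
                               ecr$worse_drug_id, e_mat, scores)
    } else {
      ge <- list(loss = 0, dE = 0 * e_mat)
    }
    # The objective combines per-triple mean losses: with raw sums the binary
    # term (hundreds of triples) swamps beta and freezes w_E near zero, which
    # would make the effectiveness supervision inert. The exported loss
    # operations stay sum-scaled as defined.
    n_i <- nrow(triples)
    n_e <- if (has_ecr) nrow(ecr) else 1L
    m_i <- gi$loss / n_i; m_e <- ge$loss / n_e
    theta_sq <- sum(vapply(weights, function(w) sum(w^2), numeric(1)))
    if (!is.null(config$weight_override)) {
      w_i <- config$weight_override[[1L]]; w_e <- config$weight_override[[2L]]
      total <- w_i * m_i + w_e * m_e + config$lambda * theta_sq
    } else {
      bl <- bayesian_multiloss(m_i, m_e, config$beta, config$lambda, theta_sq)
      w_i <- bl$w_i; w_e <- bl$w_e; total <- bl$total
    }
    if (!is.finite(total)) {
      stop(sprintf("fine-tuning diverged (non-finite loss) at epoch %d", epoch),
           call. = FALSE)
    }
    d_e <- (w_i / n_i) * gi$dE + (w_e / n_e) * ge$dE
    bwd <- residual_bwd(adjacency, weights, fwd, d_e)
    grads <- Map(function(g, w) g + 2 * config$lambda * w, bwd$dW, weights)
    step <- adam_step(weights, grads, opt, lr = config$learning_rate)
    weights <- step$weights; opt <- step$state
    log_rows[[epoch]] <- data.frame(epoch = epoch, loss_binary = gi$loss,
                                    loss_ecr = ge$loss, w_i = w_i, w_e = w_e,
                                    total = total)
    if (config$verbose && epoch %% 20L == 0L) {
      message(sprintf("epoch %4d  total %.4f (binary %.4f, ecr %.4f)",
                      epoch, total, gi$loss, ge$loss))
    }
  }
  fwd <- residual_fwd(adjacency, z0, weights)
  e_mat <- fwd$H
  structure(list(
    weights = weights,
    embeddings = e_mat,
    scores = e_mat[dis_ids, , drop = FALSE] %*% t(e_mat[drug_ids, , drop = FALSE]),
    log = do.call(rbind, log_rows),
    config = config,
    adjacency = adjacency
  ), class = "finetune_model")
}

# Loss and gradient w.r.t. the full embedding matrix for one pairwise set.
pairwise_loss_grad <- function(u, i, j, e_mat, scores) {
  iu <- match(u, rownames(scores)); ii <- match(i, colnames(scores))
  ij <- match(j, colnames(scores))
  nu <- match(u, rownames(e_mat)); ni <- match(i, rownames(e_mat))
  nj <- match(j, rownames(e_mat))
  diff <- scores[cbind(iu, ii)] - scores[cbind(iu, ij)]
  loss <- sum(softplus(-diff))
  g <- -sigmoid(-diff)               # d loss / d diff
  d_e <- matrix(0, nrow(e_mat), ncol(e_mat), dimnames = dimnames(e_mat))
  add_rows <- function(d_e, idx, contrib) {
    agg <- rowsum(contrib, idx)
    rows <- as.integer(rownames(agg))
    d_e[rows, ] <- d_e[rows, , drop = FALSE] + agg
    d_e
  }
  d_e <- add_rows(d_e, nu, g * (e_mat[ni, , drop = FALSE] - e_mat[nj, , drop = FALSE]))
  d_e <- add_rows(d_e, ni, g * e_mat[nu, , drop = FALSE])
  d_e <- add_rows(d_e, nj, -g * e_mat[nu, , drop = FALSE])
  list(loss = loss, dE = d_e)
}

#' Disease-by-drug score matrix of a fine-tuned model
#' @param model a `finetune_model`.
#' @return numeric matrix (diseases x drugs) of inner-product scores.
#' @export
score_matrix <- function(model) model$scores
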