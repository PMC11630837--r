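# Model-augmented graph contrastive pretraining.
#
# Two stochastically augmented views of the DDHG (edge dropping + whole-
# dimension feature masking) are encoded by a shared-weight GCN whose
# propagation depth is jittered between views (the "model augmentation").
# Embeddings of the same node across views are pulled together against all
# other nodes of both views with a normalized-temperature cosine loss.
# Gradients are computed analytically (no autodiff dependency); the test
# suite checks them against finite differences.

#' Augment a heterogeneous graph into a contrastive view
#'
#' Each edge (over all three relation types) is removed independently with
#' probability `p_edge`; each feature dimension is masked (zeroed across all
#' nodes) independently with probability `p_feat`. Deterministic given
#' `seed`.
#'
#' @param graph a `heterograph`.
#' @param features numeric matrix covering all graph nodes (ids as rownames).
#' @param p_edge,p_feat probabilities in \[0, 1).
#' @param seed integer.
#' @return object of class `graph_view` with fields `adjacency`
#'   (a `normalized_adjacency` built from the kept edges), `features`,
#'   `kept_edge_fraction`, `masked_dims`.
#' @export
augment_graph <- function(graph, features, p_edge, p_feat, seed) {
  for (p in list(p_edge = p_edge, p_feat = p_feat)) {
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1) {
      input_error("augmentation probabilities must lie in [0, 1)")
    }
  }
  nodes <- node_order(graph)
  features <- align_features(features, nodes)
  n_dd <- nrow(graph$edges_dd); n_ss <- nrow(graph$edges_ss); n_ds <- nrow(graph$edges_ds)
  n_edges <- n_dd + n_ss + n_ds
  draws <- with_seed(seed, list(
    keep = stats::runif(n_edges) >= p_edge,
    mask = stats::runif(ncol(features)) < p_feat
  ))
  keep <- draws$keep
  view_graph <- heterograph(
    graph$drugs, graph$diseases,
    edges_dd = graph$edges_dd[keep[seq_len(n_dd)], , drop = FALSE],
    edges_ss = graph$edges_ss[keep[n_dd + seq_len(n_ss)], , drop = FALSE],
    edges_ds = graph$edges_ds[keep[n_dd + n_ss + seq_len(n_ds)], , drop = FALSE]
  )
  masked_dims <- which(draws$mask)
  f <- features
  if (length(masked_dims) > 0L) f[, masked_dims] <- 0
  structure(
    list(adjacency = build_normalized_adjacency(view_graph, nodes = nodes),
         features = f,
         kept_edge_fraction = if (n_edges == 0L) 1 else sum(keep) / n_edges,
         masked_dims = masked_dims),
    class = "graph_view")
}

align_features <- function(features, nodes) {
  validate_feature_matrix(features)
  missing <- setdiff(nodes, rownames(features))
  if (length(missing) > 0L) {
    input_error("feature matrix missing node \"%s\"", missing[[1L]])
  }
  features[nodes, , drop = FALSE]
}

#' Initialize GCN encoder weights
#'
#' Glorot-uniform layer weights: layer 1 maps `d_in -> d`, the remaining
#' `n_layers - 1` map `d -> d`.
#'
#' @param d_in input feature dimension.
#' @param d embedding dimension.
#' @param n_layers maximum propagation depth the weights must support.
#' @param seed integer.
#' @return list of weight matrices.
#' @export
init_encoder_weights <- function(d_in, d, n_layers, seed) {
  with_seed(seed, lapply(seq_len(n_layers), function(l) {
    nin <- if (l == 1L) d_in else d
    lim <- sqrt(6 / (nin + d))
    matrix(stats::runif(nin * d, -lim, lim), nin, d)
  }))
}

#' Encode a graph view with a GCN
#'
#' `H^(0)` is the view's feature matrix and
#' `H^(l) = act(A_hat H^(l-1) W^(l))` for `l = 1..depth`.
#'
#' @param view a `graph_view`, or a list with fields `adjacency`
#'   (`normalized_adjacency`) and `features`.
#' @param weights list of weight matrices (at least `depth` of them).
#' @param depth number of propagation layers to apply.
#' @return numeric embedding matrix with node ids as rownames.
#' @export
gcn_encode <- function(view, weights, depth) {
  gcn_forward(view, weights, depth)$H
}

# Forward pass keeping intermediates for backprop.
# Returns H (final), hs (list H^(0..depth)), pre (list of pre-activations).
gcn_forward <- function(view, weights, depth) {
  if (depth < 1L || depth > length(weights)) {
    input_error("depth must be between 1 and length(weights)")
  }
  a_hat <- view$adjacency$matrix
  h <- align_features(view$features, view$adjacency$node_order)
  if (ncol(h) != nrow(weights[[1L]])) {
    input_error("feature dimension %d does not match weight input dimension %d",
                ncol(h), nrow(weights[[1L]]))
  }
  hs <- vector("list", depth + 1L); hs[[1L]] <- h
  pre <- vector("list", depth)
  for (l in seq_len(depth)) {
    pre[[l]] <- as.matrix(a_hat %*% hs[[l]]) %*% weights[[l]]
    hs[[l + 1L]] <- relu(pre[[l]])
  }
  out <- hs[[depth + 1L]]
  rownames(out) <- view$adjacency$node_order
  list(H = out, hs = hs, pre = pre)
}

# Backprop dL/dH_final through the GCN; returns list(dW = per-layer grads).
gcn_backward <- function(view, weights, depth, fwd, d_out) {
  a_hat <- view$adjacency$matrix
  d_w <- lapply(weights, function(w) array(0, dim(w)))
  dh <- d_out
  for (l in rev(seq_len(depth))) {
    dm <- dh * (fwd$pre[[l]] > 0)
    ah <- as.matrix(a_hat %*% fwd$hs[[l]])
    d_w[[l]] <- crossprod(ah, dm)
    dh <- as.matrix(a_hat %*% (dm %*% t(weights[[l]])))
  }
  d_w
}

#' Symmetric normalized-temperature contrastive loss
#'
#' For node i in one view the positive is node i in the other view; the
#' negatives are all other nodes of both views. Similarity is cosine scaled
#' by `1 / tau`; the loss is averaged over nodes and symmetrized across the
#' two views. A single-node graph has no negatives and zero loss. Zero-norm
#' rows are guarded by adding 1e-12 to the norms.
#'
#' @param z1,z2 embedding matrices with identical node order.
#' @param tau positive temperature.
#' @return non-negative scalar loss.
#' @export
contrastive_loss <- function(z1, z2, tau) {
  infonce(z1, z2, tau, grad = FALSE)$loss
}

# Loss and (optionally) analytic gradients w.r.t. z1, z2.
infonce <- function(z1, z2, tau, grad = TRUE) {
  if (!isTRUE(all.equal(dim(z1), dim(z2)))) input_error("view embeddings differ in shape")
  if (!is.null(rownames(z1)) && !is.null(rownames(z2)) &&
      !identical(rownames(z1), rownames(z2))) {
    input_error("view embeddings differ in node order")
  }
  if (!is.numeric(tau) || tau <= 0) input_error("tau must be positive")
  n <- nrow(z1)
  eps <- 1e-12
  n1 <- sqrt(rowSums(z1^2)) + eps
  n2 <- sqrt(rowSums(z2^2)) + eps
  u <- z1 / n1
  v <- z2 / n2
  e_c <- exp(tcrossprod(u, v) / tau)           # cross-view similarities
  e_a1 <- exp(tcrossprod(u) / tau); diag(e_a1) <- 0  # intra-view negatives
  e_a2 <- exp(tcrossprod(v) / tau); diag(e_a2) <- 0
  d1 <- rowSums(e_c) + rowSums(e_a1)           # anchor in view 1
  d2 <- colSums(e_c) + rowSums(e_a2)           # anchor in view 2
  pos <- diag(tcrossprod(u, v)) / tau
  loss <- mean((-pos + log(d1)) + (-pos + log(d2))) / 2
  if (!grad) return(list(loss = loss))
  w <- 1 / (2 * n)
  g_c <- w * (e_c / d1 + sweep(e_c, 2L, d2, "/"))
  diag(g_c) <- diag(g_c) - 2 * w
  g_a1 <- w * (e_a1 / d1)
  g_a2 <- w * (e_a2 / d2)
  du <- (g_c %*% v + (g_a1 + t(g_a1)) %*% u) / tau
  dv <- (crossprod(g_c, u) + (g_a2 + t(g_a2)) %*% v) / tau
  # back through row normalization z -> z / (||z|| + eps)
  dz1 <- (du - u * rowSums(du * u)) / n1
  dz2 <- (dv - v * rowSums(dv * v)) / n2
  list(loss = loss, dz1 = dz1, dz2 = dz2)
}

#' Default configuration for contrastive pretraining
#'
#' @param embed_dim embedding dimension d.
#' @param p_edge,p_feat augmentation probabilities.
#' @param tau contrastive temperature.
#' @param depth base propagation depth L.
#' @param depth_jitter per-view depth jitter j; view depths are drawn from
#'   `{L-j, ..., L+j}` (floored at 1).
#' @param epochs full-batch gradient steps.
#' @param learning_rate Adam learning rate.
#' @param projection_head use a two-layer projection head before the loss
#'   (discarded in the returned embeddings).
#' @param seed integer master seed.
#' @param verbose print the loss every 20 epochs.
#' @return named list of class `pretrain_config`.
#' @export
pretrain_config <- function(embed_dim = 32L, p_edge = 0.2, p_feat = 0.2,
                            tau = 0.5, depth = 2L, depth_jitter = 1L,
                            epochs = 200L, learning_rate = 1e-3,
                            projection_head = TRUE, seed = 1L,
                            verbose = FALSE) {
  structure(list(embed_dim = as.integer(embed_dim), p_edge = p_edge,
                 p_feat = p_feat, tau = tau, depth = as.integer(depth),
                 depth_jitter = as.integer(depth_jitter),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 projection_head = isTRUE(projection_head),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pretrain_config")
}

#' Contrastively pretrain node embeddings on a heterogeneous graph
#'
#' Per epoch, two augmented views are generated and encoded by the shared
#' GCN at independently jittered depths; Adam minimizes [contrastive_loss()]
#' between the (optionally projected) view embeddings. The returned matrix
#' encodes the un-augmented graph at the base depth with the trained weights
#' (projection head discarded). With `epochs = 0` this is the encoding under
#' the initial weights.
#'
#' @param graph a `heterograph`.
#' @param features numeric feature matrix covering all graph nodes.
#' @param config a [pretrain_config()].
#' @return embedding matrix (nodes x embed_dim) with attributes
#'   `loss_curve` (numeric, one value per epoch) and `weights`.
#' @export
pretrain_embeddings <- function(graph, features, config = pretrain_config()) {
  nodes <- node_order(graph)
  features <- align_features(features, nodes)
  d_in <- ncol(features); d <- config$embed_dim
  l_max <- config$depth + config$depth_jitter
  weights <- init_encoder_weights(d_in, d, l_max, derive_seed(config$seed, 0L))
  head_w <- with_seed(derive_seed(config$seed, 1L), lapply(1:2, function(i) {
    lim <- sqrt(6 / (2 * d))
    matrix(stats::runif(d * d, -lim, lim), d, d)
  }))
  params <- c(weights, if (config$projection_head) head_w)
  opt <- adam_init(params)
  full_view <- list(adjacency = build_normalized_adjacency(graph, nodes = nodes),
                    features = features)
  depth_set <- seq.int(max(1L, config$depth - config$depth_jitter),
                       config$depth + config$depth_jitter)
  curve <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    s <- function(k) derive_seed(config$seed, 10L * epoch + k)
    depths <- with_seed(s(1L), sample(depth_set, 2L, replace = TRUE))
    v1 <- augment_graph(graph, features, config$p_edge, config$p_feat, s(2L))
    v2 <- augment_graph(graph, features, config$p_edge, config$p_feat, s(3L))
    f1 <- gcn_forward(v1, weights, depths[[1L]])
    f2 <- gcn_forward(v2, weights, depths[[2L]])
    if (config$projection_head) {
      p1 <- head_forward(f1$H, head_w); p2 <- head_forward(f2$H, head_w)
      ic <- infonce(p1$out, p2$out, config$tau)
      b1 <- head_backward(f1$H, head_w, p1, ic$dz1)
      b2 <- head_backward(f2$H, head_w, p2, ic$dz2)
      dz1 <- b1$dz; dz2 <- b2$dz
      d_head <- Map(`+`, b1$dW, b2$dW)
    } else {
      ic <- infonce(f1$H, f2$H, config$tau)
      dz1 <- ic$dz1; dz2 <- ic$dz2
      d_head <- NULL
    }
    if (!is.finite(ic$loss)) {
      stop(sprintf("pretraining diverged (non-finite loss) at epoch %d", epoch),
           call. = FALSE)
    }
    curve[[epoch]] <- ic$loss
    dw1 <- gcn_backward(v1, weights, depths[[1L]], f1, dz1)
    dw2 <- gcn_backward(v2, weights, depths[[2L]], f2, dz2)
    grads <- c(Map(`+`, dw1, dw2), d_head)
    step <- adam_step(params, grads, opt, lr = config$learning_rate)
    params <- step$weights; opt <- step$state
    weights <- params[seq_len(l_max)]
    if (config$projection_head) head_w <- params[l_max + 1:2]
    if (config$verbose && epoch %% 20L == 0L) {
      message(sprintf("epoch %4d  contrastive loss %.5f", epoch, ic$loss))
    }
  }
  out <- gcn_encode(full_view, weights, config$depth)
  attr(out, "loss_curve") <- curve
  attr(out, "weights") <- weights
  out
}

head_forward <- function(h, head_w) {
  pre <- h %*% head_w[[1L]]
  hid <- relu(pre)
  list(pre = pre, hid = hid, out = hid %*% head_w[[2L]])
}

head_backward <- function(h, head_w, fwd, d_out) {
  d_w2 <- crossprod(fwd$hid, d_out)
  d_hid <- (d_out %*% t(head_w[[2L]])) * (fwd$pre > 0)
  list(dW = list(crossprod(h, d_hid), d_w2), dz = d_hid %*% t(head_w[[1L]]))
}
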