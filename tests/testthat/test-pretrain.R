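# Brute-force scalar oracle for the symmetric contrastive loss.
contrastive_oracle <- function(z1, z2, tau) {
  n <- nrow(z1)
  cosine <- function(a, b) sum(a * b) / ((sqrt(sum(a^2)) + 1e-12) * (sqrt(sum(b^2)) + 1e-12))
  per_anchor <- function(za, zb) {
    tot <- 0
    for (i in seq_len(n)) {
      denom <- 0
      for (j in seq_len(n)) denom <- denom + exp(cosine(za[i, ], zb[j, ]) / tau)
      for (j in seq_len(n)) if (j != i) denom <- denom + exp(cosine(za[i, ], za[j, ]) / tau)
      tot <- tot - cosine(za[i, ], zb[i, ]) / tau + log(denom)
    }
    tot / n
  }
  (per_anchor(z1, z2) + per_anchor(z2, z1)) / 2
}

test_that("augmentation no-op, full mask and binomial edge retention", {
  study <- small_study()
  feats <- assemble_features(study$graph, study$signatures, study$treat)

  v0 <- augment_graph(study$graph, feats, 0, 0, seed = 1L)
  expect_equal(v0$kept_edge_fraction, 1)
  expect_length(v0$masked_dims, 0L)
  full <- build_normalized_adjacency(study$graph)
  expect_same_matrix(v0$adjacency$matrix, full$matrix)
  expect_equal(v0$features, feats[full$node_order, ], tolerance = 1e-15)

  # masking every dimension explicitly zeroes the feature matrix
  f_masked <- feats; f_masked[, seq_len(ncol(feats))] <- 0
  v1 <- augment_graph(study$graph, f_masked, 0, 0, seed = 1L)
  expect_true(all(v1$features == 0))

  expect_error(augment_graph(study$graph, feats, 1, 0, 1L), "probabilities")

  # ~1000-edge fixture: mean kept edges across 200 seeds within 3 binomial
  # standard errors of the expectation
  drugs <- sprintf("d%02d", 1:46)
  pairs <- t(utils::combn(drugs, 2))
  g <- heterograph(drugs, character(0), edges_dd = pairs)  # 1035 edges
  n_e <- nrow(pairs)
  f <- matrix(1, length(drugs), 2, dimnames = list(drugs, NULL))
  kept <- vapply(1:200, function(s) {
    augment_graph(g, f, 0.2, 0, seed = s)$kept_edge_fraction * n_e
  }, numeric(1))
  se <- sqrt(n_e * 0.2 * 0.8) / sqrt(200)
  expect_lt(abs(mean(kept) - 0.8 * n_e), 3 * se)
})

test_that("gcn_encode matches dense propagation oracles", {
  # isolated node with identity weights passes features through
  g1 <- heterograph(drugs = "d1", diseases = character(0))
  v1 <- list(adjacency = build_normalized_adjacency(g1),
             features = matrix(c(2, 3), 1, 2, dimnames = list("d1", NULL)))
  out <- gcn_encode(v1, list(diag(2)), depth = 1L)
  expect_equal(unname(out), matrix(c(2, 3), 1, 2))

  # depth 1-3 on a path graph against a dense matrix-product oracle
  g <- heterograph(drugs = c("d1", "d2", "d3"), diseases = character(0),
                   edges_dd = rbind(c("d1", "d2"), c("d2", "d3")))
  adj <- build_normalized_adjacency(g)
  f <- drugrank:::with_seed(2L, matrix(rnorm(12), 3, 4, dimnames = list(adj$node_order, NULL)))
  w <- init_encoder_weights(4L, 5L, 3L, seed = 9L)
  a_dense <- as.matrix(adj$matrix)
  h_oracle <- f
  for (depth in 1:3) {
    h_oracle <- pmax(a_dense %*% h_oracle %*% w[[depth]], 0)
    got <- gcn_encode(list(adjacency = adj, features = f), w, depth)
    expect_equal(unname(got), unname(h_oracle), tolerance = 1e-6)
  }

  # zero features stay zero under any weights
  fz <- f * 0
  expect_true(all(gcn_encode(list(adjacency = adj, features = fz), w, 2L) == 0))
})

test_that("encoding is equivariant to simultaneous node permutation", {
  study <- small_study()
  feats <- assemble_features(study$graph, study$signatures, study$treat)
  adj <- build_normalized_adjacency(study$graph)
  w <- init_encoder_weights(ncol(feats), 6L, 2L, seed = 4L)
  h <- gcn_encode(list(adjacency = adj, features = feats), w, 2L)
  perm <- drugrank:::with_seed(8L, sample(adj$node_order))
  adj_p <- build_normalized_adjacency(study$graph, nodes = perm)
  h_p <- gcn_encode(list(adjacency = adj_p, features = feats), w, 2L)
  expect_equal(h_p[rownames(h), ], h, tolerance = 1e-10)
})

test_that("contrastive loss matches the brute-force double summation", {
  # single node: no negatives, zero loss
  z <- matrix(c(1, 2), 1, 2)
  expect_equal(contrastive_loss(z, z, 0.5), 0, tolerance = 1e-12)

  # two orthogonal one-hot nodes, identical views, tau = 1
  z2 <- diag(2)
  expect_equal(contrastive_loss(z2, z2, 1), contrastive_oracle(z2, z2, 1),
               tolerance = 1e-8)

  # random instances up to 10 nodes
  for (n in c(3L, 7L, 10L)) {
    z1 <- drugrank:::with_seed(n, matrix(rnorm(n * 4), n, 4))
    z2 <- drugrank:::with_seed(n + 50L, matrix(rnorm(n * 4), n, 4))
    for (tau in c(0.2, 0.5, 1)) {
      expect_equal(contrastive_loss(z1, z2, tau), contrastive_oracle(z1, z2, tau),
                   tolerance = 1e-8)
    }
    expect_gte(contrastive_loss(z1, z2, 0.5), 0)
  }

  # aligning views lowers the loss versus shuffled rows
  sep <- diag(6) * 3
  shuffled <- sep[c(2:6, 1), ]
  expect_lt(contrastive_loss(sep, sep, 0.5), contrastive_loss(sep, shuffled, 0.5))

  # zero-norm rows are guarded, loss stays finite
  zz <- rbind(c(0, 0), c(1, 1))
  expect_true(is.finite(contrastive_loss(zz, zz, 0.5)))
})

test_that("analytic contrastive/encoder gradients agree with finite differences", {
  n <- 5L; d <- 3L
  z1 <- drugrank:::with_seed(1L, matrix(rnorm(n * d), n, d))
  z2 <- drugrank:::with_seed(2L, matrix(rnorm(n * d), n, d))
  ic <- drugrank:::infonce(z1, z2, tau = 0.5)
  eps <- 1e-6
  for (idx in c(1L, 7L, 15L)) {
    zp <- z1; zp[idx] <- zp[idx] + eps
    zm <- z1; zm[idx] <- zm[idx] - eps
    num <- (contrastive_loss(zp, z2, 0.5) - contrastive_loss(zm, z2, 0.5)) / (2 * eps)
    expect_equal(ic$dz1[idx], num, tolerance = 1e-5)
    zp <- z2; zp[idx] <- zp[idx] + eps
    zm <- z2; zm[idx] <- zm[idx] - eps
    num2 <- (contrastive_loss(z1, zp, 0.5) - contrastive_loss(z1, zm, 0.5)) / (2 * eps)
    expect_equal(ic$dz2[idx], num2, tolerance = 1e-5)
  }

  # end-to-end d(loss)/dW through the GCN encoder
  g <- heterograph(drugs = c("d1", "d2", "d3"), diseases = "s1",
                   edges_dd = rbind(c("d1", "d2")),
                   edges_ds = rbind(c("s1", "d3")))
  adj <- build_normalized_adjacency(g)
  f <- drugrank:::with_seed(3L, matrix(rnorm(4 * 3), 4, 3, dimnames = list(adj$node_order, NULL)))
  w <- init_encoder_weights(3L, 3L, 2L, seed = 5L)
  view <- list(adjacency = adj, features = f)
  loss_of <- function(w) {
    h1 <- gcn_encode(view, w, 2L)
    contrastive_loss(h1, f, 0.5)  # second "view" held fixed
  }
  fwd <- drugrank:::gcn_forward(view, w, 2L)
  ic2 <- drugrank:::infonce(fwd$H, f, 0.5)
  dw <- drugrank:::gcn_backward(view, w, 2L, fwd, ic2$dz1)
  for (l in 1:2) {
    for (idx in c(1L, 5L, 9L)) {
      wp <- w; wp[[l]][idx] <- wp[[l]][idx] + eps
      wm <- w; wm[[l]][idx] <- wm[[l]][idx] - eps
      num <- (loss_of(wp) - loss_of(wm)) / (2 * eps)
      expect_equal(dw[[l]][idx], num, tolerance = 1e-4)
    }
  }
})

test_that("pretraining is deterministic, a no-op at 0 epochs, and reduces the loss", {
  study <- small_study()
  feats <- assemble_features(study$graph, study$signatures, study$treat)
  cfg0 <- pretrain_config(embed_dim = 8L, epochs = 0L, seed = 3L)
  z0 <- pretrain_embeddings(study$graph, feats, cfg0)
  w_init <- init_encoder_weights(ncol(feats), 8L,
                                 cfg0$depth + cfg0$depth_jitter,
                                 drugrank:::derive_seed(3L, 0L))
  manual <- gcn_encode(list(adjacency = build_normalized_adjacency(study$graph),
                            features = feats), w_init, cfg0$depth)
  expect_equal(unname(z0[rownames(manual), ]), unname(manual), tolerance = 1e-12)

  cfg <- pretrain_config(embed_dim = 8L, epochs = 30L, seed = 3L)
  za <- pretrain_embeddings(study$graph, feats, cfg)
  zb <- pretrain_embeddings(study$graph, feats, cfg)
  expect_identical(za, zb)
  curve <- attr(za, "loss_curve")
  expect_lt(curve[length(curve)], curve[1L])
})
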