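# Scalar reference for both pairwise ranking losses.
pairwise_oracle <- function(u, i, j, scores) {
  tot <- 0
  for (r in seq_along(u)) {
    diff <- scores[u[[r]], i[[r]]] - scores[u[[r]], j[[r]]]
    tot <- tot - log(1 / (1 + exp(-diff)))
  }
  tot
}

test_that("residual layers reduce to the identity at zero weight", {
  ids <- c("s1", "d1", "d2", "d3")
  bip <- bipartite_graph("s1", c("d1", "d2", "d3"),
                         rbind(c("s1", "d1"), c("s1", "d2")))
  adj <- build_normalized_adjacency(bip, nodes = ids)
  z0 <- rand_embedding(ids, 4L, seed = 2L)
  w0 <- list(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_equal(unname(residual_forward(adj, z0, w0)), unname(z0), tolerance = 0)

  # L = 1..3 against the dense oracle act(A Z W) + Z
  a <- as.matrix(adj$matrix)
  w <- drugrank:::with_seed(7L, lapply(1:3, function(l) matrix(rnorm(16, sd = 0.3), 4, 4)))
  h_oracle <- z0[adj$node_order, ]
  for (l in 1:3) {
    h_oracle <- pmax(a %*% h_oracle %*% w[[l]], 0) + h_oracle
    got <- residual_forward(adj, z0, w[seq_len(l)])
    expect_equal(unname(got), unname(h_oracle), tolerance = 1e-6)
  }

  # zero input stays zero through arbitrary weights
  expect_true(all(residual_forward(adj, z0 * 0, w) == 0))
})

test_that("binary triple sampling is complete, uniform and validated", {
  bip <- bipartite_graph("s1", c("a", "b"), rbind(c("s1", "a")))
  tr <- sample_binary_triples(bip, 1L, seed = 1L)
  expect_equal(tr, data.frame(disease = "s1", pos = "a", neg = "b"))

  study <- small_study()
  sp <- split_warm(study$treat, 0.2, 1L)
  for (k in c(1L, 3L)) {
    t2 <- sample_binary_triples(sp$train, k, seed = 2L)
    expect_equal(nrow(t2), nrow(sp$train$edges) * k)
    expect_true(all(t2$pos != t2$neg))
    key <- paste(t2$disease, t2$neg)
    pos_key <- paste(sp$train$edges[, 1L], sp$train$edges[, 2L])
    expect_length(intersect(key, pos_key), 0L)
  }
  expect_identical(sample_binary_triples(sp$train, 1L, 5L),
                   sample_binary_triples(sp$train, 1L, 5L))

  # uniformity over 3 eligible negatives, 10000 draws
  bip3 <- bipartite_graph("s1", c("p", "n1", "n2", "n3"), rbind(c("s1", "p")))
  draws <- unlist(lapply(1:10000, function(s) sample_binary_triples(bip3, 1L, s)$neg))
  freq <- table(draws) / length(draws)
  se <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))

  full <- bipartite_graph("s1", c("a", "b"), rbind(c("s1", "a"), c("s1", "b")))
  expect_error(sample_binary_triples(full, 1L, 1L), "s1")
})

test_that("ranking losses match scalar oracles and their analytic limits", {
  s <- matrix(0, 1, 2, dimnames = list("u", c("i", "j")))
  one <- data.frame(disease = "u", pos = "i", neg = "j")
  expect_equal(treat_ranking_loss(one, s), -log(0.5), tolerance = 1e-12)
  s[1, 1] <- 50
  expect_lt(treat_ranking_loss(one, s), 1e-9)
  s[1, 1] <- -50
  expect_equal(treat_ranking_loss(one, s), 50, tolerance = 1e-9)

  # 20 random triples against the scalar loop, both losses
  dis <- sprintf("s%d", 1:4); drugs <- sprintf("d%d", 1:6)
  sc <- drugrank:::with_seed(3L, matrix(rnorm(24), 4, 6, dimnames = list(dis, drugs)))
  tr <- drugrank:::with_seed(4L, data.frame(
    disease = sample(dis, 20, TRUE),
    pos = sample(drugs, 20, TRUE), neg = sample(drugs, 20, TRUE)))
  tr <- tr[tr$pos != tr$neg, ]
  expect_equal(treat_ranking_loss(tr, sc),
               pairwise_oracle(tr$disease, tr$pos, tr$neg, sc), tolerance = 1e-10)
  ecr <- data.frame(disease_id = tr$disease, better_drug_id = tr$pos,
                    worse_drug_id = tr$neg)
  expect_equal(as.numeric(ecr_ranking_loss(ecr, sc)),
               pairwise_oracle(tr$disease, tr$pos, tr$neg, sc), tolerance = 1e-10)

  empty <- ecr[0, ]
  le <- ecr_ranking_loss(empty, sc)
  expect_equal(as.numeric(le), 0)
  expect_false(attr(le, "usable"))

  # strictly positive and strictly decreasing in the score gap
  gaps <- seq(-5, 5, length.out = 41)
  vals <- vapply(gaps, function(g) {
    treat_ranking_loss(one, matrix(c(g, 0), 1, 2, dimnames = list("u", c("i", "j"))))
  }, numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) < 0))
})

test_that("Bayesian averaging follows the stated limits and monotonicity", {
  expect_equal(bayesian_multiloss(3, 7, beta = 0)$total, 3, tolerance = 1e-12)
  bl <- bayesian_multiloss(1, 1, beta = 2)
  expect_equal(c(bl$w_i, bl$w_e), c(0.5, 0.5))
  expect_equal(bl$total, 1.0)
  # beta sweep: w_i non-increasing, w_e non-decreasing, weights sum to 1
  betas <- c(0, 10^seq(-2, 3, length.out = 49))
  ws <- vapply(betas, function(b) {
    r <- bayesian_multiloss(2, 0.5, beta = b)
    c(r$w_i, r$w_e)
  }, numeric(2))
  expect_true(all(diff(ws[1, ]) <= 1e-15))
  expect_true(all(diff(ws[2, ]) >= -1e-15))
  expect_equal(colSums(ws), rep(1, length(betas)), tolerance = 1e-12)
  # regularization enters additively
  expect_equal(bayesian_multiloss(1, 1, 1, lambda = 0.5, theta_sq_norm = 4)$total,
               bayesian_multiloss(1, 1, 1)$total + 2)
  expect_error(bayesian_multiloss(1, 1, beta = -1), "non-negative")
})

test_that("fine-tuning gradients match finite differences", {
  ids <- c("s1", "s2", "d1", "d2", "d3")
  train <- bipartite_graph(c("s1", "s2"), c("d1", "d2", "d3"),
                           rbind(c("s1", "d1"), c("s2", "d2")))
  adj <- build_normalized_adjacency(train, nodes = ids)
  z0 <- rand_embedding(ids, 3L, seed = 6L)
  w <- drugrank:::with_seed(9L, lapply(1:2, function(l) matrix(rnorm(9, sd = 0.2), 3, 3)))
  trip <- data.frame(disease = c("s1", "s2"), pos = c("d1", "d2"), neg = c("d3", "d1"))
  loss_of <- function(w) {
    e <- residual_forward(adj, z0, w)
    sc <- e[train$diseases, ] %*% t(e[train$drugs, ])
    treat_ranking_loss(trip, sc)
  }
  fwd <- drugrank:::residual_fwd(adj, z0, w)
  e <- fwd$H
  sc <- e[train$diseases, ] %*% t(e[train$drugs, ])
  gr <- drugrank:::pairwise_loss_grad(trip$disease, trip$pos, trip$neg, e, sc)
  bwd <- drugrank:::residual_bwd(adj, w, fwd, gr$dE)
  eps <- 1e-6
  for (l in 1:2) {
    for (idx in c(1L, 4L, 8L)) {
      wp <- w; wp[[l]][idx] <- wp[[l]][idx] + eps
      wm <- w; wm[[l]][idx] <- wm[[l]][idx] - eps
      num <- (loss_of(wp) - loss_of(wm)) / (2 * eps)
      expect_equal(bwd$dW[[l]][idx], num, tolerance = 1e-4)
    }
  }
})

test_that("fine-tuning trains deterministically and reduces the objective", {
  study <- small_study()
  sp <- split_warm(study$treat, 0.2, 2L)
  z0 <- rand_embedding(node_order(study$graph), 8L, seed = 3L)

  # epochs = 0 with zero-initialized layers: scores are plain z0 inner products
  m0 <- finetune_model(sp$train, study$ecr, z0,
                       finetune_config(epochs = 0L, init_sd = 0))
  expect_equal(unname(score_matrix(m0)),
               unname(z0[sp$train$diseases, ] %*% t(z0[sp$train$drugs, ])),
               tolerance = 1e-12)

  cfg <- finetune_config(epochs = 100L, seed = 4L)
  m1 <- finetune_model(sp$train, study$ecr, z0, cfg)
  expect_lt(m1$log$total[nrow(m1$log)], m1$log$total[1L])
  expect_true(all(abs(m1$log$w_i + m1$log$w_e - 1) < 1e-12))

  m2 <- finetune_model(sp$train, study$ecr, z0, cfg)
  expect_identical(m1$weights, m2$weights)

  # ablation overrides pin the weights
  mi <- finetune_model(sp$train, study$ecr, z0,
                       finetune_config(epochs = 2L, weight_override = c(1, 0)))
  expect_true(all(mi$log$w_e == 0))
  me <- finetune_model(sp$train, study$ecr, z0,
                       finetune_config(epochs = 2L, weight_override = c(0, 1)))
  expect_true(all(me$log$w_i == 0))
})
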