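# Shared fixtures, built in code at test time.

# The spec-style minimal graph: two drugs, one disease.
tiny_graph <- function() {
  heterograph(drugs = c("d1", "d2"), diseases = "s1",
              edges_dd = rbind(c("d1", "d2")),
              edges_ds = rbind(c("s1", "d1")))
}

# Small synthetic study for module tests (40 nodes), memoized per session.
local({
  cache <- new.env(parent = emptyenv())
  small_study <<- function(seed = 11L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_study(synthetic_config(
        n_drugs = 30L, n_diseases = 10L, latent_dim = 4L, n_feat = 16L,
        treat_density = 0.1, recorded_fraction = 0.8, seed = seed))
    }
    cache[[key]]
  }
})

# Random embedding matrix with node ids.
rand_embedding <- function(ids, d, seed = 1L) {
  m <- drugrank:::with_seed(seed, matrix(stats::rnorm(length(ids) * d), length(ids), d))
  rownames(m) <- ids
  m
}

# Write node/edge TSVs for a handful of rows; returns the two paths.
write_graph_tables <- function(node_rows, edge_rows,
                               dir = withr::local_tempdir(.local_envir = parent.frame())) {
  np <- file.path(dir, "nodes.tsv"); ep <- file.path(dir, "edges.tsv")
  writeLines(c("node_id\tnode_type", node_rows), np)
  writeLines(c("source_id\ttarget_id\trelation", edge_rows), ep)
  c(nodes = np, edges = ep)
}

expect_same_matrix <- function(a, b, tol = 1e-12) {
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)), tolerance = tol)
}
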