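# Readers, writers, adjacency construction and train/test splits for the
# drug-disease heterogeneous graph (DDHG) and the treat bipartite graph.
#
# File dialect (all external tables): tab-separated, UTF-8, header row
# required, lines starting with '#' are comments.

#' Construct a drug-disease heterogeneous graph
#'
#' A DDHG holds two typed node sets (drugs, diseases) and three undirected
#' relation types: drug-drug, disease-disease and disease-drug. Edges are
#' deduplicated; self-loops and edges with unknown endpoints are rejected.
#'
#' @param drugs character vector of drug node ids.
#' @param diseases character vector of disease node ids (disjoint from drugs).
#' @param edges_dd two-column character matrix of drug-drug pairs (may have 0 rows).
#' @param edges_ss two-column character matrix of disease-disease pairs.
#' @param edges_ds two-column character matrix of (disease, drug) pairs.
#' @return An object of class `heterograph` with fields `drugs`, `diseases`,
#'   `edges_dd`, `edges_ss`, `edges_ds`.
#' @export
heterograph <- function(drugs, diseases,
                        edges_dd = empty_edges(), edges_ss = empty_edges(),
                        edges_ds = empty_edges()) {
  drugs <- as.character(drugs)
  diseases <- as.character(diseases)
  if (length(drugs) == 0L && length(diseases) == 0L) {
    input_error("a heterograph needs at least one node")
  }
  if (anyDuplicated(drugs)) input_error("duplicate drug ids")
  if (anyDuplicated(diseases)) input_error("duplicate disease ids")
  if (length(intersect(drugs, diseases)) > 0L) {
    input_error("drug and disease id sets overlap: %s",
                paste(utils::head(intersect(drugs, diseases), 3), collapse = ", "))
  }
  edges_dd <- canon_undirected(as_edge_matrix(edges_dd), drugs, drugs, "drug-drug")
  edges_ss <- canon_undirected(as_edge_matrix(edges_ss), diseases, diseases, "disease-disease")
  edges_ds <- canon_bipartite(as_edge_matrix(edges_ds), diseases, drugs, "disease-drug")
  structure(
    list(drugs = drugs, diseases = diseases,
         edges_dd = edges_dd, edges_ss = edges_ss, edges_ds = edges_ds),
    class = "heterograph"
  )
}

empty_edges <- function() matrix(character(0), ncol = 2)

as_edge_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || ncol(x) != 2L) input_error("edges must be a 2-column matrix")
  storage.mode(x) <- "character"
  dimnames(x) <- NULL
  x
}

canon_undirected <- function(e, set_a, set_b, label) {
  if (nrow(e) == 0L) return(empty_edges())
  bad <- setdiff(c(e), union(set_a, set_b))
  if (length(bad) > 0L) {
    input_error("%s edge references unknown node id \"%s\"", label, bad[[1L]])
  }
  if (any(e[, 1L] == e[, 2L])) {
    input_error("%s edge set contains a self-loop (%s)", label,
                e[which(e[, 1L] == e[, 2L])[1L], 1L])
  }
  canon <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(canon)
}

canon_bipartite <- function(e, diseases, drugs, label) {
  if (nrow(e) == 0L) return(empty_edges())
  # accept either column orientation; store (disease, drug)
  flip <- e[, 1L] %in% drugs & e[, 2L] %in% diseases
  e[flip, ] <- e[flip, c(2L, 1L), drop = FALSE]
  bad_d <- setdiff(e[, 1L], diseases)
  if (length(bad_d) > 0L) {
    input_error("%s edge references unknown disease id \"%s\"", label, bad_d[[1L]])
  }
  bad_s <- setdiff(e[, 2L], drugs)
  if (length(bad_s) > 0L) {
    input_error("%s edge references unknown drug id \"%s\"", label, bad_s[[1L]])
  }
  unique(e)
}

#' @export
print.heterograph <- function(x, ...) {
  cat(sprintf(
    "heterograph: %d drugs, %d diseases | %d drug-drug, %d disease-disease, %d disease-drug edges\n",
    length(x$drugs), length(x$diseases),
    nrow(x$edges_dd), nrow(x$edges_ss), nrow(x$edges_ds)))
  invisible(x)
}

#' Node ids of a graph in canonical order
#'
#' Heterogeneous graphs order nodes as (drugs, diseases); bipartite graphs as
#' (diseases, drugs). All matrices keyed by node id use rownames, so most code
#' is order-agnostic.
#' @param graph a `heterograph` or `bipartite_graph`.
#' @return character vector of node ids.
#' @export
node_order <- function(graph) {
  if (inherits(graph, "heterograph")) return(c(graph$drugs, graph$diseases))
  if (inherits(graph, "bipartite_graph")) return(c(graph$diseases, graph$drugs))
  input_error("unsupported graph class: %s", paste(class(graph), collapse = "/"))
}

#' Construct a disease-drug bipartite graph
#'
#' @param diseases,drugs character id vectors.
#' @param edges two-column character matrix of (disease, drug) treat edges.
#' @return An object of class `bipartite_graph`.
#' @export
bipartite_graph <- function(diseases, drugs, edges = empty_edges()) {
  diseases <- as.character(diseases)
  drugs <- as.character(drugs)
  if (anyDuplicated(diseases)) input_error("duplicate disease ids")
  if (anyDuplicated(drugs)) input_error("duplicate drug ids")
  if (length(intersect(diseases, drugs)) > 0L) {
    input_error("disease and drug id sets overlap")
  }
  edges <- as_edge_matrix(edges)
  if (nrow(edges) > 0L) {
    bad <- setdiff(edges[, 1L], diseases)
    if (length(bad) > 0L) input_error("treat edge references unknown disease \"%s\"", bad[[1L]])
    bad <- setdiff(edges[, 2L], drugs)
    if (length(bad) > 0L) input_error("treat edge references unknown drug \"%s\"", bad[[1L]])
    edges <- unique(edges)
  }
  structure(list(diseases = diseases, drugs = drugs, edges = edges),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("bipartite_graph: %d diseases x %d drugs, %d treat edges\n",
              length(x$diseases), length(x$drugs), nrow(x$edges)))
  invisible(x)
}

read_tsv_table <- function(path, required_cols) {
  if (!file.exists(path)) input_error("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8", blank.lines.skip = TRUE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    input_error("%s: missing required column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  df
}

#' Load a heterogeneous graph from node and edge tables
#'
#' `nodes.tsv` needs columns `node_id`, `node_type` (drug|disease);
#' `edges.tsv` needs `source_id`, `target_id`,
#' `relation` (drug-drug|disease-disease|disease-drug). Duplicate edges are
#' collapsed; self-loops, unknown ids and unknown relation labels are errors.
#'
#' @param node_table_path,edge_table_path paths to the TSV files.
#' @return a validated [heterograph()].
#' @export
load_heterograph <- function(node_table_path, edge_table_path) {
  nodes <- read_tsv_table(node_table_path, c("node_id", "node_type"))
  if (nrow(nodes) == 0L) input_error("%s: empty node table", node_table_path)
  bad_type <- setdiff(unique(nodes$node_type), c("drug", "disease"))
  if (length(bad_type) > 0L) {
    input_error("%s: unknown node_type \"%s\"", node_table_path, bad_type[[1L]])
  }
  edges <- read_tsv_table(edge_table_path, c("source_id", "target_id", "relation"))
  known <- c("drug-drug", "disease-disease", "disease-drug")
  bad_rel <- setdiff(unique(edges$relation), known)
  if (length(bad_rel) > 0L) {
    input_error("%s: unknown relation label \"%s\"", edge_table_path, bad_rel[[1L]])
  }
  all_ids <- nodes$node_id
  bad_id <- setdiff(unique(c(edges$source_id, edges$target_id)), all_ids)
  if (length(bad_id) > 0L) {
    row <- which(edges$source_id == bad_id[[1L]] | edges$target_id == bad_id[[1L]])[1L]
    input_error("%s row %d: edge references node id \"%s\" absent from node table",
                edge_table_path, row, bad_id[[1L]])
  }
  pick <- function(rel) {
    sel <- edges$relation == rel
    cbind(edges$source_id[sel], edges$target_id[sel])
  }
  heterograph(
    drugs = nodes$node_id[nodes$node_type == "drug"],
    diseases = nodes$node_id[nodes$node_type == "disease"],
    edges_dd = pick("drug-drug"),
    edges_ss = pick("disease-disease"),
    edges_ds = pick("disease-drug")
  )
}

#' Write a heterogeneous graph as node and edge tables
#' @param graph a `heterograph`.
#' @param node_table_path,edge_table_path output TSV paths.
#' @export
write_heterograph <- function(graph, node_table_path, edge_table_path) {
  nodes <- data.frame(
    node_id = c(graph$drugs, graph$diseases),
    node_type = c(rep("drug", length(graph$drugs)),
                  rep("disease", length(graph$diseases)))
  )
  edges <- rbind(
    data.frame(source_id = graph$edges_dd[, 1L], target_id = graph$edges_dd[, 2L],
               relation = rep("drug-drug", nrow(graph$edges_dd))),
    data.frame(source_id = graph$edges_ss[, 1L], target_id = graph$edges_ss[, 2L],
               relation = rep("disease-disease", nrow(graph$edges_ss))),
    data.frame(source_id = graph$edges_ds[, 1L], target_id = graph$edges_ds[, 2L],
               relation = rep("disease-drug", nrow(graph$edges_ds)))
  )
  utils::write.table(nodes, node_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(edges, edge_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(node_table_path, edge_table_path))
}

#' Read / write treat edges (disease_id, drug_id)
#'
#' @param path TSV path with columns `disease_id`, `drug_id`.
#' @param graph optional `heterograph`; when given, node sets are taken from
#'   it (and membership validated), otherwise they are inferred from the file.
#' @return a [bipartite_graph()].
#' @export
read_treat_edges <- function(path, graph = NULL) {
  df <- read_tsv_table(path, c("disease_id", "drug_id"))
  e <- cbind(df$disease_id, df$drug_id)
  if (is.null(graph)) {
    bipartite_graph(unique(df$disease_id), unique(df$drug_id), e)
  } else {
    bipartite_graph(graph$diseases, graph$drugs, e)
  }
}

#' @rdname read_treat_edges
#' @param bipartite a `bipartite_graph` to serialize.
#' @export
write_treat_edges <- function(bipartite, path) {
  utils::write.table(
    data.frame(disease_id = bipartite$edges[, 1L], drug_id = bipartite$edges[, 2L]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write effectiveness-comparison triples
#'
#' Each row states that for `disease_id`, `better_drug_id` treats the disease
#' more effectively than `worse_drug_id`.
#' @param path TSV path with columns `disease_id`, `better_drug_id`, `worse_drug_id`.
#' @return data.frame with those three character columns.
#' @export
read_ecr <- function(path) {
  df <- read_tsv_table(path, c("disease_id", "better_drug_id", "worse_drug_id"))
  if (any(df$better_drug_id == df$worse_drug_id)) {
    input_error("%s: comparison of a drug with itself", path)
  }
  df
}

#' @rdname read_ecr
#' @param ecr data.frame of triples to serialize.
#' @export
write_ecr <- function(ecr, path) {
  utils::write.table(ecr[, c("disease_id", "better_drug_id", "worse_drug_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a node feature matrix
#'
#' Format: first column `node_id`, then the numeric feature columns.
#' @param path TSV path.
#' @return numeric matrix with node ids as rownames.
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (names(df)[1L] != "node_id") input_error("%s: first column must be node_id", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$node_id)
  validate_feature_matrix(m)
  m
}

#' @rdname read_features
#' @param features numeric matrix with rownames.
#' @export
write_features <- function(features, path) {
  validate_feature_matrix(features)
  df <- data.frame(node_id = rownames(features), features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

validate_feature_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) input_error("features must be a numeric matrix")
  if (is.null(rownames(m))) input_error("feature matrix needs node ids as rownames")
  if (anyDuplicated(rownames(m))) input_error("duplicate node ids in feature matrix")
  if (!all(is.finite(m))) input_error("feature matrix contains non-finite values")
  invisible(m)
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Builds the standard GCN propagation operator
#' \eqn{\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}} over the union node
#' set, where A is the symmetric 0/1 adjacency of all edges and
#' \eqn{\tilde D} the degree matrix of A + I. For a bipartite graph the treat
#' edges are embedded as off-diagonal blocks over (diseases, drugs), so one
#' propagation routine serves both the pretraining and fine-tuning phases.
#'
#' @param graph a `heterograph` or `bipartite_graph`.
#' @param nodes optional node id superset/order to build over (defaults to
#'   [node_order()] of the graph); extra ids become isolated self-loop nodes.
#' @return list of class `normalized_adjacency` with fields `node_order` and
#'   `matrix` (sparse symmetric, `Matrix` package).
#' @export
build_normalized_adjacency <- function(graph, nodes = NULL) {
  if (is.null(nodes)) nodes <- node_order(graph)
  if (inherits(graph, "heterograph")) {
    e <- rbind(graph$edges_dd, graph$edges_ss, graph$edges_ds)
  } else if (inherits(graph, "bipartite_graph")) {
    e <- graph$edges
  } else {
    input_error("unsupported graph class")
  }
  missing <- setdiff(unique(c(e)), nodes)
  if (length(missing) > 0L) {
    input_error("edge endpoint \"%s\" absent from node order", missing[[1L]])
  }
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  i <- c(idx[e[, 1L]], idx[e[, 2L]], seq_len(n))
  j <- c(idx[e[, 2L]], idx[e[, 1L]], seq_len(n))
  a_tilde <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n),
                                  dimnames = list(nodes, nodes))
  a_tilde@x[] <- 1  # duplicate (i,j) entries were summed; clamp back to 0/1
  d_inv_sqrt <- 1 / sqrt(Matrix::rowSums(a_tilde))
  a_hat <- Matrix::Diagonal(x = d_inv_sqrt) %*% a_tilde %*% Matrix::Diagonal(x = d_inv_sqrt)
  a_hat <- methods::as(a_hat, "CsparseMatrix")
  dimnames(a_hat) <- list(nodes, nodes)
  structure(list(node_order = nodes, matrix = a_hat),
            class = "normalized_adjacency")
}

new_split_result <- function(train, test, mode, seed) {
  structure(list(train = train, test = test, mode = mode, seed = as.integer(seed)),
            class = "split_result")
}

#' Warm (edge-level) train/test split
#'
#' Uniformly random partition of treat edges; both sides keep the full
#' disease and drug id sets. Test size is `round(test_fraction * n)` rounded
#' half-up, with a minimum of one edge on each side.
#'
#' @param bipartite a `bipartite_graph` with at least 2 edges.
#' @param test_fraction number in (0, 1).
#' @param seed integer; the split is deterministic given the seed.
#' @return list of class `split_result` with `train`, `test`, `mode`, `seed`.
#' @export
split_warm <- function(bipartite, test_fraction, seed) {
  check_fraction(test_fraction, "test_fraction")
  n <- nrow(bipartite$edges)
  if (n < 2L) input_error("need at least 2 treat edges to split")
  n_test <- min(max(1L, as.integer(round_half_up(test_fraction * n))), n - 1L)
  test_idx <- with_seed(seed, sample.int(n, n_test))
  mk <- function(rows) bipartite_graph(bipartite$diseases, bipartite$drugs,
                                       bipartite$edges[rows, , drop = FALSE])
  new_split_result(mk(setdiff(seq_len(n), test_idx)), mk(test_idx),
                   "warm_edge", seed)
}

#' Cold (new-disease) train/test split
#'
#' Partitions diseases that have at least one treat edge; every edge follows
#' its disease, so no test disease ever appears in training.
#'
#' @inheritParams split_warm
#' @export
split_cold_disease <- function(bipartite, test_fraction, seed) {
  check_fraction(test_fraction, "test_fraction")
  eligible <- unique(bipartite$edges[, 1L])
  if (length(eligible) < 2L) {
    input_error("need at least 2 diseases with treat edges for a cold split")
  }
  n <- length(eligible)
  n_test <- min(max(1L, as.integer(round_half_up(test_fraction * n))), n - 1L)
  test_dis <- with_seed(seed, sample(eligible, n_test))
  train_dis <- setdiff(eligible, test_dis)
  pick <- function(dis) {
    e <- bipartite$edges[bipartite$edges[, 1L] %in% dis, , drop = FALSE]
    bipartite_graph(dis, bipartite$drugs, e)
  }
  new_split_result(pick(train_dis), pick(test_dis), "cold_disease", seed)
}
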