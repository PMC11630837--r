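# Initial node features: expression-perturbation signatures for recorded
# drugs, similarity-based imputation for unrecorded drugs, and
# treat-relation-derived signatures for diseases.

#' Construct a drug signature table
#'
#' Holds the expression-perturbation signature vectors of the drugs that were
#' directly profiled ("recorded" drugs). Unrecorded drugs get imputed
#' signatures via [impute_drug_signature()].
#'
#' @param signatures numeric matrix (recorded drugs x feature dims) with drug
#'   ids as rownames.
#' @return object of class `signature_table` with fields `recorded_drugs`,
#'   `signatures`, `n_feat`.
#' @export
signature_table <- function(signatures) {
  validate_feature_matrix(signatures)
  structure(list(recorded_drugs = rownames(signatures),
                 signatures = signatures,
                 n_feat = ncol(signatures)),
            class = "signature_table")
}

#' Impute the signature of an unrecorded drug from similar drugs
#'
#' Drug similarity is operationalized as drug-drug adjacency in the
#' heterogeneous graph: the imputed signature is the unweighted mean of the
#' recorded signatures among the drug's 1-hop drug-drug neighbours; if none
#' of those is recorded, the mean over recorded 2-hop neighbours; failing
#' that, the global mean of all recorded signatures.
#'
#' @param drug a drug id not present in `table$recorded_drugs`.
#' @param graph the `heterograph` supplying drug-drug edges.
#' @param table a [signature_table()].
#' @return numeric vector of length `table$n_feat`.
#' @export
impute_drug_signature <- function(drug, graph, table) {
  if (length(table$recorded_drugs) == 0L) input_error("empty signature table")
  if (drug %in% table$recorded_drugs) {
    input_error("drug \"%s\" is recorded; nothing to impute", drug)
  }
  if (!drug %in% graph$drugs) input_error("unknown drug id \"%s\"", drug)
  nb1 <- dd_neighbours(graph, drug)
  rec1 <- intersect(nb1, table$recorded_drugs)
  if (length(rec1) > 0L) {
    return(colMeans(table$signatures[rec1, , drop = FALSE]))
  }
  nb2 <- setdiff(unique(unlist(lapply(nb1, dd_neighbours, graph = graph))), drug)
  rec2 <- intersect(nb2, table$recorded_drugs)
  if (length(rec2) > 0L) {
    return(colMeans(table$signatures[rec2, , drop = FALSE]))
  }
  colMeans(table$signatures)
}

dd_neighbours <- function(graph, drug) {
  e <- graph$edges_dd
  c(e[e[, 2L] == drug, 1L], e[e[, 1L] == drug, 2L])
}

#' Derive a disease signature from its treating drugs
#'
#' The disease signature is `sign_flag` times the mean of the feature vectors
#' of all drugs with a treat edge to the disease. `sign_flag = -1` encodes
#' the view that a disease's expression state is the negation of the
#' perturbation that treats it; the default is no flip. Diseases with no
#' treating drug fall back to the global mean of drug features.
#'
#' @param disease disease id.
#' @param treat_edges a `bipartite_graph` of treat relations.
#' @param drug_features numeric matrix covering all drugs in `treat_edges`
#'   (ids as rownames).
#' @param sign_flag +1 or -1.
#' @return numeric vector of length `ncol(drug_features)`.
#' @export
derive_disease_signature <- function(disease, treat_edges, drug_features,
                                     sign_flag = 1) {
  if (!sign_flag %in% c(-1, 1)) input_error("sign_flag must be +1 or -1")
  missing <- setdiff(treat_edges$drugs, rownames(drug_features))
  if (length(missing) > 0L) {
    input_error("drug_features missing drug \"%s\"", missing[[1L]])
  }
  treaters <- treat_edges$edges[treat_edges$edges[, 1L] == disease, 2L]
  if (length(treaters) == 0L) {
    base <- colMeans(drug_features[treat_edges$drugs, , drop = FALSE])
  } else {
    base <- colMeans(drug_features[treaters, , drop = FALSE])
  }
  sign_flag * base
}

#' Assemble the full initial feature matrix for a heterogeneous graph
#'
#' One row per node in the graph's node order: recorded drugs copy their
#' signature, unrecorded drugs are imputed with [impute_drug_signature()],
#' diseases are derived with [derive_disease_signature()] from the supplied
#' treat edges (pass training-only edges to avoid leakage into evaluation).
#'
#' @param graph a `heterograph`.
#' @param table a [signature_table()]; recorded drugs must be graph drugs.
#' @param treat_edges a `bipartite_graph` used for disease derivation.
#' @param sign_flag passed to [derive_disease_signature()].
#' @return numeric matrix `(|drugs| + |diseases|) x n_feat` with node ids as
#'   rownames.
#' @export
assemble_features <- function(graph, table, treat_edges, sign_flag = 1) {
  if (length(table$recorded_drugs) == 0L) input_error("empty signature table")
  alien <- setdiff(table$recorded_drugs, graph$drugs)
  if (length(alien) > 0L) {
    input_error("signature table drug \"%s\" not in graph", alien[[1L]])
  }
  n_feat <- table$n_feat
  drug_rows <- matrix(0, length(graph$drugs), n_feat,
                      dimnames = list(graph$drugs, colnames(table$signatures)))
  recorded <- intersect(graph$drugs, table$recorded_drugs)
  drug_rows[recorded, ] <- table$signatures[recorded, , drop = FALSE]
  for (d in setdiff(graph$drugs, recorded)) {
    drug_rows[d, ] <- impute_drug_signature(d, graph, table)
  }
  # diseases see only the drugs also present in the graph
  te <- bipartite_graph(
    graph$diseases, graph$drugs,
    treat_edges$edges[treat_edges$edges[, 1L] %in% graph$diseases &
                        treat_edges$edges[, 2L] %in% graph$drugs, , drop = FALSE])
  dis_rows <- matrix(0, length(graph$diseases), n_feat,
                     dimnames = list(graph$diseases, colnames(table$signatures)))
  for (s in graph$diseases) {
    dis_rows[s, ] <- derive_disease_signature(s, te, drug_rows, sign_flag)
  }
  out <- rbind(drug_rows, dis_rows)
  rownames(out) <- c(graph$drugs, graph$diseases)
  validate_feature_matrix(out)
  out
}
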