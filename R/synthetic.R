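# Synthetic study generator with planted latent structure.
#
# Drugs and diseases get latent factor vectors; treat edges are the top
# slice of the disease-drug affinity (dot-product) matrix, drug signatures
# are a noisy linear map of drug factors, drug-drug / disease-disease edges
# connect factor-similar nodes plus Erdos-Renyi noise, and effectiveness
# comparisons order pairs of treaters by their affinity. Binary supervision
# and effectiveness supervision therefore share one planted signal while
# carrying different granularity.

#' Configuration of a synthetic study
#'
#' Defaults generate the desk-scale benchmark used throughout the test
#' suite: 150 drugs, 30 diseases, latent dimension 8, 64 feature dims,
#' signature noise sd 0.5, treat density 0.05, 70% of drugs recorded.
#'
#' @param n_drugs,n_diseases node counts.
#' @param latent_dim dimension of the planted factor vectors.
#' @param n_feat signature dimension (real landmark-gene panels are ~1000;
#'   the synthetic default is 64 for speed).
#' @param noise_sd sd of additive Gaussian noise on signatures.
#' @param treat_density fraction of drugs linked to each disease (top
#'   affinities; at least one per disease).
#' @param dd_edge_prob,ss_edge_prob Erdos-Renyi noise-edge probability among
#'   drugs / diseases, added to the similarity-derived edges.
#' @param knn_edges similarity edges per node (nearest factor-space
#'   neighbours).
#' @param recorded_fraction fraction of drugs with an observed signature.
#' @param ecr_per_disease effectiveness-comparison pairs sampled per disease.
#' @param seed integer.
#' @return named list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 150L, n_diseases = 30L, latent_dim = 8L,
                             n_feat = 64L, noise_sd = 0.5,
                             treat_density = 0.05, dd_edge_prob = 0.02,
                             ss_edge_prob = 0.05, knn_edges = 2L,
                             recorded_fraction = 0.7, ecr_per_disease = 3L,
                             seed = 1L) {
  stopifnot(n_drugs >= 2L, n_diseases >= 1L, latent_dim >= 1L, n_feat >= 1L,
            noise_sd >= 0, treat_density > 0, treat_density < 1,
            dd_edge_prob >= 0, dd_edge_prob < 1, ss_edge_prob >= 0,
            ss_edge_prob < 1, recorded_fraction > 0, recorded_fraction <= 1,
            ecr_per_disease >= 0L)
  structure(list(n_drugs = as.integer(n_drugs), n_diseases = as.integer(n_diseases),
                 latent_dim = as.integer(latent_dim), n_feat = as.integer(n_feat),
                 noise_sd = noise_sd, treat_density = treat_density,
                 dd_edge_prob = dd_edge_prob, ss_edge_prob = ss_edge_prob,
                 knn_edges = as.integer(knn_edges),
                 recorded_fraction = recorded_fraction,
                 ecr_per_disease = as.integer(ecr_per_disease),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a complete synthetic study
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_study` with fields `graph`
#'   (`heterograph`), `signatures` (`signature_table` of recorded drugs),
#'   `treat` (`bipartite_graph`), `ecr` (data.frame of comparison triples),
#'   `truth` (latent factors, loading matrix, affinity/effectiveness
#'   matrix) and `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  drugs <- sprintf("drug%03d", seq_len(cfg$n_drugs))
  diseases <- sprintf("dis%03d", seq_len(cfg$n_diseases))
  x <- matrix(stats::rnorm(cfg$n_drugs * cfg$latent_dim), cfg$n_drugs,
              dimnames = list(drugs, NULL))
  y <- matrix(stats::rnorm(cfg$n_diseases * cfg$latent_dim), cfg$n_diseases,
              dimnames = list(diseases, NULL))
  affinity <- y %*% t(x)                      # effectiveness(u, i)
  # treat edges: per disease, its top slice of affinities (never empty)
  n_per <- max(1L, as.integer(round_half_up(cfg$treat_density * cfg$n_drugs)))
  treat_edges <- do.call(rbind, lapply(diseases, function(u) {
    top <- names(sort(affinity[u, ], decreasing = TRUE))[seq_len(n_per)]
    cbind(rep(u, n_per), top)
  }))
  treat <- bipartite_graph(diseases, drugs, treat_edges)
  # noisy linear signatures for a recorded subset of drugs
  loading <- matrix(stats::rnorm(cfg$latent_dim * cfg$n_feat), cfg$latent_dim)
  sig_full <- x %*% loading +
    cfg$noise_sd * matrix(stats::rnorm(cfg$n_drugs * cfg$n_feat), cfg$n_drugs)
  colnames(sig_full) <- sprintf("g%03d", seq_len(cfg$n_feat))
  n_rec <- max(1L, as.integer(round_half_up(cfg$recorded_fraction * cfg$n_drugs)))
  recorded <- sort(sample(drugs, n_rec))
  signatures <- signature_table(sig_full[recorded, , drop = FALSE])
  # similarity edges (factor-space kNN) plus Erdos-Renyi noise
  edges_dd <- knn_plus_noise(x, cfg$knn_edges, cfg$dd_edge_prob)
  edges_ss <- if (cfg$n_diseases >= 2L) {
    knn_plus_noise(y, cfg$knn_edges, cfg$ss_edge_prob)
  } else {
    empty_edges()
  }
  graph <- heterograph(drugs, diseases, edges_dd = edges_dd,
                       edges_ss = edges_ss, edges_ds = treat$edges)
  ecr <- sample_ecr(treat, affinity, cfg$ecr_per_disease)
  structure(list(graph = graph, signatures = signatures, treat = treat,
                 ecr = ecr,
                 truth = list(drug_factors = x, disease_factors = y,
                              loading = loading, effectiveness = affinity),
                 config = cfg),
            class = "synthetic_study")
}

knn_plus_noise <- function(factors, k, p_noise) {
  ids <- rownames(factors)
  n <- length(ids)
  if (n < 2L) return(empty_edges())
  norms <- sqrt(rowSums(factors^2)) + 1e-12
  sim <- tcrossprod(factors / norms)
  diag(sim) <- -Inf
  k <- min(k, n - 1L)
  knn <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(sim[i, ], decreasing = TRUE)[seq_len(k)]
    cbind(rep(ids[[i]], k), ids[nb])
  }))
  pairs <- which(upper.tri(sim), arr.ind = TRUE)
  noise_sel <- stats::runif(nrow(pairs)) < p_noise
  noise <- cbind(ids[pairs[noise_sel, 1L]], ids[pairs[noise_sel, 2L]])
  rbind(knn, noise)
}

sample_ecr <- function(treat, affinity, per_disease) {
  if (per_disease == 0L) {
    return(data.frame(disease_id = character(0), better_drug_id = character(0),
                      worse_drug_id = character(0)))
  }
  rows <- list()
  for (u in treat$diseases) {
    treaters <- treat$edges[treat$edges[, 1L] == u, 2L]
    if (length(treaters) < 2L) next
    combos <- utils::combn(treaters, 2L)
    take <- sample.int(ncol(combos), min(per_disease, ncol(combos)))
    for (ci in take) {
      a <- combos[1L, ci]; b <- combos[2L, ci]
      if (affinity[u, a] < affinity[u, b]) { tmp <- a; a <- b; b <- tmp }
      rows[[length(rows) + 1L]] <- data.frame(disease_id = u, better_drug_id = a,
                                              worse_drug_id = b)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(disease_id = character(0), better_drug_id = character(0),
                      worse_drug_id = character(0)))
  }
  do.call(rbind, rows)
}

#' @export
print.synthetic_study <- function(x, ...) {
  print(x$graph)
  cat(sprintf("  %d recorded drug signatures (%d dims), %d treat edges, %d comparison triples\n",
              length(x$signatures$recorded_drugs), x$signatures$n_feat,
              nrow(x$treat$edges), nrow(x$ecr)))
  invisible(x)
}

#' Check that effectiveness comparisons are internally consistent
#'
#' For every disease the "better-than" relation must be acyclic (always true
#' when comparisons derive from a scalar effectiveness). An empty set is
#' consistent.
#'
#' @param ecr data.frame with columns `disease_id`, `better_drug_id`,
#'   `worse_drug_id`.
#' @return `TRUE` or `FALSE`.
#' @export
ecr_consistency_check <- function(ecr) {
  if (is.null(ecr) || nrow(ecr) == 0L) return(TRUE)
  for (u in unique(ecr$disease_id)) {
    sub <- ecr[ecr$disease_id == u, , drop = FALSE]
    if (has_cycle(sub$better_drug_id, sub$worse_drug_id)) return(FALSE)
  }
  TRUE
}

# Kahn's algorithm: a directed graph is acyclic iff repeatedly removing
# in-degree-0 nodes consumes every node.
has_cycle <- function(from, to) {
  nodes <- unique(c(from, to))
  edges <- data.frame(from = from, to = to)
  repeat {
    if (length(nodes) == 0L) return(FALSE)
    sinks_ok <- setdiff(nodes, edges$to)  # in-degree 0
    if (length(sinks_ok) == 0L) return(TRUE)
    nodes <- setdiff(nodes, sinks_ok)
    edges <- edges[!(edges$from %in% sinks_ok), , drop = FALSE]
  }
}

#' Write a synthetic study as the standard TSV file set
#'
#' Produces `nodes.tsv`, `edges.tsv`, `treat.tsv`, `ecr.tsv`,
#' `features.tsv` (recorded drug signatures) and `truth.tsv` (planted
#' latent factors, for test oracles only).
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_heterograph(study$graph, p("nodes.tsv"), p("edges.tsv"))
  write_treat_edges(study$treat, p("treat.tsv"))
  write_ecr(study$ecr, p("ecr.tsv"))
  write_features(study$signatures$signatures, p("features.tsv"))
  truth <- rbind(study$truth$drug_factors, study$truth$disease_factors)
  colnames(truth) <- sprintf("f%02d", seq_len(ncol(truth)))
  write_features(truth, p("truth.tsv"))
  invisible(vapply(c("nodes.tsv", "edges.tsv", "treat.tsv", "ecr.tsv",
                     "features.tsv", "truth.tsv"), p, character(1)))
}
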