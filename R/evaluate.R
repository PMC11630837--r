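# Ranking evaluation: filtered candidate ranks, MRR / Hit@K, relative
# improvement rate, and a silhouette diagnostic for embedding separation.

#' Rank a held-out drug among filtered candidates
#'
#' The candidate list is all drugs minus the disease's known training
#' positives (filtered ranking). Ties count against the model: the rank is
#' 1 + number of candidates scoring strictly higher + number of other
#' candidates with exactly the test drug's score.
#'
#' @param scores disease x drug score matrix with ids as dimnames.
#' @param disease disease id (row of `scores`).
#' @param test_drug the held-out positive drug.
#' @param all_drugs candidate universe.
#' @param train_positives drugs to filter out (training positives of the
#'   disease); must not contain `test_drug`.
#' @return data.frame with one row: `disease`, `target_drug`, `rank`,
#'   `n_candidates`.
#' @export
rank_candidates <- function(scores, disease, test_drug, all_drugs,
                            train_positives = character(0)) {
  candidates <- setdiff(all_drugs, train_positives)
  if (!test_drug %in% candidates) {
    stop(sprintf("test drug \"%s\" was filtered out of the candidate list", test_drug),
         call. = FALSE)
  }
  if (!disease %in% rownames(scores)) input_error("unknown disease \"%s\"", disease)
  s <- scores[disease, candidates]
  st <- scores[disease, test_drug]
  rank <- 1L + sum(s > st) + sum(s == st & candidates != test_drug)
  data.frame(disease = disease, target_drug = test_drug,
             rank = as.integer(rank), n_candidates = length(candidates))
}

#' Aggregate per-query ranks into MRR and Hit@K
#'
#' @param records data.frame of ranking records (rows as produced by
#'   [rank_candidates()]).
#' @param ks integer cutoffs for Hit@K.
#' @return list of class `metric_report` with `mrr`, `hit_at` (named
#'   numeric), `n_queries`, `per_query`.
#' @export
compute_metrics <- function(records, ks = c(1L, 3L, 10L)) {
  if (is.null(records) || nrow(records) == 0L) input_error("no ranking records")
  ranks <- records$rank
  hit <- vapply(sort(as.integer(ks)), function(k) mean(ranks <= k), numeric(1))
  names(hit) <- paste0("hit_at_", sort(as.integer(ks)))
  structure(list(mrr = mean(1 / ranks), hit_at = hit,
                 n_queries = nrow(records), per_query = records),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ranking metrics over %d queries\n  MRR   %.4f\n", x$n_queries, x$mrr))
  for (nm in names(x$hit_at)) {
    cat(sprintf("  %s %.4f\n", format(sub("hit_at_", "Hit@", nm), width = 6), x$hit_at[[nm]]))
  }
  invisible(x)
}

#' Relative improvement rate in percent
#'
#' `100 * (new - baseline) / baseline`, rounded half-up to two decimals.
#'
#' @param new,baseline metric values; `baseline` must be positive.
#' @return a percentage.
#' @export
relative_improvement <- function(new, baseline) {
  if (!is.numeric(baseline) || baseline <= 0) {
    input_error("baseline must be a positive number")
  }
  round_half_up(100 * (new - baseline) / baseline, 2)
}

#' Silhouette score of a labelled embedding
#'
#' Standard silhouette with Euclidean distances, averaged over points:
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean
#' within-cluster distance and `b(i)` the smallest mean distance to another
#' cluster. Points in singleton clusters contribute 0.
#'
#' @param embeddings numeric matrix (points x dims).
#' @param labels vector of cluster labels, one per row; at least two
#'   distinct labels and three points are required.
#' @return scalar in \[-1, 1\].
#' @export
silhouette_score <- function(embeddings, labels) {
  labels <- as.character(labels)
  n <- nrow(embeddings)
  if (length(labels) != n) input_error("one label per embedding row required")
  if (n < 3L) input_error("need at least 3 points")
  if (length(unique(labels)) < 2L) input_error("need at least 2 distinct labels")
  dm <- as.matrix(stats::dist(embeddings))
  sizes <- table(labels)
  s <- numeric(n)
  for (idx in seq_len(n)) {
    own <- labels[[idx]]
    if (sizes[[own]] == 1L) { s[[idx]] <- 0; next }
    a <- sum(dm[idx, labels == own]) / (sizes[[own]] - 1L)
    others <- setdiff(names(sizes), own)
    b <- min(vapply(others, function(cl) mean(dm[idx, labels == cl]), numeric(1)))
    s[[idx]] <- (b - a) / max(a, b)
  }
  mean(s)
}
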