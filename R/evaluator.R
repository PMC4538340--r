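#' Reference activity rankings
#'
#' A reference ranking is a ranked list derived from measured activities
#' (e.g. EC50 in uM, lower = more potent). Items are ordered by activity under
#' the lower-is-better convention, ties broken by ascending item id.
#'
#' @param activities named numeric vector, item id -> activity value.
#' @param name label, default `"reference"`.
#' @return an object of classes `reference_rank` and `ranked_list`; the
#'   activities are stored in `$scores`.
#' @export
reference_rank <- function(activities, name = "reference") {
  rl <- scores_to_rank(activities, direction = "lower_is_better", name = name)
  class(rl) <- c("reference_rank", class(rl))
  rl
}

#' Graded relevance from a reference ranking
#'
#' Turns a reference ranking of n items into a per-item relevance value
#' `rel(t) >= 0` for DCG computation:
#' * `linear` (default, parameter-free): `rel(t) = n - r_ref(t) + 1`;
#' * `exponential`: `rel(t) = 2^(n - r_ref(t))`, scaled by `2^(n-1)` so the
#'   top item has relevance 1 (nDCG is invariant to the overall scale);
#' * `binary`: `rel(t) = 1` if the item's activity is at or below `threshold`
#'   (e.g. EC50 <= 10 uM = active), else 0; requires activities and a
#'   threshold.
#'
#' @param ref a [reference_rank()] (or any [ranked_list()]; `binary` needs
#'   scores).
#' @param scheme `"linear"`, `"exponential"` or `"binary"`.
#' @param threshold activity cutoff for `binary`.
#' @return named numeric vector of relevances over the reference items.
#' @export
relevance_from_reference <- function(ref,
                                     scheme = c("linear", "exponential", "binary"),
                                     threshold = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ref, "ranked_list"))
  n <- length(ref$items)
  r <- seq_len(n)
  rel <- switch(scheme,
    linear = n - r + 1,
    exponential = 2^(n - r) / 2^(n - 1),
    binary = {
      if (is.null(threshold)) {
        stop("binary relevance requires an activity threshold")
      }
      if (is.null(ref$scores)) {
        stop("binary relevance requires the reference to carry activity values")
      }
      as.numeric(ref$scores <= threshold)
    })
  stats::setNames(rel, ref$items)
}

#' Discounted cumulative gain at a position
#'
#' \deqn{DCG_p = rel_1 + \sum_{i=2}^{p} rel_i / \log_2 i} over an ordered
#' relevance sequence (position 1 undiscounted, base-2 logarithm).
#'
#' @param rel_sequence numeric vector of relevances in list order.
#' @param p cutoff position, `1 <= p <= length(rel_sequence)`.
#' @return numeric DCG value.
#' @export
dcg <- function(rel_sequence, p = length(rel_sequence)) {
  n <- length(rel_sequence)
  if (n == 0L) stop("empty relevance sequence")
  if (p < 1 || p > n) stop("position p must lie in 1..", n)
  if (any(rel_sequence < 0)) stop("relevances must be non-negative")
  disc <- c(1, log2(seq_len(n)[-1]))
  sum(rel_sequence[seq_len(p)] / disc[seq_len(p)])
}

#' Evaluate a candidate ranking against graded relevance
#'
#' Computes DCG, ideal DCG and nDCG at every cutoff `p = 1..n`, plus the mean
#' nDCG over all cutoffs — the headline similarity scalar between the
#' candidate ordering and the reference that produced the relevances.
#'
#' @param candidate a [ranked_list()].
#' @param rel named numeric relevance vector covering the candidate universe
#'   (see [relevance_from_reference()]); at least one entry must be positive.
#' @return an `evaluation_result`: data frame `by_position` with columns
#'   `position`, `dcg`, `idcg`, `ndcg`, plus `mean_ndcg` and `n`.
#' @export
evaluate_ranking <- function(candidate, rel) {
  stopifnot(inherits(candidate, "ranked_list"))
  missing <- setdiff(candidate$items, names(rel))
  if (length(missing)) {
    stop("relevance undefined for item(s): ", paste(missing, collapse = ", "))
  }
  r <- as.numeric(rel[candidate$items])
  if (any(r < 0)) stop("relevances must be non-negative")
  if (all(r == 0)) stop("nDCG is undefined for an all-zero relevance vector")
  n <- length(r)
  disc <- c(1, log2(seq_len(n)[-1]))
  dcg_p <- cumsum(r / disc)
  ideal <- sort(r, decreasing = TRUE)
  idcg_p <- cumsum(ideal / disc)
  ndcg_p <- dcg_p / idcg_p
  structure(
    list(by_position = data.frame(position = seq_len(n), dcg = dcg_p,
                                  idcg = idcg_p, ndcg = ndcg_p),
         mean_ndcg = mean(ndcg_p), n = n),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> n=%d mean nDCG = %.4f (nDCG_n = %.4f)\n",
              x$n, x$mean_ndcg, x$by_position$ndcg[x$n]))
  invisible(x)
}

#' Normalised DCG at a position
#'
#' `nDCG_p = DCG_p / IDCG_p`, where the ideal DCG comes from the
#' relevance-descending ordering of the same items.
#'
#' @inheritParams evaluate_ranking
#' @param p cutoff position.
#' @return numeric in `[0, 1]`.
#' @export
ndcg <- function(candidate, rel, p = length(candidate$items)) {
  ev <- evaluate_ranking(candidate, rel)
  if (p < 1 || p > ev$n) stop("position p must lie in 1..", ev$n)
  ev$by_position$ndcg[p]
}

#' Mean nDCG over all cutoff positions
#'
#' Arithmetic mean of `nDCG_p` for `p = 1..n`: one scalar summarising how
#' close the candidate ordering is to the reference across the whole list
#' depth.
#'
#' @inheritParams evaluate_ranking
#' @return numeric in `[0, 1]`.
#' @export
mean_ndcg <- function(candidate, rel) {
  evaluate_ranking(candidate, rel)$mean_ndcg
}

subset_label <- function(scorers) paste(scorers, collapse = "+")

#' Sweep scorer subsets for the best-aggregating combination
#'
#' Evaluates every non-empty subset of the score table's scoring functions
#' against a reference ranking: singleton subsets are ranked directly from
#' their scores; larger subsets are fused with [aggregate_ce()] first. The
#' result table (one row per subset, sorted by decreasing mean nDCG) shows
#' which combination of docking views best reproduces the activity ordering —
#' complementary scorers rise, redundant pairs sink.
#'
#' @param table a [score_table()] with >= 2 scorers.
#' @param ref a [reference_rank()] over the same universe.
#' @param cfg a [distance_config()].
#' @param params a [ce_params()]; each subset's CE run derives its own seed
#'   from `params$seed` so the sweep is reproducible as a whole.
#' @param scheme relevance scheme for [relevance_from_reference()].
#' @param threshold activity threshold when `scheme = "binary"`.
#' @param subsets optional list of character vectors naming the subsets to
#'   evaluate; mandatory when the table has more than 12 scorers (the
#'   exhaustive sweep would need 2^k - 1 aggregations).
#' @return data frame with columns `subset`, `size`, `mean_ndcg`, `phi`
#'   (consensus objective; `NA` for singletons), sorted by `mean_ndcg`
#'   descending.
#' @export
subset_sweep <- function(table, ref, cfg = distance_config(), params,
                         scheme = "linear", threshold = NULL, subsets = NULL) {
  stopifnot(inherits(table, "score_table"), inherits(ref, "ranked_list"))
  if (length(table$scorers) < 2L) stop("subset_sweep needs at least 2 scorers")
  if (is.null(subsets)) {
    if (length(table$scorers) > 12L) {
      stop("more than 12 scorers: supply an explicit `subsets` list instead ",
           "of the exhaustive 2^k sweep")
    }
    k <- length(table$scorers)
    subsets <- unlist(lapply(seq_len(k), function(sz) {
      utils::combn(table$scorers, sz, simplify = FALSE)
    }), recursive = FALSE)
  }
  rel <- relevance_from_reference(ref, scheme = scheme, threshold = threshold)
  lists <- ranks_from_table(table)
  lists <- lapply(lists, restrict, universe = ref$items)
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    if (length(sub) == 1L) {
      cand <- lists[[sub]]
      phi <- NA_real_
    } else {
      ens <- rank_ensemble(lists[sub])
      sub_seed <- (params$seed + i) %% .Machine$integer.max
      res <- aggregate_ce(ens, cfg, ce_params(
        n_samples = params$n_samples, elite_fraction = params$elite_fraction,
        smoothing = params$smoothing, max_iterations = params$max_iterations,
        stagnation_limit = params$stagnation_limit, seed = sub_seed))
      cand <- res$best_list
      phi <- res$objective
    }
    rows[[i]] <- data.frame(subset = subset_label(sub), size = length(sub),
                            mean_ndcg = mean_ndcg(cand, rel), phi = phi)
  }
  out <- do.call(rbind, rows)
  out[order(-out$mean_ndcg, out$subset), , drop = FALSE]
}

#' Detection rate of known positives in the top of a ranking
#'
#' The fraction of the top `ceiling(top_fraction * n)` items that belong to a
#' positive-label set (e.g. ingredients whose parent herb has a reported
#' herb-drug interaction). The validation statistic for a virtual-screening
#' ranking.
#'
#' @param ranking a [ranked_list()].
#' @param positives character vector of positive item ids (subset of the
#'   ranking universe).
#' @param top_fraction fraction of the list depth to inspect, in (0, 1];
#'   the cutoff is `max(1, floor(top_fraction * n))`, so "top 10 percent" of
#'   305 items inspects 30 of them.
#' @return numeric rate in `[0, 1]`.
#' @export
detection_rate <- function(ranking, positives, top_fraction = 1.0) {
  stopifnot(inherits(ranking, "ranked_list"))
  n <- length(ranking$items)
  if (n == 0L) stop("empty ranking")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  positives <- trimws(as.character(positives))
  stray <- setdiff(positives, ranking$items)
  if (length(stray)) {
    stop("positives not present in the ranking: ", paste(stray, collapse = ", "))
  }
  k <- max(1L, floor(top_fraction * n))
  sum(ranking$items[seq_len(k)] %in% positives) / k
}

#' Detection rate as a function of list depth
#'
#' @inheritParams detection_rate
#' @param fractions vector of top fractions to evaluate.
#' @return data frame with columns `top_fraction`, `cutoff`, `detection_rate`.
#' @export
detection_curve <- function(ranking, positives,
                            fractions = seq(0.05, 1, by = 0.05)) {
  data.frame(
    top_fraction = fractions,
    cutoff = pmax(1L, floor(fractions * length(ranking$items))),
    detection_rate = vapply(fractions, function(f) {
      detection_rate(ranking, positives, f)
    }, numeric(1))
  )
}
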