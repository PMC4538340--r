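#' Distance configuration for rank comparison and aggregation
#'
#' The consensus objective minimises a sum of list-to-list distances. Two
#' metrics are supported: the Spearman footrule
#' \deqn{S(L_i, L_j) = \sum_t | r_{L_i}(t) - r_{L_j}(t) |}
#' and its weighted form
#' \deqn{WS(L_i, L_j) = \sum_t | M(r_{L_i}(t)) - M(r_{L_j}(t)) | \cdot
#'   | r_{L_i}(t) - r_{L_j}(t) |,}
#' where the importance function `M` down-weights disagreements deep in the
#' list. `M` is configurable: `linear_rank` uses \eqn{M(r) = (n - r + 1)/n}
#' (1 at the top, 1/n at the bottom, parameter-free); `normalized_score` uses
#' the min--max-normalised raw score of the item in its list (requires the
#' lists to carry scores) so that the weight reflects score gaps, not just
#' positions.
#'
#' Missing items: the sums run over the union of the two lists. In `strict`
#' mode any universe mismatch is an error; under `assign_k_plus_1` an item
#' absent from a list of length k is assigned rank k+1 there (the standard
#' top-k footrule convention) and importance weight 0.
#'
#' @param metric `"footrule"` or `"weighted_footrule"`.
#' @param weight_function `"linear_rank"` or `"normalized_score"`.
#' @param missing_rank_policy `"strict"` or `"assign_k_plus_1"`.
#' @return an object of class `distance_config`.
#' @export
distance_config <- function(metric = c("footrule", "weighted_footrule"),
                            weight_function = c("linear_rank", "normalized_score"),
                            missing_rank_policy = c("strict", "assign_k_plus_1")) {
  structure(
    list(metric = match.arg(metric),
         weight_function = match.arg(weight_function),
         missing_rank_policy = match.arg(missing_rank_policy)),
    class = "distance_config"
  )
}

# ranks of every item of `universe` in `list`; missing items get k+1 under the
# top-k policy, error under strict.
ranks_on_universe <- function(list, universe, policy, other_name = "other") {
  missing <- setdiff(universe, list$items)
  extra <- setdiff(list$items, universe)
  if (policy == "strict" && (length(missing) || length(extra))) {
    stop("universe mismatch between '", list$name, "' and ", other_name,
         " (strict mode); symmetric difference: ",
         paste(c(missing, extra), collapse = ", "))
  }
  r <- rep(length(list$items) + 1L, length(universe))
  names(r) <- universe
  present <- intersect(universe, list$items)
  r[present] <- rank_of(list, present)
  r
}

# importance weight M as a function of rank 1..k (+ value 0 at rank k+1 for
# missing items). Returns a numeric vector indexed by rank.
m_curve <- function(list, weight_function) {
  k <- length(list$items)
  if (weight_function == "linear_rank") {
    m <- (k - seq_len(k) + 1) / k
  } else {
    if (is.null(list$scores)) {
      stop("weight_function 'normalized_score' requires list '", list$name,
           "' to carry scores")
    }
    s <- as.numeric(list$scores)
    if (list$direction == "lower_is_better") s <- -s
    rng <- range(s)
    m <- if (diff(rng) == 0) rep(1, k) else (s - rng[1]) / diff(rng)
  }
  c(m, 0) # rank k+1 (missing under top-k policy) carries no importance
}

#' Spearman footrule distance between two ranked lists
#'
#' Sum of absolute rank differences over the union of the two lists; see
#' [distance_config()] for the missing-item convention.
#'
#' @param L1,L2 [ranked_list()] objects.
#' @param cfg a [distance_config()] (its `metric` field is ignored here).
#' @return non-negative numeric; 0 iff the orders are identical (strict mode).
#' @examples
#' a <- ranked_list(c("a", "b", "c", "d"))
#' b <- ranked_list(c("b", "a", "d", "c"), name = "swapped")
#' spearman_footrule(a, b)  # 4
#' @export
spearman_footrule <- function(L1, L2, cfg = distance_config()) {
  u <- sort(unique(c(L1$items, L2$items)))
  r1 <- ranks_on_universe(L1, u, cfg$missing_rank_policy, paste0("'", L2$name, "'"))
  r2 <- ranks_on_universe(L2, u, cfg$missing_rank_policy, paste0("'", L1$name, "'"))
  sum(abs(r1 - r2))
}

#' Weighted Spearman footrule distance
#'
#' Each rank-difference term is scaled by the absolute difference of the
#' importance weights of the two positions, so disagreements near the top of
#' the lists dominate. See [distance_config()] for the forms of `M`.
#'
#' @inheritParams spearman_footrule
#' @return non-negative numeric; 0 for identical orders.
#' @export
weighted_footrule <- function(L1, L2, cfg = distance_config(metric = "weighted_footrule")) {
  u <- sort(unique(c(L1$items, L2$items)))
  r1 <- ranks_on_universe(L1, u, cfg$missing_rank_policy, paste0("'", L2$name, "'"))
  r2 <- ranks_on_universe(L2, u, cfg$missing_rank_policy, paste0("'", L1$name, "'"))
  m1 <- m_curve(L1, cfg$weight_function)
  m2 <- m_curve(L2, cfg$weight_function)
  sum(abs(m1[r1] - m2[r2]) * abs(r1 - r2))
}

rank_distance <- function(L1, L2, cfg) {
  if (cfg$metric == "footrule") spearman_footrule(L1, L2, cfg)
  else weighted_footrule(L1, L2, cfg)
}

#' Aggregation objective
#'
#' \deqn{\Phi(\delta) = \sum_i w_i \, d(\delta, L_i)} — the weighted total
#' distance from a candidate consensus list to every list of the ensemble.
#' The consensus list \eqn{\delta^*} is the permutation minimising
#' \eqn{\Phi}; see [aggregate_ce()] and [aggregate_brute_force()].
#'
#' When the candidate carries no scores and `weight_function` is
#' `"normalized_score"`, each pairwise term uses the input list's own
#' importance curve for both sides (the candidate has no scores of its own to
#' normalise).
#'
#' @param candidate a [ranked_list()] over the ensemble universe.
#' @param ensemble a [rank_ensemble()].
#' @param cfg a [distance_config()].
#' @return non-negative numeric, linear in the ensemble weights.
#' @export
objective_phi <- function(candidate, ensemble, cfg = distance_config()) {
  stopifnot(inherits(ensemble, "rank_ensemble"))
  u <- ensemble_universe(ensemble)
  if (cfg$missing_rank_policy == "strict" &&
      (length(setdiff(u, candidate$items)) || length(setdiff(candidate$items, u)))) {
    stop("candidate must be a permutation of the ensemble universe; ",
         "symmetric difference: ",
         paste(c(setdiff(u, candidate$items), setdiff(candidate$items, u)),
               collapse = ", "))
  }
  total <- 0
  for (i in seq_along(ensemble$lists)) {
    L <- ensemble$lists[[i]]
    d <- if (cfg$metric == "footrule") {
      spearman_footrule(candidate, L, cfg)
    } else if (cfg$weight_function == "normalized_score" &&
               is.null(candidate$scores)) {
      weighted_footrule_shared_curve(candidate, L, cfg)
    } else {
      weighted_footrule(candidate, L, cfg)
    }
    total <- total + ensemble$weights[[i]] * d
  }
  unname(total)
}

# weighted footrule where the reference list's own importance curve is applied
# to both rank arguments (used when the candidate has no scores under
# normalized_score weighting).
weighted_footrule_shared_curve <- function(candidate, L, cfg) {
  u <- sort(unique(c(candidate$items, L$items)))
  r1 <- ranks_on_universe(candidate, u, cfg$missing_rank_policy, paste0("'", L$name, "'"))
  r2 <- ranks_on_universe(L, u, cfg$missing_rank_policy, "'candidate'")
  m <- m_curve(L, cfg$weight_function)
  mm <- c(m, rep(0, max(0, max(r1) - length(m))))
  sum(abs(mm[r1] - mm[r2]) * abs(r1 - r2))
}

# Internal matrix representation of an ensemble for the C++ objective kernel:
# ranks matrix R (n_universe x m); two importance matrices indexed by rank
# (rows 1..n+1, one column per list): Mcand applies to the candidate's ranks,
# Mlist to the input list's ranks (0 at each list's k+1). A scoreless
# candidate under normalized_score weighting borrows each list's own curve,
# mirroring objective_phi() exactly.
ensemble_matrices <- function(ensemble, cfg, universe = NULL) {
  if (is.null(universe)) universe <- ensemble_universe(ensemble)
  m <- length(ensemble$lists)
  n <- length(universe)
  R <- matrix(0L, n, m, dimnames = list(universe, names(ensemble$lists)))
  maxr <- n + 1L
  Mcand <- matrix(0, maxr, m)
  Mlist <- matrix(0, maxr, m)
  cand_linear <- c((n - seq_len(n) + 1) / n, 0)
  for (i in seq_len(m)) {
    L <- ensemble$lists[[i]]
    R[, i] <- ranks_on_universe(L, universe, cfg$missing_rank_policy,
                                "the ensemble universe")
    if (cfg$metric == "weighted_footrule") {
      mc <- m_curve(L, cfg$weight_function)
      Mlist[seq_along(mc), i] <- mc
      if (cfg$weight_function == "linear_rank") {
        Mcand[, i] <- cand_linear
      } else {
        Mcand[seq_along(mc), i] <- mc
      }
    }
  }
  list(universe = universe, R = R, Mcand = Mcand, Mlist = Mlist,
       weights = as.numeric(ensemble$weights),
       weighted = cfg$metric == "weighted_footrule")
}
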