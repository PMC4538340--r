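#' Cross-entropy search parameters
#'
#' Controls for the cross-entropy Monte Carlo search of [aggregate_ce()].
#' Defaults follow common cross-entropy rank-aggregation practice: a sample
#' size that grows with the universe (`max(200, 10 n)`), a 10% elite
#' fraction, smoothing 0.5, and early stopping once the elite-mean objective
#' has not improved for 15 iterations.
#'
#' @param n_samples permutations sampled per iteration; `NULL` means
#'   `max(200, 10 * n)` at run time.
#' @param elite_fraction fraction rho in (0,1) of samples kept as the elite
#'   set; `ceiling(rho * n_samples)` must be >= 1.
#' @param smoothing smoothing weight w in (0,1] for the probability-matrix
#'   update `P <- (1-w) P + w F_elite`.
#' @param max_iterations hard iteration cap.
#' @param stagnation_limit stop after this many iterations without improving
#'   the incumbent objective.
#' @param seed integer RNG seed (required; every run is reproducible).
#' @return an object of class `ce_params`.
#' @export
ce_params <- function(n_samples = NULL, elite_fraction = 0.1, smoothing = 0.5,
                      max_iterations = 100L, stagnation_limit = 15L, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("ce_params(): an integer seed is required for reproducibility")
  }
  if (!is.null(n_samples) && (n_samples < 1 || n_samples != round(n_samples))) {
    stop("n_samples must be a positive integer (or NULL for the default)")
  }
  if (elite_fraction <= 0 || elite_fraction >= 1) {
    stop("elite_fraction must lie in (0, 1)")
  }
  if (smoothing <= 0 || smoothing > 1) stop("smoothing must lie in (0, 1]")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (stagnation_limit < 1) stop("stagnation_limit must be >= 1")
  structure(
    list(n_samples = if (is.null(n_samples)) NULL else as.integer(n_samples),
         elite_fraction = elite_fraction, smoothing = smoothing,
         max_iterations = as.integer(max_iterations),
         stagnation_limit = as.integer(stagnation_limit),
         seed = as.integer(seed)),
    class = "ce_params"
  )
}

new_aggregation_result <- function(best_list, objective, trace, params, method,
                                   ensemble, cfg) {
  structure(
    list(best_list = best_list, objective = objective, trace = trace,
         params = params, method = method, cfg = cfg,
         n = length(best_list$items)),
    class = "aggregation_result"
  )
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf("<aggregation_result> method=%s n=%d Phi=%g\n",
              x$method, x$n, x$objective))
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat(sprintf("  iterations: %d (incumbent Phi %g -> %g)\n",
                nrow(x$trace), x$trace$incumbent_phi[1],
                x$trace$incumbent_phi[nrow(x$trace)]))
  }
  invisible(x)
}

# completed version of a (possibly top-k) list over the full universe:
# missing items appended in id order. Used only to seed the incumbent.
complete_over_universe <- function(list, universe) {
  extra <- sort(setdiff(universe, list$items))
  ranked_list(c(intersect(list$items, universe), extra), name = list$name)
}

#' Consensus ranking by cross-entropy Monte Carlo
#'
#' Searches for the permutation \eqn{\delta^*} minimising the aggregation
#' objective \eqn{\Phi(\delta) = \sum_i w_i d(\delta, L_i)}
#' (see [objective_phi()]). The search maintains an item-by-position
#' probability matrix `P`, initially uniform. Each iteration samples
#' `n_samples` permutations position by position from `P` (renormalised over
#' unused items), evaluates \eqn{\Phi}, refits `P` to the empirical
#' frequencies of the elite (best `ceiling(rho * n_samples)`) with smoothing,
#' and stops at the iteration cap or once the elite-mean objective has gone
#' `stagnation_limit` iterations without improving (the elite mean flattens
#' exactly when the sampling distribution has converged, whereas the best
#' sample is too noisy a stopping signal at realistic list lengths). The
#' returned list is the best permutation
#' ever evaluated — the input lists and the weighted mean-rank (Borda)
#' ordering are evaluated as candidates up front and seed the initial
#' probability matrix as an iteration-0 elite set, so the consensus is never
#' worse than the best input list or the Borda heuristic.
#'
#' @param ensemble a [rank_ensemble()].
#' @param cfg a [distance_config()].
#' @param params a [ce_params()] (the seed is mandatory).
#' @return an `aggregation_result`: `best_list` (a [ranked_list()] named
#'   `"consensus"`), `objective`, a per-iteration `trace` data frame, the
#'   parameters, and `method = "cross_entropy"`.
#' @export
aggregate_ce <- function(ensemble, cfg = distance_config(), params) {
  stopifnot(inherits(ensemble, "rank_ensemble"))
  if (!inherits(params, "ce_params")) stop("params must be a ce_params object")
  mats <- ensemble_matrices(ensemble, cfg)
  universe <- mats$universe
  n <- length(universe)
  if (n == 0L) stop("ensemble universe is empty")
  n_samples <- if (is.null(params$n_samples)) max(200L, 10L * n) else params$n_samples
  n_elite <- ceiling(params$elite_fraction * n_samples)
  if (n_elite < 1) stop("elite_fraction * n_samples must round up to >= 1")

  phi_of <- function(perm_rows) {
    phi_batch_cpp(perm_rows, mats$R, mats$Mcand, mats$Mlist, mats$weights,
                  mats$weighted)
  }

  # seed the incumbent with the (completed) input lists plus the
  # weight-averaged mean-rank (Borda) ordering, a strong heuristic start for
  # footrule-type objectives
  seed_perms <- do.call(rbind, lapply(ensemble$lists, function(L) {
    match(complete_over_universe(L, universe)$items, universe)
  }))
  mean_ranks <- as.numeric(mats$R %*% mats$weights) / sum(mats$weights)
  borda <- order(mean_ranks, universe, method = "radix")
  seed_perms <- rbind(seed_perms, borda)
  storage.mode(seed_perms) <- "integer"
  seed_phi <- phi_of(seed_perms)
  best_idx <- which.min(seed_phi)
  incumbent <- seed_perms[best_idx, ]
  incumbent_phi <- seed_phi[best_idx]

  if (n == 1L) {
    best <- ranked_list(universe, name = "consensus")
    return(new_aggregation_result(best, objective_phi(best, ensemble, cfg),
                                  data.frame(iteration = integer(),
                                             best_phi = numeric(),
                                             elite_mean_phi = numeric(),
                                             incumbent_phi = numeric()),
                                  params, "cross_entropy", ensemble, cfg))
  }

  set.seed(params$seed)
  # warm start: treat the input lists as an elite set at iteration 0, so the
  # search explores around the inputs instead of from a flat distribution
  P <- (1 - params$smoothing) * matrix(1 / n, n, n) +
    params$smoothing * elite_frequency_cpp(seed_perms,
                                           seq_len(nrow(seed_perms)), n)
  floor_p <- 1e-12
  trace <- vector("list", params$max_iterations)
  # stagnation is judged on the elite-mean objective: it decreases almost
  # monotonically while the sampling distribution is still concentrating and
  # flattens only at convergence, so it neither stops the search during the
  # noisy early phase (as a best-sample criterion does at n ~ 100) nor keeps
  # burning iterations after the distribution has frozen
  best_elite_mean <- Inf
  stagnant <- 0L
  iters <- 0L
  for (it in seq_len(params$max_iterations)) {
    P[P < floor_p] <- floor_p
    P <- sweep(P, 2, colSums(P), "/")
    perms <- sample_permutations_cpp(P, n_samples)
    phi <- phi_of(perms)
    ord <- order(phi)
    elite <- ord[seq_len(n_elite)]
    if (mean(phi[elite]) < best_elite_mean - 1e-12) {
      best_elite_mean <- mean(phi[elite])
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    if (phi[ord[1]] < incumbent_phi) {
      incumbent_phi <- phi[ord[1]]
      incumbent <- perms[ord[1], ]
    }
    trace[[it]] <- data.frame(iteration = it, best_phi = phi[ord[1]],
                              elite_mean_phi = mean(phi[elite]),
                              incumbent_phi = incumbent_phi)
    iters <- it
    if (incumbent_phi == 0 || stagnant >= params$stagnation_limit) break
    F <- elite_frequency_cpp(perms, as.integer(elite), n)
    P <- (1 - params$smoothing) * P + params$smoothing * F
  }
  trace <- do.call(rbind, trace[seq_len(iters)])

  best <- ranked_list(universe[incumbent], name = "consensus")
  objective <- objective_phi(best, ensemble, cfg)
  stopifnot(isTRUE(all.equal(objective, unname(incumbent_phi))))
  new_aggregation_result(best, objective, trace, params, "cross_entropy",
                         ensemble, cfg)
}

# all permutations of 1..n in lexicographic order, one per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    blk <- nrow(sub)
    out[row:(row + blk - 1L), 1] <- first
    out[row:(row + blk - 1L), -1] <- matrix(rest[sub], blk, n - 1L)
    row <- row + blk
  }
  out
}

#' Exact consensus by exhaustive enumeration
#'
#' Global minimiser of the aggregation objective over all permutations of the
#' universe. Intended as a small-scale oracle: refuses universes larger than
#' 8 items (8! = 40320 candidates). Ties are broken deterministically by
#' returning the lexicographically smallest optimal permutation (item ids in
#' ascending order).
#'
#' @inheritParams aggregate_ce
#' @return an `aggregation_result` with `method = "brute_force"`.
#' @export
aggregate_brute_force <- function(ensemble, cfg = distance_config()) {
  stopifnot(inherits(ensemble, "rank_ensemble"))
  mats <- ensemble_matrices(ensemble, cfg)
  universe <- mats$universe
  n <- length(universe)
  if (n > 8L) {
    stop("aggregate_brute_force() enumerates all n! permutations and is ",
         "limited to n <= 8 items (got ", n, "); use aggregate_ce() instead")
  }
  perms <- all_permutations(n)
  phi <- phi_batch_cpp(perms, mats$R, mats$Mcand, mats$Mlist, mats$weights,
                       mats$weighted)
  best_row <- which.min(phi) # first minimum = lexicographically smallest
  best <- ranked_list(universe[perms[best_row, ]], name = "consensus")
  objective <- objective_phi(best, ensemble, cfg)
  new_aggregation_result(best, objective,
                         data.frame(iteration = 1L, best_phi = objective,
                                    elite_mean_phi = objective,
                                    incumbent_phi = objective),
                         NULL, "brute_force", ensemble, cfg)
}
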