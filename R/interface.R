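#' Recompute a benchmark table of per-subset mean nDCG from published ranks
#'
#' Harness for replicating a published docking-aggregation benchmark from its
#' supplementary rank table: a file (or data frame) with one row per
#' compound, a reference rank column, and one rank column per scoring
#' function. For every relevance convention requested, the harness recomputes
#' the mean nDCG of each single scorer and of every aggregated scorer subset
#' against the reference. When the published nDCG values are supplied via
#' `reported`, the convention minimising the mean absolute deviation from
#' them is reported — the harness never silently asserts a match, because
#' published nDCG values depend on the (often unstated) relevance convention.
#'
#' @param ranks data frame or path to a TSV/CSV with an `item` column, the
#'   reference rank column and scorer rank columns (ranks are 1-based
#'   permutations of 1..n).
#' @param ref_col name of the reference rank column.
#' @param scorer_cols names of the scorer rank columns; defaults to all
#'   remaining columns. A named character vector relabels them
#'   (`c(A = "ASE_rank", ...)`).
#' @param schemes relevance conventions to sweep.
#' @param params a [ce_params()] for the aggregation runs.
#' @param cfg a [distance_config()].
#' @param reported optional named numeric vector, subset label (e.g.
#'   `"A+B+D"`) -> published mean nDCG, for convention comparison.
#' @param sep field separator when `ranks` is a path.
#' @return list: `table` (data frame `subset`, `size`, `scheme`,
#'   `mean_ndcg`), `by_scheme` (list of sorted per-convention tables),
#'   `best_scheme` and `comparison` when `reported` is given, and `params`.
#' @export
replicate_table1 <- function(ranks, ref_col, scorer_cols = NULL,
                             schemes = c("linear", "exponential"),
                             params, cfg = distance_config(),
                             reported = NULL, sep = "\t") {
  if (is.character(ranks)) {
    ranks <- utils::read.table(ranks, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!"item" %in% names(ranks)) stop("rank table needs an 'item' column")
  if (!ref_col %in% names(ranks)) {
    stop("reference column '", ref_col, "' not found")
  }
  if (is.null(scorer_cols)) {
    scorer_cols <- setdiff(names(ranks), c("item", ref_col))
  }
  missing <- setdiff(scorer_cols, names(ranks))
  if (length(missing)) stop("scorer column(s) not found: ",
                            paste(missing, collapse = ", "))
  labels <- if (!is.null(names(scorer_cols)) && all(nzchar(names(scorer_cols)))) {
    names(scorer_cols)
  } else {
    scorer_cols
  }
  n <- nrow(ranks)
  rank_to_list <- function(col, name) {
    r <- as.integer(ranks[[col]])
    bad <- which(is.na(r))
    if (length(bad)) {
      stop("malformed ranks in column '", col, "' at row(s): ",
           paste(bad, collapse = ", "))
    }
    if (!identical(sort(r), seq_len(n))) {
      stop("column '", col, "' is not a permutation of 1..", n)
    }
    ranked_list(ranks$item[order(r)], name = name)
  }
  ref_list <- rank_to_list(ref_col, "reference")
  # relevance schemes operate on rank position only (no activities in S1-style
  # files), so build the reference as a ranked_list and grade from position.
  scorer_lists <- Map(rank_to_list, scorer_cols, labels)
  names(scorer_lists) <- labels

  k <- length(labels)
  subsets <- unlist(lapply(seq_len(k), function(sz) {
    utils::combn(labels, sz, simplify = FALSE)
  }), recursive = FALSE)

  consensus_for <- list()
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    lab <- subset_label(sub)
    if (length(sub) == 1L) {
      consensus_for[[lab]] <- scorer_lists[[sub]]
    } else {
      sub_seed <- (params$seed + i) %% .Machine$integer.max
      res <- aggregate_ce(rank_ensemble(scorer_lists[sub]), cfg, ce_params(
        n_samples = params$n_samples, elite_fraction = params$elite_fraction,
        smoothing = params$smoothing, max_iterations = params$max_iterations,
        stagnation_limit = params$stagnation_limit, seed = sub_seed))
      consensus_for[[lab]] <- res$best_list
    }
  }

  rows <- list()
  by_scheme <- list()
  for (scheme in schemes) {
    rel <- relevance_from_reference(ref_list, scheme = scheme)
    tab <- data.frame(
      subset = names(consensus_for),
      size = vapply(subsets, length, integer(1)),
      scheme = scheme,
      mean_ndcg = vapply(consensus_for, mean_ndcg, numeric(1), rel = rel)
    )
    by_scheme[[scheme]] <- tab[order(-tab$mean_ndcg, tab$subset), ]
    rows[[scheme]] <- tab
  }
  out <- list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              by_scheme = by_scheme, params = params)
  if (!is.null(reported)) {
    dev <- vapply(schemes, function(scheme) {
      tab <- by_scheme[[scheme]]
      common <- intersect(tab$subset, names(reported))
      if (!length(common)) return(NA_real_)
      mean(abs(tab$mean_ndcg[match(common, tab$subset)] - reported[common]))
    }, numeric(1))
    out$comparison <- data.frame(scheme = schemes, mean_abs_dev = dev)
    out$best_scheme <- schemes[which.min(dev)]
  }
  out
}

#' Detection-rate replication from a ranked, flagged ingredient file
#'
#' Harness for a published screen-validation table: a file with one row per
#' ranked ingredient and a positive flag marking literature-reported
#' interactions. Computes the detection rate at the requested top fraction
#' plus the full rate-versus-depth curve.
#'
#' @param ranked data frame or file path with columns for item, final rank
#'   and positive flag.
#' @param top_fraction fraction of the list to inspect (default 0.1).
#' @param item_col,rank_col,flag_col column names (declared, not guessed).
#' @param positive_values flag values counted as positive (default `"Y"`,
#'   `TRUE`, `1`).
#' @param fractions depth grid for the curve.
#' @param sep field separator when `ranked` is a path.
#' @return list: `detection_rate`, `cutoff`, `n`, `n_positives`, `curve`
#'   (data frame from [detection_curve()]).
#' @export
replicate_detection <- function(ranked, top_fraction = 0.1,
                                item_col = "item", rank_col = "rank",
                                flag_col = "positive",
                                positive_values = c("Y", "TRUE", "1"),
                                fractions = seq(0.05, 1, by = 0.05),
                                sep = "\t") {
  if (is.character(ranked)) {
    ranked <- utils::read.table(ranked, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE, check.names = FALSE)
  }
  for (col in c(item_col, rank_col, flag_col)) {
    if (!col %in% names(ranked)) stop("column '", col, "' not found")
  }
  r <- as.integer(ranked[[rank_col]])
  if (any(is.na(r)) || !identical(sort(r), seq_len(nrow(ranked)))) {
    stop("rank column must be a permutation of 1..n")
  }
  rl <- ranked_list(ranked[[item_col]][order(r)], name = "final")
  flags <- as.character(ranked[[flag_col]])
  positives <- trimws(as.character(ranked[[item_col]]))[
    toupper(flags) %in% toupper(positive_values)]
  list(detection_rate = detection_rate(rl, positives, top_fraction),
       cutoff = max(1L, floor(top_fraction * length(rl$items))),
       n = length(rl$items), n_positives = length(positives),
       curve = detection_curve(rl, positives, fractions))
}

#' Write a machine-readable run report
#'
#' Every stochastic command of the CLI records its effective parameters,
#' seed, input file hashes and headline outputs as JSON so a run can be
#' reproduced bit for bit.
#'
#' @param path output JSON path.
#' @param params named list of effective parameters (must include any seed).
#' @param inputs character vector of input file paths (hashed with md5).
#' @param outputs named list of headline outputs.
#' @export
write_run_report <- function(path, params = list(), inputs = character(0),
                             outputs = list()) {
  hashes <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  report <- list(params = params,
                 inputs = as.list(stats::setNames(hashes, inputs)),
                 outputs = outputs,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
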