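#' Ranked lists of items
#'
#' A `ranked_list` is a named total ordering of item identifiers: position 1 is
#' the best item (most active compound, lowest docking energy). Identifiers are
#' case-sensitive, whitespace-trimmed character strings, unique within the
#' list. Optionally the list carries the raw scores that produced the ordering.
#'
#' @param items character vector of item ids, best first.
#' @param name label for the list (e.g. a scoring-function name like `"ASE"`).
#' @param scores optional named numeric vector of raw scores for the items
#'   (same direction convention as the ordering).
#' @param direction direction convention of `scores`: `"lower_is_better"`
#'   (docking energies, EC50) or `"higher_is_better"`.
#' @return an object of class `ranked_list`.
#' @export
ranked_list <- function(items, name = "ranked", scores = NULL,
                        direction = c("lower_is_better", "higher_is_better")) {
  direction <- match.arg(direction)
  items <- trimws(as.character(items))
  if (length(items) == 0L) stop("a ranked list must contain at least one item")
  if (any(!nzchar(items))) stop("item ids must be non-empty strings")
  dup <- unique(items[duplicated(items)])
  if (length(dup)) {
    stop("duplicate item ids in ranked list: ", paste(dup, collapse = ", "))
  }
  if (!is.null(scores)) {
    scores <- scores[items]
    if (any(is.na(scores))) stop("scores missing for some items in the list")
    names(scores) <- items
  }
  structure(
    list(name = as.character(name)[1], items = items, scores = scores,
         direction = direction),
    class = "ranked_list"
  )
}

#' @export
print.ranked_list <- function(x, n = 6L, ...) {
  cat(sprintf("<ranked_list '%s'> %d items\n", x$name, length(x$items)))
  k <- min(n, length(x$items))
  for (i in seq_len(k)) {
    if (is.null(x$scores)) {
      cat(sprintf("  %3d. %s\n", i, x$items[i]))
    } else {
      cat(sprintf("  %3d. %-20s %g\n", i, x$items[i], x$scores[[i]]))
    }
  }
  if (length(x$items) > k) cat(sprintf("  ... %d more\n", length(x$items) - k))
  invisible(x)
}

#' @export
length.ranked_list <- function(x) length(x$items)

#' Rank positions of items in a ranked list
#'
#' @param list a [ranked_list()].
#' @param ids optional subset of ids; defaults to all items.
#' @return named integer vector of 1-based ranks (1 = best).
#' @export
rank_of <- function(list, ids = NULL) {
  r <- seq_along(list$items)
  names(r) <- list$items
  if (is.null(ids)) return(r)
  missing <- setdiff(ids, list$items)
  if (length(missing)) {
    stop("ids not present in list '", list$name, "': ",
         paste(missing, collapse = ", "))
  }
  r[ids]
}

#' Convert raw scores to a ranked list
#'
#' Deterministic score-to-rank conversion: the best score receives rank 1 and
#' ties are broken by ascending item id (C-locale byte order), so the result
#' is a total order reproducible across platforms.
#'
#' @param scores named numeric vector, item id -> score; all finite.
#' @param direction `"lower_is_better"` (default; docking energies, EC50) or
#'   `"higher_is_better"`.
#' @param name label for the resulting list.
#' @return a [ranked_list()] carrying the scores.
#' @examples
#' scores_to_rank(c(a = -9.1, b = -7.2, c = -8.0))$items  # "a" "c" "b"
#' @export
scores_to_rank <- function(scores,
                           direction = c("lower_is_better", "higher_is_better"),
                           name = "scores") {
  direction <- match.arg(direction)
  if (length(scores) == 0L) stop("cannot rank an empty score map")
  ids <- trimws(names(scores))
  if (is.null(names(scores)) || any(!nzchar(ids))) {
    stop("scores must be a named vector with non-empty item ids")
  }
  bad <- ids[!is.finite(scores)]
  if (length(bad)) {
    stop("non-finite score for item(s): ", paste(bad, collapse = ", "))
  }
  s <- as.numeric(scores)
  key <- if (direction == "lower_is_better") s else -s
  ord <- order(key, ids, method = "radix")
  ranked_list(ids[ord], name = name,
              scores = stats::setNames(s, ids)[ord], direction = direction)
}

#' Restrict a ranked list to a sub-universe
#'
#' Keeps only the given ids, preserving their relative order and recompacting
#' ranks to `1..|universe|`.
#'
#' @param list a [ranked_list()].
#' @param universe character vector of ids, all present in `list`.
#' @return a [ranked_list()] over `universe`.
#' @export
restrict <- function(list, universe) {
  universe <- trimws(as.character(universe))
  missing <- setdiff(universe, list$items)
  if (length(missing)) {
    stop("restrict(): ids not in list '", list$name, "': ",
         paste(missing, collapse = ", "))
  }
  keep <- list$items[list$items %in% universe]
  ranked_list(keep, name = list$name,
              scores = if (is.null(list$scores)) NULL else list$scores[keep],
              direction = list$direction)
}

#' Score tables: items x scoring functions
#'
#' Container for the raw per-scorer values of a docking run: a complete
#' numeric matrix of items by scoring functions, with a direction convention
#' per scorer (docking energies default to lower-is-better).
#'
#' @param values numeric matrix, rownames = item ids, colnames = scorer names.
#' @param directions direction per scorer: a single string recycled, or a
#'   named character vector over the scorer names.
#' @return an object of class `score_table` with fields `universe`, `scorers`,
#'   `values`, `directions`.
#' @export
score_table <- function(values, directions = "lower_is_better") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("score table needs item rownames and scorer colnames")
  }
  rownames(values) <- trimws(rownames(values))
  if (anyDuplicated(rownames(values))) stop("duplicate item ids in score table")
  if (anyDuplicated(colnames(values))) stop("scorer names must be unique")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    stop("non-finite scores, e.g. item '", rownames(values)[bad[1, 1]],
         "' scorer '", colnames(values)[bad[1, 2]], "'")
  }
  scorers <- colnames(values)
  if (is.null(names(directions))) {
    directions <- stats::setNames(rep(directions, length.out = length(scorers)),
                                  scorers)
  } else {
    directions <- directions[scorers]
    if (any(is.na(directions))) stop("directions missing for some scorers")
  }
  ok <- directions %in% c("lower_is_better", "higher_is_better")
  if (!all(ok)) stop("invalid direction: ", paste(directions[!ok], collapse = ", "))
  structure(
    list(universe = rownames(values), scorers = scorers, values = values,
         directions = directions),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d items x %d scorers (%s)\n",
              length(x$universe), length(x$scorers),
              paste(x$scorers, collapse = ", ")))
  invisible(x)
}

#' Per-scorer ranked lists from a score table
#'
#' @param table a [score_table()].
#' @param scorers subset of scorer names; defaults to all.
#' @return named list of [ranked_list()] objects.
#' @export
ranks_from_table <- function(table, scorers = NULL) {
  stopifnot(inherits(table, "score_table"))
  if (is.null(scorers)) scorers <- table$scorers
  missing <- setdiff(scorers, table$scorers)
  if (length(missing)) stop("unknown scorer(s): ", paste(missing, collapse = ", "))
  out <- lapply(scorers, function(sc) {
    scores_to_rank(stats::setNames(table$values[, sc], table$universe),
                   direction = table$directions[[sc]], name = sc)
  })
  stats::setNames(out, scorers)
}

#' Weighted ensembles of ranked lists
#'
#' Bundles one or more ranked lists (the views to be fused) with positive
#' per-list weights. In strict mode all lists must be permutations of the
#' identical universe; top-k lists are admitted only under the
#' `assign_k_plus_1` missing-rank policy of [distance_config()].
#'
#' @param lists a list of [ranked_list()] objects (or a single one).
#' @param weights optional named numeric vector, list-name -> weight > 0;
#'   defaults to 1 for every list.
#' @return an object of class `rank_ensemble`.
#' @export
rank_ensemble <- function(lists, weights = NULL) {
  if (inherits(lists, "ranked_list")) lists <- list(lists)
  if (length(lists) == 0L) stop("ensemble needs at least one ranked list")
  ok <- vapply(lists, inherits, logical(1), "ranked_list")
  if (!all(ok)) stop("all ensemble members must be ranked_list objects")
  nms <- vapply(lists, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("list names in an ensemble must be unique")
  names(lists) <- nms
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(lists)), nms)
  if (is.null(names(weights))) names(weights) <- nms
  weights <- weights[nms]
  if (any(is.na(weights)) || any(weights <= 0)) {
    stop("every list needs a positive weight")
  }
  structure(list(lists = lists, weights = weights), class = "rank_ensemble")
}

#' @export
print.rank_ensemble <- function(x, ...) {
  cat(sprintf("<rank_ensemble> %d lists: %s\n", length(x$lists),
              paste(sprintf("%s (n=%d, w=%g)", names(x$lists),
                            vapply(x$lists, length, integer(1)), x$weights),
                    collapse = ", ")))
  invisible(x)
}

ensemble_universe <- function(ensemble) {
  sort(unique(unlist(lapply(ensemble$lists, function(l) l$items))))
}

#' Read / write ranked list TSV
#'
#' The on-disk format is a two-column tab-separated file with a header line
#' `item<TAB>rank`; the writer emits ranks 1..n in rank order with LF line
#' endings.
#'
#' @param path file path.
#' @param name label for the list; defaults to the file name.
#' @return `read_ranked_list()` returns a [ranked_list()].
#' @export
read_ranked_list <- function(path, name = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("item", "rank") %in% names(df))) {
    stop("ranked list file must have header columns 'item' and 'rank': ", path)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  r <- as.integer(df$rank)
  if (any(is.na(r)) || any(sort(r) != seq_along(r))) {
    stop("rank column must be a permutation of 1..n in ", path)
  }
  ranked_list(df$item[order(r)], name = name)
}

#' @param list a [ranked_list()] to write.
#' @rdname read_ranked_list
#' @export
write_ranked_list <- function(list, path) {
  df <- data.frame(item = list$items, rank = seq_along(list$items))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read a score table from CSV/TSV
#'
#' First column `item`, one numeric column per scorer. Rows with missing
#' values are rejected. Per-scorer directions come from `directions` or from a
#' sidecar JSON/YAML config (a map scorer -> direction).
#'
#' @param path CSV (default) or TSV file.
#' @param directions as in [score_table()].
#' @param sep field separator; `","` or `"\t"`.
#' @param config optional path to a JSON/YAML sidecar with a `directions` map.
#' @return a [score_table()].
#' @export
read_score_table <- function(path, directions = "lower_is_better", sep = ",",
                             config = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "item") stop("first column of a score table must be 'item'")
  if (anyNA(df)) {
    stop("incomplete rows in score table ", path, ": ",
         paste(df$item[!stats::complete.cases(df)], collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$item
  if (!is.null(config)) {
    cfg <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading a YAML sidecar requires the 'yaml' package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    if (!is.null(cfg$directions)) directions <- unlist(cfg$directions)
  }
  score_table(m, directions = directions)
}

#' @param table a [score_table()] to write.
#' @rdname read_score_table
#' @export
write_score_table <- function(table, path, sep = ",") {
  df <- data.frame(item = table$universe, table$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
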