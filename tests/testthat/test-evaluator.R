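test_that("relevance schemes follow their closed forms", {
  ref <- reference_rank(c(x = 0.2, y = 1.5, z = 30), name = "EC50")
  expect_equal(ref$items, c("x", "y", "z"))
  expect_equal(relevance_from_reference(ref), c(x = 3, y = 2, z = 1))
  expect_equal(relevance_from_reference(ref, "exponential"),
               c(x = 1, y = 0.5, z = 0.25))
  # 10 uM active/inactive split
  expect_equal(relevance_from_reference(ref, "binary", threshold = 10),
               c(x = 1, y = 1, z = 0))
  expect_error(relevance_from_reference(ref, "binary"), "threshold")

  set.seed(41)
  n <- 17
  ref2 <- reference_rank(stats::setNames(runif(n), sprintf("c%02d", 1:n)))
  expect_equal(sum(relevance_from_reference(ref2)), n * (n + 1) / 2)
})

test_that("dcg matches term-by-term evaluation", {
  expect_equal(dcg(5, p = 1), 5)
  rel <- c(3, 2, 3, 0, 1, 2)
  # independent term-by-term accumulation
  manual <- rel[1]
  for (i in 2:6) manual <- manual + rel[i] / log2(i)
  expect_equal(dcg(rel, 6), manual)
  expect_equal(dcg(rel, 6), 8.0972, tolerance = 1e-3)
  # p = 2 is the undiscounted sum of the first two relevances
  set.seed(42)
  r <- runif(8)
  expect_equal(dcg(r, 2), r[1] + r[2])
  expect_error(dcg(rel, 7), "1..6")
  expect_error(dcg(rel, 0), "1..6")
})

test_that("ndcg normalises against the ideal ordering", {
  rel <- c(a = 3, b = 2, c = 3, d = 0, e = 1, f = 2)
  cand <- ranked_list(names(rel), name = "given")
  expect_equal(ndcg(cand, rel, 6), 0.9315, tolerance = 1e-3)
  # independent check: DCG of given order over DCG of sorted order
  ideal <- sort(unname(rel), decreasing = TRUE)
  expect_equal(ndcg(cand, rel, 6), dcg(unname(rel), 6) / dcg(ideal, 6))

  perfect <- ranked_list(names(sort(rel, decreasing = TRUE)), name = "ideal")
  ev <- evaluate_ranking(perfect, rel)
  expect_true(all(abs(ev$by_position$ndcg - 1) < 1e-12))
  expect_true(all(ev$by_position$idcg > 0))
  expect_true(all(ev$by_position$ndcg >= 0 & ev$by_position$ndcg <= 1))

  strict_rel <- c(p = 4, q = 3, r = 2, s = 1)
  fwd <- ranked_list(names(strict_rel), name = "fwd")
  expect_lt(ndcg(ranked_list(rev(names(strict_rel)), name = "rev"),
                 strict_rel, 4),
            ndcg(fwd, strict_rel, 4))
  expect_error(evaluate_ranking(fwd, c(p = 0, q = 0, r = 0, s = 0)),
               "all-zero")
})

test_that("mean ndcg averages the per-position values", {
  rel <- c(a = 2, b = 1)
  expect_equal(mean_ndcg(ranked_list(c("b", "a"), name = "swap"), rel), 0.75)
  expect_equal(mean_ndcg(ranked_list(c("a", "b"), name = "fwd"), rel), 1)
  set.seed(43)
  rel2 <- stats::setNames(sample(0:5, 10, replace = TRUE) + 0.0,
                          sprintf("c%02d", 1:10))
  rel2[1] <- 3 # ensure not all zero
  cand <- ranked_list(sample(names(rel2)), name = "rand")
  ev <- evaluate_ranking(cand, rel2)
  expect_gte(ev$mean_ndcg, min(ev$by_position$ndcg))
  expect_lte(ev$mean_ndcg, max(ev$by_position$ndcg))
})

test_that("binary relevance gives ndcg 1 exactly when positives lead", {
  rel <- c(a = 1, b = 1, c = 0, d = 0)
  expect_equal(ndcg(ranked_list(c("b", "a", "d", "c"), name = "ok"), rel, 4), 1)
  expect_lt(ndcg(ranked_list(c("a", "c", "b", "d"), name = "mix"), rel, 4), 1)
})

test_that("ndcg is invariant under relabeling of item ids", {
  set.seed(44)
  rel <- stats::setNames(runif(8), sprintf("i%d", 1:8))
  cand <- ranked_list(sample(names(rel)), name = "c")
  relab <- stats::setNames(sprintf("z%d", sample(8)), names(rel))
  cand2 <- ranked_list(unname(relab[cand$items]), name = "c2")
  rel2 <- stats::setNames(unname(rel), unname(relab[names(rel)]))
  expect_equal(mean_ndcg(cand2, rel2), mean_ndcg(cand, rel))
})

test_that("detection rate counts positives in the top slice", {
  f <- system.file("extdata", "pxr_top10_ingredients.tsv", package = "dra")
  tab <- utils::read.delim(f)
  rl <- ranked_list(tab$item[order(tab$rank)], name = "final")
  expect_equal(detection_rate(rl, tab$item[tab$positive == "Y"], 1.0), 0.6)

  expect_equal(detection_rate(rl, rl$items, 0.3), 1.0)
  expect_equal(detection_rate(rl, rl$items, 1.0), 1.0)
  expect_error(detection_rate(rl, c("nope")), "nope")
  expect_error(detection_rate(rl, rl$items[1], 0), "top_fraction")
})

test_that("full-depth detection rate equals prevalence for any ranking", {
  set.seed(45)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    rl <- random_ranked_list(n)
    pos <- sample(rl$items, sample(3:10, 1))
    expect_equal(detection_rate(rl, pos, 1.0), length(pos) / n)
  }
})

test_that("random rankings detect at the prevalence rate on average", {
  set.seed(46)
  ids <- sprintf("i%03d", 1:100)
  pos <- ids[1:20]
  rates <- replicate(200, {
    detection_rate(ranked_list(sample(ids), name = "r"), pos, 0.1)
  })
  # hypergeometric expectation is the prevalence, 0.2
  expect_equal(mean(rates), 0.2, tolerance = 0.03)
})

test_that("subset sweep evaluates singletons directly and ranks true scorers first", {
  set.seed(47)
  n <- 12
  ids <- sprintf("c%02d", 1:n)
  act <- stats::setNames(sort(runif(n)), ids) # c01 most potent
  ref <- reference_rank(act)
  # scorer A reproduces the reference; B is its reversal; C is noise
  vals <- cbind(A = seq_len(n), B = rev(seq_len(n)), C = rnorm(n))
  rownames(vals) <- ids
  tab <- score_table(vals)
  sw <- subset_sweep(tab, ref, params = ce_params(seed = 9))
  expect_equal(nrow(sw), 7) # 2^3 - 1
  expect_equal(sw$subset[1], "A")
  expect_equal(sw$mean_ndcg[1], 1.0)
  expect_gt(sw$mean_ndcg[sw$subset == "A"], sw$mean_ndcg[sw$subset == "B"])
  rel <- relevance_from_reference(ref)
  for (sc in c("A", "B", "C")) {
    direct <- mean_ndcg(ranks_from_table(tab)[[sc]], rel)
    expect_equal(sw$mean_ndcg[sw$subset == sc], direct)
  }
  expect_error(subset_sweep(score_table(vals[, 1, drop = FALSE]), ref,
                            params = ce_params(seed = 1)),
               "at least 2")
})

test_that("detection curve is monotone in cutoff bookkeeping", {
  set.seed(48)
  rl <- random_ranked_list(40)
  pos <- sample(rl$items, 8)
  cv <- detection_curve(rl, pos, fractions = c(0.1, 0.5, 1.0))
  expect_equal(cv$cutoff, c(4, 20, 40))
  expect_equal(cv$detection_rate[3], 0.2)
})
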