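test_that("pair judgments follow the level rules", {
  labels <- data.frame(
    id = c("q", "t_fam", "t_sf", "t_fold", "t_other"),
    family = c("f1", "f1", "f2", "f3", "f9"),
    superfamily = c("s1", "s1", "s1", "s2", "s9"),
    fold = c("F1", "F1", "F1", "F1", "F9"),
    stringsAsFactors = FALSE)
  res <- data.frame(query = "q",
                    target = c("q", "t_fam", "t_sf", "t_fold", "t_other"),
                    similarity = c(1, 0.9, 0.8, 0.7, 0.6))
  expect_equal(judge_pairs(res, labels, "family")$label,
               c("ignore", "TP", "ignore", "ignore", "FP"))
  expect_equal(judge_pairs(res, labels, "superfamily")$label,
               c("ignore", "ignore", "TP", "ignore", "FP"))
  expect_equal(judge_pairs(res, labels, "fold")$label,
               c("ignore", "ignore", "ignore", "TP", "FP"))
  expect_error(judge_pairs(data.frame(query = "q", target = "nope",
                                      similarity = 1), labels, "fold"),
               "missing label for nope")
})

test_that("TM-score judgments use a strict 0.5 cutoff", {
  tm <- data.frame(query = "q", target = c("a", "b", "c"),
                   tm_score = c(0.51, 0.5, 0.2))
  res <- data.frame(query = "q", target = c("a", "b", "c"),
                    similarity = c(0.9, 0.8, 0.7))
  expect_equal(judge_pairs(res, tm, "tm_score")$label, c("TP", "FP", "FP"))
  expect_error(judge_pairs(data.frame(query = "q", target = "d",
                                      similarity = 1), tm, "tm_score"),
               "missing TM-score")
})

test_that("sensitivity to the first FP matches hand-counted examples", {
  expect_equal(sensitivity_to_first_fp(c("TP", "TP", "FP", "TP")), 2 / 3)
  expect_equal(sensitivity_to_first_fp(c("TP", "TP", "TP", "TP")), 1)
  expect_equal(sensitivity_to_first_fp(c("FP", "TP")), 0)
  expect_true(is.na(sensitivity_to_first_fp(c("FP", "FP"))))
  # truncated lists: the denominator can exceed the retrieved TPs
  expect_equal(sensitivity_to_first_fp(c("TP", "FP"), total_tp = 4), 1 / 4)
})

test_that("mean sensitivity averages per-query values and excludes zero-TP queries", {
  judged <- data.frame(
    query = c("q1", "q1", "q2", "q2", "q3"),
    target = c("a", "b", "a", "b", "a"),
    similarity = c(0.9, 0.8, 0.9, 0.8, 0.9),
    label = c("TP", "FP", "FP", "TP", "FP"))
  out <- auroc_mean_sensitivity(judged)
  expect_equal(as.numeric(out), 0.5)          # (1 + 0) / 2
  expect_equal(attr(out, "n_excluded"), 1L)   # q3 has no TPs
})

test_that("average precision matches the hand example and edge orderings", {
  one_query <- function(labels) {
    data.frame(query = "q", target = paste0("t", seq_along(labels)),
               similarity = rev(seq_along(labels)), label = labels)
  }
  expect_equal(as.numeric(mean_average_precision(one_query(c("TP", "FP", "TP")))),
               (1 + 2 / 3) / 2)
  expect_equal(as.numeric(mean_average_precision(one_query(rep("TP", 5)))), 1)
  n <- 6
  worst <- one_query(c(rep("FP", n - 1), "TP"))
  expect_equal(as.numeric(mean_average_precision(worst)), 1 / n)
})

test_that("precision at k counts top-k TPs with short-list padding", {
  judged <- data.frame(
    query = rep(c("q1", "q2"), each = 3),
    target = rep(c("a", "b", "c"), 2),
    similarity = rep(c(0.9, 0.8, 0.7), 2),
    label = c("TP", "TP", "FP", "TP", "FP", "FP"))
  expect_equal(as.numeric(precision_at_k(judged, 1)), 1)
  expect_equal(as.numeric(precision_at_k(judged, 3)), (2 / 3 + 1 / 3) / 2)
  # lists shorter than k count missing slots as non-relevant
  expect_equal(as.numeric(precision_at_k(judged, 10)), (2 / 10 + 1 / 10) / 2)
})

test_that("rank metrics agree with definitional oracles on random fixtures", {
  for (seed in 41:43) {
    fx <- random_judged_fixture(seed)
    judged <- judge_pairs(fx$results, fx$labels, "fold")
    judged <- judged[judged$label != "ignore", ]

    per_query <- split(judged, judged$query)
    o_sens <- vapply(per_query, function(df) {
      oracle_sensitivity(oracle_sort(df)$label)
    }, numeric(1))
    o_avep <- vapply(per_query, function(df) {
      oracle_avep(oracle_sort(df)$label)
    }, numeric(1))
    o_p10 <- vapply(per_query, function(df) {
      oracle_p_at_k(oracle_sort(df)$label, 10)
    }, numeric(1))

    expect_equal(as.numeric(auroc_mean_sensitivity(judged)),
                 mean(o_sens, na.rm = TRUE))
    expect_equal(as.numeric(mean_average_precision(judged)),
                 mean(o_avep, na.rm = TRUE))
    expect_equal(as.numeric(precision_at_k(judged, 10)), mean(o_p10))
  }
})

test_that("mean sensitivity depends only on the score ordering", {
  fx <- random_judged_fixture(44)
  fx$results$similarity <- runif(nrow(fx$results))  # break the ties
  judged <- judge_pairs(fx$results, fx$labels, "fold")
  a1 <- as.numeric(auroc_mean_sensitivity(judged))
  judged$similarity <- exp(5 * judged$similarity) - 2   # monotone transform
  expect_equal(as.numeric(auroc_mean_sensitivity(judged)), a1)
})

test_that("weighted PR curve matches a brute-force threshold sweep", {
  for (seed in 45:46) {
    fx <- random_judged_fixture(seed, n_proteins = 15)
    judged <- judge_pairs(fx$results, fx$labels, "fold")
    curve <- weighted_pr_curve(judged, fx$labels, "fold")

    stratum <- setNames(fx$labels$fold, fx$labels$id)
    sizes <- table(stratum)
    jj <- judged[judged$label != "ignore", ]
    w <- 1 / as.numeric(sizes[stratum[jj$query]])
    uni <- expand.grid(query = unique(jj$query), target = fx$labels$id,
                       stringsAsFactors = FALSE)
    uni <- uni[uni$query != uni$target, ]
    uni <- judge_pairs(uni, fx$labels, "fold")
    total_rel <- sum((1 / as.numeric(sizes[stratum[uni$query]]))[uni$label == "TP"])
    oracle <- oracle_weighted_pr(jj$similarity, jj$label, w, total_rel)

    got <- curve[order(curve$threshold), ]
    want <- oracle[order(oracle$threshold), ]
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$recall, want$recall)
    expect_equal(got$precision, want$precision)
    expect_true(attr(curve, "aupr") >= 0 && attr(curve, "aupr") <= 1)
  }
})

test_that("uniform unit weights reduce the weighted PR curve to the classic one", {
  fx <- random_judged_fixture(47)
  judged <- judge_pairs(fx$results, fx$labels, "fold")
  # same judgments, with the reciprocal-size weights overridden to 1
  c_manual <- weighted_pr_curve(judged, fx$labels, "fold",
                                weights = setNames(rep(1, length(unique(judged$query))),
                                                   unique(judged$query)))
  jj <- judged[judged$label != "ignore", ]
  uni <- expand.grid(query = unique(jj$query), target = fx$labels$id,
                     stringsAsFactors = FALSE)
  uni <- uni[uni$query != uni$target, ]
  uni <- judge_pairs(uni, fx$labels, "fold")
  oracle <- oracle_weighted_pr(jj$similarity, jj$label,
                               rep(1, nrow(jj)), sum(uni$label == "TP"))
  got <- c_manual[order(c_manual$threshold), ]
  want <- oracle[order(oracle$threshold), ]
  expect_equal(got$precision, want$precision)
  expect_equal(got$recall, want$recall)
})

test_that("removing an ignore pair changes no metric", {
  fx <- random_judged_fixture(48)
  judged <- judge_pairs(fx$results, fx$labels, "fold")
  pruned <- judged[judged$label != "ignore", ]
  expect_equal(as.numeric(auroc_mean_sensitivity(judged)),
               as.numeric(auroc_mean_sensitivity(pruned)))
  expect_equal(as.numeric(mean_average_precision(judged)),
               as.numeric(mean_average_precision(pruned)))
  expect_equal(as.numeric(precision_at_k(judged, 5)),
               as.numeric(precision_at_k(pruned, 5)))
})

test_that("quadrant analysis classifies easy and remote homology pairs", {
  pairs <- data.frame(
    tm_score = c(0.74, 0.8, 0.4, 0.9, 0.6),
    identity = c(0.216, 0.5, 0.9, 0.1, 0.35),
    recalled = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  q <- quadrant_analysis(pairs)
  expect_equal(q[["remote_recalled"]], 1L)   # (0.216, 0.74)
  expect_equal(q[["easy_recalled"]], 1L)     # (0.5, 0.8)
  expect_equal(q[["remote_missed"]], 1L)     # (0.1, 0.9)
  expect_equal(q[["easy_missed"]], 1L)       # (0.35, 0.6)
  expect_equal(sum(q), 4L)                   # TM 0.4 pair is in no quadrant
})
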