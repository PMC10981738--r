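test_that("substitution matrix is the pairwise dot product", {
  Eq <- rbind(c(1, 2), c(0, 1))
  Et <- rbind(c(2, 0), c(1, 1))
  expect_equal(substitution_matrix(Eq, Et), rbind(c(2, 3), c(0, 1)))
  # orthonormal identical rows give the identity matrix
  I3 <- diag(3)
  expect_equal(substitution_matrix(I3, I3), diag(3))
  expect_error(substitution_matrix(matrix(0, 2, 3), matrix(0, 2, 4)),
               "dimension mismatch")
  # affine rescale applies uniformly
  expect_equal(substitution_matrix(Eq, Et, scale = 2, shift = -1),
               2 * rbind(c(2, 3), c(0, 1)) - 1)
})

test_that("global alignment matches hand-computed cases", {
  a <- align_global(diag(3), gap = 1)
  expect_equal(a$score, 3)
  expect_equal(a$pairs[, 1], 0:2)
  expect_equal(a$pairs[, 2], 0:2)

  # a single strongly negative cell is best skipped with two terminal gaps
  b <- align_global(matrix(-5, 1, 1), gap = 1)
  expect_equal(b$score, -2)
  expect_equal(nrow(b$pairs), 0)

  expect_error(align_global(matrix(numeric(), 0, 0), gap = 1), "empty")
})

test_that("local alignment floors at zero and finds single positives", {
  neg <- matrix(-1, 4, 5)
  a <- align_local(neg, gap = 1)
  expect_equal(a$score, 0)
  expect_equal(nrow(a$pairs), 0)

  S <- matrix(-1, 4, 5)
  S[2, 3] <- 2.5
  b <- align_local(S, gap = 1)
  expect_equal(b$score, 2.5)
  expect_equal(unname(b$pairs[1, ]), c(1L, 2L))   # 0-based (2,3) cell
})

test_that("DP scores equal the exhaustive-enumeration oracle", {
  set.seed(21)
  for (rep in 1:40) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    S <- matrix(round(rnorm(m * n, sd = 2), 2), m, n)
    gap <- sample(c(0, 0.5, 1, 2.5), 1)
    expect_equal(align_global(S, gap)$score, oracle_global_score(S, gap))
    expect_equal(align_local(S, gap)$score, oracle_local_score(S, gap))
  }
})

test_that("traceback pairs reproduce the optimal score and are monotone", {
  set.seed(22)
  for (rep in 1:20) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    S <- matrix(rnorm(m * n), m, n)
    gap <- runif(1, 0, 2)
    for (mode in c("global", "local")) {
      a <- if (mode == "global") align_global(S, gap) else align_local(S, gap)
      p <- a$pairs
      if (nrow(p) > 1) {
        expect_true(all(diff(p[, 1]) > 0))
        expect_true(all(diff(p[, 2]) > 0))
      }
      # recompute the path score from the pair list
      k <- nrow(p)
      if (mode == "global") {
        sc <- sum(S[p + 1L]) - gap * ((m - k) + (n - k))
      } else {
        sc <- if (k == 0) 0 else
          sum(S[p + 1L]) - gap * ((p[k, 1] - p[1, 1] + 1 - k) +
                                    (p[k, 2] - p[1, 2] + 1 - k))
      }
      expect_equal(unname(sc), a$score)
    }
  }
})

test_that("one-hot embeddings reduce global alignment to textbook NW", {
  enc <- encoder_spec("mock", dim = 32, noise_sd = 0)
  set.seed(23)
  aa <- c("A", "C", "D", "E", "G")
  for (rep in 1:25) {
    sa <- paste0(sample(aa, sample(3:30, 1), replace = TRUE), collapse = "")
    sb <- paste0(sample(aa, sample(3:30, 1), replace = TRUE), collapse = "")
    gap <- sample(c(0.5, 1, 2), 1)
    S <- substitution_matrix(encode_protein(sa, enc), encode_protein(sb, enc))
    expect_equal(align_global(S, gap)$score, textbook_nw_score(sa, sb, gap))
  }
})

test_that("DP scores are invariant under transposition", {
  set.seed(24)
  for (rep in 1:10) {
    S <- matrix(rnorm(30), 5, 6)
    gap <- runif(1, 0, 2)
    expect_equal(align_global(t(S), gap)$score, align_global(S, gap)$score)
    expect_equal(align_local(t(S), gap)$score, align_local(S, gap)$score)
  }
})

test_that("local score dominates global score for gap-free non-negative matrices", {
  set.seed(25)
  for (rep in 1:10) {
    S <- matrix(abs(rnorm(24)), 4, 6)
    expect_gte(align_local(S, 0)$score, align_global(S, 0)$score)
    expect_gte(align_local(S, 2)$score, 0)
  }
})

test_that("gapped display strings are consistent with the pair list", {
  enc <- encoder_spec("mock", dim = 32, noise_sd = 0)
  sa <- "ACDGG"; sb <- "ACGG"
  S <- substitution_matrix(encode_protein(sa, enc), encode_protein(sb, enc))
  a <- align_global(S, gap = 1, query_seq = sa, target_seq = sb)
  expect_equal(nchar(a$query_aligned), nchar(a$target_aligned))
  expect_equal(gsub("-", "", a$query_aligned), sa)
  expect_equal(gsub("-", "", a$target_aligned), sb)
  # aligned columns with letters on both rows match the pair count
  qa <- strsplit(a$query_aligned, "")[[1]]
  ta <- strsplit(a$target_aligned, "")[[1]]
  expect_equal(sum(qa != "-" & ta != "-"), nrow(a$pairs))
})

test_that("alignment of candidate pairs reranks by alignment score", {
  results <- data.frame(query = "q", target = c("t1", "t2"),
                        rank = 1:2, similarity = c(0.9, 0.8),
                        provenance = "shared_clan", self = FALSE)
  alignments <- data.frame(query = "q", target = c("t1", "t2"),
                           score = c(10, 40))
  rr <- rerank_by_alignment(results, alignments)
  expect_equal(rr$target, c("t2", "t1"))
  expect_equal(rr$rank, 1:2)

  # single candidate unchanged
  rr1 <- rerank_by_alignment(results[1, ], alignments[1, ])
  expect_equal(rr1$target, "t1")

  # a pair outside the search results is an error
  stray <- data.frame(query = "q", target = "zzz", score = 1)
  expect_error(rerank_by_alignment(results, stray), "absent")

  # unaligned (below-threshold) pairs are dropped from the reranked list
  rr2 <- rerank_by_alignment(results, alignments[1, ])
  expect_false("t2" %in% rr2$target)
})

test_that("align_pairs emits scores, coordinates and optional normalization", {
  ds <- make_dataset(fixture_spec(n_proteins = 20, seed = 31))
  pairs <- data.frame(query = ds$records$id[1:3], target = ds$records$id[4:6])
  aln <- align_pairs(pairs, ds$store, "global", gap = 1, records = ds$records)
  expect_equal(nrow(aln), 3)
  expect_true(all(aln$query_end <= nchar(ds$records$sequence[1:3])))
  expect_true(all(aln$n_aligned > 0))
  norm <- align_pairs(pairs, ds$store, "global", gap = 1,
                      normalize = "aligned_length")
  expect_equal(norm$score, aln$score / aln$n_aligned)
})
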