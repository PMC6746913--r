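test_that("central-motif classification is most-specific-first", {
  expect_equal(as.character(classify_central_motif(
    window_with_context("GAGG", 2))), "GAGG")
  expect_equal(as.character(classify_central_motif(
    window_with_context("CAGG", 2))), "AGG")
  expect_equal(as.character(classify_central_motif(
    window_with_context("CAGC", 2))), "AG")
  expect_equal(as.character(classify_central_motif(
    window_with_context("CACC", 2))), "other")
})

test_that("motif classification partitions any window set", {
  set.seed(411)
  w <- rand_windows(500)
  cls <- classify_central_motif(w)
  expect_equal(sum(table(cls)), 500L)
  expect_false(anyNA(cls))
})

test_that("motif_ratios validates and defaults to the benchmark Table", {
  r <- motif_ratios()
  expect_equal(as.numeric(r), c(0.1708, 0.1576, 0.1442, 0.5274),
               tolerance = 1e-12)
  expect_equal(sum(r), 1)
  expect_error(motif_ratios(0.3, 0.3, 0.3, 0.3), "sum to 1")
  expect_error(motif_ratios(-0.1, 0.5, 0.3, 0.3), "\\[0, 1\\]")
})

test_that("largest-remainder apportionment is exact", {
  counts <- apportion_counts(10000, motif_ratios())
  expect_equal(unname(counts), c(1708L, 1576L, 1442L, 5274L))
  # remainders force rounding: total must still be exact for awkward n
  set.seed(412)
  for (i in 1:25) {
    p <- runif(4)
    p <- p / sum(p)
    n <- sample(1:997, 1)
    cnt <- apportion_counts(n, setNames(p, c("GAGG", "AGG", "AG", "other")))
    expect_equal(sum(cnt), n)
    expect_true(all(abs(cnt - n * p) <= 1))
  }
})

test_that("matched negative sampling reproduces requested stratum counts", {
  set.seed(413)
  cands <- rand_windows(8000)  # uniform windows: GAGG stratum is rare (1/64)
  neg <- sample_matched_negatives(cands, motif_ratios(), n = 200, seed = 5)
  expect_equal(nrow(neg), 200L)
  expect_true(all(neg$label == 0L))
  got <- table(classify_central_motif(neg))
  expect_equal(as.integer(got), unname(apportion_counts(200, motif_ratios())))

  # degenerate ratios: every draw from a single stratum
  r1 <- motif_ratios(1, 0, 0, 0)
  only <- sample_matched_negatives(cands, r1, n = 5, seed = 5)
  expect_true(all(classify_central_motif(only) == "GAGG"))

  # determinism contract
  n1 <- sample_matched_negatives(cands, motif_ratios(), n = 300, seed = 9)
  n2 <- sample_matched_negatives(cands, motif_ratios(), n = 300, seed = 9)
  n3 <- sample_matched_negatives(cands, motif_ratios(), n = 300, seed = 10)
  expect_identical(n1, n2)
  expect_false(identical(n1$id, n3$id))
})

test_that("matched sampling errors name the short stratum", {
  set.seed(414)
  # candidates with no GAGG windows at all
  cands <- rand_windows(200)
  cands <- cands[classify_central_motif(cands) != "GAGG", , drop = FALSE]
  expect_error(
    sample_matched_negatives(cands, motif_ratios(), n = 100, seed = 1),
    "stratum 'GAGG'.*shortfall"
  )
  lab <- cands
  lab$label <- 1L
  expect_error(sample_matched_negatives(lab, motif_ratios(), 10, 1),
               "unlabelled or negative")
})

test_that("greedy identity filter drops redundant windows and no others", {
  base <- paste0(strrep("C", 20), "A", strrep("G", 20))
  dup <- sample_windows(c("a", "b"), c(base, base))
  kept <- greedy_identity_filter(dup, threshold = 0.8)
  expect_equal(kept$id, "a")

  # differ at 9 of 41 positions: identity 32/41 ~ 0.78 <= 0.8, both kept
  ch <- strsplit(base, "")[[1]]
  ch[c(1:5, 38:41)] <- "T"
  pair <- sample_windows(c("a", "b"), c(base, paste(ch, collapse = "")))
  expect_equal(nrow(greedy_identity_filter(pair, 0.8)), 2L)

  # differ at 8 of 41: identity 33/41 > 0.8, second dropped
  ch <- strsplit(base, "")[[1]]
  ch[c(1:4, 38:41)] <- "T"
  pair <- sample_windows(c("a", "b"), c(base, paste(ch, collapse = "")))
  expect_equal(greedy_identity_filter(pair, 0.8)$id, "a")

  # threshold 1.0 removes exact duplicates only
  three <- sample_windows(c("a", "b", "c"),
                          c(base, base, paste(ch, collapse = "")))
  expect_equal(greedy_identity_filter(three, 1.0)$id, c("a", "c"))
})

test_that("greedy identity filter is idempotent and order-preserving", {
  set.seed(415)
  w <- rand_windows(120, L = 21)
  f1 <- greedy_identity_filter(w, threshold = 0.55)
  expect_true(nrow(f1) < nrow(w))  # at this threshold some windows collide
  f2 <- greedy_identity_filter(f1, threshold = 0.55)
  expect_identical(f1, f2)
  expect_identical(f1$id, w$id[w$id %in% f1$id])
})

test_that("balance_classes subsamples negatives deterministically", {
  set.seed(416)
  pos <- rand_windows(50)
  neg <- rand_windows(300)
  b1 <- balance_classes(pos, neg, seed = 3)
  expect_equal(nrow(b1$neg), 50L)
  expect_true(all(b1$pos$label == 1L) && all(b1$neg$label == 0L))
  b2 <- balance_classes(pos, neg, seed = 3)
  expect_identical(b1, b2)
  b3 <- balance_classes(pos, neg, seed = 4)
  expect_false(identical(b1$neg$id, b3$neg$id))

  same <- balance_classes(pos, rand_windows(50), seed = 1)
  expect_equal(nrow(same$neg), 50L)
  expect_error(balance_classes(neg, pos, seed = 1), "at least as many")
})
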