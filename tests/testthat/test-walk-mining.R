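test_that("entropy matches closed forms and rejects empty input", {
  expect_equal(labelEntropy(c("a", "a", "a")), 0)
  expect_equal(labelEntropy(c("a", "b")), 1)
  # 8/2/2 imbalanced three-class split
  y <- rep(c("A", "B", "C"), c(8, 2, 2))
  expect_equal(labelEntropy(y),
               -(8 / 12 * log2(8 / 12) + 2 * (2 / 12) * log2(2 / 12)))
  expect_equal(labelEntropy(y), 1.2516, tolerance = 1e-4)
  expect_error(labelEntropy(character(0)), "empty")
})

test_that("entropy is invariant to class relabeling and order", {
  y <- rep(c("A", "B", "C"), c(8, 2, 2))
  expect_equal(labelEntropy(y), labelEntropy(rev(y)))
  expect_equal(labelEntropy(y),
               labelEntropy(chartr("ABC", "ZQM", y)))
})

test_that("partitioning splits on walk presence, preserving dataset order", {
  fx <- toy()
  p <- partitionByWalk(fx$data, walk("1", 1), fx$nbhs)
  expect_equal(length(p$found), 8L)
  expect_equal(unique(classLabels(p$found)), "A")
  expect_equal(classLabels(p$not_found), c("B", "B", "C", "C"))
  expect_equal(entities(p$found), paste0("A", 1:8))

  # walk found for none / for all
  p0 <- partitionByWalk(fx$data, walk("absent", 1), fx$nbhs)
  expect_null(p0$found)
  expect_equal(length(p0$not_found), 12L)

  expect_error(partitionByWalk(fx$data, walk("1", 1), fx$nbhs[1:3]),
               "missing neighborhoods")
})

test_that("information gain reproduces the worked-example values", {
  fx <- toy()
  expect_equal(infoGain(fx$data, walk("1", 1), fx$nbhs),
               1.251629 - (4 / 12) * 1, tolerance = 1e-6)
  expect_equal(infoGain(fx$data, walk("6", 1), fx$nbhs),
               labelEntropy(classLabels(fx$data)) -
                 (10 / 12) * labelEntropy(rep(c("A", "C"), c(8, 2))),
               tolerance = 1e-12)
  # degenerate partitions give zero
  g <- labeledGraph(data.frame(from = c("a", "b"), to = c("s", "s")),
                    c(a = "A", b = "B", s = "S"))
  nb <- extractNeighborhoods(g, c("a", "b"), 1)
  expect_equal(infoGain(entityDataset(c("a", "b"), c("x", "y")),
                        walk("S", 1), nb), 0)
})

test_that("candidate enumeration is the union of present (label, depth) pairs", {
  g <- labeledGraph(data.frame(from = c("a", "b"), to = c("b", "c")),
                    c(a = "A", b = "B", c = "C"))
  nb <- extractNeighborhoods(g, "a", 2)
  cands <- enumerateCandidates(nb, 2, skipOdd = FALSE)
  expect_equal(cands$end_label, c("B", "C"))
  expect_equal(cands$depth, c(1L, 2L))
  odd <- enumerateCandidates(nb, 2, skipOdd = TRUE)
  expect_equal(odd$end_label, "C")
  expect_equal(odd$depth, 2L)
})

test_that("odd depths are skipped by default on converted graphs only", {
  tr <- triples_of("a", "p", "b")
  g <- convertToLabeledGraph(tr)
  nb <- extractNeighborhoods(g, "a", 2)
  expect_true(attr(nb, "converted"))
  cands <- enumerateCandidates(nb)        # default skipOdd = TRUE
  expect_equal(cands$depth, 2L)           # predicate at depth 1 skipped
  cands_all <- enumerateCandidates(nb, skipOdd = FALSE)
  expect_setequal(cands_all$end_label, c("p", "b"))
})

test_that("mineWalks ranks the worked example correctly with deterministic ties", {
  fx <- toy()
  top1 <- mineWalks(fx$data, fx$nbhs, n = 1)
  expect_equal(top1$end_label, "1")       # lexicographic among "1".."5"
  expect_equal(top1$depth, 1L)

  top7 <- mineWalks(fx$data, fx$nbhs, n = 7)
  expect_equal(top7$end_label, as.character(1:7))
  expect_true(min(top7$ig_bits[1:5]) > max(top7$ig_bits[6:7]))
  expect_equal(top7$n_found, c(rep(8, 5), 2, 2))
})

test_that("single-class datasets yield only zero-gain walks", {
  fx <- toy()
  pure <- entityDataset(paste0("A", 1:8), rep("A", 8))
  w <- mineWalks(pure, fx$nbhs, n = 3)
  expect_equal(nrow(w), 3L)
  expect_true(all(w$ig_bits == 0))
})

test_that("gain is bounded by the prior entropy over random planted KGs", {
  sp <- plantedKGSpec(8, 2, list(list(class = 1, depth = 2,
                                      label = "sig:T", penetrance = 0.8)),
                      seed = 21)
  kg <- makePlantedKG(sp)
  g <- convertToLabeledGraph(kg$triples)
  nb <- extractNeighborhoods(g, entities(kg$data), 4)
  all_w <- mineWalks(kg$data, nb, n = 10000, maxDepth = 4)
  H0 <- labelEntropy(classLabels(kg$data))
  expect_true(all(all_w$ig_bits >= 0 & all_w$ig_bits <= H0 + 1e-12))
  # and the vectorized scores agree with the single-walk path
  for (i in sample(nrow(all_w), 10)) {
    expect_equal(all_w$ig_bits[i],
                 infoGain(kg$data, walk(all_w$end_label[i], all_w$depth[i]),
                          nb),
                 tolerance = 1e-12)
  }
})

test_that("gain is invariant under dataset permutation and class renaming", {
  fx <- toy()
  perm <- sample(12)
  shuffled <- fx$data[perm]
  expect_equal(infoGain(shuffled, walk("6", 1), fx$nbhs),
               infoGain(fx$data, walk("6", 1), fx$nbhs))
  renamed <- entityDataset(entities(fx$data),
                           chartr("ABC", "xyz", classLabels(fx$data)))
  expect_equal(infoGain(renamed, walk("6", 1), fx$nbhs),
               infoGain(fx$data, walk("6", 1), fx$nbhs))
})

test_that("mined top-1 matches a brute-force sweep on small random graphs", {
  for (seed in 1:30) {
    set.seed(seed * 13)
    n <- sample(8:30, 1)
    g <- makeRandomGraph(n, sample(2:6, 1), runif(1, 0.03, 0.12),
                         seed = seed * 13 + 1)
    d <- sample(1:4, 1)
    ents <- paste0("v", sample(n, min(n, sample(6:12, 1))))
    y <- sample(c("pos", "neg"), length(ents), replace = TRUE)
    data <- entityDataset(ents, y)
    nb <- extractNeighborhoods(g, ents, d)
    mined <- mineWalks(data, nb, n = 1, maxDepth = d, skipOdd = FALSE)
    best <- oracle_best_ig(g, data, d)
    got <- if (nrow(mined)) mined$ig_bits[[1]] else 0
    expect_equal(got, best, tolerance = 1e-10,
                 info = sprintf("seed=%d", seed))
  }
})

test_that("candidate subsampling draws ceiling(f * m) walks reproducibly", {
  fx <- toy()
  w1 <- mineWalks(fx$data, fx$nbhs, n = 7, candidateFraction = 0.5,
                  seed = 42)
  w2 <- mineWalks(fx$data, fx$nbhs, n = 7, candidateFraction = 0.5,
                  seed = 42)
  expect_identical(w1, w2)
  expect_equal(nrow(w1), ceiling(0.5 * 7))
  expect_error(mineWalks(fx$data, fx$nbhs, candidateFraction = 1.5),
               "candidateFraction")
})

test_that("mined walks serialize to the documented TSV layout", {
  fx <- toy()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeWalks(mineWalks(fx$data, fx$nbhs, n = 3), f)
  back <- read.delim(f, colClasses = c("character", "integer", "numeric",
                                       "numeric"))
  expect_equal(names(back), c("end_label", "depth", "ig_bits", "n_found"))
  expect_equal(nrow(back), 3L)
})
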