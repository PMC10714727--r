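test_that("alphabet reduction follows the scheme and flags constants", {
  aln <- msaAlignment(c(a = "KRAS", b = "RKAT", c = "KRAY", d = "RRAF"),
                      "protein")
  red <- reduceAlphabet(aln, AA_CLASS_DEFAULT)
  ## column 1 (K,R,K,R) is constant under the charge classes
  expect_true(red$constant[1])
  expect_true(red$constant[3])   # all A
  expect_false(red$constant[4])  # polar/aromatic mix
  ## identity scheme returns residues unchanged (one class each)
  redI <- reduceAlphabet(aln, AA_CLASS_IDENTITY)
  expect_equal(redI$levels[redI$classes[, 1] + 1], unname(c(a = "K", b = "R",
                                                            c = "K", d = "R")))
  ## lookup-table oracle on a random fixture
  set.seed(1)
  m <- matrix(sample(names(AA_CLASS_DEFAULT), 40, TRUE), 4,
              dimnames = list(letters[1:4], NULL))
  red2 <- reduceAlphabet(msaAlignment(m, "protein"))
  expect_identical(red2$levels[red2$classes + 1],
                   unname(AA_CLASS_DEFAULT[m]))
  ## unknown residue errors
  expect_error(reduceAlphabet(msaAlignment(c(a = "KO", b = "KK"), "protein",
                                           validate = FALSE)),
               "unknown residue")
})

test_that("column tree patterns recover blocks, matching exhaustive search", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);")
  tt <- timedTree(tr, setNames(rep(2000, 6), tr$tip.label))
  ## constant column: one block
  sig <- columnTreePattern(setNames(rep("K", 6), tr$tip.label), tt)
  expect_equal(length(unique(sig)), 1L)
  ## perfect split on the (A,B,C,D) | (E,F) edge
  col <- setNames(c("K", "K", "K", "K", "D", "D"), tr$tip.label)
  sig2 <- columnTreePattern(col, tt)
  expect_equal(length(unique(sig2)), 2L)
  expect_equal(length(unique(sig2[c("A", "B", "C", "D")])), 1L)
  expect_equal(length(unique(sig2[c("E", "F")])), 1L)
  ## oracle: exhaustive maximal uniform clades on random columns
  exhaustive <- function(col, tr) {
    ntip <- ape::Ntip(tr)
    clades <- c(lapply(seq_len(ntip), function(i) i),
                lapply((ntip + 1):(ntip + tr$Nnode), function(nd)
                  unlist(parevol:::phangornFreeDescendants(tr, nd))))
    uniform <- vapply(clades, function(tp) length(unique(col[tp])) == 1L, TRUE)
    blocks <- rep(NA_integer_, ntip)
    sizes <- vapply(clades, length, 1L)
    ord <- order(-sizes)
    bid <- 0L
    for (ci in ord) {
      if (!uniform[ci]) next
      tp <- clades[[ci]]
      if (anyNA(blocks[tp])) {
        if (all(is.na(blocks[tp]))) {
          bid <- bid + 1L
          blocks[tp] <- bid
        }
      }
    }
    blocks
  }
  set.seed(2)
  for (r in 1:30) {
    col <- sample(c("K", "D", "A"), 6, TRUE)
    names(col) <- tr$tip.label
    sig <- columnTreePattern(col, tt)
    oracle <- exhaustive(unname(as.integer(factor(col,
                                                  levels = c("K", "D", "A")))),
                         tr)
    ## same partition up to relabeling
    expect_equal(parevol:::`.cpp_partition_score`(unname(sig),
                                                  oracle - 1L), 1.0)
  }
})

test_that("pair scores are symmetric, bounded and exact for duplicates", {
  tt <- simulateTimedTree(10, samplingWindow = 0.001, Ne = 20, seed = 3)
  sim <- simulateCoevolvingAlignment(tt, nBackground = 12, nPlantedPairs = 1,
                                     rate = 0.01, seed = 4)
  red <- reduceAlphabet(sim$alignment)
  pr <- detectCoevolvingPairs(red, tt, nPermutations = 200, seed = 5)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  tp <- sim$truth
  dup <- pr[pr$column_i == tp$column_i & pr$column_j == tp$column_j, ]
  expect_equal(dup$score, 1.0)
  expect_true(all(pr$column_i < pr$column_j))
  expect_error(detectCoevolvingPairs(red, tt, nPermutations = 50), "100")
})

test_that("planted pairs are recovered and clustered", {
  rec <- logical(10)
  for (i in seq_len(10)) {
    tt <- simulateTimedTree(12, samplingWindow = 0.001, Ne = 30, seed = i)
    sim <- simulateCoevolvingAlignment(tt, nBackground = 30,
                                       nPlantedPairs = 1, rate = 0.01,
                                       seed = 200 + i)
    red <- reduceAlphabet(sim$alignment)
    pr <- detectCoevolvingPairs(red, tt, nPermutations = 1000, alpha = 0.05,
                                seed = 300 + i)
    tp <- sim$truth
    hit <- pr[pr$column_i == tp$column_i & pr$column_j == tp$column_j, ]
    rec[i] <- nrow(hit) == 1 && hit$pValue <= 0.01
  }
  expect_gte(sum(rec), 9L)
})

test_that("domain weights sum direct and indirect interactions", {
  doms <- data.frame(domain = c("fingers", "palm", "thumb"),
                     start = c(1, 11, 21), end = c(10, 20, 30))
  pairs <- data.frame(column_i = c(2, 3), column_j = c(5, 8),
                      score = c(1.0, 0.5),
                      pValue = 0.001, pAdjust = 0.001,
                      significant = TRUE, cluster = c(1L, 2L))
  W <- summarizeWeights(pairs, doms)
  expect_equal(W["fingers", "fingers"], 1.5)
  expect_true(isSymmetric(W))
  ## cross-domain single pair
  pairs2 <- data.frame(column_i = 2, column_j = 15, score = 1.0,
                       pValue = 0.001, pAdjust = 0.001, significant = TRUE,
                       cluster = 1L)
  W2 <- summarizeWeights(pairs2, doms)
  expect_equal(W2["fingers", "palm"], 1.0)
  expect_equal(W2["palm", "fingers"], 1.0)
  ## 3-member cluster spanning palm/fingers/thumb: indirect (a,b) via shared c
  pairs3 <- data.frame(column_i = c(2, 15), column_j = c(15, 25),
                       score = c(0.9, 0.8), pValue = 0.001, pAdjust = 0.001,
                       significant = TRUE, cluster = 1L)
  W3 <- summarizeWeights(pairs3, doms)
  expect_equal(W3["fingers", "palm"], 0.9)
  expect_equal(W3["palm", "thumb"], 0.8)
  expect_equal(W3["fingers", "thumb"], min(0.9, 0.8))  # indirect via column 15
  ## overlapping domains error
  badDoms <- data.frame(domain = c("a", "b"), start = c(1, 5), end = c(6, 10))
  expect_error(summarizeWeights(pairs, badDoms), "overlap")
  ## total weight is conserved under domain relabeling
  domsR <- doms
  domsR$domain <- c("x", "y", "z")
  expect_equal(sum(summarizeWeights(pairs3, domsR)),
               sum(W3))
})

test_that("randomized-tie permutation p-values are uniform on null data", {
  tt <- simulateTimedTree(12, samplingWindow = 0.001, Ne = 30, seed = 1)
  set.seed(4)
  m <- matrix(sample(names(AA_CLASS_DEFAULT), 12 * 33, TRUE), 12,
              dimnames = list(treeOf(tt)$tip.label, NULL))
  red0 <- reduceAlphabet(msaAlignment(m, "protein"))
  pr0 <- detectCoevolvingPairs(red0, tt, nPermutations = 500, alpha = 0.05,
                               seed = 11, tieBreak = "randomized")
  expect_gte(nrow(pr0), 500L)
  ks <- suppressWarnings(stats::ks.test(pr0$pValue, "punif"))
  expect_gt(ks$p.value, 0.01)
})
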