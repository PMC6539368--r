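# Diversity measures, greedy ranking and majority-vote fusion. Oracles live
# in helper-fixtures.R and are loop-level transcriptions of the definitions.

test_that("pairwise disagreement counts mismatching correctness patterns", {
  expect_equal(disagreementPair(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_equal(disagreementPair(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(disagreementPair(c(1, 1), c(0, 0)), 1)
  expect_equal(disagreementPair(c(1, 0), c(0, 1)),
               disagreementPair(c(0, 1), c(1, 0)))
  expect_error(disagreementPair(c(1, 0), c(1, 0, 1)), "length")
})

test_that("set-level measures match hand-computable fixtures", {
  M <- rbind(c(1, 1, 0, 0),
             c(1, 0, 1, 0),
             c(0, 1, 1, 1))
  expect_equal(disagreementAvg(M, 1:2), disagreementPair(M[1, ], M[2, ]))
  expect_equal(disagreementAvg(M), oracleDisagreementAvg(M))
  expect_equal(entropyMeasure(M), oracleEntropy(M))
  expect_equal(cfd(M), oracleCFD(M))
  expect_equal(combinedTheta(M),
               disagreementAvg(M) + entropyMeasure(M) + cfd(M))

  # identical rows: no diversity at all
  same <- rbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1))
  expect_equal(disagreementAvg(same), 0)
  expect_equal(entropyMeasure(same), 0)
  expect_equal(combinedTheta(same), 0)

  # unanimity correct: entropy 0 and CFD 0 (P0 = 1)
  allc <- matrix(1, 3, 5)
  expect_equal(entropyMeasure(allc), 0)
  expect_equal(cfd(allc), 0)

  # L = 3, every sample split 1 or 2 correct: maximal entropy
  M3 <- rbind(c(1, 0, 1, 0), c(0, 1, 1, 1), c(1, 1, 0, 0))
  expect_equal(entropyMeasure(M3), 1)

  # L = 2, half split half unanimous
  M2 <- rbind(c(1, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(entropyMeasure(M2), 0.5)

  # CFD limits: complementary failures -> 1; coincident failures -> 0
  comp <- rbind(c(0, 1, 1, 1), c(1, 0, 1, 1))
  expect_equal(cfd(comp), 1)
  co <- rbind(c(0, 0), c(0, 0))
  expect_equal(cfd(co), 0)

  # singleton subset is defined as zero diversity, with a warning
  expect_warning(v <- disagreementAvg(M, 1), "fewer than 2")
  expect_equal(v, 0)
})

test_that("measures equal brute-force oracles on every small binary matrix", {
  for (T in 2:3) for (N in 1:4) {
    for (M in allBinaryMatrices(T, N)) {
      expect_equal(disagreementAvg(M), oracleDisagreementAvg(M))
      expect_equal(entropyMeasure(M), oracleEntropy(M))
      expect_equal(cfd(M), oracleCFD(M))
    }
  }
})

test_that("measures are invariant to sample and classifier reordering", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      M <- matrix(rbinom(5 * 8, 1, 0.7), nrow = 5)
      ps <- sample(ncol(M))
      pc <- sample(nrow(M))
      for (f in list(disagreementAvg, entropyMeasure, cfd)) {
        expect_equal(f(M), f(M[, ps, drop = FALSE]))
        expect_equal(f(M), f(M[pc, , drop = FALSE]))
      }
    }
  })
})

test_that("duplicating the most redundant classifier never increases
           average disagreement", {
  # (duplicating an unusually diverse member can raise the average:
  # the guarantee holds for the member with the smallest summed
  # disagreement, since twice the minimum never exceeds the total)
  withr::with_seed(8, {
    for (rep in 1:20) {
      M <- matrix(rbinom(4 * 6, 1, 0.6), nrow = 4)
      D <- sapply(1:4, function(r)
        sum(sapply((1:4)[-r], function(k) mean(M[r, ] != M[k, ]))))
      dup <- rbind(M, M[which.min(D), ])
      expect_lte(disagreementAvg(dup), disagreementAvg(M) + 1e-12)
    }
  })
})

test_that("greedy ranking seeds with accuracy then maximizes combined theta", {
  # planted fixture: A most accurate, B duplicates A, C complements A
  A <- c(1, 1, 1, 0)
  B <- A
  C <- c(0, 0, 1, 1)
  M <- rbind(A, B, C)
  rownames(M) <- NULL
  acc <- c(mean(A), mean(B) - 0.01, mean(C))  # A wins the seed
  rk <- rankClassifiers(M, acc)
  expect_identical(rk$classifier, c(1L, 3L, 2L))  # complement before duplicate
  expect_equal(rk$theta[1], 0)
  expect_gt(rk$theta[2], rk$theta[3] - 1e-12)

  # single classifier
  rk1 <- rankClassifiers(matrix(c(1, 0, 1), 1), 0.7)
  expect_identical(rk1$classifier, 1L)
  expect_equal(rk1$theta, 0)

  # always a permutation; idempotent
  withr::with_seed(13, {
    for (rep in 1:10) {
      M <- matrix(rbinom(6 * 9, 1, 0.7), nrow = 6)
      r1 <- rankClassifiers(M)
      expect_setequal(r1$classifier, 1:6)
      expect_identical(r1, rankClassifiers(M))
      # matches the independent greedy oracle
      expect_identical(r1$classifier, as.integer(oracleRanking(M, rowMeans(M))))
    }
  })
})

test_that("majority vote follows counts and rank-order tie-breaking", {
  p <- rbind(c("W", "W"), c("W", "R"), c("R", "R"))
  expect_identical(majorityVote(p, 1:3), c("W", "R"))

  # single classifier passthrough
  expect_identical(majorityVote(p, 2), p[2, ])

  # 2-voter tie: the higher-ranked selected classifier decides
  p2 <- rbind(c("W"), c("R"))
  expect_identical(majorityVote(p2, c(2, 1)), "R")
  expect_identical(majorityVote(p2, c(1, 2)), "W")

  # 4-voter 2-2 tie among classes; rank order decides between tied classes
  p4 <- rbind("GU", "GD", "GD", "GU")
  expect_identical(majorityVote(p4, c(3, 1, 2, 4)), "GD")
  expect_identical(majorityVote(p4, c(1, 3, 2, 4)), "GU")

  expect_error(majorityVote(p, integer(0)), "no selected")
})

test_that("correctness matrix marks agreement with the truth", {
  preds <- rbind(c("W", "S", "J"), c("W", "W", "J"))
  C <- correctnessMatrix(preds, yval = c("W", "S", "R"))
  expect_identical(C, rbind(c(1L, 1L, 0L), c(1L, 0L, 0L)))
  expect_equal(dim(C), c(2, 3))
})

test_that("selectTopN returns rank-order prefixes and validates n", {
  M <- matrix(rbinom(5 * 6, 1, 0.6), nrow = 5)
  rk <- rankClassifiers(M)
  expect_identical(selectTopN(rk, 5), rk$classifier)
  expect_identical(selectTopN(rk, 1), rk$classifier[1])
  expect_error(selectTopN(rk, 0), "n must be")
  expect_error(selectTopN(rk, 6), "n must be")
})
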