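wts <- function() {
  data.frame(
    ID = c("rs000001", "rs000002", "rs000003", "rs3135388", "rs000005"),
    CHR = c(1L, 2L, 6L, 6L, 6L),
    BP = c(1000L, 2000L, 26000000L, 32500000L, 35000000L),
    BETA = c(0.5, -0.2, 0.3, 1.1, 0.4),
    P = c(0.001, 0.009, 0.0005, 1e-8, 0.01),
    stringsAsFactors = FALSE)
}

test_that("variant selection applies strict P_T and exclusions", {
  w <- wts()
  sel <- selectVariants(w, pThreshold = 0.01)
  expect_false("rs000005" %in% sel$ID)      # p = 0.01 excluded: strict <
  expect_identical(nrow(sel), 4L)

  sel <- selectVariants(w, excludeIds = "rs3135388")
  expect_false("rs3135388" %in% sel$ID)

  # MHC region is half-open [start, end): BP 35,000,000 survives
  sel <- selectVariants(w, pThreshold = 0.05,
                        excludeRegions = mhcRegion())
  expect_identical(sel$ID, c("rs000001", "rs000002", "rs000005"))

  expect_identical(selectVariants(w, pThreshold = 1)$ID,
                   w$ID[w$P < 1])
  expect_error(selectVariants(w, pThreshold = 0), "pThreshold")
  expect_error(
    selectVariants(w, excludeRegions = data.frame(CHR = 6, start = 10,
                                                  end = 10)),
    "start < end")
  expect_warning(selectVariants(w, pThreshold = 1e-10), "no variants")

  bad <- w; bad$P[1] <- 0
  expect_error(selectVariants(bad), "p-values")
})

test_that("raw scores equal the hand-computed dosage-weight sums", {
  d <- matrix(c(0, 1, 2), ncol = 1,
              dimnames = list(paste0("P", 1:3), "rs000001"))
  w <- wts()[1, ]
  ss <- computePRS(d, w, standardize = FALSE)
  expect_equal(unname(rawScores(ss)), c(0, 0.5, 1.0))
  expect_null(scaledScores(ss))
  expect_identical(nVariantsUsed(ss), 1L)

  d2 <- matrix(c(2, 0, 1, 1, 0, 2), ncol = 2,
               dimnames = list(paste0("P", 1:3),
                               c("rs000001", "rs000002")))
  ss2 <- computePRS(d2, wts()[1:2, ], standardize = FALSE)
  expect_equal(unname(rawScores(ss2)),
               c(2 * 0.5 + 1 * -0.2, 0 * 0.5 + 0 * -0.2,
                 1 * 0.5 + 2 * -0.2))

  std <- computePRS(d2, wts()[1:2, ])
  expect_lt(abs(mean(scaledScores(std))), 1e-10)
  expect_lt(abs(sd(scaledScores(std)) - 1), 1e-10)

  expect_error(computePRS(d, wts()[1:2, ]), "rs000002")
  expect_error(computePRS(d * 2, w, standardize = FALSE), "\\[0, 2\\]")
  dconst <- matrix(1, nrow = 3, ncol = 1,
                   dimnames = list(NULL, "rs000001"))
  expect_error(computePRS(dconst, w), "zero variance")
})

test_that("scores are additive, exclusion-monotone and scale-equivariant", {
  withr::with_seed(61, {
    g <- simulateGenotypes(30, nVariants = 12, seed = 61)
  })
  w <- g$weights
  d <- g$dosages

  splitA <- w[1:5, ]; splitB <- w[6:12, ]
  rawAll <- rawScores(computePRS(d, w, standardize = FALSE))
  rawA <- rawScores(computePRS(d, splitA, standardize = FALSE))
  rawB <- rawScores(computePRS(d, splitB, standardize = FALSE))
  expect_equal(rawAll, rawA + rawB)

  nAll <- nrow(selectVariants(w, pThreshold = 1))
  nExcl <- nrow(selectVariants(w, pThreshold = 1,
                               excludeIds = w$ID[1:3]))
  nRegion <- nrow(selectVariants(w, pThreshold = 1,
                                 excludeIds = w$ID[1:3],
                                 excludeRegions = mhcRegion()))
  expect_true(nExcl <= nAll && nRegion <= nExcl)

  wDouble <- w; wDouble$BETA <- 2 * w$BETA
  expect_equal(rawScores(computePRS(d, wDouble, standardize = FALSE)),
               2 * rawAll)
  expect_equal(scaledScores(computePRS(d, wDouble)),
               scaledScores(computePRS(d, w)))
})
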