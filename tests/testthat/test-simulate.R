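test_that("genotype dosages follow Binomial(2, MAF) and inputs validate", {
  g <- simulateGenotypes(10000, nVariants = 1, mafRange = c(0.5, 0.5),
                         seed = 11)
  expect_gt(mean(g$dosages), 0.97)
  expect_lt(mean(g$dosages), 1.03)

  g4 <- simulateGenotypes(2000, nVariants = 5, mafRange = c(0.2, 0.4),
                          seed = 9)
  af <- colMeans(g4$dosages) / 2
  se <- sqrt(g4$weights$MAF * (1 - g4$weights$MAF) / (2 * 2000))
  expect_true(all(abs(af - g4$weights$MAF) <= 3 * se))
  expect_true(all(g4$weights$P > 0 & g4$weights$P <= 1))
  expect_false(anyDuplicated(g4$weights$ID) > 0)

  expect_error(simulateGenotypes(10, nVariants = 0), "at least 1")
  expect_error(simulateGenotypes(10, mafRange = c(0, 0.5)), "mafRange")
  expect_error(simulateGenotypes(10, mafRange = c(0.1, 0.6)), "mafRange")

  expect_identical(simulateGenotypes(50, 20, seed = 3),
                   simulateGenotypes(50, 20, seed = 3))
})

test_that("covariate table has the stated schema and marginals", {
  cv <- simulateCovariates(10000, seed = 21)
  expect_identical(names(cv),
                   c("subject", "age", "sex", paste0("PC", 1:10),
                     "handedness", "maternalEducation"))
  expect_gt(mean(cv$sex), 0.45)
  expect_lt(mean(cv$sex), 0.55)
  expect_true(all(cv$age >= 9 & cv$age <= 12))
  expect_true(all(cv$handedness %in% 0:1))
  expect_true(all(cv$maternalEducation %in% c("low", "mid", "high")))
  expect_identical(simulateCovariates(30, seed = 4),
                   simulateCovariates(30, seed = 4))
  expect_error(simulateCovariates(1), "at least 2")
})

test_that("cohort generation is deterministic with exact plant bookkeeping", {
  tmpl <- tinyTemplate()
  plants <- randomPlants(c(1L, 2L, 2L), c(4L, 7L, 5L), tmpl,
                         polarity = c("pothole", "molehill", "pothole"),
                         magnitude = 6, seed = 5)
  sim1 <- simulateCohort(5, tmpl, plants = plants, seed = 9)
  sim2 <- simulateCohort(5, tmpl, plants = plants, seed = 9)
  expect_identical(faData(sim1$cohort), faData(sim2$cohort))

  expect_equal(sim1$truth$volumeMM3,
               sim1$truth$nVoxels * prod(tmpl$voxelSize))
  expect_identical(sim1$truth$nVoxels, c(4L, 7L, 5L))
  expect_identical(sim1$truth$subject, c("S001", "S002", "S002"))

  # planted voxels are shifted by the configured multiple of the noise SD
  simNull <- simulateCohort(5, tmpl, plants = NULL, seed = 9)
  v <- plants$voxels[[1]]
  idx <- cbind(v, 1L)
  expect_equal(faData(sim1$cohort)[idx],
               faData(simNull$cohort)[idx] - 6 * 0.02)
})

test_that("invalid plants are rejected with informative errors", {
  tmpl <- tinyTemplate()
  v <- randomPlants(1L, 6L, tmpl, seed = 2)$voxels[[1]]
  overlapping <- data.frame(subject = c(1L, 1L),
                            polarity = c("pothole", "pothole"),
                            magnitude = 6,
                            voxels = I(list(v, v[1:3, , drop = FALSE])))
  expect_error(simulateCohort(3, tmpl, plants = overlapping),
               "overlapping plants.*1&2")

  flat <- list(fa = array(0.1, c(16, 16, 16)), atlas = tmpl$atlas,
               voxelSize = c(2, 2, 2))
  expect_error(simulateCohort(3, flat, plants = overlapping[1, ]),
               "no voxels with FA above 0.2")

  outside <- data.frame(subject = 9L, polarity = "pothole", magnitude = 6,
                        voxels = I(list(v)))
  expect_error(simulateCohort(3, tmpl, plants = outside),
               "outside the cohort")

  eligible <- which(tmpl$fa > 0.2)
  farPair <- arrayInd(c(eligible[1], eligible[length(eligible)]),
                      dim(tmpl$fa))
  disjoint <- data.frame(subject = 1L, polarity = "pothole", magnitude = 6,
                         voxels = I(list(farPair)))
  expect_error(simulateCohort(3, tmpl, plants = disjoint),
               "not contiguous")
})

test_that("score-linked anomaly counts follow the linear Poisson link", {
  tmpl <- tinyTemplate()
  withr::with_seed(31, {
    s400 <- as.vector(scale(rnorm(400)))
    s1k <- as.vector(scale(rnorm(1000)))
  })

  nullLink <- plantPrsLinkedAnomalies(s400, tmpl, lambda0 = 1, b = 0,
                                      sizeRange = c(2L, 4L), seed = 7)
  expect_lt(abs(cor(s400, nullLink$counts)), 3 / sqrt(400))

  posLink <- plantPrsLinkedAnomalies(s1k, tmpl, lambda0 = 2, b = 0.8,
                                     sizeRange = c(2L, 3L), seed = 8)
  expect_gt(cor(s1k, posLink$counts, method = "spearman"), 0)

  zero <- plantPrsLinkedAnomalies(s400, tmpl, lambda0 = 0, b = 0, seed = 9)
  expect_true(all(zero$counts == 0L))
  expect_identical(nrow(zero$plants), 0L)

  expect_error(
    plantPrsLinkedAnomalies(s400, tmpl, lambda0 = 0.1, b = 1,
                            truncate = FALSE, seed = 10),
    "negative anomaly rate")
})

test_that("background plants add both polarities without entering truth counts", {
  tmpl <- tinyTemplate()
  withr::with_seed(12, s <- as.vector(scale(rnorm(40))))
  res <- plantPrsLinkedAnomalies(s, tmpl, lambda0 = 0, b = 0,
                                 sizeRange = c(2L, 4L),
                                 bgPotholeRate = 2, bgMolehillRate = 1,
                                 seed = 13)
  expect_true(all(res$counts == 0L))
  expect_gt(sum(res$plants$polarity == "pothole"), 0)
  expect_gt(sum(res$plants$polarity == "molehill"), 0)
  sim <- simulateCohort(40, tmpl, plants = res$plants, seed = 14)
  expect_identical(nrow(sim$truth), nrow(res$plants))
})
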