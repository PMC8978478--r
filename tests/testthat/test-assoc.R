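test_that("linear fits recover exact and closed-form solutions", {
  d <- data.frame(y = 2 * (1:10), x = 1:10)
  f <- suppressWarnings(fitLinear(d, "y", "x"))  # exact fit by design
  expect_equal(f$beta, 2)
  expect_equal(f$deltaR2, 1)
  expect_identical(f$n, 10L)

  # against the normal-equations oracle, with one covariate
  withr::with_seed(81, {
    x <- rnorm(10); cv <- rnorm(10)
    y <- 1 + 0.7 * x - 0.3 * cv + rnorm(10)
  })
  d <- data.frame(y = y, x = x, cv = cv)
  f <- fitLinear(d, "y", "x", "cv")
  o <- olsOracle(y, x, cv)
  expect_equal(f$beta, o$beta, tolerance = 1e-10)
  expect_equal(f$se, o$se, tolerance = 1e-10)
  expect_equal(f$p, o$p, tolerance = 1e-10)

  # delta-R2 equals the nested-model difference computed by hand
  r2 <- function(fit) summary(fit)$r.squared
  expect_equal(f$deltaR2, r2(lm(y ~ x + cv)) - r2(lm(y ~ cv)),
               tolerance = 1e-12)

  expect_error(fitLinear(d[1:3, ], "y", "x", "cv"), "too few")
  expect_error(fitLinear(data.frame(y = 1:5, x = 1), "y", "x"),
               "constant")
  expect_error(fitLinear(data.frame(y = rep(1, 5), x = 1:5), "y", "x"),
               "constant")
  d$dup <- d$x
  expect_error(fitLinear(d, "y", "x", c("cv", "dup")), "aliased|rank")
  expect_error(fitLinear(d, "y", "missing"), "lacks column")
})

test_that("the Poisson sensitivity family matches a direct GLM fit", {
  withr::with_seed(84, {
    x <- rnorm(200)
    cv <- rnorm(200)
    y <- rpois(200, exp(1 + 0.3 * x))
  })
  d <- data.frame(y = y, x = x, cv = cv)
  f <- fitLinear(d, "y", "x", "cv", family = "poisson")
  g <- glm(y ~ x + cv, family = poisson(), data = d)
  expect_equal(f$beta, coef(g)[["x"]], tolerance = 1e-10)
  expect_equal(f$p, summary(g)$coefficients["x", "Pr(>|z|)"],
               tolerance = 1e-10)
  expect_gt(f$deltaR2, 0)
  expect_error(fitLinear(d, "y", "x", family = "poisson",
                         standardizeOutcome = TRUE), "incompatible")
})

test_that("a permuted exposure is null: |beta| < 3 SE in nearly all fits", {
  withr::with_seed(82, {
    n <- 2000
    y <- rpois(n, 5)
    hits <- vapply(1:200, function(i) {
      d <- data.frame(y = y, x = sample(rnorm(n)))
      f <- fitLinear(d, "y", "x")
      abs(f$beta) < 3 * f$se
    }, logical(1))
  })
  expect_gte(mean(hits), 0.99)
})

test_that("BH q-values match the hand-applied step-up definition", {
  expect_equal(fdrBH(c(0.001, 0.02, 0.03, 0.04)),
               c(0.004, 0.04, 0.04, 0.04))
  expect_equal(fdrBH(0.37), 0.37)
  expect_equal(fdrBH(rep(1, 5)), rep(1, 5))
  expect_identical(fdrBH(numeric(0)), numeric(0))
  expect_error(fdrBH(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdrBH(c(0.5, NA)), "\\[0, 1\\]")

  withr::with_seed(83, {
    for (i in 1:50) {
      p <- runif(sample(1:30, 1))
      expect_equal(fdrBH(p), bhOracle(p))
      expect_true(all(fdrBH(p) >= p))   # BH never shrinks a p-value
    }
  })
})

suiteFixture <- function(n, b = 0, seed = 1) {
  withr::with_seed(seed, {
    covs <- simulateCovariates(n, seed = seed + 1)
    s <- as.vector(scale(rnorm(n)))
    names(s) <- covs$subject
    counts <- expand.grid(subject = covs$subject,
                          polarity = c("pothole", "molehill"),
                          thresholdMM3 = c(25, 50, 100, 200),
                          stringsAsFactors = FALSE)
    lambda <- ifelse(counts$polarity == "molehill",
                     pmax(3 + b * s[counts$subject], 0), 3)
    counts$count <- rpois(nrow(counts), lambda)
  })
  list(counts = counts, covs = covs, scores = s)
}

test_that("the genetic suite runs 8 FDR-grouped models and validates input", {
  fx <- suiteFixture(300, b = 0.9, seed = 91)
  res <- runGlobalSuite(fx$counts, fx$covs, fx$scores, suite = "prs")
  expect_identical(nrow(res), 8L)
  expect_identical(unique(res$exposure), "prs")
  expect_setequal(res$thresholdMM3, c(25, 50, 100, 200))
  expect_equal(res$q, fdrBH(res$p))
  expect_true(all(res$deltaR2 >= -1e-12))
  # planted positive score-molehill link shows positive molehill betas
  expect_true(all(res$beta[res$polarity == "molehill"] > 0))

  expect_error(runGlobalSuite(fx$counts, fx$covs, NULL, suite = "prs"),
               "scores")
  few <- fx$scores[1:10]
  expect_error(runGlobalSuite(fx$counts, fx$covs, few, suite = "prs"),
               "mismatch")
})

test_that("the descriptive suite fits 16 mutually adjusted sex/age models", {
  fx <- suiteFixture(300, seed = 92)
  res <- runGlobalSuite(fx$counts, fx$covs, suite = "descriptive")
  expect_identical(nrow(res), 16L)
  expect_setequal(res$exposure, c("sex", "age"))
  expect_equal(res$q, fdrBH(res$p))
})

test_that("the tract suite fits 17 models with handedness only when lateral", {
  tmpl <- tinyTemplate()
  atlas <- tmpl$atlas
  n <- 200
  withr::with_seed(93, {
    covs <- simulateCovariates(n, seed = 94)
    s <- as.vector(scale(rnorm(n))); names(s) <- covs$subject
    tc <- expand.grid(subject = covs$subject,
                      label = c(as.integer(names(tractNames(atlas))), 0L),
                      polarity = c("pothole", "molehill"),
                      thresholdMM3 = 25,
                      stringsAsFactors = FALSE)
    tc$count <- rpois(nrow(tc), 2)
    tc$tract <- "x"
  })
  res <- runTractSuite(tc, covs, s, atlas)
  expect_identical(nrow(res), 17L)
  expect_true(all(res$q >= res$p))            # all-null BH property
  expect_setequal(res$laterality, c("left", "right", "midline"))

  noHand <- covs[setdiff(names(covs), "handedness")]
  expect_error(runTractSuite(tc, noHand, s, atlas), "handedness")
  resNoHand <- runTractSuite(tc, noHand, s, atlas,
                             requireHandedness = FALSE)
  expect_identical(nrow(resNoHand), 17L)
})

test_that("handedness enters lateralized tract models and only those", {
  tmpl <- tinyTemplate()
  atlas <- tmpl$atlas
  n <- 150
  withr::with_seed(95, {
    covs <- simulateCovariates(n, seed = 96)
    s <- as.vector(scale(rnorm(n))); names(s) <- covs$subject
    tc <- expand.grid(subject = covs$subject,
                      label = c(as.integer(names(tractNames(atlas))), 0L),
                      polarity = "molehill", thresholdMM3 = 25,
                      stringsAsFactors = FALSE)
    # make counts depend on handedness so the adjustment changes the fit
    tc$count <- rpois(nrow(tc), 2 + 2 * covs$handedness[
      match(tc$subject, covs$subject)])
  })
  res <- runTractSuite(tc, covs, s, atlas)
  resNo <- runTractSuite(tc, covs[setdiff(names(covs), "handedness")],
                         s, atlas, requireHandedness = FALSE)
  lateral <- res$laterality != "midline"
  expect_true(all(res$se[lateral] != resNo$se[lateral]))
  expect_equal(res$beta[!lateral], resNo$beta[!lateral])
})
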