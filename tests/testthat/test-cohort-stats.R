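test_that("in-brace correction is the relative Cobb-angle reduction", {
  expect_equal(computeIBC(40, 30), 25)
  expect_equal(computeIBC(30.5, 30.5), 0)
  expect_equal(computeIBC(38.4, 32.2), 100 * (38.4 - 32.2) / 38.4)
  # worsening in brace is negative, not an error
  expect_lt(computeIBC(30, 35), 0)
  expect_error(computeIBC(0, 10), "preCA")
  expect_error(computeIBC(-5, 10), "preCA")
  # vectorised
  expect_equal(computeIBC(c(40, 50), c(30, 40)), c(25, 20))
})

test_that("Spearman's rho matches the rank formula and handles ties/constants", {
  expect_equal(spearmanRho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearmanRho(1:3, c(3, 2, 1)), -1)
  expect_equal(spearmanRho(1:4, c(2, 1, 4, 3)), 0.6)
  # tie-free random cases against the classical formula
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:9, 1)
    x <- sample(1000, n); y <- sample(1000, n)
    expect_equal(spearmanRho(x, y), oracleSpearmanTieFree(x, y),
                 tolerance = 1e-12)
  }
  # invariance under strictly increasing transforms
  x <- c(3, 1, 4, 1.5, 9, 2.6); y <- c(2, 7, 1, 8, 2.8, 1.8)
  expect_equal(spearmanRho(exp(x), y), spearmanRho(x, y))
  expect_equal(spearmanRho(x, y^3), spearmanRho(x, y))
  # ties: average ranks (cross-checked against stats::cor on ranks)
  xt <- c(1, 2, 2, 3); yt <- c(1, 3, 2, 4)
  expect_equal(spearmanRho(xt, yt), stats::cor(rank(xt), rank(yt)))
  # constant vector: flagged undefined, not an error
  r <- spearmanRho(rep(1, 5), 1:5)
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
  expect_error(spearmanRho(1:2, 1:2), "n >= 3")
})

test_that("strength bins reproduce the conventional classification", {
  expect_equal(as.character(classifyStrength(-0.85)), "strong")
  expect_equal(as.character(classifyStrength(0.64)), "moderate")
  expect_equal(as.character(classifyStrength(-0.72)), "strong")
  expect_equal(as.character(classifyStrength(0.10)), "little if any")
  # bin edges: half-open, boundary to the lower category's printed edge
  cases <- c("0.25" = "little if any", "0.251" = "weak", "0.495" = "weak",
             "0.5" = "moderate", "0.695" = "moderate", "0.7" = "strong",
             "0.89" = "strong", "0.9" = "very strong", "1" = "very strong",
             "0" = "little if any")
  for (v in names(cases))
    expect_equal(as.character(classifyStrength(as.numeric(v))),
                 unname(cases[v]), info = v)
  # symmetric in sign
  for (r in c(0.1, 0.3, 0.6, 0.8, 0.95))
    expect_equal(classifyStrength(r), classifyStrength(-r))
  expect_true(is.na(classifyStrength(NA)))
  expect_error(classifyStrength(1.2), "rho")
})

test_that("correlation tables are deterministic, ordered and sign-correct", {
  set.seed(7)
  n <- 12
  base <- as.data.frame(stats::setNames(
    lapply(segmentFeatureNames(), function(f) rep(0.5, n)),
    segmentFeatureNames()))
  rec <- cbind(data.frame(lenkeType = rep(5, n)), base)
  # plant a perfect monotone relation in one positive feature
  rec$peakPositive_PLM <- seq(1, 4, length.out = n)
  rec$ibcAP <- 10 + 3 * rec$peakPositive_PLM
  tb <- correlationTable(rec, 5, "ibcAP")
  expect_equal(tb$feature, segmentFeatureNames())
  expect_equal(tb$rho[tb$feature == "peakPositive_PLM"], 1)
  expect_equal(as.character(tb$category[tb$feature == "peakPositive_PLM"]),
               "very strong")
  expect_true(all(tb$n == n))
  # constant features are flagged NA, not fabricated
  expect_true(all(is.na(tb$rho[tb$feature != "peakPositive_PLM"])))
  # permutation invariance
  tb2 <- correlationTable(rec[sample(n), ], 5, "ibcAP")
  expect_equal(tb2, tb)
  # peak-negative features correlate by expansion depth (magnitude):
  # deeper expansion with lower IBC gives a negative rho
  rec$peakNegative_PLM <- -seq(1, 6, length.out = n)
  rec$ibcAP <- 30 + 2 * rec$peakNegative_PLM
  tb3 <- correlationTable(rec, 5, "ibcAP")
  expect_equal(tb3$rho[tb3$feature == "peakNegative_PLM"], -1)
  # too few records
  expect_error(correlationTable(rec[1:2, ], 5, "ibcAP"), ">= 3")
  expect_error(correlationTable(rec, 1, "ibcAP"), "Lenke")
})

test_that("cohort summaries use sample SD and flag singleton groups", {
  rec <- data.frame(lenkeType = c(1, 1, 1, 5),
                    ibcAP = c(10, 20, 30, 12))
  s <- summarizeCohort(rec, "ibcAP")
  g1 <- s[s$lenkeType == 1, ]
  expect_equal(g1$mean, 20)
  expect_equal(g1$sd, 10)
  g5 <- s[s$lenkeType == 5, ]
  expect_true(is.na(g5$sd))
  expect_true(g5$sdUndefined)
  # identical values: SD 0
  s2 <- summarizeCohort(data.frame(lenkeType = 1, ibcAP = rep(7, 4)), "ibcAP")
  expect_equal(s2$sd, 0)
  # brute-force two-pass oracle on 1000 random values
  set.seed(5)
  x <- rnorm(1000, 50, 12)
  s3 <- summarizeCohort(data.frame(lenkeType = 1, ibcAP = x), "ibcAP")
  m <- sum(x) / 1000
  expect_equal(s3$mean, m, tolerance = 1e-10)
  expect_equal(s3$sd, sqrt(sum((x - m)^2) / 999), tolerance = 1e-10)
  expect_error(summarizeCohort(rec[0, ]), "no records")
})
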