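dnHours <- rep(c(4, 10, 16, 22), each = 2)

test_that("Lomb-Scargle detects a noiseless cosine at the tested period", {
  y <- cos(2 * pi * dnHours / 24)
  r <- lombScargleTest(y, dnHours, permutations = 999, seed = 1)
  expect_lte(r$p, 0.01)
  # all-equal series has no periodic signal by definition
  expect_equal(lombScargleTest(rep(2, 8), dnHours, seed = 1)$p, 1)
})

test_that("Lomb-Scargle power matches a direct periodogram evaluation", {
  # independent evaluation of the classical normalized periodogram on a
  # 6-point toy series
  t6 <- c(4, 10, 16, 22, 28, 34)
  set.seed(8)
  y <- rnorm(6)
  w <- 2 * pi / 24
  tau <- atan2(sum(sin(2 * w * t6)), sum(cos(2 * w * t6))) / (2 * w)
  yc <- y - mean(y)
  direct <- (sum(yc * cos(w * (t6 - tau)))^2 / sum(cos(w * (t6 - tau))^2) +
             sum(yc * sin(w * (t6 - tau)))^2 / sum(sin(w * (t6 - tau))^2)) /
    (2 * var(y))
  got <- lombScargleTest(y, t6, permutations = 9, seed = 1)$power
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("permutation p-values respect their lower bound", {
  y <- cos(2 * pi * dnHours / 24)
  for (B in c(9, 99, 999)) {
    p <- lombScargleTest(y, dnHours, permutations = B, seed = 3)$p
    expect_gte(p, 1 / (B + 1))
    expect_lte(p, 1)
  }
})

test_that("template test reaches tau 1 on a perfectly ordered series", {
  y <- cos(2 * pi * dnHours / 24)          # phase-0 template itself
  r <- jtkTemplateTest(y, dnHours)
  expect_equal(r$tau, 1, tolerance = 1e-12)
  expect_equal(r$phase, 0)
  expect_lt(r$p, 0.01)
})

test_that("tau-b equals brute-force pair counting, including ties", {
  toys <- list(c(1.2, 0.5, 3.1, 0.5, 2.0),
               c(2, 2, 1, 3, 1),
               c(0.1, 0.2, 0.3, 0.4, 0.5),
               c(5, 4, 3, 2, 1))
  t5 <- c(4, 10, 16, 22, 4)
  templates <- vapply(c(0, 6, 12, 18),
                      function(ph) cos(2 * pi * (t5 - ph) / 24), numeric(5))
  for (y in toys) {
    r <- jtkTemplateTest(y, t5)
    brute <- max(apply(templates, 2, tauBruteForce, x = y))
    expect_equal(r$tau, brute, tolerance = 1e-12)
  }
})

test_that("the enumeration null is exact: uniform sub-alpha rejection", {
  set.seed(20)
  Y <- matrix(rnorm(2000 * 8), 2000, 8)
  p <- dielcycle:::.jtkTestMatrix(Y, dnHours)$p
  expect_true(all(p >= 1 / factorial(8) & p <= 1))
  # rejection never exceeds the nominal level for an exact test
  for (a in c(0.01, 0.05, 0.1))
    expect_lte(mean(p < a), a + 3 * sqrt(a * (1 - a) / 2000))
})

test_that("cosinor fits a noiseless cosine exactly", {
  y <- 3 + 2 * cos(2 * pi * (dnHours - 10) / 24)
  r <- cosinorTest(y, dnHours)
  expect_equal(r$amplitude, 2, tolerance = 1e-9)
  expect_equal(r$acrophase, 10, tolerance = 1e-9)
  expect_lt(r$p, 1e-6)
})

test_that("cosinor coefficients match a normal-equations solve", {
  t6 <- c(4, 8, 14, 20, 28, 40)
  set.seed(9)
  y <- rnorm(6, 5, 2)
  w <- 2 * pi / 24
  X <- cbind(1, cos(w * t6), sin(w * t6))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- cosinorTest(y, t6)
  expect_equal(r$coefficients, as.vector(beta), tolerance = 1e-9)
  # and the F-test agrees with R's linear-model machinery
  fit <- lm(y ~ X - 1)
  fit0 <- lm(y ~ 1)
  pa <- anova(fit0, fit)$`Pr(>F)`[2]
  expect_equal(r$p, pa, tolerance = 1e-9)
})

test_that("degenerate cosinor designs are rejected", {
  expect_error(cosinorTest(rnorm(4), rep(4, 4)), class = "diel_rank_deficient")
  # constant series carries no rhythm
  expect_equal(cosinorTest(rep(1, 8), dnHours)$p, 1)
})

test_that("rejection rate grows with amplitude", {
  rates <- vapply(c(0, 0.5, 1, 2), function(A) {
    set.seed(300 + A * 10)
    n <- 200
    Y <- t(vapply(seq_len(n), function(i)
      A * cos(2 * pi * (dnHours - sample(c(4, 10, 16, 22), 1)) / 24) +
        rnorm(8, 0, 1), numeric(8)))
    mean(dielcycle:::.cosinorMatrix(Y, dnHours)$p < 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) > -0.05))    # monotone within MC error
  expect_lt(rates[1], 0.12)
  # closed-form oracle: the aligned cosine at the 8 design points has
  # sum-of-squares 4 A^2, so the F(2, 5) noncentrality is 4 A^2 / sigma^2
  powerExpected <- pf(qf(0.95, 2, 5), 2, 5, ncp = 4 * 2^2, lower.tail = FALSE)
  expect_lt(abs(rates[4] - powerExpected), 0.1)
})

test_that("between-period correlation matches the closed-form t transform", {
  sheet <- dielSampleSheet(rep(1L, 8))
  m <- rbind(same = c(1, 2, 4, 3, 2, 4, 8, 6),        # identical z halves
             anti = c(1, 2, 4, 3, 4, 3, 1, 2),
             mixed = c(0.3, 1.9, 0.6, 1.1, 1.2, 0.8, 1.4, 0.2),
             flathalf = c(1, 1, 1, 1, 5, 2, 3, 4))
  colnames(m) <- sheet$sample_id
  pc <- periodCorrelation(conditionProfiles(DielExperiment(m, sheet)))
  expect_equal(pc$r[1], 1, tolerance = 1e-9)
  expect_true(pc$significant[1])
  expect_equal(pc$r[2], -1, tolerance = 1e-9)
  # closed form: t = r sqrt(df / (1 - r^2)), two-sided at df = 2
  z <- zscoreProfile(m[3, ])$z
  r <- cor(z[1:4], z[5:8])
  pExpected <- 2 * pt(-abs(r * sqrt(2 / (1 - r^2))), df = 2)
  expect_equal(pc$p[3], pExpected, tolerance = 1e-9)
  # zero-variance half: undefined, never significant
  expect_true(pc$undefined[4])
  expect_false(pc$significant[4])
  # the announced threshold for |r| = 0.99 at n = 4
  p99 <- 2 * pt(-abs(0.99 * sqrt(2 / (1 - 0.99^2))), df = 2)
  expect_lt(p99, 0.05)
})

test_that("consensus splits candidates by pattern match", {
  per <- S4Vectors::DataFrame(
    gene_id = c("g1", "g2", "g3", "g4"),
    candidate = c(TRUE, TRUE, FALSE, FALSE))
  pat <- S4Vectors::DataFrame(
    gene_id = c("g1", "g2", "g3", "g4"),
    matched = c(TRUE, FALSE, TRUE, FALSE))
  cs <- consensusSets(per, pat)
  expect_identical(cs$candidate, c("g1", "g2"))
  expect_identical(cs$high_sensitivity, "g1")
  expect_identical(cs$excluded, "g2")
  # no candidates -> all sets empty
  per$candidate[] <- FALSE
  cs0 <- consensusSets(per, pat)
  expect_identical(lengths(cs0), c(candidate = 0L, high_sensitivity = 0L,
                                   excluded = 0L))
  expect_error(consensusSets(per[1:3, ], pat), class = "diel_gene_mismatch")
})

test_that("the final partition applies the category rules and flags", {
  pat <- S4Vectors::DataFrame(
    gene_id = paste0("g", 1:5),
    matched = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    constant = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    flat = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    pattern_label = c("b", "e", NA, NA, NA),
    phase_group = c("morning", "dusk", NA, NA, NA))
  cons <- list(candidate = c("g1", "g3"), high_sensitivity = "g1",
               excluded = "g3")
  corr <- S4Vectors::DataFrame(gene_id = paste0("g", 1:5),
                               significant = c(TRUE, TRUE, TRUE, FALSE,
                                               FALSE))
  calls <- finalPartition(pat, cons, corr)
  expect_identical(calls$category,
                   c("statistical_rhythmic", "general_rhythm", "nonrhythmic",
                     "nonrhythmic", "nonrhythmic"))
  # pattern-matched gene without periodicity support is general rhythm
  expect_identical(calls$pattern_label[2], "e")
  expect_match(calls$flags[1], "significant_correlation")
  expect_identical(calls$flags[2], "")     # sig corr only tags statistical
  expect_match(calls$flags[3], "low_sensitivity")
  expect_match(calls$flags[4], "constant")
  # labels are none exactly for nonrhythmic genes
  expect_identical(calls$pattern_label == "none",
                   calls$category == "nonrhythmic")
  # additivity: statistical + general = pattern-matched
  expect_equal(sum(calls$category != "nonrhythmic"), sum(pat$matched))
})

test_that("a candidate with mismatched periods is excluded low-sensitivity", {
  sim <- simulateDielExperiment(nGenes = 80, fracRhythmic = 0.4,
                                fracLowSensitivity = 0.4,
                                fracFluctuating = 0, fracConstant = 0,
                                fracLowAbundance = 0, noiseSd = 0.05,
                                seed = 23)
  res <- runDielPipeline(sim$experiment, permutations = 199)
  tr <- sim$truth
  ls <- tr$gene_id[tr$truth_class == "low_sensitivity"]
  cand <- res$periodicity$gene_id[res$periodicity$candidate]
  lsCand <- intersect(ls, cand)
  expect_gt(length(lsCand), 0)
  idx <- match(lsCand, res$calls$gene_id)
  expect_true(all(res$calls$category[idx] == "nonrhythmic"))
  expect_true(all(grepl("low_sensitivity", res$calls$flags[idx])))
})
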