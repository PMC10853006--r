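test_that("the worked-example profile yields down-up-up / up / down-up-up", {
  sg <- extractSigns(zWorked)
  expect_identical(sg$dn, c("down", "up", "up"))
  expect_identical(sg$transition, "up")
  expect_identical(sg$cl, c("down", "up", "up"))
  expect_true(sg$matched)
  cp <- classifyPattern(zWorked)
  expect_identical(cp$label, "a")
  expect_identical(cp$phase_group, "morning")
  expect_identical(cp$peak, "DN4")
  expect_identical(cp$trough, "DN10")
})

test_that("patterns differing between periods do not match", {
  # up/up/down in DN vs up/down/down in CL (the low-sensitivity shape)
  z <- c(-1, 0, 1, -0.5, -1, 1, 0.5, -0.6)
  sg <- extractSigns(z)
  expect_identical(sg$dn, c("up", "up", "down"))
  expect_identical(sg$cl, c("up", "down", "down"))
  expect_false(sg$matched)
})

test_that("exact ties give flat signs and disqualify matching", {
  z <- c(1, 1, -0.5, 0.2, 1, 0.9, -0.5, 0.2)
  sg <- extractSigns(z)
  expect_identical(sg$dn[1], "flat")
  expect_false(sg$matched)
  expect_error(extractSigns(rep(1, 8)), class = "diel_constant_profile")
  expect_error(classifyPattern(c(1, 1, 0, -1)), class = "diel_unclassifiable")
})

test_that("epsilon widens the flat band", {
  z <- c(0, 0.05, 1, 2, 0, 0.05, 1, 2)
  expect_identical(extractSigns(z)$dn[1], "up")
  expect_identical(extractSigns(z, epsilon = 0.1)$dn[1], "flat")
})

test_that("cyclic sign enumeration yields exactly 14 achievable classes", {
  # brute force over all 16 up/down assignments of the cyclic 4-sign
  # sequence: all-up and all-down are impossible (differences sum to zero)
  grid <- expand.grid(s1 = c(1, -1), s2 = c(1, -1),
                      s3 = c(1, -1), s4 = c(1, -1))
  achievable <- grid[rowSums(grid) != 4 & rowSums(grid) != -4, ]
  expect_equal(nrow(achievable), 14L)
  labs <- apply(achievable, 1, function(s) {
    # realize the sign sequence as a 4-vector: cumulative sums of signed
    # steps sized so that the wrap sign is honored
    steps <- as.numeric(s[1:3])
    # choose magnitudes: make the wrap difference match s[4]
    for (mag in list(c(1, 1, 1), c(3, 1, 1), c(1, 1, 3), c(1, 3, 1),
                     c(2, 3, 2))) {
      z <- cumsum(c(0, steps * mag))
      wrap <- sign(z[1] - z[4])
      if (wrap == s[4]) return(classifyPattern(z)$label)
    }
    NA_character_
  })
  expect_false(anyNA(labs))
  expect_equal(sort(unname(labs)), letters[1:14])
})

test_that("random profiles each get one label; major labels obey argmax", {
  set.seed(10)
  labs <- character(1e4)
  for (i in seq_len(1e4)) {
    z <- rnorm(4)
    cp <- classifyPattern(z)
    labs[i] <- cp$label
    expect_true(cp$label %in% letters[1:14])
    if (cp$label %in% letters[1:12]) {
      expect_identical(cp$label, majorLabelOracle(z))
      dn <- c("DN4", "DN10", "DN16", "DN22")
      expect_identical(cp$peak, dn[which.max(z)])
      expect_identical(cp$trough, dn[which.min(z)])
    } else {
      expect_true(isAlternating(z))
    }
  }
  # unimodal profiles are exactly the major-labelled ones
  expect_gt(sum(labs %in% letters[1:12]), 0)
  expect_gt(sum(labs %in% c("m", "n")), 0)
})

test_that("alternating profiles map to the minor patterns by peak position", {
  expect_identical(classifyPattern(c(-1, 1, -1, 1))$label, "m")
  expect_identical(classifyPattern(c(1, -1, 1, -1))$label, "n")
  cp <- classifyPattern(c(-2, 3, -1, 2))
  expect_identical(cp$label, "m")
  expect_identical(cp$peak, "DN10,DN22")
})

test_that("negating z swaps peak and trough consistently", {
  set.seed(11)
  for (i in 1:200) {
    z <- rnorm(4)
    a <- classifyPattern(z)
    b <- classifyPattern(-z)
    if (a$label %in% letters[1:12]) {
      expect_identical(b$peak, a$trough)
      expect_identical(b$trough, a$peak)
    } else {
      expect_true(b$label %in% c("m", "n"))
      expect_false(a$label == b$label)
    }
    # sign extraction maps up <-> down under negation
    z8 <- c(z, rnorm(4))
    s1 <- extractSigns(z8); s2 <- extractSigns(-z8)
    flipped <- c(up = "down", down = "up", flat = "flat")
    expect_identical(s2$dn, unname(flipped[s1$dn]))
  }
})

test_that("classification is invariant to shifting and positive scaling", {
  set.seed(12)
  z <- rnorm(4)
  ref <- classifyPattern(z)$label
  for (i in 1:20) {
    expect_identical(classifyPattern(z * runif(1, .01, 50) +
                                       rnorm(1, 0, 10))$label, ref)
  }
})

test_that("pattern calls flag constant and flat genes, label matched ones", {
  sheet <- dielSampleSheet(rep(1L, 8))
  m <- rbind(cosinor = 10 * (1 + 0.9 * cos(2 * pi * (conditionHours() %% 24
                                                     - 10) / 24)),
             constant = rep(2, 8),
             tied = c(1, 1, 2, 3, 1, 1, 2, 3))
  colnames(m) <- sheet$sample_id
  x <- DielExperiment(m, sheet)
  pat <- callPatternRhythmic(conditionProfiles(x))
  expect_true(pat$matched[1])
  expect_identical(pat$phase_group[1], "dusk")
  expect_true(pat$constant[2])
  expect_false(pat$matched[2])
  expect_true(pat$flat[3])
  expect_false(pat$matched[3])
})

test_that("low-sensitivity genes are not pattern-rhythmic by construction", {
  sim <- simulateDielExperiment(nGenes = 60, fracRhythmic = 0,
                                fracLowSensitivity = 1, fracFluctuating = 0,
                                fracConstant = 0, fracLowAbundance = 0,
                                noiseSd = 0, seed = 17)
  pat <- callPatternRhythmic(conditionProfiles(sim$experiment))
  expect_false(any(pat$matched))
})

test_that("pattern calling recovers truth with high sensitivity", {
  hits <- misses <- 0; fp <- tn <- 0
  for (s in 1:3) {
    sim <- simulateDielExperiment(nGenes = 1500, amplitude = 1,
                                  noiseSd = 0.1, seed = 200 + s)
    xf <- filterLowAbundance(sim$experiment)
    pat <- callPatternRhythmic(conditionProfiles(xf))
    tr <- sim$truth[match(pat$gene_id, sim$truth$gene_id), ]
    pos <- tr$truth_class %in% c("rhythmic", "fluctuating")
    hits <- hits + sum(pat$matched[pos]); misses <- misses + sum(!pat$matched[pos])
    neg <- !pos
    fp <- fp + sum(pat$matched[neg]); tn <- tn + sum(!pat$matched[neg])
  }
  expect_gte(hits / (hits + misses), 0.9)
  # random DN/CL sign agreement happens at rate 88/576 ~ 0.153, so
  # specificity against a noise-dominated background sits near 0.85
  expect_gte(tn / (tn + fp), 0.8)
})
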