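## Periodicity-test ensemble on the DN period: Lomb-Scargle periodogram with
## a permutation null, a rank-based cosine-template (JTK-style) test with an
## exact enumeration null, and cosinor harmonic regression; plus a 48-h
## cosinor detector used as the second, independent candidate source.

.dielCache <- new.env(parent = emptyenv())

## evaluate `code` under a temporary RNG seed, restoring global RNG state
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  code
}

## all n! permutations of 1..n as an (n!) x n integer matrix (n <= 8)
.allPerms <- function(n) {
  key <- paste0("perms_", n)
  if (!is.null(.dielCache[[key]])) return(.dielCache[[key]])
  P <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- ((pos - 1L) * m + 1L):(pos * m)
      out[rows, pos] <- k
      out[rows, -pos] <- P
    }
    P <- out
  }
  .dielCache[[key]] <- P
  P
}

## ---------------------------------------------------------------- Lomb-Scargle

.lsSetup <- function(hours, period) {
  w <- 2 * pi / period
  tau <- atan2(sum(sin(2 * w * hours)), sum(cos(2 * w * hours))) / (2 * w)
  ct <- cos(w * (hours - tau))
  st <- sin(w * (hours - tau))
  list(ct = ct, st = st, Cc = sum(ct^2), Ss = sum(st^2))
}

## unnormalized LS statistic per row (permutation-invariant scale omitted)
.lsStat <- function(Yc, su) {
  as.vector((Yc %*% su$ct)^2 / su$Cc + (Yc %*% su$st)^2 / su$Ss)
}

.lsTestMatrix <- function(Y, hours, period = 24, permutations = 999,
                          seed = NULL) {
  stopifnot(length(unique(hours[hours <= period])) >= 4L)
  su <- .lsSetup(hours, period)
  Yc <- Y - rowMeans(Y)
  constant <- rowSums(abs(Yc)) == 0
  obs <- .lsStat(Yc, su)
  n <- ncol(Y)
  permIdx <- .withSeed(seed,
                       replicate(permutations, sample.int(n), simplify = TRUE))
  cnt <- integer(nrow(Y))
  for (b in seq_len(permutations)) {
    pb <- .lsStat(Yc[, permIdx[, b], drop = FALSE], su)
    cnt <- cnt + (pb >= obs * (1 - 1e-12) - 1e-300)
  }
  p <- (1 + cnt) / (permutations + 1)
  p[constant] <- 1
  p
}

#' Lomb-Scargle periodicity test at a fixed period
#'
#' Computes the normalized Lomb-Scargle power of the observations at the test
#' period (default 24 h) and a permutation p-value: the observations are
#' shuffled across timepoints `permutations` times and
#' p = (1 + #\{permuted power >= observed\}) / (permutations + 1).  All-equal
#' observations give p = 1.
#'
#' @param y numeric observations (replicate-level; duplicated hours allowed).
#' @param hours sampling hours of each observation; at least 4 distinct
#'   timepoints within one period.
#' @param period test period in hours (default 24).
#' @param permutations number of permutations (default 999).
#' @param seed integer seed for the permutation draw (RNG state restored).
#' @return list with `power` (normalized periodogram value) and `p`.
#' @examples
#' h <- rep(c(4, 10, 16, 22), each = 2)
#' lombScargleTest(cos(2 * pi * h / 24), h, seed = 1)
#' @export
lombScargleTest <- function(y, hours, period = 24, permutations = 999,
                            seed = NULL) {
  stopifnot(length(y) == length(hours))
  Y <- matrix(y, nrow = 1L)
  p <- .lsTestMatrix(Y, hours, period, permutations, seed)
  su <- .lsSetup(hours, period)
  v <- var(y)
  power <- if (v == 0) 0 else .lsStat(Y - mean(y), su) / (2 * v)
  list(power = unname(power), p = p)
}

## ------------------------------------------------------- JTK-style template

.jtkTemplates <- function(hours, period = 24, phases = c(0, 6, 12, 18)) {
  vapply(phases, function(ph) cos(2 * pi * (hours - ph) / period),
         numeric(length(hours)))
}

.pairSigns <- function(v, pairs, tol = 1e-12) {
  d <- v[pairs[1L, ]] - v[pairs[2L, ]]
  s <- sign(d)
  s[abs(d) <= tol] <- 0
  s
}

## per-row Kendall tau-b against each template; returns list(tau=G x K, ...)
.jtkObserved <- function(Y, SX, tx, pairs) {
  n0 <- ncol(pairs)
  G <- nrow(Y)
  signY <- matrix(0, G, n0)
  for (k in seq_len(n0)) {
    d <- Y[, pairs[1L, k]] - Y[, pairs[2L, k]]
    signY[, k] <- sign(d)
  }
  ty <- rowSums(signY == 0)
  num <- signY %*% SX
  denom <- sqrt(outer(n0 - ty, n0 - tx))
  tau <- num / denom
  tau[!is.finite(tau)] <- NA_real_
  list(tau = tau, ty = ty)
}

## exact null of max-tau for a given multiset of observation values
.jtkNullExact <- function(values, SX, tx, pairs) {
  n <- length(values)
  n0 <- ncol(pairs)
  P <- .allPerms(n)
  V <- matrix(sort(values)[P], nrow(P), n)
  M <- matrix(0, nrow(P), n0)
  for (k in seq_len(n0)) {
    d <- V[, pairs[1L, k]] - V[, pairs[2L, k]]
    s <- sign(d)
    s[abs(d) <= 1e-12] <- 0
    M[, k] <- s
  }
  ty <- rowSums(M == 0)       # constant over perms, but keep general
  num <- M %*% SX
  taus <- num / sqrt(outer(n0 - ty, n0 - tx))
  sort(do.call(pmax, as.data.frame(taus)))
}

## The exact null depends on the observations only through the tie structure
## of their sorted values, so nulls are cached per (design, tie signature):
## one enumeration serves every gene with the same signature.
.tieSignature <- function(v, tol = 1e-12) {
  paste(as.integer(diff(sort(v)) > tol), collapse = "")
}

.jtkNullCached <- function(sig, SX, tx, pairs, key) {
  k <- paste0("jtknull_", key, "_", sig)
  if (!is.null(.dielCache[[k]])) return(.dielCache[[k]])
  ## representative values with this tie structure: dense ranks of sorted v
  rep_vals <- cumsum(c(0L, as.integer(strsplit(sig, "")[[1L]])))
  nul <- .jtkNullExact(rep_vals, SX, tx, pairs)
  .dielCache[[k]] <- nul
  nul
}

.jtkPFromNull <- function(stat, nullSorted) {
  N <- length(nullSorted)
  idx <- findInterval(stat - 1e-9, nullSorted)
  (N - idx) / N
}

.jtkTestMatrix <- function(Y, hours, period = 24, permutations = 999,
                           seed = NULL, phases = c(0, 6, 12, 18)) {
  n <- ncol(Y)
  X <- .jtkTemplates(hours, period, phases)
  pairs <- utils::combn(n, 2L)
  SX <- apply(X, 2L, .pairSigns, pairs = pairs)
  tx <- colSums(SX == 0)
  obs <- .jtkObserved(Y, SX, tx, pairs)
  stat <- suppressWarnings(
    apply(obs$tau, 1L, max, na.rm = TRUE))
  allEqual <- obs$ty == ncol(pairs)
  stat[allEqual] <- -Inf
  p <- rep(NA_real_, nrow(Y))
  if (n <= 8L) {
    key <- paste(n, period, paste(signif(sort(hours), 8), collapse = ","),
                 paste(phases, collapse = ","), sep = "_")
    sigs <- apply(Y, 1L, .tieSignature)
    for (sg in unique(sigs[!allEqual])) {
      nul <- .jtkNullCached(sg, SX, tx, pairs, key)
      sel <- sigs == sg & !allEqual
      p[sel] <- .jtkPFromNull(stat[sel], nul)
    }
  } else {
    permIdx <- .withSeed(seed,
                         replicate(permutations, sample.int(n),
                                   simplify = TRUE))
    cnt <- integer(nrow(Y))
    for (b in seq_len(permutations)) {
      ob <- .jtkObserved(Y[, permIdx[, b], drop = FALSE], SX, tx, pairs)
      sb <- suppressWarnings(apply(ob$tau, 1L, max, na.rm = TRUE))
      cnt <- cnt + (sb >= stat - 1e-9)
    }
    p <- (1 + cnt) / (permutations + 1)
  }
  p[allEqual] <- 1
  list(p = p, tau = stat,
       phase = phases[max.col(replace(obs$tau, is.na(obs$tau), -Inf))])
}

#' Rank-based cosine-template periodicity test (JTK-style)
#'
#' Kendall's tau-b is computed between the observations and a reference
#' cosine of the test period evaluated at the observation hours, for each of
#' the four phase offsets 0, 6, 12, 18 h; the statistic is the maximum tau.
#' The one-sided p-value is the exact tail probability of max-tau under the
#' permutation null: full enumeration of all n! observation permutations when
#' n <= 8 (the study design has 4 timepoints x 2 replicates), otherwise
#' Monte-Carlo with a fixed seed.  Ties are handled by the tau-b denominator.
#'
#' @inheritParams lombScargleTest
#' @param phases template phase offsets in hours.
#' @return list with `tau` (max tau-b), `phase` (offset of the best
#'   template) and `p`.
#' @examples
#' h <- rep(c(4, 10, 16, 22), each = 2)
#' jtkTemplateTest(cos(2 * pi * h / 24) + rnorm(8, 0, .1), h)
#' @export
jtkTemplateTest <- function(y, hours, period = 24, permutations = 999,
                            seed = NULL, phases = c(0, 6, 12, 18)) {
  stopifnot(length(y) == length(hours))
  r <- .jtkTestMatrix(matrix(y, 1L), hours, period, permutations, seed,
                      phases)
  list(tau = unname(r$tau), phase = unname(r$phase), p = unname(r$p))
}

## ---------------------------------------------------------------- cosinor

.cosinorMatrix <- function(Y, hours, period = 24) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * hours), sin(w * hours))
  if (qr(X)$rank < 3L)
    stop(dielError("rank_deficient",
                   "cosinor design matrix is rank deficient"))
  B <- Y %*% X %*% solve(crossprod(X))
  RSS1 <- pmax(rowSums((Y - B %*% t(X))^2), 0)
  RSS0 <- rowSums((Y - rowMeans(Y))^2)
  df2 <- ncol(Y) - 3L
  Fst <- ((RSS0 - RSS1) / 2) / (RSS1 / df2)
  p <- pf(Fst, 2, df2, lower.tail = FALSE)
  p[RSS0 <= 1e-300] <- 1            # constant gene: nothing to explain
  list(p = p,
       amplitude = sqrt(B[, 2]^2 + B[, 3]^2),
       acrophase = (atan2(B[, 3], B[, 2]) / w) %% period,
       coefficients = B)
}

#' Cosinor (harmonic regression) periodicity test
#'
#' Least-squares fit of y = M + a cos(2 pi t / period) + b sin(2 pi t /
#' period); the two harmonic coefficients are tested against the
#' intercept-only model with an F-test (df 2 and n - 3).  The amplitude is
#' sqrt(a^2 + b^2) and the acrophase (peak hour) is atan2(b, a) / omega
#' mapped into [0, period).
#'
#' @inheritParams lombScargleTest
#' @return list with `p`, `amplitude`, `acrophase` and the length-3
#'   `coefficients` (intercept, cos, sin).
#' @examples
#' h <- rep(c(4, 10, 16, 22), each = 2)
#' cosinorTest(2 * cos(2 * pi * (h - 10) / 24), h)
#' @export
cosinorTest <- function(y, hours, period = 24) {
  stopifnot(length(y) == length(hours), length(y) >= 4L)
  r <- .cosinorMatrix(matrix(y, 1L), hours, period)
  list(p = unname(r$p), amplitude = unname(r$amplitude),
       acrophase = unname(r$acrophase),
       coefficients = as.vector(r$coefficients))
}

## ----------------------------------------------------------- gene-level runs

#' Run the periodicity-test ensemble on every gene
#'
#' All tests run on log2(abundance + 1) over the DN period (hours 4-22;
#' replicate-level observations), mirroring detection "based on the DN
#' period": the Lomb-Scargle permutation test, the rank-based cosine-template
#' test, and the cosinor F-test.  `meta_significant` requires all three
#' p-values below `alpha` (raw, no multiple-testing correction).  A second,
#' independent detector — a cosinor F-test over the full 48-h series (both
#' periods) — plays the role of an orthogonal rhythm caller;
#' `surrogate_significant` marks its detections and the candidate set is the
#' union of the two routes (switch the second detector off with
#' `surrogate = FALSE`).
#'
#' @param x a [DielExperiment-class]; for the study design, first reduce to
#'   two replicates per condition with [selectTopCorrelatedDuplicates()].
#' @param alpha significance level (default 0.05).
#' @param permutations permutation count for the Lomb-Scargle null.
#' @param seed integer seed for the permutation draws.
#' @param surrogate include the 48-h cosinor detector in the candidate union.
#' @return [S4Vectors::DataFrame], one row per gene: `gene_id`, `p_ls`,
#'   `p_jtk`, `p_cos`, `p_cos48`, `amplitude`, `acrophase`,
#'   `meta_significant`, `surrogate_significant`, `candidate`.
#' @export
periodicityTests <- function(x, alpha = 0.05, permutations = 999, seed = 1,
                             surrogate = TRUE) {
  stopifnot(is(x, "DielExperiment"))
  lg <- log2(abundance(x) + 1)
  hrs <- hoursSinceLight(x)
  dn <- hrs <= 22
  Y <- lg[, dn, drop = FALSE]
  tdn <- hrs[dn]
  p_ls <- .lsTestMatrix(Y, tdn, 24, permutations, seed)
  jtk <- .jtkTestMatrix(Y, tdn, 24, permutations, seed + 1L)
  cdn <- .cosinorMatrix(Y, tdn, 24)
  c48 <- .cosinorMatrix(lg, hrs, 24)
  meta <- p_ls < alpha & jtk$p < alpha & cdn$p < alpha
  surr <- if (surrogate) c48$p < alpha else rep(FALSE, nrow(lg))
  DataFrame(gene_id = rownames(lg), p_ls = p_ls, p_jtk = jtk$p,
            p_cos = cdn$p, p_cos48 = c48$p, amplitude = cdn$amplitude,
            acrophase = cdn$acrophase, meta_significant = meta,
            surrogate_significant = surr, candidate = meta | surr)
}

#' Consensus of periodicity tests and pattern matching
#'
#' Candidates are genes detected by the three-test consensus or by the 48-h
#' cosinor detector.  Candidates whose DN and CL sign patterns match are the
#' high-sensitivity rhythmic genes; candidates whose patterns disagree
#' between the two periods show low sensitivity and are excluded.
#'
#' @param periodicity result of [periodicityTests()].
#' @param patterns result of [callPatternRhythmic()] over the same genes.
#' @return list of gene id vectors: `candidate`, `high_sensitivity`,
#'   `excluded`.
#' @export
consensusSets <- function(periodicity, patterns) {
  if (!setequal(periodicity$gene_id, patterns$gene_id))
    stop(dielError("gene_mismatch",
                   "periodicity and pattern results cover different genes"))
  matched <- patterns$matched[match(periodicity$gene_id, patterns$gene_id)]
  cand <- periodicity$candidate
  list(candidate = periodicity$gene_id[cand],
       high_sensitivity = periodicity$gene_id[cand & matched],
       excluded = periodicity$gene_id[cand & !matched])
}

#' Between-period correlation of a gene's profile
#'
#' Pearson correlation between the four DN and the four CL z-scores of each
#' gene, with the two-sided t-based p-value at df = 2 (the exact permutation
#' null at n = 4 cannot reach 0.05, so the t transform is used).
#'
#' @param profiles a [ConditionProfiles-class].
#' @param alpha significance level for the `significant` flag.
#' @return [S4Vectors::DataFrame] with `gene_id`, `r`, `p`, `significant`,
#'   `undefined` (TRUE when either half has zero variance; such genes are
#'   never significant).
#' @export
periodCorrelation <- function(profiles, alpha = 0.05) {
  stopifnot(is(profiles, "ConditionProfiles"))
  z <- profileZ(profiles)
  n <- nrow(z)
  r <- p <- rep(NA_real_, n)
  undef <- logical(n)
  for (i in seq_len(n)) {
    dnz <- z[i, 1:4]; clz <- z[i, 5:8]
    if (sd(dnz) == 0 || sd(clz) == 0) {
      undef[i] <- TRUE
      next
    }
    ct <- cor.test(dnz, clz)
    r[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  DataFrame(gene_id = rownames(z), r = r, p = p,
            significant = !undef & !is.na(p) & p < alpha,
            undefined = undef)
}

#' Final rhythmic-gene partition
#'
#' Combines the pattern calls, the periodicity consensus and the
#' between-period correlation into one call per gene:
#' `statistical_rhythmic` genes are the high-sensitivity set (periodicity
#' candidate with matching DN/CL patterns); `general_rhythm` genes are
#' pattern-matched but lack periodicity support; everything else is
#' `nonrhythmic`.  Statistical-rhythmic genes with a significant
#' between-period correlation carry the `significant_correlation` flag;
#' candidates with mismatched patterns carry `low_sensitivity`; constant
#' profiles and flat transition signs are flagged too.  By construction
#' #statistical + #general = #pattern-matched.
#'
#' @param patterns result of [callPatternRhythmic()].
#' @param consensus result of [consensusSets()].
#' @param correlations result of [periodCorrelation()].
#' @return [S4Vectors::DataFrame] with `gene_id`, `category`,
#'   `pattern_label`, `phase_group` (both `"none"` for nonrhythmic genes) and
#'   `flags` (semicolon-joined tokens, empty when none).
#' @export
finalPartition <- function(patterns, consensus, correlations) {
  genes <- patterns$gene_id
  matched <- patterns$matched
  hs <- genes %in% consensus$high_sensitivity
  excl <- genes %in% consensus$excluded
  if (any(hs & !matched) || any(excl & matched) || any(hs & excl))
    stop(dielError("inconsistent_sets",
                   "consensus sets inconsistent with pattern matching"))
  category <- ifelse(hs, "statistical_rhythmic",
                     ifelse(matched, "general_rhythm", "nonrhythmic"))
  sig <- correlations$significant[match(genes, correlations$gene_id)]
  sig[is.na(sig)] <- FALSE
  flagMat <- cbind(significant_correlation = hs & sig,
                   constant = patterns$constant,
                   low_sensitivity = excl,
                   flat_transition = patterns$flat & !patterns$constant)
  flags <- unname(apply(flagMat, 1L, function(f)
    paste(colnames(flagMat)[f], collapse = ";")))
  DataFrame(gene_id = genes, category = category,
            pattern_label = ifelse(category == "nonrhythmic", "none",
                                   patterns$pattern_label),
            phase_group = ifelse(category == "nonrhythmic", "none",
                                 patterns$phase_group),
            flags = flags)
}
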