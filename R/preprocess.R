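## Abundance filtering, replicate concordance, duplicate selection, condition
## averaging and z-score standardization.

#' Remove low-abundance genes
#'
#' A gene is removed when its mean abundance across all samples falls below
#' `cutoff` (default 0.1, the conventional TPM/RPKM floor).  Aggregating by
#' the mean keeps the rule independent of sample order and drops genes whose
#' z-scores would be noise-dominated.
#'
#' @param x a [DielExperiment-class].
#' @param cutoff non-negative abundance threshold.
#' @return the filtered `DielExperiment`, gene order preserved;
#'   `metadata(x)$removed_genes` holds the ids of the removed genes.
#' @examples
#' sim <- simulateDielExperiment(nGenes = 50, seed = 1)
#' filt <- filterLowAbundance(sim$experiment)
#' length(S4Vectors::metadata(filt)$removed_genes)
#' @export
filterLowAbundance <- function(x, cutoff = 0.1) {
  stopifnot(is(x, "DielExperiment"), cutoff >= 0)
  keep <- rowMeans(abundance(x)) >= cutoff
  out <- x[keep, ]
  if (!any(keep))
    warning("all genes fall below the abundance cutoff")
  metadata(out)$removed_genes <- rownames(x)[!keep]
  out
}

.pairIndex <- function(k) {
  ## all unordered replicate pairs, lexicographic (ties break to low indices)
  utils::combn(k, 2L)
}

#' Replicate concordance per condition
#'
#' Pearson correlation between every replicate pair within each condition,
#' computed over genes on log2(abundance + 1) (log stabilizes variance across
#' the dynamic range), with the two-sided t-based p-value.
#'
#' @param x a [DielExperiment-class].
#' @return [S4Vectors::DataFrame] with one row per replicate pair: columns
#'   `condition`, `rep_a`, `rep_b`, `r`, `p`; conditions with a single
#'   replicate are skipped with a message.
#' @export
replicateConcordance <- function(x) {
  stopifnot(is(x, "DielExperiment"))
  lg <- log2(abundance(x) + 1)
  cond <- condition(x)
  reps <- replicateId(x)
  rows <- list()
  for (cc in dielConditions()) {
    idx <- which(cond == cc)
    idx <- idx[order(reps[idx])]
    if (length(idx) < 2L) {
      message("condition ", cc, " has a single replicate; skipped")
      next
    }
    pr <- .pairIndex(length(idx))
    for (j in seq_len(ncol(pr))) {
      a <- idx[pr[1L, j]]; b <- idx[pr[2L, j]]
      if (nrow(lg) >= 3L) {
        ct <- cor.test(lg[, a], lg[, b])
        r <- unname(ct$estimate); p <- ct$p.value
      } else {
        ## too few genes for a t-based p; the coefficient is still defined
        r <- cor(lg[, a], lg[, b]); p <- NA_real_
      }
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cc, rep_a = reps[a], rep_b = reps[b],
                   r = r, p = p)
    }
  }
  DataFrame(do.call(rbind, rows))
}

#' Keep the most-correlated replicate pair per condition
#'
#' Periodicity tests require an equal number of replicates per timepoint; one
#' condition of the study design is duplicate-only, so per condition the two
#' replicates with the highest pairwise Pearson correlation (log2(x+1) over
#' genes) are retained.  Ties break to the lowest replicate indices; a
#' condition that is already a duplicate is kept unchanged.
#'
#' @param x a [DielExperiment-class] in which every condition has at least
#'   two replicates.
#' @return a `DielExperiment` with exactly two replicates per condition (a
#'   column subset of the input).
#' @export
selectTopCorrelatedDuplicates <- function(x) {
  stopifnot(is(x, "DielExperiment"))
  lg <- log2(abundance(x) + 1)
  cond <- condition(x)
  reps <- replicateId(x)
  keep <- integer()
  for (cc in dielConditions()) {
    idx <- which(cond == cc)
    idx <- idx[order(reps[idx])]
    if (length(idx) < 2L)
      stop(dielError("too_few_replicates",
                     paste("condition", cc, "has fewer than 2 replicates")))
    if (length(idx) == 2L) {
      keep <- c(keep, idx)
      next
    }
    pr <- .pairIndex(length(idx))
    rs <- vapply(seq_len(ncol(pr)), function(j)
      cor(lg[, idx[pr[1L, j]]], lg[, idx[pr[2L, j]]]), numeric(1))
    best <- which.max(rs)   # first max = lexicographically lowest pair
    keep <- c(keep, idx[pr[, best]])
  }
  x[, keep]
}

#' Per-gene condition means
#'
#' Arithmetic mean abundance over the available replicates of each condition
#' (unequal replicate counts are allowed), in canonical condition order.
#'
#' @param x a [DielExperiment-class].
#' @return numeric matrix, genes x 8, columns `dielConditions()`.
#' @export
conditionMeans <- function(x) {
  stopifnot(is(x, "DielExperiment"))
  a <- abundance(x)
  cond <- condition(x)
  out <- vapply(dielConditions(), function(cc)
    rowMeans(a[, cond == cc, drop = FALSE]), numeric(nrow(a)))
  if (nrow(a) == 1L) {
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(a),
                                                  dielConditions()))
  }
  out
}

#' Standardize an 8-condition profile to z-scores
#'
#' z = (x - mean(x)) / sd(x) with the sample standard deviation (divisor
#' n - 1), applied across the eight condition means of one gene.  A constant
#' profile (sd = 0) cannot be standardized: `constant` is `TRUE` and the z
#' row is an all-zero placeholder.
#'
#' @param means numeric vector of 8 condition means, or a genes x 8 matrix.
#' @return for a vector: `list(z = <8-vector>, constant = <logical>)`; for a
#'   matrix: `list(z = <matrix>, constant = <logical vector>)`.
#' @examples
#' zscoreProfile(c(1.2, 0.5, 0.1, 0.4, 1.0, 0.6, 0.2, 0.5))
#' @export
zscoreProfile <- function(means) {
  if (is.matrix(means)) {
    stopifnot(ncol(means) == 8L, all(is.finite(means)))
    mu <- rowMeans(means)
    s <- sqrt(rowSums((means - mu)^2) / (ncol(means) - 1))
    constant <- s == 0
    z <- (means - mu) / ifelse(constant, 1, s)
    z[constant, ] <- 0
    list(z = z, constant = constant)
  } else {
    stopifnot(length(means) == 8L, all(is.finite(means)))
    s <- sd(means)
    if (s == 0)
      list(z = rep(0, 8L), constant = TRUE)
    else
      list(z = (means - mean(means)) / s, constant = FALSE)
  }
}

#' Condition profiles (means + z-scores) for all genes
#'
#' Averages replicates per condition and standardizes each gene's eight
#' means; see [zscoreProfile()].
#'
#' @param x a [DielExperiment-class] (normally already filtered with
#'   [filterLowAbundance()]).
#' @return a [ConditionProfiles-class] object.
#' @export
conditionProfiles <- function(x) {
  m <- conditionMeans(x)
  zs <- zscoreProfile(m)
  se <- SummarizedExperiment(
    assays = SimpleList(mean = m, z = zs$z),
    rowData = DataFrame(constant = zs$constant, row.names = rownames(m)))
  new("ConditionProfiles", se)
}
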