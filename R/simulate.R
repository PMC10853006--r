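## Ground-truth simulator for the diel design: replicated abundance matrices
## with known rhythmic structure, so every downstream stage is testable.

.TRUTH_CLASSES <- c("rhythmic", "low_sensitivity", "fluctuating",
                    "constant", "arrhythmic")

## analytic condition means of one gene: mu * (1 + A cos(2 pi (t - phase)/per))
.waveMeans <- function(mu, amplitude, phase, period = 24,
                       clPhase = phase) {
  h <- conditionHours()
  ph <- c(rep(phase, 4L), rep(clPhase, 4L))
  mu * (1 + amplitude * cos(2 * pi * (h %% 24 - ph) / period))
}

#' Taxonomy label of a noiseless waveform
#'
#' Computes the pattern label that a gene following the given waveform would
#' receive in the absence of noise, by classifying the analytic condition
#' means with [classifyPattern()] — so recovery tests compare like with like.
#' A 24-h cosinor peaking at hour `phase` is unimodal with its trough half a
#' period later (phase 4 -> pattern b, 10 -> e, 16 -> h, 22 -> k); a 12-h
#' fluctuation alternates (maxima at DN10/DN22 -> m, at DN4/DN16 -> n).
#'
#' @param phase peak hour, one of 4, 10, 16, 22.
#' @param waveform `"cosinor24"` or `"fluct12"`.
#' @return the pattern label, a single character.
#' @examples
#' truthPattern(4, "cosinor24")   # "b": peak DN4, trough DN16
#' truthPattern(10, "fluct12")    # "m": maxima DN10 and DN22
#' @export
truthPattern <- function(phase, waveform = c("cosinor24", "fluct12")) {
  waveform <- match.arg(waveform)
  stopifnot(phase %in% c(4, 10, 16, 22))
  per <- if (waveform == "cosinor24") 24 else 12
  m <- .waveMeans(1, 0.8, phase, per)[1:4]
  classifyPattern(m)$label
}

#' Simulate a replicated diel expression experiment with ground truth
#'
#' Generates a gene x sample abundance matrix under the study design (eight
#' conditions, triplicate except duplicate CL16 by default).  Gene classes:
#'
#' * `rhythmic`: condition mean mu (1 + A cos(2 pi (t - phase)/24)), peak
#'   phase drawn from \{4, 10, 16, 22\}, same phase in both periods.
#' * `low_sensitivity`: rhythmic in DN but with a different peak phase in CL,
#'   so the two periods' sign patterns disagree.
#' * `fluctuating`: 12-h period (two maxima per day, patterns m/n).
#' * `constant`: flat condition mean (A = 0).
#' * `arrhythmic` (the remainder): per-condition log2-Normal(0, `wanderSd`)
#'   wander — condition-to-condition variation with no temporal structure.
#'
#' Every replicate observation is its condition mean times `2^e` with
#' e ~ Normal(0, `noiseSd`): multiplicative log-normal noise keeps abundances
#' non-negative.  Replicate Pearson concordance on log2(x + 1) is about 0.997
#' at the default sd 0.15 and falls into the 0.93-0.99 range typical of real
#' replicated RNA-seq near sd 0.5.  A `fracLowAbundance`
#' subset of the constant/arrhythmic genes is scaled below the 0.1 abundance
#' cutoff.  Identical seeds give bit-identical output.
#'
#' @param nGenes number of genes (default 8000, the study's post-filter
#'   scale).
#' @param fracRhythmic,fracLowSensitivity,fracFluctuating,fracConstant class
#'   fractions; they must sum to at most 1 and the remainder is arrhythmic.
#'   Defaults mirror the study: 0.39 rhythmic (3,098/7,985), 0.12
#'   low-sensitivity (971/7,985), 0.05 fluctuating, 0.05 constant.
#' @param fracLowAbundance fraction of genes (drawn from the constant and
#'   arrhythmic classes) scaled below the abundance cutoff.
#' @param amplitude relative amplitude A >= 0 of rhythmic genes (default 1).
#' @param noiseSd log2-scale replicate noise sd (default 0.15).
#' @param wanderSd log2-scale per-condition sd of arrhythmic genes.
#' @param baselineLog2Mean,baselineLog2Sd log2 baseline abundance
#'   distribution (default Normal(5, 2), median 32 TPM).
#' @param replicates named integer vector of replicate counts per condition.
#' @param seed integer seed; the global RNG state is restored afterwards.
#' @return list with `experiment` (a [DielExperiment-class] whose `rowData`
#'   carries the truth table: `truth_class`, `true_peak_condition`,
#'   `true_pattern_label`, `cl_peak_condition`, `low_abundance`) and `truth`
#'   (the same table as a [S4Vectors::DataFrame]).
#' @examples
#' sim <- simulateDielExperiment(nGenes = 100, seed = 7)
#' table(sim$truth$truth_class)
#' @export
simulateDielExperiment <- function(nGenes = 8000,
                                   fracRhythmic = 0.39,
                                   fracLowSensitivity = 0.12,
                                   fracFluctuating = 0.05,
                                   fracConstant = 0.05,
                                   fracLowAbundance = 0.05,
                                   amplitude = 1,
                                   noiseSd = 0.15,
                                   wanderSd = 0.5,
                                   baselineLog2Mean = 5,
                                   baselineLog2Sd = 2,
                                   replicates = c(DN4 = 3, DN10 = 3,
                                                  DN16 = 3, DN22 = 3,
                                                  CL4 = 3, CL10 = 3,
                                                  CL16 = 2, CL22 = 3),
                                   seed = 1) {
  if (nGenes < 1L)
    stop(dielError("bad_config", "nGenes must be at least 1"))
  fr <- c(fracRhythmic, fracLowSensitivity, fracFluctuating, fracConstant)
  if (any(fr < 0) || sum(fr) > 1 || fracLowAbundance < 0 ||
      fracLowAbundance > 1)
    stop(dielError("bad_config", "class fractions must be in [0,1], sum <= 1"))
  if (amplitude < 0 || noiseSd < 0)
    stop(dielError("bad_config", "amplitude and noiseSd must be >= 0"))
  sheet <- dielSampleSheet(replicates)
  nS <- nrow(sheet)
  dnPhases <- c(4, 10, 16, 22)

  .withSeed(seed, {
    counts <- floor(nGenes * fr)
    nArr <- nGenes - sum(counts)
    cls <- rep(c(.TRUTH_CLASSES[1:4], "arrhythmic"), c(counts, nArr))
    mu <- 2^rnorm(nGenes, baselineLog2Mean, baselineLog2Sd)

    phase <- rep(NA_real_, nGenes)
    clPhase <- rep(NA_real_, nGenes)
    isRh <- cls == "rhythmic"
    isLS <- cls == "low_sensitivity"
    isFl <- cls == "fluctuating"
    phase[isRh | isLS] <- sample(dnPhases, sum(isRh | isLS), replace = TRUE)
    clPhase[isRh] <- phase[isRh]
    ## CL peak differs from the DN peak: shift by 6, 12 or 18 h
    clPhase[isLS] <- (phase[isLS] +
                        sample(c(6, 12, 18), sum(isLS), replace = TRUE) -
                        4) %% 24 + 4
    phase[isFl] <- sample(c(4, 10), sum(isFl), replace = TRUE)
    clPhase[isFl] <- phase[isFl]

    ## low-abundance genes come from the non-rhythmic background
    pool <- which(cls %in% c("constant", "arrhythmic"))
    nLow <- min(length(pool), round(fracLowAbundance * nGenes))
    lowIdx <- if (nLow > 0) sample(pool, nLow) else integer()
    low <- logical(nGenes)
    low[lowIdx] <- TRUE
    mu[low] <- 2^runif(nLow, -10, log2(0.05))

    condMean <- matrix(0, nGenes, 8L,
                       dimnames = list(NULL, dielConditions()))
    for (i in seq_len(nGenes)) {
      condMean[i, ] <- switch(
        cls[i],
        rhythmic = .waveMeans(mu[i], amplitude, phase[i]),
        low_sensitivity = .waveMeans(mu[i], amplitude, phase[i],
                                     clPhase = clPhase[i]),
        fluctuating = .waveMeans(mu[i], amplitude, phase[i], period = 12),
        constant = rep(mu[i], 8L),
        arrhythmic = mu[i] * 2^rnorm(8L, 0, wanderSd))
    }

    eps <- matrix(rnorm(nGenes * nS, 0, noiseSd), nGenes, nS)
    vals <- condMean[, sheet$condition, drop = FALSE] * 2^eps
    rownames(vals) <- sprintf("gene%05d", seq_len(nGenes))
    colnames(vals) <- sheet$sample_id

    lbl <- rep(NA_character_, nGenes)
    lbl[isRh | isLS] <- vapply(phase[isRh | isLS], truthPattern,
                               character(1), waveform = "cosinor24")
    lbl[isFl] <- vapply(phase[isFl], truthPattern, character(1),
                        waveform = "fluct12")
    peakCond <- ifelse(is.na(phase), NA_character_,
                       paste0("DN", phase))
    truth <- DataFrame(gene_id = rownames(vals), truth_class = cls,
                       true_peak_condition = peakCond,
                       true_pattern_label = lbl,
                       cl_peak_condition = ifelse(is.na(clPhase),
                                                  NA_character_,
                                                  paste0("DN", clPhase %% 24)),
                       low_abundance = low)
    x <- DielExperiment(vals, sheet)
    rd <- truth[, -1L]
    rownames(rd) <- truth$gene_id
    rowData(x) <- rd
    metadata(x)$sim_config <- list(
      nGenes = nGenes, fracRhythmic = fracRhythmic,
      fracLowSensitivity = fracLowSensitivity,
      fracFluctuating = fracFluctuating, fracConstant = fracConstant,
      fracLowAbundance = fracLowAbundance, amplitude = amplitude,
      noiseSd = noiseSd, wanderSd = wanderSd,
      baselineLog2Mean = baselineLog2Mean, baselineLog2Sd = baselineLog2Sd,
      replicates = as.list(replicates), seed = seed)
    list(experiment = x, truth = truth)
  })
}
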