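# Shared fixtures built in code.

# Eight z-scores of a morning-phased worked-example gene
# (DN4, DN10, DN16, DN22, CL4, CL10, CL16, CL22).
zWorked <- c(1.71, -0.94, -0.49, 0.41, 0.92, -1.16, -0.67, 0.23)

# Small experiment with explicit values: one replicate set per condition
# pattern, triplicate except duplicate CL16 (23 samples).
makeToyExperiment <- function(nGenes = 2, seed = 99, noiseSd = 0.2) {
  sim <- simulateDielExperiment(nGenes = nGenes, fracRhythmic = 0.5,
                                fracLowSensitivity = 0, fracFluctuating = 0,
                                fracConstant = 0, fracLowAbundance = 0,
                                noiseSd = noiseSd, seed = seed)
  sim$experiment
}

# independent Kendall tau-b oracle: brute-force pair counting
tauBruteForce <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# independent major-label oracle: peak = argmax, trough = argmin, label from
# the peak/trough table stated by the taxonomy
majorLabelOracle <- function(z4) {
  dn <- c("DN4", "DN10", "DN16", "DN22")
  tab <- list(DN4  = c(DN10 = "a", DN16 = "b", DN22 = "c"),
              DN10 = c(DN16 = "d", DN22 = "e", DN4 = "f"),
              DN16 = c(DN22 = "g", DN4 = "h", DN10 = "i"),
              DN22 = c(DN4 = "j", DN10 = "k", DN16 = "l"))
  peak <- dn[which.max(z4)]
  trough <- dn[which.min(z4)]
  unname(tab[[peak]][trough])
}

# TRUE when the cyclic difference-sign sequence of z4 is alternating
isAlternating <- function(z4) {
  s <- sign(c(diff(z4), z4[1] - z4[4]))
  all(s == c(1, -1, 1, -1)) || all(s == c(-1, 1, -1, 1))
}
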