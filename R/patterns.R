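## Up/down sign-pattern extraction, between-period matching, and the
## 14-class peak/trough taxonomy (patterns a-n, phase groups).

## Major label lookup: peak condition x trough condition.  Patterns group by
## peak time: morning (a-c, peak DN4), dusk (d-f, DN10), evening (g-i, DN16),
## dawn (j-l, DN22); within a group the label advances with the trough time.
.DN <- c("DN4", "DN10", "DN16", "DN22")
.MAJOR_LABELS <- matrix(NA_character_, 4, 4, dimnames = list(.DN, .DN))
.MAJOR_LABELS["DN4",  c("DN10", "DN16", "DN22")] <- c("a", "b", "c")
.MAJOR_LABELS["DN10", c("DN16", "DN22", "DN4")]  <- c("d", "e", "f")
.MAJOR_LABELS["DN16", c("DN22", "DN4", "DN10")]  <- c("g", "h", "i")
.MAJOR_LABELS["DN22", c("DN4", "DN10", "DN16")]  <- c("j", "k", "l")

.PHASE_OF_LABEL <- c(a = "morning", b = "morning", c = "morning",
                     d = "dusk", e = "dusk", f = "dusk",
                     g = "evening", h = "evening", i = "evening",
                     j = "dawn", k = "dawn", l = "dawn",
                     m = "minor", n = "minor")

#' Phase group of a pattern label
#'
#' @param label character vector of pattern labels (`"a"` to `"n"`).
#' @return character vector: `"morning"` (a-c), `"dusk"` (d-f), `"evening"`
#'   (g-i), `"dawn"` (j-l) or `"minor"` (m, n); `NA` labels give `"none"`.
#' @export
phaseGroup <- function(label) {
  out <- unname(.PHASE_OF_LABEL[label])
  out[is.na(out)] <- "none"
  out
}

.signOf <- function(d, epsilon = 0) {
  ifelse(d > epsilon, "up", ifelse(d < -epsilon, "down", "flat"))
}

#' Extract up/down sign patterns from a z-score profile
#'
#' Each within-period transition is classified as `"up"` (z increased
#' relative to the previous timepoint), `"down"` (decreased) or `"flat"`
#' (|difference| <= `epsilon`; with the default `epsilon = 0`, an exact tie).
#' The DN period yields three signs (DN4->DN10->DN16->DN22), the CL period
#' three signs (CL4->...->CL22).  The DN22->CL4 transition crosses the period
#' boundary; it is recorded but never used when matching patterns.  The wrap
#' sign, sign(z[DN4] - z[DN22]), closes the DN period into a cycle for
#' classification.  `matched` is `TRUE` when DN and CL signs are identical
#' and contain no flat.
#'
#' @param z numeric vector of 8 z-scores in canonical condition order.
#' @param epsilon non-negative tie tolerance (default 0: strict binary
#'   up/down; ties disqualify a gene from matching).
#' @return list with elements `dn`, `cl` (3 signs each), `transition`,
#'   `wrap`, and logical `matched`.
#' @examples
#' extractSigns(c(1.71, -0.94, -0.49, 0.41, 0.92, -1.16, -0.67, 0.23))
#' @export
extractSigns <- function(z, epsilon = 0) {
  stopifnot(length(z) == 8L, all(is.finite(z)), epsilon >= 0)
  if (sd(z) == 0)
    stop(dielError("constant_profile",
                   "constant profile: signs undefined (filter upstream)"))
  d <- diff(z)
  dn <- .signOf(d[1:3], epsilon)
  cl <- .signOf(d[5:7], epsilon)
  list(dn = dn, cl = cl,
       transition = .signOf(d[4], epsilon),
       wrap = .signOf(z[1] - z[4], epsilon),
       matched = all(dn == cl) && !any(c(dn, cl) == "flat"))
}

#' Classify a DN profile into the 14-pattern peak/trough taxonomy
#'
#' The four DN z-scores are closed into a cycle by the wrap difference
#' z[DN4] - z[DN22] and the four cyclic transition signs are formed.  All-up
#' and all-down cycles are impossible (the four differences sum to zero), so
#' 14 sign cycles remain: 12 with exactly one up-run and one down-run
#' (unimodal) and 2 alternating.  A unimodal cycle gets the major label whose
#' peak is the condition where up flips to down and whose trough is where
#' down flips to up (a-c peak DN4, d-f DN10, g-i DN16, j-l DN22; the label
#' advances with the trough).  Alternating cycles are the minor fluctuating
#' patterns: `m` with maxima at DN10 and DN22 (peaks just before the
#' light/dark and dark/light transitions), `n` with maxima at DN4 and DN16
#' (just after).  Any flat sign makes the profile unclassifiable.
#'
#' @param zdn numeric vector: either the 4 DN z-scores or a full 8-score
#'   profile (the first 4 entries are used).
#' @param epsilon tie tolerance passed to the sign extraction.
#' @return list with `label` (`"a"`..`"n"`), `phase_group`, `peak`
#'   (condition; for minor labels the two maxima, comma-joined) and `trough`.
#' @examples
#' classifyPattern(c(1.71, -0.94, -0.49, 0.41))   # pattern a, morning
#' classifyPattern(c(-1, 1, -1, 1))               # pattern m
#' @export
classifyPattern <- function(zdn, epsilon = 0) {
  if (length(zdn) == 8L) zdn <- zdn[1:4]
  stopifnot(length(zdn) == 4L, all(is.finite(zdn)))
  ## cyclic transition signs: s[1] DN4->DN10, s[2] DN10->DN16,
  ## s[3] DN16->DN22, s[4] DN22->DN4 (wrap)
  s <- .signOf(c(diff(zdn), zdn[1] - zdn[4]), epsilon)
  if (any(s == "flat"))
    stop(dielError("unclassifiable",
                   "flat transition sign: profile unclassifiable"))
  into <- s[c(4L, 1L, 2L, 3L)]        # sign of the transition into each DN point
  outof <- s                          # sign of the transition out of it
  peaks <- which(into == "up" & outof == "down")
  troughs <- which(into == "down" & outof == "up")
  if (length(peaks) == 1L) {
    peak <- .DN[peaks]
    trough <- .DN[troughs]
    label <- .MAJOR_LABELS[peak, trough]
    list(label = label, phase_group = phaseGroup(label),
         peak = peak, trough = trough)
  } else {
    ## alternating cycle: two local maxima
    label <- if (setequal(.DN[peaks], c("DN10", "DN22"))) "m" else "n"
    list(label = label, phase_group = "minor",
         peak = paste(.DN[peaks], collapse = ","),
         trough = paste(.DN[troughs], collapse = ","))
  }
}

#' Call pattern-rhythmic genes and label them
#'
#' A gene is pattern-rhythmic when its DN and CL up/down sign patterns are
#' identical with no flat transition ([extractSigns()] `matched`).  Each
#' pattern-rhythmic gene is labeled from its DN profile with
#' [classifyPattern()]; labels are assigned from the DN half only, the CL
#' half serves matching.  Constant genes and genes with a flat sign anywhere
#' are never matched and are flagged.
#'
#' @param profiles a [ConditionProfiles-class] object.
#' @param epsilon tie tolerance (default 0).
#' @return [S4Vectors::DataFrame], one row per gene: `gene_id`, `dn_signs`,
#'   `cl_signs`, `transition_sign`, `wrap_sign` (comma-joined sign strings),
#'   `matched`, `constant`, `flat` (any flat among dn/cl/wrap signs),
#'   `pattern_label`, `phase_group`, `peak`, `trough` (NA when not matched).
#' @export
callPatternRhythmic <- function(profiles, epsilon = 0) {
  stopifnot(is(profiles, "ConditionProfiles"))
  z <- profileZ(profiles)
  const <- isConstant(profiles)
  n <- nrow(z)
  dn_signs <- cl_signs <- trans <- wrap <- rep(NA_character_, n)
  matched <- flat <- logical(n)
  label <- phase <- peak <- trough <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (const[i]) { flat[i] <- TRUE; next }
    sg <- extractSigns(z[i, ], epsilon)
    dn_signs[i] <- paste(sg$dn, collapse = ",")
    cl_signs[i] <- paste(sg$cl, collapse = ",")
    trans[i] <- sg$transition
    wrap[i] <- sg$wrap
    flat[i] <- any(c(sg$dn, sg$cl, sg$wrap) == "flat")
    matched[i] <- sg$matched
    if (sg$matched && sg$wrap != "flat") {
      cp <- classifyPattern(z[i, 1:4], epsilon)
      label[i] <- cp$label
      phase[i] <- cp$phase_group
      peak[i] <- cp$peak
      trough[i] <- cp$trough
    } else if (sg$matched) {
      ## matched within periods but flat wrap: cannot place on the cycle
      matched[i] <- FALSE
      flat[i] <- TRUE
    }
  }
  DataFrame(gene_id = rownames(z), dn_signs = dn_signs, cl_signs = cl_signs,
            transition_sign = trans, wrap_sign = wrap, matched = matched,
            constant = const, flat = flat, pattern_label = label,
            phase_group = phase, peak = peak, trough = trough)
}
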