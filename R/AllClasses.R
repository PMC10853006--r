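#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData rowData<-
#' @importFrom stats var sd cor cor.test pf pt rnorm runif median quantile
#' @importFrom utils read.delim write.table combn head
NULL

## Fixed experimental design: one 12L:12D day/night cycle (DN) followed by one
## continuous-light cycle (CL), sampled every 6 h starting 4 h after light
## onset.  All condition-ordered vectors in the package use this order.
.DIEL_CONDITIONS <- c("DN4", "DN10", "DN16", "DN22",
                      "CL4", "CL10", "CL16", "CL22")
.DIEL_HOURS <- c(4, 10, 16, 22, 28, 34, 40, 46)
names(.DIEL_HOURS) <- .DIEL_CONDITIONS
## DN16 and DN22 fall in the dark half of the DN cycle; everything else is lit.
.DIEL_LIGHT <- c("light", "light", "dark", "dark",
                 "light", "light", "light", "light")
names(.DIEL_LIGHT) <- .DIEL_CONDITIONS

#' Canonical condition order and hours of the diel design
#'
#' The design has eight sampling conditions: DN4, DN10, DN16, DN22 during a
#' 12 h light : 12 h dark cycle, then CL4, CL10, CL16, CL22 under continuous
#' light.  `dielConditions()` returns the fixed condition order used by every
#' condition-ordered vector in the package; `conditionHours()` returns the
#' hours since light onset of day 1 (4, 10, ..., 46) named by condition;
#' `conditionLight()` returns the light state (dark only for DN16 and DN22).
#'
#' @return `dielConditions()`: character vector of length 8.
#'   `conditionHours()`: named numeric vector. `conditionLight()`: named
#'   character vector with values `"light"`/`"dark"`.
#' @examples
#' dielConditions()
#' conditionHours()["CL4"]
#' @export
dielConditions <- function() .DIEL_CONDITIONS

#' @rdname dielConditions
#' @export
conditionHours <- function() .DIEL_HOURS

#' @rdname dielConditions
#' @export
conditionLight <- function() .DIEL_LIGHT

## Structured validation errors so callers (and the CLI) can distinguish bad
## input from internal failure.
dielError <- function(subclass, message, call = sys.call(-1)) {
  structure(
    class = c(paste0("diel_", subclass), "dielValidationError",
              "error", "condition"),
    list(message = message, call = call)
  )
}

#' DielExperiment: replicated diel expression data
#'
#' An extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' gene x sample non-negative abundance matrix (assay `"abundance"`, TPM or
#' RPKM) together with the sample sheet in `colData` (columns `sample_id`,
#' `condition`, `hours`, `light`, `replicate`).  Validity enforces the design:
#' every condition present at least once, hours and light consistent with the
#' condition, replicate indices unique within a condition, non-negative
#' values, unique gene identifiers.
#'
#' @slot unitKind character, `"TPM"` or `"RPKM"`.
#' @export
setClass("DielExperiment",
         contains = "SummarizedExperiment",
         slots = c(unitKind = "character"))

setValidity("DielExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("sample_id", "condition", "hours", "light", "replicate")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  cond <- as.character(cd$condition)
  if (!all(cond %in% .DIEL_CONDITIONS))
    msg <- c(msg, paste("unknown condition(s):",
                        paste(unique(setdiff(cond, .DIEL_CONDITIONS)),
                              collapse = ", ")))
  else {
    if (!all(.DIEL_CONDITIONS %in% cond))
      msg <- c(msg, paste("missing condition(s):",
                          paste(setdiff(.DIEL_CONDITIONS, cond),
                                collapse = ", ")))
    if (!all(cd$hours == .DIEL_HOURS[cond]))
      msg <- c(msg, "hours inconsistent with condition")
    if (!all(cd$light == .DIEL_LIGHT[cond]))
      msg <- c(msg, "light state inconsistent with condition")
    if (anyDuplicated(paste(cond, cd$replicate)))
      msg <- c(msg, "replicate indices not unique within condition")
  }
  if (!identical(object@unitKind %in% c("TPM", "RPKM"), TRUE))
    msg <- c(msg, "unitKind must be 'TPM' or 'RPKM'")
  a <- assay(object)
  if (anyNA(a) || any(a < 0))
    msg <- c(msg, "abundances must be non-negative and non-missing")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (!identical(colnames(object), as.character(cd$sample_id)))
    msg <- c(msg, "column names must equal sample_id")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a DielExperiment
#'
#' @param abundance numeric gene x sample matrix with unique rownames (gene
#'   ids).  Column names must match `sheet$sample_id`.
#' @param sheet data.frame or DataFrame with columns `sample_id`,
#'   `condition`, `replicate`; `hours` and `light` are filled in from the
#'   condition when absent.
#' @param unitKind `"TPM"` (default) or `"RPKM"`.
#' @return A validated [DielExperiment-class] object, columns ordered as in
#'   `sheet`.
#' @examples
#' sheet <- dielSampleSheet(replicates = c(rep(1, 8)))
#' m <- matrix(runif(8 * 2), 2, 8,
#'             dimnames = list(c("g1", "g2"), sheet$sample_id))
#' DielExperiment(m, sheet)
#' @export
DielExperiment <- function(abundance, sheet, unitKind = c("TPM", "RPKM")) {
  unitKind <- match.arg(unitKind)
  sheet <- as.data.frame(sheet)
  if (!all(c("sample_id", "condition", "replicate") %in% colnames(sheet)))
    stop(dielError("bad_sheet",
                   "sample sheet needs sample_id, condition, replicate"))
  bad <- setdiff(as.character(sheet$condition), .DIEL_CONDITIONS)
  if (length(bad))
    stop(dielError("bad_sheet", paste("unknown condition(s):",
                                      paste(unique(bad), collapse = ", "))))
  if (is.null(sheet$hours))
    sheet$hours <- unname(.DIEL_HOURS[as.character(sheet$condition)])
  if (is.null(sheet$light))
    sheet$light <- unname(.DIEL_LIGHT[as.character(sheet$condition)])
  abundance <- as.matrix(abundance)
  if (anyDuplicated(rownames(abundance)))
    stop(dielError("duplicate_gene",
                   paste("duplicate gene id(s):",
                         paste(unique(rownames(abundance)[
                           duplicated(rownames(abundance))]), collapse = ", "))))
  miss <- setdiff(colnames(abundance), as.character(sheet$sample_id))
  if (length(miss))
    stop(dielError("missing_sample",
                   paste("sample(s) absent from sheet:",
                         paste(miss, collapse = ", "))))
  miss2 <- setdiff(as.character(sheet$sample_id), colnames(abundance))
  if (length(miss2))
    stop(dielError("missing_sample",
                   paste("sheet sample(s) absent from matrix:",
                         paste(miss2, collapse = ", "))))
  if (anyNA(abundance) || any(abundance < 0))
    stop(dielError("negative_value",
                   "abundance matrix contains negative or missing values"))
  abundance <- abundance[, as.character(sheet$sample_id), drop = FALSE]
  cd <- DataFrame(sheet[, c("sample_id", "condition", "hours",
                            "light", "replicate")])
  rownames(cd) <- as.character(sheet$sample_id)
  se <- SummarizedExperiment(assays = SimpleList(abundance = abundance),
                             colData = cd)
  new("DielExperiment", se, unitKind = unitKind)
}

#' Build a standard sample sheet for the diel design
#'
#' @param replicates integer vector of replicate counts, one per condition in
#'   canonical order, or a named vector.  Defaults to the study design:
#'   triplicate everywhere except duplicate CL16.
#' @return data.frame with columns sample_id, condition, hours, light,
#'   replicate; sample ids are `<condition>_r<replicate>`.
#' @examples
#' head(dielSampleSheet())
#' @export
dielSampleSheet <- function(replicates = c(DN4 = 3, DN10 = 3, DN16 = 3,
                                           DN22 = 3, CL4 = 3, CL10 = 3,
                                           CL16 = 2, CL22 = 3)) {
  if (is.null(names(replicates))) {
    stopifnot(length(replicates) == 8L)
    names(replicates) <- .DIEL_CONDITIONS
  }
  stopifnot(all(.DIEL_CONDITIONS %in% names(replicates)),
            all(replicates >= 1))
  replicates <- replicates[.DIEL_CONDITIONS]
  cond <- rep(.DIEL_CONDITIONS, replicates)
  rep_i <- unlist(lapply(replicates, seq_len), use.names = FALSE)
  data.frame(sample_id = paste0(cond, "_r", rep_i),
             condition = cond,
             hours = unname(.DIEL_HOURS[cond]),
             light = unname(.DIEL_LIGHT[cond]),
             replicate = rep_i,
             stringsAsFactors = FALSE)
}

#' @describeIn DielExperiment-class abundance unit, `"TPM"` or `"RPKM"`.
#' @param x a `DielExperiment`.
#' @export
unitKind <- function(x) {
  stopifnot(is(x, "DielExperiment"))
  x@unitKind
}

#' @describeIn DielExperiment-class the abundance assay matrix.
#' @export
abundance <- function(x) assay(x, "abundance")

#' @describeIn DielExperiment-class condition of each sample.
#' @export
condition <- function(x) as.character(colData(x)$condition)

#' @describeIn DielExperiment-class hours since light onset of each sample.
#' @export
hoursSinceLight <- function(x) as.numeric(colData(x)$hours)

#' @describeIn DielExperiment-class replicate index of each sample.
#' @export
replicateId <- function(x) as.integer(colData(x)$replicate)

setMethod("show", "DielExperiment", function(object) {
  cat("DielExperiment (", object@unitKind, "): ",
      nrow(object), " genes x ", ncol(object), " samples\n", sep = "")
  tab <- table(factor(condition(object), levels = .DIEL_CONDITIONS))
  cat("replicates per condition:\n")
  print(tab)
  invisible(NULL)
})

#' ConditionProfiles: per-gene condition means and z-scores
#'
#' A [SummarizedExperiment::SummarizedExperiment] with exactly eight columns
#' (the conditions in canonical order) and two assays: `"mean"`, the per-gene
#' arithmetic mean abundance of each condition, and `"z"`, the condition
#' means standardized per gene to mean 0 / sd 1 (sample sd, divisor n-1).
#' Genes whose eight means are identical cannot be standardized; they carry
#' `rowData(x)$constant == TRUE` and an all-zero z row.
#'
#' @seealso [conditionProfiles()], [zscoreProfile()]
#' @export
setClass("ConditionProfiles", contains = "SummarizedExperiment")

setValidity("ConditionProfiles", function(object) {
  if (!identical(colnames(object), .DIEL_CONDITIONS))
    return("columns must be the 8 conditions in canonical order")
  if (!all(c("mean", "z") %in% names(assays(object))))
    return("assays 'mean' and 'z' required")
  if (!"constant" %in% colnames(rowData(object)))
    return("rowData column 'constant' required")
  z <- assay(object, "z")
  ok <- !rowData(object)$constant
  if (any(ok)) {
    zz <- z[ok, , drop = FALSE]
    m <- rowMeans(zz)
    s <- sqrt(rowSums((zz - m)^2) / (ncol(zz) - 1))
    if (any(abs(m) > 1e-9) || any(abs(s - 1) > 1e-9))
      return("non-constant z rows must have mean 0, sd 1 (within 1e-9)")
  }
  TRUE
})

#' @describeIn ConditionProfiles-class matrix of per-condition mean
#'   abundances (genes x 8).
#' @param x a `ConditionProfiles` object.
#' @export
profileMeans <- function(x) assay(x, "mean")

#' @describeIn ConditionProfiles-class matrix of per-gene z-scores
#'   (genes x 8).
#' @export
profileZ <- function(x) assay(x, "z")

#' @describeIn ConditionProfiles-class logical; TRUE for genes whose eight
#'   condition means are identical (z undefined).
#' @export
isConstant <- function(x) rowData(x)$constant

setMethod("show", "ConditionProfiles", function(object) {
  cat("ConditionProfiles: ", nrow(object), " genes x 8 conditions (",
      sum(rowData(object)$constant), " constant)\n", sep = "")
  invisible(NULL)
})
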