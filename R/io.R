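## TSV input/output for expression matrices, sample sheets, rhythm calls and
## pipeline configuration.  Numeric values are written with 17 significant
## digits so that write -> read is the identity on doubles.

.writeNumericTSV <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read and write diel expression data
#'
#' `readDielExperiment()` reads a tab-separated abundance matrix (first
#' column gene id, header row of sample ids) plus a sample sheet TSV with
#' columns `sample_id`, `condition`, `hours`, `light`, `replicate`, validates
#' the pair and returns a [DielExperiment-class] with columns harmonized to
#' sheet order.  `writeDielExperiment()` writes the matrix and sheet back;
#' values are written with enough digits that a round trip is bit-identical.
#'
#' Validation failures raise typed conditions: `diel_missing_sample` (matrix
#' and sheet disagree on samples), `diel_negative_value`,
#' `diel_duplicate_gene`.
#'
#' @param path path of the abundance matrix TSV (genes in rows).
#' @param sheetPath path of the sample sheet TSV.
#' @param unitKind `"TPM"` or `"RPKM"`.
#' @return `readDielExperiment()`: a `DielExperiment`.
#'   `writeDielExperiment()`: invisibly, the two paths written.
#' @export
readDielExperiment <- function(path, sheetPath, unitKind = c("TPM", "RPKM")) {
  unitKind <- match.arg(unitKind)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop(dielError("bad_matrix", "matrix needs a gene id column and samples"))
  genes <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  sheet <- read.delim(sheetPath, check.names = FALSE,
                      stringsAsFactors = FALSE)
  DielExperiment(m, sheet, unitKind = unitKind)
}

#' @rdname readDielExperiment
#' @param x a `DielExperiment`.
#' @export
writeDielExperiment <- function(x, path, sheetPath) {
  stopifnot(is(x, "DielExperiment"))
  df <- data.frame(gene_id = rownames(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(abundance(x), check.names = FALSE))
  .writeNumericTSV(df, path)
  write.table(as.data.frame(colData(x)), sheetPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(path, sheetPath))
}

.CALL_COLUMNS <- c("gene_id", "category", "pattern_label", "phase_group",
                   "flags")
.CATEGORIES <- c("statistical_rhythmic", "general_rhythm", "nonrhythmic")
.PHASE_GROUPS <- c("morning", "dusk", "evening", "dawn", "minor", "none")

#' Read and write rhythm-call tables
#'
#' Rhythm calls (the final per-gene partition, see [finalPartition()]) are
#' written as a TSV with fixed column order `gene_id`, `category`,
#' `pattern_label`, `phase_group`, `flags`; flags are semicolon-joined tokens
#' and an empty flag set is an empty field.  Row order is input order.
#'
#' @param calls a `DataFrame`/data.frame of rhythm calls with the five
#'   columns above (as produced by [finalPartition()]).
#' @param path output (or input) TSV path.
#' @return `writeCalls()`: invisibly, `path`.  `readCalls()`: a
#'   [S4Vectors::DataFrame] with the five columns.
#' @export
writeCalls <- function(calls, path) {
  calls <- as.data.frame(calls)
  if (nrow(calls) == 0L)
    stop(dielError("empty_calls", "no rhythm calls to write"))
  stopifnot(all(.CALL_COLUMNS %in% colnames(calls)))
  write.table(calls[, .CALL_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = NULL, colClasses = "character")
  stopifnot(identical(colnames(df), .CALL_COLUMNS))
  DataFrame(df)
}

#' Read a pipeline configuration file
#'
#' Configuration is YAML (or flat `key: value`) with any subset of the keys
#' below; missing keys take the package defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return named list with elements `abundance_cutoff` (0.1), `alpha` (0.05),
#'   `epsilon` (0), `seed` (1), `permutations` (999), `replicate_policy`
#'   (`"top_duplicates"` or `"all"`), `surrogate` (TRUE: include the 48-h
#'   cosinor detector in the candidate union).
#' @export
readDielConfig <- function(path = NULL) {
  cfg <- list(abundance_cutoff = 0.1, alpha = 0.05, epsilon = 0, seed = 1L,
              permutations = 999L, replicate_policy = "top_duplicates",
              surrogate = TRUE)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop(dielError("bad_config", paste("unknown config key(s):",
                                         paste(bad, collapse = ", "))))
    cfg[names(user)] <- user
  }
  if (!cfg$replicate_policy %in% c("top_duplicates", "all"))
    stop(dielError("bad_config",
                   "replicate_policy must be 'top_duplicates' or 'all'"))
  cfg$seed <- as.integer(cfg$seed)
  cfg$permutations <- as.integer(cfg$permutations)
  cfg
}
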