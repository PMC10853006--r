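## End-to-end orchestration: filter -> concordance -> profiles -> patterns ->
## periodicity -> consensus -> correlation -> final partition, plus reporting
## and diagnostic plots.

#' Run the full diel rhythm pipeline
#'
#' Filters low-abundance genes, checks replicate concordance, averages
#' replicates and standardizes profiles, extracts and matches sign patterns,
#' runs the periodicity ensemble (on the top-correlated duplicate pair per
#' condition by default), forms the consensus and the final partition, and
#' tags statistical-rhythmic genes with a significant between-period
#' correlation.  The run is a pure function of the inputs and the seed; when
#' `outdir` is given, all stage tables (TSV) and a JSON summary are written
#' there deterministically.
#'
#' @param x a [DielExperiment-class].
#' @param config a configuration list as returned by [readDielConfig()];
#'   individual elements can be overridden via `...`.
#' @param outdir optional output directory (created if needed).
#' @param ... named overrides of config entries (e.g. `alpha = 0.01`).
#' @return a list with elements `summary` (counts: `n_input`, `n_filtered`,
#'   `n_pattern_matched`, `n_candidates`, `n_statistical`, `n_general`,
#'   `n_sig_correlation`; `label_histogram`; `config`; `seed`), `calls`
#'   (the full per-gene call table including filtered-out genes, flagged
#'   `low_abundance`), plus the stage outputs `filtered`, `concordance`,
#'   `profiles`, `patterns`, `periodicity`, `consensus`, `correlation`.
#' @examples
#' sim <- simulateDielExperiment(nGenes = 60, seed = 3)
#' res <- runDielPipeline(sim$experiment, permutations = 99)
#' res$summary$counts
#' @export
runDielPipeline <- function(x, config = readDielConfig(), outdir = NULL,
                            ...) {
  stopifnot(is(x, "DielExperiment"))
  over <- list(...)
  bad <- setdiff(names(over), names(config))
  if (length(bad))
    stop(dielError("bad_config", paste("unknown config override(s):",
                                       paste(bad, collapse = ", "))))
  config[names(over)] <- over

  stage <- "filter"
  res <- tryCatch({
    xf <- filterLowAbundance(x, config$abundance_cutoff)
    removed <- metadata(xf)$removed_genes

    stage <- "concordance"
    conc <- replicateConcordance(xf)

    stage <- "profiles"
    prof <- conditionProfiles(xf)

    stage <- "patterns"
    pat <- callPatternRhythmic(prof, config$epsilon)

    stage <- "periodicity"
    xsel <- if (config$replicate_policy == "top_duplicates")
      selectTopCorrelatedDuplicates(xf) else xf
    per <- periodicityTests(xsel, alpha = config$alpha,
                            permutations = config$permutations,
                            seed = config$seed,
                            surrogate = isTRUE(config$surrogate))

    stage <- "consensus"
    cons <- consensusSets(per, pat)

    stage <- "correlation"
    corr <- periodCorrelation(prof, alpha = config$alpha)

    stage <- "partition"
    calls <- finalPartition(pat, cons, corr)
    if (length(removed)) {
      lowCalls <- DataFrame(gene_id = removed, category = "nonrhythmic",
                            pattern_label = "none", phase_group = "none",
                            flags = "low_abundance")
      calls <- rbind(calls, lowCalls)
    }
    calls <- calls[match(rownames(x), calls$gene_id), ]

    labHist <- table(factor(pat$pattern_label[pat$matched],
                            levels = letters[1:14]))
    counts <- list(n_input = nrow(x),
                   n_filtered = nrow(xf),
                   n_pattern_matched = sum(pat$matched),
                   n_candidates = length(cons$candidate),
                   n_statistical = length(cons$high_sensitivity),
                   n_general = sum(calls$category == "general_rhythm"),
                   n_sig_correlation =
                     sum(grepl("significant_correlation", calls$flags)))
    if (counts$n_statistical + counts$n_general != counts$n_pattern_matched)
      stop(dielError("inconsistent_sets",
                     "partition identity violated (internal error)"))
    list(summary = list(counts = counts,
                        label_histogram = as.list(labHist),
                        config = config, seed = config$seed),
         calls = calls, filtered = xf, concordance = conc, profiles = prof,
         patterns = pat, periodicity = per, consensus = cons,
         correlation = corr)
  }, error = function(e) {
    stop(dielError("stage_failure",
                   paste0("pipeline stage '", stage, "' failed: ",
                          conditionMessage(e))))
  })

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeDielExperiment(res$filtered, file.path(outdir, "filtered.tsv"),
                        file.path(outdir, "samples.tsv"))
    .writeNumericTSV(as.data.frame(res$concordance),
                     file.path(outdir, "concordance.tsv"))
    zdf <- data.frame(gene_id = rownames(res$profiles),
                      as.data.frame(profileZ(res$profiles)),
                      check.names = FALSE)
    .writeNumericTSV(zdf, file.path(outdir, "zprofiles.tsv"))
    write.table(as.data.frame(res$patterns),
                file.path(outdir, "patterns.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .writeNumericTSV(as.data.frame(res$periodicity),
                     file.path(outdir, "periodicity.tsv"))
    writeCalls(res$calls, file.path(outdir, "calls.tsv"))
    jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Plot per-label z-score profiles
#'
#' Writes one small-multiple panel (PDF) per requested pattern label, showing
#' the z-score trajectories of that label's genes over the 48 h of the
#' experiment, with the dark hours of the DN period (hours 12-24, the
#' DN16/DN22 span) shaded; the corresponding CL span is lit and left
#' unshaded.
#'
#' @param profiles a [ConditionProfiles-class].
#' @param calls the call table from [finalPartition()] or
#'   [runDielPipeline()].
#' @param path directory for the output files (created if needed).
#' @param labels pattern labels to plot; default: every label present among
#'   the non-`"none"` calls.
#' @param genes optional gene id subset; unknown ids raise an error listing
#'   them.
#' @param maxGenes at most this many gene traces per panel.
#' @return invisibly, the vector of files written (one per label); plotting
#'   nothing gives a warning and no file.
#' @export
plotProfiles <- function(profiles, calls, path, labels = NULL, genes = NULL,
                         maxGenes = 50) {
  stopifnot(is(profiles, "ConditionProfiles"))
  calls <- as.data.frame(calls)
  if (!is.null(genes)) {
    unknown <- setdiff(genes, calls$gene_id)
    if (length(unknown))
      stop(dielError("unknown_gene",
                     paste("unknown gene(s):",
                           paste(unknown, collapse = ", "))))
    calls <- calls[calls$gene_id %in% genes, , drop = FALSE]
  }
  calls <- calls[calls$pattern_label != "none", , drop = FALSE]
  if (is.null(labels))
    labels <- sort(unique(calls$pattern_label))
  labels <- intersect(labels, calls$pattern_label)
  if (!length(labels)) {
    warning("no genes to plot")
    return(invisible(character()))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  hrs <- conditionHours()
  files <- character()
  for (lb in labels) {
    ids <- calls$gene_id[calls$pattern_label == lb]
    ids <- intersect(ids, rownames(profiles))
    ids <- head(ids, maxGenes)
    if (!length(ids)) next
    f <- file.path(path, paste0("pattern_", lb, ".pdf"))
    grDevices::pdf(f, width = 5, height = 4)
    z <- profileZ(profiles)[ids, , drop = FALSE]
    graphics::plot(NA, xlim = c(0, 48), ylim = range(z),
                   xlab = "hours since light onset", ylab = "z-score",
                   main = sprintf("pattern %s (%d genes)", lb, length(ids)))
    graphics::rect(12, graphics::par("usr")[3], 24, graphics::par("usr")[4],
                   col = grDevices::grey(0.85), border = NA)
    for (i in seq_len(nrow(z)))
      graphics::lines(hrs, z[i, ], col = grDevices::grey(0.55, 0.5))
    graphics::lines(hrs, colMeans(z), lwd = 2)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
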