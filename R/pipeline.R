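# End-to-end orchestration: design -> oligos -> EOP -> polarity -> report.

#' Pipeline run configuration
#'
#' Collects the paths and parameters of a full run. Serializable to YAML
#' ([write_run_config()]); a copy is recorded in every output directory
#' for provenance.
#'
#' @param genome path to the annotated genome (GenBank, or FASTA with
#'   `gene_table`).
#' @param counts optional path to a spot-count TSV.
#' @param units optional path to a transcriptional-unit TSV/JSON.
#' @param rerun_counts optional path to the spot-count TSV of a
#'   trans-complementation re-assay.
#' @param complemented genes supplied in trans in the re-assay.
#' @param gene_table optional gene-coordinate TSV for FASTA genomes.
#' @param control_id control sample id in the counts tables.
#' @param threshold essentiality threshold on mean EOP.
#' @param design a [design_config()].
#' @param seed integer seed for any randomness in the run.
#' @param outdir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(genome, counts = NULL, units = NULL,
                       rerun_counts = NULL, complemented = character(),
                       gene_table = NULL, control_id = NULL,
                       threshold = 1e-3, design = design_config(),
                       seed = 1L, outdir = "phagemap_out") {
  structure(list(genome = genome, counts = counts, units = units,
                 rerun_counts = rerun_counts, complemented = complemented,
                 gene_table = gene_table, control_id = control_id,
                 threshold = threshold, design = design,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#' @param config a `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$design <- unclass(x$design)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  dc <- do.call(design_config, x$design)
  x$design <- NULL
  x$complemented <- as.character(unlist(x$complemented))
  do.call(run_config, c(x, list(design = dc)))
}

#' Run the essentiality-mapping pipeline
#'
#' Stages: read genome; design guides genome-wide; build the oligo order
#' sheet; if a spot-count table is given, compute per-gene EOP and
#' classify; if a transcript map is given, interpret the calls for
#' roadblock polarity (optionally combining a trans-complementation
#' re-assay). All tables are written as TSV into `config$outdir` along
#' with a `run_config.yaml` copy and a `summary.tsv` of headline tallies.
#' Stages without inputs are skipped with a note.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress notes.
#' @return (invisibly) a list with the design report, order sheet, EOP
#'   table, interpretation, and the summary tally list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(config$outdir, "run_config.yaml"))

  fmt <- if (grepl("\\.(fa|fasta|fna)$", config$genome,
                   ignore.case = TRUE)) "fasta" else "genbank"
  g <- read_genome(config$genome, fmt, gene_table = config$gene_table)
  say("loaded ", g$accession, ": ", nrow(g$features), " genes")

  report <- design_genome(g, config$design)
  write_design_report(report, file.path(config$outdir, "design.tsv"))
  sheet <- export_order_sheet(report, config$design$spacer_length)
  utils::write.table(sheet, file.path(config$outdir, "oligo_order.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("designed ", nrow(report$guides), " guides (",
      nrow(report$untargetable), " untargetable)")

  eop <- NULL
  interp <- NULL
  informative <- character(0)
  if (!is.null(config$counts)) {
    counts <- read_spot_counts(config$counts)
    eop <- analyze_spot_table(counts, config$control_id, config$threshold)
    write_eop_table(eop, file.path(config$outdir, "eop.tsv"))
    say("classified ", nrow(eop), " genes from plaque counts")
  } else say("no counts table: assay stages skipped")

  if (!is.null(config$units) && !is.null(eop)) {
    units <- read_transcript_units(config$units)
    calls <- stats::setNames(eop$call, eop$locus_tag)
    interp <- interpret_calls(calls, units)
    informative <- informative_essentials(interp)
    if (!is.null(config$rerun_counts)) {
      rerun <- analyze_spot_table(read_spot_counts(config$rerun_counts),
                                  config$control_id, config$threshold)
      rerun_calls <- calls
      rerun_calls[rerun$locus_tag] <- rerun$call
      interp2 <- interpret_calls(rerun_calls, units,
                                 complemented = config$complemented)
      informative <- union(informative, informative_essentials(interp2))
      interp <- merge(interp,
                      interp2[, c("locus_tag", "status")],
                      by = "locus_tag", suffixes = c("", "_rerun"),
                      all.x = TRUE, sort = FALSE)
    }
    utils::write.table(interp, file.path(config$outdir, "polarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (!is.null(config$units)) {
    say("transcript map given without counts: polarity stage skipped")
  }

  calls_tab <- if (!is.null(eop)) tally_calls(eop$call, NULL) else NULL
  summary <- list(
    genes = nrow(g$features),
    guides_designed = nrow(report$guides),
    untargetable = nrow(report$untargetable),
    essential = if (!is.null(calls_tab)) unname(calls_tab["E"]) else NA,
    nonessential = if (!is.null(calls_tab)) unname(calls_tab["NE"]) else NA,
    intermediate = if (!is.null(calls_tab))
      unname(calls_tab["intermediate"]) else NA,
    informative_essentials = paste(informative, collapse = ","))
  summary_df <- data.frame(key = names(summary),
                           value = vapply(summary, function(v)
                             as.character(if (is.null(v) || is.na(v)) ""
                                          else v), character(1)))
  utils::write.table(summary_df, file.path(config$outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genome = g, design = report, order_sheet = sheet,
                 eop = eop, interpretation = interp, summary = summary))
}
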