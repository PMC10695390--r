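# Polarity-aware interpretation of CRISPRi essentiality calls.
#
# A DNA-bound dCas12a/crRNA complex is a transcription roadblock: a
# knockdown in any gene of a polycistronic transcript also silences every
# gene downstream on that transcript. An "essential" readout is therefore
# only informative for the last gene on a transcript that is required for
# plaque formation; essential readouts upstream of another essential gene
# are potentially polar artifacts, and a nonessential readout upstream of
# an essential gene implies the roadblock was read through (an anomaly
# worth flagging). Supplying a downstream gene in trans (e.g., an
# antiterminator from a plasmid) masks its requirement and lets the genes
# upstream of it be re-evaluated.

#' Transcriptional units from a table or list
#'
#' @param x either a named list of character vectors (each vector the
#'   locus tags of one unit, ordered 5' to 3' in transcription order), or a
#'   `data.frame` with columns `unit_name, rank, locus_tag`.
#' @return named list of character vectors, validated (nonempty, no
#'   duplicates within a unit).
#' @export
transcript_units <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("unit_name", "rank", "locus_tag") %in% names(x)))
    x <- lapply(split(x, x$unit_name), function(u)
      u$locus_tag[order(as.numeric(u$rank))])
  }
  stopifnot(is.list(x), length(x) >= 1L)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("unit", seq_along(x))
  for (nm in names(x)) {
    if (!length(x[[nm]])) stop("unit '", nm, "' is empty", call. = FALSE)
    if (anyDuplicated(x[[nm]]))
      stop("duplicate gene within unit '", nm, "'", call. = FALSE)
  }
  x
}

#' Read transcriptional units from TSV or JSON
#' @param path TSV with columns `unit_name, rank, locus_tag`, or a JSON
#'   object mapping unit names to ordered gene arrays.
#' @return named list of character vectors.
#' @export
read_transcript_units <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    transcript_units(lapply(jsonlite::read_json(path), unlist))
  } else {
    transcript_units(utils::read.delim(path, stringsAsFactors = FALSE))
  }
}

interpret_one_unit <- function(unit, calls) {
  # returns per-gene status within one unit; genes without an E/NE call are
  # untested and never act as downstream blockers
  call_of <- calls[unit]
  is_e <- !is.na(call_of) & call_of == "E"
  last_e <- if (any(is_e)) max(which(is_e)) else 0L
  status <- character(length(unit))
  for (i in seq_along(unit)) {
    status[i] <- if (is.na(call_of[i]) || !call_of[i] %in% c("E", "NE"))
      "untested"
    else if (call_of[i] == "E") {
      if (i < last_e) "potentially_polar" else "informative_essential"
    } else {
      if (i < last_e) "readthrough_anomaly" else "nonessential"
    }
  }
  stats::setNames(status, unit)
}

combine_status <- function(statuses) {
  # conservative union across the units containing a gene: an essential
  # call is informative only if informative in every unit (a roadblock on
  # shared DNA blocks all transcripts through it)
  if ("potentially_polar" %in% statuses) return("potentially_polar")
  if ("informative_essential" %in% statuses) return("informative_essential")
  if ("readthrough_anomaly" %in% statuses) return("readthrough_anomaly")
  if ("nonessential" %in% statuses) return("nonessential")
  "untested"
}

#' Interpret essentiality calls over transcriptional units
#'
#' Within each unit (after removing trans-complemented genes from the
#' evaluation, since their requirement is masked by the plasmid copy), an
#' `E` call is `informative_essential` iff no gene strictly downstream in
#' the same unit is called `E`; an `E` call with a downstream `E` is
#' `potentially_polar`; an `NE` call with a downstream `E` is a
#' `readthrough_anomaly`. Genes appearing in no unit are `unplaced`; genes
#' without an E/NE call are `untested`. Genes served by several units get
#' the most conservative combination of their per-unit statuses.
#'
#' @param calls named character vector (`E`/`NE`; other values or `NA` are
#'   treated as untested), names are gene identifiers.
#' @param units transcriptional units ([transcript_units()] input).
#' @param complemented identifiers of genes supplied in trans.
#' @return `data.frame` with columns `locus_tag, call, status,
#'   explanation`.
#' @export
interpret_calls <- function(calls, units, complemented = character()) {
  units <- transcript_units(units)
  stopifnot(!is.null(names(calls)))
  all_unit_genes <- unique(unlist(units))
  extra <- setdiff(complemented, all_unit_genes)
  if (length(extra))
    stop("complemented genes not found in any unit: ",
         paste(extra, collapse = ", "), call. = FALSE)
  per_gene <- list()
  for (nm in names(units)) {
    unit <- setdiff(units[[nm]], complemented)
    if (!length(unit)) next
    st <- interpret_one_unit(unit, calls)
    for (g in names(st)) per_gene[[g]] <- c(per_gene[[g]], st[[g]])
  }
  ids <- union(names(calls), setdiff(all_unit_genes, complemented))
  status <- vapply(ids, function(g) {
    if (g %in% complemented) "complemented"
    else if (is.null(per_gene[[g]])) "unplaced"
    else combine_status(per_gene[[g]])
  }, character(1))
  explanation <- c(
    informative_essential = "essential call with no downstream essential gene on any transcript",
    potentially_polar = "essential call upstream of an essential gene; may be a polar artifact",
    readthrough_anomaly = "nonessential call upstream of an essential gene; roadblock read through",
    nonessential = "nonessential call with no downstream essential gene",
    untested = "no E/NE call available",
    unplaced = "gene not assigned to any transcriptional unit",
    complemented = "supplied in trans; knockdown phenotype masked")
  out <- data.frame(locus_tag = ids,
                    call = unname(calls[ids]),
                    status = unname(status),
                    explanation = unname(explanation[status]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Informative essential genes from an interpretation
#' @param interpretation result of [interpret_calls()].
#' @return character vector of locus tags.
#' @export
informative_essentials <- function(interpretation) {
  interpretation$locus_tag[interpretation$status == "informative_essential"]
}

#' Reconcile base and trans-complementation rerun calls
#'
#' A gene called essential in the base assay but nonessential when a
#' downstream gene is supplied in trans was a polar artifact; one still
#' essential in the rerun is confirmed essential (its requirement does not
#' run through the complemented gene).
#'
#' @param base,rerun `data.frame`s with columns `locus_tag` and `call`
#'   (or named character vectors of calls).
#' @param complemented_gene the gene supplied in trans in the rerun
#'   (recorded in the output attributes).
#' @return `data.frame` with columns `locus_tag, base_call, rerun_call,
#'   resolution` where resolution is one of `polar_artifact`,
#'   `confirmed_essential`, `unchanged`.
#' @export
reconcile_complementation <- function(base, rerun, complemented_gene = NULL) {
  as_calls <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$call, x$locus_tag)
    else x
  }
  base <- as_calls(base); rerun <- as_calls(rerun)
  missing <- setdiff(names(base), names(rerun))
  if (length(missing))
    warning("genes missing from rerun, left unchanged: ",
            paste(missing, collapse = ", "), call. = FALSE)
  res <- vapply(names(base), function(g) {
    b <- base[[g]]
    r <- if (g %in% names(rerun)) rerun[[g]] else NA_character_
    if (!is.na(b) && b == "E" && !is.na(r) && r == "NE") "polar_artifact"
    else if (!is.na(b) && b == "E" && !is.na(r) && r == "E")
      "confirmed_essential"
    else "unchanged"
  }, character(1))
  out <- data.frame(locus_tag = names(base), base_call = unname(base),
                    rerun_call = unname(rerun[names(base)]),
                    resolution = unname(res), stringsAsFactors = FALSE)
  attr(out, "complemented_gene") <- complemented_gene
  rownames(out) <- NULL
  out
}
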