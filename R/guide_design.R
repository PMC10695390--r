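#' Guide design configuration
#'
#' Parameters of the Cas12a CRISPRi spacer designer. Defaults encode the
#' design rules used throughout this package: a TTTV PAM, a 28-nt spacer
#' taken from the coding strand immediately downstream of the PAM, and a
#' positional window requiring the PAM to start between 20% and 33% of the
#' way through the coding sequence (inclusive at both bounds), which avoids
#' alternative start sites near the annotated start codon while keeping the
#' roadblock promoter-distal end effects at bay.
#'
#' @param pam_motif IUPAC pattern for the PAM (default `"TTTV"`).
#' @param spacer_length spacer length in nt (default 28).
#' @param window_lo,window_hi PAM-start position as a fraction of CDS
#'   length; candidates outside `[window_lo, window_hi]` are ignored.
#' @param strand_policy only `"coding_strand_only"` is supported: the
#'   spacer is defined on the coding strand of the targeted gene.
#' @param fallback `"none"` (strict window; genes without an in-window PAM
#'   are reported untargetable) or `"extend_downstream"` (widen the window
#'   to `[window_lo, 1]` before declaring a gene untargetable).
#' @return an object of class `design_config`.
#' @export
design_config <- function(pam_motif = "TTTV", spacer_length = 28L,
                          window_lo = 0.20, window_hi = 0.33,
                          strand_policy = "coding_strand_only",
                          fallback = c("none", "extend_downstream")) {
  fallback <- match.arg(fallback)
  strand_policy <- match.arg(strand_policy, "coding_strand_only")
  pam_motif <- toupper(pam_motif)
  if (!nzchar(pam_motif) ||
      !all(strsplit(pam_motif, "")[[1]] %in% names(IUPAC_CODES)))
    stop("pam_motif must be a nonempty IUPAC nucleotide pattern",
         call. = FALSE)
  spacer_length <- as.integer(spacer_length)
  stopifnot(spacer_length > 0L,
            window_lo >= 0, window_lo < window_hi, window_hi <= 1)
  structure(list(pam_motif = pam_motif, spacer_length = spacer_length,
                 window_lo = window_lo, window_hi = window_hi,
                 strand_policy = strand_policy, fallback = fallback),
            class = "design_config")
}

#' Find all matches of an IUPAC pattern in a sequence
#'
#' Positions where `pattern` matches `sequence` under IUPAC semantics:
#' ambiguity codes in the pattern expand (V matches A/C/G), while letters in
#' the sequence are taken literally, so an N in the sequence matches no
#' pattern base. Backed by [Biostrings::matchPattern()] with
#' `fixed = c(pattern = FALSE, subject = TRUE)`.
#'
#' @param pattern nonempty IUPAC nucleotide pattern.
#' @param sequence nucleotide string to scan.
#' @return integer vector of 1-based match start positions (possibly empty).
#' @export
#' @examples
#' match_iupac("TTTV", "TTTAGG")  # 1
#' match_iupac("TTTV", "TTTT")    # none: V excludes T
match_iupac <- function(pattern, sequence) {
  pattern <- toupper(pattern)
  if (!nzchar(pattern) ||
      !all(strsplit(pattern, "")[[1]] %in% names(IUPAC_CODES)))
    stop("invalid IUPAC code in pattern '", pattern, "'", call. = FALSE)
  sequence <- toupper(sequence)
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  hits <- Biostrings::matchPattern(
    pattern, Biostrings::DNAString(sequence),
    fixed = c(pattern = FALSE, subject = TRUE))
  as.integer(BiocGenerics::start(hits))
}

untargetable_result <- function(locus_tag, gene, reason) {
  structure(list(locus_tag = locus_tag, gene = gene, status = "untargetable",
                 reason = reason), class = "guide_candidate")
}

#' Design one crRNA spacer for a gene
#'
#' Scans the coding strand of the gene for PAM matches whose start position,
#' as a fraction of CDS length, lies inside the design window, and whose
#' full spacer (the `spacer_length` bases immediately downstream of the PAM
#' on the coding strand) exists within the genome sequence. The spacer may
#' extend past the 3' end of the CDS but never past the genome. Among
#' eligible candidates the one with the smallest CDS offset is returned
#' (deterministic earliest-usable-site rule); genes with no eligible PAM
#' are reported untargetable with a reason.
#'
#' @param g a `phage_genome`.
#' @param feature locus_tag or one-row feature `data.frame`.
#' @param config a [design_config()].
#' @return an object of class `guide_candidate`: either a designed guide
#'   (`status = "ok"`, with fields `spacer`, `pam_sequence`,
#'   `pam_cds_offset` (0-based), `pam_fraction`, `genomic_pam_start`,
#'   `genomic_strand`) or an untargetable record (`status =
#'   "untargetable"`, with `reason`).
#' @export
design_guide <- function(g, feature, config = design_config()) {
  f <- feature_row(g, feature)
  cds_len <- f$end - f$start + 1L
  if (cds_len <= config$spacer_length)
    return(untargetable_result(f$locus_tag, f$gene, "gene too short"))
  cds <- coding_sequence(g, f)
  pam_len <- nchar(config$pam_motif)
  glen <- genome_length(g)

  # coding-direction context extended past the CDS 3' end so spacers may
  # overhang the stop codon while staying within the genome
  if (f$strand == "+") {
    ext_end <- min(glen, f$end + config$spacer_length)
    context <- substr(g$sequence, f$start, ext_end)
  } else {
    ext_start <- max(1L, f$start - config$spacer_length)
    context <- reverse_complement(substr(g$sequence, ext_start, f$end))
  }

  pams <- match_iupac(config$pam_motif, cds)
  if (!length(pams))
    return(untargetable_result(f$locus_tag, f$gene, "no PAM in window"))
  frac <- (pams - 1) / cds_len
  lo <- config$window_lo
  hi <- if (config$fallback == "extend_downstream") 1.0 else config$window_hi
  in_window <- pams[frac >= lo & frac <= hi]
  if (config$fallback == "extend_downstream") {
    strict <- pams[frac >= config$window_lo & frac <= config$window_hi]
    if (length(strict)) in_window <- strict  # prefer the strict window
  }
  for (p in sort(in_window)) {
    sp_start <- p + pam_len
    sp_end <- sp_start + config$spacer_length - 1L
    if (sp_end > nchar(context)) next  # spacer would run off the genome
    spacer <- substr(context, sp_start, sp_end)
    if (grepl("N", spacer, fixed = TRUE)) next
    genomic_pam_start <- if (f$strand == "+") f$start + p - 1L
                         else f$end - p + 1L
    return(structure(list(
      locus_tag = f$locus_tag, gene = f$gene, status = "ok",
      pam_cds_offset = p - 1L, pam_fraction = (p - 1) / cds_len,
      pam_sequence = substr(cds, p, p + pam_len - 1L), spacer = spacer,
      genomic_pam_start = genomic_pam_start, genomic_strand = f$strand,
      reason = NA_character_), class = "guide_candidate"))
  }
  untargetable_result(f$locus_tag, f$gene, "no PAM in window")
}

#' @export
print.guide_candidate <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<guide> %s: PAM %s at CDS offset %d (%.3f), spacer %s\n",
                x$locus_tag, x$pam_sequence, x$pam_cds_offset,
                x$pam_fraction, x$spacer))
  } else {
    cat(sprintf("<guide> %s: untargetable (%s)\n", x$locus_tag, x$reason))
  }
  invisible(x)
}

#' Design crRNA spacers genome-wide
#'
#' Applies [design_guide()] to every annotated gene. The result is a pure
#' function of `(g, config)`: repeated runs are identical.
#'
#' @param g a `phage_genome` with at least one feature.
#' @param config a [design_config()].
#' @return an object of class `design_report`: list with `guides` (one row
#'   per designed guide) and `untargetable` (locus_tag + reason) data
#'   frames. Every input gene appears in exactly one of the two.
#' @export
design_genome <- function(g, config = design_config()) {
  if (!nrow(g$features)) stop("genome has no annotated genes", call. = FALSE)
  res <- lapply(seq_len(nrow(g$features)), function(i)
    design_guide(g, g$features[i, ], config))
  ok <- vapply(res, function(x) x$status == "ok", logical(1))
  guides <- if (any(ok)) do.call(rbind, lapply(res[ok], function(x)
    data.frame(locus_tag = x$locus_tag, gene = x$gene,
               pam_genomic_start = x$genomic_pam_start,
               strand = x$genomic_strand, pam_seq = x$pam_sequence,
               pam_cds_offset = x$pam_cds_offset,
               pam_fraction = x$pam_fraction, spacer = x$spacer,
               stringsAsFactors = FALSE)))
  else data.frame(locus_tag = character(), gene = character(),
                  pam_genomic_start = integer(), strand = character(),
                  pam_seq = character(), pam_cds_offset = integer(),
                  pam_fraction = numeric(), spacer = character(),
                  stringsAsFactors = FALSE)
  untargetable <- if (any(!ok)) do.call(rbind, lapply(res[!ok], function(x)
    data.frame(locus_tag = x$locus_tag, gene = x$gene, reason = x$reason,
               stringsAsFactors = FALSE)))
  else data.frame(locus_tag = character(), gene = character(),
                  reason = character(), stringsAsFactors = FALSE)
  structure(list(guides = guides, untargetable = untargetable,
                 config = config), class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %d guides designed, %d untargetable genes\n",
              nrow(x$guides), nrow(x$untargetable)))
  invisible(x)
}

#' Write a design report as TSV
#'
#' One row per input gene. Designed guides carry `status = "ok"`;
#' untargetable genes carry `status = "untargetable"` and a reason.
#' `pam_cds_offset` is the 0-based offset of the PAM start within the CDS.
#'
#' @param report a `design_report`.
#' @param path output path.
#' @export
write_design_report <- function(report, path) {
  g <- report$guides
  g$status <- rep("ok", nrow(g))
  g$reason <- rep(NA_character_, nrow(g))
  u <- report$untargetable
  if (nrow(u)) {
    u <- data.frame(locus_tag = u$locus_tag, gene = u$gene,
                    pam_genomic_start = NA_integer_, strand = NA_character_,
                    pam_seq = NA_character_, pam_cds_offset = NA_integer_,
                    pam_fraction = NA_real_, spacer = NA_character_,
                    status = "untargetable", reason = u$reason,
                    stringsAsFactors = FALSE)
    g <- rbind(g, u)
  }
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a design report TSV back into a `design_report`
#' @param path path written by [write_design_report()].
#' @return a `design_report`.
#' @export
read_design_report <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ok <- tab$status == "ok"
  structure(list(
    guides = tab[ok, setdiff(names(tab), c("status", "reason")),
                 drop = FALSE],
    untargetable = tab[!ok, c("locus_tag", "gene", "reason"), drop = FALSE],
    config = NULL), class = "design_report")
}
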