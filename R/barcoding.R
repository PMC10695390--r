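# Barcode-insertion construct design and Barseq-style barcode counting.
#
# A recombination template for inserting a random 20-nt DNA barcode at a
# nonessential locus consists of two 100-nt homology arms copied exactly
# from the genome around the insertion point, with the barcode between two
# fixed primer-binding flanks in the middle. A counterselection guide for
# nuclease-active Cas12a targets the wild-type junction (its protospacer
# spans the insertion point) so that recombinants, whose junction is
# interrupted by the cassette, escape cutting.

# placeholder primer-binding flanks; real designs supply their own
DEFAULT_LEFT_FLANK <- "CAGCGTACGGTAGTCGTCAC"
DEFAULT_RIGHT_FLANK <- "GTCGACCTGCAGCGTACGTT"

has_homopolymer <- function(x, n = 5L) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", n, n, n, n), x)
}

gc_fraction <- function(x) {
  chars <- strsplit(x, "")[[1]]
  mean(chars %in% c("G", "C"))
}

random_barcode <- function(length = 20L, gc_range = c(0.25, 0.75),
                           max_homopolymer = 4L, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    bc <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                collapse = "")
    gc <- gc_fraction(bc)
    if (gc >= gc_range[1] && gc <= gc_range[2] &&
        !has_homopolymer(bc, max_homopolymer + 1L)) return(bc)
  }
  stop("could not draw a barcode satisfying composition filters",
       call. = FALSE)
}

hamming <- function(a, b) str_mismatches(a, b)

#' Generate a set of random DNA barcodes
#'
#' Seeded, deterministic barcode generation with Barseq-compatible
#' composition filters: GC fraction within `gc_range`, no homopolymer run
#' longer than `max_homopolymer`, and minimum pairwise Hamming distance
#' within the set.
#'
#' @param n number of barcodes.
#' @param length barcode length in nt (default 20).
#' @param seed integer RNG seed.
#' @param gc_range allowed GC fraction range.
#' @param max_homopolymer longest allowed homopolymer run.
#' @param min_hamming minimum pairwise Hamming distance (default 3).
#' @return character vector of `n` barcodes.
#' @export
generate_barcodes <- function(n, length = 20L, seed = 1L,
                              gc_range = c(0.25, 0.75),
                              max_homopolymer = 4L, min_hamming = 3L) {
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 1000L * n)
        stop("could not generate a barcode set with the requested ",
             "pairwise distance", call. = FALSE)
      bc <- random_barcode(length, gc_range, max_homopolymer)
      if (all(vapply(out, hamming, integer(1), b = bc) >= min_hamming))
        out <- c(out, bc)
    }
    out
  })
}

#' Design a barcode-insertion recombination construct
#'
#' Copies `arm_length` nt of genomic sequence on each side of the
#' insertion point (the midpoint of the locus by default) as homology
#' arms, and places a seeded random barcode between the two primer-binding
#' flanks. Deterministic given `seed`.
#'
#' @param g a `phage_genome`.
#' @param locus a locus_tag, a one-row feature `data.frame`, or a single
#'   genomic coordinate: the insertion point falls between `locus` and
#'   `locus + 1`.
#' @param arm_length homology arm length in nt (default 100).
#' @param barcode_length barcode length in nt (default 20).
#' @param seed integer RNG seed for the barcode draw.
#' @param left_flank,right_flank fixed primer-binding sequences
#'   (configurable; package defaults are placeholders).
#' @param calls optional named character vector of essentiality calls; a
#'   warning is raised when inserting at a locus called `E`.
#' @return object of class `barcode_construct`: list with `locus_tag`,
#'   `insertion_point`, `upstream_arm`, `downstream_arm`, `barcode`,
#'   `left_flank`, `right_flank`, `full_sequence`.
#' @export
design_construct <- function(g, locus, arm_length = 100L,
                             barcode_length = 20L, seed = 1L,
                             left_flank = DEFAULT_LEFT_FLANK,
                             right_flank = DEFAULT_RIGHT_FLANK,
                             calls = NULL) {
  left_flank <- check_dna(left_flank, allow_n = FALSE, "left_flank")
  right_flank <- check_dna(right_flank, allow_n = FALSE, "right_flank")
  if (is.numeric(locus) && length(locus) == 1L) {
    m <- as.integer(locus)
    locus_tag <- sprintf("pos%d", m)
  } else {
    f <- feature_row(g, locus)
    locus_tag <- f$locus_tag
    m <- f$start + (f$end - f$start) %/% 2L
    if (!is.null(calls) && !is.na(calls[locus_tag]) &&
        calls[locus_tag] == "E")
      warning("inserting at essential locus ", locus_tag, call. = FALSE)
  }
  glen <- genome_length(g)
  if (m - arm_length + 1L < 1L || m + arm_length > glen)
    stop("insufficient genomic flank for ", arm_length,
         "-nt homology arms at position ", m, call. = FALSE)
  upstream <- substr(g$sequence, m - arm_length + 1L, m)
  downstream <- substr(g$sequence, m + 1L, m + arm_length)
  barcode <- with_seed(seed, random_barcode(barcode_length))
  structure(list(
    locus_tag = locus_tag, insertion_point = m,
    upstream_arm = upstream, downstream_arm = downstream,
    barcode = barcode, left_flank = left_flank, right_flank = right_flank,
    full_sequence = paste0(upstream, left_flank, barcode, right_flank,
                           downstream)), class = "barcode_construct")
}

#' @export
print.barcode_construct <- function(x, ...) {
  cat(sprintf("<construct> %s @%d: arms %d/%d nt, barcode %s\n",
              x$locus_tag, x$insertion_point, nchar(x$upstream_arm),
              nchar(x$downstream_arm), x$barcode))
  invisible(x)
}

#' In-silico recombinant genome sequence for a construct
#'
#' The wild-type sequence with the barcode cassette
#' (`left_flank + barcode + right_flank`) inserted at the construct's
#' insertion point.
#'
#' @param g a `phage_genome`.
#' @param construct a `barcode_construct` designed on `g`.
#' @return nucleotide string.
#' @export
recombinant_sequence <- function(g, construct) {
  m <- construct$insertion_point
  paste0(substr(g$sequence, 1L, m),
         construct$left_flank, construct$barcode, construct$right_flank,
         substr(g$sequence, m + 1L, genome_length(g)))
}

count_site_matches <- function(site, sequence) {
  # exact occurrences of a protospacer+PAM site on either strand
  s <- Biostrings::DNAString(sequence)
  length(Biostrings::matchPattern(site, s)) +
    length(Biostrings::matchPattern(reverse_complement(site), s))
}

#' Design a counterselection guide spanning a construct's junction
#'
#' Searches both strands around the insertion point for a PAM whose
#' spacer covers the junction, so that the protospacer is present in the
#' wild-type genome but interrupted (absent) in the recombinant. Cutting
#' only needs a target, so unlike knockdown design both strands are
#' scanned.
#'
#' @param g a `phage_genome`.
#' @param construct a `barcode_construct` designed on `g`.
#' @param config a [design_config()]; supplies the PAM motif and spacer
#'   length.
#' @return a `guide_candidate` (status `"ok"`) whose `spacer` spans the
#'   insertion point; errors listing the nearest PAM positions when no
#'   spanning guide exists.
#' @export
design_counterselection_guide <- function(g, construct,
                                          config = design_config()) {
  m <- construct$insertion_point
  ls <- config$spacer_length
  pl <- nchar(config$pam_motif)
  glen <- genome_length(g)
  recomb <- recombinant_sequence(g, construct)
  # search window: any PAM whose spacer could reach the junction
  w_lo <- max(1L, m - ls - pl)
  w_hi <- min(glen, m + ls + pl)
  window <- substr(g$sequence, w_lo, w_hi)

  candidates <- list()
  # plus strand: PAM at genomic q, spacer covers [q+pl, q+pl+ls-1]
  for (p in match_iupac(config$pam_motif, window)) {
    q <- w_lo + p - 1L
    sp_start <- q + pl; sp_end <- sp_start + ls - 1L
    if (sp_start <= m && sp_end >= m + 1L && sp_end <= glen)
      candidates[[length(candidates) + 1L]] <-
        list(strand = "+", pam_start = q,
             spacer = substr(g$sequence, sp_start, sp_end),
             pam_seq = substr(g$sequence, q, q + pl - 1L),
             dist = abs((sp_start + sp_end) / 2 - (m + 0.5)))
  }
  # minus strand: scan the reverse complement of the window
  rc_window <- reverse_complement(window)
  for (p in match_iupac(config$pam_motif, rc_window)) {
    q <- w_hi - p + 1L                      # genomic coord of PAM 5' base
    sp_hi <- q - pl                         # spacer runs 3'->5' genomically
    sp_lo <- sp_hi - ls + 1L
    if (sp_lo <= m && sp_hi >= m + 1L && sp_lo >= 1L)
      candidates[[length(candidates) + 1L]] <-
        list(strand = "-", pam_start = q,
             spacer = reverse_complement(substr(g$sequence, sp_lo, sp_hi)),
             pam_seq = reverse_complement(
               substr(g$sequence, q - pl + 1L, q)),
             dist = abs((sp_lo + sp_hi) / 2 - (m + 0.5)))
  }
  # keep candidates whose protospacer+PAM hits wild type but not the
  # recombinant
  keep <- Filter(function(cand) {
    site <- paste0(cand$pam_seq, cand$spacer)
    count_site_matches(site, g$sequence) >= 1L &&
      count_site_matches(site, recomb) == 0L
  }, candidates)
  if (!length(keep)) {
    nearest <- vapply(candidates, function(cand) cand$pam_start, integer(1))
    stop("no PAM positions a junction-spanning spacer at insertion point ",
         m, if (length(nearest))
           paste0("; nearest PAMs at ",
                  paste(sort(nearest), collapse = ", "))
         else "; no PAM near the junction at all", call. = FALSE)
  }
  best <- keep[[order(vapply(keep, `[[`, numeric(1), "dist"))[1]]]
  structure(list(
    locus_tag = construct$locus_tag, gene = NA_character_, status = "ok",
    pam_cds_offset = NA_integer_, pam_fraction = NA_real_,
    pam_sequence = best$pam_seq, spacer = best$spacer,
    genomic_pam_start = best$pam_start, genomic_strand = best$strand,
    reason = NA_character_), class = "guide_candidate")
}

# ---- Barseq counting ------------------------------------------------------

#' Count barcodes in amplicon reads
#'
#' For each read, locates `left_flank` allowing up to
#' `max_flank_mismatches` mismatches, extracts the following
#' `barcode_length` nt, and requires `right_flank` immediately after
#' (again within the mismatch budget). Extracted barcodes are matched
#' exactly against the expected set, or tallied as distinct k-mers in
#' discover mode; everything else is unassigned.
#'
#' @param reads FASTQ path, `DNAStringSet`, or character vector of read
#'   sequences.
#' @param expected character vector of known barcodes, or `NULL` for
#'   discover mode.
#' @param left_flank,right_flank fixed primer-binding sequences.
#' @param max_flank_mismatches per-flank mismatch budget (default 1).
#' @param barcode_length barcode length (default 20).
#' @return object of class `barcode_counts`: list with `counts` (named
#'   integer vector), `fraction` (relative abundance over assigned reads),
#'   `assigned`, `unassigned`, `total`.
#' @export
count_barcodes <- function(reads, expected = NULL,
                           left_flank = DEFAULT_LEFT_FLANK,
                           right_flank = DEFAULT_RIGHT_FLANK,
                           max_flank_mismatches = 1L,
                           barcode_length = 20L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- tryCatch(
      Biostrings::readDNAStringSet(reads, format = "fastq"),
      error = function(e) stop("unreadable FASTQ '", reads, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  stopifnot(methods::is(reads, "DNAStringSet"))
  total <- length(reads)
  lf_len <- nchar(left_flank); rf_len <- nchar(right_flank)

  hits <- Biostrings::vmatchPattern(left_flank, reads,
                                    max.mismatch = max_flank_mismatches)
  starts <- vapply(BiocGenerics::start(hits), function(s)
    if (length(s)) s[1] else NA_integer_, integer(1))
  seqs <- as.character(reads)
  bc_start <- starts + lf_len
  barcode <- substr(seqs, bc_start, bc_start + barcode_length - 1L)
  right_obs <- substr(seqs, bc_start + barcode_length,
                      bc_start + barcode_length + rf_len - 1L)
  ok <- !is.na(starts) & nchar(barcode) == barcode_length &
    nchar(right_obs) == rf_len
  ok[ok] <- vapply(which(ok), function(i)
    str_mismatches(right_obs[i], right_flank) <= max_flank_mismatches,
    logical(1))
  extracted <- barcode[ok]
  if (!is.null(expected)) {
    assigned_mask <- extracted %in% expected
    counts <- table(factor(extracted[assigned_mask], levels = expected))
    counts <- stats::setNames(as.integer(counts), names(counts))
    assigned <- sum(assigned_mask)
  } else {
    tab <- table(extracted)
    counts <- stats::setNames(as.integer(tab), names(tab))
    assigned <- length(extracted)
  }
  structure(list(counts = counts,
                 fraction = if (assigned > 0) counts / assigned
                            else counts * NA_real_,
                 assigned = assigned,
                 unassigned = total - assigned,
                 total = total), class = "barcode_counts")
}

#' @export
print.barcode_counts <- function(x, ...) {
  cat(sprintf("<barcode_counts> %d reads: %d assigned to %d barcodes, %d unassigned\n",
              x$total, x$assigned, length(x$counts), x$unassigned))
  invisible(x)
}

#' Barcode count table as a data.frame
#' @param x a `barcode_counts`.
#' @param sample sample label for the first column.
#' @param ... unused.
#' @return `data.frame` with columns `sample, barcode, count, fraction`.
#' @export
as.data.frame.barcode_counts <- function(x, sample = "sample1", ...) {
  data.frame(sample = sample, barcode = names(x$counts),
             count = unname(x$counts), fraction = unname(x$fraction),
             stringsAsFactors = FALSE)
}

#' Write a barcode count table (TSV)
#' @param x a `barcode_counts`.
#' @param path output path.
#' @param sample sample label.
#' @export
write_barcode_counts <- function(x, path, sample = "sample1") {
  utils::write.table(as.data.frame(x, sample = sample), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
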