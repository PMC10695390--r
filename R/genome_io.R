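#' Construct a gene feature table row
#'
#' A gene feature is an annotated coding sequence with strand and 1-based
#' inclusive genomic coordinates (the convention of GenBank and of the
#' Bioconductor ranges infrastructure). Features that would wrap the origin
#' of a circular genome are rejected: `start <= end` always.
#'
#' @param locus_tag unique identifier for the feature.
#' @param start,end 1-based inclusive genomic coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param gene optional gene symbol.
#' @param product optional free-text product description.
#' @return one-row `data.frame` with columns
#'   `locus_tag, gene, start, end, strand, product`.
#' @export
gene_feature <- function(locus_tag, start, end, strand, gene = NA_character_,
                         product = NA_character_) {
  stopifnot(is.character(locus_tag), length(locus_tag) == 1L, nzchar(locus_tag))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("invalid feature coordinates for ", locus_tag,
         ": need 1 <= start <= end", call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'", call. = FALSE)
  data.frame(locus_tag = locus_tag, gene = as.character(gene),
             start = start, end = end, strand = strand,
             product = as.character(product), stringsAsFactors = FALSE)
}

#' Construct an annotated genome object
#'
#' Container for a phage genome: an accession, a nucleotide sequence over
#' `{A,C,G,T,N}` (other ambiguity codes are rejected on input), a topology,
#' and an ordered feature table. `N` is permitted in the sequence but never
#' matches any PAM base during guide design.
#'
#' @param accession text accession / identifier.
#' @param sequence nucleotide string.
#' @param features `data.frame` as built by [gene_feature()] (zero or more
#'   rows); locus tags must be unique and coordinates within the sequence.
#' @param topology `"linear"` or `"circular"`. Circular genomes are stored
#'   as such but origin-wrapping features are not supported.
#' @return an object of class `phage_genome`.
#' @export
genome <- function(accession, sequence, features = NULL,
                   topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- check_dna(sequence, allow_n = TRUE, what = "genome sequence")
  if (is.null(features)) {
    features <- data.frame(locus_tag = character(), gene = character(),
                           start = integer(), end = integer(),
                           strand = character(), product = character(),
                           stringsAsFactors = FALSE)
  }
  needed <- c("locus_tag", "gene", "start", "end", "strand", "product")
  missing_cols <- setdiff(needed, names(features))
  if ("gene" %in% missing_cols) features$gene <- NA_character_
  if ("product" %in% missing_cols) features$product <- NA_character_
  stopifnot(all(c("locus_tag", "start", "end", "strand") %in% names(features)))
  features <- features[, needed, drop = FALSE]
  if (anyDuplicated(features$locus_tag))
    stop("duplicate locus_tags: ",
         paste(unique(features$locus_tag[duplicated(features$locus_tag)]),
               collapse = ", "), call. = FALSE)
  glen <- nchar(sequence)
  bad <- features$start < 1L | features$end > glen |
    features$start > features$end
  if (any(bad))
    stop("feature coordinates outside sequence bounds (or origin-wrapping, ",
         "which is unsupported): ",
         paste(features$locus_tag[bad], collapse = ", "), call. = FALSE)
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'", call. = FALSE)
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(accession = accession, sequence = sequence,
                 topology = topology, features = features),
            class = "phage_genome")
}

#' @export
print.phage_genome <- function(x, ...) {
  cat(sprintf("<phage_genome> %s: %s bp (%s), %d annotated genes\n",
              x$accession, format(nchar(x$sequence), big.mark = ","),
              x$topology, nrow(x$features)))
  invisible(x)
}

#' Genome length in nucleotides
#' @param g a `phage_genome`.
#' @return integer length.
#' @export
genome_length <- function(g) nchar(g$sequence)

feature_row <- function(g, feature) {
  if (is.character(feature)) {
    i <- match(feature, g$features$locus_tag)
    if (is.na(i)) stop("no feature with locus_tag '", feature, "'",
                       call. = FALSE)
    g$features[i, , drop = FALSE]
  } else if (is.data.frame(feature) && nrow(feature) == 1L) {
    feature
  } else stop("feature must be a locus_tag or a one-row feature data.frame",
              call. = FALSE)
}

#' Strand-aware coding sequence of a gene
#'
#' Returns the coding-strand sequence of a feature: the genomic slice
#' `[start, end]` for `+` strand genes, its reverse complement for `-`
#' strand genes. Always uppercase; length equals `end - start + 1`.
#'
#' @param g a `phage_genome`.
#' @param feature a locus_tag or a one-row feature `data.frame`.
#' @return nucleotide string.
#' @export
coding_sequence <- function(g, feature) {
  f <- feature_row(g, feature)
  if (f$start < 1L || f$end > genome_length(g))
    stop("feature outside genome bounds", call. = FALSE)
  s <- substr(g$sequence, f$start, f$end)
  if (f$strand == "-") s <- reverse_complement(s)
  toupper(s)
}

# ---- GenBank flat file I/O ------------------------------------------------
# Minimal reader/writer for simple single-record phage genomes: LOCUS,
# FEATURES with plain or complement() CDS spans, ORIGIN. Compound
# (join/order) locations are rejected: phage genomes here have simple spans.

parse_genbank_location <- function(loc, line_no) {
  loc <- gsub("[<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|complement", loc))
    stop("compound/joined CDS location at line ", line_no,
         " is not supported: ", loc, call. = FALSE)
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
  if (length(m) != 3L) {
    m1 <- regmatches(loc, regexec("^([0-9]+)$", loc))[[1]]
    if (length(m1) == 2L) return(list(start = as.integer(m1[2]),
                                      end = as.integer(m1[2]),
                                      strand = strand))
    stop("cannot parse CDS location at line ", line_no, ": ", loc,
         call. = FALSE)
  }
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  locus_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  accession <- if (length(locus_fields) >= 2) locus_fields[2] else "unknown"
  topology <- if (any(grepl("circular", lines[1]))) "circular" else "linear"
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) {
    acc <- strsplit(trimws(acc_line[1]), "\\s+")[[1]]
    if (length(acc) >= 2) accession <- acc[2]
  }
  ver_line <- grep("^VERSION", lines, value = TRUE)
  if (length(ver_line)) {
    ver <- strsplit(trimws(ver_line[1]), "\\s+")[[1]]
    if (length(ver) >= 2) accession <- ver[2]
  }

  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) stop("no ORIGIN section in ", path, call. = FALSE)
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > origin_at[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1] + 1L):(end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_at <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_at)) {
    block <- lines[(feat_at[1] + 1L):(origin_at[1] - 1L)]
    # feature keys start at column 6; qualifier/continuation lines at 22
    key_idx <- grep("^ {5}\\S", block)
    for (j in seq_along(key_idx)) {
      i0 <- key_idx[j]
      i1 <- if (j < length(key_idx)) key_idx[j + 1] - 1L else length(block)
      header <- trimws(block[i0])
      parts <- strsplit(header, "\\s+")[[1]]
      key <- parts[1]
      if (key != "CDS") next
      body <- block[i0:i1]
      # location may continue over lines until the first qualifier
      qual_start <- grep("^\\s+/", body)
      loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(body)
      loc <- paste(trimws(sub("^ {5}CDS", "", body[1])),
                   paste(trimws(body[seq_len(loc_end)][-1]), collapse = ""),
                   sep = "")
      loc <- gsub("\\s", "", loc)
      pos <- parse_genbank_location(loc, feat_at[1] + i0)
      quals <- paste(trimws(body[loc_end + seq_len(length(body) - loc_end)]),
                     collapse = " ")
      get_qual <- function(name) {
        m <- regmatches(quals,
                        regexec(sprintf('/%s="([^"]*)"', name), quals))[[1]]
        if (length(m) == 2L) m[2] else NA_character_
      }
      feats[[length(feats) + 1L]] <- data.frame(
        locus_tag = get_qual("locus_tag"), gene = get_qual("gene"),
        start = pos$start, end = pos$end, strand = pos$strand,
        product = get_qual("product"), stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  if (!is.null(features)) {
    no_tag <- is.na(features$locus_tag)
    features$locus_tag[no_tag] <- ifelse(
      !is.na(features$gene[no_tag]), features$gene[no_tag],
      sprintf("CDS_%04d", which(no_tag)))
    bad <- features$end > nchar(sequence)
    if (any(bad))
      stop("CDS outside sequence bounds in ", path, ": ",
           paste(features$locus_tag[bad], collapse = ", "), call. = FALSE)
  }
  genome(accession, sequence, features, topology)
}

#' Read an annotated genome
#'
#' @param path path to a GenBank flat file, or to a FASTA file when
#'   `format = "fasta"`.
#' @param format `"genbank"` or `"fasta"`. The FASTA route requires a
#'   `gene_table` with columns `locus_tag, gene, start, end, strand`
#'   (coordinates 1-based inclusive, as in the file format documentation).
#' @param gene_table optional path to the TSV gene-coordinate table.
#' @return a `phage_genome`.
#' @export
read_genome <- function(path, format = c("genbank", "fasta"),
                        gene_table = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "genbank") return(read_genbank(path))
  dss <- Biostrings::readDNAStringSet(path)
  if (!length(dss)) stop("empty FASTA: ", path, call. = FALSE)
  accession <- strsplit(names(dss)[1], "\\s+")[[1]][1]
  features <- if (!is.null(gene_table)) read_gene_table(gene_table) else NULL
  genome(accession, as.character(dss[[1]]), features)
}

#' Read a gene-coordinate table (TSV, 1-based inclusive coordinates)
#' @param path TSV with columns `locus_tag, gene, start, end, strand`.
#' @return feature `data.frame`.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("locus_tag", "gene", "start", "end", "strand")
  if (!all(needed %in% names(tab)))
    stop("gene table must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (!"product" %in% names(tab)) tab$product <- NA_character_
  tab[, c(needed, "product")]
}

#' Write the gene-coordinate table of a genome (TSV, 1-based inclusive)
#' @param g a `phage_genome`.
#' @param path output path.
#' @export
write_gene_table <- function(g, path) {
  utils::write.table(g$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

format_genbank_sequence <- function(sequence) {
  n <- nchar(sequence)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, paste(tolower(tens), collapse = " "))
  }, character(1))
}

#' Write a genome as a GenBank flat file
#'
#' Emits a minimal single-record flat file (LOCUS, FEATURES with source and
#' CDS entries, ORIGIN) that round-trips through [read_genome()].
#'
#' @param g a `phage_genome`.
#' @param path output path.
#' @export
write_genbank <- function(g, path) {
  n <- nchar(g$sequence)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   PHG",
                   g$accession, n, g$topology),
           sprintf("DEFINITION  %s.", g$accession),
           sprintf("ACCESSION   %s", sub("\\.[0-9]+$", "", g$accession)),
           sprintf("VERSION     %s", g$accession),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     CDS             %s", loc),
             sprintf('                     /locus_tag="%s"', f$locus_tag))
    if (!is.na(f$gene) && nzchar(f$gene))
      out <- c(out, sprintf('                     /gene="%s"', f$gene))
    if (!is.na(f$product) && nzchar(f$product))
      out <- c(out, sprintf('                     /product="%s"', f$product))
  }
  out <- c(out, "ORIGIN", format_genbank_sequence(g$sequence), "//")
  writeLines(out, path)
  invisible(path)
}

#' Write a genome (GenBank or FASTA)
#' @param g a `phage_genome`.
#' @param path output path.
#' @param format `"genbank"` or `"fasta"`.
#' @export
write_genome <- function(g, path, format = c("genbank", "fasta")) {
  format <- match.arg(format)
  if (format == "genbank") return(write_genbank(g, path))
  dss <- Biostrings::DNAStringSet(g$sequence)
  names(dss) <- g$accession
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
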