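# Seeded simulators with known ground truth, plus the transcribed
# published benchmark tables shipped under inst/extdata.

#' Simulation specification
#'
#' Parameters of the synthetic-data generators. Defaults describe a small
#' phage-like genome (20 ATG-initiated, stop-terminated ORFs of 300-900 nt
#' on random strands with short intergenic gaps) in which every gene is
#' guaranteed a TTTV PAM starting inside the 20-33% design window, and a
#' spot-titration experiment with a control titer of 5e9 PFU/mL, a 10-fold
#' dilution series (10^0..10^-8), 2-uL spots, and Poisson plaque-counting
#' noise.
#'
#' @param seed integer seed; every simulator is a pure function of it.
#' @param n_genes number of genes.
#' @param gene_length_range ORF length range in nt (rounded to codons).
#' @param intergenic_range intergenic gap range in nt.
#' @param gc_fraction GC content of random sequence.
#' @param plant_pam_fraction fraction of genes guaranteed an in-window
#'   PAM. With `0`, genes are built from a T-free internal-codon alphabet
#'   so no TTTV can occur anywhere in any gene.
#' @param true_eop named numeric vector of true EOPs per simulated sample.
#' @param control_titer control lawn titer in PFU/mL.
#' @param dilution_exponents integer dilution exponents k (10^-k).
#' @param n_replicates replicates per sample.
#' @param spot_volume_uL spot volume (default 2).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, n_genes = 20L,
                            gene_length_range = c(300L, 900L),
                            intergenic_range = c(20L, 80L),
                            gc_fraction = 0.5, plant_pam_fraction = 1.0,
                            true_eop = c(gene_E = 1e-5, gene_NE = 1.0),
                            control_titer = 5e9,
                            dilution_exponents = 0:8,
                            n_replicates = 3L, spot_volume_uL = 2) {
  stopifnot(n_genes >= 1L, gc_fraction > 0, gc_fraction < 1,
            plant_pam_fraction >= 0, plant_pam_fraction <= 1,
            all(true_eop > 0), control_titer > 0,
            all(dilution_exponents >= 0), n_replicates >= 1L)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 intergenic_range = as.integer(intergenic_range),
                 gc_fraction = gc_fraction,
                 plant_pam_fraction = plant_pam_fraction,
                 true_eop = true_eop, control_titer = control_titer,
                 dilution_exponents = as.integer(dilution_exponents),
                 n_replicates = as.integer(n_replicates),
                 spot_volume_uL = spot_volume_uL),
            class = "simulation_spec")
}

random_codon <- function(gc, no_t = FALSE) {
  stops <- c("TAA", "TAG", "TGA")
  repeat {
    codon <- if (no_t) {
      p <- c((1 - gc) / 2, gc / 2, gc / 2)  # A, C, G renormalised
      paste(sample(c("A", "C", "G"), 3, replace = TRUE,
                   prob = p / sum(p)), collapse = "")
    } else {
      paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }
    if (!codon %in% stops) return(codon)
  }
}

synth_orf <- function(len, gc, plant_pam, no_t_schedule) {
  # ATG + internal codons + TAA; optionally overwrite two internal codons
  # with TTT GCA so a TTTG PAM starts inside the design window
  n_codons <- len %/% 3L
  stopifnot(n_codons >= 4L)
  internal <- vapply(seq_len(n_codons - 2L), function(i)
    random_codon(gc, no_t = no_t_schedule), character(1))
  if (plant_pam) {
    # codon index c puts its first base at gene position 3*c+1 (after ATG);
    # choose c so the PAM-start fraction (3*c)/len sits mid-window
    target <- round(0.25 * len / 3)
    c_idx <- max(1L, min(length(internal) - 1L, target))
    internal[c_idx] <- "TTT"
    internal[c_idx + 1L] <- "GCA"
  }
  paste0("ATG", paste(internal, collapse = ""), "TAA")
}

#' Generate a synthetic annotated phage-like genome
#'
#' Genes are ATG-initiated, stop-terminated ORFs placed on random strands
#' with random intergenic gaps. Genes flagged for PAM planting (the first
#' `plant_pam_fraction` of genes) carry a TTTG starting ~25% of the way
#' through the coding sequence, guaranteeing an in-window design site;
#' with `plant_pam_fraction = 0` the internal codons avoid T entirely so
#' no gene contains any TTTV. Deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @param path optional path; when given, the genome is also written as a
#'   GenBank flat file.
#' @return a `phage_genome`.
#' @export
generate_genome <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  g <- with_seed(spec$seed, {
    no_t <- spec$plant_pam_fraction == 0
    n_plant <- round(spec$plant_pam_fraction * spec$n_genes)
    pieces <- character(0)
    feats <- list()
    pos <- 1L
    lead <- random_dna(sample(spec$intergenic_range[1]:
                              spec$intergenic_range[2], 1),
                       spec$gc_fraction)
    pieces <- c(pieces, lead); pos <- pos + nchar(lead)
    for (i in seq_len(spec$n_genes)) {
      len <- sample(spec$gene_length_range[1]:spec$gene_length_range[2], 1)
      len <- (len %/% 3L) * 3L
      orf <- synth_orf(len, spec$gc_fraction, plant_pam = i <= n_plant,
                       no_t_schedule = no_t)
      strand <- sample(c("+", "-"), 1)
      seg <- if (strand == "+") orf else reverse_complement(orf)
      feats[[i]] <- gene_feature(sprintf("SYN_%03d", i),
                                 start = pos, end = pos + len - 1L,
                                 strand = strand,
                                 gene = sprintf("g%02d", i),
                                 product = "synthetic ORF")
      pieces <- c(pieces, seg); pos <- pos + len
      gap <- random_dna(sample(spec$intergenic_range[1]:
                               spec$intergenic_range[2], 1),
                        spec$gc_fraction)
      pieces <- c(pieces, gap); pos <- pos + nchar(gap)
    }
    tail <- random_dna(40L, spec$gc_fraction)  # room for 3'-overhanging spacers
    pieces <- c(pieces, tail)
    genome(sprintf("SYNPHG_seed%d", spec$seed),
           paste(pieces, collapse = ""), do.call(rbind, feats))
  })
  if (!is.null(path)) write_genbank(g, path)
  g
}

#' Simulate spot-titration plaque counts
#'
#' Control spot counts are Poisson with mean
#' `control_titer * volume_mL * 10^-k`; each target's counts use
#' `true_eop * control_titer` instead. Spots whose drawn count exceeds
#' `lawn_threshold` are recorded as lawn-cleared (uncountable).
#' Deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec()]; `spec$true_eop` names the target
#'   samples.
#' @param lawn_threshold counts above this are uncountable confluent
#'   lysis (default 100 per 2-uL spot).
#' @param control_id sample_id for the nontargeting control.
#' @return spot-count `data.frame` in the layout of
#'   [read_spot_counts()].
#' @export
simulate_spot_counts <- function(spec, lawn_threshold = 100L,
                                 control_id = "control") {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed + 1L, {
    vol_ml <- spec$spot_volume_uL / 1000
    samples <- c(stats::setNames(spec$control_titer, control_id),
                 spec$true_eop * spec$control_titer)
    rows <- list()
    for (s in names(samples)) {
      for (r in seq_len(spec$n_replicates)) {
        mu <- samples[[s]] * vol_ml * 10^-spec$dilution_exponents
        n <- stats::rpois(length(mu), mu)
        cleared <- n > lawn_threshold
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, replicate_id = r,
          dilution_exponent = spec$dilution_exponents,
          plaques = ifelse(cleared, NA_integer_, n),
          volume_uL = spec$spot_volume_uL,
          control_flag = s == control_id,
          lawn_cleared = cleared, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate Barseq amplicon reads
#'
#' Draws each read's barcode from `barcodes` with probabilities
#' `proportions` and emits reads of the form
#' `pad + left_flank + barcode + right_flank + pad`. Deterministic given
#' `seed`.
#'
#' @param barcodes character vector of barcodes.
#' @param proportions sampling probabilities (normalised internally).
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @param left_flank,right_flank primer-binding sequences.
#' @param pad_length random padding on each side (default 5 nt).
#' @param path optional FASTQ output path.
#' @return `DNAStringSet` of reads (invisibly the path when `path` is
#'   given).
#' @export
simulate_barcode_reads <- function(barcodes, proportions, n_reads,
                                   seed = 1L,
                                   left_flank = DEFAULT_LEFT_FLANK,
                                   right_flank = DEFAULT_RIGHT_FLANK,
                                   pad_length = 5L, path = NULL) {
  stopifnot(length(barcodes) == length(proportions), all(proportions >= 0))
  reads <- with_seed(seed, {
    picks <- sample(seq_along(barcodes), n_reads, replace = TRUE,
                    prob = proportions / sum(proportions))
    vapply(picks, function(i)
      paste0(random_dna(pad_length), left_flank, barcodes[i], right_flank,
             random_dna(pad_length)), character(1))
  })
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- sprintf("read%06d", seq_along(dss))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(dss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  strrep("I", nchar(reads))))
    return(invisible(path))
  }
  dss
}

#' Load a shipped benchmark fixture table
#'
#' The published lambda and P1 essentiality tables, transcribed verbatim
#' (including their internal inconsistencies; fixtures are evidence, not
#' opinion), plus the lambda lytic transcript map used by the polarity
#' interpreter. `lambda_table1_pq` is the separate re-assay block in which
#' the late-gene activator Q was supplied in trans.
#'
#' For the essentiality tables the returned data.frame carries the
#' printed columns plus derived helpers: `id` (locus_tag, falling back to
#' gene name for rows printed without one), `eop_value` (numeric EOP,
#' `NA` where not printed or not numeric), and `eop_censored` (printed as
#' an upper bound "<x").
#'
#' @param name one of `"lambda_table1"`, `"lambda_table1_pq"`,
#'   `"p1_table2"`, `"lambda_transcripts"`.
#' @return `data.frame` (for `lambda_transcripts`, columns
#'   `unit_name, rank, locus_tag`).
#' @export
load_fixture <- function(name = c("lambda_table1", "lambda_table1_pq",
                                  "p1_table2", "lambda_transcripts")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "phagemap")
  if (!nzchar(path) || !file.exists(path))
    stop("fixture '", name, "' not installed", call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (name == "lambda_transcripts") {
    tab$rank <- as.integer(tab$rank)
    return(tab)
  }
  tab$id <- ifelse(nzchar(tab$locus_tag), tab$locus_tag, tab$gene)
  raw <- trimws(tab$eop_average)
  tab$eop_censored <- grepl("^<", raw)
  num <- suppressWarnings(as.numeric(sub("^<", "", raw)))
  tab$eop_value <- num
  tab$sd_value <- suppressWarnings(as.numeric(tab$sd))
  tab
}

#' Essentiality calls of a fixture table as a named vector
#'
#' @param fixture a table from [load_fixture()].
#' @param column call column (default the study's own calls).
#' @return named character vector keyed by `id`; `NT`/blank become `NA`.
#' @export
fixture_calls <- function(fixture, column = "call_this_work") {
  calls <- trimws(fixture[[column]])
  calls[!calls %in% c("E", "NE")] <- NA_character_
  stats::setNames(calls, fixture$id)
}
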