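# Independent brute-force oracles, deliberately written without touching
# the implementation paths they check.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# position-by-position scan; N in the sequence matches nothing because the
# allowed sets only ever contain concrete bases
brute_iupac_scan <- function(pattern, sequence) {
  pat <- strsplit(pattern, "")[[1]]
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars); k <- length(pat)
  if (n < k) return(integer(0))
  ok <- vapply(seq_len(k), function(j) chars %in% ORACLE_IUPAC[[pat[j]]],
               logical(n))
  hits <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) hits <- hits & ok[j:(n - k + j), j]
  which(hits)
}

# per-base complement-and-reverse, independent of Biostrings
brute_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# informative-essential set by direct "last E index per unit" computation
brute_informative <- function(units, calls, complemented = character()) {
  out <- character(0)
  per_gene_informative <- list()
  for (u in units) {
    u <- setdiff(u, complemented)
    is_e <- !is.na(calls[u]) & calls[u] == "E"
    if (!any(is_e)) next
    last <- u[max(which(is_e))]
    for (g in u[is_e]) {
      per_gene_informative[[g]] <- c(per_gene_informative[[g]], g == last)
    }
  }
  out <- names(Filter(all, per_gene_informative))
  if (is.null(out)) character(0) else out
}

# analyze-style per-replicate EOP estimates: each target replicate's titer
# over the pooled (replicate-averaged) control titer
replicate_eops <- function(counts, target_id, control_id = "control") {
  ctrl <- counts[counts$sample_id == control_id, ]
  tgt <- counts[counts$sample_id == target_id, ]
  ctrl_titer <- mean(vapply(split(ctrl, ctrl$replicate_id), function(r)
    titer_from_spots(r)$value, numeric(1)))
  vapply(split(tgt, tgt$replicate_id), function(r)
    compute_eop(titer_from_spots(r), ctrl_titer)$value, numeric(1))
}

# union of base-assay and trans-complemented interpretations, the way the
# lambda argument combines them
informative_union <- function(calls_base, calls_rerun, units, complemented) {
  union(informative_essentials(interpret_calls(calls_base, units)),
        informative_essentials(interpret_calls(calls_rerun, units,
                                               complemented = complemented)))
}

lambda_base_calls <- function() fixture_calls(load_fixture("lambda_table1"))

lambda_rerun_calls <- function() {
  base <- lambda_base_calls()
  pq <- fixture_calls(load_fixture("lambda_table1_pq"))
  pq <- pq[!is.na(pq)]
  base[names(pq)] <- pq
  base
}
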