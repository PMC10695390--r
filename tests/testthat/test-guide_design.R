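test_that("IUPAC matching honours code semantics and rejects bad codes", {
  expect_identical(match_iupac("TTTV", "TTTT"), integer(0))  # V excludes T
  expect_identical(match_iupac("TTTV", "TTTAGG"), 1L)
  expect_identical(match_iupac("TTTV", "TTTNGG"), integer(0))  # N matches nothing
  expect_identical(match_iupac("TTTV", "ATTTCTTTG"), c(2L, 6L))
  expect_identical(match_iupac("TTTV", "TT"), integer(0))
  expect_error(match_iupac("TTTX", "ACGT"), "IUPAC")
})

test_that("IUPAC matching equals a brute-force position scan", {
  set.seed(403)
  patterns <- c("TTTV", "YTTN", "WSKM", "ACGT")
  for (i in 1:40) {
    s <- random_seq(500)
    for (p in patterns) {
      expect_identical(match_iupac(p, s), as.integer(brute_iupac_scan(p, s)))
    }
  }
  # sequences containing N
  s <- paste0("TTTN", random_seq(100), "NNNN")
  expect_identical(match_iupac("TTTV", s),
                   as.integer(brute_iupac_scan("TTTV", s)))
})

make_gene_with_pam <- function(pam_offsets, len = 300, pam = "TTTC") {
  # plus-strand gene of given length with PAMs planted at 1-based offsets,
  # all other positions drawn from an A/C/G alphabet so no stray TTTV occurs
  set.seed(sum(pam_offsets) + len)
  chars <- sample(c("A", "C", "G"), len, replace = TRUE)
  for (off in pam_offsets) {
    chars[off:(off + 3)] <- strsplit(pam, "")[[1]]
  }
  paste(chars, collapse = "")
}

test_that("designed spacer is the 28 nt immediately downstream of the PAM", {
  # PAM planted so it starts at 0-based CDS offset 75 (fraction 0.25)
  gene <- make_gene_with_pam(76, len = 300)
  g <- genome("t", paste0(gene, strrep("A", 40)),
              gene_feature("g1", 1, 300, "+"))
  cand <- design_guide(g, "g1")
  expect_equal(cand$status, "ok")
  expect_equal(cand$pam_cds_offset, 75L)
  expect_equal(cand$pam_fraction, 0.25)
  expect_identical(cand$spacer, substr(gene, 80, 107))  # 0-based 79..106
  expect_equal(nchar(cand$spacer), 28L)
})

test_that("minus-strand design works in coding-strand space", {
  gene <- make_gene_with_pam(76, len = 300)
  g <- genome("t", paste0(strrep("A", 40), brute_revcomp(gene)),
              gene_feature("g1", 41, 340, "-"))
  cand <- design_guide(g, "g1")
  expect_equal(cand$status, "ok")
  expect_equal(cand$pam_cds_offset, 75L)
  expect_identical(cand$spacer, substr(gene, 80, 107))
})

test_that("genes without usable PAMs are untargetable with a reason", {
  no_pam <- paste(rep("ACG", 100), collapse = "")
  g <- genome("t", no_pam, gene_feature("g1", 1, 300, "+"))
  cand <- design_guide(g, "g1")
  expect_equal(cand$status, "untargetable")
  expect_match(cand$reason, "no PAM")
  # PAM outside the window only
  gene <- make_gene_with_pam(10, len = 300)  # fraction 0.03 < 0.20
  g2 <- genome("t", paste0(gene, strrep("A", 40)),
               gene_feature("g1", 1, 300, "+"))
  expect_equal(design_guide(g2, "g1")$status, "untargetable")
  # short gene
  g3 <- genome("t", strrep("ACG", 9), gene_feature("g1", 1, 27, "+"))
  expect_match(design_guide(g3, "g1")$reason, "too short")
})

test_that("the smallest-offset in-window PAM wins the tie-break", {
  gene <- make_gene_with_pam(c(67, 91), len = 300)  # fractions 0.22, 0.30
  g <- genome("t", paste0(gene, strrep("A", 40)),
              gene_feature("g1", 1, 300, "+"))
  cand <- design_guide(g, "g1")
  expect_equal(cand$pam_cds_offset, 66L)
  expect_equal(round(cand$pam_fraction, 2), 0.22)
})

test_that("spacers may overhang the CDS 3' end but never the genome", {
  # gene of 100 nt, PAM at offset 30 (fraction 0.30): spacer runs to
  # coding position 62 -- inside; PAM at the window edge of a short gene
  # with no downstream genome forces rejection
  gene <- make_gene_with_pam(30, len = 100)
  g <- genome("t", gene, gene_feature("g1", 1, 100, "+"))
  cand <- design_guide(g, "g1")
  expect_equal(cand$status, "ok")
  # short gene whose only in-window spacer runs one base past the CDS end:
  # rejected when the genome stops there, designed once flank exists
  gene2 <- make_gene_with_pam(15, len = 45)  # fraction 14/45 = 0.31
  g2 <- genome("t", gene2, gene_feature("g1", 1, 45, "+"))
  expect_equal(design_guide(g2, "g1")$status, "untargetable")
  g3 <- genome("t", paste0(gene2, strrep("A", 40)),
               gene_feature("g1", 1, 45, "+"))
  cand3 <- design_guide(g3, "g1")
  expect_equal(cand3$status, "ok")
  expect_equal(nchar(cand3$spacer), 28L)
  expect_identical(substr(cand3$spacer, 1, 27), substr(gene2, 19, 45))
})

test_that("every emitted spacer reconstructs from the genome sequence", {
  g <- generate_genome(simulation_spec(seed = 23, n_genes = 30))
  rep <- design_genome(g)
  expect_equal(nrow(rep$guides) + nrow(rep$untargetable), 30L)
  for (i in seq_len(nrow(rep$guides))) {
    gu <- rep$guides[i, ]
    f <- g$features[g$features$locus_tag == gu$locus_tag, ]
    if (f$strand == "+") {
      sp_start <- f$start + gu$pam_cds_offset + 4L
      expect_identical(substr(g$sequence, sp_start, sp_start + 27L),
                       gu$spacer)
      expect_identical(substr(g$sequence, gu$pam_genomic_start,
                              gu$pam_genomic_start + 3L), gu$pam_seq)
    } else {
      sp_hi <- f$end - gu$pam_cds_offset - 4L
      expect_identical(brute_revcomp(substr(g$sequence, sp_hi - 27L, sp_hi)),
                       gu$spacer)
    }
    expect_gte(gu$pam_fraction, 0.20)
    expect_lte(gu$pam_fraction, 0.33)
  }
})

test_that("design is deterministic and monotone under window shrinking", {
  g <- generate_genome(simulation_spec(seed = 29, n_genes = 15,
                                       plant_pam_fraction = 0.5))
  r1 <- design_genome(g)
  r2 <- design_genome(g)
  expect_identical(r1$guides, r2$guides)
  wide <- design_genome(g, design_config(window_lo = 0.10,
                                         window_hi = 0.50))
  narrow <- design_genome(g, design_config(window_lo = 0.20,
                                           window_hi = 0.33))
  expect_true(all(narrow$guides$locus_tag %in% wide$guides$locus_tag))
})

test_that("extend_downstream fallback rescues genes with late PAMs only", {
  gene <- make_gene_with_pam(151, len = 300)  # fraction 0.50, out of window
  g <- genome("t", paste0(gene, strrep("A", 40)),
              gene_feature("g1", 1, 300, "+"))
  expect_equal(design_guide(g, "g1")$status, "untargetable")
  cand <- design_guide(g, "g1",
                       design_config(fallback = "extend_downstream"))
  expect_equal(cand$status, "ok")
  expect_equal(cand$pam_cds_offset, 150L)
})

test_that("design report TSV serialises and reads back", {
  g <- generate_genome(simulation_spec(seed = 31, n_genes = 8,
                                       plant_pam_fraction = 0.75))
  rep <- design_genome(g)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_design_report(rep, tf)
  tab <- read.delim(tf, stringsAsFactors = FALSE)
  expect_setequal(tab$locus_tag, g$features$locus_tag)
  expect_setequal(unique(tab$status), c("ok", "untargetable"))
  rt <- read_design_report(tf)
  expect_equal(sort(rt$guides$locus_tag), sort(rep$guides$locus_tag))
})
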