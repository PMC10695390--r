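test_that("construct arms are exact genomic slices around the midpoint", {
  g <- generate_genome(simulation_spec(seed = 61, n_genes = 10))
  con <- design_construct(g, "SYN_004", seed = 5)
  m <- con$insertion_point
  expect_identical(con$upstream_arm, substr(g$sequence, m - 99, m))
  expect_identical(con$downstream_arm, substr(g$sequence, m + 1, m + 100))
  expect_equal(nchar(con$upstream_arm), 100L)
  expect_equal(nchar(con$downstream_arm), 100L)
  expect_equal(nchar(con$barcode), 20L)
  expect_identical(con$full_sequence,
                   paste0(con$upstream_arm, con$left_flank, con$barcode,
                          con$right_flank, con$downstream_arm))
  # coordinate insertion point and determinism
  con2 <- design_construct(g, 500, seed = 5)
  expect_equal(con2$insertion_point, 500L)
  expect_identical(con$barcode, con2$barcode)  # same seed, same draw
  con3 <- design_construct(g, "SYN_004", seed = 6)
  expect_false(identical(con$barcode, con3$barcode))
})

test_that("construct design warns at essential loci and checks flanks", {
  g <- generate_genome(simulation_spec(seed = 61, n_genes = 10))
  expect_warning(design_construct(g, "SYN_004", seed = 1,
                                  calls = c(SYN_004 = "E")), "essential")
  expect_error(design_construct(g, 20, seed = 1), "flank")
})

test_that("generated barcode sets satisfy composition and distance filters", {
  bcs <- generate_barcodes(25, seed = 71)
  expect_equal(length(bcs), 25L)
  expect_true(all(nchar(bcs) == 20L))
  gc <- vapply(strsplit(bcs, ""), function(ch)
    mean(ch %in% c("G", "C")), numeric(1))
  expect_true(all(gc >= 0.25 & gc <= 0.75))
  expect_false(any(grepl("A{5}|C{5}|G{5}|T{5}", bcs)))
  dist <- outer(bcs, bcs, Vectorize(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])))
  expect_true(all(dist[upper.tri(dist)] >= 3L))
  expect_identical(bcs, generate_barcodes(25, seed = 71))
})

test_that("counterselection guides span the junction and miss recombinants", {
  # plant a PAM 10 nt upstream of the insertion point on an A/C/G
  # background so the spanning spacer is unique
  set.seed(410)
  backbone <- paste(sample(c("A", "C", "G"), 600, replace = TRUE),
                    collapse = "")
  m <- 300L
  seq <- paste0(substr(backbone, 1, m - 11), "TTTA",
                substr(backbone, m - 7, 600))
  g <- genome("t", seq, gene_feature("g1", 50, 550, "+"))
  con <- design_construct(g, m, seed = 3)
  guide <- design_counterselection_guide(g, con)
  expect_equal(guide$status, "ok")
  # the protospacer occurs in wild type and not in the recombinant
  rec <- recombinant_sequence(g, con)
  expect_gte(length(match_iupac(guide$spacer, g$sequence)) +
               length(match_iupac(reverse_complement(guide$spacer),
                                  g$sequence)), 1L)
  expect_equal(length(match_iupac(guide$spacer, rec)) +
                 length(match_iupac(reverse_complement(guide$spacer), rec)),
               0L)
  # the spacer genuinely covers both sides of the junction
  wt_hit <- match_iupac(guide$spacer, g$sequence)
  if (length(wt_hit)) {
    expect_lte(wt_hit[1], m)
    expect_gte(wt_hit[1] + 27L, m + 1L)
  }
})

test_that("junctions with no nearby PAM raise an informative error", {
  # A/C-only neighbourhood: no TTTV on either strand near the junction
  seq <- paste(rep("AC", 400), collapse = "")
  g <- genome("t", seq, NULL)
  con <- design_construct(g, 400, seed = 1)
  expect_error(design_counterselection_guide(g, con), "junction|no PAM")
})

test_that("barcode counting assigns perfect reads and rejects bad flanks", {
  bcs <- generate_barcodes(2, seed = 81)
  reads <- simulate_barcode_reads(bcs[1], 1, 100, seed = 82)
  ct <- count_barcodes(reads, expected = bcs)
  expect_equal(unname(ct$counts[bcs[1]]), 100L)
  expect_equal(unname(ct$fraction[bcs[1]]), 1.0)
  expect_equal(ct$unassigned, 0L)

  # two mismatches inside the left flank exceed the budget of one
  lf <- phagemap:::DEFAULT_LEFT_FLANK
  lf_bad <- paste0("GG", substr(lf, 3, nchar(lf)))
  stopifnot(substr(lf, 1, 2) != "GG")
  bad_read <- paste0("ACGTA", lf_bad, bcs[1],
                     phagemap:::DEFAULT_RIGHT_FLANK, "ACGTA")
  ct_bad <- count_barcodes(bad_read, expected = bcs,
                           max_flank_mismatches = 1)
  expect_equal(ct_bad$assigned, 0L)
  expect_equal(ct_bad$unassigned, 1L)
  # one mismatch is tolerated
  lf_one <- paste0("G", substr(lf, 2, nchar(lf)))
  one_read <- paste0("ACGTA", lf_one, bcs[1],
                     phagemap:::DEFAULT_RIGHT_FLANK, "ACGTA")
  expect_equal(count_barcodes(one_read, expected = bcs)$assigned, 1L)
})

test_that("counting conserves reads and ignores read order", {
  bcs <- generate_barcodes(3, seed = 83)
  reads <- as.character(simulate_barcode_reads(bcs, c(5, 3, 2), 500,
                                               seed = 84))
  junk <- replicate(25, random_seq(60))
  all_reads <- c(reads, junk)
  ct <- count_barcodes(all_reads, expected = bcs)
  expect_equal(ct$assigned + ct$unassigned, ct$total)
  expect_equal(ct$total, 525L)
  expect_equal(sum(ct$fraction), 1.0)
  perm <- sample(all_reads)
  ct2 <- count_barcodes(perm, expected = bcs)
  expect_identical(ct$counts, ct2$counts)
})

test_that("discover mode tallies distinct extracted 20-mers", {
  bcs <- generate_barcodes(2, seed = 85)
  reads <- simulate_barcode_reads(bcs, c(1, 1), 200, seed = 86)
  ct <- count_barcodes(reads, expected = NULL)
  expect_setequal(names(ct$counts), bcs)
  expect_equal(sum(ct$counts), 200L)
})

test_that("design + in-silico recombination + counting recovers the barcode", {
  g <- generate_genome(simulation_spec(seed = 87, n_genes = 12))
  con <- design_construct(g, "SYN_007", seed = 88)
  rec <- recombinant_sequence(g, con)
  expect_equal(nchar(rec),
               genome_length(g) + 20L + nchar(con$left_flank) +
                 nchar(con$right_flank))
  # amplicon reads straddling the cassette
  cassette_at <- con$insertion_point + 1L - 10L
  amplicon <- substr(rec, cassette_at,
                     cassette_at + 19L + 20L +
                       nchar(con$left_flank) + nchar(con$right_flank))
  ct <- count_barcodes(rep(amplicon, 50), expected = NULL)
  expect_identical(names(ct$counts), con$barcode)
  expect_equal(unname(ct$counts), 50L)
})

test_that("FASTQ round trip through the simulator and counter", {
  bcs <- generate_barcodes(2, seed = 91)
  tf <- withr::local_tempfile(fileext = ".fastq")
  simulate_barcode_reads(bcs, c(0.7, 0.3), 300, seed = 92, path = tf)
  ct <- count_barcodes(tf, expected = bcs)
  expect_equal(ct$total, 300L)
  expect_equal(ct$assigned, 300L)
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("this is", "not a fastq record"), bad)
  expect_error(count_barcodes(bad, expected = bcs), "unreadable FASTQ")
})
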