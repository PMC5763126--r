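test_that("ORF length maps to protein length under the stop-inclusive convention", {
  expect_equal(protein_length_from_orf(615), 204L)
  expect_equal(protein_length_from_orf(501), 166L)
  expect_equal(protein_length_from_orf(6), 1L)
  expect_error(protein_length_from_orf(616), "divisible")
  expect_error(protein_length_from_orf(3), "shorter")
})

test_that("translate_orf enforces start, stop and frame", {
  expect_equal(translate_orf("ATGAAATAA"), "MK")
  expect_equal(translate_orf("ATGTAA"), "M")
  expect_error(translate_orf("ATGTAATAA"), "internal stop at codon 2")
  expect_error(translate_orf("AAAAAATAA"), "begin with ATG")
  expect_error(translate_orf("ATGAAAAAA"), "stop codon")
  expect_error(translate_orf("ATGAANTAA"), "ambiguous base in codon 2")
  expect_error(translate_orf("ATGAATAA"), "divisible")
})

test_that("molecular weight uses average residue masses plus one water", {
  expect_equal(molecular_weight("G"), 75.0672, tolerance = 1e-6)
  expect_equal(molecular_weight("GG"), 2 * 57.0519 + 18.0153, tolerance = 1e-6)
  expect_error(molecular_weight("AB"), "non-standard residue 'B' at position 2")
  expect_error(molecular_weight(""), "empty")
  # strictly increasing under residue appending, always above water
  set.seed(3)
  s <- ""
  for (i in 1:15) {
    s2 <- paste0(s, sample(names(sodkit:::RESIDUE_MASS_AVG), 1))
    if (nzchar(s)) expect_gt(molecular_weight(s2), molecular_weight(s))
    expect_gt(molecular_weight(s2), 18.02)
    s <- s2
  }
})

test_that("poly-A signals are found 1-based, ascending, overlaps included", {
  set.seed(5)
  tx <- random_dna(900, letters = c("C", "G", "T"))  # no accidental AATAAA
  substr(tx, 879, 884) <- "AATAAA"
  expect_equal(find_polya_signals(tx, 800), 879L)

  tx2 <- random_dna(900, letters = c("C", "G", "T"))
  substr(tx2, 825, 830) <- "AATAAA"
  substr(tx2, 851, 856) <- "AATAAA"
  expect_equal(find_polya_signals(tx2, 700), c(825L, 851L))

  expect_equal(find_polya_signals("AATAATAAA", 1), 4L)
  expect_equal(find_polya_signals("AATAAATAAA", 1), c(1L, 5L))  # overlap chain
  expect_equal(find_polya_signals("CCCCCCCC", 1), integer(0))
})

test_that("architecture summary recovers a constructed two-exon 5'UTR-intron gene", {
  # layout: 100 pad | exon1 = 60 nt UTR | intron 40 | exon2 = 40 UTR + ORF 30 + UTR3 50
  set.seed(21)
  utr5a <- random_dna(60, c("C", "G"))
  intron <- random_dna(40)
  utr5b <- random_dna(40, c("C", "G"))
  orf <- "ATGAAACCCGGGTTTAAACCCGGGTTTTAA"  # 30 nt
  utr3 <- paste0(random_dna(20, c("C", "G")), "AATAAA", random_dna(24, c("C", "G")))
  genome <- tibble::tibble(
    id = "c1",
    seq = paste0(random_dna(100), utr5a, intron, utr5b, orf, utr3)
  )
  genes <- tibble::tibble(
    gene_id = "g", seq_id = "c1", strand = "+",
    exons = list(tibble::tibble(start = c(100L, 200L), end = c(160L, 320L))),
    cds_start = 240L, cds_end = 270L
  )
  a <- summarize_architecture(genes, genome)
  expect_equal(a$n_exons, 2L)
  expect_equal(a$n_introns, 1L)
  expect_equal(a$utr_introns[[1]], "5'")
  expect_equal(a$orf_nt, 30L)
  expect_equal(a$protein_aa, 9L)
  expect_equal(a$utr5_nt, 100L)
  expect_equal(a$utr3_nt, 50L)
  expect_equal(a$polya_positions[[1]], 151L)
  expect_equal(a$flags, "")
  expect_equal(a$protein_aa, nchar(translate_orf(orf)))
  # length conservation
  expect_equal(a$utr5_nt + a$orf_nt + a$utr3_nt, a$transcript_nt)
})

test_that("single-exon gene with CDS spanning the whole exon has empty UTRs", {
  genome <- tibble::tibble(id = "c1", seq = paste0(random_dna(50), "ATGAAATAA", random_dna(10)))
  genes <- tibble::tibble(
    gene_id = "g", seq_id = "c1", strand = "+",
    exons = list(tibble::tibble(start = 50L, end = 59L)),
    cds_start = 50L, cds_end = 59L
  )
  a <- summarize_architecture(genes, genome)
  expect_equal(a$utr5_nt, 0L)
  expect_equal(a$utr3_nt, 0L)
  expect_equal(a$n_introns, 0L)
})

test_that("five-exon synthetic locus reports four introns and exact truth", {
  plan <- sod_locus_plans()$sodb1
  loc <- generate_locus(123, gene_id = plan$gene_id, seq_id = plan$seq_id,
                        strand = plan$strand,
                        architecture_plan = plan$architecture_plan,
                        motif_plan = plan$motif_plan)
  a <- summarize_architecture(loc$genes, loc$genome)
  tr <- loc$truth
  expect_equal(a$n_exons, 5L)
  expect_equal(a$n_introns, 4L)
  expect_equal(a$orf_nt, tr$orf_nt)
  expect_equal(a$protein_aa, 204L)
  expect_equal(a$utr5_nt, tr$utr5_nt)
  expect_equal(a$utr3_nt, tr$utr3_nt)
  expect_equal(a$polya_positions[[1]], tr$polya_positions)
  expect_equal(a$flags, "")
})

test_that("minus-strand synthetic loci yield identical architecture truth", {
  plan <- sod_locus_plans()$sodb2   # minus strand, 3 exons
  loc <- generate_locus(77, gene_id = plan$gene_id, seq_id = plan$seq_id,
                        strand = plan$strand,
                        architecture_plan = plan$architecture_plan,
                        motif_plan = plan$motif_plan)
  a <- summarize_architecture(loc$genes, loc$genome)
  expect_equal(a$orf_nt, 501L)
  expect_equal(a$protein_aa, 166L)
  expect_equal(a$utr5_nt, 180L)
  expect_equal(a$utr3_nt, 59L)
  expect_equal(a$n_exons, 3L)
  expect_equal(a$utr_introns[[1]], "5'")
  expect_equal(a$polya_positions[[1]], 721L)
  expect_equal(a$flags, "")
})

test_that("annotated protein lengths that contradict the ORF are flagged, not errors", {
  plan <- sod_locus_plans()$soda   # annotation says 155 aa, ORF arithmetic 153
  loc <- generate_locus(9, gene_id = plan$gene_id, seq_id = plan$seq_id,
                        strand = plan$strand,
                        architecture_plan = plan$architecture_plan,
                        motif_plan = plan$motif_plan)
  a <- summarize_architecture(loc$genes, loc$genome)
  expect_equal(a$protein_aa, 153L)
  expect_match(a$flags, "length_discrepancy")
})
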