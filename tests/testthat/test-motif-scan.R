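test_that("compile_motif follows the IUPAC code and rejects bad patterns", {
  xre <- compile_motif("XRE", "TGCRCNC")
  # position 4 allows {A,G} (R), position 6 allows all four (N)
  expect_true(all(vapply(c("TGCACAC", "TGCGCTC"), function(s) {
    nrow(scan_sequence(s, xre, "+")) == 1L
  }, logical(1))))
  expect_equal(nrow(scan_sequence("TGCCCAC", xre, "+")), 0L)

  exact <- compile_motif("x", "ACGT")
  expect_equal(scan_sequence("AACGTA", exact, "+")$start, 1L)

  expect_error(compile_motif("bad", "ACJT"), "position 3")
  expect_error(compile_motif("bad", ""), "empty")
})

test_that("scan_sequence reports strand-aware, overlapping hits", {
  are <- compile_motif("ARE", "TGACNNNGC")
  h <- scan_sequence("TGACAAAGC", are, "+")
  expect_equal(h$start, 0L)
  expect_equal(h$matched_seq, "TGACAAAGC")

  h2 <- scan_sequence("GCTTTGTCA", are, "-")
  expect_equal(h2$start, 0L)
  expect_equal(h2$strand, "-")

  hare <- compile_motif("hARE", "TGACNNN")
  h3 <- scan_sequence("TGACTGACAAA", hare, "+")
  expect_equal(h3$start, c(0L, 4L))

  # shorter window than pattern: empty result, not an error
  expect_equal(nrow(scan_sequence("TGA", hare)), 0L)
  expect_error(scan_sequence("TGACJAA", hare), "invalid character")
})

test_that("subject ambiguity uses subset semantics (N matches only pattern N)", {
  hare <- compile_motif("hARE", "TGACNNN")
  expect_equal(nrow(scan_sequence("TGACNNN", hare, "+")), 1L)
  exact <- compile_motif("x", "TGACAAA")
  expect_equal(nrow(scan_sequence("TGACNNN", exact, "+")), 0L)
  expect_equal(nrow(scan_sequence("TGACRAA", exact, "+")), 0L)
})

test_that("scanner equals the set-based oracle on random windows and patterns", {
  set.seed(2024)
  for (i in 1:150) {
    L <- sample(20:400, 1)
    win <- random_dna(L, letters = c(rep(c("A", "C", "G", "T"), 10), "N", "R"))
    m <- sample(4:9, 1)
    pat <- random_dna(m, letters = c(rep(c("A", "C", "G", "T"), 3),
                                     "N", "R", "Y", "S", "W"))
    if (runif(1) < 0.5) {  # plant an instance to guarantee hits
      inst <- strsplit(pat, "")[[1]]
      inst <- vapply(inst, function(ch) sample(ORACLE_SETS[[ch]], 1), character(1))
      p0 <- sample(L - m + 1, 1)
      substr(win, p0, p0 + m - 1) <- paste(inst, collapse = "")
    }
    got <- scan_sequence(win, compile_motif("m", pat))
    want <- oracle_scan(win, pat)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  set.seed(7)
  hare <- compile_motif("hARE", "TGACNNN")
  for (i in 1:20) {
    win <- random_dna(200)
    fwd <- scan_sequence(win, hare)
    rev <- scan_sequence(revcomp(win), hare)
    expect_equal(sort(fwd$matched_seq), sort(revcomp(rev$matched_seq)))
    # mirrored offsets, strands swapped
    expect_setequal(
      paste(200 - (fwd$start + fwd$length), chartr("+-", "-+", fwd$strand)),
      paste(rev$start, rev$strand)
    )
  }
})

test_that("appending bases never removes hits and keeps offsets stable", {
  set.seed(8)
  hare <- compile_motif("hARE", "TGACNNN")
  win <- paste0("TGACGGG", random_dna(100))
  base <- scan_sequence(win, hare)
  for (i in 1:10) {
    win <- paste0(win, random_dna(17))
    grown <- scan_sequence(win, hare)
    expect_true(all(paste(base$start, base$strand) %in%
                      paste(grown$start, grown$strand)))
    base <- grown
  }
})

test_that("extract_upstream honours strand, orientation and truncation", {
  genome <- tibble::tibble(id = "c1", seq = random_dna(3000))
  plus <- tibble::tibble(
    gene_id = "gp", seq_id = "c1", strand = "+",
    exons = list(tibble::tibble(start = 900L, end = 2000L)),
    cds_start = 1000L, cds_end = 1900L
  )
  w <- extract_upstream(plus, genome, 1000L)
  expect_equal(w$seq, substr(genome$seq, 1, 1000))
  expect_false(w$truncated)

  minus <- tibble::tibble(
    gene_id = "gm", seq_id = "c1", strand = "-",
    exons = list(tibble::tibble(start = 500L, end = 1500L)),
    cds_start = 600L, cds_end = 1400L
  )
  wm <- extract_upstream(minus, genome, 800L)
  expect_equal(wm$seq, revcomp(substr(genome$seq, 1401, 2200)))

  near_edge <- tibble::tibble(
    gene_id = "ge", seq_id = "c1", strand = "+",
    exons = list(tibble::tibble(start = 400L, end = 900L)),
    cds_start = 500L, cds_end = 800L
  )
  expect_warning(we <- extract_upstream(near_edge, genome, 2000L), "truncated")
  expect_equal(we$width, 500L)

  bad <- dplyr::mutate(plus, seq_id = "nope")
  expect_error(extract_upstream(bad, genome), "scaffold")
})

test_that("a minus-strand promoter equals the plus-strand one on the mirrored gene", {
  set.seed(99)
  genome_fwd <- random_dna(2000)
  plus <- tibble::tibble(
    gene_id = "g", seq_id = "c", strand = "+",
    exons = list(tibble::tibble(start = 1200L, end = 1800L)),
    cds_start = 1300L, cds_end = 1700L
  )
  w_plus <- extract_upstream(plus, tibble::tibble(id = "c", seq = genome_fwd), 600L)
  minus <- tibble::tibble(
    gene_id = "g", seq_id = "c", strand = "-",
    exons = list(tibble::tibble(start = 2000L - 1800L, end = 2000L - 1200L)),
    cds_start = 2000L - 1700L, cds_end = 2000L - 1300L
  )
  w_minus <- extract_upstream(minus, tibble::tibble(id = "c", seq = revcomp(genome_fwd)), 600L)
  expect_equal(w_minus$seq, w_plus$seq)
})

test_that("count table matches a brute-force enumeration and mirrors the layout", {
  set.seed(31)
  genome <- tibble::tibble(
    id = c("c1", "c2"),
    seq = c(random_dna(1500), random_dna(1500))
  )
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), seq_id = c("c1", "c2"), strand = c("+", "-"),
    exons = list(tibble::tibble(start = 1100L, end = 1400L),
                 tibble::tibble(start = 100L, end = 400L)),
    cds_start = c(1150L, 150L), cds_end = c(1350L, 350L)
  )
  motifs <- default_motifs()
  tab <- build_count_table(genes, genome, motifs, window_nt = 1000L)
  expect_equal(names(tab), c("gene_id", "ARE 5'-3'", "ARE 3'-5'",
                             "hARE 5'-3'", "hARE 3'-5'",
                             "XRE 5'-3'", "XRE 3'-5'"))
  wins <- extract_upstream(genes, genome, 1000L)
  for (g in 1:2) {
    for (m in 1:3) {
      oh <- oracle_scan(wins$seq[g], motifs$pattern[m])
      expect_equal(tab[[paste(motifs$name[m], "5'-3'")]][g], sum(oh$strand == "+"))
      expect_equal(tab[[paste(motifs$name[m], "3'-5'")]][g], sum(oh$strand == "-"))
    }
  }
})

test_that("an all-A promoter yields an all-zero count row", {
  genome <- tibble::tibble(id = "c1", seq = strrep("A", 1200))
  genes <- tibble::tibble(
    gene_id = "g", seq_id = "c1", strand = "+",
    exons = list(tibble::tibble(start = 1000L, end = 1199L)),
    cds_start = 1000L, cds_end = 1199L
  )
  tab <- build_count_table(genes, genome, window_nt = 1000L)
  expect_true(all(tab[1, -1] == 0))
})

test_that("motif TSV config round-trips and rejects bad definitions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(default_motifs(), f)
  expect_equal(read_motifs(f), default_motifs())
  writeLines("name\tpattern\nbad\tAXC", f)
  expect_error(read_motifs(f), "invalid character")
})
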