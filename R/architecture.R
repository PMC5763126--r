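# Average (not monoisotopic) residue masses in Da, matching the usual
# "deduced molecular weight" convention for conceptual translations.
RESIDUE_MASS_AVG <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS_AVG <- 18.0153

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Protein length implied by an ORF length
#'
#' Uses the convention that the open reading frame includes the stop codon,
#' so a protein of `n` residues corresponds to an ORF of `3 * (n + 1)` nt.
#'
#' @param orf_nt ORF length(s) in nucleotides; each must be a multiple of 3
#'   and at least 6 (start plus stop codon).
#' @return Integer vector of amino-acid counts, `orf_nt / 3 - 1`.
#' @examples
#' protein_length_from_orf(615)  # 204
#' protein_length_from_orf(501)  # 166
#' @export
protein_length_from_orf <- function(orf_nt) {
  stopifnot(is.numeric(orf_nt))
  if (any(orf_nt %% 3 != 0)) {
    stop("ORF length not divisible by 3: ",
         paste(orf_nt[orf_nt %% 3 != 0], collapse = ", "), call. = FALSE)
  }
  if (any(orf_nt < 6)) stop("ORF shorter than start + stop codon", call. = FALSE)
  as.integer(orf_nt / 3 - 1)
}

#' Translate an ORF to protein (standard genetic code)
#'
#' Requires a canonical ORF: length divisible by 3, `ATG` start, a standard
#' stop codon (`TAA`/`TAG`/`TGA`) at the end and no internal stop codon.
#' Ambiguity letters inside a codon are rejected.
#'
#' @param orf_seq DNA string of the ORF, stop codon included.
#' @return One-letter protein string of length `nchar(orf_seq)/3 - 1`
#'   (the stop codon is not represented).
#' @examples
#' translate_orf("ATGAAATAA")  # "MK"
#' @export
translate_orf <- function(orf_seq) {
  orf_seq <- validate_dna(orf_seq, id = "ORF")
  n <- nchar(orf_seq)
  if (n %% 3 != 0) stop("ORF length ", n, " not divisible by 3", call. = FALSE)
  if (n < 6) stop("ORF shorter than start + stop codon", call. = FALSE)
  codons <- substring(orf_seq, seq(1, n, 3), seq(3, n, 3))
  if (codons[1] != "ATG") stop("ORF does not begin with ATG", call. = FALSE)
  amb <- grepl("[^ACGT]", codons)
  if (any(amb)) {
    stop("ambiguous base in codon ", which(amb)[1], " ('", codons[which(amb)[1]],
         "')", call. = FALSE)
  }
  k <- length(codons)
  if (!(codons[k] %in% STOP_CODONS)) {
    stop("ORF does not end with a stop codon", call. = FALSE)
  }
  aa <- unname(Biostrings::GENETIC_CODE[codons[-k]])
  internal_stop <- which(aa == "*")
  if (length(internal_stop) > 0L) {
    stop("internal stop at codon ", internal_stop[1], call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param protein One-letter protein string (20 standard residues).
#' @return Mass in daltons.
#' @examples
#' molecular_weight("G")  # 75.0672
#' @export
molecular_weight <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  res <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  bad <- which(!(res %in% names(RESIDUE_MASS_AVG)))
  if (length(bad) > 0L) {
    stop("non-standard residue '", res[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  sum(RESIDUE_MASS_AVG[res]) + WATER_MASS_AVG
}

#' Find polyadenylation signals in the 3' UTR of a mature transcript
#'
#' Reports the 1-based start position on the mature transcript of every
#' occurrence of the signal (default the canonical `AATAAA`) at or after
#' `utr3_start`, ascending; overlapping occurrences are all reported.
#'
#' @param transcript Mature transcript DNA string.
#' @param utr3_start 1-based position where the 3' UTR begins.
#' @param signal Signal hexamer to search (config knob; e.g. `"ATTAAA"`).
#' @return Integer vector of 1-based positions (possibly empty).
#' @export
find_polya_signals <- function(transcript, utr3_start, signal = "AATAAA") {
  transcript <- validate_dna(transcript, id = "transcript")
  stopifnot(utr3_start >= 1, utr3_start <= nchar(transcript))
  m <- nchar(signal)
  starts <- seq_len(nchar(transcript) - m + 1L)
  starts <- starts[starts >= utr3_start]
  if (length(starts) == 0L) return(integer(0))
  hits <- starts[substring(transcript, starts, starts + m - 1L) == signal]
  as.integer(hits)
}

# Transcript coordinate (0-based) of a genomic coordinate g lying in the
# exon union, on the plus-strand spliced transcript.
.tx_pos <- function(exons, g) {
  off <- 0L
  for (j in seq_len(nrow(exons))) {
    if (g >= exons$start[j] && g <= exons$end[j]) {
      return(off + (g - exons$start[j]))
    }
    off <- off + (exons$end[j] - exons$start[j])
  }
  NA_integer_
}

#' Summarise the architecture of annotated genes
#'
#' For each gene model, splices the exons into the mature transcript,
#' locates the coding sequence on it and derives the descriptive layout:
#' ORF and protein length, deduced average molecular weight, UTR lengths,
#' exon/intron counts, classification of each intron as lying in the
#' 5' UTR, the CDS, or the 3' UTR, and polyadenylation-signal positions.
#' A gene whose spliced CDS is not a canonical ORF is reported with a flag
#' (`invalid_orf`) rather than an error; if the input carries an
#' `annotated_protein_aa` column, any disagreement with the computed
#' protein length is flagged `length_discrepancy`.
#'
#' @param genes Gene-model tibble ([read_gene_models()]); may carry an
#'   optional `annotated_protein_aa` column.
#' @param genomes Sequence tibble ([read_fasta()]).
#' @param polya_signal Poly-A signal to search for in the 3' UTR.
#' @return A tibble with one row per gene: `gene_id`, `transcript_nt`,
#'   `orf_nt`, `protein_aa`, `mw_kda`, `utr5_nt`, `utr3_nt`, `n_exons`,
#'   `n_introns`, `utr_introns` (list of `"5'"`/`"3'"` labels),
#'   `polya_positions` (list of 1-based mature-transcript positions),
#'   `flags` (comma-separated, empty when clean).
#' @export
summarize_architecture <- function(genes, genomes, polya_signal = "AATAAA") {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    hit <- which(genomes$id == g$seq_id)
    if (length(hit) == 0L) {
      stop("scaffold '", g$seq_id, "' not found for gene '", g$gene_id, "'",
           call. = FALSE)
    }
    chrom <- genomes$seq[hit[1]]
    ex <- g$exons[[1]]
    flags <- character(0)

    plus_tx <- paste(substring(chrom, ex$start + 1L, ex$end), collapse = "")
    tx_len <- nchar(plus_tx)

    cds_lo <- .tx_pos(ex, g$cds_start)
    cds_hi <- .tx_pos(ex, g$cds_end)   # end is half-open; exon ends admit it
    if (is.na(cds_lo) || is.na(cds_hi)) {
      stop("CDS of gene '", g$gene_id, "' is not inside the exon union",
           call. = FALSE)
    }
    orf_nt <- sum(pmax(0L, pmin(ex$end, g$cds_end) - pmax(ex$start, g$cds_start)))

    if (g$strand == "+") {
      transcript <- plus_tx
      utr5 <- cds_lo
    } else {
      transcript <- revcomp(plus_tx)
      utr5 <- tx_len - cds_hi
    }
    utr3 <- tx_len - utr5 - orf_nt

    protein_aa <- if (orf_nt %% 3 == 0 && orf_nt >= 6) {
      as.integer(orf_nt / 3 - 1)
    } else {
      flags <- c(flags, "orf_not_multiple_of_3")
      NA_integer_
    }

    orf_seq <- substr(transcript, utr5 + 1L, utr5 + orf_nt)
    mw_kda <- NA_real_
    prot <- tryCatch(translate_orf(orf_seq), error = function(e) e)
    if (inherits(prot, "error")) {
      flags <- c(flags, "invalid_orf")
    } else {
      mw_kda <- molecular_weight(prot) / 1000
    }

    if ("annotated_protein_aa" %in% names(genes) &&
        !is.na(g$annotated_protein_aa) && !is.na(protein_aa) &&
        g$annotated_protein_aa != protein_aa) {
      flags <- c(flags, "length_discrepancy")
    }

    # classify introns by genomic position relative to the CDS span
    n_ex <- nrow(ex)
    intron_class <- character(0)
    if (n_ex > 1L) {
      for (j in seq_len(n_ex - 1L)) {
        lo <- ex$end[j]; hi <- ex$start[j + 1L]
        cls <- if (hi <= g$cds_start) "5'" else if (lo >= g$cds_end) "3'" else "CDS"
        if (g$strand == "-" && cls != "CDS") cls <- if (cls == "5'") "3'" else "5'"
        intron_class <- c(intron_class, cls)
      }
    }

    polya <- find_polya_signals(transcript,
                                utr3_start = min(utr5 + orf_nt + 1L, tx_len),
                                signal = polya_signal)

    tibble::tibble(
      gene_id = g$gene_id,
      transcript_nt = tx_len,
      orf_nt = as.integer(orf_nt),
      protein_aa = protein_aa,
      mw_kda = mw_kda,
      utr5_nt = as.integer(utr5),
      utr3_nt = as.integer(utr3),
      n_exons = n_ex,
      n_introns = n_ex - 1L,
      utr_introns = list(intron_class[intron_class != "CDS"]),
      polya_positions = list(polya),
      flags = paste(flags, collapse = ",")
    )
  })
}

#' Flatten an architecture table for TSV export
#'
#' List columns are collapsed into comma-separated strings so the table
#' can be written as plain TSV.
#'
#' @param arch Output of [summarize_architecture()].
#' @return A tibble with only atomic columns.
#' @export
flatten_architecture <- function(arch) {
  dplyr::mutate(
    arch,
    utr_introns = purrr::map_chr(.data$utr_introns, paste, collapse = ","),
    polya_positions = purrr::map_chr(.data$polya_positions, paste, collapse = ",")
  )
}
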