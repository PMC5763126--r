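# --- independent naive scanner -----------------------------------------
# The ground-truth ledger is always produced by this position-by-position
# set-based matcher, never by assuming a planting plan succeeded. It shares
# no code with the production bitmask scanner.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T")
)

# 0-based offsets where `pattern` matches `chars` (character vector) under
# subset semantics, checked one position at a time.
naive_match_offsets <- function(chars, pattern) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- length(pat)
  L <- length(chars)
  if (L < m) return(integer(0))
  hits <- integer(0)
  for (off in 0:(L - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      subj <- IUPAC_SETS[[chars[off + j]]]
      if (!all(subj %in% IUPAC_SETS[[pat[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# Per-motif, per-strand hit counts of a window, by the naive matcher.
naive_scan_counts <- function(window, motifs) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    tibble::tibble(
      motif_name = motifs$name[i],
      strand = c("+", "-"),
      n = c(
        length(naive_match_offsets(chars, motifs$pattern[i])),
        length(naive_match_offsets(chars, revcomp(motifs$pattern[i])))
      )
    )
  })
}

# --- small generation helpers ------------------------------------------

random_dna_chars <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

random_orf_chars <- function(orf_nt) {
  stopifnot(orf_nt %% 3 == 0, orf_nt >= 6)
  n_mid <- orf_nt / 3 - 2
  mid <- if (n_mid > 0) sample(SENSE_CODONS, n_mid, replace = TRUE) else character(0)
  strsplit(paste(c("ATG", mid, "TAA"), collapse = ""), "", fixed = TRUE)[[1]]
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a label.
split_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h * 97 + 1) %% 2147483629)
}

# Instantiate a degenerate pattern as a concrete ACGT string.
instantiate_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

# Mutate one base inside each unwanted hit (avoiding protected positions)
# until the naive scanner finds no match outside the protected intervals.
mask_accidental <- function(chars, motifs, protected, max_iter = 200L) {
  in_protected <- function(off, len) {
    if (nrow(protected) == 0L) return(FALSE)
    any(protected$start == off & protected$len == len & protected$exact)
  }
  covered <- rep(FALSE, length(chars))
  if (nrow(protected) > 0L) {
    for (r in seq_len(nrow(protected))) {
      covered[(protected$start[r] + 1L):(protected$start[r] + protected$len[r])] <- TRUE
    }
  }
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (i in seq_len(nrow(motifs))) {
      for (pat in c(motifs$pattern[i], revcomp(motifs$pattern[i]))) {
        m <- nchar(pat)
        for (off in naive_match_offsets(chars, pat)) {
          if (in_protected(off, m)) next
          pos <- ((off + 1L):(off + m))
          free <- pos[!covered[pos]]
          if (length(free) == 0L) next  # fully inside planted material; keep
          p <- free[sample.int(length(free), 1L)]
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
          dirty <- TRUE
        }
      }
    }
    if (!dirty) return(chars)
  }
  chars
}

# --- locus generator ----------------------------------------------------

#' Generate a synthetic gene locus with planted promoter motifs
#'
#' Builds a genomic scaffold holding one gene with a prescribed
#' architecture (UTR lengths, ORF length, intron layout, polyadenylation
#' signals) and a promoter window immediately upstream of the start codon
#' carrying a prescribed number of motif occurrences per orientation.
#' The window background is uniform ACGT with accidental motif matches
#' removed by single-base substitution; concrete motif instances are then
#' planted at non-overlapping random positions. The emitted ground truth
#' is re-derived by an independent naive scanner over the final sequence
#' (and a plain substring scan for poly-A signals), so it is exact even if
#' planting interacts with the background; if the planted counts cannot be
#' made to equal the plan after `max_attempts` re-draws, the scanned
#' counts are reported as the truth.
#'
#' @param seed Integer seed; the generator is a pure function of
#'   (seed, plans).
#' @param gene_id,seq_id Identifiers for the gene and its scaffold.
#' @param strand `"+"` or `"-"`; a minus-strand locus is the reverse
#'   complement of the corresponding plus-strand construction.
#' @param architecture_plan List with `utr5_nt`, `orf_nt` (multiple of 3),
#'   `utr3_nt`, `polya_at` (1-based mature-transcript positions of planted
#'   `AATAAA` signals), and `introns`, a tibble with `after_tx_nt`
#'   (mature-transcript coordinate after which the intron is inserted) and
#'   `length`.
#' @param motif_plan Tibble with `name`, `fwd`, `rev` target counts; names
#'   must appear in `motifs`.
#' @param motifs Motif definition tibble (default [default_motifs()]).
#' @param window_nt Length of the planted promoter window upstream of the
#'   start codon.
#' @param max_attempts Re-draws allowed to hit the planted counts exactly.
#' @return A list: `genome` (one-row sequence tibble), `genes` (one-row
#'   gene-model tibble, with `annotated_protein_aa` if supplied in the
#'   plan), and `truth` (motif counts per orientation, architecture
#'   quantities, poly-A positions).
#' @export
generate_locus <- function(seed, gene_id, seq_id, strand = "+",
                           architecture_plan, motif_plan,
                           motifs = default_motifs(),
                           window_nt = 1000L, max_attempts = 40L) {
  ap <- architecture_plan
  stopifnot(ap$orf_nt %% 3 == 0, ap$orf_nt >= 6, strand %in% c("+", "-"))
  tx_len <- ap$utr5_nt + ap$orf_nt + ap$utr3_nt
  utr3_start <- ap$utr5_nt + ap$orf_nt + 1L
  if (length(ap$polya_at) > 0L) {
    stopifnot(all(ap$polya_at >= utr3_start), all(ap$polya_at + 5L <= tx_len))
  }
  introns <- if (!is.null(ap$introns) && nrow(ap$introns) > 0L) {
    dplyr::arrange(ap$introns, .data$after_tx_nt)
  } else {
    tibble::tibble(after_tx_nt = integer(0), length = integer(0))
  }
  stopifnot(all(introns$after_tx_nt > 0), all(introns$after_tx_nt < tx_len))
  need <- sum((nchar(motifs$pattern[match(motif_plan$name, motifs$name)])) *
                (motif_plan$fwd + motif_plan$rev))
  if (need > window_nt * 0.8) {
    stop("motif plan infeasible: planted material would fill >80% of the window",
         call. = FALSE)
  }

  withr::with_seed(split_seed(seed, paste0("locus:", gene_id)), {
    # mature transcript (5'->3' of the gene)
    tx <- c(random_dna_chars(ap$utr5_nt), random_orf_chars(ap$orf_nt),
            random_dna_chars(ap$utr3_nt))
    # scrub accidental poly-A signals from the 3' UTR, then plant
    scrub_region <- utr3_start:tx_len
    repeat {
      u3 <- paste(tx[scrub_region], collapse = "")
      occ <- naive_match_offsets(strsplit(u3, "", fixed = TRUE)[[1]], "AATAAA")
      if (length(occ) == 0L) break
      p <- scrub_region[occ[1] + sample.int(6L, 1L)]
      tx[p] <- sample(setdiff(c("A", "C", "G", "T"), tx[p]), 1L)
    }
    for (pos in ap$polya_at) {
      tx[pos:(pos + 5L)] <- strsplit("AATAAA", "", fixed = TRUE)[[1]]
    }

    # splice in introns: genomic gene body on the plus strand
    cuts <- c(0L, introns$after_tx_nt, tx_len)
    body <- character(0)
    exon_lens <- integer(0)
    intron_lens <- introns$length
    for (s in seq_len(length(cuts) - 1L)) {
      seg <- tx[(cuts[s] + 1L):cuts[s + 1L]]
      body <- c(body, seg)
      exon_lens <- c(exon_lens, length(seg))
      if (s <= nrow(introns)) body <- c(body, random_dna_chars(introns$length[s]))
    }
    pad5 <- window_nt + 100L
    pad3 <- 50L
    genome_chars <- c(random_dna_chars(pad5), body, random_dna_chars(pad3))

    # exon/CDS coordinates (0-based half-open) on the plus strand
    exon_start <- integer(0); off <- pad5
    for (s in seq_along(exon_lens)) {
      exon_start <- c(exon_start, off)
      off <- off + exon_lens[s]
      if (s <= length(intron_lens)) off <- off + intron_lens[s]
    }
    exons <- tibble::tibble(start = exon_start, end = exon_start + exon_lens)
    tx2g <- function(txpos0) {   # 0-based transcript -> 0-based genomic
      rem <- txpos0
      for (s in seq_along(exon_lens)) {
        if (rem < exon_lens[s]) return(exons$start[s] + rem)
        rem <- rem - exon_lens[s]
      }
      exons$end[length(exon_lens)]
    }
    cds_start <- tx2g(ap$utr5_nt)
    # half-open genomic end = genomic position of the last CDS base + 1
    # (keeps the end inside the containing exon even at an exon boundary)
    cds_end <- tx2g(ap$utr5_nt + ap$orf_nt - 1L) + 1L

    # --- promoter window planting ---
    win_from <- cds_start - window_nt  # 0-based
    stopifnot(win_from >= 0L)
    targets <- motif_plan |>
      dplyr::mutate(len = nchar(motifs$pattern[match(.data$name, motifs$name)])) |>
      dplyr::arrange(dplyr::desc(.data$len))  # longest (nesting) first

    ok <- FALSE
    final_win <- NULL
    for (attempt in seq_len(max_attempts)) {
      win <- random_dna_chars(window_nt)
      win <- mask_accidental(win, motifs,
                             protected = tibble::tibble(start = integer(0),
                                                        len = integer(0),
                                                        exact = logical(0)))
      occupied <- rep(FALSE, window_nt)
      planted <- tibble::tibble(start = integer(0), len = integer(0), exact = logical(0))
      feasible <- TRUE
      for (r in seq_len(nrow(targets))) {
        nm <- targets$name[r]
        pat <- motifs$pattern[motifs$name == nm]
        m <- nchar(pat)
        for (s in c("+", "-")) {
          want <- if (s == "+") targets$fwd[r] else targets$rev[r]
          have <- length(naive_match_offsets(
            win, if (s == "+") pat else revcomp(pat)))
          extra <- want - have
          if (extra < 0L) { feasible <- FALSE; break }
          while (extra > 0L) {
            free <- which(!vapply(0:(window_nt - m), function(o) {
              any(occupied[(o + 1L):(o + m)])
            }, logical(1))) - 1L
            if (length(free) == 0L) { feasible <- FALSE; break }
            o <- free[sample.int(length(free), 1L)]
            inst <- instantiate_pattern(pat)
            if (s == "-") inst <- revcomp(inst)
            win[(o + 1L):(o + m)] <- strsplit(inst, "", fixed = TRUE)[[1]]
            occupied[(o + 1L):(o + m)] <- TRUE
            planted <- dplyr::bind_rows(planted,
              tibble::tibble(start = o, len = m, exact = TRUE))
            extra <- extra - 1L
            # planting may have disturbed neighbouring background; recount
            have2 <- length(naive_match_offsets(
              win, if (s == "+") pat else revcomp(pat)))
            extra <- want - have2
          }
          if (!feasible) break
        }
        if (!feasible) break
      }
      if (!feasible) next
      counts <- naive_scan_counts(paste(win, collapse = ""), motifs)
      match_plan <- all(vapply(seq_len(nrow(motif_plan)), function(r) {
        cc <- counts[counts$motif_name == motif_plan$name[r], ]
        cc$n[cc$strand == "+"] == motif_plan$fwd[r] &&
          cc$n[cc$strand == "-"] == motif_plan$rev[r]
      }, logical(1)))
      # motifs not named in the plan must not occur at all
      others <- setdiff(motifs$name, motif_plan$name)
      clean <- all(counts$n[counts$motif_name %in% others] == 0L)
      if (match_plan && clean) { ok <- TRUE; final_win <- win; break }
    }
    if (!ok) final_win <- win  # scanned counts below make the truth exact anyway
    genome_chars[(win_from + 1L):(win_from + window_nt)] <- final_win

    genome_seq <- paste(genome_chars, collapse = "")
    L <- nchar(genome_seq)

    if (strand == "-") {
      genome_seq <- revcomp(genome_seq)
      new_exons <- tibble::tibble(start = L - rev(exons$end),
                                  end = L - rev(exons$start))
      exons <- new_exons
      tmp <- cds_start
      cds_start <- L - cds_end
      cds_end <- L - tmp
    }

    truth_counts <- naive_scan_counts(paste(final_win, collapse = ""), motifs)
    # poly-A truth by plain substring scan over the mature transcript
    tx_str <- paste(tx, collapse = "")
    pa <- integer(0)
    for (p in utr3_start:(tx_len - 5L)) {
      if (substr(tx_str, p, p + 5L) == "AATAAA") pa <- c(pa, p)
    }

    genes <- tibble::tibble(
      gene_id = gene_id, seq_id = seq_id, strand = strand,
      exons = list(exons), cds_start = cds_start, cds_end = cds_end
    )
    if (!is.null(ap$annotated_protein_aa)) {
      genes$annotated_protein_aa <- ap$annotated_protein_aa
    }
    list(
      genome = tibble::tibble(id = seq_id, seq = genome_seq),
      genes = genes,
      truth = list(
        gene_id = gene_id,
        motif_counts = truth_counts,
        orf_nt = ap$orf_nt,
        protein_aa = as.integer(ap$orf_nt / 3 - 1),
        utr5_nt = ap$utr5_nt,
        utr3_nt = ap$utr3_nt,
        transcript_nt = tx_len,
        n_exons = length(exon_lens),
        n_introns = nrow(introns),
        polya_positions = pa,
        window_nt = window_nt,
        planting_converged = ok
      )
    )
  })
}

# --- qPCR generator -----------------------------------------------------

#' Generate a synthetic qPCR Ct dataset with known fold changes
#'
#' Emulates a full-factorial priming x challenge design measured by
#' RT-qPCR against a housekeeping reference. Per treatment cell and
#' biological replicate, the reference-gene Ct is drawn
#' `Normal(ref_ct_mean, noise_sd)`; each target's Ct is
#' `ref Ct + baseline dCt - log2(fold change) + Normal(0, noise_sd)`, and
#' technical replicates add `Normal(0, noise_sd / 2)`. With zero noise the
#' 2^-ddCt pipeline recovers every planted fold change exactly.
#'
#' @param seed Integer seed.
#' @param fold_changes Tibble `priming`, `challenge`, `gene`, `fold`
#'   (> 0); the calibrator cell should have fold 1.
#' @param noise_sd Ct noise standard deviation in cycles.
#' @param n_bio,n_tech Biological and technical replicates per cell.
#' @param reference_gene Name of the housekeeping gene (fold identically 1).
#' @param ref_ct_mean Mean reference-gene Ct.
#' @param baseline_dct Baseline target-minus-reference dCt (cycles).
#' @return List with `ct` (long-format Ct tibble) and `truth`
#'   (`fold_changes` plus the noise settings).
#' @export
generate_qpcr_dataset <- function(seed, fold_changes, noise_sd = 0.2,
                                  n_bio = 3L, n_tech = 2L,
                                  reference_gene = "rp49",
                                  ref_ct_mean = 20, baseline_dct = 3) {
  stopifnot(all(fold_changes$fold > 0), noise_sd >= 0, n_bio >= 1, n_tech >= 1)
  cells <- dplyr::distinct(fold_changes, .data$priming, .data$challenge)
  genes <- unique(fold_changes$gene)
  withr::with_seed(split_seed(seed, "qpcr"), {
    rows <- list()
    for (i in seq_len(nrow(cells))) {
      for (b in seq_len(n_bio)) {
        sid <- paste(cells$priming[i], cells$challenge[i], b, sep = "_")
        ref_ct <- stats::rnorm(1, ref_ct_mean, noise_sd)
        add <- function(gene, true_ct) {
          tibble::tibble(
            sample_id = sid, priming = cells$priming[i],
            challenge = cells$challenge[i], gene = gene, bio_rep = b,
            tech_rep = seq_len(n_tech),
            ct = true_ct + stats::rnorm(n_tech, 0, noise_sd / 2)
          )
        }
        rows[[length(rows) + 1L]] <- add(reference_gene, ref_ct)
        for (gene in genes) {
          fold <- fold_changes$fold[
            fold_changes$priming == cells$priming[i] &
              fold_changes$challenge == cells$challenge[i] &
              fold_changes$gene == gene]
          stopifnot(length(fold) == 1L)
          tgt <- ref_ct + baseline_dct - log2(fold) + stats::rnorm(1, 0, noise_sd)
          rows[[length(rows) + 1L]] <- add(gene, tgt)
        }
      }
    }
    list(
      ct = dplyr::bind_rows(rows),
      truth = list(fold_changes = fold_changes, noise_sd = noise_sd,
                   n_bio = n_bio, n_tech = n_tech,
                   reference_gene = reference_gene,
                   ref_ct_mean = ref_ct_mean, baseline_dct = baseline_dct)
    )
  })
}

# --- activity generator -------------------------------------------------

#' Generate a synthetic NBT-inhibition assay with known 50% points
#'
#' Inhibition follows a logistic (Hill) curve in the enzyme amount,
#' `100 * a^h / (a^h + x50^h)`, sampled at `n_points` amounts spaced
#' geometrically around the true `x50` (which is itself included when
#' `n_points` is odd, so the noiseless 50% point is planted exactly).
#' Sample absorbances are `a_blank * (1 - inhibition/100)` plus Gaussian
#' noise. Lowry standards lie on an exact line through the origin with
#' slope `lowry_slope`, plus noise.
#'
#' @param seed Integer seed.
#' @param samples Tibble with `sample_id`, true `x50_ul` and
#'   `protein_mg_per_ml`; optional `priming`/`challenge`/`experiment`
#'   columns are carried into the assay table.
#' @param n_points Readings per curve.
#' @param span_log2 Half-width of the amount grid in log2 units.
#' @param hill Hill slope of the inhibition curve.
#' @param noise_sd Absorbance noise SD.
#' @param a_blank Blank absorbance.
#' @param lowry_slope Absorbance per (mg/mL) of the Lowry line.
#' @return List with `assay`, `lowry_standards`, `lowry_samples`, `truth`.
#' @export
generate_activity_dataset <- function(seed, samples, n_points = 5L,
                                      span_log2 = 1, hill = 1.5,
                                      noise_sd = 0, a_blank = 0.8,
                                      lowry_slope = 0.5) {
  stopifnot(all(samples$x50_ul > 0), n_points >= 2L)
  carry <- intersect(c("priming", "challenge", "experiment"), names(samples))
  withr::with_seed(split_seed(seed, "activity"), {
    assay <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
      x50 <- samples$x50_ul[i]
      amounts <- x50 * 2^seq(-span_log2, span_log2, length.out = n_points)
      inh <- 100 * amounts^hill / (amounts^hill + x50^hill)
      a_sample <- a_blank * (1 - inh / 100) + stats::rnorm(n_points, 0, noise_sd)
      out <- tibble::tibble(
        sample_id = samples$sample_id[i],
        amount = amounts, a_blank = a_blank, a_sample = a_sample
      )
      dplyr::bind_cols(out, samples[i, carry, drop = FALSE])
    })
    standards <- tibble::tibble(
      conc = seq(0, 1, by = 0.25),
      absorbance = lowry_slope * seq(0, 1, by = 0.25) +
        stats::rnorm(5, 0, noise_sd)
    )
    lowry_samples <- tibble::tibble(
      sample_id = samples$sample_id,
      absorbance = lowry_slope * samples$protein_mg_per_ml +
        stats::rnorm(nrow(samples), 0, noise_sd)
    )
    truth <- dplyr::mutate(
      samples,
      units_per_ul = 1 / .data$x50_ul,
      specific_activity_u_per_mg = 1000 / (.data$x50_ul * .data$protein_mg_per_ml)
    )
    list(assay = assay, lowry_standards = standards,
         lowry_samples = lowry_samples, truth = truth)
  })
}

# --- survival generator -------------------------------------------------

#' Generate synthetic survival counts per treatment cell
#'
#' Binomial survival per experiment per priming x challenge cell.
#'
#' @param seed Integer seed.
#' @param probs Tibble with `priming`, `challenge` and true survival
#'   probability `p` in \[0, 1\].
#' @param n_per_cell Individuals per cell per experiment (> 0).
#' @param n_experiments Independent experiments.
#' @return List with `counts` (tibble `priming`, `challenge`, `experiment`,
#'   `alive`, `total`) and `truth` (`probs`).
#' @export
generate_survival_dataset <- function(seed, probs, n_per_cell = 30L,
                                      n_experiments = 3L) {
  stopifnot(all(probs$p >= 0), all(probs$p <= 1), n_per_cell > 0)
  withr::with_seed(split_seed(seed, "survival"), {
    counts <- tidyr::expand_grid(
      probs, experiment = seq_len(n_experiments)
    ) |>
      dplyr::mutate(
        alive = stats::rbinom(dplyr::n(), n_per_cell, .data$p),
        total = n_per_cell
      ) |>
      dplyr::select("priming", "challenge", "experiment", "alive", "total")
    list(counts = counts, truth = list(probs = probs, n_per_cell = n_per_cell,
                                       n_experiments = n_experiments))
  })
}
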