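#' Compile a degenerate IUPAC consensus motif
#'
#' Turns a name/pattern pair into a compiled motif whose per-position
#' allowed-base sets follow the IUPAC code (`N` = {A,C,G,T}, `R` = {A,G},
#' ...). Matching uses subset semantics: a subject position satisfies a
#' pattern position iff the subject letter's base set is a subset of the
#' pattern letter's set, so a masked (`N`) subject base matches only a
#' pattern `N`, and ambiguity in the genome can never inflate counts.
#'
#' @param name Motif name (e.g. `"ARE"`).
#' @param pattern IUPAC consensus string (e.g. `"TGACNNNGC"`).
#' @return An object of class `sod_motif` with elements `name`, `pattern`,
#'   forward and reverse bitmask vectors.
#' @examples
#' compile_motif("XRE", "TGCRCNC")
#' @export
compile_motif <- function(name, pattern) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) || !nzchar(pattern)) {
    stop("empty motif pattern for '", name, "'", call. = FALSE)
  }
  pattern <- validate_dna(pattern, id = sprintf("motif '%s'", name))
  structure(
    list(
      name = name,
      pattern = pattern,
      fwd = iupac_encode(pattern),
      rev = iupac_encode(revcomp(pattern))
    ),
    class = "sod_motif"
  )
}

#' @export
print.sod_motif <- function(x, ...) {
  cat(sprintf("<sod_motif> %s = %s (%d nt)\n", x$name, x$pattern, nchar(x$pattern)))
  invisible(x)
}

#' The default cis-element motif set
#'
#' The antioxidant responsive element (ARE, `TGACNNNGC`), its half site
#' (hARE, `TGACNNN`) and the xenobiotic responsive element
#' (XRE, `TGCRCNC`). ARE and hARE are counted independently: an ARE
#' occurrence also yields an hARE hit at the same offset because the half
#' site is a prefix of the full element.
#'
#' @return A tibble with columns `name` and `pattern`.
#' @export
default_motifs <- function() {
  tibble::tibble(
    name = c("ARE", "hARE", "XRE"),
    pattern = c("TGACNNNGC", "TGACNNN", "TGCRCNC")
  )
}

#' Read a motif set from a TSV config file
#'
#' Two tab-separated columns, `name` and `pattern` (header required).
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `name`, `pattern`; patterns validated.
#' @export
read_motifs <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("name", "pattern") %in% names(m))) {
    stop("motif config must have columns 'name' and 'pattern'", call. = FALSE)
  }
  if (anyDuplicated(m$name)) stop("duplicate motif names in ", path, call. = FALSE)
  purrr::walk2(m$name, m$pattern, compile_motif)
  tibble::as_tibble(m[, c("name", "pattern")])
}

# Offsets (0-based) where the bitmask pattern matches the encoded window
# under subset semantics: subject set within pattern set at every position,
# i.e. bitwAnd(subject, pattern) == subject.
match_offsets <- function(win_bits, pat_bits) {
  L <- length(win_bits)
  m <- length(pat_bits)
  if (L < m) return(integer(0))
  n <- L - m + 1L
  ok <- rep(TRUE, n)
  for (j in seq_len(m)) {
    sub <- win_bits[j:(j + n - 1L)]
    ok <- ok & (bitwAnd(sub, pat_bits[j]) == sub)
  }
  which(ok) - 1L
}

#' Scan a window for a degenerate motif on one or both strands
#'
#' Reports every occurrence (overlaps included). Reverse-orientation hits
#' are matches of the reverse complement of the pattern and are reported in
#' forward-window coordinates with `strand == "-"`; `matched_seq` is always
#' the forward-strand slice of the window.
#'
#' @param window DNA string to scan.
#' @param motif A `sod_motif` from [compile_motif()].
#' @param strands Subset of `c("+", "-")`.
#' @param gene_id Optional identifier carried through to the hit table.
#' @return Tibble of hits: `motif_name`, `gene_id`, `start` (0-based offset
#'   in the window), `length`, `strand`, `matched_seq`. A window shorter
#'   than the pattern yields zero rows.
#' @examples
#' are <- compile_motif("ARE", "TGACNNNGC")
#' scan_sequence("TGACAAAGC", are)
#' @export
scan_sequence <- function(window, motif, strands = c("+", "-"), gene_id = NA_character_) {
  stopifnot(inherits(motif, "sod_motif"))
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  window <- validate_dna(window, id = "scan window", allow_empty = TRUE)
  m <- nchar(motif$pattern)
  empty <- tibble::tibble(
    motif_name = character(), gene_id = character(), start = integer(),
    length = integer(), strand = character(), matched_seq = character()
  )
  if (nchar(window) < m) return(empty)
  bits <- iupac_encode(window)
  rows <- purrr::map(strands, function(s) {
    off <- match_offsets(bits, if (s == "+") motif$fwd else motif$rev)
    if (length(off) == 0L) return(NULL)
    tibble::tibble(
      motif_name = motif$name,
      gene_id = gene_id,
      start = off,
      length = m,
      strand = s,
      matched_seq = substring(window, off + 1L, off + m)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Extract the upstream promoter window of a gene
#'
#' Returns the `window_nt` bases immediately 5' of the CDS start (for a
#' plus-strand gene) or the reverse complement of the `window_nt` bases
#' immediately 3' of the CDS end (minus strand), i.e. the region upstream
#' of the start codon, oriented 5' to 3' relative to the gene. The window
#' is truncated with a warning at the contig boundary.
#'
#' @param genes Gene-model tibble ([read_gene_models()]), any number of rows.
#' @param genomes Sequence tibble ([read_fasta()]).
#' @param window_nt Window length in nucleotides (default 1000; 2000 covers
#'   the full span usually inspected around stress-responsive promoters).
#' @return Tibble: `gene_id`, `seq` (the window, gene orientation),
#'   `width`, `truncated`.
#' @export
extract_upstream <- function(genes, genomes, window_nt = 1000L) {
  stopifnot(window_nt >= 1L)
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    hit <- which(genomes$id == g$seq_id)
    if (length(hit) == 0L) {
      stop("scaffold '", g$seq_id, "' for gene '", g$gene_id,
           "' not found among genome sequences", call. = FALSE)
    }
    chrom <- genomes$seq[hit[1]]
    L <- nchar(chrom)
    if (g$strand == "+") {
      to <- g$cds_start                      # 0-based, exclusive
      from <- max(0L, to - window_nt)
      win <- substr(chrom, from + 1L, to)
    } else {
      from <- g$cds_end                      # 0-based, inclusive start of downstream
      to <- min(L, from + window_nt)
      win <- revcomp(substr(chrom, from + 1L, to))
    }
    truncated <- nchar(win) < window_nt
    if (truncated) {
      warning(sprintf(
        "upstream window of gene '%s' truncated to %d nt at the contig boundary",
        g$gene_id, nchar(win)), call. = FALSE)
    }
    tibble::tibble(gene_id = g$gene_id, seq = win,
                   width = nchar(win), truncated = truncated)
  })
}

#' Scan promoter windows of all genes for a motif set
#'
#' Composes [extract_upstream()] and [scan_sequence()] over every
#' gene x motif combination.
#'
#' @inheritParams extract_upstream
#' @param motifs Tibble with columns `name`, `pattern` (see
#'   [default_motifs()]).
#' @return Tibble of hits as in [scan_sequence()], with `gene_id` filled.
#' @export
scan_promoters <- function(genes, genomes, motifs = default_motifs(),
                           window_nt = 1000L) {
  windows <- extract_upstream(genes, genomes, window_nt)
  compiled <- purrr::map2(motifs$name, motifs$pattern, compile_motif)
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    purrr::map_dfr(compiled, function(m) {
      scan_sequence(windows$seq[i], m, gene_id = windows$gene_id[i])
    })
  })
}

#' Build the motif x orientation count table
#'
#' One row per gene, one column per motif and orientation, motif-major
#' with the forward (5'-3') column before the reverse (3'-5') column.
#' Overlapping occurrences all count, and nested motifs are counted
#' independently (an ARE site also contributes an hARE count).
#'
#' @inheritParams scan_promoters
#' @return A tibble of class `sod_count_table`: `gene_id` then columns
#'   named `"<motif> 5'-3'"` and `"<motif> 3'-5'"`.
#' @export
build_count_table <- function(genes, genomes, motifs = default_motifs(),
                              window_nt = 1000L) {
  hits <- scan_promoters(genes, genomes, motifs, window_nt)
  count_table_from_hits(hits, gene_ids = genes$gene_id, motif_names = motifs$name)
}

# Shared tabulation used both by the pipeline and the synthetic-truth path.
count_table_from_hits <- function(hits, gene_ids, motif_names) {
  grid <- tidyr::expand_grid(
    gene_id = gene_ids, motif_name = motif_names, strand = c("+", "-")
  )
  counts <- hits |>
    dplyr::count(.data$gene_id, .data$motif_name, .data$strand, name = "n")
  tab <- grid |>
    dplyr::left_join(counts, by = c("gene_id", "motif_name", "strand")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      orientation = ifelse(.data$strand == "+", "5'-3'", "3'-5'"),
      col = paste(.data$motif_name, .data$orientation)
    )
  wide <- tab |>
    dplyr::select("gene_id", "col", "n") |>
    tidyr::pivot_wider(names_from = "col", values_from = "n")
  ord <- c("gene_id", as.vector(t(outer(motif_names, c("5'-3'", "3'-5'"), paste))))
  wide <- wide[, ord]
  wide <- wide[match(gene_ids, wide$gene_id), ]
  class(wide) <- c("sod_count_table", class(wide))
  wide
}

#' Write per-hit BED output
#'
#' BED6 (0-based half-open) rows for every motif hit, coordinates relative
#' to the scanned window.
#'
#' @param hits Hit tibble from [scan_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- hits |>
    dplyr::transmute(
      chrom = .data$gene_id, start = .data$start,
      end = .data$start + .data$length,
      name = .data$motif_name, score = 0L, strand = .data$strand
    )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
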