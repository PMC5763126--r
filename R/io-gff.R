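#' Read gene models from a GFF3 file
#'
#' Expects `gene`, `exon` and `CDS` features where exons and CDS segments
#' carry a `Parent` attribute naming the gene's `ID`. GFF3 1-based
#' inclusive coordinates are converted to the package-internal 0-based
#' half-open convention; user-facing reports convert back to 1-based.
#'
#' Each CDS segment must lie inside a single exon (a CDS line straddling
#' an intron is inconsistent with splicing and is an error); the gene-level
#' `cds_start`/`cds_end` span is the genomic extent of all CDS segments.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per gene: `gene_id`, `seq_id`, `strand`,
#'   `exons` (list column of tibbles with 0-based half-open `start`/`end`,
#'   sorted, disjoint), `cds_start`, `cds_end` (0-based half-open span).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = vapply(
      if (!is.null(gr$Parent)) as.list(gr$Parent) else rep(list(character()), length(gr)),
      function(p) if (length(p)) p[[1]] else NA_character_, character(1)
    ),
    annotated_protein_aa = if (!is.null(gr$annotated_protein_aa)) {
      suppressWarnings(as.integer(as.character(gr$annotated_protein_aa)))
    } else {
      NA_integer_
    }
  )
  genes <- dplyr::filter(df, .data$type == "gene")
  if (nrow(genes) == 0L) stop("no gene features in ", path, call. = FALSE)
  kids <- dplyr::filter(df, .data$type %in% c("exon", "CDS"))
  orphan <- setdiff(stats::na.omit(unique(kids$parent)), genes$id)
  if (length(orphan) > 0L) {
    stop("exon/CDS feature(s) with no parent gene: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(kids$parent)) stop("exon/CDS feature without Parent attribute", call. = FALSE)

  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- dplyr::filter(kids, .data$parent == g$id, .data$type == "exon") |>
      dplyr::arrange(.data$start)
    cds <- dplyr::filter(kids, .data$parent == g$id, .data$type == "CDS") |>
      dplyr::arrange(.data$start)
    if (nrow(ex) == 0L) stop("gene '", g$id, "' has no exons", call. = FALSE)
    if (nrow(cds) == 0L) stop("gene '", g$id, "' has no CDS", call. = FALSE)
    if (any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene '", g$id, "'", call. = FALSE)
    }
    # every CDS segment must fit inside one exon
    for (j in seq_len(nrow(cds))) {
      inside <- any(ex$start <= cds$start[j] & cds$end[j] <= ex$end)
      if (!inside) {
        stop("CDS segment [", cds$start[j] + 1L, ", ", cds$end[j],
             "] of gene '", g$id, "' is not contained in a single exon",
             call. = FALSE)
      }
    }
    out <- tibble::tibble(
      gene_id = g$id,
      seq_id = g$seq_id,
      strand = g$strand,
      exons = list(tibble::tibble(start = ex$start, end = ex$end)),
      cds_start = min(cds$start),
      cds_end = max(cds$end)
    )
    if ("annotated_protein_aa" %in% names(g) && !is.na(g$annotated_protein_aa)) {
      out$annotated_protein_aa <- as.integer(g$annotated_protein_aa)
    }
    out
  })
}

#' Write gene models to a GFF3 file
#'
#' Deterministic writer (genes in input order, features sorted by start)
#' producing `gene`, `exon` and `CDS` lines with `ID`/`Parent` attributes.
#' Internal 0-based half-open coordinates are converted to GFF3 1-based
#' inclusive on output.
#'
#' @param genes Tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    fmt <- function(type, s0, e0, attr) {
      sprintf("%s\tsodkit\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$seq_id, type, s0 + 1L, e0, g$strand, attr)
    }
    gene_attr <- paste0("ID=", g$gene_id)
    if ("annotated_protein_aa" %in% names(genes) && !is.na(g$annotated_protein_aa)) {
      gene_attr <- paste0(gene_attr, ";annotated_protein_aa=", g$annotated_protein_aa)
    }
    lines <- c(lines,
      fmt("gene", min(ex$start), max(ex$end), gene_attr),
      vapply(seq_len(nrow(ex)), function(j) {
        fmt("exon", ex$start[j], ex$end[j],
            sprintf("ID=%s.exon%d;Parent=%s", g$gene_id, j, g$gene_id))
      }, character(1))
    )
    # CDS emitted per overlapping exon segment
    k <- 0L
    for (j in seq_len(nrow(ex))) {
      s <- max(ex$start[j], g$cds_start)
      e <- min(ex$end[j], g$cds_end)
      if (s < e) {
        k <- k + 1L
        lines <- c(lines, fmt("CDS", s, e,
          sprintf("ID=%s.cds%d;Parent=%s", g$gene_id, k, g$gene_id)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
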