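#' Read a FASTA file into a tibble of sequence records
#'
#' Parses a (multi-line, possibly CRLF) FASTA file, uppercases the
#' sequences and validates them against the 15-letter IUPAC DNA alphabet.
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `seq` (uppercase DNA).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "acgt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    seqs[i] <- validate_dna(seqs[i], id = sprintf("record '%s'", ids[i]))
  }
  tibble::tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequence records to a FASTA file
#'
#' Inverse of [read_fasta()]: writing then re-reading is the identity on
#' `id` and `seq`. Records are written in input order, 70 columns per line.
#'
#' @param records Tibble/data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  lines <- unlist(purrr::map2(records$id, records$seq, function(id, s) {
    s <- toupper(s)
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}
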