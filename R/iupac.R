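# IUPAC nucleotide alphabet: bitmask encoding A=1, C=2, G=4, T=8.
# An ambiguity letter is the OR of the bases it stands for.

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

IUPAC_LETTERS <- names(IUPAC_BITS)

# Complement permutes the bitmask (A<->T, C<->G), hence R<->Y, K<->M,
# B<->V, D<->H; S, W and N are self-complementary.
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

#' Validate a DNA string over the IUPAC alphabet
#'
#' Checks that every character of `seq` (after uppercasing) is one of the
#' 15 IUPAC nucleotide letters (`A C G T M R W S Y K V H D B N`). RNA (`U`)
#' and gap characters are rejected.
#'
#' @param seq A single character string.
#' @param id Identifier used in error messages (e.g. a FASTA record id).
#' @param allow_empty If `FALSE` (default) an empty string is an error.
#' @return The validated, uppercased string, invisibly usable downstream.
#' @examples
#' validate_dna("acgtn")
#' @export
validate_dna <- function(seq, id = "sequence", allow_empty = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (!nzchar(seq)) {
    if (allow_empty) return(seq)
    stop("empty sequence in ", id, call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% IUPAC_LETTERS))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid character '%s' in %s at position %d",
      chars[bad[1]], id, bad[1]
    ), call. = FALSE)
  }
  seq
}

#' Reverse complement of an IUPAC DNA string
#'
#' IUPAC-aware: ambiguity letters are complemented by permuting their base
#' sets (`R`<->`Y`, `K`<->`M`, `B`<->`V`, `D`<->`H`; `S`, `W`, `N` map to
#' themselves), so `revcomp()` is an involution on the full 15-letter
#' alphabet. Vectorised over its argument.
#'
#' @param seq Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements, uppercase.
#' @examples
#' revcomp("TGAC")     # "GTCA"
#' revcomp("TGCRCNC")  # "GNGYGCA"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  out <- vapply(seq, function(s) {
    s <- validate_dna(s, allow_empty = TRUE)
    if (!nzchar(s)) return("")
    comp <- chartr(
      paste(names(IUPAC_COMPLEMENT), collapse = ""),
      paste(unname(IUPAC_COMPLEMENT), collapse = ""),
      s
    )
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out
}

# Encode a DNA string as an integer bitmask vector.
iupac_encode <- function(seq) {
  unname(IUPAC_BITS[strsplit(toupper(seq), "", fixed = TRUE)[[1]]])
}
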