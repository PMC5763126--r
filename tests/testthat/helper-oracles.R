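# Independent oracles used across the suite. These deliberately share no
# code with the package internals.

# --- IUPAC set-based motif matching oracle ------------------------------

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(
  A = "T", T = "A", C = "G", G = "C", M = "K", K = "M", R = "Y", Y = "R",
  W = "W", S = "S", V = "B", B = "V", H = "D", D = "H", N = "N"
)

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# 0-based offsets where pattern matches window under subset semantics,
# checked one offset and one position at a time.
oracle_offsets <- function(window, pattern) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- length(pat)
  # subject letters whose base set is a subset of the pattern letter's set
  allowed <- lapply(pat, function(p) {
    names(ORACLE_SETS)[vapply(ORACLE_SETS, function(s) {
      all(s %in% ORACLE_SETS[[p]])
    }, logical(1))]
  })
  L <- length(chars)
  if (L < m) return(integer(0))
  hits <- integer(0)
  for (off in 0:(L - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!(chars[off + j] %in% allowed[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# strand-aware oracle hit table comparable with scan_sequence() output
oracle_scan <- function(window, pattern, strands = c("+", "-")) {
  out <- list()
  if ("+" %in% strands) {
    off <- oracle_offsets(window, pattern)
    if (length(off)) out$p <- data.frame(start = off, strand = "+")
  }
  if ("-" %in% strands) {
    off <- oracle_offsets(window, oracle_revcomp(pattern))
    if (length(off)) out$m <- data.frame(start = off, strand = "-")
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), strand = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# --- exact Wilcoxon rank-sum oracle by full enumeration -----------------

oracle_wilcoxon_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  pl <- mean(u_all <= u_obs)
  pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

# --- misc ---------------------------------------------------------------

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# a minimal single-gene FASTA + GFF3 fixture written to a tempdir
write_tiny_locus <- function(dir, gene_lines, genome_seq, seq_id = "chr1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "g.fasta")
  writeLines(c(paste0(">", seq_id), genome_seq), fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3", gene_lines), gff)
  list(fasta = fa, gff = gff)
}
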