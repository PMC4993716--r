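# Independent oracles and fixture builders shared across test files.

# IUPAC base sets, written out independently of the package internals.
ORACLE_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Regex scan for recognition matches (overlaps via lookahead). Valid for
# unambiguous ACGT subject sequences.
oracle_find_sites <- function(residues, recognition) {
  cls <- vapply(strsplit(recognition, "", fixed = TRUE)[[1]], function(s) {
    b <- ORACLE_BASES[[s]]
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1))
  pat <- paste0("(?=", paste(cls, collapse = ""), ")")
  hits <- gregexpr(pat, residues, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# Maximum number of pairwise-disjoint intervals, by dynamic programming
# (weighted interval scheduling with unit weights) -- independent of the
# greedy scan used in the package.
oracle_max_disjoint <- function(intervals) {
  if (length(intervals) == 0L) return(0L)
  ivl <- do.call(rbind, intervals)
  ord <- order(ivl[, 2])
  ivl <- ivl[ord, , drop = FALSE]
  n <- nrow(ivl)
  dp <- numeric(n + 1L)
  for (i in seq_len(n)) {
    prev <- 0L
    for (j in seq_len(i - 1L)) if (ivl[j, 2] <= ivl[i, 1]) prev <- j
    dp[i + 1L] <- max(dp[i], dp[prev + 1L] + 1)
  }
  as.integer(dp[n + 1L])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

make_aln <- function(residues, ids = sprintf("s%d", seq_along(residues))) {
  as_aligned_set(data.frame(id = ids, description = ids,
                            residues = residues,
                            stringsAsFactors = FALSE))
}

# random symmetric distance matrix with zero diagonal and distinct labels
random_dist <- function(n, labels = paste0("t", seq_len(n))) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2)
  d <- d + t(d)
  dimnames(d) <- list(labels, labels)
  d
}
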