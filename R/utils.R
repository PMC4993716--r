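# Shared low-level helpers: IUPAC alphabet, labelled-matrix TSV i/o,
# partition comparison.

# Bit masks over {A=1, C=2, G=4, T=8}; every IUPAC nucleotide code is the
# union of its base set. "-" (gap) deliberately absent: gapped symbols are
# stripped before any physical-sequence operation.
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.IUPAC_LETTERS <- names(.IUPAC_MASK)

# Base set of each code, for building regex character classes and
# reverse complements.
.IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.ALLOWED_RESIDUES <- c(.IUPAC_LETTERS, "-")

.COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param x character scalar over the IUPAC alphabet (gaps allowed).
#' @return the reverse complement, same alphabet.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.COMPLEMENT))
  if (length(bad) > 0L)
    stop("non-IUPAC symbol in sequence: ", paste(bad, collapse = ", "))
  paste(rev(unname(.COMPLEMENT[chars])), collapse = "")
}

.validate_residues <- function(residues, id) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), .ALLOWED_RESIDUES)
  if (length(bad) > 0L)
    stop(sprintf("record '%s' contains illegal symbol(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Write a labelled matrix as TSV
#'
#' First row holds column labels, first column row labels; round-trips
#' losslessly with [read_matrix_tsv()].
#'
#' @param m matrix with non-NULL dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  if (!is.matrix(m)) stop("input must be a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must carry row and column labels")
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled matrix from TSV
#'
#' @param path file written by [write_matrix_tsv()].
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items;
#' 1 means identical partitions, 0 the expected value under random
#' labelling. Used to score recovery of true group structure by
#' clustering.
#'
#' @param a,b vectors of cluster labels, equal length.
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
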