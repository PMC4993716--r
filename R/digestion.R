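# In-silico restriction digestion.
#
# Matching rule: a sequence window matches the recognition site when, at
# every position, the window symbol's base set is a subset of the
# recognition symbol's base set. An N in the recognition site accepts any
# base; an N in the sequence never certifies a definite site (conservative
# calling, as in restriction mappers). Scanning is single-strand; all
# built-in enzymes are palindromic so this finds every double-strand site.
# Sequences are linear (amplicons), gaps must be stripped by the caller.
#
# Positions are 1-based: a match start is the 1-based index of the
# window's first residue; a cut point c means the duplex is severed
# after residue c (so c residues lie to its left).

.residue_masks <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  m <- .IUPAC_MASK[chars]
  if (anyNA(m))
    stop("sequence contains gap or non-IUPAC symbol(s): ",
         paste(unique(chars[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Find recognition-site matches in an ungapped sequence
#'
#' Overlapping matches are all reported.
#'
#' @param residues ungapped IUPAC DNA string.
#' @param enzyme a `restriction_enzyme`.
#' @return sorted integer vector of 1-based match start positions.
#' @examples
#' alu <- compile_enzyme("AluI", "AG'CT")
#' find_sites("AAGCTA", alu)  # 2
#' @export
find_sites <- function(residues, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  seq_mask <- .residue_masks(residues)
  rec_mask <- .residue_masks(enzyme$recognition)
  L <- length(rec_mask)
  n <- length(seq_mask)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    # window symbol base set must be contained in recognition base set
    ok <- ok & bitwAnd(seq_mask[j:(n - L + j)], bitwNot(rec_mask[j])) == 0L
  }
  which(ok)
}

#' Digest an ungapped sequence with one enzyme
#'
#' Cut points are match start − 1 + cut offset, deduplicated; cuts falling
#' at the very ends (0 or sequence length) produce no new fragment and are
#' dropped. Fragments partition the sequence, so their lengths always sum
#' to its length.
#'
#' @param residues ungapped IUPAC DNA string.
#' @param enzyme a `restriction_enzyme`.
#' @param id optional strain id carried through to reports.
#' @return a `digest_result`: list with `id`, `enzyme`, `match_starts`,
#'   `cut_points` and a `fragments` data.frame (start, end, length;
#'   1-based inclusive).
#' @export
digest <- function(residues, enzyme, id = NA_character_) {
  if (!nzchar(residues)) stop("cannot digest an empty sequence")
  starts <- find_sites(residues, enzyme)
  n <- nchar(residues)
  cuts <- sort(unique(starts - 1L + enzyme$cut_offset))
  cuts <- cuts[cuts > 0L & cuts < n]
  bounds <- c(0L, cuts, n)
  frags <- data.frame(start = bounds[-length(bounds)] + 1L,
                      end = bounds[-1],
                      stringsAsFactors = FALSE)
  frags$length <- frags$end - frags$start + 1L
  out <- list(id = id, enzyme = enzyme$name, match_starts = starts,
              cut_points = cuts, fragments = frags)
  class(out) <- "digest_result"
  stopifnot(sum(frags$length) == n,
            nrow(frags) == length(cuts) + 1L)
  out
}

#' Digest every sequence with every enzyme
#'
#' Gaps are stripped per sequence before scanning (restriction sites are
#' physical, not columnar).
#'
#' @param seqs a `seq_set`.
#' @param enzymes named list of `restriction_enzyme` (default the ten
#'   built-ins, [default_enzymes()]).
#' @return a `digest_set`: list of lists, `[[enzyme]][[strain id]]` ->
#'   `digest_result`, with attributes `strains` and `enzymes` preserving
#'   input order.
#' @export
digest_set <- function(seqs, enzymes = default_enzymes()) {
  ungapped <- strip_gaps(seqs$residues)
  out <- lapply(enzymes, function(e) {
    stats::setNames(
      lapply(seq_len(nrow(seqs)),
             function(i) digest(ungapped[i], e, id = seqs$id[i])),
      seqs$id)
  })
  attr(out, "strains") <- seqs$id
  attr(out, "enzymes") <- vapply(enzymes, `[[`, character(1), "name")
  class(out) <- "digest_set"
  out
}

#' Site presence/absence matrix
#'
#' One row per strain, one column per enzyme; a cell is 1 when the strain
#' carries at least one recognition site for that enzyme (presence, not
#' count).
#'
#' @param seqs a `seq_set`.
#' @param enzymes named list of `restriction_enzyme`.
#' @return integer 0/1 matrix, strains x enzymes, in input order.
#' @export
site_matrix <- function(seqs, enzymes = default_enzymes()) {
  stopifnot(nrow(seqs) >= 1L, length(enzymes) >= 1L)
  ungapped <- strip_gaps(seqs$residues)
  m <- vapply(enzymes, function(e) {
    vapply(ungapped,
           function(s) as.integer(length(find_sites(s, e)) > 0L),
           integer(1), USE.NAMES = FALSE)
  }, integer(nrow(seqs)))
  matrix(m, nrow = nrow(seqs),
         dimnames = list(seqs$id,
                         unname(vapply(enzymes, `[[`, character(1),
                                       "name"))))
}

#' Fragment (band) presence/absence matrix
#'
#' Per enzyme, fragment lengths observed across all strains are clustered
#' into bins by single linkage: sorted lengths are chained together while
#' the relative difference between neighbours, (b - a) / a, is at most
#' `tolerance`. Each (enzyme, bin) pair becomes one binary feature; a
#' strain scores 1 when it has at least one fragment in the bin.
#' Tolerance 0 gives exact-length bins (in-silico lengths are exact);
#' 0.02 emulates gel resolution.
#'
#' @param digests a `digest_set`.
#' @param tolerance relative length fraction >= 0 (default 0).
#' @return integer 0/1 matrix, strains x features; feature names are
#'   "enzyme:length" or "enzyme:lo-hi" for merged bins.
#' @export
band_matrix <- function(digests, tolerance = 0) {
  stopifnot(inherits(digests, "digest_set"))
  if (tolerance < 0) stop("tolerance must be >= 0")
  strains <- attr(digests, "strains")
  cols <- list()
  for (ename in attr(digests, "enzymes")) {
    per_strain <- lapply(digests[[ename]], function(d) d$fragments$length)
    lens <- sort(unique(unlist(per_strain)))
    if (length(lens) == 0L) next
    # single linkage on a line: chain sorted neighbours within tolerance
    brk <- if (length(lens) > 1L)
      (diff(lens) / lens[-length(lens)]) > tolerance else logical(0)
    bin_of <- c(0L, cumsum(brk)) + 1L
    for (b in unique(bin_of)) {
      members <- lens[bin_of == b]
      label <- if (length(members) == 1L)
        sprintf("%s:%d", ename, members[1])
      else sprintf("%s:%d-%d", ename, min(members), max(members))
      cols[[label]] <- vapply(per_strain,
                              function(fl) as.integer(any(fl %in% members)),
                              integer(1))[strains]
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- strains
  m
}

#' Fragment counts (virtual-gel OTUs) per strain and enzyme
#'
#' Each fragment is a discrete band; the count per lane is the number of
#' cut points plus one.
#'
#' @param digests a `digest_set`.
#' @return data.frame with columns strain, enzyme, fragments.
#' @export
otu_counts <- function(digests) {
  stopifnot(inherits(digests, "digest_set"))
  strains <- attr(digests, "strains")
  enzymes <- attr(digests, "enzymes")
  do.call(rbind, lapply(enzymes, function(e) {
    data.frame(strain = strains, enzyme = e,
               fragments = vapply(digests[[e]][strains],
                                  function(d) nrow(d$fragments),
                                  integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Long-format fragment table
#'
#' @param digests a `digest_set`.
#' @return data.frame (strain, enzyme, fragment, start, end, length),
#'   coordinates 1-based inclusive on the ungapped sequence.
#' @export
fragment_table <- function(digests) {
  stopifnot(inherits(digests, "digest_set"))
  rows <- list()
  for (e in attr(digests, "enzymes")) {
    for (s in attr(digests, "strains")) {
      fr <- digests[[e]][[s]]$fragments
      rows[[paste(e, s)]] <- data.frame(
        strain = s, enzyme = e, fragment = seq_len(nrow(fr)),
        fr, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
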