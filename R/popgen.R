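# DnaSP-style nucleotide polymorphism statistics on an alignment.
#
# All statistics are computed on the columns surviving "complete
# deletion": a column is kept only when every sequence carries an
# unambiguous base (A/C/G/T) there — gaps and ambiguity codes anywhere in
# a column exclude it globally.

.aln_char_matrix <- function(aln) {
  stopifnot(inherits(aln, "aligned_set"))
  do.call(rbind, strsplit(aln$residues, "", fixed = TRUE))
}

#' Complete-deletion site filter
#'
#' @param aln an `aligned_set`.
#' @return a `site_filter`: list with `included` (1-based column indices
#'   kept), `n_excluded`, and `total` columns.
#' @export
complete_deletion <- function(aln) {
  m <- .aln_char_matrix(aln)
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(keep))
    stop("complete deletion removed every column; no unambiguous sites")
  out <- list(included = which(keep), n_excluded = sum(!keep),
              total = ncol(m))
  class(out) <- "site_filter"
  out
}

#' Polymorphism summary of an alignment
#'
#' Computes, over the included columns: segregating sites S (columns with
#' >= 2 states), total mutations eta = sum(states - 1) per column,
#' singleton variable sites (exactly two states, minor count 1),
#' parsimony-informative sites (>= 2 states each carried by >= 2
#' sequences), monomorphic sites, haplotype count h and diversity
#' Hd = n(1 - sum f^2)/(n - 1), average pairwise differences k, nucleotide
#' diversity Pi = k / L, and the four-gamete minimum number of
#' recombination events Rm.
#'
#' @param aln an `aligned_set` with n >= 2 sequences.
#' @param filter a `site_filter` (default [complete_deletion()]).
#' @return a `popgen_summary` list; see fields above plus `n` and `L`.
#' @export
popgen_summary <- function(aln, filter = complete_deletion(aln)) {
  m <- .aln_char_matrix(aln)[, filter$included, drop = FALSE]
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  L <- ncol(m)
  n_states <- vapply(seq_len(L), function(j) length(unique(m[, j])),
                     integer(1))
  S <- sum(n_states >= 2L)
  eta <- sum(n_states - 1L)
  singleton <- 0L
  pis <- 0L
  for (j in which(n_states >= 2L)) {
    tab <- sort(table(m[, j]))
    if (length(tab) == 2L && tab[1] == 1L) singleton <- singleton + 1L
    if (sum(tab >= 2L) >= 2L) pis <- pis + 1L
  }
  hap <- apply(m, 1, paste, collapse = "")
  h <- length(unique(hap))
  f <- as.numeric(table(hap)) / n
  Hd <- n * (1 - sum(f^2)) / (n - 1)
  # average pairwise differences over all C(n,2) pairs
  diffs <- 0
  for (i in seq_len(n - 1L)) {
    for (jj in (i + 1L):n) diffs <- diffs + sum(m[i, ] != m[jj, ])
  }
  k <- diffs / choose(n, 2)
  Pi <- k / L
  biallelic <- which(n_states == 2L)
  rm_events <- four_gamete_rm(m[, biallelic, drop = FALSE],
                              positions = biallelic)
  out <- list(n = n, L = L, S = S, eta = eta,
              singleton_sites = singleton,
              parsimony_informative_sites = pis,
              monomorphic_sites = L - S,
              n_haplotypes = h, haplotype_diversity = Hd,
              avg_pairwise_differences = k, nucleotide_diversity = Pi,
              Rm = rm_events)
  class(out) <- "popgen_summary"
  stopifnot(out$monomorphic_sites + S == L,
            S <= eta,
            singleton + pis <= S,
            Hd >= 0, Hd <= 1 + 1e-12,
            abs(Pi * L - k) < 1e-9,
            rm_events >= 0)
  out
}

#' @export
print.popgen_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Polymorphism summary: n = %d sequences, L = %d sites\n",
           "  segregating sites (S)        %d\n",
           "  total mutations (eta)        %d\n",
           "  singleton variable sites     %d\n",
           "  parsimony-informative sites  %d\n",
           "  monomorphic sites            %d\n",
           "  haplotypes (h)               %d\n",
           "  haplotype diversity (Hd)     %.4f\n",
           "  avg pairwise differences (k) %.4f\n",
           "  nucleotide diversity (Pi)    %.5f\n",
           "  min recombination (Rm)       %d\n"),
    x$n, x$L, x$S, x$eta, x$singleton_sites,
    x$parsimony_informative_sites, x$monomorphic_sites, x$n_haplotypes,
    x$haplotype_diversity, x$avg_pairwise_differences,
    x$nucleotide_diversity, x$Rm))
  invisible(x)
}

#' Between-group diversity
#'
#' Average pairwise differences across two groups,
#' k_between = mean over all (i in X, j in Y) of per-pair differing
#' included columns, plus eta over the pooled rows of both groups. The
#' site filter is the global complete-deletion filter of the full
#' alignment, so within- and between-group numbers are comparable.
#'
#' @param aln an `aligned_set`.
#' @param groups a `group_assignment` covering the alignment ids.
#' @param pair character vector of two group names.
#' @param filter a `site_filter` (default global complete deletion).
#' @return list with `groups`, `k_between`, `eta_union`, `n_x`, `n_y`.
#' @export
between_groups <- function(aln, groups, pair,
                           filter = complete_deletion(aln)) {
  stopifnot(length(pair) == 2L)
  unknown <- setdiff(pair, groups$groups)
  if (length(unknown) > 0L)
    stop("unknown group name(s): ", paste(unknown, collapse = ", "))
  m <- .aln_char_matrix(aln)[, filter$included, drop = FALSE]
  rownames(m) <- aln$id
  gx <- names(groups$mapping)[groups$mapping == pair[1]]
  gy <- names(groups$mapping)[groups$mapping == pair[2]]
  gx <- intersect(gx, aln$id); gy <- intersect(gy, aln$id)
  if (length(gx) == 0L || length(gy) == 0L)
    stop("empty group among: ", paste(pair, collapse = ", "))
  total <- 0
  for (i in gx) for (j in gy) total <- total + sum(m[i, ] != m[j, ])
  pooled <- m[c(gx, gy), , drop = FALSE]
  eta_union <- sum(apply(pooled, 2,
                         function(col) length(unique(col)) - 1L))
  list(groups = pair, k_between = total / (length(gx) * length(gy)),
       eta_union = eta_union, n_x = length(gx), n_y = length(gy))
}

#' Minimum number of recombination events (four-gamete test)
#'
#' Hudson-Kaplan bound: every pair of biallelic sites exhibiting all four
#' two-locus haplotypes requires a recombination event strictly between
#' them; Rm is the size of a maximal set of non-overlapping such
#' intervals, found by the standard left-to-right greedy scan on interval
#' right endpoints.
#'
#' @param m character or numeric matrix of biallelic site patterns
#'   (sequences x sites).
#' @param positions optional site positions (default column index).
#' @return integer Rm >= 0.
#' @export
four_gamete_rm <- function(m, positions = seq_len(ncol(m))) {
  if (ncol(m) < 2L) return(0L)
  stopifnot(length(positions) == ncol(m))
  nsite <- ncol(m)
  ivl <- list()
  for (i in seq_len(nsite - 1L)) {
    for (j in (i + 1L):nsite) {
      gametes <- unique(paste(m[, i], m[, j]))
      if (length(gametes) == 4L)
        ivl[[length(ivl) + 1L]] <- c(positions[i], positions[j])
    }
  }
  if (length(ivl) == 0L) return(0L)
  ivl <- do.call(rbind, ivl)
  ivl <- ivl[order(ivl[, 2], ivl[, 1]), , drop = FALSE]
  rm_count <- 0L
  last_right <- -Inf
  for (r in seq_len(nrow(ivl))) {
    if (ivl[r, 1] >= last_right) {
      rm_count <- rm_count + 1L
      last_right <- ivl[r, 2]
    }
  }
  rm_count
}
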