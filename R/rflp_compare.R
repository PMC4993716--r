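# Jaccard similarity on binary profiles and UPGMA clustering.

#' Jaccard similarity between two binary profiles
#'
#' Sj = a / (a + b + c), with a = positions where both are 1, b = first
#' only, c = second only. Two all-zero profiles are identical banding
#' patterns, so 1 is returned (with a warning, since no character supports
#' it).
#'
#' @param x,y 0/1 vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
jaccard <- function(x, y) {
  if (length(x) != length(y))
    stop("profile length mismatch: ", length(x), " vs ", length(y))
  if (length(x) == 0L) stop("empty profiles")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("profiles must be binary (0/1)")
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1)
  if (a + b + cc == 0) {
    warning("both profiles all-zero; returning similarity 1")
    return(1)
  }
  a / (a + b + cc)
}

#' Pairwise Jaccard similarity matrix
#'
#' @param m binary matrix, strains x features.
#' @return symmetric similarity matrix with unit diagonal, labelled by
#'   the row names of `m`.
#' @export
pairwise_similarity <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  n <- nrow(m)
  s <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s[i, j] <- s[j, i] <- suppressWarnings(jaccard(m[i, ], m[j, ]))
    }
  }
  dimnames(s) <- list(rownames(m), rownames(m))
  s
}

#' Convert a similarity matrix to a distance matrix
#'
#' @param s symmetric similarity matrix in \[0, 1\].
#' @return D = 1 - S, elementwise.
#' @export
to_distance <- function(s) {
  d <- 1 - s
  diag(d) <- 0
  d
}

.check_distance <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance input must be a square matrix")
  if (any(d < 0)) stop("negative distances")
  if (max(abs(d - t(d))) > 1e-12) stop("asymmetric distance matrix")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(nrow(d)))
  d
}

#' UPGMA (unweighted average-linkage) clustering
#'
#' Repeatedly merges the pair of clusters with minimal average
#' inter-cluster distance; the new node sits at half the merge distance,
#' and the distance between clusters is the arithmetic mean of all
#' member-pair distances (unweighted in member counts). Ties are broken by
#' the lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its smallest leaf label), so output is deterministic.
#'
#' @param d symmetric distance matrix with labels.
#' @return an `rflp_dendrogram`: list with `labels`, hclust-style `merge`,
#'   `merge_dist` (distance at each merge) and `node_height`
#'   (ultrametric height = merge_dist / 2).
#' @export
upgma <- function(d) {
  d <- .check_distance(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items")
  labels <- rownames(d)
  # active clusters: leaf index sets + hclust node codes
  members <- as.list(seq_len(n))
  codes <- as.integer(-seq_len(n))
  keys <- labels
  merge <- matrix(0L, n - 1L, 2L)
  merge_dist <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        dij <- mean(d[members[[i]], members[[j]]])
        pair_key <- sort(c(keys[i], keys[j]))
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (pair_key[1] < best$key[1] ||
              (pair_key[1] == best$key[1] && pair_key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = pair_key)
        }
      }
    }
    i <- best$i; j <- best$j
    # deterministic child order: smaller cluster key first
    first_i <- keys[i] <= keys[j]
    merge[step, ] <- if (first_i) c(codes[i], codes[j]) else
      c(codes[j], codes[i])
    merge_dist[step] <- best$d
    members[[i]] <- c(members[[i]], members[[j]])
    keys[i] <- min(keys[i], keys[j])
    codes[i] <- step
    members[[j]] <- NULL
    keys <- keys[-j]
    codes <- codes[-j]
  }
  out <- list(labels = labels, merge = merge, merge_dist = merge_dist,
              node_height = merge_dist / 2)
  class(out) <- "rflp_dendrogram"
  out
}

#' Convert a dendrogram to a stats::hclust object
#'
#' Heights are the merge distances (twice the ultrametric node heights),
#' matching what `stats::hclust(method = "average")` stores, so
#' `stats::cutree()` and `stats::cophenetic()` work directly.
#'
#' @param tree an `rflp_dendrogram`.
#' @return an object of class `hclust`.
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "rflp_dendrogram"))
  n <- length(tree$labels)
  leaf_order <- function(node) {
    if (node < 0L) return(-node)
    c(leaf_order(tree$merge[node, 1]), leaf_order(tree$merge[node, 2]))
  }
  structure(list(merge = tree$merge, height = tree$merge_dist,
                 order = leaf_order(n - 1L), labels = tree$labels,
                 method = "average", call = match.call(),
                 dist.method = "jaccard"),
            class = "hclust")
}

#' Cut a dendrogram into k groups
#'
#' @param tree an `rflp_dendrogram`.
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cut_groups <- function(tree, k) stats::cutree(as_hclust(tree), k = k)

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the merge distance at which leaves i and j first share
#' a cluster (= twice the ultrametric node height).
#'
#' @param tree an `rflp_dendrogram`.
#' @return symmetric labelled matrix.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "rflp_dendrogram"))
  n <- length(tree$labels)
  cm <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  leaves <- function(node) if (node < 0L) -node else
    c(leaves(tree$merge[node, 1]), leaves(tree$merge[node, 2]))
  for (step in seq_len(n - 1L)) {
    a <- leaves(tree$merge[step, 1])
    b <- leaves(tree$merge[step, 2])
    cm[a, b] <- tree$merge_dist[step]
    cm[b, a] <- tree$merge_dist[step]
  }
  cm
}

.newick_label <- function(x) {
  if (grepl("[\\s()\\[\\]:;,']", x, perl = TRUE))
    paste0("'", gsub("'", "''", x), "'") else x
}

.format_bl <- function(x) format(x, digits = 10, scientific = FALSE,
                                 trim = TRUE)

#' Serialize a dendrogram to a newick string
#'
#' Branch lengths are parent height minus child height (leaves have
#' height 0), so root-to-leaf path lengths all equal the root height
#' (ultrametric tree).
#'
#' @param tree an `rflp_dendrogram`.
#' @return newick string terminated by ";".
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "rflp_dendrogram"))
  h <- tree$node_height
  render <- function(node, parent_h) {
    if (node < 0L) {
      lab <- .newick_label(tree$labels[-node])
      return(paste0(lab, ":", .format_bl(parent_h)))
    }
    kids <- vapply(tree$merge[node, ], render, character(1),
                   parent_h = h[node])
    inner <- paste0("(", paste(kids, collapse = ","), ")")
    if (is.na(parent_h)) inner else
      paste0(inner, ":", .format_bl(parent_h - h[node]))
  }
  paste0(render(length(h), NA_real_), ";")
}

#' Write a dendrogram to a newick file
#'
#' @param tree an `rflp_dendrogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(to_newick(tree), path)
  invisible(path)
}
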