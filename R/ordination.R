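# PCA of binary RFLP profiles and Mandel's h / k consistency statistics.

#' Principal component analysis of a profile matrix
#'
#' Columns are mean-centered but not variance-scaled (binary features
#' share a scale); the decomposition is by singular values of the centered
#' matrix. Sign convention: within each component, the loading with the
#' largest absolute value is made positive, so output is reproducible
#' across SVD implementations.
#'
#' @param x numeric matrix, strains x features.
#' @param n_components number of components to keep (default
#'   `min(nrow(x) - 1, ncol(x))`).
#' @return an `rflp_pca`: list with `scores` (strains x components),
#'   `loadings` (features x components, orthonormal columns) and
#'   `explained` (fraction of total variance per component,
#'   non-increasing).
#' @export
rflp_pca <- function(x, n_components = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components < 1L || n_components > max_comp)
    stop("n_components must be in [1, ", max_comp, "]")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  total <- sum(sv$d^2)
  if (total < 1e-12) stop("zero total variance: all rows identical")
  keep <- seq_len(n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  scores <- xc %*% loadings
  # deterministic sign: largest-|loading| entry positive per component
  for (j in keep) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(x), paste0("PC", keep))
  dimnames(loadings) <- list(colnames(x), paste0("PC", keep))
  out <- list(scores = scores, loadings = loadings,
              explained = sv$d[keep]^2 / total)
  class(out) <- "rflp_pca"
  out
}

#' Mandel's h statistic
#'
#' Standardized deviation of each group mean from the grand mean:
#' h_i = (x_i - x..) / s, where x.. is the mean of group means and s their
#' standard deviation (divisor p - 1). Always sums to zero and is bounded
#' by (p - 1) / sqrt(p) in absolute value.
#'
#' @param group_means numeric vector of p >= 3 group means.
#' @return numeric vector h_1..h_p.
#' @export
mandel_h <- function(group_means) {
  p <- length(group_means)
  if (p < 3L) stop("need at least 3 groups")
  s <- stats::sd(group_means)
  if (s == 0) stop("zero between-group variance")
  (group_means - mean(group_means)) / s
}

#' Mandel's k statistic
#'
#' Ratio of each group's standard deviation to the pooled (root mean
#' square) standard deviation: k_i = s_i / sbar with
#' sbar = sqrt(mean(s_i^2)). Satisfies sum(k_i^2) = p.
#'
#' @param group_sds numeric vector of p >= 2 group standard deviations.
#' @return numeric vector k_1..k_p.
#' @export
mandel_k <- function(group_sds) {
  p <- length(group_sds)
  if (p < 2L) stop("need at least 2 groups")
  if (any(group_sds < 0)) stop("negative standard deviation")
  sbar <- sqrt(mean(group_sds^2))
  if (sbar == 0) stop("all group standard deviations are zero")
  group_sds / sbar
}

#' Critical value for Mandel's h
#'
#' Per-group two-sided critical value at significance alpha under a
#' normal null: h_crit = (p - 1) t / sqrt(p (p - 2 + t^2)) with t the
#' Student quantile at 1 - alpha/2 on p - 2 degrees of freedom
#' (Wilrich / ISO 5725 form). Always below the algebraic bound
#' (p - 1)/sqrt(p).
#'
#' @param p number of groups (>= 3).
#' @param alpha significance level in (0, 1).
#' @return critical value.
#' @export
h_crit <- function(p, alpha = 0.05) {
  if (p < 3L) stop("need at least 3 groups")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  t <- stats::qt(1 - alpha / 2, df = p - 2)
  (p - 1) * t / sqrt(p * (p - 2 + t^2))
}

#' Critical value for Mandel's k
#'
#' k_crit = sqrt(p / (1 + (p - 1)/F)) with F the upper-alpha quantile of
#' the F distribution on (n - 1) and (p - 1)(n - 1) degrees of freedom,
#' for a balanced design of p groups with n replicates each. Always below
#' sqrt(p).
#'
#' @param p number of groups (>= 2).
#' @param n replicates per group (>= 2).
#' @param alpha significance level in (0, 1).
#' @return critical value.
#' @export
k_crit <- function(p, n, alpha = 0.05) {
  if (p < 2L || n < 2L) stop("need p >= 2 groups and n >= 2 replicates")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  f <- stats::qf(1 - alpha, df1 = n - 1, df2 = (p - 1) * (n - 1))
  sqrt(p / (1 + (p - 1) / f))
}

#' Mandel consistency report for grouped replicate observations
#'
#' Computes per-group means and standard deviations, h and k statistics,
#' critical values at level alpha, and flags groups exceeding them.
#' k_crit assumes a balanced design; with unequal replicate counts it is
#' omitted with a warning.
#'
#' @param observations list of numeric vectors (one per group, each with
#'   >= 2 replicates) or a groups x replicates matrix.
#' @param alpha significance level (default 0.05).
#' @return a `mandel_report`: list with `stats` (data.frame: group, n,
#'   mean, sd, h, k, h_flag, k_flag), `grand_mean`, `between_sd`,
#'   `pooled_sd`, `h_crit`, `k_crit` (NA when unbalanced), `alpha`.
#' @export
mandel_report <- function(observations, alpha = 0.05) {
  if (is.matrix(observations))
    observations <- split(observations, row(observations))
  p <- length(observations)
  if (p < 3L) stop("need at least 3 groups")
  ns <- lengths(observations)
  if (any(ns < 2L)) stop("every group needs >= 2 replicates")
  grp <- names(observations)
  if (is.null(grp)) grp <- paste0("group", seq_len(p))
  means <- vapply(observations, mean, numeric(1))
  sds <- vapply(observations, stats::sd, numeric(1))
  h <- mandel_h(means)
  k <- mandel_k(sds)
  hc <- h_crit(p, alpha)
  balanced <- length(unique(ns)) == 1L
  if (balanced) {
    kc <- k_crit(p, ns[1], alpha)
  } else {
    warning("unbalanced design: k_crit omitted")
    kc <- NA_real_
  }
  stopifnot(abs(sum(h)) < 1e-9, abs(sum(k^2) - p) < 1e-9,
            all(abs(h) <= (p - 1) / sqrt(p) + 1e-12))
  out <- list(
    stats = data.frame(group = grp, n = as.integer(ns), mean = means,
                       sd = sds, h = h, k = k,
                       h_flag = abs(h) > hc,
                       k_flag = if (balanced) k > kc else NA,
                       row.names = NULL, stringsAsFactors = FALSE),
    grand_mean = mean(means), between_sd = stats::sd(means),
    pooled_sd = sqrt(mean(sds^2)), h_crit = hc, k_crit = kc,
    alpha = alpha)
  class(out) <- "mandel_report"
  out
}

#' @export
print.mandel_report <- function(x, ...) {
  cat(sprintf("Mandel consistency report (p = %d groups, alpha = %g)\n",
              nrow(x$stats), x$alpha))
  cat(sprintf("h_crit = %.4f  k_crit = %s\n", x$h_crit,
              ifelse(is.na(x$k_crit), "NA (unbalanced)",
                     sprintf("%.4f", x$k_crit))))
  print(x$stats, digits = 4)
  invisible(x)
}
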