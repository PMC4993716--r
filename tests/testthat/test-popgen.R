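# Complete deletion, polymorphism summaries, between-group diversity,
# four-gamete Rm.

test_that("complete_deletion keeps only unambiguous columns", {
  expect_equal(complete_deletion(make_aln(c("A-C", "AAC", "ATC")))$included,
               c(1L, 3L))
  expect_equal(complete_deletion(make_aln(c("ANC", "AAC")))$included,
               c(1L, 3L))
  aln <- make_aln(c("ACGT", "ACGA"))
  expect_equal(complete_deletion(aln)$included, 1:4)
  expect_error(complete_deletion(make_aln(c("A-", "-A"))),
               "every column")
})

test_that("popgen_summary matches hand-computed toy alignments", {
  s <- popgen_summary(make_aln(c("AAA", "AAT", "ATT")))
  expect_equal(s$L, 3L)
  expect_equal(s$S, 2L)
  expect_equal(s$eta, 2L)
  expect_equal(s$singleton_sites, 2L)
  expect_equal(s$parsimony_informative_sites, 0L)
  expect_equal(s$n_haplotypes, 3L)
  expect_equal(s$haplotype_diversity, 1)
  expect_equal(s$avg_pairwise_differences, 4 / 3)
  expect_equal(s$nucleotide_diversity, 4 / 9)
  expect_equal(s$Rm, 0L)

  s2 <- popgen_summary(make_aln(c("AAT", "AAT", "ATA", "ATA")))
  expect_equal(s2$S, 2L)
  expect_equal(s2$parsimony_informative_sites, 2L)
  expect_equal(s2$singleton_sites, 0L)
  expect_equal(s2$n_haplotypes, 2L)
  expect_equal(s2$haplotype_diversity, 2 / 3)
  expect_equal(s2$avg_pairwise_differences, 4 / 3)

  s3 <- popgen_summary(make_aln(rep("ACGT", 4)))
  expect_equal(s3$S, 0L)
  expect_equal(s3$eta, 0L)
  expect_equal(s3$n_haplotypes, 1L)
  expect_equal(s3$haplotype_diversity, 0)
  expect_equal(s3$avg_pairwise_differences, 0)
  expect_equal(s3$Rm, 0L)
})

test_that("three-state singleton columns count as neither singleton nor PIS", {
  # column 2 has states A/C/G with two singletons (DnaSP convention)
  s <- popgen_summary(make_aln(c("AAA", "ACA", "AGA", "AAA")))
  expect_equal(s$S, 1L)
  expect_equal(s$eta, 2L)
  expect_equal(s$singleton_sites, 0L)
  expect_equal(s$parsimony_informative_sites, 0L)
})

test_that("summary identities hold on random alignments", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    L <- sample(20:60, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * L,
                       replace = TRUE, prob = c(rep(0.23, 4), 0.04, 0.04)),
                n, L)
    residues <- apply(m, 1, paste, collapse = "")
    aln <- tryCatch(make_aln(residues), error = function(e) NULL)
    if (is.null(aln)) next
    filt <- tryCatch(complete_deletion(aln), error = function(e) NULL)
    if (is.null(filt)) next
    s <- popgen_summary(aln, filt)
    expect_equal(s$monomorphic_sites + s$S, s$L)
    expect_lte(s$S, s$eta)
    expect_lte(s$singleton_sites + s$parsimony_informative_sites, s$S)
    expect_gte(s$haplotype_diversity, 0)
    expect_lte(s$haplotype_diversity, 1)
    # k / Pi = L exactly (the identity the headline numbers satisfy)
    expect_equal(s$nucleotide_diversity * s$L,
                 s$avg_pairwise_differences, tolerance = 1e-9)
  }
})

test_that("between_groups averages cross-group differences", {
  aln <- make_aln(c("AAA", "AAT", "ATT"), ids = c("x1", "y1", "y2"))
  ga <- group_assignment(c("x1", "y1", "y2"), c("X", "Y", "Y"))
  bg <- between_groups(aln, ga, c("X", "Y"))
  expect_equal(bg$k_between, 1.5)
  expect_gte(bg$eta_union, 0)

  # member-wise identical groups have zero between-group distance
  aln2 <- make_aln(c("ACGT", "ACGT"), ids = c("a1", "b1"))
  ga2 <- group_assignment(c("a1", "b1"), c("A", "B"))
  expect_equal(between_groups(aln2, ga2, c("A", "B"))$k_between, 0)

  expect_error(between_groups(aln, ga, c("X", "Z")), "unknown group")
})

test_that("eta over pooled groups dominates each group's eta", {
  set.seed(42)
  for (i in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T"), 6 * 30, replace = TRUE),
                6, 30)
    residues <- apply(m, 1, paste, collapse = "")
    ids <- sprintf("s%d", 1:6)
    aln <- make_aln(residues, ids)
    ga <- group_assignment(ids, rep(c("X", "Y"), each = 3))
    filt <- complete_deletion(aln)
    bg <- between_groups(aln, ga, c("X", "Y"), filt)
    eta_of <- function(rows) {
      sub <- make_aln(residues[rows], ids[rows])
      popgen_summary(sub, filt)$eta
    }
    expect_gte(bg$eta_union, eta_of(1:3))
    expect_gte(bg$eta_union, eta_of(4:6))
  }
})

test_that("four-gamete Rm matches examples and the DP oracle", {
  m4 <- do.call(rbind, strsplit(c("AA", "AT", "TA", "TT"), ""))
  expect_equal(four_gamete_rm(m4), 1L)
  m3 <- do.call(rbind, strsplit(c("AA", "AT", "TT"), ""))
  expect_equal(four_gamete_rm(m3), 0L)
  expect_equal(four_gamete_rm(matrix("A", 2, 1)), 0L)

  set.seed(43)
  for (i in 1:30) {
    m <- matrix(sample(c(0L, 1L), 8 * 20, replace = TRUE), 8, 20)
    # oracle: conflicting pairs found independently, counted by DP
    ivl <- list()
    for (a in 1:19) for (b in (a + 1):20) {
      pats <- unique(m[, c(a, b), drop = FALSE])
      if (nrow(pats) == 4L) ivl[[length(ivl) + 1L]] <- c(a, b)
    }
    expect_equal(four_gamete_rm(m), oracle_max_disjoint(ivl))
  }
})
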