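# Synthetic alignment generator: determinism, planted-site truth,
# divergence calibration.

test_that("config validation catches inconsistent worlds", {
  expect_error(synth_config(seed = 1, d_within = 0.4, d_between = 0.2),
               "d_within <= d_between")
  expect_error(synth_config(seed = 1, d_between = 0.9), "0.75")
  expect_error(synth_config(
    seed = 1, planted_sites = list(
      list(enzyme = "HaeIII", position = 500, groups = "pseudomonas"))),
    "exceeds alignment length")
  expect_error(synth_config(
    seed = 1, planted_sites = list(
      list(enzyme = "HaeIII", position = 50, groups = "pseudomonas"),
      list(enzyme = "AluI", position = 52, groups = "pseudomonas"))),
    "overlap")
  expect_error(synth_config(
    seed = 1, knockouts = list(list(enzyme = "AluI", group = "pseudomonas"))),
    "without a planted site")
})

test_that("defaults reproduce the stated world", {
  ds <- synth_generate(synth_config(seed = 5))
  expect_equal(attr(ds$alignment, "length"), 458L)
  expect_equal(nrow(ds$alignment), 19L)
  expect_equal(length(ds$groups$groups), 3L)
  # generated alignments pass the package's own validation round trip
  f <- tempfile(fileext = ".fasta")
  write_fasta(ds$alignment, f)
  back <- read_aligned(f)
  expect_equal(back$residues, ds$alignment$residues)
  expect_true(check_groups(ds$groups, ds$alignment))
})

test_that("identical seed gives byte-identical output", {
  cfg <- synth_config(seed = 99)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(synth_generate(cfg)$alignment, f1)
  write_fasta(synth_generate(cfg)$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero divergence yields identical sequences", {
  ds <- synth_generate(synth_config(seed = 3, d_within = 0, d_between = 0,
                                    gap_columns = 0,
                                    ambiguous_columns = 0))
  expect_equal(length(unique(ds$alignment$residues)), 1L)
  s <- popgen_summary(ds$alignment)
  expect_equal(s$S, 0L)
  expect_equal(s$n_haplotypes, 1L)
})

test_that("planted sites and knockouts are exactly reflected in profiles", {
  # site planted in all groups, no mutation: column all 1
  cfg <- synth_config(seed = 7, d_within = 0, d_between = 0,
                      gap_columns = 0, ambiguous_columns = 0,
                      planted_sites = list(
                        list(enzyme = "HaeIII", position = 50,
                             groups = c("pseudomonas", "proteobacteria",
                                        "actinobacteria"))))
  ds <- synth_generate(cfg)
  m <- site_matrix(ds$alignment, default_enzymes()["HaeIII"])
  expect_true(all(m[, "HaeIII"] == 1L))
  expect_true(all(ds$truth[, "HaeIII"] == 1L))

  # knockout removes the site from one group only
  cfg2 <- synth_config(seed = 8,
                       planted_sites = list(
                         list(enzyme = "AluI", position = 100,
                              groups = c("pseudomonas", "proteobacteria",
                                         "actinobacteria"))),
                       knockouts = list(
                         list(enzyme = "AluI", group = "proteobacteria")))
  ds2 <- synth_generate(cfg2)
  m2 <- site_matrix(ds2$alignment, default_enzymes()["AluI"])
  grp <- ds2$groups$mapping[rownames(m2)]
  expect_true(all(m2[grp != "proteobacteria", "AluI"] == 1L))
  expect_true(all(m2[grp == "proteobacteria", "AluI"] == 0L))
  # the truth table is the regex-verifiable expectation
  expect_equal(unname(m2[, "AluI"]), unname(ds2$truth[rownames(m2), "AluI"]))
  for (i in seq_len(nrow(ds2$alignment))) {
    hits <- oracle_find_sites(strip_gaps(ds2$alignment$residues[i]), "AGCT")
    expect_equal(length(hits) > 0,
                 ds2$truth[ds2$alignment$id[i], "AluI"] == 1L)
  }
})

test_that("within-group divergence matches the generator's model", {
  # P(two siblings differ at a site) = 2 d (1 - d) + (2/3) d^2
  d_w <- 0.01
  expected <- 2 * d_w * (1 - d_w) + (2 / 3) * d_w^2
  per_seed <- vapply(1:50, function(seed) {
    ds <- synth_generate(synth_config(seed = seed, d_within = d_w,
                                      gap_columns = 0,
                                      ambiguous_columns = 0))
    m <- do.call(rbind, strsplit(ds$alignment$residues, ""))
    g <- unname(ds$groups$mapping[ds$alignment$id])
    diffs <- c()
    for (grp in unique(g)) {
      idx <- which(g == grp)
      for (a in idx[-length(idx)]) for (b in idx[idx > a])
        diffs <- c(diffs, mean(m[a, ] != m[b, ]))
    }
    mean(diffs)
  }, numeric(1))
  se <- stats::sd(per_seed) / sqrt(length(per_seed))
  expect_lt(abs(mean(per_seed) - expected), 3 * se)
})

test_that("the bundled ribotype matrix has the published structure", {
  m <- example_site_profiles()
  expect_equal(dim(m), c(19L, 10L))
  expect_true(all(m %in% c(0L, 1L)))
  expect_true(all(m[, "HaeIII"] == 1L))
  expect_true(all(m[, "HhaI"] == 1L))
  expect_true(all(m[, "RsaI"] == 1L))
  expect_equal(unname(m["p", ]), c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 0L))
})
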