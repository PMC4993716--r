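# Enzyme compilation, degenerate site scanning, digestion, profile
# matrices.

test_that("compile_enzyme parses sites with cut marks", {
  alu <- compile_enzyme("AluI", "AG'CT")
  expect_equal(alu$recognition, "AGCT")
  expect_equal(alu$cut_offset, 2L)

  mbo <- compile_enzyme("MboI", "'GATC")
  expect_equal(mbo$recognition, "GATC")
  expect_equal(mbo$cut_offset, 0L)

  # typographic apostrophe accepted
  expect_equal(compile_enzyme("HhaI", "GCG’C")$cut_offset, 3L)

  expect_error(compile_enzyme("X", "AGCT"), "cut mark")
  expect_error(compile_enzyme("X", "A''GCT"), "cut mark")
  expect_error(compile_enzyme("X", "AG'CZ"), "non-IUPAC")
})

test_that("the packaged enzyme table equals the built-in registry", {
  f <- system.file("extdata", "enzymes_16s_panel.tsv",
                   package = "rflptools")
  tab <- read_enzyme_table(f)
  builtin <- default_enzymes()
  expect_equal(names(tab), names(builtin))
  for (n in names(tab)) {
    expect_equal(tab[[n]]$recognition, builtin[[n]]$recognition)
    expect_equal(tab[[n]]$cut_offset, builtin[[n]]$cut_offset)
  }
})

test_that("the ten built-in enzymes are palindromic", {
  enz <- default_enzymes()
  expect_length(enz, 10L)
  expect_true(all(vapply(enz, is_palindromic, logical(1))))
  # and a non-palindromic user enzyme warns
  expect_warning(compile_enzyme("FokI", "GGATG'"), "non-palindromic")
})

test_that("find_sites applies the subset matching rule", {
  alu <- compile_enzyme("AluI", "AG'CT")
  dde <- compile_enzyme("DdeI", "C'TNAG")
  hinf <- compile_enzyme("HinfI", "G'ANTC")
  expect_equal(find_sites("AAGCTA", alu), 2L)
  expect_equal(find_sites("CTTAGCTGAG", dde), c(1L, 6L))
  # recognition N accepts any sequence symbol, even N
  expect_equal(find_sites("GANTC", hinf), 1L)
  # sequence N never certifies a specific-base position
  expect_equal(find_sites("AGNTC", alu), integer(0))
  expect_equal(find_sites("AG", alu), integer(0))
  # gapped input is the caller's bug
  expect_error(find_sites("AG-CT", alu), "gap")
})

test_that("digest produces cut points and a partitioning fragment set", {
  alu <- compile_enzyme("AluI", "AG'CT")
  d <- digest("AAGCTA", alu)
  expect_equal(d$cut_points, 3L)
  expect_equal(d$fragments$length, c(3L, 3L))

  expect_equal(digest("TTTT", alu)$fragments$length, 4L)

  dde <- compile_enzyme("DdeI", "C'TNAG")
  d2 <- digest("CTTAGCTGAG", dde)
  expect_equal(d2$cut_points, c(1L, 6L))
  expect_equal(d2$fragments$length, c(1L, 5L, 4L))

  # cuts at the sequence boundary create no empty fragment
  mbo <- compile_enzyme("MboI", "'GATC")
  d3 <- digest("GATCA", mbo)
  expect_equal(d3$fragments$length, 5L)
  expect_error(digest("", alu), "empty")
})

test_that("site scan matches the regex oracle on random sequences", {
  set.seed(7)
  enz <- default_enzymes()
  for (i in 1:100) {
    s <- random_dna(sample(200:800, 1))
    for (e in enz) {
      expect_identical(find_sites(s, e),
                       oracle_find_sites(s, e$recognition))
    }
  }
})

test_that("fragment lengths always sum to the ungapped length", {
  set.seed(8)
  enz <- default_enzymes()
  for (i in 1:25) {
    s <- random_dna(sample(200:1500, 1))
    for (e in enz) {
      d <- digest(s, e)
      expect_equal(sum(d$fragments$length), nchar(s))
      expect_equal(nrow(d$fragments), length(d$cut_points) + 1L)
    }
  }
})

test_that("reverse-complement scanning mirrors the site set", {
  set.seed(9)
  for (e in default_enzymes()) {
    s <- random_dna(600)
    rc <- reverse_complement(s)
    L <- nchar(e$recognition)
    mirrored <- sort(nchar(s) - L + 2L - find_sites(s, e))
    expect_equal(find_sites(rc, e), mirrored)
  }
})

test_that("adding a recognition substring never decreases the site count", {
  set.seed(10)
  for (e in default_enzymes()) {
    site <- gsub("N", "A", e$recognition)  # one concrete realization
    if (length(oracle_find_sites(site, e$recognition)) == 0L)
      site <- gsub("N", "T", e$recognition)
    for (i in 1:5) {
      s <- random_dna(300)
      pos <- sample(300 - nchar(site), 1)
      s2 <- paste0(substr(s, 1, pos), site,
                   substr(s, pos + 1, nchar(s)))
      expect_gte(length(find_sites(s2, e)), length(find_sites(s, e)))
    }
  }
})

test_that("site_matrix records presence, not count, and strips gaps", {
  enz <- default_enzymes()[c("AluI", "HaeIII")]
  seqs <- data.frame(id = c("x", "y", "z"), description = "",
                     residues = c("AAGCTA", "GGCCGGCC", "AG-CT"))
  m <- site_matrix(seqs, enz)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["x", ], c(AluI = 1L, HaeIII = 0L))
  expect_equal(m["y", ], c(AluI = 0L, HaeIII = 1L))  # two sites, one bit
  expect_equal(m["z", "AluI"], 1L)  # gap stripped before scanning
})

test_that("band_matrix bins fragment lengths per enzyme", {
  alu <- default_enzymes()["AluI"]
  seqs <- data.frame(id = c("s1", "s2"), description = "",
                     residues = c("AAGCTA", "TTTTTT"))
  bm <- band_matrix(digest_set(seqs, alu), tolerance = 0)
  expect_equal(sort(colnames(bm)), c("AluI:3", "AluI:6"))
  expect_equal(unname(bm["s1", c("AluI:3", "AluI:6")]), c(1L, 0L))
  expect_equal(unname(bm["s2", c("AluI:3", "AluI:6")]), c(0L, 1L))

  # identical digests give identical rows
  seqs2 <- data.frame(id = c("a", "b"), description = "",
                      residues = c("AAGCTA", "AAGCTA"))
  bm2 <- band_matrix(digest_set(seqs2, alu))
  expect_equal(bm2["a", ], bm2["b", ])

  expect_error(band_matrix(digest_set(seqs, alu), tolerance = -1),
               ">= 0")
})

test_that("band binning merges lengths within relative tolerance", {
  # lengths 100+101 = 201 vs 99+102: single linkage at 0.02 merges
  # 99,100,101,102 into one bin per side of the cut
  hae <- default_enzymes()["HaeIII"]
  at <- function(n) paste(rep(c("A", "T"), length.out = n), collapse = "")
  seqs <- data.frame(id = c("u", "v"), description = "",
                     residues = c(paste0(at(98), "GGCC", at(99)),
                                  paste0(at(99), "GGCC", at(98))))
  ds <- digest_set(seqs, hae)
  exact <- band_matrix(ds, tolerance = 0)
  merged <- band_matrix(ds, tolerance = 0.02)
  expect_gt(ncol(exact), ncol(merged))
  expect_true(all(merged == 1L))
})

test_that("otu_counts equals cut count + 1", {
  set.seed(11)
  enz <- default_enzymes()
  seqs <- data.frame(id = c("s1", "s2"), description = "",
                     residues = c(random_dna(400), random_dna(400)))
  counts <- otu_counts(digest_set(seqs, enz))
  for (r in seq_len(nrow(counts))) {
    e <- enz[[counts$enzyme[r]]]
    s <- seqs$residues[seqs$id == counts$strain[r]]
    oracle_cuts <- unique(oracle_find_sites(s, e$recognition) - 1L +
                            e$cut_offset)
    oracle_cuts <- oracle_cuts[oracle_cuts > 0 & oracle_cuts < nchar(s)]
    expect_equal(counts$fragments[r], length(oracle_cuts) + 1L)
  }
})
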