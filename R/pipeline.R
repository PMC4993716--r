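# End-to-end orchestration: digestion -> RFLP matrices -> Jaccard/UPGMA
# -> PCA -> Mandel -> polymorphism summaries, with a file-based CLI.

.write_sign_matrix <- function(m, path, signs = FALSE) {
  if (signs) {
    ch <- ifelse(m == 1, "+", "-")
    dimnames(ch) <- dimnames(m)
    write_matrix_tsv_char(ch, path)
  } else write_matrix_tsv(m, path)
}

write_matrix_tsv_char <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full virtual-RFLP analysis
#'
#' Accepts either an alignment (full pipeline: digestion, site and band
#' matrices, Jaccard/UPGMA, PCA, Mandel consistency, polymorphism
#' statistics) or a ready-made binary profile matrix ("matrix-only" mode:
#' similarity, UPGMA and PCA only). All outputs are plain text in
#' `out_dir`; a run log records parameters.
#'
#' @param alignment an `aligned_set`, or path to an aligned FASTA.
#' @param profiles binary matrix (or TSV path) used instead of an
#'   alignment; ignored when `alignment` is given.
#' @param groups a `group_assignment` or path to a group-map TSV
#'   (optional; enables Mandel and between-group statistics).
#' @param enzymes named list of `restriction_enzyme`
#'   (default [default_enzymes()]).
#' @param profile_level which profile feeds similarity/PCA in alignment
#'   mode: "band" (default, virtual-gel bands) or "site".
#' @param band_tolerance relative fragment-length tolerance for band
#'   binning (default 0).
#' @param n_components PCA components (default 2).
#' @param alpha significance level for Mandel critical values.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the computed objects and file paths.
#' @export
run_rflp_pipeline <- function(alignment = NULL, profiles = NULL,
                              groups = NULL,
                              enzymes = default_enzymes(),
                              profile_level = c("band", "site"),
                              band_tolerance = 0, n_components = 2L,
                              alpha = 0.05, out_dir) {
  profile_level <- match.arg(profile_level)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("rflptools %s",
                         as.character(utils::packageVersion("rflptools"))),
                 sprintf("date: %s", format(Sys.time(), "%Y-%m-%d")),
                 sprintf("profile_level: %s", profile_level),
                 sprintf("band_tolerance: %g", band_tolerance),
                 sprintf("n_components: %d", n_components),
                 sprintf("alpha: %g", alpha))
  paths <- list()
  out <- list()

  if (is.character(groups)) groups <- read_group_map(groups)
  if (is.character(alignment)) alignment <- read_aligned(alignment)
  if (is.character(profiles)) {
    profiles <- read_matrix_tsv(profiles)
    storage.mode(profiles) <- "integer"
  }
  if (is.null(alignment) && is.null(profiles))
    stop("stage input: provide an alignment or a profile matrix")

  if (!is.null(alignment)) {
    if (!is.null(groups)) check_groups(groups, alignment)
    digests <- digest_set(alignment, enzymes)
    out$site_matrix <- site_matrix(alignment, enzymes)
    out$band_matrix <- band_matrix(digests, tolerance = band_tolerance)
    out$fragments <- fragment_table(digests)
    out$otu_counts <- otu_counts(digests)
    paths$site_matrix <- file.path(out_dir, "site_matrix.tsv")
    write_matrix_tsv(out$site_matrix, paths$site_matrix)
    paths$band_matrix <- file.path(out_dir, "band_matrix.tsv")
    write_matrix_tsv(out$band_matrix, paths$band_matrix)
    paths$fragments <- file.path(out_dir, "fragments.tsv")
    utils::write.table(out$fragments, paths$fragments, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    profiles <- if (profile_level == "band") out$band_matrix else
      out$site_matrix
  }

  # similarity -> distance -> UPGMA
  out$similarity <- pairwise_similarity(profiles)
  out$tree <- upgma(to_distance(out$similarity))
  paths$similarity <- file.path(out_dir, "similarity.tsv")
  write_matrix_tsv(out$similarity, paths$similarity)
  paths$tree <- file.path(out_dir, "upgma.nwk")
  write_newick(out$tree, paths$tree)

  # PCA (guard: degenerate all-identical profiles)
  nc <- min(n_components, nrow(profiles) - 1L, ncol(profiles))
  out$pca <- tryCatch(rflp_pca(profiles, nc), error = function(e) {
    log_lines <<- c(log_lines, paste("pca skipped:", conditionMessage(e)))
    NULL
  })
  if (!is.null(out$pca)) {
    paths$pca <- file.path(out_dir, "pca_scores.tsv")
    hdr <- paste0("# explained_variance_fraction: ",
                  paste(signif(out$pca$explained, 6), collapse = "\t"))
    writeLines(hdr, paths$pca)
    suppressWarnings(utils::write.table(
      data.frame(strain = rownames(out$pca$scores), out$pca$scores,
                 check.names = FALSE),
      paths$pca, sep = "\t", quote = FALSE, row.names = FALSE,
      append = TRUE))
  }

  # Mandel consistency on per-enzyme mean fragment counts per group
  if (!is.null(alignment) && !is.null(groups) &&
      length(groups$groups) >= 3L) {
    counts <- out$otu_counts
    counts$group <- groups$mapping[counts$strain]
    obs <- lapply(groups$groups, function(g) {
      sub <- counts[counts$group == g, ]
      tapply(sub$fragments, sub$enzyme, mean)
    })
    names(obs) <- groups$groups
    out$mandel <- tryCatch(mandel_report(obs, alpha = alpha),
                           error = function(e) {
                             log_lines <<- c(log_lines,
                                             paste("mandel skipped:",
                                                   conditionMessage(e)))
                             NULL
                           })
    if (!is.null(out$mandel)) {
      paths$mandel <- file.path(out_dir, "mandel.tsv")
      utils::write.table(out$mandel$stats, paths$mandel, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  # polymorphism statistics
  if (!is.null(alignment)) {
    filt <- complete_deletion(alignment)
    out$popgen <- popgen_summary(alignment, filt)
    report <- unclass(out$popgen)
    if (!is.null(groups)) {
      per_group <- list()
      for (g in groups$groups) {
        ids <- intersect(names(groups$mapping)[groups$mapping == g],
                         alignment$id)
        if (length(ids) < 2L) next
        sub <- alignment[alignment$id %in% ids, ]
        sub <- as_aligned_set(sub)
        per_group[[g]] <- unclass(popgen_summary(sub, filt))
      }
      report$per_group <- per_group
      pairs <- utils::combn(groups$groups, 2, simplify = FALSE)
      report$between_groups <- lapply(pairs, function(pr)
        between_groups(alignment, groups, pr, filt))
    }
    paths$popgen <- file.path(out_dir, "popgen.json")
    jsonlite::write_json(report, paths$popgen, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  paths$log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, paths$log)
  invisible(c(out, list(paths = paths)))
}

.cli_args <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

.flag <- function(flags, name, default = NULL, required = FALSE) {
  if (!is.null(flags[[name]])) return(flags[[name]])
  if (required) stop("missing required flag --", name)
  default
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `digest`, `matrix`, `cluster`, `pca`,
#' `mandel`, `popgen`, `all`. Run with no arguments for usage. Designed
#' to be called from the `exec/rflp` script but equally usable in R for
#' testing.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return 0 invisibly on success; stops with an error message naming the
#'   failing stage otherwise.
#' @export
rflp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rflp <subcommand> [--flags]",
    "  simulate --seed N --out DIR [--length L] [--d-within X]",
    "           [--d-between Y] [--gap-columns G]",
    "  digest   --aln FASTA --out DIR [--enzymes TSV] [--tolerance T]",
    "  matrix   --aln FASTA --out TSV [--enzymes TSV] [--signs]",
    "  cluster  --input MATRIX_TSV --out NWK [--similarity TSV]",
    "  pca      --input MATRIX_TSV --out TSV [--components K]",
    "  mandel   --aln FASTA --groups TSV --out TSV [--alpha A]",
    "  popgen   --aln FASTA --out JSON [--groups TSV] [--pair A,B]",
    "  all      (--aln FASTA | --matrix TSV) --out DIR [--groups TSV]",
    "           [--level band|site] [--tolerance T] [--alpha A]",
    sep = "\n")
  if (length(args) == 0L) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  flags <- .cli_args(args[-1])
  enzymes <- if (!is.null(flags$enzymes))
    read_enzyme_table(flags$enzymes) else default_enzymes()

  switch(cmd,
    simulate = {
      seed <- as.integer(.flag(flags, "seed", required = TRUE))
      outdir <- .flag(flags, "out", required = TRUE)
      cfg <- synth_config(
        seed = seed,
        length = as.integer(.flag(flags, "length", 458L)),
        d_within = as.numeric(.flag(flags, "d-within", 0.01)),
        d_between = as.numeric(.flag(flags, "d-between", 0.30)),
        gap_columns = as.integer(.flag(flags, "gap-columns", 10L)))
      ds <- synth_generate(cfg)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(ds$alignment, file.path(outdir, "aln.fasta"))
      write_group_map(ds$groups, file.path(outdir, "groups.tsv"))
      jsonlite::write_json(
        list(seed = seed, truth = if (is.null(ds$truth)) NULL else
          as.data.frame(ds$truth)),
        file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
      message("simulated alignment written to ", outdir)
    },
    digest = {
      aln <- read_aligned(.flag(flags, "aln", required = TRUE))
      outdir <- .flag(flags, "out", required = TRUE)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      dg <- digest_set(aln, enzymes)
      utils::write.table(fragment_table(dg),
                         file.path(outdir, "fragments.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(otu_counts(dg),
                         file.path(outdir, "otu_counts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_matrix_tsv(site_matrix(aln, enzymes),
                       file.path(outdir, "site_matrix.tsv"))
      tol <- as.numeric(.flag(flags, "tolerance", 0))
      write_matrix_tsv(band_matrix(dg, tolerance = tol),
                       file.path(outdir, "band_matrix.tsv"))
      message("digest outputs written to ", outdir)
    },
    matrix = {
      aln <- read_aligned(.flag(flags, "aln", required = TRUE))
      m <- site_matrix(aln, enzymes)
      .write_sign_matrix(m, .flag(flags, "out", required = TRUE),
                         signs = isTRUE(flags$signs))
    },
    cluster = {
      m <- read_matrix_tsv(.flag(flags, "input", required = TRUE))
      s <- pairwise_similarity(m)
      if (!is.null(flags$similarity)) write_matrix_tsv(s, flags$similarity)
      write_newick(upgma(to_distance(s)),
                   .flag(flags, "out", required = TRUE))
    },
    pca = {
      m <- read_matrix_tsv(.flag(flags, "input", required = TRUE))
      k <- as.integer(.flag(flags, "components",
                            min(nrow(m) - 1L, ncol(m))))
      p <- rflp_pca(m, k)
      outp <- .flag(flags, "out", required = TRUE)
      writeLines(paste0("# explained_variance_fraction: ",
                        paste(signif(p$explained, 6), collapse = "\t")),
                 outp)
      suppressWarnings(utils::write.table(
        data.frame(strain = rownames(p$scores), p$scores,
                   check.names = FALSE),
        outp, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    },
    mandel = {
      aln <- read_aligned(.flag(flags, "aln", required = TRUE))
      groups <- read_group_map(.flag(flags, "groups", required = TRUE))
      check_groups(groups, aln)
      dg <- digest_set(aln, enzymes)
      counts <- otu_counts(dg)
      counts$group <- groups$mapping[counts$strain]
      obs <- lapply(groups$groups, function(g) {
        sub <- counts[counts$group == g, ]
        tapply(sub$fragments, sub$enzyme, mean)
      })
      names(obs) <- groups$groups
      rep <- mandel_report(obs,
                           alpha = as.numeric(.flag(flags, "alpha", 0.05)))
      utils::write.table(rep$stats, .flag(flags, "out", required = TRUE),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    popgen = {
      aln <- read_aligned(.flag(flags, "aln", required = TRUE))
      filt <- complete_deletion(aln)
      report <- unclass(popgen_summary(aln, filt))
      if (!is.null(flags$pair)) {
        if (is.null(flags$groups))
          stop("--pair requires --groups (group map TSV)")
        groups <- read_group_map(flags$groups)
        check_groups(groups, aln)
        pr <- strsplit(flags$pair, ",", fixed = TRUE)[[1]]
        report$between <- between_groups(aln, groups, pr, filt)
      }
      jsonlite::write_json(report, .flag(flags, "out", required = TRUE),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    },
    all = {
      run_rflp_pipeline(
        alignment = flags$aln, profiles = flags$matrix,
        groups = flags$groups, enzymes = enzymes,
        profile_level = .flag(flags, "level", "band"),
        band_tolerance = as.numeric(.flag(flags, "tolerance", 0)),
        alpha = as.numeric(.flag(flags, "alpha", 0.05)),
        out_dir = .flag(flags, "out", required = TRUE))
    },
    stop("unknown subcommand '", cmd, "'\n", usage)
  )
  invisible(0L)
}
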