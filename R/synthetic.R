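# Seeded generator of group-structured aligned datasets.
#
# The stated world it emulates: ~19 sequences in 3 groups over a 458-column
# aligned 16S region, star topology within groups (one ancestor per group
# derived from a common uniform-random ancestor), independent per-site
# uniform substitution (Jukes-Cantor-like), alignment-artifact gap and
# ambiguity columns, and optional planting / knockout of restriction
# recognition sites with an exact per-strain truth table.

.BASES <- c("A", "C", "G", "T")

#' Configuration for the synthetic alignment generator
#'
#' @param seed integer RNG seed (mandatory; identical seed gives a
#'   byte-identical dataset).
#' @param length alignment columns (default 458).
#' @param groups named integer vector: group name -> member count
#'   (default 3 groups totalling 19: 4 pseudomonas isolates, 7 reference
#'   proteobacteria, 8 actinobacteria).
#' @param d_within per-site substitution probability from group ancestor
#'   to member (default 0.01).
#' @param d_between per-site substitution probability from the common
#'   ancestor to each group ancestor (default 0.30). Must satisfy
#'   0 <= d_within <= d_between <= 0.75.
#' @param gap_columns number of columns forced to contain a gap in at
#'   least one sequence (default 10).
#' @param ambiguous_columns number of columns forced to contain an N in at
#'   least one sequence (default 2).
#' @param planted_sites list of `list(enzyme =, position =, groups =)`
#'   entries: the enzyme's recognition sequence is written at that column
#'   into every member of the carrying groups. Sites must not overlap.
#' @param knockouts list of `list(enzyme =, group =)` entries: in that
#'   group, the planted site's middle base is substituted by a fixed
#'   non-matching base (chosen deterministically from the seed).
#' @param enzymes named list of `restriction_enzyme` used to resolve
#'   planted/knockout enzyme names (default [default_enzymes()]).
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(seed,
                         length = 458L,
                         groups = c(pseudomonas = 4L, proteobacteria = 7L,
                                    actinobacteria = 8L),
                         d_within = 0.01,
                         d_between = 0.30,
                         gap_columns = 10L,
                         ambiguous_columns = 2L,
                         planted_sites = list(),
                         knockouts = list(),
                         enzymes = default_enzymes()) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            length >= 1L, length(groups) >= 1L, all(groups >= 1L),
            !is.null(names(groups)), all(nzchar(names(groups))))
  if (!(0 <= d_within && d_within <= d_between && d_between <= 0.75))
    stop("require 0 <= d_within <= d_between <= 0.75")
  if (gap_columns < 0L || ambiguous_columns < 0L)
    stop("column counts must be >= 0")
  windows <- list()
  planted_sites <- lapply(planted_sites, function(ps) {
    ps$position <- as.integer(ps$position)
    ps
  })
  for (ps in planted_sites) {
    stopifnot(all(c("enzyme", "position", "groups") %in% names(ps)))
    enz <- enzymes[[ps$enzyme]]
    if (is.null(enz)) stop("unknown enzyme in planted_sites: ", ps$enzyme)
    w <- c(ps$position, ps$position + nchar(enz$recognition) - 1L)
    if (w[1] < 1L || w[2] > length)
      stop("planted site for ", ps$enzyme, " exceeds alignment length")
    for (prev in windows) {
      if (w[1] <= prev[2] && prev[1] <= w[2])
        stop("planted sites overlap")
    }
    windows[[length(windows) + 1L]] <- w
    bad <- setdiff(ps$groups, names(groups))
    if (length(bad) > 0L)
      stop("planted site references unknown group(s): ",
           paste(bad, collapse = ", "))
  }
  planted_enz <- vapply(planted_sites, `[[`, character(1), "enzyme")
  for (ko in knockouts) {
    stopifnot(all(c("enzyme", "group") %in% names(ko)))
    if (!(ko$enzyme %in% planted_enz))
      stop("knockout of ", ko$enzyme, " without a planted site")
    if (!(ko$group %in% names(groups)))
      stop("knockout references unknown group: ", ko$group)
  }
  out <- list(seed = as.integer(seed), length = as.integer(length),
              groups = groups, d_within = d_within, d_between = d_between,
              gap_columns = as.integer(gap_columns),
              ambiguous_columns = as.integer(ambiguous_columns),
              planted_sites = planted_sites, knockouts = knockouts,
              enzymes = enzymes)
  class(out) <- "synth_config"
  out
}

.mutate_sites <- function(chars, prob) {
  if (prob <= 0) return(chars)
  hit <- stats::runif(length(chars)) < prob
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(.BASES, b), 1L), character(1))
  }
  chars
}

# replace a degenerate recognition string by one concrete realization
.concretize <- function(recognition) {
  vapply(strsplit(recognition, "", fixed = TRUE)[[1]],
         function(sym) {
           opts <- .IUPAC_BASES[[sym]]
           if (length(opts) == 1L) opts else sample(opts, 1L)
         }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic group-structured alignment
#'
#' Draws a uniform-random ancestor, derives one ancestor per group by
#' mutating each site with probability `d_between`, derives members from
#' their group ancestor with probability `d_within`, then overwrites
#' planted recognition sites into carrying groups, applies knockouts, and
#' finally injects gap and ambiguity columns (outside planted windows).
#' For every enzyme involved in planting or knockout, accidental matches
#' elsewhere in a sequence are scrubbed (middle base substituted), so the
#' returned truth table is exact: presence 1 iff the strain's group
#' carries the planted, un-knocked-out site.
#'
#' @param config a `synth_config`.
#' @return a `synth_dataset`: list with `alignment` (an `aligned_set`),
#'   `groups` (a `group_assignment`) and `truth` (strains x planted
#'   enzymes 0/1 matrix, NULL when nothing is planted).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  L <- config$length
  ancestor <- sample(.BASES, L, replace = TRUE)
  group_names <- names(config$groups)
  ids <- character(0)
  id_group <- character(0)
  seqs <- list()
  for (g in group_names) {
    g_anc <- .mutate_sites(ancestor, config$d_between)
    for (i in seq_len(config$groups[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      ids <- c(ids, id)
      id_group <- c(id_group, g)
      seqs[[id]] <- .mutate_sites(g_anc, config$d_within)
    }
  }

  planted_windows <- integer(0)
  truth <- NULL
  touched <- character(0)
  if (length(config$planted_sites) > 0L) {
    ko_key <- vapply(config$knockouts,
                     function(ko) paste(ko$enzyme, ko$group), character(1))
    enz_names <- vapply(config$planted_sites, `[[`, character(1), "enzyme")
    truth <- matrix(0L, length(ids), length(enz_names),
                    dimnames = list(ids, enz_names))
    for (ps in config$planted_sites) {
      enz <- config$enzymes[[ps$enzyme]]
      site <- .concretize(enz$recognition)
      w <- ps$position:(ps$position + length(site) - 1L)
      planted_windows <- c(planted_windows, w)
      mid <- (length(site) + 1L) %/% 2L
      rec_sym <- strsplit(enz$recognition, "", fixed = TRUE)[[1]][mid]
      non_matching <- setdiff(.BASES, .IUPAC_BASES[[rec_sym]])
      ko_base <- if (length(non_matching) == 1L) non_matching else
        sample(non_matching, 1L)
      for (j in seq_along(ids)) {
        g <- id_group[j]
        if (!(g %in% ps$groups)) next
        seqs[[ids[j]]][w] <- site
        if (paste(ps$enzyme, g) %in% ko_key) {
          seqs[[ids[j]]][w[mid]] <- ko_base
        } else {
          truth[ids[j], ps$enzyme] <- 1L
        }
      }
    }
    touched <- unique(enz_names)
  }

  # scrub accidental matches of touched enzymes outside planted windows
  for (ename in touched) {
    enz <- config$enzymes[[ename]]
    span <- nchar(enz$recognition)
    planted_pos <- vapply(config$planted_sites, function(ps)
      if (ps$enzyme == ename) ps$position else NA_integer_, integer(1))
    planted_pos <- planted_pos[!is.na(planted_pos)]
    rec_syms <- strsplit(enz$recognition, "", fixed = TRUE)[[1]]
    for (id in ids) {
      for (pass in 1:10) {
        hits <- find_sites(paste(seqs[[id]], collapse = ""), enz)
        keep <- hits %in% planted_pos & truth[id, ename] == 1L
        stray <- hits[!keep]
        if (length(stray) == 0L) break
        for (s in stray) {
          # break the match at a position outside any planted window,
          # preferring the middle of the stray site
          offs <- seq_len(span)
          offs <- offs[order(abs(offs - (span + 1L) / 2))]
          offs <- offs[!((s + offs - 1L) %in% planted_windows)]
          if (length(offs) == 0L) next
          o <- offs[1]
          choices <- setdiff(.BASES, .IUPAC_BASES[[rec_syms[o]]])
          seqs[[id]][s + o - 1L] <- if (length(choices) == 1L) choices else
            sample(choices, 1L)
        }
      }
    }
  }

  # alignment-artifact columns (never inside a planted window)
  free_cols <- setdiff(seq_len(L), planted_windows)
  n_art <- config$gap_columns + config$ambiguous_columns
  if (n_art > length(free_cols))
    stop("length too small for requested gap/ambiguity columns")
  if (n_art > 0L) {
    art_cols <- sample(free_cols, n_art)
    gap_cols <- art_cols[seq_len(config$gap_columns)]
    amb_cols <- setdiff(art_cols, gap_cols)
    for (col in gap_cols) {
      id <- sample(ids, 1L)  # draw once: index in `[[<-` is evaluated twice
      seqs[[id]][col] <- "-"
    }
    for (col in amb_cols) {
      id <- sample(ids, 1L)
      seqs[[id]][col] <- "N"
    }
  }

  residues <- vapply(seqs, paste, character(1), collapse = "")
  aln <- .new_seq_set(ids, ids, unname(residues[ids]), aligned = TRUE)
  out <- list(alignment = aln,
              groups = group_assignment(ids, id_group),
              truth = truth,
              config = config)
  class(out) <- "synth_dataset"
  out
}

#' Bundled 19-strain ribotype presence/absence matrix
#'
#' A published site-presence survey of 19 rhizosphere bacterial 16S rRNA
#' ribotypes (strains labelled a-s: isolated Pseudomonas strains,
#' reference proteobacteria, and Frankia-dominated actinobacteria) against
#' the ten standard enzymes of [default_enzymes()]. Serves as a
#' first-class matrix-only input to the pipeline and as ground truth for
#' the Jaccard/UPGMA stages.
#'
#' @return integer 0/1 matrix, 19 strains x 10 enzymes.
#' @export
example_site_profiles <- function() {
  rows <- c(
    AluI   = "+++++++++++++++--++",
    BstUI  = "++++++++++++++++-++",
    DdeI   = "+-++-++++++++++-+++",
    HaeIII = "+++++++++++++++++++",
    HhaI   = "+++++++++++++++++++",
    HinfI  = "+++++++++++++++----",
    MboI   = "+++++++++++++-++-++",
    MspI   = "+++++++++++-+++-+++",
    RsaI   = "+++++++++++++++++++",
    TaqI   = "+++++++++++++++--++")
  m <- vapply(rows, function(r)
    as.integer(strsplit(r, "", fixed = TRUE)[[1]] == "+"),
    integer(19))
  rownames(m) <- letters[1:19]
  m
}
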