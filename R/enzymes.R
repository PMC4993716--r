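# Restriction enzyme definitions.
#
# An enzyme is written the way catalogues print it: the recognition site
# with an apostrophe at the cut position, e.g. AG'CT (AluI) cuts between
# the G and the C on the written strand. Degenerate positions use IUPAC
# codes (DdeI C'TNAG).

#' Compile a restriction enzyme from its written site
#'
#' @param name enzyme name.
#' @param site_with_mark recognition site containing exactly one cut mark;
#'   the straight apostrophe and the typographic variants \code{’}
#'   and backtick are all accepted.
#' @return a `restriction_enzyme`: list(name, recognition, cut_offset)
#'   where `cut_offset` is the 0-based position of the cut within the
#'   recognition sequence.
#' @examples
#' compile_enzyme("AluI", "AG'CT")   # recognition AGCT, cut_offset 2
#' compile_enzyme("MboI", "'GATC")   # cuts before the site, offset 0
#' @export
compile_enzyme <- function(name, site_with_mark) {
  stopifnot(is.character(name), nzchar(name),
            is.character(site_with_mark), nzchar(site_with_mark))
  site <- chartr("’`", "''", toupper(site_with_mark))
  chars <- strsplit(site, "", fixed = TRUE)[[1]]
  marks <- which(chars == "'")
  if (length(marks) != 1L)
    stop("site '", site_with_mark, "' must contain exactly one cut mark")
  recognition <- paste(chars[-marks], collapse = "")
  if (!nzchar(recognition)) stop("empty recognition site")
  bad <- setdiff(strsplit(recognition, "", fixed = TRUE)[[1]],
                 .IUPAC_LETTERS)
  if (length(bad) > 0L)
    stop("non-IUPAC symbol(s) in recognition site: ",
         paste(bad, collapse = ", "))
  out <- list(name = name, recognition = recognition,
              cut_offset = marks - 1L)
  class(out) <- "restriction_enzyme"
  if (!is_palindromic(out))
    warning("enzyme ", name, " has a non-palindromic recognition site; ",
            "only the given strand is scanned")
  out
}

#' Is an enzyme's recognition site its own reverse complement?
#'
#' All ten built-in enzymes are palindromic under IUPAC equivalence, so
#' single-strand scanning finds every double-strand site.
#'
#' @param enzyme a `restriction_enzyme`.
#' @return logical scalar.
#' @export
is_palindromic <- function(enzyme) {
  identical(enzyme$recognition, reverse_complement(enzyme$recognition))
}

#' The ten standard 16S ribotyping enzymes
#'
#' Four-to-five-base cutters routinely used for 16S rRNA gene RFLP:
#' AluI AG'CT, BstUI CG'CG, DdeI C'TNAG, HaeIII GG'CC, HhaI GCG'C,
#' HinfI G'ANTC, MboI 'GATC, MspI C'CGG, RsaI GT'AC, TaqI T'CGA.
#'
#' @return named list of `restriction_enzyme` objects, in the standard
#'   (alphabetical) order used by all profile matrices.
#' @export
default_enzymes <- function() {
  sites <- c(AluI = "AG'CT", BstUI = "CG'CG", DdeI = "C'TNAG",
             HaeIII = "GG'CC", HhaI = "GCG'C", HinfI = "G'ANTC",
             MboI = "'GATC", MspI = "C'CGG", RsaI = "GT'AC",
             TaqI = "T'CGA")
  stats::setNames(
    lapply(names(sites), function(n) compile_enzyme(n, sites[[n]])),
    names(sites))
}

#' Read an enzyme table
#'
#' TSV with two columns: name, site-with-cut-mark. A header row whose
#' first field is "name" is skipped.
#'
#' @param path file path.
#' @return named list of `restriction_enzyme` objects in file order.
#' @export
read_enzyme_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "[\t ]+")
  if (length(fields) > 0L && identical(tolower(fields[[1]][1]), "name"))
    fields <- fields[-1]
  if (length(fields) == 0L) stop("empty enzyme table: ", path)
  enz <- lapply(fields, function(f) compile_enzyme(f[1], f[2]))
  stats::setNames(enz, vapply(enz, `[[`, character(1), "name"))
}
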