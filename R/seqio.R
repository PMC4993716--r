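# Sequence, alignment and group-map i/o with validation.
#
# A sequence set is a data.frame with class "seq_set" and columns
# id / description / residues; an alignment additionally has class
# "aligned_set" and an attribute "length" (number of columns). Residues
# are uppercase IUPAC nucleotide codes plus "-" ("." on input is
# normalized to "-").

.new_seq_set <- function(id, description, residues, aligned = FALSE) {
  df <- data.frame(id = id, description = description, residues = residues,
                   stringsAsFactors = FALSE)
  class(df) <- c(if (aligned) "aligned_set", "seq_set", "data.frame")
  if (aligned) attr(df, "length") <- nchar(df$residues[1])
  df
}

#' Read sequences from a FASTA file
#'
#' The id is the first whitespace-delimited header token; the full header
#' is kept as the description. Residues are uppercased and "." is
#' normalized to "-". Rejects empty files, duplicate ids and any symbol
#' outside the IUPAC alphabet + gap, naming the offending record.
#'
#' @param path FASTA file.
#' @return a `seq_set` data.frame (columns id, description, residues).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("FASTA record with empty header in '", path, "'")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  residues <- chartr(".", "-", toupper(as.character(set)))
  if (any(!nzchar(residues)))
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(residues)], collapse = ", "))
  for (i in seq_along(ids)) .validate_residues(residues[i], ids[i])
  .new_seq_set(ids, headers, unname(residues))
}

#' Read an aligned FASTA file
#'
#' As [read_fasta()] but enforces that all records have identical length
#' and that there are at least two of them.
#'
#' @param path aligned FASTA file.
#' @return an `aligned_set` (subclass of `seq_set`) with attribute
#'   `length` = number of alignment columns.
#' @export
read_aligned <- function(path) {
  seqs <- read_fasta(path)
  as_aligned_set(seqs)
}

#' Validate a sequence set as an alignment
#'
#' @param seqs a `seq_set`.
#' @return the same records with class `aligned_set`.
#' @export
as_aligned_set <- function(seqs) {
  if (nrow(seqs) < 2L)
    stop("an alignment needs at least 2 sequences, got ", nrow(seqs))
  lens <- nchar(seqs$residues)
  if (length(unique(lens)) > 1L) {
    stop(sprintf(
      "ragged alignment: shortest '%s' (%d), longest '%s' (%d)",
      seqs$id[which.min(lens)], min(lens),
      seqs$id[which.max(lens)], max(lens)))
  }
  .new_seq_set(seqs$id, seqs$description, seqs$residues, aligned = TRUE)
}

#' Write a sequence set to FASTA
#'
#' @param seqs a `seq_set`.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a strain-to-group map
#'
#' Two-column delimited text (id, group). A first line whose first field
#' is literally "id" is treated as a header and skipped. Group order is
#' first-appearance order.
#'
#' @param path TSV/whitespace-delimited file.
#' @return a `group_assignment`: list with `mapping` (named character:
#'   id -> group) and `groups` (ordered distinct group names).
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty group map: ", path)
  fields <- strsplit(lines, "[\t ]+")
  if (identical(tolower(fields[[1]][1]), "id")) fields <- fields[-1]
  if (length(fields) == 0L) stop("group map has no data rows: ", path)
  ids <- vapply(fields, `[`, character(1), 1L)
  grp <- vapply(fields, `[`, character(1), 2L)
  if (anyNA(grp) || any(!nzchar(grp)))
    stop("blank group for id(s): ",
         paste(ids[is.na(grp) | !nzchar(grp)], collapse = ", "))
  group_assignment(ids, grp)
}

#' Construct a group assignment
#'
#' @param ids character vector of sequence ids.
#' @param groups character vector of group names, parallel to `ids`.
#' @return a `group_assignment` object.
#' @export
group_assignment <- function(ids, groups) {
  stopifnot(length(ids) == length(groups))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    for (d in dup) {
      if (length(unique(groups[ids == d])) > 1L)
        stop("id '", d, "' mapped to conflicting groups")
    }
    keep <- !duplicated(ids)
    ids <- ids[keep]; groups <- groups[keep]
  }
  mapping <- stats::setNames(groups, ids)
  out <- list(mapping = mapping, groups = unique(groups))
  class(out) <- "group_assignment"
  out
}

#' Check a group assignment against a sequence set
#'
#' Every mapped id must exist in the set and every group keeps >= 1
#' member among the set's ids.
#'
#' @param groups a `group_assignment`.
#' @param seqs a `seq_set`.
#' @return invisibly TRUE, or an error naming offenders.
#' @export
check_groups <- function(groups, seqs) {
  missing <- setdiff(names(groups$mapping), seqs$id)
  if (length(missing) > 0L)
    stop("group map id(s) absent from sequence set: ",
         paste(missing, collapse = ", "))
  present <- groups$mapping[intersect(names(groups$mapping), seqs$id)]
  empty <- setdiff(groups$groups, unique(present))
  if (length(empty) > 0L)
    stop("group(s) with no member in sequence set: ",
         paste(empty, collapse = ", "))
  invisible(TRUE)
}

#' Write a group assignment as TSV
#'
#' @param groups a `group_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(groups, path) {
  df <- data.frame(id = names(groups$mapping),
                   group = unname(groups$mapping))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove gap characters from residues
#'
#' @param residues character vector of residue strings.
#' @return the strings with all "-" removed.
#' @export
strip_gaps <- function(residues) gsub("-", "", residues, fixed = TRUE)
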