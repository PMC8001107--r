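#' @keywords internal
"_PACKAGE"

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AMBIG <- c("B", "J", "Z", "X", "U", "O")

#' Construct a grouped alignment
#'
#' A grouped alignment is an aligned set of protein sequences in which every
#' sequence carries a paralog-group label (e.g. ABCG1 ... ABCG8). It is the
#' substrate for all per-column conservation statistics: entropy is computed
#' both across the whole column and within each group.
#'
#' Residues are upper-cased and the alternative gap character `.` is
#' normalised to `-`. Ambiguity letters (B, J, Z, X, U, O) are retained in the
#' sequences but are tallied separately from the 20 standard amino acids and
#' never enter an entropy calculation.
#'
#' @param sequences character vector of aligned sequences (equal lengths).
#' @param ids character vector of unique sequence identifiers.
#' @param groups character vector of group labels, parallel to `sequences`.
#' @return An object of class `grouped_alignment`: a list with a character
#'   matrix `residues` (one row per sequence, one column per alignment
#'   column), `ids`, `groups` (factor), `group_levels`, and `n_columns`.
#' @examples
#' aln <- grouped_alignment(c("ACDE", "ACDE", "VCDE", "VCDE"),
#'                          ids = paste0("s", 1:4),
#'                          groups = c("g1", "g1", "g2", "g2"))
#' aln$n_columns
#' @export
grouped_alignment <- function(sequences, ids, groups) {
  stopifnot(is.character(sequences), is.character(ids), is.character(groups))
  if (length(sequences) != length(ids) || length(ids) != length(groups))
    stop("sequences, ids and groups must have equal length", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sequences <- gsub(".", "-", toupper(sequences), fixed = TRUE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("alignment-shape error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  n_columns <- lens[1L]
  if (n_columns < 1L)
    stop("alignment-shape error: zero-length alignment", call. = FALSE)
  bad <- setdiff(unique(unlist(strsplit(sequences, ""))),
                 c(AA20, AMBIG, "-"))
  if (length(bad))
    stop("invalid residue letters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  group_levels <- unique(groups)
  sizes <- table(factor(groups, levels = group_levels))
  if (any(sizes < 2L))
    stop("degenerate-group error: group(s) with fewer than 2 sequences: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  mat <- matrix(unlist(strsplit(sequences, ""), use.names = FALSE),
                nrow = length(sequences), ncol = n_columns, byrow = TRUE,
                dimnames = list(ids, NULL))
  structure(
    list(residues = mat, ids = ids,
         groups = factor(groups, levels = group_levels),
         group_levels = group_levels, n_columns = n_columns),
    class = "grouped_alignment")
}

#' Read a grouped alignment from aligned FASTA plus a group map
#'
#' @param fasta_path path to an aligned FASTA file (wrapped or unwrapped).
#' @param group_map_path path to a TSV with header `sequence_id<TAB>group`
#'   assigning every sequence to a paralog group.
#' @return A [grouped_alignment] object.
#' @details Every FASTA sequence must appear in the group map and vice versa;
#'   sequences must share one length; every group needs at least two members
#'   (within-group entropy of a singleton is degenerate).
#' @export
read_alignment <- function(fasta_path, group_map_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aa))
  map <- utils::read.delim(group_map_path, header = TRUE,
                           colClasses = "character")
  if (!all(c("sequence_id", "group") %in% names(map)))
    stop("group map must have columns 'sequence_id' and 'group'",
         call. = FALSE)
  missing_in_map <- setdiff(ids, map$sequence_id)
  missing_in_fasta <- setdiff(map$sequence_id, ids)
  if (length(missing_in_map) || length(missing_in_fasta))
    stop("membership error: ",
         if (length(missing_in_map))
           paste0("sequences absent from group map: ",
                  paste(missing_in_map, collapse = ", "), "; ") else "",
         if (length(missing_in_fasta))
           paste0("group-map entries absent from FASTA: ",
                  paste(missing_in_fasta, collapse = ", ")) else "",
         call. = FALSE)
  groups <- map$group[match(ids, map$sequence_id)]
  grouped_alignment(as.character(aa), ids, groups)
}

#' Write a grouped alignment back to aligned FASTA and a group-map TSV
#'
#' The FASTA is wrapped at 60 columns. Re-reading the pair with
#' [read_alignment()] reproduces the alignment exactly.
#'
#' @param aln a [grouped_alignment].
#' @param fasta_path,group_map_path output paths.
#' @return Invisibly, `aln`.
#' @export
write_alignment <- function(aln, fasta_path, group_map_path) {
  stopifnot(inherits(aln, "grouped_alignment"))
  seqs <- apply(aln$residues, 1L, paste, collapse = "")
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- aln$ids
  Biostrings::writeXStringSet(aa, fasta_path, width = 60L)
  utils::write.table(
    data.frame(sequence_id = aln$ids, group = as.character(aln$groups)),
    group_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(aln)
}

#' Per-column residue tallies
#'
#' Tallies the residues of one alignment column, overall and within each
#' group. Gaps are counted separately, and ambiguity letters go to an
#' `ambiguous` bucket so that entropy stays on the 20-letter amino-acid
#' alphabet.
#'
#' @param aln a [grouped_alignment].
#' @param column_index 1-based column index.
#' @return A list of class `column_profile` with `column_index`,
#'   `counts_overall` (named integer over amino acids present), `gap_count`,
#'   `ambiguous_count`, and `by_group`: per group a list with `counts`,
#'   `gap_count`, `ambiguous_count`.
#' @export
column_profile <- function(aln, column_index) {
  stopifnot(inherits(aln, "grouped_alignment"))
  if (length(column_index) != 1L || column_index < 1L ||
      column_index > aln$n_columns)
    stop("bounds error: column_index ", column_index, " outside 1..",
         aln$n_columns, call. = FALSE)
  col <- aln$residues[, column_index]
  tally <- function(x) {
    list(counts = table_counts(x[x %in% AA20]),
         gap_count = sum(x == "-"),
         ambiguous_count = sum(x %in% AMBIG))
  }
  overall <- tally(col)
  by_group <- lapply(split(col, aln$groups), tally)
  structure(
    list(column_index = as.integer(column_index),
         counts_overall = overall$counts,
         gap_count = overall$gap_count,
         ambiguous_count = overall$ambiguous_count,
         by_group = by_group),
    class = "column_profile")
}

# named integer counts of a character vector, alphabetical, zero entries
# dropped
table_counts <- function(x) {
  if (!length(x)) return(integer(0))
  tab <- table(x)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
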