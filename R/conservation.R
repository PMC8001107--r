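#' Entropy and gap-filter parameters
#'
#' Defaults follow the standard protocol for entropy-based conservation
#' calling in paralog families: a column is conserved when its Shannon
#' entropy is strictly below 2/3 of a bit, and a column is discarded as
#' gap-dominated when at least 10% of all sequences, or at least 30% of the
#' sequences of any one group, are gaps there.
#'
#' @param conservation_threshold_bits entropy cutoff in bits; conservation
#'   is entropy strictly below this value. Must lie in (0, log2(20)].
#' @param gap_fraction_overall overall gap fraction at or above which a
#'   column is flagged as Gap.
#' @param gap_fraction_per_group per-group gap fraction at or above which a
#'   column is flagged as Gap.
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(conservation_threshold_bits = 2 / 3,
                           gap_fraction_overall = 0.10,
                           gap_fraction_per_group = 0.30) {
  if (!(conservation_threshold_bits > 0 &&
        conservation_threshold_bits <= log2(20)))
    stop("conservation_threshold_bits must be in (0, log2(20)]",
         call. = FALSE)
  if (gap_fraction_overall < 0 || gap_fraction_overall > 1 ||
      gap_fraction_per_group < 0 || gap_fraction_per_group > 1)
    stop("gap fractions must be in [0, 1]", call. = FALSE)
  structure(list(conservation_threshold_bits = conservation_threshold_bits,
                 gap_fraction_overall = gap_fraction_overall,
                 gap_fraction_per_group = gap_fraction_per_group),
            class = "entropy_params")
}

#' Shannon entropy of a residue count vector
#'
#' H = -sum_a p_a log2 p_a over the 20 amino acids, with p_a the observed
#' frequency among usable (non-gap, non-ambiguous) residues. No pseudocounts
#' and no sequence weighting: the estimate is the plug-in entropy of the
#' column. Ranges from 0 (a single residue) to log2(20) ~ 4.32 bits (all
#' twenty equally frequent).
#'
#' @param residue_counts named numeric vector of residue counts (names are
#'   amino-acid letters); zero counts are ignored.
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(A = 12))            # 0
#' shannon_entropy(c(A = 7, V = 1))      # 0.5436 -- conserved at 2/3 bit
#' shannon_entropy(c(A = 3, V = 1))      # 0.8113 -- not conserved
#' @export
shannon_entropy <- function(residue_counts) {
  counts <- residue_counts[residue_counts > 0]
  total <- sum(counts)
  if (total < 1)
    stop("empty-column error: no usable residues", call. = FALSE)
  p <- counts / total
  -sum(p * log2(p))
}

#' Gap filter for one column
#'
#' A column is Gap when its overall gap fraction reaches
#' `gap_fraction_overall`, or the gap fraction within any single group
#' reaches `gap_fraction_per_group`. Both comparisons are inclusive (>=,
#' "at least").
#'
#' @param profile a [column_profile].
#' @param aln the [grouped_alignment] the profile came from.
#' @param params an [entropy_params] object.
#' @return Logical.
#' @export
is_gap_column <- function(profile, aln, params = entropy_params()) {
  n_total <- length(aln$ids)
  if (profile$gap_count / n_total >= params$gap_fraction_overall)
    return(TRUE)
  sizes <- table(aln$groups)
  for (g in aln$group_levels) {
    if (profile$by_group[[g]]$gap_count / sizes[[g]] >=
        params$gap_fraction_per_group)
      return(TRUE)
  }
  FALSE
}

# most common residue among a group's counts; alphabetical tie-break
most_common_residue <- function(counts) {
  top <- names(counts)[counts == max(counts)]
  sort(top)[1L]
}

#' Classify one alignment column
#'
#' The classification procedure, in order:
#' 1. the gap filter ([is_gap_column()]): Gap columns are excluded from all
#'    further analysis;
#' 2. whole-column entropy strictly below the threshold: the column is
#'    conserved across the whole family (`ALL_CONSERVED`), one block holding
#'    every group with the overall most-common residue;
#' 3. otherwise entropy per group: groups below the threshold are conserved
#'    and record their most-common residue; no conserved group gives
#'    `NOT_CONSERVED`, and any conserved group gives `PATTERN`, with blocks
#'    formed by merging conserved groups that record the same residue.
#'
#' Divergence typing over the blocks: `TOTAL` for `ALL_CONSERVED`; `TYPE_II`
#' when every group is conserved but not family-wide (two or more blocks);
#' `TYPE_I` when exactly one block exists and every other group is
#' unconserved; `MIXED` for any other column with at least one conserved
#' group; `NONE` for Gap and not-conserved columns. The rare boundary where
#' every group conserves the same residue yet whole-column entropy stays at
#' or above the threshold is kept as a single-block `PATTERN`, typed
#' `TYPE_II` with `boundary = TRUE`.
#'
#' @param profile a [column_profile].
#' @param aln the [grouped_alignment].
#' @param params an [entropy_params] object.
#' @return A list of class `column_call`: `column_index`, `status`,
#'   `blocks` (list of `list(residue=, groups=)`), `unconserved` (character),
#'   `divergence` and logical `boundary`.
#' @export
classify_column <- function(profile, aln, params = entropy_params()) {
  groups <- aln$group_levels
  call_obj <- function(status, blocks = list(), unconserved = character(0),
                       divergence = "NONE", boundary = FALSE) {
    structure(list(column_index = profile$column_index, status = status,
                   blocks = blocks, unconserved = unconserved,
                   divergence = divergence, boundary = boundary),
              class = "column_call")
  }
  if (is_gap_column(profile, aln, params))
    return(call_obj("GAP"))
  if (sum(profile$counts_overall) < 1)
    stop("empty-column error: column ", profile$column_index,
         " has no usable residues", call. = FALSE)
  h_all <- shannon_entropy(profile$counts_overall)
  if (h_all < params$conservation_threshold_bits) {
    res <- most_common_residue(profile$counts_overall)
    return(call_obj("ALL_CONSERVED",
                    blocks = list(list(residue = res, groups = groups)),
                    divergence = "TOTAL"))
  }
  conserved_res <- character(0)
  unconserved <- character(0)
  for (g in groups) {
    counts <- profile$by_group[[g]]$counts
    if (sum(counts) < 1)
      stop("empty-column error: group ", g, " has no usable residues in ",
           "column ", profile$column_index, call. = FALSE)
    if (shannon_entropy(counts) < params$conservation_threshold_bits)
      conserved_res[g] <- most_common_residue(counts)
    else
      unconserved <- c(unconserved, g)
  }
  if (!length(conserved_res))
    return(call_obj("NOT_CONSERVED", unconserved = unconserved))
  blocks <- lapply(split(names(conserved_res), conserved_res),
                   function(gs) list(residue = conserved_res[[gs[1L]]],
                                     groups = gs[order(match(gs, groups))]))
  blocks <- canonical_blocks(unname(blocks))
  n_blocks <- length(blocks)
  divergence <-
    if (!length(unconserved) && n_blocks >= 2L) "TYPE_II"
    else if (n_blocks == 1L && length(unconserved) &&
             length(blocks[[1L]]$groups) + length(unconserved) ==
             length(groups)) "TYPE_I"
    else if (length(unconserved)) "MIXED"
    else "TYPE_II"  # single block, all groups, whole-column not conserved
  boundary <- !length(unconserved) && n_blocks == 1L
  call_obj("PATTERN", blocks = blocks, unconserved = unconserved,
           divergence = divergence, boundary = boundary)
}

# canonical block order: size descending, then lexicographic smallest member
canonical_blocks <- function(blocks) {
  if (!length(blocks)) return(blocks)
  sizes <- vapply(blocks, function(b) length(b$groups), integer(1))
  firsts <- vapply(blocks, function(b) sort(b$groups)[1L], character(1))
  blocks[order(-sizes, firsts)]
}

#' Classify every column of a grouped alignment
#'
#' Runs [classify_column()] over the whole alignment and summarises the
#' result: a per-column call and a census of statuses and divergence types.
#' This is the package's central fitting step; the returned object feeds
#' [pattern_census()], [region_enrichment()], [sidechain_summary()] and the
#' reporting functions.
#'
#' @param aln a [grouped_alignment].
#' @param params an [entropy_params] object.
#' @return An object of class `divergence_calls`: list with `calls` (one
#'   `column_call` per column), `census` (named integer: GAP, ALL_CONSERVED,
#'   NOT_CONSERVED, PATTERN), `divergence_census` (TOTAL, TYPE_I, TYPE_II,
#'   MIXED, NONE), `params`, `groups`, `n_columns`, `n_sequences`.
#' @examples
#' aln <- grouped_alignment(c("RRR", "RRR", "RRR", "RRR"),
#'                          paste0("s", 1:4), c("g1", "g1", "g2", "g2"))
#' fit <- classify_alignment(aln)
#' fit$census
#' @export
classify_alignment <- function(aln, params = entropy_params()) {
  stopifnot(inherits(aln, "grouped_alignment"))
  calls <- lapply(seq_len(aln$n_columns), function(j)
    classify_column(column_profile(aln, j), aln, params))
  statuses <- vapply(calls, `[[`, character(1), "status")
  divs <- vapply(calls, `[[`, character(1), "divergence")
  census <- vapply(c("GAP", "ALL_CONSERVED", "NOT_CONSERVED", "PATTERN"),
                   function(s) sum(statuses == s), integer(1))
  div_census <- vapply(c("TOTAL", "TYPE_I", "TYPE_II", "MIXED", "NONE"),
                       function(d) sum(divs == d), integer(1))
  structure(
    list(calls = calls, census = census, divergence_census = div_census,
         params = params, groups = aln$group_levels,
         n_columns = aln$n_columns, n_sequences = length(aln$ids)),
    class = "divergence_calls")
}

#' Fraction of non-gap columns conserved within each group
#'
#' For every group, the fraction of non-gap columns whose within-group
#' entropy falls below the conservation threshold (columns conserved across
#' the whole family count as conserved in every group). These per-group
#' probabilities drive the expected pattern frequencies of
#' [expected_pattern_counts()] under the independence model.
#'
#' @param aln a [grouped_alignment].
#' @param params an [entropy_params] object.
#' @return Named numeric vector of per-group conservation probabilities.
#' @export
group_conservation_probs <- function(aln, params = entropy_params()) {
  stopifnot(inherits(aln, "grouped_alignment"))
  groups <- aln$group_levels
  hits <- stats::setNames(numeric(length(groups)), groups)
  n_nongap <- 0L
  for (j in seq_len(aln$n_columns)) {
    prof <- column_profile(aln, j)
    if (is_gap_column(prof, aln, params)) next
    n_nongap <- n_nongap + 1L
    for (g in groups) {
      counts <- prof$by_group[[g]]$counts
      if (sum(counts) >= 1 &&
          shannon_entropy(counts) < params$conservation_threshold_bits)
        hits[g] <- hits[g] + 1
    }
  }
  if (n_nongap == 0L) return(hits)
  hits / n_nongap
}

#' @export
print.divergence_calls <- function(x, ...) {
  cat("Conservation-divergence classification\n")
  cat(sprintf("  %d sequences in %d groups (%s), %d columns\n",
              x$n_sequences, length(x$groups),
              paste(x$groups, collapse = ", "), x$n_columns))
  cat(sprintf("  entropy threshold %.4g bits; gap filter >=%.0f%% overall, >=%.0f%% per group\n",
              x$params$conservation_threshold_bits,
              100 * x$params$gap_fraction_overall,
              100 * x$params$gap_fraction_per_group))
  cat("  status census: ",
      paste(sprintf("%s=%d", names(x$census), x$census), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.divergence_calls <- function(object, ...) {
  print(object)
  cat("  divergence census: ",
      paste(sprintf("%s=%d", names(object$divergence_census),
                    object$divergence_census), collapse = ", "),
      "\n", sep = "")
  nboundary <- sum(vapply(object$calls, `[[`, logical(1), "boundary"))
  if (nboundary)
    cat(sprintf("  %d single-block boundary column(s)\n", nboundary))
  invisible(object)
}

#' @export
as.data.frame.divergence_calls <- function(x, ...) {
  data.frame(
    column = vapply(x$calls, `[[`, integer(1), "column_index"),
    status = vapply(x$calls, `[[`, character(1), "status"),
    divergence = vapply(x$calls, `[[`, character(1), "divergence"),
    boundary = vapply(x$calls, `[[`, logical(1), "boundary"),
    pattern = vapply(x$calls, function(cl)
      if (cl$status %in% c("PATTERN", "ALL_CONSERVED"))
        format(call_pattern(cl, x$groups)) else "", character(1)),
    blocks = vapply(x$calls, format_blocks, character(1)),
    stringsAsFactors = FALSE)
}

#' @export
plot.divergence_calls <- function(x, ...) {
  graphics::barplot(x$divergence_census, ylab = "columns",
                    main = "Divergence census", ...)
  invisible(x)
}

# serialize blocks as R:ABCG2|S:ABCG5|Q:ABCG1+ABCG4|H:ABCG8
format_blocks <- function(call) {
  if (!length(call$blocks)) return("")
  paste(vapply(call$blocks, function(b)
    paste0(b$residue, ":", paste(b$groups, collapse = "+")),
    character(1)), collapse = "|")
}
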