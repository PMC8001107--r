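#' Conservation patterns
#'
#' A conservation pattern is the residue-agnostic identity of a divergence
#' signature: a partition of the conserved subset of groups into blocks that
#' share a residue, with the remaining groups unconserved. It is written in
#' bracket notation, e.g. `(ABCG1,ABCG4)(ABCG2)(ABCG5)(ABCG8)` -- groups
#' inside one bracket conserve the same residue, groups absent from every
#' bracket are unconserved.
#'
#' @param blocks list of character vectors, each a non-empty block of group
#'   labels; blocks must be pairwise disjoint.
#' @param groups character vector of all group labels in the family.
#' @return An object of class `conservation_pattern` with canonical block
#'   ordering (size descending, then lexicographically smallest member) and
#'   the derived `unconserved` set.
#' @examples
#' p <- conservation_pattern(list(c("ABCG1", "ABCG4"), "ABCG2"),
#'                           groups = c("ABCG1", "ABCG2", "ABCG4",
#'                                      "ABCG5", "ABCG8"))
#' format(p)  # "(ABCG1,ABCG4)(ABCG2)"
#' @export
conservation_pattern <- function(blocks, groups) {
  stopifnot(is.list(blocks), length(blocks) >= 1L, is.character(groups))
  blocks <- lapply(blocks, function(b) sort(as.character(b)))
  members <- unlist(blocks)
  if (!length(members) || anyDuplicated(members))
    stop("blocks must be non-empty and pairwise disjoint", call. = FALSE)
  if (!all(members %in% groups))
    stop("unknown group label(s): ",
         paste(setdiff(members, groups), collapse = ", "), call. = FALSE)
  sizes <- lengths(blocks)
  firsts <- vapply(blocks, `[`, character(1), 1L)
  blocks <- blocks[order(-sizes, firsts)]
  structure(list(blocks = blocks,
                 unconserved = setdiff(groups, members),
                 groups = groups),
            class = "conservation_pattern")
}

#' @export
format.conservation_pattern <- function(x, ...) {
  paste(vapply(x$blocks, function(b)
    paste0("(", paste(b, collapse = ","), ")"), character(1)),
    collapse = "")
}

#' @export
print.conservation_pattern <- function(x, ...) {
  cat(format(x))
  if (length(x$unconserved))
    cat("  [unconserved: ", paste(x$unconserved, collapse = ", "), "]",
        sep = "")
  cat("\n")
  invisible(x)
}

#' @export
`==.conservation_pattern` <- function(e1, e2) {
  format(e1) == format(e2) &&
    setequal(e1$groups, e2$groups)
}

# pattern of a PATTERN/ALL_CONSERVED column call
call_pattern <- function(call, groups) {
  conservation_pattern(lapply(call$blocks, `[[`, "groups"), groups)
}

# all set partitions of a character vector, as lists of blocks
set_partitions <- function(x) {
  n <- length(x)
  if (n == 0L) return(list(list()))
  if (n == 1L) return(list(list(x)))
  rest <- set_partitions(x[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1L], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(x[1L]), p)
  }
  out
}

#' Enumerate all theoretically possible conservation patterns
#'
#' Every non-empty subset of the k groups can be the conserved set, and each
#' conserved set can be partitioned into same-residue blocks in Bell(|set|)
#' ways, so the total is sum over i = 1..k of choose(k, i) * Bell(i). For
#' the five mammalian ABCG paralogs (k = 5) this gives 202 patterns.
#'
#' @param groups character vector of group labels (or a single integer k,
#'   in which case labels `G1..Gk` are used).
#' @return List of [conservation_pattern] objects, no duplicates under the
#'   canonical form.
#' @examples
#' length(enumerate_patterns(5))  # 202
#' length(enumerate_patterns(c("A", "B")))  # 4: (A), (B), (A,B), (A)(B)
#' @export
enumerate_patterns <- function(groups) {
  if (is.numeric(groups) && length(groups) == 1L) {
    if (groups < 1) stop("need at least one group", call. = FALSE)
    groups <- paste0("G", seq_len(groups))
  }
  stopifnot(is.character(groups), length(groups) >= 1L)
  k <- length(groups)
  out <- list()
  for (i in seq_len(k)) {
    subsets <- utils::combn(groups, i, simplify = FALSE)
    for (s in subsets) {
      for (p in set_partitions(s))
        out[[length(out) + 1L]] <- conservation_pattern(p, groups)
    }
  }
  out
}

#' Poisson significance threshold for pattern counts
#'
#' Observed counts per conservation pattern are modelled as Poisson with
#' rate lambda = n_columns / n_patterns (non-gap columns spread uniformly
#' over the possible patterns). With a Bonferroni-style correction of the
#' family alpha over the n_patterns tests, the threshold is the smallest
#' integer n at which the exact Poisson CDF reaches 1 - alpha / n_patterns;
#' a pattern observed in strictly more than n columns is significant.
#'
#' @param n_columns number of non-gap columns.
#' @param n_patterns number of possible conservation patterns.
#' @param family_alpha family-wise significance level (default 0.1).
#' @return Integer threshold n.
#' @examples
#' significance_threshold(595, 202, 0.1)  # 10
#' @export
significance_threshold <- function(n_columns, n_patterns,
                                   family_alpha = 0.1) {
  if (n_columns < 0 || n_patterns < 1)
    stop("need n_columns >= 0 and n_patterns >= 1", call. = FALSE)
  if (!(family_alpha > 0 && family_alpha < 1))
    stop("family_alpha must lie in (0, 1)", call. = FALSE)
  lambda <- n_columns / n_patterns
  target <- 1 - family_alpha / n_patterns
  n <- 0L
  while (stats::ppois(n, lambda) < target)
    n <- n + 1L
  n
}

#' Probability of a specific block partition of a conserved set
#'
#' Given that a set of n groups is conserved at a column, with each group's
#' conserved residue an independent uniform draw from the 20-letter
#' amino-acid alphabet, the probability that the groups fall into one
#' specific partition with m blocks (same residue within a block, distinct
#' residues across blocks) is 19! / ((20 - m)! * 20^(n - 1)). The
#' probabilities over all partitions of an n-set sum to one, and two groups
#' sharing one block has probability 1/20 = 0.05.
#'
#' @param n size of the conserved set (1..20).
#' @param m number of blocks in the partition (1..n).
#' @return Probability.
#' @examples
#' partition_probability(2, 1)  # 0.05
#' partition_probability(3, 3)  # 342/400
#' @export
partition_probability <- function(n, m) {
  if (m > n || m < 1 || n < 1 || n > 20)
    stop("domain error: need 1 <= m <= n <= 20", call. = FALSE)
  exp(lfactorial(19) - lfactorial(20 - m) - (n - 1) * log(20))
}

#' Expected pattern counts under the independence model
#'
#' E(pattern) = N * prod over conserved groups of p_g * prod over
#' unconserved groups of (1 - p_g) * partition_probability(n, m), where N is
#' the number of non-gap columns, p_g each group's conservation probability
#' (see [group_conservation_probs()]), n the conserved-set size and m the
#' block count of the pattern's specific partition. Groups are treated as
#' conserving independently; paralogs are in truth phylogenetically
#' correlated, so these are a null reference, not a fitted model.
#'
#' @param probs named numeric vector of per-group conservation
#'   probabilities (names = all group labels).
#' @param n_nongap_columns number of non-gap columns.
#' @param patterns optional list of [conservation_pattern]; defaults to all
#'   patterns from [enumerate_patterns()] over `names(probs)`.
#' @return Named numeric vector of expected counts, names in bracket
#'   notation.
#' @export
expected_pattern_counts <- function(probs, n_nongap_columns,
                                    patterns = NULL) {
  stopifnot(is.numeric(probs), !is.null(names(probs)),
            all(probs >= 0 & probs <= 1))
  groups <- names(probs)
  if (is.null(patterns)) patterns <- enumerate_patterns(groups)
  vals <- vapply(patterns, function(p) {
    conserved <- unlist(p$blocks)
    n <- length(conserved)
    m <- length(p$blocks)
    n_nongap_columns * prod(probs[conserved]) *
      prod(1 - probs[p$unconserved]) * partition_probability(n, m)
  }, numeric(1))
  names(vals) <- vapply(patterns, format, character(1))
  vals
}

#' Census of observed conservation patterns with significance calls
#'
#' Tallies every conserved column's pattern (columns conserved across the
#' whole family count as the single all-group block), attaches expected
#' counts under the independence model when the alignment is supplied, and
#' flags patterns observed strictly more often than the Poisson threshold.
#'
#' @param fit a `divergence_calls` object from [classify_alignment()].
#' @param family_alpha family-wise alpha for [significance_threshold()].
#' @param aln optionally, the [grouped_alignment] that was classified; when
#'   given, per-group conservation probabilities and expected counts are
#'   computed.
#' @return An object of class `pattern_census`: list with `observed` (named
#'   integer, bracket notation, decreasing), `n_nongap_columns`,
#'   `n_possible_patterns`, `significance_threshold`, `significant`
#'   (character vector of significant patterns), and optionally `expected`
#'   and `group_probs`.
#' @export
pattern_census <- function(fit, family_alpha = 0.1, aln = NULL) {
  stopifnot(inherits(fit, "divergence_calls"))
  groups <- fit$groups
  conserved_calls <- Filter(function(cl)
    cl$status %in% c("PATTERN", "ALL_CONSERVED"), fit$calls)
  keys <- vapply(conserved_calls, function(cl)
    format(call_pattern(cl, groups)), character(1))
  observed <- if (length(keys)) {
    tab <- sort(table(keys), decreasing = TRUE)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  n_nongap <- fit$n_columns - fit$census[["GAP"]]
  n_possible <- length(enumerate_patterns(groups))
  thr <- significance_threshold(n_nongap, n_possible, family_alpha)
  out <- list(observed = observed,
              n_nongap_columns = n_nongap,
              n_possible_patterns = n_possible,
              significance_threshold = thr,
              family_alpha = family_alpha,
              significant = names(observed)[observed > thr])
  if (!is.null(aln)) {
    out$group_probs <- group_conservation_probs(aln, fit$params)
    out$expected <- expected_pattern_counts(out$group_probs, n_nongap)
  }
  structure(out, class = "pattern_census")
}

#' @export
print.pattern_census <- function(x, ...) {
  cat("Conservation-pattern census\n")
  cat(sprintf("  %d non-gap columns, %d possible patterns, %d observed\n",
              x$n_nongap_columns, x$n_possible_patterns,
              length(x$observed)))
  cat(sprintf("  Poisson threshold %d (family alpha %.3g): %d significant pattern(s)\n",
              x$significance_threshold, x$family_alpha,
              length(x$significant)))
  invisible(x)
}

#' @export
summary.pattern_census <- function(object, ...) {
  print(object)
  top <- utils::head(object$observed, 10L)
  for (nm in names(top))
    cat(sprintf("  %4d  %s%s\n", top[[nm]], nm,
                if (nm %in% object$significant) "  *" else ""))
  invisible(object)
}

#' Pattern frequency in a region versus the whole alignment
#'
#' Compares how often a conservation pattern occurs among a chosen set of
#' alignment columns (for instance the 15 polar-relay columns) with its
#' frequency across all non-gap columns. Both fractions are returned with
#' their integer numerators and denominators; no hypothesis test is
#' performed.
#'
#' @param fit a `divergence_calls` object.
#' @param region_columns integer vector of 1-based column indices.
#' @param pattern a [conservation_pattern].
#' @return List with `fraction_in_region`, `fraction_overall`, and the
#'   integer `region_count`, `region_size`, `overall_count`,
#'   `n_nongap_columns`.
#' @export
region_enrichment <- function(fit, region_columns, pattern) {
  stopifnot(inherits(fit, "divergence_calls"),
            inherits(pattern, "conservation_pattern"))
  region_columns <- unique(as.integer(region_columns))
  if (!length(region_columns))
    stop("domain error: empty region", call. = FALSE)
  if (any(region_columns < 1L | region_columns > fit$n_columns))
    stop("domain error: region column outside alignment", call. = FALSE)
  key <- format(pattern)
  col_key <- vapply(fit$calls, function(cl)
    if (cl$status %in% c("PATTERN", "ALL_CONSERVED"))
      format(call_pattern(cl, fit$groups)) else "", character(1))
  statuses <- vapply(fit$calls, `[[`, character(1), "status")
  region_count <- sum(col_key[region_columns] == key)
  overall_count <- sum(col_key == key)
  n_nongap <- sum(statuses != "GAP")
  list(fraction_in_region = region_count / length(region_columns),
       fraction_overall = if (n_nongap) overall_count / n_nongap else 0,
       region_count = region_count,
       region_size = length(region_columns),
       overall_count = overall_count,
       n_nongap_columns = n_nongap)
}
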