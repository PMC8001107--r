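#' Plan one synthetic alignment column
#'
#' A column plan fixes the intended classification of one column of a
#' synthetic alignment: its status, and for pattern columns the partition of
#' groups into same-residue blocks together with each block's residue.
#' Conserved groups emit their block residue with probability
#' `1 - noise_rate` and a uniform other residue otherwise. Unconserved
#' groups receive an (as even as possible) spread over a 10-letter
#' sub-alphabet, which keeps their within-group entropy at or above 1 bit
#' for any group of two or more sequences -- safely above the 2/3-bit
#' conservation cutoff, so that noise-free recovery of the plan is exact.
#'
#' @param status one of `"GAP"`, `"ALL_CONSERVED"`, `"NOT_CONSERVED"`,
#'   `"PATTERN"`.
#' @param blocks for `PATTERN`: named list mapping a residue letter to a
#'   character vector of group labels (residues must be distinct across
#'   blocks); for `ALL_CONSERVED`: a single residue letter may be given via
#'   `blocks = list(R = NULL)` style or left `NULL` to pick `"A"`.
#' @param unconserved group labels left unconserved (for `PATTERN`).
#' @param noise_rate per-sequence substitution probability for conserved
#'   groups.
#' @param gap_rate for `GAP` columns: fraction of all sequences gapped
#'   (default 0.15, comfortably past the 10% overall filter).
#' @return A list of class `column_plan`.
#' @export
column_plan <- function(status, blocks = NULL, unconserved = character(0),
                        noise_rate = 0, gap_rate = 0.15) {
  status <- match.arg(status,
                      c("GAP", "ALL_CONSERVED", "NOT_CONSERVED", "PATTERN"))
  if (noise_rate < 0 || noise_rate >= 1)
    stop("noise_rate must be in [0, 1)", call. = FALSE)
  if (status == "PATTERN") {
    if (is.null(blocks) || !length(blocks))
      stop("PATTERN plan needs at least one block", call. = FALSE)
    if (anyDuplicated(names(blocks)))
      stop("block residues must be distinct across blocks", call. = FALSE)
    if (length(blocks) == 1L && !length(unconserved))
      stop("single-block PATTERN with no unconserved group is ",
           "ALL_CONSERVED; plan it as such", call. = FALSE)
  }
  if (status == "ALL_CONSERVED" && is.null(blocks))
    blocks <- stats::setNames(list(NULL), "A")
  structure(list(status = status, blocks = blocks,
                 unconserved = unconserved, noise_rate = noise_rate,
                 gap_rate = gap_rate),
            class = "column_plan")
}

#' Specify a synthetic grouped alignment
#'
#' The default layout emulates a five-paralog mammalian family sampled
#' across ~35 species: five groups of 35 sequences each (175 sequences).
#'
#' @param plans list of [column_plan] objects, one per column.
#' @param group_sizes named integer vector: group label -> number of
#'   sequences. Default five ABCG-style groups of 35.
#' @param seed integer seed governing all randomness of the generator.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(plans,
                            group_sizes = stats::setNames(
                              rep(35L, 5L),
                              c("ABCG1", "ABCG2", "ABCG4", "ABCG5",
                                "ABCG8")),
                            seed = 1L) {
  stopifnot(is.list(plans), length(plans) >= 1L,
            all(vapply(plans, inherits, logical(1), "column_plan")),
            is.numeric(group_sizes), !is.null(names(group_sizes)),
            all(group_sizes >= 2))
  structure(list(plans = plans, group_sizes = group_sizes,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# expected plug-in entropy of the noisy conserved-group distribution:
# correct residue with prob 1-eps, each of the other 19 with eps/19
noisy_entropy_bound <- function(eps) {
  if (eps <= 0) return(0)
  -( (1 - eps) * log2(1 - eps) + eps * log2(eps / 19) )
}

# validate a plan analytically against the classifier's thresholds
validate_plan <- function(plan, group_sizes, params) {
  thr <- params$conservation_threshold_bits
  groups <- names(group_sizes)
  if (plan$status %in% c("ALL_CONSERVED", "PATTERN") &&
      plan$noise_rate > 0) {
    h <- noisy_entropy_bound(plan$noise_rate)
    if (h >= thr)
      stop("plan-validation error: noise_rate ", plan$noise_rate,
           " gives expected within-group entropy ", signif(h, 4),
           " bits >= threshold ", signif(thr, 4), call. = FALSE)
  }
  if (plan$status == "PATTERN") {
    members <- unlist(plan$blocks)
    bad <- setdiff(c(members, plan$unconserved), groups)
    if (length(bad))
      stop("plan-validation error: unknown group(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (!setequal(c(members, plan$unconserved), groups) ||
        anyDuplicated(c(members, plan$unconserved)))
      stop("plan-validation error: blocks plus unconserved must ",
           "partition the group set", call. = FALSE)
    # expected whole-column entropy must clear the threshold, else the
    # column would be called ALL_CONSERVED
    n_total <- sum(group_sizes)
    shares <- vapply(plan$blocks, function(gs)
      sum(group_sizes[gs]) / n_total, numeric(1))
    h_min <- -sum(shares * log2(shares))  # unconserved mass only adds bits
    if (length(plan$unconserved) == 0 && h_min < thr)
      stop("plan-validation error: planted blocks give whole-column ",
           "entropy ", signif(h_min, 4), " bits < threshold; the column ",
           "would classify as ALL_CONSERVED", call. = FALSE)
  }
  if (plan$status == "GAP" && plan$gap_rate <= 0)
    stop("plan-validation error: GAP column needs gap_rate > 0",
         call. = FALSE)
  invisible(TRUE)
}

# an as-even-as-possible multiset over `alphabet`, randomly assigned
spread_residues <- function(n, alphabet) {
  base <- rep(alphabet, length.out = max(n, length(alphabet)))[seq_len(n)]
  sample(base, n)
}

#' Generate a grouped alignment with planted column classifications
#'
#' Draws each column according to its [column_plan] and returns both the
#' alignment and the planted ground truth. With `noise_rate = 0` everywhere,
#' classification of the generated alignment with the same thresholds
#' recovers every planted status, divergence type and pattern exactly; the
#' generator checks each plan's feasibility analytically (expected entropies
#' versus the thresholds) and refuses infeasible plans.
#'
#' Gap columns place `ceiling(gap_rate * n_sequences)` gaps (at least
#' enough to meet the overall filter) on a random subset of sequences;
#' remaining cells get an unconserved spread.
#'
#' @param spec a [simulation_spec].
#' @param params the [entropy_params] the plans must be feasible for.
#' @return List with `alignment` (a [grouped_alignment]) and `truth`, a
#'   data frame with `column`, `status`, `divergence`, `pattern` (bracket
#'   notation, empty for non-conserved columns).
#' @examples
#' spec <- simulation_spec(list(column_plan("ALL_CONSERVED")), seed = 7)
#' gen <- generate_alignment(spec)
#' gen$truth
#' @export
generate_alignment <- function(spec, params = entropy_params()) {
  stopifnot(inherits(spec, "simulation_spec"))
  for (plan in spec$plans) validate_plan(plan, spec$group_sizes, params)
  group_sizes <- spec$group_sizes
  groups <- names(group_sizes)
  n_seq <- sum(group_sizes)
  group_of <- rep(groups, times = group_sizes)
  ids <- paste0(group_of, "_", unlist(lapply(group_sizes, seq_len)))
  n_col <- length(spec$plans)
  mat <- matrix("-", nrow = n_seq, ncol = n_col)
  truth <- data.frame(column = seq_len(n_col),
                      status = character(n_col),
                      divergence = character(n_col),
                      pattern = character(n_col),
                      stringsAsFactors = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  rows_of <- split(seq_len(n_seq), factor(group_of, levels = groups))
  for (j in seq_len(n_col)) {
    plan <- spec$plans[[j]]
    col <- character(n_seq)
    emit_conserved <- function(rows, residue, eps) {
      x <- rep(residue, length(rows))
      if (eps > 0) {
        flip <- stats::runif(length(rows)) < eps
        if (any(flip))
          x[flip] <- sample(setdiff(AA20, residue), sum(flip),
                            replace = TRUE)
      }
      x
    }
    emit_unconserved <- function(rows, avoid = character(0)) {
      alphabet <- sample(setdiff(AA20, avoid), 10L)
      spread_residues(length(rows), alphabet)
    }
    if (plan$status == "GAP") {
      n_gap <- max(ceiling(plan$gap_rate * n_seq),
                   ceiling(params$gap_fraction_overall * n_seq))
      gap_rows <- sample(n_seq, n_gap)
      for (g in groups) {
        rows <- setdiff(rows_of[[g]], gap_rows)
        if (length(rows)) col[rows] <- emit_unconserved(rows)
      }
      col[gap_rows] <- "-"
      truth$status[j] <- "GAP"; truth$divergence[j] <- "NONE"
    } else if (plan$status == "ALL_CONSERVED") {
      res <- names(plan$blocks)[1L]
      col <- emit_conserved(seq_len(n_seq), res, plan$noise_rate)
      truth$status[j] <- "ALL_CONSERVED"; truth$divergence[j] <- "TOTAL"
      truth$pattern[j] <- format(conservation_pattern(
        list(groups), groups))
    } else if (plan$status == "NOT_CONSERVED") {
      for (g in groups)
        col[rows_of[[g]]] <- emit_unconserved(rows_of[[g]])
      truth$status[j] <- "NOT_CONSERVED"; truth$divergence[j] <- "NONE"
    } else {
      block_res <- names(plan$blocks)
      for (i in seq_along(plan$blocks)) {
        for (g in plan$blocks[[i]]) {
          col[rows_of[[g]]] <- emit_conserved(rows_of[[g]], block_res[i],
                                              plan$noise_rate)
        }
      }
      for (g in plan$unconserved)
        col[rows_of[[g]]] <- emit_unconserved(rows_of[[g]],
                                              avoid = block_res)
      pat <- conservation_pattern(unname(plan$blocks), groups)
      n_blocks <- length(plan$blocks)
      truth$status[j] <- "PATTERN"
      truth$divergence[j] <-
        if (!length(plan$unconserved) && n_blocks >= 2L) "TYPE_II"
        else if (n_blocks == 1L) "TYPE_I"
        else "MIXED"
      truth$pattern[j] <- format(pat)
    }
    mat[, j] <- col
  }
  aln <- grouped_alignment(apply(mat, 1L, paste, collapse = ""),
                           ids, group_of)
  list(alignment = aln, truth = truth)
}

#' Write a tiny synthetic PDB structure with exact inter-atom distances
#'
#' Builds a minimal, valid PDB file for testing distance-cutoff residue
#' extraction. Each protein residue is a single glycine C-alpha atom; chains
#' are laid out far apart (residues 20 Angstrom apart along x, chains 200
#' Angstrom apart along y) so that only the explicitly requested contacts
#' fall within typical cutoffs. Contacts and ligand atoms are placed at
#' exactly the requested distances.
#'
#' @param path output path for the PDB file.
#' @param chains named integer vector: chain id -> number of residues.
#' @param contacts optional data frame with columns `chain_i`, `res_i`,
#'   `chain_j`, `res_j`, `distance`: residue `res_j` of `chain_j` is moved
#'   to sit exactly `distance` Angstrom from residue `res_i` of `chain_i`.
#' @param ligand optional data frame with columns `near_chain`, `near_res`,
#'   `distance` (one row per ligand atom) placing HETATM atoms of residue
#'   `LIG` (chain `X`) at exact distances from the named residues.
#' @return `path`, invisibly.
#' @export
generate_structure_fixture <- function(path, chains = c(A = 3L),
                                       contacts = NULL, ligand = NULL) {
  stopifnot(is.numeric(chains), !is.null(names(chains)),
            all(chains >= 1))
  if (!is.null(contacts) && any(contacts$distance <= 0))
    stop("construction error: contact distances must be positive",
         call. = FALSE)
  if (!is.null(ligand) && any(ligand$distance <= 0))
    stop("construction error: ligand distances must be positive",
         call. = FALSE)
  coords <- list()
  for (ci in seq_along(chains)) {
    ch <- names(chains)[ci]
    for (r in seq_len(chains[[ci]]))
      coords[[paste0(ch, ".", r)]] <-
        c(x = 20 * r, y = 200 * (ci - 1), z = 0)
  }
  if (!is.null(contacts)) {
    for (i in seq_len(nrow(contacts))) {
      ki <- paste0(contacts$chain_i[i], ".", contacts$res_i[i])
      kj <- paste0(contacts$chain_j[i], ".", contacts$res_j[i])
      if (is.null(coords[[ki]]) || is.null(coords[[kj]]))
        stop("construction error: contact names unknown residue",
             call. = FALSE)
      # place j along +z above i: exact requested distance
      coords[[kj]] <- coords[[ki]] + c(0, 0, contacts$distance[i])
    }
  }
  lines <- character(0)
  serial <- 0L
  atom_line <- function(record, name, resname, chain, resno, xyz,
                        element) {
    serial <<- serial + 1L
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, name, resname, chain, resno,
            xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
  }
  for (ci in seq_along(chains)) {
    ch <- names(chains)[ci]
    for (r in seq_len(chains[[ci]]))
      lines <- c(lines, atom_line("ATOM", "CA", "GLY", ch, r,
                                  coords[[paste0(ch, ".", r)]], "C"))
    lines <- c(lines, "TER")
  }
  if (!is.null(ligand)) {
    for (i in seq_len(nrow(ligand))) {
      k <- paste0(ligand$near_chain[i], ".", ligand$near_res[i])
      if (is.null(coords[[k]]))
        stop("construction error: ligand anchored to unknown residue",
             call. = FALSE)
      xyz <- coords[[k]] + c(0, 0, -ligand$distance[i])
      lines <- c(lines, atom_line("HETATM", "C1", "LIG", "X", i, xyz,
                                  "C"))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
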