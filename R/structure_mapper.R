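#' Map alignment columns to reference residue numbers
#'
#' Builds the bijection between the non-gap columns of one alignment
#' sequence (the reference, e.g. human ABCG2) and residue numbers in that
#' ungapped sequence, optionally shifted by a fixed offset to match a
#' structure's author numbering. Queries run in both directions via
#' [column_to_residue()] and [residue_to_column()].
#'
#' @param aln a [grouped_alignment].
#' @param reference_id sequence id of the reference.
#' @param offset integer added to every residue number (default 0).
#' @return An object of class `column_residue_map`: list with
#'   `reference_id`, `offset` and `pairs`, a data frame with `column`,
#'   `residue_number` and `residue_letter`.
#' @export
build_column_residue_map <- function(aln, reference_id, offset = 0L) {
  stopifnot(inherits(aln, "grouped_alignment"))
  if (!reference_id %in% aln$ids)
    stop("membership error: reference id '", reference_id,
         "' not in alignment", call. = FALSE)
  seq <- aln$residues[reference_id, ]
  nongap <- which(seq != "-")
  pairs <- data.frame(column = nongap,
                      residue_number = seq_along(nongap) + as.integer(offset),
                      residue_letter = seq[nongap],
                      stringsAsFactors = FALSE)
  structure(list(reference_id = reference_id, offset = as.integer(offset),
                 pairs = pairs),
            class = "column_residue_map")
}

#' @rdname build_column_residue_map
#' @param map a `column_residue_map`.
#' @param column 1-based alignment column index.
#' @return `column_to_residue`: the residue number, or `NA` if the reference
#'   is gapped at that column.
#' @export
column_to_residue <- function(map, column) {
  i <- match(column, map$pairs$column)
  map$pairs$residue_number[i]
}

#' @rdname build_column_residue_map
#' @param residue_number residue number in reference (author) numbering.
#' @return `residue_to_column`: the alignment column, or `NA`.
#' @export
residue_to_column <- function(map, residue_number) {
  i <- match(residue_number, map$pairs$residue_number)
  map$pairs$column[i]
}

#' @export
print.column_residue_map <- function(x, ...) {
  cat(sprintf("Column-residue map for '%s': %d residues, offset %d\n",
              x$reference_id, nrow(x$pairs), x$offset))
  invisible(x)
}

# read a structure with bio3d, dispatching on extension
read_structure <- function(structure_path) {
  if (!file.exists(structure_path))
    stop("format error: no such structure file: ", structure_path,
         call. = FALSE)
  ext <- tolower(tools::file_ext(structure_path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(structure_path)
    else bio3d::read.pdb(structure_path),
    error = function(e) stop("format error: cannot parse '",
                             structure_path, "': ", conditionMessage(e),
                             call. = FALSE))
  pdb
}

# drop hydrogens and keep the highest-occupancy alternate conformer per atom
filter_atoms <- function(atom, include_hydrogens = FALSE) {
  if (!include_hydrogens) {
    elesy <- if ("elesy" %in% names(atom)) atom$elesy else
      substr(gsub("^[0-9]", "", atom$elety), 1L, 1L)
    atom <- atom[!(toupper(trimws(elesy)) %in% c("H", "D")), , drop = FALSE]
  }
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
  if (anyDuplicated(key)) {
    occ <- if ("o" %in% names(atom)) atom$o else rep(1, nrow(atom))
    occ[is.na(occ)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(atom)), key),
                          function(i) i[which.max(occ[i])]))
    atom <- atom[sort(keep), , drop = FALSE]
  }
  atom
}

# unique residue identity rows (chain, resno+insert, resname) for atom rows
residue_selection <- function(atom, idx) {
  if (!length(idx))
    return(data.frame(chain = character(0), resnum = character(0),
                      resname = character(0), stringsAsFactors = FALSE))
  sel <- atom[idx, , drop = FALSE]
  key <- paste(sel$chain, sel$resno, sel$insert)
  first <- !duplicated(key)
  out <- data.frame(chain = sel$chain[first],
                    resnum = paste0(sel$resno[first], sel$insert[first]),
                    resname = sel$resid[first],
                    stringsAsFactors = FALSE)
  out[order(out$chain, sel$resno[first], sel$insert[first]), ,
      drop = FALSE]
}

# indices of rows in atom_a with any atom within cutoff of atom_b
within_cutoff <- function(atom_a, atom_b, cutoff) {
  if (!nrow(atom_a) || !nrow(atom_b)) return(integer(0))
  xa <- as.matrix(atom_a[, c("x", "y", "z")])
  xb <- as.matrix(atom_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  which(apply(d2, 1L, function(r) any(sqrt(r) <= cutoff)))
}

#' Residues near a bound ligand
#'
#' Extracts all residues of a target chain having at least one heavy atom
#' within `cutoff_angstrom` (inclusive) of any heavy atom of the ligand --
#' the standard definition of a binding pocket at a distance cutoff.
#' Hydrogens are excluded by default (cryo-EM structures typically lack
#' them); alternate locations keep the highest-occupancy conformer only.
#'
#' @param structure_path path to a PDB or mmCIF file.
#' @param target_chain author chain id of the protein chain.
#' @param ligand_selector either a residue name (e.g. `"LIG"`, matched
#'   against HETATM residue names) or a chain id holding the ligand.
#' @param cutoff_angstrom distance cutoff in Angstrom (default 5).
#' @param include_hydrogens include hydrogen/deuterium atoms.
#' @return Data frame with columns `chain`, `resnum` (author numbering,
#'   insertion code appended) and `resname`.
#' @export
residues_near_ligand <- function(structure_path, target_chain,
                                 ligand_selector, cutoff_angstrom = 5,
                                 include_hydrogens = FALSE) {
  pdb <- read_structure(structure_path)
  atom <- filter_atoms(pdb$atom, include_hydrogens)
  lig <- atom[atom$type == "HETATM" &
                (atom$resid == ligand_selector |
                   atom$chain == ligand_selector), , drop = FALSE]
  if (!nrow(lig))
    lig <- atom[atom$chain == ligand_selector &
                  atom$chain != target_chain, , drop = FALSE]
  if (!nrow(lig))
    stop("selection error: ligand selector '", ligand_selector,
         "' matches no atoms; available chains: ",
         paste(unique(atom$chain), collapse = ", "), call. = FALSE)
  prot <- atom[atom$chain == target_chain & atom$type == "ATOM", ,
               drop = FALSE]
  if (!nrow(prot))
    stop("selection error: no polymer atoms in chain '", target_chain,
         "'; available chains: ",
         paste(unique(atom$chain), collapse = ", "), call. = FALSE)
  residue_selection(prot, within_cutoff(prot, lig, cutoff_angstrom))
}

#' Residues at a protomer-protomer interface
#'
#' Extracts, for each of two chains, the residues with any heavy atom within
#' `cutoff_angstrom` of the partner chain -- the dimer-interface residue set
#' at a distance cutoff. Only polymer (ATOM) residues are considered on both
#' sides; waters and ligands sitting between the protomers do not mediate
#' membership.
#'
#' @inheritParams residues_near_ligand
#' @param chain_a,chain_b author chain ids of the two protomers.
#' @return Data frame (`chain`, `resnum`, `resname`) holding both sides of
#'   the interface.
#' @export
interface_residues <- function(structure_path, chain_a, chain_b,
                               cutoff_angstrom = 5,
                               include_hydrogens = FALSE) {
  pdb <- read_structure(structure_path)
  atom <- filter_atoms(pdb$atom, include_hydrogens)
  poly <- atom[atom$type == "ATOM", , drop = FALSE]
  a <- poly[poly$chain == chain_a, , drop = FALSE]
  b <- poly[poly$chain == chain_b, , drop = FALSE]
  for (ch in c(chain_a, chain_b)[c(!nrow(a), !nrow(b))])
    stop("selection error: no polymer atoms in chain '", ch,
         "'; available chains: ",
         paste(unique(atom$chain), collapse = ", "), call. = FALSE)
  rbind(residue_selection(a, within_cutoff(a, b, cutoff_angstrom)),
        residue_selection(b, within_cutoff(b, a, cutoff_angstrom)))
}

#' Sidechain chemistry of a pattern's conserved residues, per group
#'
#' For every column carrying the given conservation pattern, each conserved
#' group's recorded residue is classified as charged, hydroxylated (serine
#' or threonine) or other, and the counts are accumulated per group. This
#' reproduces summaries such as "seven charged residues in ABCG8 versus one
#' in ABCG2" over a pattern's column set.
#'
#' @param fit a `divergence_calls` object from [classify_alignment()].
#' @param pattern a [conservation_pattern]; only columns whose call matches
#'   it exactly contribute.
#' @param charged residue letters counted as charged. Histidine is included
#'   by default but the set is configurable (its protonation is
#'   context-dependent).
#' @param hydroxylated residue letters counted as hydroxylated.
#' @return Matrix with one row per conserved group of the pattern and
#'   columns `charged`, `hydroxylated`, `other`, `total`; a zero-row matrix
#'   if the pattern never occurs.
#' @export
sidechain_summary <- function(fit, pattern,
                              charged = c("D", "E", "K", "R", "H"),
                              hydroxylated = c("S", "T")) {
  stopifnot(inherits(fit, "divergence_calls"),
            inherits(pattern, "conservation_pattern"))
  key <- format(pattern)
  groups <- unlist(pattern$blocks)
  out <- matrix(0L, nrow = length(groups), ncol = 4L,
                dimnames = list(groups,
                                c("charged", "hydroxylated", "other",
                                  "total")))
  for (cl in fit$calls) {
    if (!cl$status %in% c("PATTERN", "ALL_CONSERVED")) next
    if (format(call_pattern(cl, fit$groups)) != key) next
    for (b in cl$blocks) {
      cls <- if (b$residue %in% charged) "charged"
             else if (b$residue %in% hydroxylated) "hydroxylated"
             else "other"
      for (g in b$groups) {
        out[g, cls] <- out[g, cls] + 1L
        out[g, "total"] <- out[g, "total"] + 1L
      }
    }
  }
  out
}
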