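# Shared fixtures: all built in code, nothing read from disk.

ABCG_GROUPS <- c("ABCG1", "ABCG2", "ABCG4", "ABCG5", "ABCG8")

# a small two-group alignment: 4 sequences x 10 columns
tiny_alignment <- function() {
  grouped_alignment(
    c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKV", "ACDEFGHIKV"),
    ids = c("a1", "a2", "b1", "b2"),
    groups = c("gA", "gA", "gB", "gB"))
}

# five groups of `size` sequences, one column per entry of `cols`;
# cols is a list of length-5 character vectors (residue per group) or a
# single string "gap"/"mix" handled by the caller
per_group_column_alignment <- function(cols, size = 3L) {
  n_col <- length(cols)
  seqs <- character(0); ids <- character(0); groups <- character(0)
  for (g in seq_along(ABCG_GROUPS)) {
    for (s in seq_len(size)) {
      seqs <- c(seqs, paste(vapply(cols, function(co) co[g], ""),
                            collapse = ""))
      ids <- c(ids, paste0(ABCG_GROUPS[g], "_", s))
      groups <- c(groups, ABCG_GROUPS[g])
    }
  }
  grouped_alignment(seqs, ids, groups)
}

# Bell numbers via the Bell triangle -- independent oracle for the
# pattern-count closed form
bell_numbers <- function(n) {
  out <- numeric(n)
  row <- 1
  for (i in seq_len(n)) {
    out[i] <- row[1]
    nxt <- numeric(i + 1)
    nxt[1] <- row[i]
    for (j in seq_len(i)) nxt[j + 1] <- nxt[j] + row[j]
    row <- nxt
  }
  out
}

# independent plug-in entropy (different code path from the package)
oracle_entropy <- function(letters) {
  letters <- letters[letters %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]]
  p <- as.numeric(table(letters)) / length(letters)
  -sum(p * log(p)) / log(2)
}
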