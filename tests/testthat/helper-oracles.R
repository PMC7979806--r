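# Independent oracles and fixture builders shared across the suite.
# Each oracle is a direct, naive restatement of the quantity it checks and
# never calls the implementation path it validates.

# exhaustive enumeration of every global alignment (monotone lattice path),
# scored incrementally with affine gaps: a gap run of length L costs
# open + (L - 1) * extend
oracle_align_score <- function(a, b, subst, open = 10, ext = 1) {
  la <- strsplit(a, "")[[1]]
  lb <- strsplit(b, "")[[1]]
  n <- length(la)
  m <- length(lb)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i == n && j == m) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i < n && j < m)
      rec(i + 1L, j + 1L, 0L, sc + subst[la[i + 1L], lb[j + 1L]])
    if (i < n) rec(i + 1L, j, 1L, sc - if (prev == 1L) ext else open)
    if (j < m) rec(i, j + 1L, 2L, sc - if (prev == 2L) ext else open)
  }
  rec(0L, 0L, 0L, 0)
  best
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
})

random_aa_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# closed-form SASA of two identical overlapping spheres (expanded radius R,
# center distance d < 2R): each sphere loses a cap of height R - d/2
two_sphere_sasa <- function(r, probe, d) {
  R <- r + probe
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# brute-force connected components of the threshold graph on a point set
oracle_threshold_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d <= cutoff && lab[j] < lab[i]) {
          lab[i] <- lab[j]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# two labelings describe the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# minimal fixed-column PDB ATOM line writer for hand-built fixtures
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = NULL) {
  if (is.null(element))
    element <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), alt, resname, chain, resno,
          x, y, z, occ, 0, element)
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# small mutation-table fixture in the catalog TSV dialect
write_fixture_catalog <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
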