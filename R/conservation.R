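#' Default alignment parameters
#'
#' BLOSUM62 with gap open 10 and gap extend 1 on the raw integer score
#' scale. The gap convention charges `gap_open` for the first position of a
#' gap run and `gap_extend` for each additional position, so a run of length
#' L costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param matrix substitution matrix name (any matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`) or a numeric
#'   matrix with amino-acid dimnames.
#' @param gap_open penalty for the first position of a gap run (positive).
#' @param gap_extend penalty per additional gap position (positive).
#' @return a list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "align_params")
}

substitution_matrix <- function(spec) {
  if (is.matrix(spec)) return(spec)
  env <- new.env()
  utils::data(list = spec, package = "Biostrings", envir = env)
  get(spec, envir = env)
}

check_aa_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(what, " must be a single non-empty string")
  letters <- strsplit(seq, "")[[1]]
  ok <- letters %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  if (!all(ok))
    stop(what, ": illegal character '", letters[which(!ok)[1]],
         "' at position ", which(!ok)[1])
  letters
}

#' Optimal global alignment of two protein sequences (affine gaps)
#'
#' Needleman-Wunsch global alignment with affine gap penalties (Gotoh
#' three-state recursion). Traceback ties are resolved deterministically:
#' substitution column first, then gap in `seq_b` (consuming `seq_a`), then
#' gap in `seq_a`, so repeated runs are bit-identical.
#'
#' @param seq_a,seq_b protein sequences (single strings over the 20 standard
#'   amino acids; `X` tolerated and scored by the substitution matrix).
#' @param params an [align_params()] object.
#' @param id_a,id_b sequence identifiers stored in the result.
#' @return an object of class `aligned_pair`: list with `id_a`, `id_b`,
#'   `rows` (two equal-length gapped strings), `score`, and `params`.
#' @examples
#' global_align("HEAGAWGHEE", "PAWHEAE")
#' @export
global_align <- function(seq_a, seq_b, params = align_params(),
                         id_a = "a", id_b = "b") {
  la <- check_aa_seq(seq_a, "seq_a")
  lb <- check_aa_seq(seq_b, "seq_b")
  subst <- substitution_matrix(params$matrix)
  alpha <- rownames(subst)
  ia <- match(la, alpha)
  ib <- match(lb, alpha)
  if (anyNA(ia) || anyNA(ib))
    stop("sequence letter missing from the substitution matrix alphabet")
  res <- .nw_affine_cpp(ia - 1L, ib - 1L, subst,
                        params$gap_open, params$gap_extend)
  ops <- res$ops
  ra <- rb <- character(length(ops))
  i <- j <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      i <- i + 1L; j <- j + 1L
      ra[k] <- la[i]; rb[k] <- lb[j]
    } else if (ops[k] == 1L) {
      i <- i + 1L
      ra[k] <- la[i]; rb[k] <- "-"
    } else {
      j <- j + 1L
      ra[k] <- "-"; rb[k] <- lb[j]
    }
  }
  new_aligned_pair(id_a, id_b,
                   c(paste(ra, collapse = ""), paste(rb, collapse = "")),
                   score = res$score, params = params)
}

#' Construct an aligned pair from two gapped rows
#'
#' Used when an external alignment (or a generator that knows the truth
#' alignment) supplies the rows directly.
#'
#' @param id_a,id_b sequence identifiers.
#' @param rows character vector of two equal-length gapped rows; no column
#'   may carry a gap in both.
#' @param score optional aligner objective value.
#' @param params optional [align_params()].
#' @return an `aligned_pair`.
#' @export
aligned_pair <- function(id_a, id_b, rows, score = NA_real_, params = NULL) {
  new_aligned_pair(id_a, id_b, rows, score, params)
}

new_aligned_pair <- function(id_a, id_b, rows, score = NA_real_,
                             params = NULL) {
  if (length(rows) != 2L || nchar(rows[1]) != nchar(rows[2]))
    stop("an aligned pair needs two equal-length rows")
  ga <- strsplit(rows[1], "")[[1]] == "-"
  gb <- strsplit(rows[2], "")[[1]] == "-"
  if (any(ga & gb))
    stop("alignment contains a column with a gap in both rows")
  structure(list(id_a = id_a, id_b = id_b, rows = rows,
                 score = score, params = params),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, width = 60, ...) {
  cat("aligned_pair:", x$id_a, "vs", x$id_b,
      sprintf("(%d columns, score %s)\n", nchar(x$rows[1]),
              format(x$score)))
  n <- nchar(x$rows[1])
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    cat(substr(x$rows[1], s, e), "\n")
    cat(substr(x$rows[2], s, e), "\n\n")
  }
  invisible(x)
}

#' Read an alignment from an aligned-FASTA or Clustal file
#'
#' Rows are preserved verbatim, gaps included. For `format = "clustal"` the
#' Biostrings reader is used (header line starting `CLUSTAL`, blocks of
#' `id  sequence` rows, optional conservation lines). Two rows give an
#' `aligned_pair`; more give a plain character matrix of rows with one row
#' per sequence.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return an `aligned_pair` (2 rows) or a named character vector of aligned
#'   rows (> 2).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    aln <- Biostrings::readAAStringSet(path)
    rows <- as.character(aln)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    rows <- as.character(aln)
  }
  if (length(rows) < 2L) stop("alignment must contain at least two rows")
  if (anyDuplicated(names(rows)))
    stop("duplicate sequence ids in alignment: ",
         names(rows)[anyDuplicated(names(rows))])
  if (length(unique(nchar(rows))) != 1L)
    stop("ragged alignment: rows differ in length")
  if (length(rows) == 2L)
    return(new_aligned_pair(names(rows)[1], names(rows)[2], unname(rows)))
  rows
}

#' Percent identity of an aligned pair
#'
#' Identical non-gap columns as a percentage of either the total number of
#' alignment columns (default) or the length of the shorter ungapped
#' sequence; both conventions are reported because published identity
#' figures rarely state theirs.
#'
#' @param pair an `aligned_pair`.
#' @param denominator `"columns"` or `"shorter_seq"`.
#' @return a list with `identical_columns`, `columns`, `shorter_seq`,
#'   `identity` (the requested convention) and `identity_columns` /
#'   `identity_shorter` (both conventions).
#' @export
percent_identity <- function(pair, denominator = c("columns", "shorter_seq")) {
  stopifnot(inherits(pair, "aligned_pair"))
  denominator <- match.arg(denominator)
  a <- strsplit(pair$rows[1], "")[[1]]
  b <- strsplit(pair$rows[2], "")[[1]]
  ident <- sum(a == b & a != "-")
  ncol <- length(a)
  nshort <- min(sum(a != "-"), sum(b != "-"))
  out <- list(identical_columns = ident, columns = ncol,
              shorter_seq = nshort,
              identity_columns = 100 * ident / ncol,
              identity_shorter = 100 * ident / nshort)
  out$identity <- if (denominator == "columns") out$identity_columns
                  else out$identity_shorter
  out
}

#' Residue-position correspondence between the two rows of an alignment
#'
#' Walks the alignment columns and records, for every column where both rows
#' carry a residue, the matched pair of 1-based sequence positions. Matched
#' positions are strictly increasing in both sequences (monotonicity) and
#' each position appears at most once.
#'
#' @param pair an `aligned_pair`.
#' @return an object of class `residue_correspondence`: list with `pairs`
#'   (data.frame `pos_a`, `aa_a`, `pos_b`, `aa_b`, `status`
#'   identical/substituted), `unmatched_a`, `unmatched_b` (positions aligned
#'   to a gap).
#' @export
residue_correspondence <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  a <- strsplit(pair$rows[1], "")[[1]]
  b <- strsplit(pair$rows[2], "")[[1]]
  pos_a <- cumsum(a != "-")
  pos_b <- cumsum(b != "-")
  both <- a != "-" & b != "-"
  pairs <- data.frame(pos_a = pos_a[both], aa_a = a[both],
                      pos_b = pos_b[both], aa_b = b[both],
                      status = ifelse(a[both] == b[both],
                                      "identical", "substituted"),
                      stringsAsFactors = FALSE)
  structure(list(id_a = pair$id_a, id_b = pair$id_b, pairs = pairs,
                 unmatched_a = pos_a[a != "-" & b == "-"],
                 unmatched_b = pos_b[b != "-" & a == "-"],
                 len_a = sum(a != "-"), len_b = sum(b != "-")),
            class = "residue_correspondence")
}

#' Map a residue position across a correspondence
#'
#' @param corr a `residue_correspondence`.
#' @param pos_a 1-based position in sequence A (scalar or vector).
#' @param from `"a"` (default) or `"b"`: which sequence `pos_a` refers to.
#' @return integer vector of partner positions; `NA` marks a position
#'   aligned to a gap. Out-of-range positions are an error.
#' @export
map_residue <- function(corr, pos_a, from = c("a", "b")) {
  stopifnot(inherits(corr, "residue_correspondence"))
  from <- match.arg(from)
  len <- if (from == "a") corr$len_a else corr$len_b
  if (any(pos_a < 1 | pos_a > len))
    stop("position out of range 1..", len)
  key <- if (from == "a") corr$pairs$pos_a else corr$pairs$pos_b
  val <- if (from == "a") corr$pairs$pos_b else corr$pairs$pos_a
  val[match(pos_a, key)]
}

#' Write a residue correspondence as TSV
#'
#' @param corr a `residue_correspondence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_correspondence <- function(corr, path) {
  write.table(corr$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call conserved residues against one or more ortholog alignments
#'
#' For each human residue position of interest, looks up the aligned column
#' in each ortholog pairwise alignment (human sequence as row A) and records
#' whether the ortholog carries the identical residue, a substitution, or a
#' gap. A residue is conserved when it is identical in at least one
#' designated ortholog — the strict-identity convention; a similarity mode
#' (`mode = "similar"`: positive substitution score also counts) is
#' available but off by default.
#'
#' @param positions integer vector of 1-based human residue positions, or a
#'   `residue_set` from [mutated_residues()].
#' @param human_seq the human protein sequence (used to verify that each
#'   alignment's A row ungaps to it).
#' @param alignments a named list of `aligned_pair` objects, human sequence
#'   as the first row; names are the ortholog labels.
#' @param mode `"identity"` (default) or `"similar"`.
#' @param params [align_params()] whose matrix scores the `"similar"` mode.
#' @return a data.frame of class `conservation_calls`: `position`,
#'   `human_aa`, one status column per ortholog (identical / substituted /
#'   gap), and logical `conserved`.
#' @export
call_conserved <- function(positions, human_seq, alignments,
                           mode = c("identity", "similar"),
                           params = align_params()) {
  mode <- match.arg(mode)
  if (inherits(positions, "residue_set")) positions <- positions$position
  positions <- sort(unique(as.integer(positions)))
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be a named list (ortholog labels)")
  human <- check_aa_seq(human_seq, "human_seq")
  subst <- substitution_matrix(params$matrix)

  status <- matrix(NA_character_, nrow = length(positions),
                   ncol = length(alignments),
                   dimnames = list(NULL, names(alignments)))
  conserved <- rep(FALSE, length(positions))
  for (orth in names(alignments)) {
    pair <- alignments[[orth]]
    stopifnot(inherits(pair, "aligned_pair"))
    ungapped <- gsub("-", "", pair$rows[1])
    if (!identical(ungapped, human_seq))
      stop("alignment '", orth, "': row A does not ungap to the stated ",
           "human sequence")
    corr <- residue_correspondence(pair)
    hit <- match(positions, corr$pairs$pos_a)
    st <- rep("gap", length(positions))
    matched <- !is.na(hit)
    st[matched] <- corr$pairs$status[hit[matched]]
    status[, orth] <- st
    conserved <- conserved | st == "identical"
    if (mode == "similar" && any(matched)) {
      aa_a <- corr$pairs$aa_a[hit[matched]]
      aa_b <- corr$pairs$aa_b[hit[matched]]
      sim <- subst[cbind(aa_a, aa_b)] > 0
      conserved[matched] <- conserved[matched] | sim
    }
  }
  out <- data.frame(position = positions,
                    human_aa = human[positions],
                    status, conserved = conserved,
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("conservation_calls", class(out))
  out
}

#' Fully conserved columns of a short aligned region block
#'
#' Given equal-length region sequences (e.g. one HEAT-repeat unit from each
#' of several PIKK orthologs, already aligned), reports the columns at which
#' all rows carry the identical residue.
#'
#' @param seqs character vector of equal-length region sequences (gaps
#'   allowed; a gap column is never conserved).
#' @return a data.frame with `column` (1-based), `residue` for each fully
#'   conserved column.
#' @export
hr_block_alignment <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least two region sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("region sequences must be equal length (pre-aligned block)")
  m <- do.call(rbind, strsplit(seqs, ""))
  same <- apply(m, 2, function(col) length(unique(col)) == 1L && col[1] != "-")
  data.frame(column = which(same), residue = m[1, same],
             stringsAsFactors = FALSE)
}
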