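#' Parse a protein-change string into consequence class and residue change
#'
#' Classifies an HGVS-p-like short protein change (as exported by cBioPortal,
#' e.g. `"S1413F"`, `"Q100*"`, `"K200fs"`, `"E300del"`) into one of four
#' consequence classes and extracts the residue position and amino acids
#' where the string encodes them.
#'
#' Classification rules, applied in order:
#' \enumerate{
#'   \item contains `*` or ends in `fs` (optionally `fs*<n>`): `truncation`;
#'   \item contains `del`, `ins` or `dup` (without a frameshift): `inframe`;
#'   \item matches a single substitution `[A-Z][0-9]+[A-Z]` with distinct
#'     standard amino acids: `missense`;
#'   \item anything else (splice notation, `X`, unparseable): `other`.
#' }
#' A leading `"p."` prefix is tolerated. Positions are 1-based protein
#' coordinates. Unknown grammars are never an error; they classify as
#' `other` with the position absent.
#'
#' @param change character vector of protein-change strings (non-empty).
#' @return a data.frame with columns `protein_change`, `consequence`
#'   (factor: missense/truncation/inframe/other), `position` (integer, NA
#'   when not encoded), `ref_aa`, `alt_aa` (NA except for missense).
#' @examples
#' parse_protein_change(c("S1413F", "Q100*", "E300del", "X100_splice"))
#' @export
parse_protein_change <- function(change) {
  if (length(change) == 0L) return(parse_result(character(0)))
  if (!is.character(change) || anyNA(change) || any(!nzchar(change)))
    stop("protein change strings must be non-empty character values")
  x <- sub("^p\\.", "", change)

  cons <- rep("other", length(x))
  pos <- rep(NA_integer_, length(x))
  ref <- alt <- rep(NA_character_, length(x))

  trunc <- grepl("\\*", x) | grepl("fs$", x)
  inframe <- !trunc & grepl("del|ins|dup", x, ignore.case = FALSE)
  mis_pat <- "^([A-Z])([0-9]+)([A-Z])$"
  mis <- !trunc & !inframe & grepl(mis_pat, x)

  aa1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (any(mis)) {
    r <- sub(mis_pat, "\\1", x[mis])
    a <- sub(mis_pat, "\\3", x[mis])
    p <- as.integer(sub(mis_pat, "\\2", x[mis]))
    ok <- r %in% aa1 & a %in% aa1 & r != a
    idx <- which(mis)[ok]
    cons[idx] <- "missense"
    pos[idx] <- p[ok]
    ref[idx] <- r[ok]
    alt[idx] <- a[ok]
  }
  # position for truncation/inframe: first residue number in the string
  num_pat <- "^[^0-9]*([0-9]+).*$"
  for (cls in list(which(trunc), which(inframe))) {
    has_num <- grepl("[0-9]", x[cls])
    p <- rep(NA_integer_, length(cls))
    p[has_num] <- as.integer(sub(num_pat, "\\1", x[cls][has_num]))
    pos[cls] <- p
  }
  cons[trunc] <- "truncation"
  cons[inframe] <- "inframe"

  parse_result(x, cons, pos, ref, alt)
}

parse_result <- function(x, cons = character(0), pos = integer(0),
                         ref = character(0), alt = character(0)) {
  data.frame(protein_change = x,
             consequence = factor(cons, levels = consequence_levels()),
             position = as.integer(pos),
             ref_aa = as.character(ref),
             alt_aa = as.character(alt),
             stringsAsFactors = FALSE)
}

consequence_levels <- function() c("missense", "truncation", "inframe", "other")

# header synonyms accepted on input (cBioPortal export dialects)
catalog_header_synonyms <- function() {
  list(gene = c("gene", "Hugo_Symbol", "Gene"),
       sample_id = c("sample_id", "Tumor_Sample_Barcode", "Sample ID",
                     "Sample.ID", "SAMPLE_ID"),
       cancer_type = c("cancer_type", "Cancer Type", "Cancer.Type",
                       "CANCER_TYPE"),
       protein_change = c("protein_change", "Protein Change",
                          "Protein.Change", "HGVSp_Short"),
       mutation_type = c("mutation_type", "Mutation Type", "Mutation.Type",
                         "Variant_Classification"))
}

#' Load a cBioPortal-style mutation table into a mutation catalog
#'
#' Reads a tab-separated mutation export (header required; UTF-8) with
#' columns `gene`, `sample_id`, `cancer_type`, `protein_change` (cBioPortal
#' export headers such as `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Protein Change`/`HGVSp_Short` are accepted as synonyms), classifies each
#' protein change with [parse_protein_change()], and returns a
#' `mutation_catalog`.
#'
#' `cohort_size` is the total number of tumor samples screened, which must be
#' supplied because samples without a mutation never appear in an export.
#'
#' @param path path to the TSV file.
#' @param cohort_size total number of samples in the cohort (> 0).
#' @param genes optional character vector; rows for other genes are skipped.
#' @return an object of class `mutation_catalog`: a list with `records`
#'   (data.frame, one row per mutation with `row` giving the source data-row
#'   number), `cohort_size`, and `provenance`.
#' @seealso [write_catalog()], [gene_mutation_frequency()],
#'   [mutated_residues()], [consequence_counts()]
#' @export
load_catalog <- function(path, cohort_size, genes = NULL) {
  stopifnot(is.numeric(cohort_size), length(cohort_size) == 1L)
  if (cohort_size <= 0) stop("cohort_size must be a positive count")
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
  syn <- catalog_header_synonyms()
  cols <- lapply(syn, function(alts) {
    hit <- intersect(alts, names(raw))
    if (length(hit)) hit[1] else NA_character_
  })
  mandatory <- c("gene", "sample_id", "cancer_type", "protein_change")
  missing_col <- mandatory[is.na(unlist(cols[mandatory]))]
  if (length(missing_col))
    stop("mutation table is missing mandatory column(s): ",
         paste(missing_col, collapse = ", "))

  n <- nrow(raw)
  records <- data.frame(
    gene = as.character(raw[[cols$gene]]),
    sample_id = as.character(raw[[cols$sample_id]]),
    cancer_type = as.character(raw[[cols$cancer_type]]),
    protein_change = as.character(raw[[cols$protein_change]]),
    row = seq_len(n),
    stringsAsFactors = FALSE)

  bad <- which(is.na(records$sample_id) | !nzchar(records$sample_id))
  if (length(bad))
    stop("row ", bad[1], ": missing sample id")
  bad <- which(is.na(records$protein_change) | !nzchar(records$protein_change))
  if (length(bad))
    stop("row ", bad[1], ": missing protein change")

  if (!is.null(genes)) records <- records[records$gene %in% genes, ]

  parsed <- parse_protein_change(records$protein_change)
  records$consequence <- parsed$consequence
  records$position <- parsed$position
  records$ref_aa <- parsed$ref_aa
  records$alt_aa <- parsed$alt_aa
  rownames(records) <- NULL

  n_samples <- length(unique(records$sample_id))
  if (cohort_size < n_samples)
    stop("cohort_size (", cohort_size, ") is smaller than the number of ",
         "distinct samples carrying a mutation (", n_samples, ")")

  new_mutation_catalog(records, cohort_size,
                       provenance = list(path = path, n_rows = n))
}

new_mutation_catalog <- function(records, cohort_size, provenance = list()) {
  structure(list(records = records,
                 cohort_size = as.integer(cohort_size),
                 provenance = provenance),
            class = "mutation_catalog")
}

#' Build a mutation catalog from an in-memory data frame
#'
#' Convenience constructor used by the synthetic-data generator and by
#' worked examples; applies the same parsing and consistency checks as
#' [load_catalog()] but takes a data.frame with columns `gene`, `sample_id`,
#' `cancer_type`, `protein_change`.
#'
#' @param df data.frame of mutation rows.
#' @param cohort_size total number of samples screened.
#' @return a `mutation_catalog`.
#' @export
mutation_catalog <- function(df, cohort_size) {
  need <- c("gene", "sample_id", "cancer_type", "protein_change")
  if (!all(need %in% names(df)))
    stop("data frame must have columns: ", paste(need, collapse = ", "))
  if (cohort_size <= 0) stop("cohort_size must be a positive count")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  records <- df[need]
  records$row <- seq_len(nrow(records))
  parsed <- parse_protein_change(records$protein_change)
  records <- cbind(records, parsed[c("consequence", "position",
                                     "ref_aa", "alt_aa")])
  n_samples <- length(unique(records$sample_id))
  if (cohort_size < n_samples)
    stop("cohort_size is smaller than the number of distinct mutated samples")
  new_mutation_catalog(records, cohort_size)
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("mutation_catalog:", nrow(x$records), "records,",
      length(unique(x$records$sample_id)), "samples with a mutation,",
      "cohort size", x$cohort_size, "\n")
  tab <- table(x$records$gene)
  if (length(tab)) {
    cat("genes:", paste(sprintf("%s (%d)", names(tab), tab),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a mutation catalog back to the input TSV dialect
#'
#' Writes the canonical columns (`gene`, `sample_id`, `cancer_type`,
#' `protein_change`) tab-separated with a header, so that
#' [load_catalog()] on the output reproduces identical records.
#'
#' @param catalog a `mutation_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  out <- catalog$records[c("gene", "sample_id", "cancer_type",
                           "protein_change")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene mutation frequency across the cohort
#'
#' The percentage of cohort samples carrying at least one mutation in the
#' gene; a sample counts once regardless of how many mutations it carries
#' (e.g. 2551 ATM-mutated samples in a 46,588-sample cohort give 5.5%).
#'
#' @param catalog a `mutation_catalog`.
#' @param gene gene symbol.
#' @return a list with `gene`, `mutated_samples`, `cohort_size`, `frequency`
#'   (raw percentage) and `frequency_pct` (rounded to one decimal, half-up,
#'   as conventionally printed).
#' @export
gene_mutation_frequency <- function(catalog, gene) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  if (catalog$cohort_size <= 0) stop("cohort_size must be positive")
  rec <- catalog$records[catalog$records$gene == gene, ]
  k <- length(unique(rec$sample_id))
  raw <- 100 * k / catalog$cohort_size
  list(gene = gene, mutated_samples = k, cohort_size = catalog$cohort_size,
       frequency = raw, frequency_pct = round1_half_up(raw))
}

#' Residues of a gene mutated in the catalog
#'
#' Returns the set of protein positions mutated in the gene, optionally
#' restricted to a cancer type, with one entry per position however many
#' records or distinct substitutions hit it. The default consequence filter
#' is `"missense"` (residues "mutated to a different residue"); pass several
#' classes or all four to widen it.
#'
#' @param catalog a `mutation_catalog`.
#' @param gene gene symbol.
#' @param cancer_type optional single cancer-type label; an unknown label is
#'   an error listing the known labels.
#' @param consequences character vector of consequence classes to keep.
#' @return an object of class `residue_set`: data.frame with columns `gene`,
#'   `position`, `cancer_types` (comma-joined), `n_records`, `alt_residues`
#'   (comma-joined distinct alternate residues).
#' @export
mutated_residues <- function(catalog, gene, cancer_type = NULL,
                             consequences = "missense") {
  stopifnot(inherits(catalog, "mutation_catalog"))
  consequences <- match.arg(consequences, consequence_levels(),
                            several.ok = TRUE)
  rec <- catalog$records[catalog$records$gene == gene, ]
  if (!is.null(cancer_type)) {
    known <- sort(unique(catalog$records$cancer_type))
    if (!cancer_type %in% known)
      stop("unknown cancer type '", cancer_type, "'; known types: ",
           paste(known, collapse = ", "))
    rec <- rec[rec$cancer_type == cancer_type, ]
  }
  rec <- rec[rec$consequence %in% consequences & !is.na(rec$position), ]
  if (nrow(rec) == 0L) {
    out <- data.frame(gene = character(0), position = integer(0),
                      cancer_types = character(0), n_records = integer(0),
                      alt_residues = character(0), stringsAsFactors = FALSE)
    class(out) <- c("residue_set", class(out))
    return(out)
  }
  sp <- split(rec, rec$position)
  out <- data.frame(
    gene = gene,
    position = as.integer(names(sp)),
    cancer_types = vapply(sp, function(d)
      paste(sort(unique(d$cancer_type)), collapse = ","), character(1)),
    n_records = vapply(sp, nrow, integer(1)),
    alt_residues = vapply(sp, function(d)
      paste(sort(unique(d$alt_aa[!is.na(d$alt_aa)])), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  class(out) <- c("residue_set", class(out))
  out
}

#' Counts of mutation records per consequence class for a gene
#'
#' @param catalog a `mutation_catalog`.
#' @param gene gene symbol.
#' @return named integer vector over the four classes (missense, truncation,
#'   inframe, other); the counts partition the gene's records.
#' @export
consequence_counts <- function(catalog, gene) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  rec <- catalog$records[catalog$records$gene == gene, ]
  tab <- table(factor(rec$consequence, levels = consequence_levels()))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Write a residue set as TSV
#'
#' @param rset a `residue_set` from [mutated_residues()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_residue_set <- function(rset, path) {
  write.table(as.data.frame(rset), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
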