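#' Read a PDB coordinate file into a structure model
#'
#' Parses ATOM records of the first MODEL via bio3d, drops HETATM (waters
#' included) and, by default, hydrogens; among alternate-location conformers
#' of the same atom the highest-occupancy one is kept (ties resolved toward
#' altloc `"A"`). Unresolved (disordered) stretches are inferred per chain
#' from gaps in the author residue numbering.
#'
#' @param path path to a PDB file.
#' @param keep_hydrogens keep H atoms (default FALSE).
#' @return an object of class `structure_model`; see [structure_model()].
#' @export
read_structure <- function(path, keep_hydrogens = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)

  elem <- atoms$elesy
  # infer element from atom name when the element column is blank
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- substr(gsub("[0-9]", "", trimws(atoms$elety[blank])), 1, 1)
  atoms$element <- toupper(trimws(elem))
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]

  # altloc: keep the highest-occupancy conformer, ties toward altloc 'A'
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
               sep = "\r")
  ord <- order(key, -occ, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$eleno), , drop = FALSE]

  df <- data.frame(chain = as.character(atoms$chain),
                   resno = as.integer(atoms$resno),
                   insert = ifelse(is.na(atoms$insert), "",
                                   as.character(atoms$insert)),
                   resid = as.character(atoms$resid),
                   elety = trimws(as.character(atoms$elety)),
                   element = atoms$element,
                   x = atoms$x, y = atoms$y, z = atoms$z,
                   o = ifelse(is.na(atoms$o), 1, atoms$o),
                   stringsAsFactors = FALSE)
  structure_model(df, provenance = list(path = path))
}

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z` and optionally `insert`, `o`.
#' @param provenance optional metadata list.
#' @return an object of class `structure_model`: list with `atoms`,
#'   `residues` (one row per (chain, resno, insert)), `chains`, and
#'   `unresolved` (per-chain author-numbering gaps, data.frame `chain`,
#'   `start`, `end`).
#' @export
structure_model <- function(atoms, provenance = list()) {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  rownames(atoms) <- NULL

  rid <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  first <- !duplicated(rid)
  residues <- data.frame(chain = atoms$chain[first],
                         resno = atoms$resno[first],
                         insert = atoms$insert[first],
                         resid = atoms$resid[first],
                         stringsAsFactors = FALSE)

  unresolved <- do.call(rbind, lapply(split(residues$resno, residues$chain),
    function(v) {
      v <- sort(unique(v))
      if (length(v) < 2L) return(NULL)
      d <- diff(v)
      i <- which(d > 1L)
      if (!length(i)) return(NULL)
      data.frame(start = v[i] + 1L, end = v[i + 1L] - 1L)
    }))
  if (is.null(unresolved)) {
    unresolved <- data.frame(chain = character(0), start = integer(0),
                             end = integer(0), stringsAsFactors = FALSE)
  } else {
    unresolved$chain <- sub("\\.[0-9]+$", "", rownames(unresolved))
    unresolved <- unresolved[c("chain", "start", "end")]
    rownames(unresolved) <- NULL
  }

  structure(list(atoms = atoms, residues = residues,
                 chains = unique(atoms$chain), unresolved = unresolved,
                 provenance = provenance),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,", nrow(x$residues),
      "residues,", length(x$chains), "chain(s)",
      paste0("[", paste(x$chains, collapse = ","), "]"), "\n")
  if (nrow(x$unresolved))
    cat("unresolved gaps:",
        paste(sprintf("%s:%d-%d", x$unresolved$chain, x$unresolved$start,
                      x$unresolved$end), collapse = ", "), "\n")
  invisible(x)
}

#' Map a protein sequence position onto a structure residue
#'
#' Converts a 1-based protein position to author numbering via an integer
#' offset (author = position + offset; 0 for structures numbered like the
#' sequence) and looks the residue up in the chain. Positions falling in an
#' unresolved (disordered) gap are reported explicitly, never dropped.
#'
#' @param model a `structure_model`.
#' @param chain chain identifier.
#' @param seq_pos 1-based protein position.
#' @param offset integer added to `seq_pos` to obtain author numbering.
#' @return a list with `resolved` (logical), `chain`, `resno` (author
#'   number) and, when resolved, `resid` and `n_atoms`. Positions outside
#'   the chain's author-number span are an error.
#' @export
map_position <- function(model, chain, seq_pos, offset = 0L) {
  stopifnot(inherits(model, "structure_model"))
  if (!chain %in% model$chains)
    stop("unknown chain '", chain, "'")
  resno <- as.integer(seq_pos + offset)
  rs <- model$residues[model$residues$chain == chain, ]
  if (resno < min(rs$resno) || resno > max(rs$resno))
    stop("position ", seq_pos, " (author number ", resno,
         ") outside chain ", chain, " span ", min(rs$resno), "-",
         max(rs$resno))
  hit <- which(rs$resno == resno)
  if (!length(hit))
    return(list(resolved = FALSE, chain = chain, resno = resno))
  at <- model$atoms[model$atoms$chain == chain &
                      model$atoms$resno == resno, ]
  list(resolved = TRUE, chain = chain, resno = resno,
       resid = rs$resid[hit[1]], n_atoms = nrow(at))
}

residue_atoms <- function(model, chain, resno) {
  at <- model$atoms[model$atoms$chain == chain & model$atoms$resno == resno, ,
                    drop = FALSE]
  if (nrow(at) == 0L)
    stop("residue ", chain, ":", resno, " is not resolved in the model")
  at
}

#' Distance between two residues
#'
#' Euclidean distance in Angstrom, either between the two C-alpha atoms
#' (`mode = "ca"`, the default) or the minimum over all heavy-atom pairs
#' (`mode = "min_heavy"`). Published structure-figure distances rarely state
#' the atoms measured, so both conventions are exposed.
#'
#' @param model a `structure_model`.
#' @param res_a,res_b residues as `list(chain =, resno =)` or `"A:123"`
#'   strings.
#' @param mode `"ca"` or `"min_heavy"`.
#' @return distance in Angstrom (numeric scalar).
#' @export
residue_distance <- function(model, res_a, res_b,
                             mode = c("ca", "min_heavy")) {
  mode <- match.arg(mode)
  ra <- parse_residue_ref(res_a)
  rb <- parse_residue_ref(res_b)
  at_a <- residue_atoms(model, ra$chain, ra$resno)
  at_b <- residue_atoms(model, rb$chain, rb$resno)
  if (mode == "ca") {
    at_a <- at_a[at_a$elety == "CA", , drop = FALSE]
    at_b <- at_b[at_b$elety == "CA", , drop = FALSE]
    if (nrow(at_a) == 0L || nrow(at_b) == 0L)
      stop("C-alpha atom missing; use mode = 'min_heavy'")
  } else {
    at_a <- at_a[at_a$element != "H", , drop = FALSE]
    at_b <- at_b[at_b$element != "H", , drop = FALSE]
  }
  xa <- as.matrix(at_a[c("x", "y", "z")])
  xb <- as.matrix(at_b[c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

parse_residue_ref <- function(res) {
  if (is.character(res) && length(res) == 1L) {
    parts <- strsplit(res, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("residue reference must be 'chain:resno'")
    return(list(chain = parts[1], resno = as.integer(parts[2])))
  }
  if (is.list(res) && all(c("chain", "resno") %in% names(res)))
    return(list(chain = res$chain, resno = as.integer(res$resno)))
  stop("residue reference must be 'chain:resno' or list(chain=, resno=)")
}

#' Single-linkage spatial clusters of residues
#'
#' Builds the graph joining residue pairs at distance at most `cutoff`
#' (Angstrom) and returns its connected components — the single-linkage
#' clusters at that threshold.
#'
#' @param model a `structure_model`.
#' @param residues list or character vector of residue references (see
#'   [residue_distance()]).
#' @param cutoff distance threshold in Angstrom.
#' @param mode distance convention, `"ca"` or `"min_heavy"`.
#' @return a data.frame with `chain`, `resno`, `cluster` (1-based component
#'   labels; empty input gives an empty frame). The largest cluster gets
#'   label 1.
#' @export
cluster_residues <- function(model, residues, cutoff,
                             mode = c("ca", "min_heavy")) {
  mode <- match.arg(mode)
  if (length(residues) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      cluster = integer(0), stringsAsFactors = FALSE))
  refs <- lapply(residues, parse_residue_ref)
  n <- length(refs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      d <- residue_distance(model, refs[[i]], refs[[j]], mode = mode)
      adj[i, j] <- adj[j, i] <- d <= cutoff
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel so larger clusters come first, ties by first appearance
  sizes <- table(comp)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  data.frame(chain = vapply(refs, `[[`, character(1), "chain"),
             resno = vapply(refs, function(r) as.integer(r$resno),
                            integer(1)),
             cluster = as.integer(relabel[as.character(comp)]),
             stringsAsFactors = FALSE)
}

#' Read a domain map from a BED-like TSV
#'
#' Tab-separated with header `name`, `start`, `end`; 1-based inclusive
#' protein coordinates. Sub-motifs (e.g. TRD3 inside FAT, PRD inside the
#' kinase domain) may nest inside a parent interval; top-level domains must
#' not overlap each other.
#'
#' @param path path to the TSV.
#' @return a `domain_map` data.frame (`name`, `start`, `end`).
#' @export
read_domain_map <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  domain_map(d)
}

#' Construct a domain map
#'
#' @param d data.frame with columns `name`, `start`, `end` (1-based,
#'   inclusive).
#' @return a `domain_map`.
#' @export
domain_map <- function(d) {
  if (!all(c("name", "start", "end") %in% names(d)))
    stop("domain map needs columns name, start, end")
  if (any(d$start > d$end)) stop("domain start must not exceed end")
  if (anyDuplicated(d$name)) stop("duplicate domain names")
  class(d) <- c("domain_map", "data.frame")
  d
}

#' Innermost domain containing a position
#'
#' Returns, for each position, the name of the deepest (shortest) interval
#' containing it, or `"unannotated"` when no interval does.
#'
#' @param dmap a `domain_map`.
#' @param position integer vector of 1-based positions.
#' @return character vector of domain names.
#' @export
annotate_domain <- function(dmap, position) {
  stopifnot(inherits(dmap, "domain_map"))
  vapply(as.integer(position), function(p) {
    hit <- which(dmap$start <= p & p <= dmap$end)
    if (!length(hit)) return("unannotated")
    widths <- dmap$end[hit] - dmap$start[hit]
    dmap$name[hit[which.min(widths)]]
  }, character(1))
}
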