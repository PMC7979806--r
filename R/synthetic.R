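# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Specification of a synthetic tumor cohort
#'
#' Describes a cohort with per-cancer-type sample counts, planted hotspot
#' residues mutated recurrently in that type, and an optional uniform
#' background mutation rate. Defaults follow the desk-scale validation
#' cohort used throughout the package: three cancer types, about 200
#' samples, noiseless background so planted signal is exactly recoverable.
#'
#' @param gene gene symbol carried on every record.
#' @param protein_length protein length in residues.
#' @param cancer_types named integer vector: samples per cancer type.
#' @param hotspots named list (same names) of planted hotspot positions;
#'   `NULL` draws `n_hotspots` positions per type from the seed.
#' @param n_hotspots hotspots drawn per type when `hotspots` is `NULL`.
#' @param hotspot_prob per-sample probability that a hotspot residue is
#'   mutated in a sample of its type (hotspot mutations are missense).
#' @param background_rate per-residue, per-sample probability of a
#'   background mutation anywhere in the protein (0 = noiseless).
#' @param consequence_mix fractions (summing to 1) of background mutations
#'   falling in each consequence class.
#' @param cohort_size total screened samples; defaults to the sum of
#'   per-type counts and may exceed it (samples without mutations).
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(gene = "ATM", protein_length = 3056,
                        cancer_types = c(colorectal = 70,
                                         endometrial = 70,
                                         non_hodgkin_lymphoma = 60),
                        hotspots = NULL, n_hotspots = 5,
                        hotspot_prob = 0.2, background_rate = 0,
                        consequence_mix = c(missense = 0.70,
                                            truncation = 0.20,
                                            inframe = 0.05,
                                            other = 0.05),
                        cohort_size = NULL, seed = 1) {
  stopifnot(hotspot_prob >= 0, hotspot_prob <= 1,
            background_rate >= 0, background_rate <= 1)
  if (any(consequence_mix < 0) || abs(sum(consequence_mix) - 1) > 1e-8)
    stop("consequence_mix fractions must be non-negative and sum to 1")
  if (!setequal(names(consequence_mix), consequence_levels()))
    stop("consequence_mix must name the four consequence classes")
  cohort_size <- cohort_size %||% sum(cancer_types)
  if (cohort_size < sum(cancer_types))
    stop("per-type sample counts exceed cohort_size")
  if (!is.null(hotspots)) {
    if (!setequal(names(hotspots), names(cancer_types)))
      stop("hotspots must be named like cancer_types")
    if (any(unlist(hotspots) < 1 | unlist(hotspots) > protein_length))
      stop("hotspot positions outside 1..protein_length")
  }
  structure(list(gene = gene, protein_length = protein_length,
                 cancer_types = cancer_types, hotspots = hotspots,
                 n_hotspots = n_hotspots, hotspot_prob = hotspot_prob,
                 background_rate = background_rate,
                 consequence_mix = consequence_mix,
                 cohort_size = cohort_size, seed = seed),
            class = "cohort_spec")
}

#' Simulate a tumor cohort mutation table with known ground truth
#'
#' Draws, for every sample of each cancer type, Bernoulli mutations at that
#' type's planted hotspot residues (always missense, so hotspot recovery via
#' [mutated_residues()] with the default filter is exact) and optional
#' background mutations at uniform positions with consequences drawn from
#' the spec's mix. The same spec and seed reproduce the output bit for bit.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `table` (mutation rows in the catalog TSV dialect),
#'   `catalog` (a ready `mutation_catalog`), and `truth`: planted `hotspots`
#'   per type, `hotspot_hits` per type (hotspot positions actually mutated
#'   at least once), per-type `residue_sets` (all missense positions
#'   emitted), and the full emitted record table.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  aa <- aa_alphabet()
  with_seed(spec$seed, {
    hotspots <- spec$hotspots
    if (is.null(hotspots)) {
      hotspots <- lapply(spec$cancer_types, function(...)
        sort(sample.int(spec$protein_length, spec$n_hotspots)))
      names(hotspots) <- names(spec$cancer_types)
    }
    # fixed per-position reference residue so repeated hits at a position
    # share the same reference amino acid
    ref_by_pos <- sample(aa, spec$protein_length, replace = TRUE)

    rows <- list()
    for (type in names(spec$cancer_types)) {
      n_s <- spec$cancer_types[[type]]
      ids <- sprintf("%s_S%04d", type, seq_len(n_s))
      hp <- hotspots[[type]]
      for (s in seq_len(n_s)) {
        hit <- hp[runif(length(hp)) < spec$hotspot_prob]
        for (p in hit) {
          ref <- ref_by_pos[p]
          alt <- sample(setdiff(aa, ref), 1)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = spec$gene, sample_id = ids[s], cancer_type = type,
            protein_change = paste0(ref, p, alt),
            origin = "hotspot", stringsAsFactors = FALSE)
        }
        if (spec$background_rate > 0) {
          n_bg <- rbinom(1, spec$protein_length, spec$background_rate)
          if (n_bg > 0) {
            pos <- sample.int(spec$protein_length, n_bg)
            cls <- sample(names(spec$consequence_mix), n_bg, replace = TRUE,
                          prob = spec$consequence_mix)
            for (i in seq_len(n_bg)) {
              p <- pos[i]
              ref <- ref_by_pos[p]
              change <- switch(cls[i],
                missense = paste0(ref, p, sample(setdiff(aa, ref), 1)),
                truncation = paste0(ref, p, "*"),
                inframe = paste0(ref, p, "del"),
                other = paste0("X", p, "_splice"))
              rows[[length(rows) + 1L]] <- data.frame(
                gene = spec$gene, sample_id = ids[s], cancer_type = type,
                protein_change = change, origin = "background",
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene = character(0), sample_id = character(0),
                 cancer_type = character(0), protein_change = character(0),
                 origin = character(0), stringsAsFactors = FALSE)

    parsed <- parse_protein_change2(tab$protein_change)
    residue_sets <- lapply(names(spec$cancer_types), function(type) {
      keep <- tab$cancer_type == type & parsed$consequence == "missense"
      sort(unique(parsed$position[keep]))
    })
    names(residue_sets) <- names(spec$cancer_types)
    hotspot_hits <- lapply(names(spec$cancer_types), function(type) {
      keep <- tab$cancer_type == type & tab$origin == "hotspot"
      sort(unique(parsed$position[keep]))
    })
    names(hotspot_hits) <- names(spec$cancer_types)

    list(table = tab[c("gene", "sample_id", "cancer_type",
                       "protein_change")],
         catalog = mutation_catalog(tab, spec$cohort_size),
         truth = list(hotspots = hotspots, hotspot_hits = hotspot_hits,
                      residue_sets = residue_sets, records = tab,
                      seed = spec$seed))
  })
}

# internal alias avoiding repeated S3 dispatch cost in the generator
parse_protein_change2 <- function(x) {
  if (length(x) == 0L)
    return(data.frame(consequence = character(0), position = integer(0)))
  parse_protein_change(x)
}

#' Simulate a diverged ortholog sequence with protected conserved core
#'
#' Substitutes residues of an ancestral sequence at uniformly chosen
#' unprotected sites until the realized identity is within one percentage
#' point of the target; protected positions are never touched and a
#' substitution never reproduces the original residue. Optional indels
#' (never at protected sites) are applied after substitution.
#'
#' @param ancestral ancestral protein sequence (single string).
#' @param target_identity target fraction of identical positions in (0, 1].
#' @param protected integer vector of positions that must stay identical.
#' @param indel_rate per-site probability of an indel event (0 = none);
#'   events are deletions or short (1-3 aa) insertions with equal chance.
#' @param seed RNG seed.
#' @return a list with `sequence` and `truth` (`substituted` positions,
#'   `protected`, `realized_identity`, `indels` data.frame).
#' @export
simulate_ortholog <- function(ancestral, target_identity,
                              protected = integer(0), indel_rate = 0,
                              seed = 1) {
  letters_anc <- check_aa_seq(ancestral, "ancestral")
  L <- length(letters_anc)
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must be in (0, 1]")
  protected <- sort(unique(as.integer(protected)))
  if (length(protected) && (min(protected) < 1 || max(protected) > L))
    stop("protected positions outside the sequence")
  n_sub <- round((1 - target_identity) * L)
  free_sites <- setdiff(seq_len(L), protected)
  if (n_sub > length(free_sites))
    stop("target identity ", target_identity, " is below the floor of ",
         length(protected) / L, " imposed by protected positions")
  realized <- (L - n_sub) / L
  if (abs(realized - target_identity) > 0.01)
    stop("cannot realize identity within 1 percentage point of target ",
         "(sequence too short)")
  aa <- aa_alphabet()
  with_seed(seed, {
    sub_pos <- sort(sample(free_sites, n_sub))
    out <- letters_anc
    for (p in sub_pos) out[p] <- sample(setdiff(aa, letters_anc[p]), 1)

    indels <- data.frame(position = integer(0), type = character(0),
                         length = integer(0), stringsAsFactors = FALSE)
    if (indel_rate > 0) {
      ev <- free_sites[runif(length(free_sites)) < indel_rate]
      segs <- as.list(out)
      for (p in ev) {
        if (runif(1) < 0.5) {
          segs[[p]] <- ""
          indels <- rbind(indels, data.frame(position = p, type = "del",
                                             length = 1L))
        } else {
          len <- sample(3, 1)
          ins <- paste(sample(aa, len, replace = TRUE), collapse = "")
          segs[[p]] <- paste0(segs[[p]], ins)
          indels <- rbind(indels, data.frame(position = p, type = "ins",
                                             length = len))
        }
      }
      seq_out <- paste(unlist(segs), collapse = "")
    } else {
      seq_out <- paste(out, collapse = "")
    }
    list(sequence = seq_out,
         truth = list(substituted = sub_pos, protected = protected,
                      target_identity = target_identity,
                      realized_identity = realized, indels = indels,
                      seed = seed))
  })
}

#' Specification of a toy structure with known burial ground truth
#'
#' Two arrangements of a C-alpha-only poly-alanine trace:
#' `"helix"` — an ideal alpha-helix (rise 1.5 A per residue, 100 degrees
#' per residue, helix radius 2.3 A), every residue ground-truth surface;
#' `"lattice_ball"` — residues on a cubic lattice filling a ball outward
#' from the origin, ground-truth buried iff all six lattice neighbors are
#' occupied.
#'
#' The default lattice spacing of 4.5 A places face neighbors inside
#' mutual occlusion range of the expanded C-alpha spheres (2 x (1.7 + 1.4)
#' = 6.2 A) while diagonal neighbors (4.5 * sqrt(2) = 6.36 A) stay outside
#' it, so the six-neighbor burial rule is geometrically exact for the
#' Shrake-Rupley classifier rather than merely approximate.
#'
#' @param arrangement `"helix"` or `"lattice_ball"`.
#' @param n_residues number of residues (>= 1).
#' @param spacing lattice spacing in Angstrom (lattice_ball only).
#' @param chain chain identifier for the generated model.
#' @param seed stored for provenance; the geometry is deterministic.
#' @return a list of class `toy_structure_spec`.
#' @export
toy_structure_spec <- function(arrangement = c("lattice_ball", "helix"),
                               n_residues = 100, spacing = 4.5,
                               chain = "A", seed = 1) {
  arrangement <- match.arg(arrangement)
  stopifnot(n_residues >= 1, spacing > 0)
  structure(list(arrangement = arrangement, n_residues = n_residues,
                 spacing = spacing, chain = chain, seed = seed),
            class = "toy_structure_spec")
}

#' Simulate a toy structure with known surface/buried ground truth
#'
#' @param spec a [toy_structure_spec()].
#' @return a list with `model` (a `structure_model`), `atoms` (the C-alpha
#'   table) and `truth` (data.frame `resno`, `surface` logical).
#' @export
simulate_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_structure_spec"))
  n <- spec$n_residues
  if (spec$arrangement == "helix") {
    i <- seq_len(n) - 1
    theta <- i * 100 * pi / 180
    xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    surface <- rep(TRUE, n)
  } else {
    # integer lattice sites sorted by distance from origin, ties broken
    # lexicographically, so the ball grows deterministically
    r_max <- ceiling((3 * n / (4 * pi))^(1 / 3)) + 2
    g <- seq(-r_max, r_max)
    sites <- expand.grid(x = g, y = g, z = g)
    d2 <- sites$x^2 + sites$y^2 + sites$z^2
    ord <- order(d2, sites$x, sites$y, sites$z)
    sites <- sites[ord[seq_len(n)], , drop = FALSE]
    key <- paste(sites$x, sites$y, sites$z)
    occupied <- function(x, y, z) paste(x, y, z) %in% key
    surface <- !(occupied(sites$x + 1, sites$y, sites$z) &
                 occupied(sites$x - 1, sites$y, sites$z) &
                 occupied(sites$x, sites$y + 1, sites$z) &
                 occupied(sites$x, sites$y - 1, sites$z) &
                 occupied(sites$x, sites$y, sites$z + 1) &
                 occupied(sites$x, sites$y, sites$z - 1))
    xyz <- as.matrix(sites) * spec$spacing
  }
  atoms <- data.frame(chain = spec$chain, resno = seq_len(n), insert = "",
                      resid = "ALA", elety = "CA", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
                      stringsAsFactors = FALSE)
  list(model = structure_model(atoms, provenance = list(spec = spec)),
       atoms = atoms,
       truth = data.frame(resno = seq_len(n), surface = surface))
}

#' Write a structure model as a PDB file
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[c("x", "y", "z")]))),
                   resno = at$resno, chain = at$chain, resid = at$resid,
                   elety = at$elety, o = at$o, b = rep(0, nrow(at)))
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of (possibly gapped) sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a generator truth record as JSON
#'
#' @param truth a truth list from one of the simulators.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
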