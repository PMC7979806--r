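# Bondi-type van der Waals radii (Angstrom); hydrogens are excluded from
# SASA by default so the H entry only matters with keep_hydrogens = TRUE.
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

# Theoretical maximum accessible surface area per residue type (Angstrom^2),
# Tien-style Gly-X-Gly reference values, used to normalise absolute SASA
# into relative SASA.
max_ref_sasa <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom accessible area by deterministic sphere-point sampling
#' (golden-spiral lattice, no random numbers, so results are bit-stable for
#' a fixed `n_points`), sums it per residue, and normalises by the residue
#' type's theoretical maximum to give relative SASA. Atoms of elements
#' missing from the radius table are an error unless `default_radius` is
#' given.
#'
#' @param model a `structure_model`. SASA is computed in the full model
#'   context (all chains present), so for a dimeric complex burial reflects
#'   the assembly, not the isolated protomer.
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points number of test points per atom sphere.
#' @param radii named vector of van der Waals radii by element.
#' @param default_radius optional fallback radius for unknown elements.
#' @return an object of class `sasa_profile`: data.frame with `chain`,
#'   `resno`, `resid`, `sasa` (absolute, Angstrom^2) and `rel_sasa`
#'   (fraction of the reference maximum; `NA` for residue types without a
#'   reference value).
#' @export
shrake_rupley <- function(model, probe_radius = 1.4, n_points = 960,
                          radii = vdw_radii, default_radius = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  r <- unname(radii[at$element])
  if (anyNA(r)) {
    unknown <- unique(at$element[is.na(r)])
    if (is.null(default_radius))
      stop("no van der Waals radius for element(s): ",
           paste(unknown, collapse = ", "),
           " (supply default_radius to override)")
    r[is.na(r)] <- default_radius
  }
  area <- .sasa_atoms_cpp(as.matrix(at[c("x", "y", "z")]), r,
                          probe_radius, as.integer(n_points))
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  per_res <- tapply(area, factor(key, levels = unique(key)), sum)
  res <- model$residues
  out <- data.frame(chain = res$chain, resno = res$resno,
                    resid = res$resid,
                    sasa = as.numeric(per_res),
                    stringsAsFactors = FALSE)
  out$rel_sasa <- out$sasa / unname(max_ref_sasa[out$resid])
  attr(out, "probe_radius") <- probe_radius
  attr(out, "n_points") <- n_points
  class(out) <- c("sasa_profile", "data.frame")
  out
}

#' Per-atom SASA for an arbitrary set of spheres
#'
#' Low-level interface used for analytic validation (isolated spheres,
#' two-sphere overlaps) and by [shrake_rupley()].
#'
#' @param xyz numeric matrix of centers (n x 3).
#' @param radii numeric vector of van der Waals radii.
#' @param probe_radius probe radius in Angstrom.
#' @param n_points test points per sphere.
#' @return numeric vector of per-sphere accessible areas (Angstrom^2).
#' @export
sasa_atoms <- function(xyz, radii, probe_radius = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(radii))
  .sasa_atoms_cpp(xyz, as.numeric(radii), probe_radius,
                  as.integer(n_points))
}

#' Classify residues as surface or buried from a SASA profile
#'
#' A resolved residue is `surface` when its relative SASA is at least
#' `threshold` (default 0.25), otherwise `buried`. Unresolved residues of
#' the model (author-numbering gaps) are appended with class `unresolved`
#' and excluded from every denominator.
#'
#' @param profile a `sasa_profile` from [shrake_rupley()].
#' @param threshold relative-SASA surface threshold in `[0, 1]`.
#' @param model optional `structure_model` whose unresolved gaps are
#'   appended to the classification.
#' @return an object of class `burial_classes`: data.frame with the profile
#'   columns plus `class` (surface / buried / unresolved), carrying
#'   attributes `n_surface`, `n_resolved` and `threshold`.
#' @export
classify_burial <- function(profile, threshold = 0.25, model = NULL) {
  stopifnot(inherits(profile, "sasa_profile") || is.data.frame(profile))
  out <- as.data.frame(profile)
  out$class <- ifelse(out$rel_sasa >= threshold, "surface", "buried")
  if (!is.null(model) && nrow(model$unresolved)) {
    gaps <- model$unresolved
    extra <- do.call(rbind, lapply(seq_len(nrow(gaps)), function(i)
      data.frame(chain = gaps$chain[i],
                 resno = seq(gaps$start[i], gaps$end[i]),
                 resid = NA_character_, sasa = NA_real_,
                 rel_sasa = NA_real_, class = "unresolved",
                 stringsAsFactors = FALSE)))
    out <- rbind(out, extra)
    out <- out[order(out$chain, out$resno), ]
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- threshold
  attr(out, "n_resolved") <- sum(out$class != "unresolved")
  attr(out, "n_surface") <- sum(out$class == "surface", na.rm = TRUE)
  class(out) <- c("burial_classes", "data.frame")
  out
}

#' Write a SASA/burial table as TSV
#'
#' @param classes a `burial_classes` (or `sasa_profile`) data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_burial <- function(classes, path) {
  write.table(as.data.frame(classes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
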