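#' Domain enrichment of a residue set
#'
#' Tests whether residues of interest fall inside a domain more often than
#' its share of the protein length predicts. With `k` of `n` tested residues
#' in a domain covering fraction `f_dom` of the protein, the fold enrichment
#' is `(k/n) / f_dom`; the headline p-value is the exact one-sided binomial
#' tail `P(X >= k)` with `X ~ Binomial(n, f_dom)` (no normal approximation).
#' When integer domain and protein lengths are supplied, the hypergeometric
#' tail (sampling residues without replacement) is reported alongside.
#'
#' @param k number of tested residues inside the domain.
#' @param n total number of tested residues (`0 <= k <= n`).
#' @param domain_len domain length in residues (used with `protein_len`).
#' @param protein_len protein length in residues.
#' @param f_dom domain fraction of the protein; computed from the lengths
#'   when omitted.
#' @return an object of class `enrichment_result`: list with `k`, `n`,
#'   `f_dom`, `fold`, `p_binomial` and `p_hypergeometric` (NA unless both
#'   lengths given).
#' @examples
#' # 139 of 336 conserved mutated residues in a kinase domain covering ~15%
#' domain_enrichment(139, 336, f_dom = 0.15)
#' @export
domain_enrichment <- function(k, n, domain_len = NULL, protein_len = NULL,
                              f_dom = NULL) {
  if (is.null(f_dom)) {
    if (is.null(domain_len) || is.null(protein_len))
      stop("supply f_dom or both domain_len and protein_len")
    if (domain_len <= 0 || protein_len <= 0 || domain_len > protein_len)
      stop("need 0 < domain_len <= protein_len")
    f_dom <- domain_len / protein_len
  }
  if (f_dom <= 0 || f_dom > 1) stop("f_dom must be in (0, 1]")
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n")
  fold <- if (n == 0) NA_real_ else (k / n) / f_dom
  p_binom <- if (n == 0) NA_real_ else
    pbinom(k - 1, size = n, prob = f_dom, lower.tail = FALSE)
  p_hyper <- NA_real_
  if (!is.null(domain_len) && !is.null(protein_len) && n > 0) {
    p_hyper <- phyper(k - 1, m = domain_len, n = protein_len - domain_len,
                      k = n, lower.tail = FALSE)
  }
  structure(list(k = k, n = n, f_dom = f_dom, fold = fold,
                 p_binomial = p_binom, p_hypergeometric = p_hyper),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d/%d residues in domain (%.1f%%), domain share %.1f%% -> fold %.2f, binomial P = %.3g\n",
              x$k, x$n, 100 * x$k / max(1, x$n), 100 * x$f_dom, x$fold,
              x$p_binomial))
  invisible(x)
}

#' Overlap structure of labeled residue sets
#'
#' Exact set sizes, all pairwise intersection sizes, the size of the
#' intersection of all sets, and the union size — the numbers behind a
#' Venn-style comparison of per-cancer-type residue sets.
#'
#' @param sets a named list (>= 2 entries, unique labels) of position
#'   vectors, or of `residue_set` objects.
#' @return an object of class `overlap_result`: list with `sizes` (named),
#'   `pairwise` (data.frame `set_a`, `set_b`, `intersection`, `union`),
#'   `common_all` (k-way intersection size), `union_all`, and `elements`
#'   (list with `common_all` members).
#' @export
overlap_analysis <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set labels: ", names(sets)[anyDuplicated(names(sets))])
  sets <- lapply(sets, function(s) {
    if (inherits(s, "residue_set")) s <- s$position
    sort(unique(s))
  })
  labs <- names(sets)
  sizes <- vapply(sets, length, integer(1))
  cmb <- utils::combn(labs, 2)
  pairwise <- data.frame(
    set_a = cmb[1, ], set_b = cmb[2, ],
    intersection = apply(cmb, 2, function(p)
      length(intersect(sets[[p[1]]], sets[[p[2]]]))),
    union = apply(cmb, 2, function(p)
      length(union(sets[[p[1]]], sets[[p[2]]]))),
    stringsAsFactors = FALSE)
  common <- Reduce(intersect, sets)
  structure(list(sizes = sizes, pairwise = pairwise,
                 common_all = length(common),
                 union_all = length(Reduce(union, sets)),
                 elements = list(common_all = common)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap of", length(x$sizes), "sets:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
      "\n")
  cat("common to all:", x$common_all, "| union:", x$union_all, "\n")
  invisible(x)
}

#' Fraction of a residue subset on the protein surface
#'
#' Counts surface residues among the resolved members of a subset of a
#' burial classification; unresolved residues are reported separately and
#' excluded from the denominator.
#'
#' @param classes a `burial_classes` data.frame from [classify_burial()].
#' @param positions optional integer vector restricting to author residue
#'   numbers (all classified residues when omitted).
#' @param chain optional chain restriction.
#' @return a list with `n_surface`, `n_resolved`, `n_unresolved` and
#'   `fraction` (`NA` with a flag when nothing is resolved).
#' @export
surface_fraction <- function(classes, positions = NULL, chain = NULL) {
  d <- as.data.frame(classes)
  if (!is.null(chain)) d <- d[d$chain == chain, ]
  if (!is.null(positions)) d <- d[d$resno %in% positions, ]
  n_unres <- sum(d$class == "unresolved")
  d <- d[d$class != "unresolved", ]
  n_resolved <- nrow(d)
  n_surface <- sum(d$class == "surface")
  list(n_surface = n_surface, n_resolved = n_resolved,
       n_unresolved = n_unres,
       fraction = if (n_resolved == 0) NA_real_ else n_surface / n_resolved,
       undefined = n_resolved == 0)
}
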