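#' Assemble a pipeline run configuration
#'
#' Collects inputs and thresholds for a full analysis run. Every input
#' beyond the mutation catalog is optional: stages whose inputs are missing
#' are skipped with a warning, so the pipeline runs without any structure
#' or alignment download.
#'
#' @param catalog path to a mutation TSV or a `mutation_catalog`.
#' @param cohort_size total screened samples (required with a path).
#' @param genes character vector of gene symbols to analyse.
#' @param human_seqs named character vector (or FASTA path) of the analysed
#'   proteins' sequences; names are gene symbols.
#' @param alignments per gene, a named list of `aligned_pair`s (or paths to
#'   aligned FASTA files) against the designated orthologs.
#' @param structures per gene, a path to a PDB file (or a
#'   `structure_model`).
#' @param structure_chains per gene, the chain holding that protein
#'   (default: first chain).
#' @param structure_offsets per gene, integer author-numbering offset.
#' @param domain_maps per gene, a path to a domain TSV or a `domain_map`.
#' @param consequences consequence classes defining "mutated residues".
#' @param burial_threshold relative-SASA surface threshold.
#' @param cluster_cutoff single-linkage distance cutoff in Angstrom.
#' @param distance_mode `"ca"` or `"min_heavy"`.
#' @param out_dir output directory for the TSV/JSON report bundle.
#' @param seed seed recorded in the summary (the analysis itself is
#'   deterministic).
#' @return a list of class `run_config`.
#' @export
run_config <- function(catalog, cohort_size = NULL, genes = NULL,
                       human_seqs = NULL, alignments = NULL,
                       structures = NULL, structure_chains = NULL,
                       structure_offsets = NULL, domain_maps = NULL,
                       consequences = "missense",
                       burial_threshold = 0.25, cluster_cutoff = 24,
                       distance_mode = "ca", out_dir = ".", seed = 1) {
  stopifnot(burial_threshold >= 0, burial_threshold <= 1,
            cluster_cutoff > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are the arguments of [run_config()]
#' (paths stay paths; they are opened by [run_pipeline()]).
#'
#' @param path path to the YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(run_config, vals)
}

#' Run the full mutation-mapping pipeline
#'
#' Executes catalog ingestion, conservation calling, structural mapping and
#' enrichment/overlap statistics, writing a TSV for each result table plus a
#' machine-readable JSON summary (`summary.json`) whose numbers all also
#' appear in a TSV. Outputs are byte-identical across re-runs of the same
#' configuration.
#'
#' Stages and their outputs under `config$out_dir`:
#' \describe{
#'   \item{gene_summary.tsv}{per-gene mutation frequency and consequence
#'     counts;}
#'   \item{residues_<gene>.tsv}{per-cancer-type mutated-residue sets;}
#'   \item{conservation_<gene>.tsv}{per-residue conservation calls (needs
#'     `human_seqs` + `alignments`);}
#'   \item{burial_<gene>.tsv / clusters_<gene>.tsv}{surface/buried classes
#'     of mutated residues and single-linkage clusters of the surface ones
#'     (needs `structures`);}
#'   \item{enrichment.tsv / overlap.tsv}{kinase-domain enrichment (needs
#'     `domain_maps`) and per-cancer-type overlaps.}
#' }
#'
#' @param config a [run_config()] or a path to a YAML file for
#'   [read_run_config()].
#' @return the report bundle, invisibly: a list with `gene_summary`,
#'   `residue_sets`, `conservation`, `burial`, `clusters`, `enrichment`,
#'   `overlap` and `summary` (the JSON content).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  catalog <- config$catalog
  if (is.character(catalog)) {
    if (is.null(config$cohort_size))
      stop("stage catalog: cohort_size is required when loading from a file")
    catalog <- load_catalog(catalog, config$cohort_size, config$genes)
  }
  stopifnot(inherits(catalog, "mutation_catalog"))
  genes <- config$genes %||% sort(unique(catalog$records$gene))

  human_seqs <- config$human_seqs
  if (is.character(human_seqs) && length(human_seqs) == 1L &&
      file.exists(human_seqs)) {
    ss <- Biostrings::readAAStringSet(human_seqs)
    human_seqs <- setNames(as.character(ss), names(ss))
  }

  # (a) per-gene frequency and consequence counts
  gene_summary <- do.call(rbind, lapply(genes, function(g) {
    fr <- gene_mutation_frequency(catalog, g)
    cc <- consequence_counts(catalog, g)
    data.frame(gene = g, mutated_samples = fr$mutated_samples,
               cohort = fr$cohort_size, frequency_pct = fr$frequency_pct,
               missense = cc[["missense"]], truncation = cc[["truncation"]],
               inframe = cc[["inframe"]], other = cc[["other"]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(gene_summary))
    gene_summary <- data.frame(gene = character(0),
                               mutated_samples = integer(0),
                               cohort = integer(0),
                               frequency_pct = numeric(0),
                               missense = integer(0),
                               truncation = integer(0),
                               inframe = integer(0), other = integer(0),
                               stringsAsFactors = FALSE)
  write.table(gene_summary, file.path(config$out_dir, "gene_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cancer_types <- sort(unique(catalog$records$cancer_type))
  residue_sets <- list()
  conservation <- list()
  burial <- list()
  clusters <- list()
  enrichment <- list()
  overlap <- list()

  for (g in genes) {
    # (b) per-cancer-type residue sets
    per_type <- lapply(cancer_types, function(ct)
      mutated_residues(catalog, g, cancer_type = ct,
                       consequences = config$consequences))
    names(per_type) <- cancer_types
    all_set <- mutated_residues(catalog, g,
                                consequences = config$consequences)
    residue_sets[[g]] <- list(all = all_set, by_type = per_type)
    rs_tab <- do.call(rbind, lapply(cancer_types, function(ct) {
      d <- as.data.frame(per_type[[ct]])
      if (nrow(d)) cbind(cancer_type = ct, d) else NULL
    }))
    if (!is.null(rs_tab))
      write.table(rs_tab,
                  file.path(config$out_dir, paste0("residues_", g, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)

    # conservation calls
    aln <- config$alignments[[g]]
    if (!is.null(aln) && !is.null(human_seqs[[g]])) {
      aln <- lapply(aln, function(a)
        if (is.character(a)) read_alignment(a) else a)
      calls <- call_conserved(all_set, human_seqs[[g]], aln)
      conservation[[g]] <- calls
      write.table(as.data.frame(calls),
                  file.path(config$out_dir,
                            paste0("conservation_", g, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (!is.null(aln) || !is.null(human_seqs[[g]])) {
      warning("gene ", g, ": conservation stage skipped ",
              "(needs both human_seqs and alignments)")
    }

    # (c) structural stage
    st <- config$structures[[g]]
    if (!is.null(st)) {
      model <- if (is.character(st)) read_structure(st) else st
      chain <- config$structure_chains[[g]] %||% model$chains[1]
      offset <- config$structure_offsets[[g]] %||% 0L
      prof <- shrake_rupley(model, probe_radius = 1.4)
      cls <- classify_burial(prof, threshold = config$burial_threshold,
                             model = model)
      focus <- if (!is.null(conservation[[g]]))
        conservation[[g]]$position[conservation[[g]]$conserved]
        else all_set$position
      focus_author <- focus + offset
      sub <- cls[cls$chain == chain & cls$resno %in% focus_author, ,
                 drop = FALSE]
      burial[[g]] <- sub
      write.table(as.data.frame(sub),
                  file.path(config$out_dir, paste0("burial_", g, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      surf <- sub$resno[sub$class == "surface"]
      if (length(surf)) {
        cl <- cluster_residues(model,
                               lapply(surf, function(r)
                                 list(chain = chain, resno = r)),
                               cutoff = config$cluster_cutoff,
                               mode = config$distance_mode)
        clusters[[g]] <- cl
        write.table(cl,
                    file.path(config$out_dir,
                              paste0("clusters_", g, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    # (d) enrichment and overlap
    dm <- config$domain_maps[[g]]
    if (!is.null(dm)) {
      dm <- if (is.character(dm)) read_domain_map(dm) else dm
      tested <- if (!is.null(conservation[[g]]))
        conservation[[g]]$position[conservation[[g]]$conserved]
        else all_set$position
      if (length(tested)) {
        prot_len <- max(dm$end)
        enr <- do.call(rbind, lapply(seq_len(nrow(dm)), function(i) {
          k <- sum(tested >= dm$start[i] & tested <= dm$end[i])
          e <- domain_enrichment(k, length(tested),
                                 domain_len = dm$end[i] - dm$start[i] + 1L,
                                 protein_len = prot_len)
          data.frame(gene = g, domain = dm$name[i], k = e$k, n = e$n,
                     f_dom = e$f_dom, fold = e$fold,
                     p_binomial = e$p_binomial,
                     p_hypergeometric = e$p_hypergeometric,
                     stringsAsFactors = FALSE)
        }))
        enrichment[[g]] <- enr
      }
    }
    nonempty <- Filter(function(d) nrow(d) > 0, per_type)
    if (length(nonempty) >= 2) {
      ov <- overlap_analysis(lapply(nonempty, function(d) d$position))
      overlap[[g]] <- ov
    }
  }

  if (length(enrichment))
    write.table(do.call(rbind, enrichment),
                file.path(config$out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(overlap)) {
    ov_tab <- do.call(rbind, lapply(names(overlap), function(g) {
      o <- overlap[[g]]
      rbind(data.frame(gene = g, set_a = names(o$sizes),
                       set_b = "", value = as.integer(o$sizes),
                       quantity = "size", stringsAsFactors = FALSE),
            data.frame(gene = g, set_a = o$pairwise$set_a,
                       set_b = o$pairwise$set_b,
                       value = o$pairwise$intersection,
                       quantity = "intersection", stringsAsFactors = FALSE),
            data.frame(gene = g, set_a = "all", set_b = "all",
                       value = o$common_all, quantity = "common_all",
                       stringsAsFactors = FALSE))
    }))
    write.table(ov_tab, file.path(config$out_dir, "overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = config$seed,
    genes = genes,
    cohort_size = catalog$cohort_size,
    frequencies = setNames(as.list(gene_summary$frequency_pct),
                           gene_summary$gene),
    n_mutated_residues = setNames(
      lapply(residue_sets, function(r) nrow(r$all)), names(residue_sets)),
    n_conserved = setNames(lapply(conservation, function(cc)
      sum(cc$conserved)), names(conservation)),
    surface_counts = setNames(lapply(burial, function(b)
      list(n_surface = sum(b$class == "surface"),
           n_resolved = sum(b$class != "unresolved"))), names(burial)),
    enrichment = setNames(lapply(enrichment, function(e)
      setNames(as.list(e$fold), e$domain)), names(enrichment)),
    overlap_common_all = setNames(lapply(overlap, function(o)
      o$common_all), names(overlap)))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(gene_summary = gene_summary, residue_sets = residue_sets,
                 conservation = conservation, burial = burial,
                 clusters = clusters, enrichment = enrichment,
                 overlap = overlap, summary = summary))
}
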