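#' Full run configuration
#'
#' One flat list of every tunable in the pipeline, with the package
#' defaults; unknown keys are rejected. The resolved configuration is
#' attached to every [run_full()] result.
#'
#' @param ... overrides of the defaults listed below.
#' @return named list of settings.
#' @export
kkp_config <- function(...) {
  cfg <- list(
    pattern = "both",            # triplet order: PKK, KKP or both
    min_bp = 900,                # strict gene-length bounds
    max_bp = 1300,
    evalue_max = 1e-5,           # independent E-value cutoff on domain hits
    max_shared_aa = 15,          # tolerated overlap between accepted segments
    allow_intervening = FALSE,   # permit one 'other' CDS inside the triplet
    max_gap_bp = Inf,            # intergenic cap within the triplet
    prophage_containment = FALSE,# TRUE: require full containment, not 1 bp
    p4_window_genes = 20,        # Psu rescue radius (CDS positions)
    mge_window_genes = 5,        # MGE adjacency, gene arm
    mge_window_bp = 3000,        # MGE adjacency, bp arm (OR semantics)
    identity_threshold = 90,     # family edges strictly above this
    identity_denominator = "columns",
    family_combine = "mean",     # mean or min of the three identities
    match = 1, mismatch = -2,    # DNA alignment scoring
    gap_open = -5, gap_extend = -1,
    band = NULL, band_threshold = 5000)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("config error: unknown setting(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Run the whole mining pipeline over a dataset
#'
#' scan -> classify -> context-annotate -> summarize, one genome at a
#' time; results are independent of genome processing order and
#' deterministic given inputs and configuration. The log records counts
#' at every filter stage.
#'
#' @param inputs a dataset directory (see [load_dataset()]) or an
#'   in-memory dataset list (`generate_dataset()` layout).
#' @param config a [kkp_config()] list.
#' @param out_dir optional; when given, writes `clusters.tsv`,
#'   `contexts.tsv`, `summary.tsv` and `run_log.txt` there.
#' @return list `clusters`, `contexts`, `summary`, `log`, `config`.
#' @export
run_full <- function(inputs, config = kkp_config(), out_dir = NULL) {
  ds <- if (is.character(inputs)) load_dataset(inputs) else inputs
  clusters <- list(); contexts <- list()
  for (gid in names(ds$genomes)) {
    g <- ds$genomes[[gid]]
    tab <- g$table
    cds_ids <- tab$gene_id[!is.na(tab$index)]
    archs <- tryCatch(
      build_architectures(g$hits, gene_ids = cds_ids,
                          evalue_max = config$evalue_max,
                          max_shared_aa = config$max_shared_aa),
      error = function(e) stop("stage error [domain_arch] genome ", gid, ": ",
                               conditionMessage(e)))
    cl <- tryCatch(classify_clusters(tab, archs, config),
                   error = function(e) stop("stage error [kkp_scan] genome ",
                                            gid, ": ", conditionMessage(e)))
    cx <- tryCatch(
      annotate_contexts(cl[cl$status == "authentic", , drop = FALSE],
                        tab, archs, g$intervals, g$mge, config),
      error = function(e) stop("stage error [context] genome ", gid, ": ",
                               conditionMessage(e)))
    clusters[[gid]] <- cl
    contexts[[gid]] <- cx
  }
  clusters <- do.call(rbind, clusters) %||% .empty_candidates()
  contexts <- do.call(rbind, contexts) %||%
    annotate_contexts(.empty_candidates(), NULL, NULL)
  rownames(clusters) <- rownames(contexts) <- NULL
  smry <- summarize_contexts(contexts)
  len_pass <- if (nrow(clusters))
    clusters$len_pass1 & clusters$len_pass2 & clusters$len_pass3 else logical(0)
  log <- c(sprintf("genomes: %d", length(ds$genomes)),
           sprintf("candidates: %d", nrow(clusters)),
           sprintf("length_pass: %d", sum(len_pass)),
           sprintf("architecture_pass: %d", sum(len_pass & clusters$architecture_pass)),
           sprintf("authentic: %d", sum(clusters$status == "authentic")),
           sprintf("context_%s: %d", smry$category[smry$taxon == "all"],
                   smry$count[smry$taxon == "all"]),
           sprintf("mge_among_nonprophage: %s",
                   attr(smry, "mge_among_nonprophage")))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_results(clusters, file.path(out_dir, "clusters.tsv"))
    write_results(contexts, file.path(out_dir, "contexts.tsv"))
    write_results(smry, file.path(out_dir, "summary.tsv"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(clusters = clusters, contexts = contexts, summary = smry,
       log = log, config = config)
}
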