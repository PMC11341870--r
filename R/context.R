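#' Prophage-interval overlap evidence for a cluster
#'
#' Evidence when the cluster span (min start to max end of the three
#' genes) overlaps any prophage interval by at least one bp, or — with
#' `containment = TRUE` — lies entirely inside one.
#'
#' @param cluster one row of [classify_clusters()] output.
#' @param intervals data.frame from [read_intervals()].
#' @param containment require full containment instead of >= 1 bp overlap.
#' @return data.frame of evidence rows (kind, identifier, distance_genes,
#'   distance_bp), zero rows when none.
#' @export
overlaps_prophage <- function(cluster, intervals, containment = FALSE) {
  if (is.null(intervals) || !nrow(intervals)) return(.no_evidence())
  iv <- intervals[intervals$contig_id == cluster$contig_id, , drop = FALSE]
  if (!nrow(iv)) return(.no_evidence())
  hit <- if (containment)
    iv$start <= cluster$start & iv$end >= cluster$end
  else
    iv$start <= cluster$end & iv$end >= cluster$start
  iv <- iv[hit, , drop = FALSE]
  if (!nrow(iv)) return(.no_evidence())
  data.frame(kind = "prophage_interval",
             identifier = sprintf("%s:%d-%d[%s]", iv$contig_id, iv$start,
                                  iv$end, iv$label),
             distance_genes = 0L, distance_bp = 0L, stringsAsFactors = FALSE)
}

.no_evidence <- function() {
  data.frame(kind = character(), identifier = character(),
             distance_genes = integer(), distance_bp = integer(),
             stringsAsFactors = FALSE)
}

#' P4 prophage rescue by a nearby Psu gene
#'
#' Automated prophage callers frequently miss the ~11 kb P4 satellite
#' prophages, so clusters are rescued as P4-associated when a gene with
#' the phage polarity suppression protein role (Psu, PF07455) lies within
#' `window_genes` contig positions of any cluster gene.
#'
#' @param cluster one cluster row.
#' @param table the `genome_table`.
#' @param archs role table from [build_architectures()].
#' @param window_genes rescue radius in CDS positions (default 20).
#' @return evidence data.frame (kind `psu_gene`), zero rows when none.
#' @export
rescue_p4 <- function(cluster, table, archs, window_genes = 20) {
  psu_ids <- archs$gene_id[archs$role == "Psu"]
  if (!length(psu_ids)) return(.no_evidence())
  cds <- table[!is.na(table$index) & table$contig_id == cluster$contig_id, , drop = FALSE]
  psu <- cds[cds$gene_id %in% psu_ids, , drop = FALSE]
  if (!nrow(psu)) return(.no_evidence())
  cl_idx <- c(cluster$idx1, cluster$idx2, cluster$idx3)
  dist_genes <- vapply(psu$index, function(i) min(abs(i - cl_idx)), 0L)
  keep <- dist_genes <= window_genes
  if (!any(keep)) return(.no_evidence())
  psu <- psu[keep, , drop = FALSE]
  dist_bp <- vapply(seq_len(nrow(psu)), function(i)
    .span_distance_bp(psu$start[i], psu$end[i], cluster$start, cluster$end), 0L)
  data.frame(kind = "psu_gene", identifier = psu$gene_id,
             distance_genes = dist_genes[keep], distance_bp = dist_bp,
             stringsAsFactors = FALSE)
}

.span_distance_bp <- function(s1, e1, s2, e2) {
  max(0L, max(s1, s2) - min(e1, e2) - 1L)
}

#' MGE-linkage evidence for a cluster
#'
#' A cluster is linked to a mobile-genetic-element gene when that gene is
#' within `window_genes` contig positions of the nearest cluster gene OR
#' within `window_bp` of the cluster span (OR semantics; both distances
#' recorded on the evidence).
#'
#' @param cluster one cluster row.
#' @param table the `genome_table`.
#' @param mge data.frame from [read_mge_table()].
#' @param window_genes gene-distance arm (default 5).
#' @param window_bp bp-distance arm (default 3000).
#' @return evidence data.frame (kind `mge_gene`), one row per linked gene.
#' @export
mge_linked <- function(cluster, table, mge, window_genes = 5, window_bp = 3000) {
  if (is.null(mge) || !nrow(mge)) return(.no_evidence())
  cds <- table[!is.na(table$index) & table$contig_id == cluster$contig_id, , drop = FALSE]
  mg <- cds[cds$gene_id %in% mge$gene_id, , drop = FALSE]
  # the cluster's own genes cannot serve as their own MGE evidence
  own <- c(cluster$gene1, cluster$gene2, cluster$gene3)
  mg <- mg[!mg$gene_id %in% own, , drop = FALSE]
  if (!nrow(mg)) return(.no_evidence())
  cl_idx <- c(cluster$idx1, cluster$idx2, cluster$idx3)
  dist_genes <- vapply(mg$index, function(i) min(abs(i - cl_idx)), 0L)
  dist_bp <- vapply(seq_len(nrow(mg)), function(i)
    .span_distance_bp(mg$start[i], mg$end[i], cluster$start, cluster$end), 0L)
  keep <- dist_genes <= window_genes | dist_bp <= window_bp
  if (!any(keep)) return(.no_evidence())
  cat_of <- setNames(mge$category, mge$gene_id)
  data.frame(kind = "mge_gene",
             identifier = sprintf("%s[%s]", mg$gene_id[keep],
                                  unname(cat_of[mg$gene_id[keep]])),
             distance_genes = dist_genes[keep], distance_bp = dist_bp[keep],
             stringsAsFactors = FALSE)
}

#' Assign the genomic-context category of one cluster
#'
#' Precedence: prophage > P4_prophage > MGE_linked > other. A Psu gene
#' inside a predicted prophage region therefore resolves to `prophage`
#' (the psu evidence is retained on the annotation).
#'
#' @param cluster one cluster row.
#' @param evidence data.frame combining the evidence of
#'   [overlaps_prophage()], [rescue_p4()] and [mge_linked()].
#' @return list `cluster_id`, `category`, `evidence`.
#' @export
assign_context <- function(cluster, evidence) {
  category <- if (any(evidence$kind == "prophage_interval")) "prophage"
  else if (any(evidence$kind == "psu_gene")) "P4_prophage"
  else if (any(evidence$kind == "mge_gene")) "MGE_linked"
  else "other"
  list(cluster_id = cluster$cluster_id, category = category,
       evidence = evidence)
}

#' Annotate the genomic context of every cluster
#'
#' @param clusters [classify_clusters()] output (typically the authentic
#'   subset, but any rows work).
#' @param table the `genome_table`.
#' @param archs role table.
#' @param intervals prophage intervals (may be `NULL`).
#' @param mge MGE table (may be `NULL`).
#' @param config a [kkp_config()] list (windows, containment flag).
#' @return data.frame `cluster_id`, `category`, `n_prophage`, `n_psu`,
#'   `n_mge`, `evidence` (semicolon-joined identifiers).
#' @export
annotate_contexts <- function(clusters, table, archs, intervals = NULL,
                              mge = NULL, config = kkp_config()) {
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    ev <- rbind(overlaps_prophage(cl, intervals, config$prophage_containment),
                rescue_p4(cl, table, archs, config$p4_window_genes),
                mge_linked(cl, table, mge, config$mge_window_genes,
                           config$mge_window_bp))
    a <- assign_context(cl, ev)
    data.frame(cluster_id = a$cluster_id, genome_id = cl$genome_id,
               category = a$category,
               n_prophage = sum(ev$kind == "prophage_interval"),
               n_psu = sum(ev$kind == "psu_gene"),
               n_mge = sum(ev$kind == "mge_gene"),
               evidence = paste(ev$identifier, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(cluster_id = character(), genome_id = character(),
                      category = character(), n_prophage = integer(),
                      n_psu = integer(), n_mge = integer(),
                      evidence = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summarize context categories
#'
#' Counts and fractions per category, overall and (optionally) per taxon,
#' with the non-prophage subtotal reported as "x out of y" MGE-linked.
#'
#' @param annotations [annotate_contexts()] output.
#' @param taxa optional named vector genome_id -> taxon label.
#' @return data.frame of counts/fractions; attribute
#'   `mge_among_nonprophage` carries the "x out of y" string.
#' @export
summarize_contexts <- function(annotations, taxa = NULL) {
  cats <- c("prophage", "P4_prophage", "MGE_linked", "other")
  tally <- function(df, label) {
    n <- nrow(df)
    data.frame(taxon = label, category = cats,
               count = vapply(cats, function(c) sum(df$category == c), 0L),
               fraction = if (n) vapply(cats, function(c)
                 sum(df$category == c) / n, 0) else rep(NA_real_, 4),
               stringsAsFactors = FALSE)
  }
  out <- tally(annotations, "all")
  if (!is.null(taxa)) {
    tx <- unname(taxa[annotations$genome_id])
    for (t in sort(unique(tx)))
      out <- rbind(out, tally(annotations[which(tx == t), , drop = FALSE], t))
  }
  rownames(out) <- NULL
  nonpro <- annotations[!annotations$category %in% c("prophage", "P4_prophage"), ,
                        drop = FALSE]
  attr(out, "mge_among_nonprophage") <-
    sprintf("%d out of %d", sum(nonpro$category == "MGE_linked"), nrow(nonpro))
  out
}
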