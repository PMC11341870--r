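#' Enumerate candidate KKP triplets
#'
#' Slides over every run of three consecutive CDS genes on a contig and
#' keeps those on one strand whose roles, read in transcription order
#' (descending coordinates on the minus strand), match the phosphatase /
#' kinase / kinase pattern. The search pattern is `"PKK"` (phosphatase
#' first, the published search order), `"KKP"` (kinase-kinase-phosphatase,
#' the operon name order), or `"both"` (default). Kinase roles at this
#' stage are any of Pkinase_plain / Pkinase_CSD / Pkinase_FHA; accessory
#' domain status is judged later by [apply_architecture_filter()].
#'
#' @param table a `genome_table`.
#' @param archs role table from [build_architectures()]; every CDS in
#'   `table` must have a row.
#' @param pattern `"both"`, `"PKK"` or `"KKP"`.
#' @param allow_intervening when `TRUE`, one CDS of role `other` may sit
#'   inside the triplet (default `FALSE`: strictly consecutive indices).
#' @param max_gap_bp cap on the intergenic distance between consecutive
#'   triplet genes; default `Inf` (adjacency by index suffices).
#' @return data.frame of candidates in coordinate order: contig, strand,
#'   matched pattern, the three gene ids / indices / roles / lengths in
#'   transcription order, and the genomic span.
#' @export
scan_triplets <- function(table, archs, pattern = c("both", "PKK", "KKP"),
                          allow_intervening = FALSE, max_gap_bp = Inf) {
  pattern <- match.arg(pattern)
  genome_id <- attr(table, "genome_id") %||% NA_character_
  cds <- table[!is.na(table$index), , drop = FALSE]
  missing <- setdiff(cds$gene_id, archs$gene_id)
  if (length(missing))
    stop("lookup error: no architecture for gene(s): ",
         paste(head(missing, 5), collapse = ", "))
  role_of <- setNames(archs$role, archs$gene_id)
  kin <- c("Pkinase_plain", "Pkinase_CSD", "Pkinase_FHA")
  out <- list()
  for (ct in unique(cds$contig_id)) {
    g <- cds[cds$contig_id == ct, , drop = FALSE]
    g <- g[order(g$index), , drop = FALSE]
    n <- nrow(g)
    if (n < 3) next
    roles <- unname(role_of[g$gene_id])
    windows <- lapply(seq_len(max(0, n - 2)), function(i) i:(i + 2))
    if (allow_intervening && n >= 4) {
      for (i in seq_len(n - 3)) {       # one skippable interior 'other' gene
        if (roles[i + 1] == "other") windows[[length(windows) + 1]] <- c(i, i + 2, i + 3)
        if (roles[i + 2] == "other") windows[[length(windows) + 1]] <- c(i, i + 1, i + 3)
      }
    }
    for (idx in windows) {
      st <- g$strand[idx]
      if (length(unique(st)) != 1) next
      if (is.finite(max_gap_bp)) {
        gaps <- vapply(1:2, function(k)
          intergenic_distance_bp(g[idx[k], ], g[idx[k + 1], ]), 0L)
        if (any(gaps > max_gap_bp)) next
      }
      tx <- if (st[1] == "+") idx else rev(idx)   # transcription order
      r <- roles[tx]
      matched <- NA_character_
      if (pattern %in% c("both", "PKK") &&
          r[1] == "PP2C" && r[2] %in% kin && r[3] %in% kin) {
        matched <- "PKK"
      } else if (pattern %in% c("both", "KKP") &&
                 r[1] %in% kin && r[2] %in% kin && r[3] == "PP2C") {
        matched <- "KKP"
      }
      if (is.na(matched)) next
      out[[length(out) + 1]] <- data.frame(
        genome_id = genome_id, contig_id = ct, strand = st[1],
        pattern_matched = matched,
        gene1 = g$gene_id[tx[1]], gene2 = g$gene_id[tx[2]], gene3 = g$gene_id[tx[3]],
        idx1 = g$index[tx[1]], idx2 = g$index[tx[2]], idx3 = g$index[tx[3]],
        role1 = r[1], role2 = r[2], role3 = r[3],
        len1 = g$length_bp[tx[1]], len2 = g$length_bp[tx[2]], len3 = g$length_bp[tx[3]],
        start = min(g$start[idx]), end = max(g$end[idx]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_candidates())
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_candidates <- function() {
  data.frame(genome_id = character(), contig_id = character(),
             strand = character(), pattern_matched = character(),
             gene1 = character(), gene2 = character(), gene3 = character(),
             idx1 = integer(), idx2 = integer(), idx3 = integer(),
             role1 = character(), role2 = character(), role3 = character(),
             len1 = integer(), len2 = integer(), len3 = integer(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

#' Gene-length filter for a candidate triplet
#'
#' Each gene passes iff `min_bp < length_bp < max_bp` — strict bounds,
#' defaults 900 and 1300 bp — and the candidate passes iff all three genes
#' do.
#'
#' @param cand one candidate row from [scan_triplets()].
#' @param min_bp,max_bp strict length bounds in bp.
#' @return list with `length_pass` (logical per gene) and `reasons`
#'   (LEN_SHORT / LEN_LONG codes).
#' @export
apply_length_filter <- function(cand, min_bp = 900, max_bp = 1300) {
  if (min_bp >= max_bp) stop("config error: min_bp must be < max_bp")
  len <- c(cand$len1, cand$len2, cand$len3)
  pass <- len > min_bp & len < max_bp
  reasons <- character(0)
  if (any(len <= min_bp)) reasons <- c(reasons, "LEN_SHORT")
  if (any(len >= max_bp)) reasons <- c(reasons, "LEN_LONG")
  list(length_pass = pass, reasons = reasons)
}

#' Kinase accessory-domain filter for a candidate triplet
#'
#' Passes iff, of the two kinase genes, exactly one has role Pkinase_CSD
#' and the other Pkinase_FHA; either kinase position may carry either
#' accessory. Rejection codes: NO_CSD, NO_FHA, DUP_ACCESSORY.
#'
#' @param cand one candidate row from [scan_triplets()].
#' @return list with `architecture_pass` and `reasons`.
#' @export
apply_architecture_filter <- function(cand) {
  r <- c(cand$role1, cand$role2, cand$role3)
  kroles <- r[r != "PP2C"]
  n_csd <- sum(kroles == "Pkinase_CSD")
  n_fha <- sum(kroles == "Pkinase_FHA")
  reasons <- character(0)
  if (n_csd == 0) reasons <- c(reasons, "NO_CSD")
  if (n_fha == 0) reasons <- c(reasons, "NO_FHA")
  if (n_csd > 1 || n_fha > 1) reasons <- c(reasons, "DUP_ACCESSORY")
  list(architecture_pass = n_csd == 1 && n_fha == 1, reasons = reasons)
}

#' Scan a genome and classify every candidate triplet
#'
#' Composition of [scan_triplets()], [apply_length_filter()] and
#' [apply_architecture_filter()]: one row per candidate with per-filter
#' flags, rejection reasons, the role-resolved component genes (pfpC-like
#' phosphatase, pfkA-like CSD kinase, pfkB-like FHA kinase) and the final
#' status (`authentic` / `rejected`).
#'
#' @inheritParams scan_triplets
#' @param config a [kkp_config()] list (pattern, min_bp, max_bp).
#' @return data.frame of KKP clusters; `cluster_id` is
#'   genome:contig:first-index.
#' @export
classify_clusters <- function(table, archs, config = kkp_config()) {
  cand <- scan_triplets(table, archs, pattern = config$pattern,
                        allow_intervening = config$allow_intervening,
                        max_gap_bp = config$max_gap_bp)
  n <- nrow(cand)
  flt <- lapply(seq_len(n), function(i) {
    lf <- apply_length_filter(cand[i, ], config$min_bp, config$max_bp)
    af <- apply_architecture_filter(cand[i, ])
    list(lp = lf$length_pass, ap = af$architecture_pass,
         reasons = c(lf$reasons, af$reasons))
  })
  cand$len_pass1 <- vapply(flt, function(x) x$lp[1], NA)
  cand$len_pass2 <- vapply(flt, function(x) x$lp[2], NA)
  cand$len_pass3 <- vapply(flt, function(x) x$lp[3], NA)
  cand$architecture_pass <- vapply(flt, function(x) x$ap, NA)
  cand$reasons <- vapply(flt, function(x) paste(x$reasons, collapse = ","), "")
  cand$status <- ifelse(cand$reasons == "", "authentic", "rejected")
  # role-resolved components (NA unless that role is present exactly once)
  pick <- function(i, role) {
    r <- c(cand$role1[i], cand$role2[i], cand$role3[i])
    g <- c(cand$gene1[i], cand$gene2[i], cand$gene3[i])
    hit <- g[r == role]
    if (length(hit) == 1) hit else NA_character_
  }
  cand$pfpC_like <- vapply(seq_len(n), pick, "", role = "PP2C")
  cand$pfkA_like <- vapply(seq_len(n), pick, "", role = "Pkinase_CSD")
  cand$pfkB_like <- vapply(seq_len(n), pick, "", role = "Pkinase_FHA")
  cand$cluster_id <- if (n) sprintf("%s:%s:%d", cand$genome_id, cand$contig_id,
                                    pmin(cand$idx1, cand$idx3)) else character(0)
  cand
}

#' Fraction of candidates that are authentic KKP clusters
#'
#' @param clusters output of [classify_clusters()].
#' @return percentage (0-100), or `NA` with attribute `undefined = TRUE`
#'   when there are no candidates.
#' @export
authentic_fraction <- function(clusters) {
  n <- nrow(clusters)
  if (n == 0) return(structure(NA_real_, undefined = TRUE))
  100 * sum(clusters$status == "authentic") / n
}
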