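# Independent oracles used across tests. These deliberately re-derive the
# expected behaviour from first principles and share no code with the
# package implementation.

# Brute-force triplet oracle: tests every (i, i+1, i+2) CDS window on every
# contig directly against the pattern, strand, length and accessory rules.
oracle_clusters <- function(table, archs, min_bp = 900, max_bp = 1300,
                            pattern = "both") {
  role <- setNames(archs$role, archs$gene_id)
  kin <- c("Pkinase_plain", "Pkinase_CSD", "Pkinase_FHA")
  cds <- as.data.frame(table)
  cds <- cds[!is.na(cds$index), , drop = FALSE]
  rows <- list()
  for (ct in unique(cds$contig_id)) {
    g <- cds[cds$contig_id == ct, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 3) next
    for (i in seq_len(nrow(g) - 2)) {
      w <- g[i:(i + 2), ]
      if (length(unique(w$strand)) != 1) next
      r <- unname(role[w$gene_id])
      if (w$strand[1] == "-") r <- rev(r)
      pkk <- r[1] == "PP2C" && r[2] %in% kin && r[3] %in% kin
      kkp <- r[1] %in% kin && r[2] %in% kin && r[3] == "PP2C"
      ok <- switch(pattern, both = pkk || kkp, PKK = pkk, KKP = kkp)
      if (!ok) next
      kr <- r[r != "PP2C"]
      auth <- all(w$length_bp > min_bp & w$length_bp < max_bp) &&
        sum(kr == "Pkinase_CSD") == 1 && sum(kr == "Pkinase_FHA") == 1
      rows[[length(rows) + 1]] <- data.frame(
        genome_id = attr(table, "genome_id"), contig_id = ct,
        i1 = w$index[1], i2 = w$index[2], i3 = w$index[3],
        status = if (auth) "authentic" else "rejected",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(genome_id = character(), contig_id = character(),
                      i1 = integer(), i2 = integer(), i3 = integer(),
                      status = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Canonical comparable key set for a classify_clusters() result.
cluster_keys <- function(clusters) {
  if (!nrow(clusters)) return(character(0))
  idx <- t(apply(clusters[, c("idx1", "idx2", "idx3")], 1, sort))
  sort(sprintf("%s:%s:%d-%d-%d:%s", clusters$genome_id, clusters$contig_id,
               idx[, 1], idx[, 2], idx[, 3], clusters$status))
}

oracle_keys <- function(oracle) {
  if (!nrow(oracle)) return(character(0))
  sort(sprintf("%s:%s:%d-%d-%d:%s", oracle$genome_id, oracle$contig_id,
               oracle$i1, oracle$i2, oracle$i3, oracle$status))
}

# Full-matrix affine (Gotoh) DP in plain R, score only: the exhaustive
# alignment oracle for the compiled aligner.
oracle_affine_score <- function(a, b, sub, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  H <- matrix(NEG, n + 1, m + 1); E <- H; F <- H
  H[1, 1] <- 0
  for (j in 2:(m + 1)) { E[1, j] <- gap_open + (j - 1) * gap_extend; H[1, j] <- E[1, j] }
  for (i in 2:(n + 1)) { F[i, 1] <- gap_open + (i - 1) * gap_extend; H[i, 1] <- F[i, 1] }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend, E[i, j - 1] + gap_extend)
    F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend, F[i - 1, j] + gap_extend)
    H[i, j] <- max(H[i - 1, j - 1] + sub[A[i - 1], B[j - 1]], E[i, j], F[i, j])
  }
  H[n + 1, m + 1]
}

dna_sub <- function(match = 1, mismatch = -2) {
  b <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
  diag(m) <- match
  m
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Union-find connected components, independent of igraph.
oracle_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (adj[i, j]) parent[find(i)] <- find(j)
  vapply(seq_len(n), find, 0L)
}

# Build architectures for one generated genome bundle.
archs_of <- function(g, ...) {
  build_architectures(g$hits, gene_ids = g$table$gene_id[!is.na(g$table$index)],
                      ...)
}

# Reverse-complement a genome table: flip coordinates and strands on each
# contig (sequence length taken as max end + margin).
mirror_table <- function(table) {
  df <- as.data.frame(table)
  for (ct in unique(df$contig_id)) {
    sel <- df$contig_id == ct
    L <- max(df$end[sel]) + 50L
    s <- df$start[sel]; e <- df$end[sel]
    df$start[sel] <- L - e + 1L
    df$end[sel] <- L - s + 1L
    df$strand[sel] <- ifelse(df$strand[sel] == "+", "-", "+")
  }
  make_gene_table(df, genome_id = paste0(attr(table, "genome_id"), "_rc"),
                  taxon = attr(table, "taxon"))
}

# Hand-built single-contig gene table plus a role table, for targeted
# scanner cases. length in bp, default in the accepted band.
toy_genome <- function(roles, strands, lengths = rep(1002L, length(roles)),
                       gap = 50L, genome_id = "toy") {
  n <- length(roles)
  start <- integer(n); end <- integer(n); pos <- 1L
  for (i in seq_len(n)) {
    start[i] <- pos + gap
    end[i] <- start[i] + lengths[i] - 1L
    pos <- end[i] + 1L
  }
  ids <- sprintf("%s_g%02d", genome_id, seq_len(n))
  tab <- make_gene_table(data.frame(
    gene_id = ids, contig_id = "c1", start = start, end = end,
    strand = strands, type = "CDS", stringsAsFactors = FALSE),
    genome_id = genome_id)
  archs <- data.frame(gene_id = ids, role = roles, arch = roles,
                      stringsAsFactors = FALSE)
  list(table = tab, archs = archs)
}
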