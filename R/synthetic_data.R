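#' Configuration for the synthetic genome generator
#'
#' Defaults describe a desk-scale bacterial genome: ~100 CDS per contig,
#' log-normal gene lengths around 900 bp, short intergenic gaps, one
#' planted authentic KKP cluster per genome and no decoys. Planted cluster
#' genes are forced into the 900-1300 bp band (multiples of 3). The
#' context mix over authentic clusters defaults to prophage 0.60,
#' P4_prophage 0.15, MGE_linked 0.15, other 0.10 so every category is
#' populated in small batteries.
#'
#' @param seed integer seed; all randomness flows from it, with per-genome
#'   substreams derived by counter so adding genomes never perturbs
#'   earlier ones.
#' @param n_genomes number of genomes.
#' @param genes_per_genome CDS count per genome (single contig).
#' @param n_authentic authentic clusters planted per genome.
#' @param decoys named integer vector of per-genome decoy counts over
#'   classes WRONG_ORDER, MIXED_STRAND, NON_ADJACENT, LEN_OUT, NO_CSD,
#'   NO_FHA, KK_PAIR_ONLY.
#' @param context_mix category sampling weights for authentic clusters.
#' @param background_roles sampling weights of background gene roles
#'   (`other`, lone `Pkinase_plain`, lone `PP2C`).
#' @param family_plan optional list of groups `list(size =, identity =)`:
#'   consecutive authentic clusters (across genomes, in order) whose three
#'   proteins are planted at the given exact pairwise identity.
#' @param gene_len_meanlog,gene_len_sdlog background length distribution.
#' @param emit_dna generate contig DNA (needed only for region
#'   extraction/alignment tests; skipping it speeds large batteries).
#' @export
synth_config <- function(seed = 1, n_genomes = 1, genes_per_genome = 100,
                         n_authentic = 1,
                         decoys = c(WRONG_ORDER = 0, MIXED_STRAND = 0,
                                    NON_ADJACENT = 0, LEN_OUT = 0,
                                    NO_CSD = 0, NO_FHA = 0, KK_PAIR_ONLY = 0),
                         context_mix = c(prophage = 0.60, P4_prophage = 0.15,
                                         MGE_linked = 0.15, other = 0.10),
                         background_roles = c(other = 0.95,
                                              Pkinase_plain = 0.03, PP2C = 0.02),
                         family_plan = NULL,
                         gene_len_meanlog = log(900), gene_len_sdlog = 0.35,
                         emit_dna = TRUE) {
  classes <- c("WRONG_ORDER", "MIXED_STRAND", "NON_ADJACENT", "LEN_OUT",
               "NO_CSD", "NO_FHA", "KK_PAIR_ONLY")
  full <- setNames(integer(7), classes)
  full[names(decoys)] <- as.integer(decoys)
  bad <- setdiff(names(decoys), classes)
  if (length(bad)) stop("config error: unknown decoy class: ",
                        paste(bad, collapse = ", "))
  if (abs(sum(context_mix) - 1) > 1e-9)
    stop("config error: context_mix fractions must sum to 1")
  list(seed = as.integer(seed), n_genomes = n_genomes,
       genes_per_genome = genes_per_genome, n_authentic = n_authentic,
       decoys = full, context_mix = context_mix,
       background_roles = background_roles, family_plan = family_plan,
       gene_len_meanlog = gene_len_meanlog, gene_len_sdlog = gene_len_sdlog,
       emit_dna = emit_dna)
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Plant a protein family at an exact pairwise identity
#'
#' Draws a random ancestor of length `len` and derives `n - 1` variants by
#' point substitutions at one shared position set, each variant carrying a
#' distinct residue at every mutated position. All `n` sequences therefore
#' have exact pairwise (gapless) identity `100 * (1 - k/len)` with
#' `k = round((1 - t/100) * len)`.
#'
#' @param target target percent identity in (0, 100].
#' @param n number of family members (n - 1 <= 18).
#' @param len protein length (default 300 aa).
#' @return character vector of `n` amino-acid sequences.
#' @export
plant_identity_family <- function(target, n, len = 300) {
  if (target <= 0 || target > 100)
    stop("config error: target identity must be in (0, 100]")
  if (n - 1 > 18) stop("config error: at most 19 members per family")
  anc <- sample(.AA, len, replace = TRUE)
  k <- round((1 - target / 100) * len)
  seqs <- list(anc)
  if (n > 1 && k > 0) {
    pos <- sample.int(len, k)
    for (j in 2:n) {
      v <- anc
      for (p in pos) {
        used <- vapply(seqs, `[`, "", p)
        v[p] <- sample(setdiff(.AA, used), 1)
      }
      seqs[[j]] <- v
    }
  } else if (n > 1) {
    seqs <- rep(list(anc), n)
  }
  vapply(seqs, paste, "", collapse = "")
}

#' Generate a seeded synthetic dataset with planted truth
#'
#' Builds `n_genomes` single-contig genomes with planted authentic KKP
#' clusters, typed decoys, genomic-context scaffolding (prophage
#' intervals, Psu genes, MGE-labelled genes) and a truth table recording
#' every planted item. Identical configs give identical output
#' (byte-identical files when written via [write_dataset()]).
#'
#' @param config a [synth_config()] list.
#' @param out_dir optional directory; when given, all files are written
#'   there via [write_dataset()].
#' @return list with `genomes` (per genome: `table`, `hits`, `intervals`,
#'   `mge`, `dna`, `proteins`), `truth` (data.frame) and `config`.
#' @export
generate_dataset <- function(config = synth_config(), out_dir = NULL) {
  # family-plan sequences come from the master stream, assigned to
  # authentic items in generation order
  fam_seqs <- list(); fam_assign <- integer(0)
  if (!is.null(config$family_plan)) {
    set.seed(config$seed %% 2147483647L)
    for (gi in seq_along(config$family_plan)) {
      grp <- config$family_plan[[gi]]
      trio <- lapply(1:3, function(x)
        plant_identity_family(grp$identity, grp$size))
      for (m in seq_len(grp$size)) {
        fam_seqs[[length(fam_seqs) + 1]] <-
          c(pfpC = trio[[1]][m], pfkA = trio[[2]][m], pfkB = trio[[3]][m])
        fam_assign <- c(fam_assign, gi)
      }
    }
    total_auth <- config$n_authentic * config$n_genomes
    if (length(fam_seqs) > total_auth)
      stop("config error: family plan needs more authentic clusters (",
           length(fam_seqs), ") than planted (", total_auth, ")")
  }
  genomes <- list(); truth <- list(); auth_counter <- 0L
  for (gn in seq_len(config$n_genomes)) {
    set.seed((config$seed + gn * 7919L) %% 2147483647L)
    gid <- sprintf("syng%03d", gn)
    g <- .generate_genome(gid, config, fam_seqs, fam_assign, auth_counter)
    auth_counter <- auth_counter + config$n_authentic
    genomes[[gid]] <- g$genome
    truth[[gid]] <- g$truth
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  ds <- list(genomes = genomes, truth = truth, config = config)
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

.generate_genome <- function(gid, config, fam_seqs, fam_assign, auth_offset) {
  n <- config$genes_per_genome
  contig <- paste0(gid, "_c1")
  items <- c(rep("authentic", config$n_authentic),
             rep(names(config$decoys), config$decoys))
  n_items <- length(items)
  sep <- 40L
  if (n_items > 0 && 10L + n_items * sep > n)
    stop("config error: ", n_items, " planted items need at least ",
         10L + n_items * sep, " genes, have ", n)
  items <- if (n_items > 1) sample(items) else items
  starts <- if (n_items)
    10L + (seq_len(n_items) - 1L) * sep + sample.int(6L, n_items, replace = TRUE) - 1L
  else integer(0)

  # background scaffold
  role <- sample(names(config$background_roles), n, replace = TRUE,
                 prob = config$background_roles)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- round(stats::rlnorm(n, config$gene_len_meanlog, config$gene_len_sdlog) / 3) * 3
  len <- pmin(pmax(len, 150L), 3600L)
  planted <- rep(FALSE, n)
  mge_rows <- list(); intervals <- list(); truth_rows <- list()
  item_meta <- list()

  in_band_len <- function(k) sample(seq(903L, 1299L, by = 3L), k, replace = TRUE)
  auth_idx_here <- 0L
  for (ii in seq_along(items)) {
    cls <- items[ii]; s <- starts[ii]
    width <- switch(cls, NON_ADJACENT = 4L, KK_PAIR_ONLY = 2L, 3L)
    guard <- max(1L, s - 3L):min(n, s + width + 2L)
    role[guard] <- "other"          # clean flanks: no background near-misses
    st <- sample(c("+", "-"), 1)
    kperm <- sample(c("Pkinase_CSD", "Pkinase_FHA"))
    tr <- switch(cls,
      authentic    = c("PP2C", kperm),
      LEN_OUT      = c("PP2C", kperm),
      MIXED_STRAND = c("PP2C", kperm),
      NO_CSD       = c("PP2C", sample(c("Pkinase_plain", "Pkinase_FHA"))),
      NO_FHA       = c("PP2C", sample(c("Pkinase_CSD", "Pkinase_plain"))),
      WRONG_ORDER  = c(kperm[1], "PP2C", kperm[2]),
      NON_ADJACENT = c("PP2C", "other", kperm),
      KK_PAIR_ONLY = kperm)
    slots <- s:(s + width - 1L)
    co_roles <- if (st == "+") tr else rev(tr)
    role[slots] <- co_roles
    strand[slots] <- st
    len[slots] <- in_band_len(width)
    if (cls == "MIXED_STRAND")
      strand[s + 1L] <- if (st == "+") "-" else "+"
    if (cls == "LEN_OUT")
      len[sample(slots, 1)] <- sample(c(840L, 1398L), 1)
    planted[slots] <- TRUE
    # pattern genes in coordinate order (exclude the intervening 'other')
    pat <- slots[co_roles != "other"]
    ctx <- NA_character_; fam <- NA_integer_; fam_rank <- NA_integer_
    if (cls == "authentic") {
      auth_idx_here <- auth_idx_here + 1L
      ctx <- sample(names(config$context_mix), 1, prob = config$context_mix)
      gidx <- auth_offset + auth_idx_here
      if (gidx <= length(fam_assign)) {
        fam <- fam_assign[gidx]
        fam_rank <- gidx
      }
    }
    if (!is.na(fam_rank)) len[slots] <- 903L    # matches the 300-aa family proteins
    item_meta[[ii]] <- list(class = cls, slots = slots, pattern = pat,
                            strand = st, context = ctx, family = fam,
                            fam_rank = fam_rank)
  }

  # coordinates: short intergenic gaps, occasionally abutting
  gaps <- pmax(0L, round(stats::rexp(n, 1 / 80)))
  start <- integer(n); end <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    start[i] <- pos + gaps[i]
    end[i] <- start[i] + len[i] - 1L
    pos <- end[i] + 1L
  }
  gene_id <- sprintf("%s_g%04d", gid, seq_len(n))

  # context scaffolding
  for (ii in seq_along(item_meta)) {
    m <- item_meta[[ii]]
    if (is.na(m$context)) next
    span <- c(start[min(m$pattern)], end[max(m$pattern)])
    side_pick <- function(d) {
      cand <- c(min(m$pattern) - d, max(m$pattern) + d)
      cand <- cand[cand >= 1 & cand <= n]
      cand <- cand[!planted[cand]]
      if (!length(cand)) NA_integer_ else cand[1]
    }
    if (m$context == "prophage") {
      pad <- sample(500:1500, 2, replace = TRUE)
      intervals[[length(intervals) + 1]] <- data.frame(
        contig_id = contig, start = max(1L, span[1] - pad[1]),
        end = span[2] + pad[2], label = "prophage", source = "synthetic",
        stringsAsFactors = FALSE)
    } else if (m$context == "P4_prophage") {
      psu_at <- side_pick(sample(3:10, 1))
      if (is.na(psu_at)) stop("config error: no room for a Psu gene near item")
      role[psu_at] <- "Psu"
    } else if (m$context == "MGE_linked") {
      mge_at <- side_pick(sample(1:4, 1))
      if (is.na(mge_at)) stop("config error: no room for an MGE gene near item")
      mge_rows[[length(mge_rows) + 1]] <- data.frame(
        gene_id = gene_id[mge_at],
        category = sample(c("integrase", "transposase", "RM_system",
                            "TA_system", "phage_gene"), 1),
        stringsAsFactors = FALSE)
    }
  }

  # truth rows (coordinate-order 0-based CDS indices of the pattern genes)
  for (ii in seq_along(item_meta)) {
    m <- item_meta[[ii]]
    p <- m$pattern
    truth_rows[[ii]] <- data.frame(
      item_id = sprintf("%s_item%02d", gid, ii), genome_id = gid,
      contig_id = contig, class = m$class, strand = m$strand,
      idx1 = p[1] - 1L, idx2 = p[2] - 1L,
      idx3 = if (length(p) >= 3) p[3] - 1L else NA_integer_,
      gene1 = gene_id[p[1]], gene2 = gene_id[p[2]],
      gene3 = if (length(p) >= 3) gene_id[p[3]] else NA_character_,
      context = m$context, family_group = m$family,
      stringsAsFactors = FALSE)
  }

  # domain hit table
  plen <- pmax(50L, len %/% 3L - 1L)
  hits <- .synth_hits(gene_id, role, plen)

  # proteins for planted pattern genes (family-planned trios override)
  proteins <- character(0)
  for (m in item_meta) {
    for (p in m$pattern) {
      if (role[p] == "other") next
      aa <- paste(sample(.AA, plen[p], replace = TRUE), collapse = "")
      proteins[gene_id[p]] <- aa
    }
    if (!is.na(m$fam_rank)) {
      fs <- fam_seqs[[m$fam_rank]]
      comp_role <- role[m$pattern]
      proteins[gene_id[m$pattern[comp_role == "PP2C"]]] <- fs[["pfpC"]]
      proteins[gene_id[m$pattern[comp_role == "Pkinase_CSD"]]] <- fs[["pfkA"]]
      proteins[gene_id[m$pattern[comp_role == "Pkinase_FHA"]]] <- fs[["pfkB"]]
    }
  }

  df <- data.frame(gene_id = gene_id, contig_id = contig, start = start,
                   end = end, strand = strand, type = "CDS",
                   product = paste0("synthetic ", role, " protein"),
                   stringsAsFactors = FALSE)
  # one tRNA feature to exercise the CDS-universe rule
  trna_at <- min(n, 5L)
  df <- rbind(df, data.frame(
    gene_id = paste0(gid, "_tRNA1"), contig_id = contig,
    start = end[trna_at] + 10L, end = end[trna_at] + 85L,
    strand = "+", type = "tRNA", product = "tRNA-Met",
    stringsAsFactors = FALSE))
  table <- make_gene_table(df, genome_id = gid)

  dna <- NULL
  if (isTRUE(config$emit_dna)) {
    total <- max(end) + 200L
    dna <- setNames(paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                          collapse = ""), contig)
  }
  ivs <- if (length(intervals)) do.call(rbind, intervals) else
    data.frame(contig_id = character(), start = integer(), end = integer(),
               label = character(), source = character(), stringsAsFactors = FALSE)
  mge <- if (length(mge_rows)) do.call(rbind, mge_rows) else
    data.frame(gene_id = character(), category = character(),
               stringsAsFactors = FALSE)
  list(genome = list(genome_id = gid, table = table, hits = hits,
                     intervals = ivs, mge = mge, dna = dna,
                     proteins = proteins),
       truth = if (length(truth_rows)) do.call(rbind, truth_rows) else
         data.frame(item_id = character(), genome_id = character(),
                    contig_id = character(), class = character(),
                    strand = character(), idx1 = integer(), idx2 = integer(),
                    idx3 = integer(), gene1 = character(), gene2 = character(),
                    gene3 = character(), context = character(),
                    family_group = integer(), stringsAsFactors = FALSE))
}

.synth_hits <- function(gene_id, role, plen) {
  rows <- list()
  ev <- function(lo = 20, hi = 60) 10^-stats::runif(1, lo, hi)
  add <- function(g, acc, name, from, to, bits, ie = ev()) {
    rows[[length(rows) + 1]] <<- data.frame(
      gene_id = g, accession = acc, name = name, i_evalue = ie,
      bitscore = round(bits, 1), ali_from = as.integer(from),
      ali_to = as.integer(to), tlen = NA_integer_, stringsAsFactors = FALSE)
  }
  for (i in seq_along(gene_id)) {
    g <- gene_id[i]; r <- role[i]; L <- plen[i]
    if (r == "PP2C") {
      acc <- sample(c("PF13672", "COG0631"), 1)
      add(g, acc, "PP2C", 15, max(20, L - 15), stats::runif(1, 150, 250))
    } else if (r %in% c("Pkinase_plain", "Pkinase_CSD", "Pkinase_FHA")) {
      acc <- sample(c("PF00069", "COG0515"), 1)
      kend <- min(265, L - 60)
      add(g, acc, "Pkinase", 10, kend, stats::runif(1, 180, 280))
      if (r == "Pkinase_CSD")
        add(g, "PF00313", "CSD", max(kend + 5, L - 80), L - 10,
            stats::runif(1, 40, 80))
      if (r == "Pkinase_FHA")
        add(g, "PF00498", "FHA", max(kend + 5, L - 80), L - 10,
            stats::runif(1, 40, 80))
    } else if (r == "Psu") {
      add(g, "PF07455", "Psu", 10, max(15, L - 10), stats::runif(1, 100, 200))
    } else {
      u <- stats::runif(1)
      if (u < 0.08) {
        add(g, "PF03235", "DUF262", 10, max(15, L - 10), stats::runif(1, 30, 90))
      } else if (u < 0.10) {
        # near-miss: a weak kinase hit that the E-value filter must drop
        add(g, "PF00069", "Pkinase", 10, max(15, min(200, L - 5)),
            stats::runif(1, 10, 18), ie = 10^-stats::runif(1, 1, 4))
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), accession = character(),
                      name = character(), i_evalue = numeric(),
                      bitscore = numeric(), ali_from = integer(),
                      ali_to = integer(), tlen = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$tlen <- plen[match(out$gene_id, gene_id)]
  out
}
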