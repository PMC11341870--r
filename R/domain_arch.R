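#' Default domain vocabulary
#'
#' Maps Pfam/COG accessions onto the canonical labels of the KKP search:
#' the Ser/Thr kinase domain (PF00069/COG0515, Pkinase), the PP2C
#' phosphatase domain (PF13672/COG0631), the cold shock domain (PF00313),
#' the forkhead-associated domain (PF00498) and the phage P4 polarity
#' suppression protein Psu (PF07455).
#'
#' @param extra named character vector of additional accession -> label
#'   entries (or overrides).
#' @return named character vector accession -> label.
#' @export
domain_vocabulary <- function(extra = NULL) {
  v <- c(PF00069 = "Pkinase", COG0515 = "Pkinase",
         PF13672 = "PP2C",    COG0631 = "PP2C",
         PF00313 = "CSD",
         PF00498 = "FHA",
         PF07455 = "Psu")
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("vocabulary extensions must be named accession -> label")
    v[names(extra)] <- extra
  }
  v
}

#' Read per-domain hits from a HMMER3 domtblout-dialect table
#'
#' Whitespace-delimited per-domain table with '#' comment lines. Which name
#' column carries the gene depends on how the search was run: `hmmsearch`
#' puts the sequence in the target column (the default here), `hmmscan`
#' puts it in the query column.
#'
#' @param path domtblout file.
#' @param gene_in `"target"` (hmmsearch convention) or `"query"` (hmmscan).
#' @return data.frame `gene_id`, `accession`, `name`, `i_evalue`,
#'   `bitscore`, `ali_from`, `ali_to`.
#' @export
read_domain_hits <- function(path, gene_in = c("target", "query")) {
  gene_in <- match.arg(gene_in)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(gene_id = character(), accession = character(),
                      name = character(), i_evalue = numeric(),
                      bitscore = numeric(), ali_from = integer(),
                      ali_to = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\\s+")
  nf <- vapply(parts, length, 0L)
  if (any(nf < 22))
    stop("parse error: line ", lineno[which(nf < 22)[1]],
         ": fewer than 22 fields")
  f <- function(i) vapply(parts, `[`, "", i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(f(i)))
    if (anyNA(x))
      stop("parse error: line ", lineno[which(is.na(x))[1]],
           ": non-numeric ", what)
    x
  }
  # domtblout columns: 1 target, 2 t-acc, 4 query, 5 q-acc, 13 i-Evalue,
  # 14 domain score, 18-19 ali coords
  gene <- if (gene_in == "target") f(1) else f(4)
  dname <- if (gene_in == "target") f(4) else f(1)
  acc <- if (gene_in == "target") f(5) else f(2)
  acc <- sub("\\.\\d+$", "", acc)
  out <- data.frame(
    gene_id = gene, accession = acc, name = dname,
    i_evalue = num(13, "i-Evalue"), bitscore = num(14, "domain score"),
    ali_from = as.integer(num(18, "ali from")),
    ali_to = as.integer(num(19, "ali to")),
    stringsAsFactors = FALSE)
  if (any(out$i_evalue < 0))
    stop("parse error: line ", lineno[which(out$i_evalue < 0)[1]],
         ": negative i-Evalue")
  if (any(out$ali_from > out$ali_to))
    stop("parse error: line ", lineno[which(out$ali_from > out$ali_to)[1]],
         ": ali_from > ali_to")
  out
}

#' Resolve the domain hits of one gene into a non-overlapping architecture
#'
#' Hits above `evalue_max` (independent E-value) are dropped; the rest are
#' accepted greedily by descending bitscore (ties broken by position then
#' accession, so hit order never matters), rejecting any hit that overlaps
#' an already accepted segment by more than `max_shared_aa` residues.
#'
#' @param hits data.frame of [read_domain_hits()] rows, all one gene.
#' @param vocab accession -> label map, see [domain_vocabulary()]; hits
#'   with accessions outside the map get label `"other"`.
#' @param evalue_max independent E-value cutoff (default 1e-5).
#' @param max_shared_aa maximum residues two accepted segments may share
#'   (default 15).
#' @return a `gene_architecture`: list with `gene_id`, `segments`
#'   (data.frame label/ali_from/ali_to/bitscore sorted by position) and
#'   `role`.
#' @export
build_architecture <- function(hits, vocab = domain_vocabulary(),
                               evalue_max = 1e-5, max_shared_aa = 15) {
  gid <- unique(hits$gene_id)
  if (length(gid) > 1)
    stop("domain error: hits span multiple gene_ids: ",
         paste(gid, collapse = ", "))
  if (length(gid) == 0) gid <- NA_character_
  hits <- hits[hits$i_evalue <= evalue_max, , drop = FALSE]
  hits <- hits[order(-hits$bitscore, hits$ali_from, hits$accession), , drop = FALSE]
  acc_from <- integer(0); acc_to <- integer(0); keep <- integer(0)
  for (i in seq_len(nrow(hits))) {
    ov <- pmin(acc_to, hits$ali_to[i]) - pmax(acc_from, hits$ali_from[i]) + 1L
    if (!length(ov) || all(ov <= max_shared_aa)) {
      keep <- c(keep, i)
      acc_from <- c(acc_from, hits$ali_from[i])
      acc_to <- c(acc_to, hits$ali_to[i])
    }
  }
  seg <- hits[keep, , drop = FALSE]
  lab <- unname(vocab[seg$accession])
  lab[is.na(lab)] <- "other"
  segments <- data.frame(label = lab, ali_from = seg$ali_from,
                         ali_to = seg$ali_to, bitscore = seg$bitscore,
                         stringsAsFactors = FALSE)
  segments <- segments[order(segments$ali_from, segments$ali_to), , drop = FALSE]
  rownames(segments) <- NULL
  arch <- structure(list(gene_id = gid, segments = segments, role = NA_character_),
                    class = "gene_architecture")
  arch$role <- classify_gene_role(arch)
  arch
}

#' Classify a gene architecture into a KKP search role
#'
#' Roles: `PP2C` (phosphatase domain, no kinase), `Pkinase_CSD` /
#' `Pkinase_FHA` (kinase with the accessory domain starting strictly after
#' the kinase segment ends — the "variable C-terminus"), `Pkinase_plain`,
#' `Psu`, `other`. An N-terminal accessory domain does not confer the
#' fused role. When both CSD and FHA follow the kinase, the higher-bitscore
#' accessory wins and a warning flags the ambiguity; kinase/phosphatase
#' roles take precedence over Psu when they co-occur (also warned).
#'
#' @param arch a `gene_architecture` (or its `segments` data.frame).
#' @return role string; total and deterministic.
#' @export
classify_gene_role <- function(arch) {
  seg <- if (is.list(arch) && !is.null(arch$segments)) arch$segments else arch
  gid <- if (is.list(arch) && !is.null(arch$gene_id)) arch$gene_id else "?"
  has <- function(l) any(seg$label == l)
  kin <- seg[seg$label == "Pkinase", , drop = FALSE]
  role <- "other"
  if (nrow(kin)) {
    kend <- min(kin$ali_to)   # accessory must follow the (first) kinase domain
    cterm <- seg[seg$label %in% c("CSD", "FHA") & seg$ali_from > kend, , drop = FALSE]
    if (nrow(cterm)) {
      if (all(c("CSD", "FHA") %in% cterm$label)) {
        warning("gene ", gid, ": both CSD and FHA after the kinase domain; ",
                "assigning by higher bitscore")
        cterm <- cterm[which.max(cterm$bitscore), , drop = FALSE]
      }
      best <- cterm$label[which.max(cterm$bitscore)]
      role <- if (best == "CSD") "Pkinase_CSD" else "Pkinase_FHA"
    } else role <- "Pkinase_plain"
  } else if (has("PP2C")) {
    role <- "PP2C"
  } else if (has("Psu")) {
    role <- "Psu"
  }
  if (role %in% c("PP2C", "Pkinase_CSD", "Pkinase_FHA", "Pkinase_plain") &&
      has("Psu"))
    warning("gene ", gid, ": Psu co-occurs with kinase/phosphatase domains; ",
            "kinase/phosphatase role takes precedence")
  role
}

#' Build architectures for every gene in a hit table
#'
#' @param hits full [read_domain_hits()] table (any number of genes).
#' @param gene_ids genes guaranteed a row in the output even when hitless
#'   (role `other`, empty architecture); typically the CDS universe.
#' @inheritParams build_architecture
#' @return data.frame `gene_id`, `role`, `arch` (compact label string),
#'   with the per-gene `gene_architecture` objects in attribute
#'   `architectures`.
#' @export
build_architectures <- function(hits, gene_ids = NULL,
                                vocab = domain_vocabulary(),
                                evalue_max = 1e-5, max_shared_aa = 15) {
  split_hits <- split(hits, hits$gene_id)
  ids <- union(names(split_hits), gene_ids %||% character())
  ids <- sort(ids)
  archs <- lapply(ids, function(g) {
    h <- split_hits[[g]]
    if (is.null(h))
      h <- data.frame(gene_id = character(), accession = character(),
                      name = character(), i_evalue = numeric(),
                      bitscore = numeric(), ali_from = integer(),
                      ali_to = integer(), stringsAsFactors = FALSE)
    a <- build_architecture(h, vocab, evalue_max, max_shared_aa)
    a$gene_id <- g
    a
  })
  names(archs) <- ids
  out <- data.frame(
    gene_id = ids,
    role = vapply(archs, `[[`, "", "role"),
    arch = vapply(archs, function(a) paste(a$segments$label, collapse = "+"), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "architectures") <- archs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
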