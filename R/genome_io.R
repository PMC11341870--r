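#' Read an annotated gene table from GFF3 or GenBank
#'
#' Builds the package's genome table: one row per feature with 1-based
#' inclusive coordinates, strand, and a 0-based per-contig index over CDS
#' features ordered by start (ties broken by end, then gene id). CDS features
#' are the gene universe of the triplet scan; tRNA/rRNA and other feature
#' types are retained with `index = NA` and never scanned.
#'
#' @param path GFF3 (`format = "gff3"`) or GenBank flat file
#'   (`format = "genbank"`).
#' @param genome_id genome identifier stored on the table.
#' @param format input dialect; default guesses from the file extension.
#' @param taxon optional character vector of lineage labels (phylum..genus).
#' @return a `genome_table`: data.frame with columns `gene_id`, `contig_id`,
#'   `start`, `end`, `strand`, `type`, `index`, `length_bp`,
#'   `protein_len_aa`, `product`, and attributes `genome_id`, `taxon`.
#' @export
read_gene_table <- function(path, genome_id,
                            format = c("auto", "gff3", "genbank"),
                            taxon = character()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "gff3"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "gff3") .read_gff3_genes(path) else .read_genbank_genes(path)
  make_gene_table(df, genome_id = genome_id, taxon = taxon)
}

.read_gff3_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse failure in ", path, ": ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  if ("locus_tag" %in% names(md)) {
    lt <- as.character(md$locus_tag)
    id <- ifelse(is.na(id) | id == "", lt, id)
  }
  data.frame(
    gene_id  = id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start    = GenomicRanges::start(gr),
    end      = GenomicRanges::end(gr),
    strand   = as.character(GenomicRanges::strand(gr)),
    type     = as.character(md$type),
    product  = if ("product" %in% names(md)) as.character(md$product) else NA_character_,
    stringsAsFactors = FALSE
  )
}

# Minimal GenBank flat-file feature reader: CDS/tRNA/rRNA features with
# location, locus_tag and product. Join()ed and complement() locations are
# reduced to their outer span; that is all the scan needs.
.read_genbank_genes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_lines <- grep("^LOCUS", lines)
  if (!length(locus_lines)) stop("GenBank parse failure: no LOCUS line in ", path)
  feat_start <- grep("^FEATURES", lines)
  rows <- list()
  for (li in seq_along(locus_lines)) {
    from <- locus_lines[li]
    to <- if (li < length(locus_lines)) locus_lines[li + 1] - 1 else length(lines)
    block <- lines[from:to]
    contig <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    fs <- grep("^FEATURES", block)
    if (!length(fs)) next
    fe <- grep("^(ORIGIN|CONTIG)", block)
    fe <- if (length(fe)) min(fe[fe > fs]) - 1 else length(block)
    feat <- block[(fs + 1):fe]
    starts <- grep("^ {5}\\S", feat)
    for (k in seq_along(starts)) {
      a <- starts[k]
      b <- if (k < length(starts)) starts[k + 1] - 1 else length(feat)
      key <- sub("^ {5}(\\S+).*", "\\1", feat[a])
      if (!key %in% c("CDS", "tRNA", "rRNA")) next
      body <- paste(trimws(feat[a:b]), collapse = " ")
      loc <- sub(paste0("^", key, "\\s+(\\S+).*"), "\\1", body)
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) < 2) stop("GenBank parse failure: bad location '", loc, "'")
      tag <- if (grepl('/locus_tag="', body))
        sub('.*?/locus_tag="([^"]+)".*', "\\1", body) else NA_character_
      prod <- if (grepl('/product="', body))
        sub('.*?/product="([^"]+)".*', "\\1", body) else NA_character_
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = tag, contig_id = contig, start = min(nums), end = max(nums),
        strand = strand, type = key, product = prod, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      type = character(), product = character()))
  do.call(rbind, rows)
}

#' Construct and validate a genome table from a feature data.frame
#'
#' @param df data.frame with `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `type` (optional, defaults to CDS) and `product` (optional).
#' @inheritParams read_gene_table
#' @export
make_gene_table <- function(df, genome_id, taxon = character()) {
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (!"type" %in% names(df)) df$type <- "CDS"
  if (!"product" %in% names(df)) df$product <- NA_character_
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(is.na(df$gene_id) | df$gene_id == ""))
    stop("validation error: feature without a gene_id")
  if (anyDuplicated(df$gene_id))
    stop("validation error: duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(df$start > df$end)) stop("validation error: start > end")
  if (!all(df$strand %in% c("+", "-")))
    stop("validation error: strand must be '+' or '-'")
  ord <- order(df$contig_id, df$start, df$end, df$gene_id)
  df <- df[ord, , drop = FALSE]
  df$length_bp <- df$end - df$start + 1L
  df$protein_len_aa <- ifelse(df$type == "CDS",
                              pmax(0L, df$length_bp %/% 3L - 1L), NA_integer_)
  df$index <- NA_integer_
  is_cds <- df$type == "CDS"
  for (ct in unique(df$contig_id)) {
    sel <- which(is_cds & df$contig_id == ct)
    df$index[sel] <- seq_along(sel) - 1L
  }
  rownames(df) <- NULL
  structure(df, genome_id = genome_id, taxon = taxon,
            class = c("genome_table", "data.frame"))
}

#' @export
print.genome_table <- function(x, ...) {
  cat("genome_table '", attr(x, "genome_id"), "': ",
      sum(x$type == "CDS"), " CDS on ", length(unique(x$contig_id)),
      " contig(s)\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Read prophage (or other) intervals from BED or TSV
#'
#' BED is 0-based half-open and converted on read; TSV is taken as 1-based
#' inclusive with columns contig, start, end and optional label, source.
#' All intervals are returned 1-based inclusive.
#'
#' @param path interval file.
#' @param dialect `"bed"` or `"tsv"`.
#' @param default_label label applied when the file carries none.
#' @return data.frame `contig_id`, `start`, `end`, `label`, `source`.
#' @export
read_intervals <- function(path, dialect = c("bed", "tsv"),
                           default_label = "prophage") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty interval file: ", path)
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), label = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\\s+")
  out <- data.frame(
    contig_id = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 2)),
    end   = as.integer(vapply(parts, `[`, "", 3)),
    label = vapply(parts, function(p) if (length(p) >= 4) p[4] else default_label, ""),
    source = basename(path),
    stringsAsFactors = FALSE)
  if (dialect == "bed") out$start <- out$start + 1L
  if (any(is.na(out$start) | is.na(out$end)))
    stop("validation error: non-numeric interval coordinates in ", path)
  if (any(out$start < 1L) || any(out$start > out$end))
    stop("validation error: bad interval coordinates after normalization in ", path)
  out
}

#' Read an MGE gene-category table
#'
#' Two-column TSV mapping gene_id to a mobile-genetic-element category
#' (integrase, transposase, RM_system, TA_system, phage_gene, other_MGE).
#'
#' @param path TSV file; lines starting with '#' ignored.
#' @param table optional `genome_table`; when given, every gene_id must
#'   resolve into it.
#' @return data.frame `gene_id`, `category`.
#' @export
read_mge_table <- function(path, table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("gene_id", "category"),
                   colClasses = "character", blank.lines.skip = TRUE)
  ok <- c("integrase", "transposase", "RM_system", "TA_system",
          "phage_gene", "other_MGE")
  bad <- setdiff(unique(df$category), ok)
  if (length(bad)) stop("validation error: unknown MGE category: ",
                        paste(bad, collapse = ", "))
  if (!is.null(table)) {
    missing <- setdiff(df$gene_id, table$gene_id)
    if (length(missing)) stop("validation error: MGE gene_id not in genome table: ",
                              paste(missing, collapse = ", "))
  }
  df
}

#' Neighboring genes by contig index
#'
#' Up to `k` CDS genes on each side of the query gene (by per-contig CDS
#' index), excluding the query; truncated at contig ends, no wraparound.
#'
#' @param table a `genome_table`.
#' @param gene_id query gene.
#' @param k gene count per side (>= 0).
#' @export
neighbors <- function(table, gene_id, k) {
  stopifnot(k >= 0)
  row <- table[table$gene_id == gene_id, , drop = FALSE]
  if (!nrow(row)) stop("lookup error: unknown gene_id '", gene_id, "'")
  if (is.na(row$index)) stop("gene '", gene_id, "' is not a CDS feature")
  if (k == 0) return(table[0, , drop = FALSE])
  cds <- table[table$contig_id == row$contig_id & !is.na(table$index), , drop = FALSE]
  keep <- abs(cds$index - row$index) <= k & cds$index != row$index
  cds[keep, , drop = FALSE]
}

#' Intergenic distance between two genes in bp
#'
#' Zero when the gene intervals overlap or abut; otherwise the gap between
#' the nearer boundaries.
#'
#' @param a,b single-row gene records (data.frames with `contig_id`,
#'   `start`, `end`).
#' @export
intergenic_distance_bp <- function(a, b) {
  if (a$contig_id != b$contig_id)
    stop("domain error: genes on different contigs")
  gap <- max(a$start, b$start) - min(a$end, b$end) - 1L
  max(0L, gap)
}

#' Write a result table to TSV (or authentic clusters to GFF3)
#'
#' TSV output has a deterministic column order and is stably sorted by
#' genome, contig and start when those columns exist, so identical inputs
#' give byte-identical files and tables round-trip through
#' [read_results()].
#'
#' @param records data.frame of results.
#' @param path output file.
#' @param format `"tsv"` or `"gff3"` (GFF3 export needs cluster span
#'   columns `contig_id`, `start`, `end`, `strand`, `cluster_id`).
#' @export
write_results <- function(records, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  sortcols <- intersect(c("genome_id", "contig_id", "start"), names(records))
  if (length(sortcols) && nrow(records))
    records <- records[do.call(order, records[sortcols]), , drop = FALSE]
  if (format == "tsv") {
    ok <- tryCatch({
      write.table(records, path, sep = "\t", quote = FALSE,
                  row.names = FALSE, na = "NA")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("I/O error: cannot write ", path)
  } else {
    need <- c("cluster_id", "contig_id", "start", "end", "strand")
    miss <- setdiff(need, names(records))
    if (length(miss)) stop("GFF3 export needs columns: ", paste(miss, collapse = ", "))
    gff <- c("##gff-version 3",
             if (nrow(records)) sprintf(
               "%s\tkkpminer\tKKP_cluster\t%d\t%d\t.\t%s\t.\tID=%s",
               records$contig_id, records$start, records$end,
               records$strand, records$cluster_id))
    writeLines(gff, path)
  }
  invisible(path)
}

#' Read a result TSV written by [write_results()]
#'
#' Columns are type-converted conservatively so that empty character
#' fields survive the round trip (they are not collapsed to NA).
#'
#' @param path TSV file with header.
#' @export
read_results <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                   stringsAsFactors = FALSE, check.names = FALSE, quote = "",
                   na.strings = character(0))
  for (nm in names(df)) {
    x <- df[[nm]]
    isna <- x == "NA"
    body <- x[!isna & x != ""]
    v <- if (!length(body)) {
      x
    } else if (all(body %in% c("TRUE", "FALSE"))) {
      as.logical(x)
    } else if (all(grepl("^-?\\d+$", body))) {
      suppressWarnings(as.integer(x))
    } else if (all(grepl("^[-+]?(\\d+\\.?\\d*|\\.\\d+)([eE][-+]?\\d+)?$", body) |
                   body %in% c("Inf", "-Inf", "NaN"))) {
      suppressWarnings(as.numeric(x))
    } else x
    if (is.character(v)) v[isna] <- NA_character_
    df[[nm]] <- v
  }
  df
}
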