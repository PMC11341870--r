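#' Write a synthetic dataset to disk in the dialects the readers consume
#'
#' Per genome: `<id>.gff3`, `<id>.fna` (when DNA was generated),
#' `<id>.domtbl` (HMMER3 domtblout dialect, gene in the target column),
#' `<id>_prophage.bed` (0-based half-open), `<id>_mge.tsv`,
#' `<id>_proteins.faa`; plus one `truth.tsv`. Output is byte-identical
#' for identical datasets.
#'
#' @param ds dataset from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in ds$genomes) {
    gid <- g$genome_id
    .write_gff3(g$table, file.path(dir, paste0(gid, ".gff3")))
    .write_domtbl(g$hits, file.path(dir, paste0(gid, ".domtbl")))
    iv <- g$intervals
    bed <- if (nrow(iv)) sprintf("%s\t%d\t%d\t%s", iv$contig_id,
                                 iv$start - 1L, iv$end, iv$label) else character(0)
    writeLines(bed, file.path(dir, paste0(gid, "_prophage.bed")))
    mge <- if (nrow(g$mge)) sprintf("%s\t%s", g$mge$gene_id, g$mge$category)
           else character(0)
    writeLines(mge, file.path(dir, paste0(gid, "_mge.tsv")))
    if (length(g$proteins))
      writeLines(as.vector(rbind(paste0(">", names(g$proteins)),
                                 unname(g$proteins))),
                 file.path(dir, paste0(gid, "_proteins.faa")))
    if (!is.null(g$dna))
      writeLines(c(paste0(">", names(g$dna)), .wrap60(g$dna)),
                 file.path(dir, paste0(gid, ".fna")))
  }
  write_results(ds$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

.wrap60 <- function(s) {
  n <- nchar(s)
  substring(s, seq(1, n, 60), pmin(seq(60, n + 59, 60), n))
}

.write_gff3 <- function(table, path) {
  df <- as.data.frame(table)
  attrs <- sprintf("ID=%s;product=%s", df$gene_id, df$product)
  lines <- c("##gff-version 3",
             sprintf("%s\tkkpminer_synth\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                     df$contig_id, df$type, df$start, df$end, df$strand,
                     ifelse(df$type == "CDS", "0", "."), attrs))
  writeLines(lines, path)
}

.write_domtbl <- function(hits, path) {
  hdr <- c("# synthetic per-domain hits (HMMER3 domtblout dialect)",
           "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target")
  if (!nrow(hits)) { writeLines(hdr, path); return(invisible(path)) }
  qlen <- hits$ali_to - hits$ali_from + 1L
  tlen <- ifelse(is.na(hits$tlen), hits$ali_to + 10L, hits$tlen)
  lines <- sprintf(
    "%-20s %-10s %5d %-20s %-10s %5d %9s %6s %5.1f %3d %3d %9s %9s %6s %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
    hits$gene_id, "-", tlen, hits$name, hits$accession, qlen,
    formatC(hits$i_evalue, format = "e", digits = 1),
    formatC(hits$bitscore, format = "f", digits = 1), 0, 1L, 1L,
    formatC(hits$i_evalue, format = "e", digits = 1),
    formatC(hits$i_evalue, format = "e", digits = 1),
    formatC(hits$bitscore, format = "f", digits = 1), 0,
    1L, qlen, hits$ali_from, hits$ali_to,
    pmax(1L, hits$ali_from - 2L), pmin(tlen, hits$ali_to + 2L), 0.95)
  writeLines(c(hdr, lines), path)
}

#' Load a dataset directory written by [write_dataset()]
#'
#' Reads every genome back through the package's own readers (GFF3,
#' domtblout, BED, MGE TSV, FASTA) into the in-memory dataset layout.
#'
#' @param dir dataset directory.
#' @return list with `genomes` and `truth` as in [generate_dataset()].
#' @export
load_dataset <- function(dir) {
  gffs <- sort(list.files(dir, pattern = "\\.gff3$", full.names = TRUE))
  if (!length(gffs)) stop("no .gff3 genomes under ", dir)
  genomes <- list()
  for (gf in gffs) {
    gid <- sub("\\.gff3$", "", basename(gf))
    stem <- file.path(dir, gid)
    tab <- read_gene_table(gf, genome_id = gid, format = "gff3")
    hits <- read_domain_hits(paste0(stem, ".domtbl"), gene_in = "target")
    bed <- paste0(stem, "_prophage.bed")
    ivs <- if (file.exists(bed) && file.size(bed) > 0)
      read_intervals(bed, dialect = "bed") else
      data.frame(contig_id = character(), start = integer(), end = integer(),
                 label = character(), source = character(),
                 stringsAsFactors = FALSE)
    mgef <- paste0(stem, "_mge.tsv")
    mge <- if (file.exists(mgef) && file.size(mgef) > 0)
      read_mge_table(mgef, table = tab) else
      data.frame(gene_id = character(), category = character(),
                 stringsAsFactors = FALSE)
    prot <- character(0)
    faa <- paste0(stem, "_proteins.faa")
    if (file.exists(faa) && file.size(faa) > 0) {
      aa <- Biostrings::readAAStringSet(faa)
      prot <- setNames(as.character(aa), names(aa))
    }
    dna <- NULL
    fna <- paste0(stem, ".fna")
    if (file.exists(fna)) {
      d <- Biostrings::readDNAStringSet(fna)
      dna <- setNames(as.character(d), sub("\\s.*", "", names(d)))
    }
    genomes[[gid]] <- list(genome_id = gid, table = tab, hits = hits,
                           intervals = ivs, mge = mge, dna = dna,
                           proteins = prot)
  }
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) read_results(truth_path) else NULL
  list(genomes = genomes, truth = truth)
}
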