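#' Extract a genomic region from a FASTA sequence set
#'
#' @param fasta a [Biostrings::DNAStringSet] or FASTA file path.
#' @param contig sequence name.
#' @param start,end 1-based inclusive coordinates within the contig.
#' @param strand `"+"` or `"-"` (minus returns the reverse complement).
#' @return character DNA sequence.
#' @export
extract_region <- function(fasta, contig, start, end, strand = "+") {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    fasta <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*", "", names(fasta))
  hit <- match(contig, nm)
  if (is.na(hit)) stop("range error: contig '", contig, "' not in FASTA")
  len <- Biostrings::width(fasta)[hit]
  if (start < 1 || end > len || start > end)
    stop("range error: ", start, "..", end, " outside contig of length ", len)
  s <- Biostrings::subseq(fasta[[hit]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

.dna_submat <- function(match = 1, mismatch = -2) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0    # ambiguous base: neutral
  m
}

#' Global affine-gap alignment of two DNA sequences
#'
#' Optimal global (Needleman-Wunsch/Gotoh) alignment under
#' match/mismatch scoring with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`). For regions longer than `band_threshold`
#' the dynamic program is restricted to a diagonal band of half-width
#' `band`, which is exact whenever the optimal path stays in band. Ties
#' are broken deterministically: match/mismatch over gap, gap in `b` over
#' gap in `a`, gap extension over gap opening.
#'
#' @param a,b DNA sequences (character).
#' @param match,mismatch,gap_open,gap_extend scoring (defaults +1, -2,
#'   -5, -1).
#' @param band half-width of the banded DP, or `NULL` for full DP; the
#'   default bands sequences longer than `band_threshold` at 256.
#' @param band_threshold length above which banding engages.
#' @return an `alignment_result`: list with `score`, `columns`, `matches`,
#'   `mismatches`, `gap_columns`, `percent_identity`, `gap_runs`
#'   (data.frame), `aligned_a`, `aligned_b`.
#' @export
global_align_affine <- function(a, b, match = 1, mismatch = -2,
                                gap_open = -5, gap_extend = -1,
                                band = NULL, band_threshold = 5000) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  la <- nchar(a); lb <- nchar(b)
  if (is.null(band))
    band <- if (max(la, lb) > band_threshold)
      max(256L, abs(la - lb)) else max(la, lb)
  if (band < abs(la - lb))
    stop("config error: band (", band, ") < length difference (",
         abs(la - lb), ")")
  aln <- align_affine_cpp(a, b, .dna_submat(match, mismatch),
                          gap_open, gap_extend, as.integer(band))
  .alignment_result(aln, a, b)
}

.alignment_result <- function(aln, a, b) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  gap_a <- ca == "-"; gap_b <- cb == "-"
  matches <- sum(!gap_a & !gap_b & ca == cb)
  mismatches <- sum(!gap_a & !gap_b & ca != cb)
  gap_columns <- sum(gap_a | gap_b)
  res <- list(score = aln$score, columns = length(ca), matches = matches,
              mismatches = mismatches, gap_columns = gap_columns,
              percent_identity = 100 * matches / length(ca),
              gap_runs = .gap_runs(ca, cb, a, b),
              aligned_a = aln$aligned_a, aligned_b = aln$aligned_b)
  structure(res, class = "alignment_result")
}

# Maximal gap runs per sequence with the 10-mer flanking the gap site on
# the ungapped sequence that carries the gap.
.gap_runs <- function(ca, cb, a, b) {
  one_seq <- function(gaps, which_seq, seq_str, other_cols) {
    if (!any(gaps)) return(NULL)
    r <- rle(gaps)
    col_end <- cumsum(r$lengths)
    col_start <- col_end - r$lengths + 1L
    runs <- which(r$values)
    # ungapped position in the carrier just before each run
    pos_before <- vapply(col_start[runs], function(cs)
      sum(!gaps[seq_len(cs - 1L)]), 0L)
    flank <- vapply(pos_before, function(p) {
      lo <- max(1L, p - 9L)
      if (p == 0) "" else substr(seq_str, lo, p)
    }, "")
    data.frame(gap_in = which_seq, start_col = col_start[runs],
               length = r$lengths[runs], flank_10mer = flank,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_seq(ca == "-", "a", a), one_seq(cb == "-", "b", b))
  if (is.null(out))
    out <- data.frame(gap_in = character(), start_col = integer(),
                      length = integer(), flank_10mer = character(),
                      stringsAsFactors = FALSE)
  out[order(out$start_col, out$gap_in), , drop = FALSE]
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(paste0("alignment: %d columns, %d matches, %d mismatches, ",
                     "%d gap columns\nidentity %.2f%%, score %g, %d gap run(s)\n"),
              x$columns, x$matches, x$mismatches, x$gap_columns,
              x$percent_identity, x$score, nrow(x$gap_runs)))
  if (nrow(x$gap_runs)) print(x$gap_runs)
  invisible(x)
}

#' Extract, align and report two genomic regions
#'
#' End-to-end comparison used for prophage-region claims: extracts both
#' regions, aligns them globally, and reports percent identity together
#' with the inventory of internal indel runs. With `internal_only = TRUE`
#' (default) gap runs touching either alignment end are dropped from the
#' report (region-boundary slop), though they still count in the identity.
#'
#' @param fastaA,fastaB FASTA paths or DNAStringSets.
#' @param regionA,regionB lists `list(contig =, start =, end =, strand =)`.
#' @param internal_only drop terminal gap runs from the report.
#' @param ... scoring arguments passed to [global_align_affine()].
#' @return `alignment_result` with an extra `report` data.frame of the
#'   (internal) gap runs.
#' @export
compare_regions <- function(fastaA, regionA, fastaB, regionB,
                            internal_only = TRUE, ...) {
  a <- do.call(extract_region, c(list(fastaA), regionA))
  b <- do.call(extract_region, c(list(fastaB), regionB))
  res <- global_align_affine(a, b, ...)
  runs <- res$gap_runs
  if (internal_only && nrow(runs)) {
    terminal <- runs$start_col == 1L |
      (runs$start_col + runs$length - 1L) == res$columns
    runs <- runs[!terminal, , drop = FALSE]
  }
  res$report <- runs
  res
}
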