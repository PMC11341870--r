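#' Percent identity of two proteins under global affine-gap alignment
#'
#' Aligns with BLOSUM62 (gap open -11, extend -1) via the package's exact
#' Gotoh aligner and reports identical aligned residue pairs as a
#' percentage of either all alignment columns (default; gap columns count
#' against identity) or the shorter sequence length.
#'
#' @param a,b protein sequences (20-letter alphabet plus X).
#' @param denominator `"columns"` or `"shorter"`.
#' @param gap_open,gap_extend affine gap penalties (negative).
#' @return percent identity in [0, 100].
#' @export
pairwise_protein_identity <- function(a, b, denominator = c("columns", "shorter"),
                                      gap_open = -11, gap_extend = -1) {
  denominator <- match.arg(denominator)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("domain error: empty protein sequence")
  aln <- align_affine_cpp(a, b, .blosum62(), gap_open, gap_extend,
                          band = max(nchar(a), nchar(b)))
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  matches <- sum(ca == cb & ca != "-")
  denom <- if (denominator == "columns") length(ca) else min(nchar(a), nchar(b))
  100 * matches / denom
}

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    keep <- intersect(rownames(m), c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"))
    .blosum62_cache$m <- m[keep, keep]
  }
  .blosum62_cache$m
}

#' Pairwise identity matrix over KKP clusters
#'
#' Computes the three component-wise identities (pfkA vs pfkA, pfkB vs
#' pfkB, pfpC vs pfpC) for every cluster pair and combines them by mean
#' (default) or min. The combined matrix is symmetric with a diagonal of
#' exactly 100.
#'
#' @param proteins data.frame with columns `cluster_id`, `pfkA`, `pfkB`,
#'   `pfpC` (amino-acid strings).
#' @param combine `"mean"` or `"min"` of the three component identities.
#' @inheritParams pairwise_protein_identity
#' @return combined identity matrix (cluster_id dimnames) with the three
#'   component matrices in attribute `components`.
#' @export
cluster_identity_matrix <- function(proteins, combine = c("mean", "min"),
                                    denominator = c("columns", "shorter")) {
  combine <- match.arg(combine)
  denominator <- match.arg(denominator)
  ids <- proteins$cluster_id
  n <- length(ids)
  comp <- lapply(c(pfkA = "pfkA", pfkB = "pfkB", pfpC = "pfpC"), function(col) {
    m <- diag(100, n)
    dimnames(m) <- list(ids, ids)
    if (n >= 2)
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- pairwise_protein_identity(
          proteins[[col]][i], proteins[[col]][j], denominator = denominator)
      }
    m
  })
  m <- switch(combine,
              mean = (comp$pfkA + comp$pfkB + comp$pfpC) / 3,
              min = pmin(comp$pfkA, comp$pfkB, comp$pfpC))
  diag(m) <- 100
  attr(m, "components") <- comp
  m
}

#' Group clusters into families by single-linkage identity
#'
#' Families are the connected components of the graph with an edge
#' wherever the combined identity strictly exceeds `threshold` (default
#' 90, matching the >90 percent amino-acid identity convention). Family
#' numbering is deterministic by smallest member id; the representative is
#' the member with the longest total protein length (ties by id).
#'
#' @param mat combined identity matrix from [cluster_identity_matrix()].
#' @param threshold identity threshold (edges strictly above it).
#' @param total_aa optional named vector cluster_id -> total protein
#'   length, used to pick representatives.
#' @return data.frame `cluster_id`, `family_id`, `representative`.
#' @export
cluster_families <- function(mat, threshold = 90, total_aa = NULL) {
  ids <- rownames(mat)
  adj <- (mat > threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  fam_key <- vapply(split(ids, comp), min, "")        # smallest member id
  ord <- rank(fam_key)                                 # deterministic numbering
  fam_id <- sprintf("F%03d", ord[as.character(comp)])
  rep_of <- vapply(split(ids, fam_id), function(members) {
    if (is.null(total_aa)) return(min(members))
    len <- total_aa[members]
    len[is.na(len)] <- -Inf
    members[order(-len, members)][1]
  }, "")
  out <- data.frame(cluster_id = ids, family_id = fam_id,
                    representative = unname(rep_of[fam_id]),
                    stringsAsFactors = FALSE)
  out[order(out$family_id, out$cluster_id), , drop = FALSE]
}

#' Annotate a kinase tree with outgroup rooting and clade membership
#'
#' Reroots the tree on the smallest clade containing all outgroup leaves,
#' then extends each reference-labelled clade to its maximal subtree
#' containing no other clade's reference leaves and no outgroup leaf.
#' Leaves outside every clade are `unassigned`.
#'
#' @param tree an [ape::phylo] object or a Newick file path / string.
#' @param outgroup_leaves leaf labels of the outgroup (e.g. the three
#'   eukaryotic kinases used to root a PfkA tree).
#' @param clade_reference_leaves named list, clade label -> character
#'   vector of reference leaf labels (e.g. `list(I = ..., II = ..., III =
#'   ...)`).
#' @return data.frame `leaf`, `clade` (clade labels, `"outgroup"`,
#'   `"unassigned"`); the rerooted tree is in attribute `tree`.
#' @export
annotate_tree <- function(tree, outgroup_leaves, clade_reference_leaves = list()) {
  tree <- .as_phylo(tree)
  tips <- tree$tip.label
  miss <- setdiff(outgroup_leaves, tips)
  if (length(miss))
    stop("lookup error: outgroup leaf absent from tree: ",
         paste(miss, collapse = ", "))
  for (cl in names(clade_reference_leaves)) {
    miss <- setdiff(clade_reference_leaves[[cl]], tips)
    if (length(miss))
      stop("lookup error: clade ", cl, " reference leaf absent from tree: ",
           paste(miss, collapse = ", "))
  }
  if (all(tips %in% outgroup_leaves)) {
    out <- data.frame(leaf = tips, clade = "outgroup", stringsAsFactors = FALSE)
    attr(out, "tree") <- tree
    return(out)
  }
  # smallest clade containing all outgroup leaves, in the input orientation
  og_clade <- if (length(outgroup_leaves) == 1) outgroup_leaves else {
    node <- ape::getMRCA(tree, outgroup_leaves)
    .tips_under(tree, node)
  }
  if (all(tips %in% og_clade))
    stop("outgroup spans the whole tree; cannot reroot")
  tree <- ape::root(tree, outgroup = og_clade, resolve.root = TRUE)
  tips <- tree$tip.label
  assignment <- setNames(rep("unassigned", length(tips)), tips)
  assignment[tips %in% og_clade] <- "outgroup"
  forbidden_of <- lapply(names(clade_reference_leaves), function(cl)
    c(og_clade, unlist(clade_reference_leaves[setdiff(names(clade_reference_leaves), cl)],
                       use.names = FALSE)))
  names(forbidden_of) <- names(clade_reference_leaves)
  for (cl in names(clade_reference_leaves)) {
    refs <- clade_reference_leaves[[cl]]
    forbidden <- forbidden_of[[cl]]
    node <- if (length(refs) == 1) match(refs, tips) else ape::getMRCA(tree, refs)
    bad <- intersect(.tips_under(tree, node), forbidden)
    if (length(bad))
      stop("monophyly error: clade ", cl,
           " references nest with other references/outgroup: ",
           paste(bad, collapse = ", "))
    repeat {                            # extend to the maximal clean subtree
      parent <- .parent_node(tree, node)
      if (is.na(parent)) break
      cand <- .tips_under(tree, parent)
      if (length(intersect(cand, forbidden))) break
      node <- parent
    }
    here <- .tips_under(tree, node)
    assignment[here] <- cl
  }
  out <- data.frame(leaf = tips, clade = unname(assignment[tips]),
                    stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  out
}

.as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, Newick file or Newick string")
}

.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

.parent_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (node == root) return(NA_integer_)
  tree$edge[tree$edge[, 2] == node, 1][1]
}

#' Write an iTOL-compatible colour-strip annotation of clade assignments
#'
#' @param assignment output of [annotate_tree()].
#' @param path output file.
#' @param colors optional named vector clade -> hex colour.
#' @export
write_itol_annotation <- function(assignment, path, colors = NULL) {
  clades <- sort(unique(assignment$clade))
  if (is.null(colors)) {
    pal <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e", "#666666")
    colors <- setNames(rep_len(pal, length(clades)), clades)
  }
  hdr <- c("DATASET_COLORSTRIP", "SEPARATOR TAB", "DATASET_LABEL\tKKP clades",
           "COLOR\t#000000", "DATA")
  rows <- sprintf("%s\t%s\t%s", assignment$leaf,
                  unname(colors[assignment$clade]), assignment$clade)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
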