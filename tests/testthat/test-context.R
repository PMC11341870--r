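# a minimal cluster row for context tests
mk_cluster <- function(start, end, idx = c(10L, 11L, 12L), contig = "c1") {
  data.frame(cluster_id = "t:c1:10", genome_id = "t", contig_id = contig,
             start = start, end = end, idx1 = idx[1], idx2 = idx[2],
             idx3 = idx[3], gene1 = "gA", gene2 = "gB", gene3 = "gC",
             stringsAsFactors = FALSE)
}

iv <- function(s, e, contig = "c1") {
  data.frame(contig_id = contig, start = s, end = e, label = "prophage",
             source = "t", stringsAsFactors = FALSE)
}

test_that("prophage overlap counts full containment and single-bp overlap", {
  cl <- mk_cluster(10000, 13500)
  expect_equal(nrow(overlaps_prophage(cl, iv(5000, 40000))), 1)
  expect_equal(nrow(overlaps_prophage(cl, iv(13500, 20000))), 1)  # 1 bp counts
  expect_equal(nrow(overlaps_prophage(cl, iv(13501, 20000))), 0)
  expect_equal(nrow(overlaps_prophage(cl, iv(5000, 40000, contig = "c2"))), 0)
  # containment option demands the whole span inside the interval
  expect_equal(nrow(overlaps_prophage(cl, iv(13500, 20000), containment = TRUE)), 0)
  expect_equal(nrow(overlaps_prophage(cl, iv(9000, 14000), containment = TRUE)), 1)
})

test_that("P4 rescue finds Psu genes within the gene window only", {
  roles <- rep("other", 40)
  roles[15:17] <- c("PP2C", "Pkinase_CSD", "Pkinase_FHA")
  g <- toy_genome(roles, rep("+", 40))
  cl <- classify_clusters(g$table, g$archs)[1, ]
  with_psu <- function(at) {
    a <- g$archs; a$role[at] <- "Psu"; a
  }
  ev <- rescue_p4(cl, g$table, with_psu(25), window_genes = 20)  # 8 genes away
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance_genes, 8L)
  expect_equal(nrow(rescue_p4(cl, g$table, g$archs)), 0)         # no Psu at all
  # outside the window
  roles2 <- rep("other", 60); roles2[3:5] <- c("PP2C", "Pkinase_CSD", "Pkinase_FHA")
  g2 <- toy_genome(roles2, rep("+", 60))
  cl2 <- classify_clusters(g2$table, g2$archs)[1, ]
  a2 <- g2$archs; a2$role[35] <- "Psu"                           # 30 genes away
  expect_equal(nrow(rescue_p4(cl2, g2$table, a2)), 0)
})

test_that("MGE adjacency uses OR semantics over the gene and bp arms", {
  # genes are ~1052 bp apart here, so gene distance d ~ d*1052 bp
  roles <- rep("other", 40); roles[15:17] <- c("PP2C", "Pkinase_CSD", "Pkinase_FHA")
  g <- toy_genome(roles, rep("+", 40))
  cl <- classify_clusters(g$table, g$archs)[1, ]
  mge_at <- function(i, cat = "transposase")
    data.frame(gene_id = g$table$gene_id[i], category = cat,
               stringsAsFactors = FALSE)
  # both arms pass (2 genes, ~2 kb)
  expect_equal(nrow(mge_linked(cl, g$table, mge_at(13))), 1)
  # gene arm fails, bp arm fails (far)
  expect_equal(nrow(mge_linked(cl, g$table, mge_at(28))), 0)
  # gene arm fails (7 genes) but bp arm passes with a wide bp window
  expect_equal(nrow(mge_linked(cl, g$table, mge_at(24),
                               window_genes = 5, window_bp = 8000)), 1)
  # gene arm passes though the bp arm fails under a tiny bp window
  expect_equal(nrow(mge_linked(cl, g$table, mge_at(13),
                               window_genes = 5, window_bp = 10)), 1)
  # a cluster gene listed in the MGE table is not its own evidence
  own <- data.frame(gene_id = cl$gene1, category = "phage_gene",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(mge_linked(cl, g$table, own)), 0)
})

test_that("category precedence is prophage > P4 > MGE > other", {
  cl <- mk_cluster(10000, 13500)
  ev_pro <- overlaps_prophage(cl, iv(5000, 40000))
  ev_psu <- data.frame(kind = "psu_gene", identifier = "p", distance_genes = 3L,
                       distance_bp = 300L, stringsAsFactors = FALSE)
  ev_mge <- data.frame(kind = "mge_gene", identifier = "m", distance_genes = 2L,
                       distance_bp = 200L, stringsAsFactors = FALSE)
  none <- ev_pro[0, ]
  # exhaustive precedence table over presence/absence of the three kinds
  for (has_pro in c(TRUE, FALSE)) for (has_psu in c(TRUE, FALSE))
    for (has_mge in c(TRUE, FALSE)) {
      ev <- rbind(if (has_pro) ev_pro else none,
                  if (has_psu) ev_psu else none,
                  if (has_mge) ev_mge else none)
      want <- if (has_pro) "prophage" else if (has_psu) "P4_prophage"
              else if (has_mge) "MGE_linked" else "other"
      expect_equal(assign_context(cl, ev)$category, want)
    }
})

test_that("context summary reports fractions and the non-prophage subtotal", {
  ann <- data.frame(
    cluster_id = sprintf("c%02d", 1:100), genome_id = "g",
    category = c(rep("prophage", 90), rep("MGE_linked", 7), rep("other", 3)),
    stringsAsFactors = FALSE)
  s <- summarize_contexts(ann)
  all_rows <- s[s$taxon == "all", ]
  expect_equal(all_rows$fraction[all_rows$category == "prophage"], 0.90)
  expect_equal(sum(all_rows$fraction), 1, tolerance = 1e-12)
  expect_equal(attr(s, "mge_among_nonprophage"), "7 out of 10")
  one <- summarize_contexts(ann[1, , drop = FALSE])
  expect_equal(one$fraction[one$category == "prophage" & one$taxon == "all"], 1)
})

test_that("generator context categories are recovered perfectly", {
  hits <- 0; total <- 0
  for (seed in 1:10) {
    ds <- generate_dataset(synth_config(seed = seed, n_genomes = 2,
                                        n_authentic = 2,
                                        genes_per_genome = 140,
                                        emit_dna = FALSE))
    for (g in ds$genomes) {
      archs <- archs_of(g)
      cl <- classify_clusters(g$table, archs)
      ann <- annotate_contexts(cl[cl$status == "authentic", ], g$table, archs,
                               g$intervals, g$mge)
      tru <- ds$truth[ds$truth$genome_id == g$genome_id &
                        ds$truth$class == "authentic", ]
      for (i in seq_len(nrow(tru))) {
        cid <- sprintf("%s:%s:%d", tru$genome_id[i], tru$contig_id[i],
                       tru$idx1[i])
        total <- total + 1
        if (ann$category[ann$cluster_id == cid] == tru$context[i])
          hits <- hits + 1
      }
    }
  }
  expect_gt(total, 20)
  expect_equal(hits, total)
})

test_that("growing the MGE windows never removes linkage", {
  roles <- rep("other", 40); roles[15:17] <- c("PP2C", "Pkinase_CSD", "Pkinase_FHA")
  g <- toy_genome(roles, rep("+", 40))
  cl <- classify_clusters(g$table, g$archs)[1, ]
  mge <- data.frame(gene_id = g$table$gene_id[21], category = "integrase",
                    stringsAsFactors = FALSE)
  linked <- vapply(c(2, 4, 6, 10), function(w)
    nrow(mge_linked(cl, g$table, mge, window_genes = w, window_bp = 1)) > 0,
    NA)
  expect_true(all(diff(linked) >= 0))
})
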