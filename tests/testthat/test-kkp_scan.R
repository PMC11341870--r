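test_that("constructed role patterns match or fail as designed", {
  # consecutive P-K-K on plus strand: one candidate
  g <- toy_genome(c("other", "PP2C", "Pkinase_CSD", "Pkinase_FHA", "other"),
                  rep("+", 5))
  cand <- scan_triplets(g$table, g$archs)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$pattern_matched, "PKK")
  # middle gene on the minus strand among plus genes: orientation filter
  g2 <- toy_genome(c("PP2C", "Pkinase_CSD", "Pkinase_FHA"),
                   c("+", "-", "+"))
  expect_equal(nrow(scan_triplets(g2$table, g2$archs)), 0)
  # minus-strand cluster: coordinate order K-K-P reads P-K-K in
  # transcription order
  g3 <- toy_genome(c("Pkinase_FHA", "Pkinase_CSD", "PP2C"), rep("-", 3))
  cand3 <- scan_triplets(g3$table, g3$archs)
  expect_equal(nrow(cand3), 1)
  expect_equal(cand3$role1, "PP2C")
  # an intervening gene breaks adjacency
  g4 <- toy_genome(c("PP2C", "Pkinase_CSD", "other", "Pkinase_FHA"),
                   rep("+", 4))
  expect_equal(nrow(scan_triplets(g4$table, g4$archs)), 0)
  # unless the intervening-gene option is on
  expect_equal(nrow(scan_triplets(g4$table, g4$archs,
                                  allow_intervening = TRUE)), 1)
})

test_that("pattern configuration restricts the accepted triplet order", {
  kkp <- toy_genome(c("Pkinase_CSD", "Pkinase_FHA", "PP2C"), rep("+", 3))
  expect_equal(nrow(scan_triplets(kkp$table, kkp$archs, pattern = "PKK")), 0)
  expect_equal(nrow(scan_triplets(kkp$table, kkp$archs, pattern = "KKP")), 1)
  expect_equal(scan_triplets(kkp$table, kkp$archs)$pattern_matched, "KKP")
})

test_that("missing architectures are a lookup error naming the gene", {
  g <- toy_genome(c("PP2C", "Pkinase_CSD", "Pkinase_FHA"), rep("+", 3))
  expect_error(scan_triplets(g$table, g$archs[-2, ]), "toy_g02")
})

test_that("length filter uses strict bounds on all three genes", {
  g <- toy_genome(c("PP2C", "Pkinase_CSD", "Pkinase_FHA"), rep("+", 3),
                  lengths = c(1000L, 1100L, 1200L))
  cand <- scan_triplets(g$table, g$archs)
  expect_equal(apply_length_filter(cand[1, ])$reasons, character(0))
  # exactly 900 fails the strict > 900 rule
  g2 <- toy_genome(c("PP2C", "Pkinase_CSD", "Pkinase_FHA"), rep("+", 3),
                   lengths = c(900L, 1100L, 1200L))
  r2 <- apply_length_filter(scan_triplets(g2$table, g2$archs)[1, ])
  expect_equal(r2$reasons, "LEN_SHORT")
  expect_equal(r2$length_pass, c(FALSE, TRUE, TRUE))
  # exactly 1300 fails the strict < 1300 rule
  g3 <- toy_genome(c("PP2C", "Pkinase_CSD", "Pkinase_FHA"), rep("+", 3),
                   lengths = c(1000L, 1300L, 1200L))
  expect_equal(apply_length_filter(scan_triplets(g3$table, g3$archs)[1, ])$reasons,
               "LEN_LONG")
  expect_error(apply_length_filter(cand[1, ], 1300, 900), "config error")
})

test_that("accessory-domain filter needs exactly one CSD and one FHA kinase", {
  mk <- function(k1, k2) {
    g <- toy_genome(c("PP2C", k1, k2), rep("+", 3))
    apply_architecture_filter(scan_triplets(g$table, g$archs)[1, ])
  }
  expect_true(mk("Pkinase_CSD", "Pkinase_FHA")$architecture_pass)
  expect_true(mk("Pkinase_FHA", "Pkinase_CSD")$architecture_pass)  # either position
  expect_equal(mk("Pkinase_plain", "Pkinase_FHA")$reasons, "NO_CSD")
  expect_equal(sort(mk("Pkinase_CSD", "Pkinase_CSD")$reasons),
               c("DUP_ACCESSORY", "NO_FHA"))
})

test_that("classified clusters equal the brute-force window oracle on 50 genomes", {
  mismatches <- 0
  for (seed in 1:10) {
    ds <- generate_dataset(synth_config(
      seed = seed, n_genomes = 5, genes_per_genome = 100, n_authentic = 1,
      decoys = c(LEN_OUT = 1), emit_dna = FALSE))
    for (g in ds$genomes) {
      archs <- archs_of(g)
      got <- cluster_keys(classify_clusters(g$table, archs))
      want <- oracle_keys(oracle_clusters(g$table, archs))
      if (!identical(got, want)) mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("reverse-complementing a genome yields mirrored clusters with identical statuses", {
  for (seed in c(2, 5)) {
    ds <- generate_dataset(synth_config(seed = seed, n_genomes = 2,
                                        n_authentic = 1,
                                        decoys = c(NO_FHA = 1),
                                        emit_dna = FALSE))
    for (g in ds$genomes) {
      archs <- archs_of(g)
      cl <- classify_clusters(g$table, archs)
      rc <- classify_clusters(mirror_table(g$table), archs)
      expect_equal(nrow(cl), nrow(rc))
      key <- function(x) sort(paste(
        apply(x[, c("gene1", "gene2", "gene3")], 1,
              function(r) paste(sort(r), collapse = "+")), x$status))
      expect_equal(key(cl), key(rc))
    }
  }
})

test_that("widening the length band never decreases the authentic count", {
  ds <- generate_dataset(synth_config(seed = 9, n_genomes = 3, n_authentic = 1,
                                      decoys = c(LEN_OUT = 1), emit_dna = FALSE))
  bands <- list(c(950, 1200), c(900, 1300), c(800, 1500), c(1, 1e6))
  counts <- vapply(bands, function(b) {
    sum(vapply(ds$genomes, function(g)
      sum(classify_clusters(g$table, archs_of(g),
                            kkp_config(min_bp = b[1], max_bp = b[2])
                            )$status == "authentic"), 0))
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("every candidate is authentic or carries at least one rejection reason", {
  ds <- generate_dataset(synth_config(
    seed = 13, n_genomes = 4, n_authentic = 1,
    decoys = c(LEN_OUT = 1, NO_CSD = 1), genes_per_genome = 140,
    emit_dna = FALSE))
  for (g in ds$genomes) {
    cl <- classify_clusters(g$table, archs_of(g))
    expect_true(all((cl$status == "authentic") == (cl$reasons == "")))
    expect_true(all(nzchar(cl$reasons[cl$status == "rejected"])))
  }
})

test_that("authentic fraction handles plain and empty cases", {
  cl <- data.frame(status = c(rep("authentic", 9), "rejected"))
  expect_equal(authentic_fraction(cl), 90.0)
  out <- authentic_fraction(cl[0, , drop = FALSE])
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
})
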