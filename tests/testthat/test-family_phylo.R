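AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
random_protein <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

test_that("protein identity matches hand-computable cases and is symmetric", {
  set.seed(101)
  p <- random_protein(100)
  expect_identical(pairwise_protein_identity(p, p), 100)
  q <- p
  at <- 37
  substr(q, at, at) <- setdiff(AA, substr(p, at, at))[1]
  expect_equal(pairwise_protein_identity(p, q), 99.0)
  for (i in 1:10) {
    a <- random_protein(sample(30:80, 1)); b <- random_protein(sample(30:80, 1))
    expect_equal(pairwise_protein_identity(a, b),
                 pairwise_protein_identity(b, a))
  }
  expect_error(pairwise_protein_identity("", "AC"), "empty")
})

test_that("protein alignment scores equal the exhaustive DP oracle on short pairs", {
  set.seed(202)
  sub <- kkpminer:::.blosum62()
  for (i in 1:60) {
    a <- random_protein(sample(2:6, 1)); b <- random_protein(sample(2:6, 1))
    got <- kkpminer:::align_affine_cpp(a, b, sub, -11, -1,
                                       band = max(nchar(a), nchar(b)))$score
    want <- oracle_affine_score(a, b, sub, -11, -1)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("the shorter-sequence denominator option lifts identity over columns", {
  a <- "MKVLAAGHWT"
  b <- paste0(a, "XXXXX")   # 5 trailing residues force end gaps
  cols <- pairwise_protein_identity(a, b, denominator = "columns")
  shrt <- pairwise_protein_identity(a, b, denominator = "shorter")
  expect_lt(cols, shrt)
  expect_equal(shrt, 100)
})

test_that("cluster identity matrix is symmetric with exact 100 diagonal", {
  set.seed(7)
  prot <- data.frame(cluster_id = c("A", "B", "C"),
                     pfkA = replicate(3, random_protein(60)),
                     pfkB = replicate(3, random_protein(60)),
                     pfpC = replicate(3, random_protein(60)),
                     stringsAsFactors = FALSE)
  m <- cluster_identity_matrix(prot)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_true(all(m >= 0 & m <= 100))
  comp <- attr(m, "components")
  expect_equal(unname(m["A", "B"]),
               unname((comp$pfkA["A", "B"] + comp$pfkB["A", "B"] +
                         comp$pfpC["A", "B"]) / 3))
})

test_that("families are single-linkage components over the identity graph", {
  ids <- c("A", "B", "C")
  m <- function(ab, bc, ac) {
    x <- diag(100, 3); dimnames(x) <- list(ids, ids)
    x["A", "B"] <- x["B", "A"] <- ab
    x["B", "C"] <- x["C", "B"] <- bc
    x["A", "C"] <- x["C", "A"] <- ac
    x
  }
  # all similar: one family
  f1 <- cluster_families(m(95, 95, 95))
  expect_equal(length(unique(f1$family_id)), 1)
  # dissimilar pair: two families
  f2 <- cluster_families(m(85, 0, 0)[1:2, 1:2])
  expect_equal(length(unique(f2$family_id)), 2)
  # chain A-B 92, B-C 92, A-C 80: single linkage joins all three
  chain <- m(92, 92, 80)
  f3 <- cluster_families(chain)
  expect_equal(length(unique(f3$family_id)), 1)
  # agrees with an independent union-find components oracle
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    x <- matrix(runif(n * n, 60, 100), n)
    x <- (x + t(x)) / 2; diag(x) <- 100
    dimnames(x) <- list(letters[1:n], letters[1:n])
    fam <- cluster_families(x, threshold = 90)
    adj <- x > 90; diag(adj) <- FALSE
    comp <- oracle_components(adj)
    # same partition: equal label co-membership matrices
    got <- outer(fam$family_id[match(letters[1:n], fam$cluster_id)],
                 fam$family_id[match(letters[1:n], fam$cluster_id)], "==")
    want <- outer(comp, comp, "==")
    expect_equal(got, want)
  }
})

test_that("threshold extremes give one family and all singletons", {
  set.seed(44)
  n <- 6
  x <- matrix(runif(n * n, 10, 99), n); x <- (x + t(x)) / 2; diag(x) <- 100
  dimnames(x) <- list(letters[1:n], letters[1:n])
  expect_equal(length(unique(cluster_families(x, threshold = 0)$family_id)), 1)
  expect_equal(length(unique(cluster_families(x, threshold = 100)$family_id)), n)
})

test_that("family representative is the longest member with ties by id", {
  ids <- c("A", "B")
  x <- matrix(c(100, 95, 95, 100), 2, dimnames = list(ids, ids))
  f <- cluster_families(x, total_aa = c(A = 900, B = 1200))
  expect_equal(unique(f$representative), "B")
  f2 <- cluster_families(x, total_aa = c(A = 900, B = 900))
  expect_equal(unique(f2$representative), "A")
})

test_that("tree annotation reroots on the outgroup and extends reference clades", {
  tr <- "((A:1,B:1):1,((C:1,D:1):1,(E:1,F:1):1):1,OG:3);"
  asn <- annotate_tree(tr, "OG", list(I = "A", II = "C", III = "E"))
  got <- setNames(asn$clade, asn$leaf)
  expect_equal(got[["B"]], "I")
  expect_equal(got[["D"]], "II")
  expect_equal(got[["F"]], "III")
  expect_equal(got[["OG"]], "outgroup")
  # rerooting preserves the leaf set
  expect_setequal(attr(asn, "tree")$tip.label, c(LETTERS[1:6], "OG"))
})

test_that("degenerate and erroneous tree inputs are handled", {
  only_og <- annotate_tree("(X:1,Y:1);", c("X", "Y"))
  expect_equal(unique(only_og$clade), "outgroup")
  tr <- "((A:1,B:1):1,(C:1,D:1):1,OG:2);"
  expect_error(annotate_tree(tr, "MISSING"), "lookup error")
  expect_error(annotate_tree(tr, "OG", list(I = "Z")), "lookup error")
  # nested references: clade II's reference inside clade I's span
  tr2 <- "(((A:1,B:1):1,C:1):1,D:1,OG:2);"
  expect_error(annotate_tree(tr2, "OG", list(I = c("A", "C"), II = "B")),
               "monophyly error")
})

test_that("rerooting keeps unrooted topology on random trees", {
  set.seed(55)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    og <- sample(tr$tip.label, 1)
    asn <- annotate_tree(tr, og)
    rerooted <- attr(asn, "tree")
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rerooted)), 0,
                 ignore_attr = TRUE)
  }
})
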