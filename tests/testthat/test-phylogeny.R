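test_that("multiple-alignment objects validate rows and build the mask", {
  msa <- as_multiple_alignment(c(a = "MKV-A", b = "MKVLA", c = "MRV-A"))
  expect_identical(msa$mask, c(1L, 2L, 3L, 5L))
  expect_error(as_multiple_alignment(c(a = "MK", b = "MKV")), "length")
  expect_error(as_multiple_alignment(c(a = "MK")), "two")
})

test_that("Poisson correction matches -ln(1-p) and a column-count oracle", {
  # identical rows: zero distance
  msa <- as_multiple_alignment(c(a = "MKVMKV", b = "MKVMKV"))
  expect_equal(poisson_distance(msa)["a", "b"], 0)
  # p = 0.1 over ten columns
  msa2 <- as_multiple_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"))
  expect_equal(poisson_distance(msa2)["a", "b"], 0.105360516, tolerance = 1e-8)
  # hand-count oracle over unmasked columns of random gapped alignments
  set.seed(12)
  res <- c("A", "C", "D", "E", "-")
  for (i in 1:20) {
    rows <- vapply(1:4, function(k)
      paste(sample(res, 30, replace = TRUE, prob = c(rep(0.23, 4), 0.08)),
            collapse = ""), character(1))
    names(rows) <- paste0("t", 1:4)
    msa <- as_multiple_alignment(rows)
    if (length(msa$mask) == 0) next
    m <- do.call(rbind, strsplit(rows, ""))[, msa$mask, drop = FALSE]
    p12 <- mean(m[1, ] != m[2, ])
    got <- poisson_distance(msa)["t1", "t2"]
    expect_equal(got, min(-log(1 - p12), 10), tolerance = 1e-9)
  }
  # strict monotonicity of the correction
  p <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(-log(1 - p)) > 0))
})

test_that("neighbor joining solves the 3-taxon closed form", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 4))
})

test_that("neighbor joining recovers additive trees exactly", {
  # 4-taxon additive matrix: check the recovered bipartition against the
  # least-squares best of all three topologies
  d <- matrix(c(0, 2, 7, 7,
                2, 0, 7, 7,
                7, 7, 0, 2,
                7, 7, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  # random additive trees: all pairwise path lengths reproduced to 1e-9
  set.seed(13)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    true <- ape::rtree(n)
    D <- ape::cophenetic.phylo(true)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    got <- nj_tree(D)
    Dg <- ape::cophenetic.phylo(got)[rownames(D), colnames(D)]
    expect_equal(Dg, D, tolerance = 1e-9)
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    true <- ape::rtree(n)
    D <- ape::cophenetic.phylo(true)
    mine <- nj_tree(D)
    apetree <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(apetree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ input validation rejects tiny or asymmetric matrices", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "3 taxa")
  d3 <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "symmetric")
})

test_that("bootstrap supports are deterministic, bounded and saturate", {
  # two clearly separated 3-leaf clusters: central edge support 100
  rows <- c(a = "AAAAAAAAAACCCCCGGGGG", b = "AAAAAAAAAACCCCAGGGGG",
            c = "AAAAAAAAAACCCAAGGGGG",
            x = "TTTTTTTTTTCCCCCGGGGG", y = "TTTTTTTTTTCCCCTGGGGG",
            z = "TTTTTTTTTTCCCTTGGGGG")
  msa <- as_multiple_alignment(rows)
  tr <- bootstrap_support(msa, B = 100, seed = 5)
  sup <- as.integer(tr$node.label[tr$node.label != ""])
  expect_true(all(sup >= 0 & sup <= 100))
  # the deepest split separates {a,b,c} from {x,y,z} in every replicate
  expect_true(100 %in% sup)
  expect_true(ape::is.monophyletic(tr, c("a", "b", "c")))
  # B = 1: supports in {0, 100}
  tr1 <- bootstrap_support(msa, B = 1, seed = 5)
  sup1 <- as.integer(tr1$node.label[tr1$node.label != ""])
  expect_true(all(sup1 %in% c(0L, 100L)))
  # determinism
  tr2 <- bootstrap_support(msa, B = 100, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # taxon-order permutation invariance at a fixed seed
  msa_p <- as_multiple_alignment(rows[c(4, 2, 6, 1, 3, 5)])
  tr3 <- bootstrap_support(msa_p, B = 100, seed = 5)
  lab <- function(t) {
    s <- setNames(t$node.label, NA)
    pp <- ape::prop.part(t)
    sets <- vapply(seq_along(pp), function(k)
      paste(sort(attr(pp, "labels")[pp[[k]]]), collapse = "|"), character(1))
    sort(paste(sets, t$node.label, sep = "="))
  }
  expect_identical(lab(tr3), lab(tr))
})

test_that("MAFFT-backed alignment handles identical and nested sequences", {
  msa <- progressive_align(c(s1 = "MKVLWAAL", s2 = "MKVLWAAL"))
  expect_identical(unname(msa$rows[1]), unname(msa$rows[2]))
  expect_false(grepl("-", msa$rows[1], fixed = TRUE))
  msa2 <- progressive_align(c(s1 = "MKV", s2 = "MV"))
  expect_identical(nchar(msa2$rows[["s1"]]), 3L)
  expect_identical(sum(strsplit(msa2$rows[["s2"]], "")[[1]] == "-"), 1L)
  expect_error(progressive_align(c(s1 = "MKV")), "two")
})

test_that("aligned families score at least the naive stacked alignment", {
  set.seed(15)
  base <- random_protein_seq(60)
  seqs <- setNames(c(base, vapply(1:9, function(i) {
    s <- base
    for (k in sample(60, 12)) substr(s, k, k) <- random_protein_seq(1)
    s
  }, character(1))), paste0("t", 1:10))
  msa <- progressive_align(seqs)
  B <- blosum62_matrix()
  sp_score <- function(rows) {
    m <- do.call(rbind, strsplit(rows, ""))
    tot <- 0
    for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      for (c0 in seq_len(ncol(m))) {
        x <- m[i, c0]; y <- m[j, c0]
        tot <- tot + if (x == "-" && y == "-") 0 else
          if (x == "-" || y == "-") -4 else B[x, y]
      }
    }
    tot
  }
  naive <- seqs  # equal lengths: stacked alignment is just the raw rows
  expect_gte(sp_score(msa$rows), sp_score(naive))
})

test_that("anchor groups drive subfamily assignment with tie detection", {
  d <- matrix(c(0, 0.1, 0.9, 0.95,
                0.1, 0, 0.9, 0.95,
                0.9, 0.9, 0, 0.2,
                0.95, 0.95, 0.2, 0), 4, 4,
              dimnames = list(c("g1", "A1", "g2", "A2"),
                              c("g1", "A1", "g2", "A2")))
  anchors <- data.frame(anchor_id = c("A1", "A2"), subfamily = c("S1", "S2"),
                        stringsAsFactors = FALSE)
  asg <- assign_subfamilies(d, anchors)
  expect_identical(asg$subfamily[asg$gene == "g1"], "S1")
  expect_identical(asg$subfamily[asg$gene == "g2"], "S2")
  # equidistant gene stays unassigned with a warning
  d["g1", "A2"] <- d["A2", "g1"] <- 0.1
  expect_warning(asg2 <- assign_subfamilies(d, anchors), "equidistant")
  expect_true(is.na(asg2$subfamily[asg2$gene == "g1"]))
})
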