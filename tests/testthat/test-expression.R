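mk_meta <- function(tissues, replicates = 2L) {
  meta <- expand.grid(tissue = names(tissues), replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample <- paste0(meta$tissue, "_r", meta$replicate)
  meta$category <- unname(tissues[meta$tissue])
  meta
}

test_that("tissue means average log2 replicates", {
  tissues <- c(root = "vegetative", leaf = "vegetative")
  meta <- mk_meta(tissues)
  mat <- matrix(c(4, 6, 6, 3), nrow = 1,
                dimnames = list("g1", c("root_r1", "leaf_r1", "root_r2", "leaf_r2")))
  m <- average_log2(mat, meta)
  expect_equal(m["g1", "root"], 5)
  expect_equal(m["g1", "leaf"], 4.5)
  # random matrix equals a brute-force tally
  set.seed(61)
  mat2 <- matrix(rnorm(5 * nrow(meta)), nrow = 5,
                 dimnames = list(paste0("g", 1:5), meta$sample))
  m2 <- average_log2(mat2, meta)
  for (ti in names(tissues)) {
    cols <- meta$sample[meta$tissue == ti]
    expect_equal(m2[, ti], rowMeans(mat2[, cols]))
  }
  expect_error(average_log2(matrix(NaN, 1, 1, dimnames = list("g", "root_r1")),
                            meta), "finite")
})

test_that("group rules are evaluated in order IV, I, III, II", {
  tissues <- c(VR = "vegetative", VL = "vegetative",
               RR = "reproductive", An = "reproductive")
  means <- rbind(
    allhigh = c(9, 9, 9, 9),
    alllow  = c(1, 1, 1, 1),
    veg     = c(9, 9, 1, 1),
    mixed   = c(9, 1, 9, 1))
  colnames(means) <- names(tissues)
  g <- classify_groups(means, tissues, tau_high = 8, tau_low = 4)
  expect_identical(g$group[match(c("allhigh", "alllow", "veg", "mixed"),
                                 g$gene)],
                   c("I", "IV", "III", "II"))
  # total partition: every gene gets exactly one group
  set.seed(62)
  rnd <- matrix(runif(80, 0, 12), nrow = 20,
                dimnames = list(paste0("g", 1:20), names(tissues)))
  g2 <- classify_groups(rnd, tissues)
  expect_identical(nrow(g2), 20L)
  expect_true(all(g2$group %in% c("I", "II", "III", "IV")))
  expect_identical(anyDuplicated(g2$gene), 0L)
})

test_that("stress calls require p < alpha with direction from the mean shift", {
  ctl <- matrix(c(8, 8, 8), 1, dimnames = list("g1", NULL))
  expect_identical(stress_de(ctl, ctl)$direction, "none")
  set.seed(63)
  down <- vapply(1:50, function(i) {
    a <- matrix(rnorm(3, 8, 0.2), 1)
    b <- matrix(rnorm(3, 6, 0.2), 1)
    stress_de(a, b)$direction
  }, character(1))
  expect_gte(mean(down == "down"), 0.95)
  expect_error(stress_de(matrix(1, 1, 1), matrix(1, 1, 2)), "replicates")
})

test_that("hormone calls use strict 2-fold / 50% boundaries and the 3 h flag", {
  rq <- data.frame(gene = c("g1", "g1", "g1", "g2", "g2"),
                   treatment = "ABA",
                   time = c(3, 6, 24, 3, 6),
                   rq = c(1.0, 2.0, 4.0, 0.4, 0.6),
                   stringsAsFactors = FALSE)
  hr <- hormone_response(rq)
  expect_identical(hr$calls$direction, c("none", "none", "up", "down", "none"))
  expect_identical(hr$early$early_responsive[hr$early$gene == "g1"], FALSE)
  expect_identical(hr$early$early_responsive[hr$early$gene == "g2"], TRUE)
  expect_error(hormone_response(transform(rq, rq = c(1, -1, 1, 1, 1))),
               "positive")
})

test_that("2^-ddCt arithmetic and multiplicativity", {
  ct <- rbind(
    data.frame(gene = "t", sample = "cal", replicate = 1:2, ct = c(25, 25)),
    data.frame(gene = "ref", sample = "cal", replicate = 1:2, ct = c(20, 20)),
    data.frame(gene = "t", sample = "s1", replicate = 1:2, ct = c(22, 22)),
    data.frame(gene = "ref", sample = "s1", replicate = 1:2, ct = c(20, 20)))
  r <- ddct(ct, reference = "ref", calibrator = "cal")
  expect_equal(r$rq[r$sample == "cal"], 1.0)
  # dCt 2 vs dCt 5: ddCt = -3, RQ = 8
  expect_equal(r$rq[r$sample == "s1"], 8.0)
  # subtracting one cycle from every target Ct in a sample doubles its RQ
  ct2 <- ct
  ct2$ct[ct2$gene == "t" & ct2$sample == "s1"] <-
    ct2$ct[ct2$gene == "t" & ct2$sample == "s1"] - 1
  r2 <- ddct(ct2, reference = "ref", calibrator = "cal")
  expect_equal(r2$rq[r2$sample == "s1"], 2 * r$rq[r$sample == "s1"])
  # missing reference in a sample is an error
  expect_error(ddct(ct[ct$gene != "ref" | ct$sample != "s1", ],
                    reference = "ref", calibrator = "cal"), "missing")
})
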