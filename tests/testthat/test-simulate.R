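test_that("planted histidine boxes occur exactly once at recorded offsets", {
  pb <- simulate_proteins_with_boxes("FAB2", n = 5, length = 200, seed = 71)
  pats <- hbox_patterns("FAB2")
  for (id in names(pb$proteins)) {
    hits <- scan_hboxes(pb$proteins[[id]], pats)$hits
    tr <- pb$truth[pb$truth$protein == id, ]
    expect_identical(nrow(hits), nrow(tr))
    expect_setequal(paste(hits$pattern, hits$start0),
                    paste(tr$pattern, tr$start0))
  }
  # n = 0 -> empty set; too-short proteins are a config error
  expect_identical(length(simulate_proteins_with_boxes("FAB2", 0, 200,
                                                       seed = 1)$proteins), 0L)
  expect_error(simulate_proteins_with_boxes("FAD2", 3, 40, seed = 1),
               "too short")
})

test_that("rejection-sampled background proteins yield zero scanner hits", {
  sim <- small_sim()
  bg_ids <- setdiff(names(sim$proteome),
                    c(sim$family$protein_id,
                      grep("\\.2$", names(sim$proteome), value = TRUE)))
  pats <- hbox_patterns()
  fp <- sum(vapply(bg_ids, function(id)
    nrow(scan_hboxes(sim$proteome[[id]], pats)$hits), integer(1)))
  expect_identical(fp, 0L)
})

test_that("the same seed reproduces the simulation byte for byte", {
  cfg <- family_sim_config(seed = 9L, n_chromosomes = 3L,
                           n_background_genes = 8L,
                           subfamilies = c(FAB2 = 2L, DES1 = 1L),
                           tandem_specs = list(),
                           segmental_specs = list())
  s1 <- simulate_family_genome(cfg)
  s2 <- simulate_family_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$gff, s2$gff)
  expect_identical(s1$proteome, s2$proteome)
  expect_identical(s1$truth, s2$truth)
})

test_that("planted tandem and segmental pairs satisfy the published criteria", {
  sim <- small_sim()
  fam <- sim$family
  # tandem: every consecutive planted pair qualifies under the rule
  cl <- sim$truth$tandem_clusters[[1]]
  expect_length(cl, 3)
  members <- fam[match(cl, fam$name), ]
  expect_identical(length(unique(members$chromosome)), 1L)
  o <- order(members$ordinal)
  for (k in 1:2) {
    i <- o[k]; j <- o[k + 1]
    expect_lte(abs(members$ordinal[i] - members$ordinal[j]) - 1L, 4L)
    aln <- global_align(members$protein[i], members$protein[j])
    expect_gt(aln$identity, 0.5)
    expect_equal(aln$identity, 0.6, tolerance = 0.031)
  }
  # segmental: planted pair passes > 75% / > 75% strictly
  sp <- sim$truth$segmental_pairs
  aln <- global_align(fam$protein[fam$name == sp$a[1]],
                      fam$protein[fam$name == sp$b[1]])
  expect_gt(aln$coverage, 0.75)
  expect_gt(aln$similarity, 0.75)
  expect_equal(aln$coverage, 0.85, tolerance = 0.031)
  expect_equal(aln$similarity, 0.85, tolerance = 0.031)
})

test_that("sub-threshold segmental plantings generate no calls", {
  cfg <- family_sim_config(
    seed = 12L, n_chromosomes = 3L, n_background_genes = 10L,
    subfamilies = c(FAB2 = 3L, DES1 = 1L),
    tandem_specs = list(),
    segmental_specs = list(list(subfamily = "FAB2", coverage = 0.5,
                                similarity = 0.5)))
  sim <- simulate_family_genome(cfg)
  td <- call_tandem(sim$family)
  sg <- call_segmental(sim$family, td$clusters)
  expect_identical(nrow(sg), 0L)
})

test_that("expression archetypes classify exactly without noise", {
  ex <- simulate_expression(seed = 81, noise_sd = 0)
  means <- average_log2(ex$mat, ex$meta)
  cats <- default_tissue_panel()
  g <- classify_groups(means, cats, tau_high = ex$tau_high, tau_low = ex$tau_low)
  expect_identical(g$group[match(ex$truth$gene, g$gene)], ex$truth$group)
  # planted group IV genes sit below the low threshold in every tissue
  iv <- ex$truth$gene[ex$truth$group == "IV"]
  expect_true(all(apply(means[iv, , drop = FALSE], 1, max) < ex$tau_low))
})

test_that("group recovery stays above 90% at replicate noise sd 0.3", {
  cats <- default_tissue_panel()
  recov <- vapply(1:5, function(s) {
    ex <- simulate_expression(seed = 100 + s, noise_sd = 0.3)
    means <- average_log2(ex$mat, ex$meta)
    g <- classify_groups(means, cats, tau_high = ex$tau_high,
                         tau_low = ex$tau_low)
    mean(g$group[match(ex$truth$gene, g$gene)] == ex$truth$group)
  }, numeric(1))
  expect_gte(mean(recov), 0.9)
})

test_that("noiseless Ct tables return the planted fold changes exactly", {
  q <- simulate_qpcr(seed = 91, ct_noise_sd = 0)
  r <- ddct(q$ct, reference = q$reference, calibrator = q$calibrator)
  tr <- q$truth
  tr$sample <- paste0(tr$treatment, "_", tr$time, "h")
  m <- merge(r, tr[, c("gene", "sample", "fold")], by = c("gene", "sample"))
  expect_gt(nrow(m), 0)
  expect_equal(m$rq, m$fold, tolerance = 1e-12)
})

test_that("noisy Ct fold-change estimates stay near truth over many seeds", {
  rqs <- vapply(1:100, function(s) {
    q <- simulate_qpcr(
      spec = data.frame(gene = "g1", treatment = "ABA", time = 3, fold = 2,
                        stringsAsFactors = FALSE),
      seed = s, replicates = 6L, ct_noise_sd = 0.1)
    r <- ddct(q$ct, reference = q$reference, calibrator = q$calibrator)
    r$rq[r$sample == "ABA_3h"]
  }, numeric(1))
  expect_gte(mean(rqs), 1.8)
  expect_lte(mean(rqs), 2.2)
})
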