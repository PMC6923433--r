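test_that("keyword screen is a case-insensitive substring match", {
  ann <- data.frame(
    locus_id = c("g1", "g2", "g3", "g4"),
    description = c("putative fatty acid desaturase 2",
                    "Fatty Acid Desaturase, chloroplastic",
                    "desaturase-like protein",
                    "expressed protein"),
    stringsAsFactors = FALSE)
  hits <- keyword_screen(ann, "fatty acid desaturase")
  expect_setequal(hits, c("g1", "g2"))
})

test_that("domain screen accepts hit tables and falls back to H-box evidence", {
  hits <- data.frame(protein_id = "LOC_Os01g00010.1", domain = "PF00487",
                     evalue = 1e-30, stringsAsFactors = FALSE)
  ds <- domain_screen(domain_hits = hits)
  expect_identical(ds$loci, "LOC_Os01g00010")
  expect_identical(ds$mode, "hit_table")
  expect_error(domain_screen(), "configuration error")

  # fallback mode on planted proteins: full recovery, zero background
  pb <- simulate_proteins_with_boxes("FAB2", n = 6, length = 200, seed = 31)
  set.seed(32)
  bg <- setNames(vapply(1:20, function(i) random_protein_seq(200), character(1)),
                 paste0("bg_", 1:20))
  pats <- hbox_patterns("FAB2")
  # keep only backgrounds with no accidental box (checked with the oracle)
  bg <- bg[vapply(bg, function(s) nrow(brute_scan(s, pats)) == 0, logical(1))]
  ds2 <- domain_screen(proteome = c(pb$proteins, bg), patterns = pats)
  expect_identical(ds2$mode, "hbox_fallback")
  expect_setequal(ds2$loci, names(pb$proteins))
})

test_that("homology screen keeps self-hits and excludes random sequences", {
  set.seed(33)
  q <- setNames(random_protein_seq(400), "Q1")
  prot <- c(setNames(q, "hit.1"),
            setNames(vapply(1:200, function(i) random_protein_seq(100),
                            character(1)),
                     paste0("rnd", 1:200, ".1")))
  res <- homology_screen(q, prot)
  expect_identical(res$locus_id, "hit")   # empirical null: 0 of 200 kept
  expect_lt(res$best_evalue, 1e-10)
  expect_error(homology_screen(character(), prot), "empty query")
})

test_that("lowering the E-value cutoff never adds candidates", {
  set.seed(34)
  q <- setNames(random_protein_seq(120), "Q1")
  prot <- setNames(vapply(1:30, function(i) {
    s <- q
    for (k in sample(120, sample(10:100, 1))) substr(s, k, k) <- random_protein_seq(1)
    s
  }, character(1)), paste0("p", 1:30, ".1"))
  cuts <- c(1e-5, 1e-10, 1e-20, 1e-40)
  kept <- lapply(cuts, function(cc) homology_screen(q, prot, evalue_max = cc)$locus_id)
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})

test_that("merging evidence unions loci and keeps the longest splice variant", {
  prot <- c("LOC_Os01g00010.1" = random_protein_seq(300),
            "LOC_Os01g00010.2" = random_protein_seq(280),
            "LOC_Os01g00020.1" = random_protein_seq(120),
            "LOC_Os01g00030.1" = random_protein_seq(150))
  ev <- list(domain = c("LOC_Os01g00010", "LOC_Os01g00020"),
             keyword = c("LOC_Os01g00020", "LOC_Os01g00030"))
  m <- merge_and_deduplicate(ev, prot)
  expect_setequal(m$locus_id,
                  c("LOC_Os01g00010", "LOC_Os01g00020", "LOC_Os01g00030"))
  expect_identical(m$protein_id[m$locus_id == "LOC_Os01g00010"],
                   "LOC_Os01g00010.1")
  # idempotent and order-independent over evidence sets
  m2 <- merge_and_deduplicate(rev(ev), prot)
  expect_identical(m[order(m$locus_id), ], m2[order(m2$locus_id), ])
  m3 <- merge_and_deduplicate(c(ev, ev), prot)
  expect_identical(nrow(m3), nrow(m))
  # manual include of an absent locus is an error
  expect_error(merge_and_deduplicate(ev, prot, manual_include = "LOC_Os09g99999"),
               "absent")
  # manual include carries its flag (truncated-member precedent)
  m4 <- merge_and_deduplicate(list(domain = character()), prot,
                              manual_include = "LOC_Os01g00030")
  expect_true(m4$manual_include[m4$locus_id == "LOC_Os01g00030"])
  expect_match(m4$sources[m4$locus_id == "LOC_Os01g00030"], "manual")
})

test_that("subfamily naming is positional with singleton and override rules", {
  cand <- data.frame(
    locus_id = paste0("L", 1:6),
    subfamily = c("FAD3/7/8", "FAD3/7/8", "DES1", "FAB2", "FAB2", "FAB2"),
    chromosome = c(12L, 11L, 2L, 3L, 1L, 2L),
    start = c(100L, 100L, 50L, 10L, 10L, 10L),
    stringsAsFactors = FALSE)
  named <- assign_family_names(cand)
  # numbered by (chromosome, start) ascending within subfamily
  expect_identical(named$name[named$locus_id == "L2"], "OsFAD378-1")
  expect_identical(named$name[named$locus_id == "L1"], "OsFAD378-2")
  expect_identical(named$name[named$locus_id == "L3"], "OsDES1")  # singleton
  expect_identical(named$name[named$locus_id == "L5"], "OsFAB2-1")
  ov <- c(L1 = "OsFAD8", L2 = "OsFAD7")
  named2 <- assign_family_names(cand, overrides = ov)
  expect_identical(named2$name[named2$locus_id == "L1"], "OsFAD8")
  expect_error(assign_family_names(cand, overrides = c(L1 = "X", L2 = "X")),
               "duplicate")
})

test_that("nine-member subfamilies number 1-9 along the chromosomes", {
  set.seed(35)
  cand <- data.frame(
    locus_id = paste0("L", 1:9), subfamily = "FAB2",
    chromosome = c(1L, 1L, 2L, 3L, 4L, 3L, 6L, 8L, 8L),
    start = c(100L, 900L, 10L, 10L, 10L, 900L, 10L, 10L, 900L),
    stringsAsFactors = FALSE)
  shuffled <- cand[sample(9), ]
  named <- assign_family_names(shuffled)
  o <- order(named$chromosome, named$start)
  expect_identical(named$name[o], paste0("OsFAB2-", 1:9))
})

test_that("identification recovers the planted family with unit recall and precision", {
  sim <- small_sim()
  dom <- domain_screen(proteome = sim$proteome)
  hom <- homology_screen(sim$queries, sim$proteome)
  kw <- keyword_screen(sim$annotation)
  cand <- merge_and_deduplicate(
    list(domain = dom$loci, homology = unique(hom$locus_id), keyword = kw),
    sim$proteome)
  expect_setequal(cand$locus_id, sim$family$locus_id)
  # each route alone already has unit recall on the planted family
  expect_true(all(sim$family$locus_id %in% dom$loci))
  expect_true(all(sim$family$locus_id %in% hom$locus_id))
  expect_true(all(sim$family$locus_id %in% kw))
  # zero background loci pass any route
  expect_true(all(dom$loci %in% sim$family$locus_id))
  expect_true(all(unique(hom$locus_id) %in% sim$family$locus_id))
  expect_true(all(kw %in% sim$family$locus_id))
  # the splice-variant locus keeps its longest transcript
  sv_locus <- locus_of_transcript(grep("\\.2$", names(sim$proteome), value = TRUE))
  expect_identical(cand$protein_id[cand$locus_id == sv_locus],
                   paste0(sv_locus, ".1"))
})
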