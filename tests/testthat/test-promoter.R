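mk_genome_model <- function(chrom_seq, cds_start, cds_end, strand = "+") {
  model <- list(mrna_id = "m1", locus_id = "g1", seqid = "Chr1",
                strand = strand, start = cds_start, end = cds_end,
                cds = data.frame(start = cds_start, end = cds_end),
                exons = data.frame(start = cds_start, end = cds_end),
                utr5 = data.frame(start = integer(), end = integer()),
                utr3 = data.frame(start = integer(), end = integer()))
  list(genome = c(Chr1 = chrom_seq), model = model)
}

test_that("promoter extraction is strand-aware and coordinate-exact", {
  set.seed(51)
  chrom <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
                 collapse = "")
  # plus strand, CDS starts at 5001: bases 3001..5000
  gm <- mk_genome_model(chrom, 5001L, 5900L)
  expect_identical(extract_promoter(gm$genome, gm$model),
                   substr(chrom, 3001, 5000))
  # minus strand, CDS ends at e: reverse complement of e+1 .. e+2000
  gm2 <- mk_genome_model(chrom, 2001L, 3000L, strand = "-")
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 3001, 5000))))
  expect_identical(extract_promoter(gm2$genome, gm2$model), expected)
  # near the contig edge the promoter truncates with a warning
  gm3 <- mk_genome_model(chrom, 501L, 1000L)
  expect_warning(p <- extract_promoter(gm3$genome, gm3$model), "truncated")
  expect_identical(nchar(p), 500L)
  # unknown seqid is an error
  gm4 <- gm; gm4$model$seqid <- "Chr9"
  expect_error(extract_promoter(gm4$genome, gm4$model), "absent")
})

test_that("element scanning reports both strands at template coordinates", {
  set.seed(52)
  # a background with no element hits, then plant motifs at known offsets
  elements <- cis_element_table()
  prom <- paste(rep("T", 2000), collapse = "")
  substr(prom, 2000 - 150 + 1, 2000 - 150 + 5) <- "ACGTG"   # ABRE at -150
  substr(prom, 2000 - 300 + 1, 2000 - 300 + 5) <- "CACGT"   # revcomp(ACGTG) at -300
  hits <- scan_elements(prom, elements)
  abre <- hits[hits$element == "ABRE", ]
  expect_identical(abre$position, c(-300L, -150L))
  expect_identical(abre$strand[abre$position == -150], "template")
  expect_identical(abre$strand[abre$position == -300], "complementary")
})

test_that("scanning the reverse complement is a strand-swapping bijection", {
  set.seed(53)
  elements <- cis_element_table()
  for (rep in 1:5) {
    prom <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                  collapse = "")
    h <- scan_elements(prom, elements)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(prom)))
    h_rc <- scan_elements(rc, elements)
    # map: template start i (1-based) of width w <-> rc start L - i - w + 2
    L <- nchar(prom)
    w <- nchar(elements$consensus)[match(h$element, elements$name)]
    i1 <- h$position + L + 1L
    mapped <- data.frame(
      element = h$element,
      position = (L - i1 - w + 2L) - L - 1L,
      strand = ifelse(h$strand == "template", "complementary", "template"),
      stringsAsFactors = FALSE)
    mapped <- mapped[order(mapped$position, mapped$element, mapped$strand), ]
    rownames(mapped) <- NULL
    got <- h_rc[, c("element", "position", "strand")]
    expect_identical(got, mapped)
  }
})

test_that("per-gene summaries conserve totals and flag multiple copies", {
  hits <- list(
    gA = data.frame(element = c("ABRE", "ABRE", "MBS"),
                    position = c(-10L, -50L, -99L),
                    strand = "template", match = "x", stringsAsFactors = FALSE),
    gB = data.frame(element = character(), position = integer(),
                    strand = character(), match = character(),
                    stringsAsFactors = FALSE))
  s <- summarize_elements(hits)
  expect_identical(unname(s$counts["gA", "ABRE"]), 2L)
  expect_true(s$multiple["gA", "ABRE"])
  expect_false(s$multiple["gA", "MBS"])
  expect_true(all(s$counts["gB", ] == 0L))
  expect_identical(sum(s$counts), nrow(hits$gA) + nrow(hits$gB))
})

test_that("planted promoter elements are recovered exactly from the genome", {
  sim <- default_sim()
  ann <- default_sim_annotation()
  pt <- sim$truth$promoter_elements
  expect_gt(nrow(pt), 20)
  total <- 0L
  for (g in unique(pt$gene)) {
    pid <- sim$family$protein_id[sim$family$name == g]
    prom <- extract_promoter(sim$genome, ann$models[[pid]])
    expect_identical(nchar(prom), 2000L)
    hits <- scan_elements(prom)
    tr <- pt[pt$gene == g, c("element", "position", "strand")]
    tr <- tr[order(tr$position, tr$element, tr$strand), ]
    rownames(tr) <- NULL
    got <- hits[, c("element", "position", "strand")]
    got$position <- as.integer(got$position)
    tr$position <- as.integer(tr$position)
    expect_identical(got, tr)
    total <- total + nrow(hits)
  }
  expect_identical(total, nrow(pt))
})
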