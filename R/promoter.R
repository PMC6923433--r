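# Promoter extraction (2 kb upstream of the ATG) and strand-aware
# cis-regulatory element scanning against an IUPAC consensus table.

.iupac_ok <- function(x) {
  grepl("^[ACGTRYSWKMBDHVN]+$", x)
}

#' Packaged cis-regulatory element table
#'
#' Default consensus table for the developmental, stress, hormone and
#' light-responsive elements commonly scanned in plant promoters (ABRE,
#' ARE, AuxRE, GARE-motif, LTR, MBS, the CGTCA/TGACG MeJA pair, TC-rich
#' repeats, WUN-motif, Box4, G-box, GT1-motif, TCT-motif, Sp1). The
#' consensi follow the standard PlantCARE vocabulary and are
#' user-replaceable; pass any data frame with columns `name`, `consensus`,
#' `category` to the scanners.
#'
#' @return Data frame with columns `name`, `consensus`, `category`.
#' @export
cis_element_table <- function() {
  read_tsv_file(system.file("extdata", "cis_elements.tsv",
                            package = "famsurvey"))
}

#' Extract the promoter upstream of the translational start
#'
#' Returns the `length` bases immediately 5' of the first CDS base,
#' strand-aware: for minus-strand genes the genomic region 3' of the CDS
#' end is taken and reverse-complemented. Near a contig edge the promoter
#' is truncated with a warning.
#'
#' @param genome Named character vector of chromosome sequences (names are
#'   GFF seqids), or a [Biostrings::DNAStringSet].
#' @param model Gene model (see [read_gff3()]).
#' @param length Promoter length in bp (default 2000).
#' @return Promoter sequence (string), 5' to 3', ending at the base
#'   immediately before the ATG.
#' @export
extract_promoter <- function(genome, model, length = 2000L) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  seqid <- model$seqid
  if (is.null(seqid) || !seqid %in% names(genome)) {
    stop("locus ", model$locus_id, ": seqid '", seqid, "' absent from genome")
  }
  chrom <- genome[[seqid]]
  cds <- model$cds
  if (is.null(cds) || !nrow(cds)) stop("gene model has no CDS")
  if (model$strand == "+") {
    atg <- min(cds$start)
    from <- atg - length
    if (from < 1L) {
      warning("promoter of ", model$locus_id, " truncated to ", atg - 1L,
              " bp at contig start")
      from <- 1L
    }
    if (atg == 1L) return("")
    substr(chrom, from, atg - 1L)
  } else {
    cds_end <- max(cds$end)
    to <- cds_end + length
    if (to > nchar(chrom)) {
      warning("promoter of ", model$locus_id, " truncated to ",
              nchar(chrom) - cds_end, " bp at contig end")
      to <- nchar(chrom)
    }
    if (cds_end == nchar(chrom)) return("")
    region <- substr(chrom, cds_end + 1L, to)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(region)))
  }
}

#' Scan a promoter for cis-regulatory elements on both strands
#'
#' IUPAC-expanded matching of each consensus on the template strand and of
#' its reverse complement (complementary-strand hits are reported at
#' template coordinates). Positions are relative to the ATG: -1 is the
#' base immediately 5' of the A, so positions lie in
#' `[-promoter_length, -1]`. Overlapping matches are all reported; hits are
#' ordered by position then element name.
#'
#' @param promoter Promoter sequence as returned by [extract_promoter()].
#' @param elements Element table (data frame with `name`, `consensus`);
#'   defaults to [cis_element_table()].
#' @return Data frame `element`, `position` (5'-most template base of the
#'   hit, relative to ATG), `strand` (`"template"`/`"complementary"`),
#'   `match` (template-strand sequence of the hit).
#' @export
scan_elements <- function(promoter, elements = cis_element_table()) {
  stopifnot(is.character(promoter), length(promoter) == 1L)
  if (!all(.iupac_ok(elements$consensus))) {
    bad <- elements$name[!.iupac_ok(elements$consensus)]
    stop("invalid IUPAC consensus for element(s): ", paste(bad, collapse = ", "))
  }
  Lp <- nchar(promoter)
  out <- list()
  if (Lp == 0L) {
    return(data.frame(element = character(), position = integer(),
                      strand = character(), match = character(),
                      stringsAsFactors = FALSE))
  }
  subject <- Biostrings::DNAString(promoter)
  for (k in seq_len(nrow(elements))) {
    cons <- Biostrings::DNAString(elements$consensus[k])
    for (strand in c("template", "complementary")) {
      pat <- if (strand == "template") cons else
        Biostrings::reverseComplement(cons)
      m <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
      if (!length(m)) next
      st <- Biostrings::start(m)
      out[[length(out) + 1L]] <- data.frame(
        element = elements$name[k],
        position = st - Lp - 1L,
        strand = strand,
        match = as.character(m),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(element = character(), position = integer(),
               strand = character(), match = character(),
               stringsAsFactors = FALSE)
  hits <- hits[order(hits$position, hits$element, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Per-gene element count table
#'
#' @param hits_by_gene Named list of [scan_elements()] results (one per
#'   gene), or a single hits data frame with an extra `gene` column.
#' @param elements Element table defining the column order.
#' @return List with `counts` (gene x element integer matrix) and
#'   `multiple` (logical matrix, `TRUE` where a gene has >= 2 copies of an
#'   element).
#' @export
summarize_elements <- function(hits_by_gene, elements = cis_element_table()) {
  if (is.data.frame(hits_by_gene)) {
    stopifnot("gene" %in% names(hits_by_gene))
    hits_by_gene <- split(hits_by_gene, hits_by_gene$gene)
  }
  genes <- names(hits_by_gene)
  counts <- matrix(0L, nrow = length(genes), ncol = nrow(elements),
                   dimnames = list(genes, elements$name))
  for (g in genes) {
    h <- hits_by_gene[[g]]
    if (!nrow(h)) next
    tab <- table(factor(h$element, levels = elements$name))
    counts[g, ] <- as.integer(tab)
  }
  list(counts = counts, multiple = counts >= 2L)
}
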