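# Gene-structure statistics (intron counts and phases, UTR presence) and
# chromosomal distribution summaries.

#' Intron/exon statistics for one gene model
#'
#' Introns are counted between consecutive CDS intervals (intron counts
#' refer to the coding sequence; introns lying wholly within UTRs are
#' reported separately and excluded from the headline count). The phase of
#' intron i is the number of bases of the interrupted codon already
#' emitted, i.e. cumulative CDS length 5' of the intron modulo 3.
#'
#' @param model A gene model as produced by [read_gff3()] (list with
#'   `cds`, `exons`, `utr5`, `utr3` interval data frames in transcription
#'   order).
#' @return List with `mrna_id`, `n_exons`, `n_introns`, `intron_phases`,
#'   `has_utr5`, `has_utr3`, `transcript_length`, `cds_length`,
#'   `n_utr_introns`, and `cds_incomplete` (`TRUE` when the CDS length is
#'   not divisible by 3, e.g. annotated truncations).
#' @export
intron_stats <- function(model) {
  cds <- model$cds
  if (is.null(cds) || !nrow(cds)) stop("gene model has no CDS intervals")
  widths <- cds$end - cds$start + 1L
  n_cds <- nrow(cds)
  phases <- if (n_cds > 1L) cumsum(widths)[-n_cds] %% 3L else integer()
  exons <- model$exons
  n_exons <- if (!is.null(exons) && nrow(exons)) nrow(exons) else n_cds
  cds_len <- sum(widths)
  list(
    mrna_id = model$mrna_id,
    n_exons = n_exons,
    n_introns = n_cds - 1L,
    intron_phases = as.integer(phases),
    has_utr5 = !is.null(model$utr5) && nrow(model$utr5) > 0L,
    has_utr3 = !is.null(model$utr3) && nrow(model$utr3) > 0L,
    transcript_length = if (!is.null(exons) && nrow(exons))
      sum(exons$end - exons$start + 1L) else cds_len,
    cds_length = cds_len,
    n_utr_introns = max(0L, n_exons - n_cds),
    cds_incomplete = (cds_len %% 3L) != 0L
  )
}

#' Structure report for a set of gene models
#'
#' @param annotation A `gene_annotation` (see [read_gff3()]), or a list of
#'   gene models.
#' @return Data frame with one row per mRNA model (gene, chromosome,
#'   coordinates, exon/intron counts, phases as a comma string, UTR flags).
#' @export
structure_report <- function(annotation) {
  models <- if (inherits(annotation, "gene_annotation")) annotation$models
            else annotation
  rows <- lapply(models, function(m) {
    st <- intron_stats(m)
    data.frame(
      mrna_id = st$mrna_id, locus_id = m$locus_id,
      chromosome = m$chromosome, start = m$start, end = m$end,
      strand = m$strand, n_exons = st$n_exons, n_introns = st$n_introns,
      phases = paste(st$intron_phases, collapse = ","),
      utr5 = st$has_utr5, utr3 = st$has_utr3,
      transcript_length = st$transcript_length,
      cds_incomplete = st$cds_incomplete,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-chromosome distribution of family members
#'
#' @param chromosomes Integer vector of chromosome numbers (one per gene),
#'   or a data frame with a `chromosome` column.
#' @param n_chromosomes Total chromosomes in the genome (12 for rice).
#' @return List with `counts` (named integer vector over all chromosomes),
#'   `occupied` (chromosomes with >= 1 member), `missing`, and `n_genes`.
#' @examples
#' tab <- read_tsv_file(system.file("extdata", "rice_desaturase_loci.tsv",
#'                                  package = "famsurvey"))
#' chromosome_distribution(locus_chromosome(tab$locus_id))$counts
#' @export
chromosome_distribution <- function(chromosomes, n_chromosomes = 12L) {
  if (is.data.frame(chromosomes)) chromosomes <- chromosomes$chromosome
  chromosomes <- as.integer(chromosomes)
  if (length(chromosomes) && any(is.na(chromosomes))) {
    stop("chromosome number missing for some loci")
  }
  if (length(chromosomes) && max(chromosomes) > n_chromosomes) {
    stop("chromosome number exceeds n_chromosomes")
  }
  counts <- table(factor(chromosomes, levels = seq_len(n_chromosomes)))
  counts <- stats::setNames(as.integer(counts), seq_len(n_chromosomes))
  occupied <- as.integer(names(counts)[counts > 0L])
  list(counts = counts, occupied = occupied,
       missing = setdiff(seq_len(n_chromosomes), occupied),
       n_genes = length(chromosomes))
}
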