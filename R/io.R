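#' Read a FASTA file
#'
#' Reads protein or nucleotide FASTA into a named character vector, one
#' element per record, preserving record order and identifiers byte-exact.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the full header
#'   lines (without the leading `>`).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "MK"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  if (file.size(path) == 0L) {
    stop("empty FASTA file: ", path)
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Parse the chromosome number from an MSU-style locus identifier
#'
#' Locus ids following the `LOC_OsNNgXXXXX` convention encode the chromosome
#' in the two digits after "Os". Non-conforming ids return `NA` and must
#' carry an explicit chromosome in the annotation.
#'
#' @param locus_id Character vector of locus identifiers.
#' @return Integer vector of chromosome numbers (`NA` where not parseable).
#' @examples
#' locus_chromosome("LOC_Os02g48560")  # 2
#' @export
locus_chromosome <- function(locus_id) {
  m <- regmatches(locus_id, regexec("^LOC_Os(\\d{2})g\\d+", locus_id))
  vapply(m, function(x) {
    if (length(x) == 2L) as.integer(x[2L]) else NA_integer_
  }, integer(1))
}

#' Strip the splice-variant suffix from a transcript/protein identifier
#'
#' Splice variants share a locus id and differ by a ".N" suffix on the
#' mRNA id (MSU-RGAP convention).
#'
#' @param id Character vector such as `"LOC_Os02g48560.1"`.
#' @return Locus ids with any trailing `.N` removed.
#' @export
locus_of_transcript <- function(id) {
  sub("\\.\\d+$", "", id)
}

# chromosome number from a GFF seqid like "Chr7", "chr07" or "7"
.seqid_chromosome <- function(seqid) {
  m <- regmatches(seqid, regexec("^[Cc]hr0*(\\d+)$|^0*(\\d+)$", seqid))
  vapply(m, function(x) {
    if (length(x) == 0L || all(x == "")) return(NA_integer_)
    v <- x[-1L][x[-1L] != ""]
    if (length(v)) as.integer(v[1L]) else NA_integer_
  }, integer(1))
}

#' Read a GFF3 gene annotation into gene models
#'
#' Parses gene/mRNA/exon/CDS/UTR features (via [rtracklayer::readGFF()]),
#' builds one gene model per mRNA and assigns every annotated gene an
#' ordinal rank on its chromosome by start coordinate. Coordinates are
#' 1-based inclusive throughout, as in the GFF3 standard.
#'
#' @param path Path to a GFF3 file.
#' @return An object of class `gene_annotation`: a list with
#'   \describe{
#'     \item{models}{named list of gene models, one per mRNA. Each model is a
#'       list with `mrna_id`, `locus_id`, `chromosome`, `strand`, `start`,
#'       `end`, and data frames `exons`, `cds`, `utr5`, `utr3` (columns
#'       `start`, `end`), all sorted in transcription order.}
#'     \item{gene_order}{data frame of all annotated genes (`locus_id`,
#'       `chromosome`, `start`, `end`, `strand`, `ordinal`) with ordinals
#'       unique per chromosome.}
#'   }
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gff <- as.data.frame(rtracklayer::readGFF(path))
  if (!nrow(gff)) stop("empty GFF3 file: ", path)
  gff$seqid <- as.character(gff$seqid)
  gff$type <- as.character(gff$type)
  gff$strand <- as.character(gff$strand)
  if (!"ID" %in% names(gff)) gff$ID <- NA_character_
  parent1 <- function(p) {
    vapply(p, function(x) if (length(x)) as.character(x[[1L]]) else NA_character_,
           character(1), USE.NAMES = FALSE)
  }
  gff$parent1 <- if ("Parent" %in% names(gff)) parent1(gff$Parent) else NA_character_

  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  if (!nrow(genes)) stop("no gene features in GFF3: ", path)
  if (anyNA(mrnas$parent1) || !all(mrnas$parent1 %in% genes$ID)) {
    bad <- mrnas$ID[is.na(mrnas$parent1) | !(mrnas$parent1 %in% genes$ID)]
    stop("mRNA feature(s) without a gene parent: ", paste(bad, collapse = ", "))
  }
  kids <- gff[gff$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ,
              drop = FALSE]
  if (nrow(kids) && (anyNA(kids$parent1) || !all(kids$parent1 %in% mrnas$ID))) {
    stop("exon/CDS/UTR feature(s) without an mRNA parent in ", path)
  }

  chrom <- .seqid_chromosome(genes$seqid)
  gene_order <- data.frame(
    locus_id = as.character(genes$ID),
    seqid = genes$seqid,
    chromosome = ifelse(is.na(chrom), locus_chromosome(as.character(genes$ID)), chrom),
    start = genes$start, end = genes$end, strand = genes$strand,
    stringsAsFactors = FALSE
  )
  if (anyNA(gene_order$chromosome)) {
    stop("cannot determine chromosome for gene(s): ",
         paste(gene_order$locus_id[is.na(gene_order$chromosome)], collapse = ", "))
  }
  gene_order <- gene_order[order(gene_order$chromosome, gene_order$start), ]
  gene_order$ordinal <- stats::ave(gene_order$start, gene_order$chromosome,
                                   FUN = seq_along)
  rownames(gene_order) <- NULL

  models <- lapply(seq_len(nrow(mrnas)), function(i) {
    m <- mrnas[i, ]
    mk <- kids[kids$parent1 == m$ID, , drop = FALSE]
    part <- function(type) {
      d <- mk[mk$type == type, c("start", "end"), drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (m$strand == "-") d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
      rownames(d) <- NULL
      d
    }
    list(
      mrna_id = as.character(m$ID),
      locus_id = as.character(m$parent1),
      chromosome = gene_order$chromosome[match(m$parent1, gene_order$locus_id)],
      seqid = m$seqid,
      strand = m$strand,
      start = m$start, end = m$end,
      exons = part("exon"),
      cds = part("CDS"),
      utr5 = part("five_prime_UTR"),
      utr3 = part("three_prime_UTR")
    )
  })
  names(models) <- vapply(models, `[[`, character(1), "mrna_id")
  structure(list(models = models, gene_order = gene_order),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", length(x$models), "mRNA model(s),",
      nrow(x$gene_order), "gene(s) on",
      length(unique(x$gene_order$chromosome)), "chromosome(s)\n")
  invisible(x)
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that
#' round-trip topology, branch lengths and integer bootstrap labels.
#'
#' @param path Path to a Newick file.
#' @return `read_newick`: an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr
}

#' @param tree A `phylo` object.
#' @rdname read_newick
#' @return `write_newick`: `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read / write tab-delimited tables
#'
#' UTF-8, tab-delimited, header row; never converts strings to factors.
#'
#' @param path File path.
#' @return `read_tsv_file`: a data frame.
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

#' @param x Data frame to write.
#' @rdname read_tsv_file
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
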