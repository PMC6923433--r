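# Pairwise protein alignment statistics feeding the homology screen and the
# duplication classifiers. The dynamic programming itself is
# Biostrings::pairwiseAlignment (Gotoh affine-gap, deterministic traceback);
# this module derives the identity/similarity/coverage statistics the
# duplication rules are phrased in, and Karlin-Altschul E-values for the
# local mode.

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

.aln_stats <- function(a_aln, b_aln, submat) {
  a <- strsplit(a_aln, "")[[1L]]
  b <- strsplit(b_aln, "")[[1L]]
  stopifnot(length(a) == length(b))
  L <- length(a)
  gap_a <- a == "-"
  gap_b <- b == "-"
  both <- !gap_a & !gap_b
  ident <- sum(both & a == b)
  # non-terminal-gap span: trim leading/trailing columns where either row
  # has a gap
  span <- which(both)
  if (length(span)) {
    s0 <- span[1L]; s1 <- span[length(span)]
    in_span <- seq.int(s0, s1)
  } else {
    in_span <- integer()
  }
  pos <- 0L
  if (length(in_span)) {
    bi <- both[in_span]
    ai <- a[in_span][bi]; bj <- b[in_span][bi]
    pos <- sum(submat[cbind(ai, bj)] > 0)
  }
  len_a <- sum(!gap_a); len_b <- sum(!gap_b)
  longer <- max(len_a, len_b)
  # residues of the longer sequence that fall inside the aligned span
  if (len_a >= len_b) {
    cov_res <- sum(!gap_a[in_span])
  } else {
    cov_res <- sum(!gap_b[in_span])
  }
  list(
    identity = ident / L,
    similarity = if (length(in_span)) pos / length(in_span) else 0,
    coverage = cov_res / longer
  )
}

.check_protein <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
    stop("non-empty protein sequence required for ", what)
  }
  aa <- strsplit(x, "")[[1L]]
  bad <- setdiff(unique(aa), names(.aa_masses))
  if (length(bad)) {
    stop("invalid residue(s) in ", what, ": ", paste(bad, collapse = ","))
  }
  invisible(x)
}

#' Global pairwise protein alignment
#'
#' Optimal affine-gap (Gotoh) global alignment with EMBOSS-needle default
#' penalties. A gap of length L costs `gap_open + L * gap_extend`.
#' Identity is the fraction of identical columns over the full alignment
#' length; similarity is the fraction of positive-substitution columns
#' within the non-terminal-gap span; coverage is the fraction of the longer
#' sequence falling inside that span.
#'
#' @param a,b Protein sequences (strings).
#' @param substitution_matrix Scoring matrix (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A `pairwise_alignment`: list with `a_aln`, `b_aln` (gapped
#'   strings), `score`, `identity`, `similarity`, `coverage`,
#'   `evalue` (`NA` in global mode).
#' @examples
#' global_align("MKV", "MRV")$identity  # 2/3
#' @export
global_align <- function(a, b, substitution_matrix = NULL,
                         gap_open = 10, gap_extend = 0.5) {
  .check_protein(a, "global_align")
  .check_protein(b, "global_align")
  if (is.null(substitution_matrix)) substitution_matrix <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  a_aln <- as.character(Biostrings::alignedPattern(pa))
  b_aln <- as.character(Biostrings::alignedSubject(pa))
  st <- .aln_stats(a_aln, b_aln, substitution_matrix)
  structure(list(a_aln = a_aln, b_aln = b_aln,
                 score = Biostrings::score(pa),
                 identity = st$identity, similarity = st$similarity,
                 coverage = st$coverage, evalue = NA_real_),
            class = "pairwise_alignment")
}

#' Local pairwise alignment with a Karlin-Altschul E-value
#'
#' Smith-Waterman optimal local alignment; the E-value for score S over
#' sequences of lengths m and n is `E = K * m * n * exp(-lambda * S)`.
#' Default lambda/K are gapped BLOSUM62 constants. The local score is
#' floored at zero, so two sequences with no positive-scoring residue pair
#' give `E = K * m * n`.
#'
#' @inheritParams global_align
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @return A `pairwise_alignment` with `evalue` set.
#' @export
local_align_evalue <- function(a, b, substitution_matrix = NULL,
                               gap_open = 10, gap_extend = 0.5,
                               lambda = 0.267, K = 0.041) {
  .check_protein(a, "local_align_evalue")
  .check_protein(b, "local_align_evalue")
  stopifnot(lambda > 0, K > 0)
  if (is.null(substitution_matrix)) substitution_matrix <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  S <- max(Biostrings::score(pa), 0)
  a_aln <- as.character(Biostrings::alignedPattern(pa))
  b_aln <- as.character(Biostrings::alignedSubject(pa))
  st <- .aln_stats(a_aln, b_aln, substitution_matrix)
  m <- nchar(a); n <- nchar(b)
  structure(list(a_aln = a_aln, b_aln = b_aln, score = S,
                 identity = st$identity, similarity = st$similarity,
                 coverage = st$coverage,
                 evalue = K * m * n * exp(-lambda * S)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "pairwise_alignment: score %.1f identity %.3f similarity %.3f coverage %.3f%s\n",
    x$score, x$identity, x$similarity, x$coverage,
    if (is.na(x$evalue)) "" else sprintf(" E=%.3g", x$evalue)))
  invisible(x)
}

#' Karlin-Altschul E-value formula
#'
#' `E = K * m * n * exp(-lambda * S)` for a local alignment score `S`
#' between sequences of lengths `m` and `n`.
#'
#' @param S Local alignment score.
#' @param m,n Sequence lengths.
#' @param lambda,K Karlin-Altschul parameters.
#' @return The expected number of chance alignments with score >= S.
#' @examples
#' karlin_altschul_evalue(100, 400, 400)  # ~1.66e-8
#' @export
karlin_altschul_evalue <- function(S, m, n, lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0, m > 0, n > 0)
  K * m * n * exp(-lambda * S)
}
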