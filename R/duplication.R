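# Tandem and segmental duplication classification. The tandem rule is
# "separation by less than 5 intervening annotated genes on one chromosome
# and > 50% protein identity"; the segmental rule is "alignable region
# covers > 75% of the longer protein and similarity of the aligned region
# > 75%". Both thresholds are strict inequalities.

.family_frame <- function(family) {
  need <- c("name", "locus_id", "chromosome", "ordinal", "protein")
  miss <- setdiff(need, names(family))
  if (length(miss)) {
    stop("family table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyNA(family$ordinal)) {
    stop("missing genome-wide ordinal for locus ",
         paste(family$locus_id[is.na(family$ordinal)], collapse = ", "))
  }
  family
}

#' Call tandem duplications
#'
#' A pair of family members qualifies iff they lie on the same chromosome,
#' fewer than `max_intervening + 1` annotated genes lie strictly between
#' them (any strand, using genome-wide gene ordinals), and their global
#' protein identity exceeds `min_identity`. Tandem clusters are the
#' single-linkage closure of qualifying pairs.
#'
#' @param family Data frame with columns `name`, `locus_id`, `chromosome`,
#'   `ordinal` (rank among all annotated genes on the chromosome) and
#'   `protein` (sequence).
#' @param max_intervening Maximum intervening gene count (default 4,
#'   i.e. "less than 5").
#' @param min_identity Identity threshold (strict `>`).
#' @return List with `clusters` (list of member-name vectors) and `pairs`
#'   (data frame of qualifying pairs with the supporting evidence:
#'   intervening count and identity).
#' @export
call_tandem <- function(family, max_intervening = 4L, min_identity = 0.5) {
  family <- .family_frame(family)
  n <- nrow(family)
  pairs <- list()
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      if (family$chromosome[i] != family$chromosome[j]) next
      intervening <- abs(family$ordinal[i] - family$ordinal[j]) - 1L
      if (intervening > max_intervening) next
      aln <- global_align(family$protein[i], family$protein[j])
      if (aln$identity <= min_identity) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        a = family$name[i], b = family$name[j],
        chromosome = family$chromosome[i],
        intervening = intervening, identity = aln$identity,
        stringsAsFactors = FALSE)
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a = character(), b = character(), chromosome = integer(),
               intervening = integer(), identity = numeric(),
               stringsAsFactors = FALSE)
  roots <- vapply(seq_len(n), find, integer(1))
  in_pair <- family$name %in% c(pairs$a, pairs$b)
  clusters <- split(family$name[in_pair], roots[in_pair])
  clusters <- unname(clusters[lengths(clusters) >= 2L])
  list(clusters = clusters, pairs = pairs)
}

#' Call segmental duplications
#'
#' Tests every unordered family pair that does not lie within one tandem
#' cluster; a pair is segmental iff alignment coverage of the longer
#' protein > `min_coverage` and similarity of the aligned region
#' > `min_similarity` (both strict). A gene may carry both labels via
#' different partners.
#'
#' @inheritParams call_tandem
#' @param tandem_clusters Cluster list from [call_tandem()] (pairs inside
#'   one cluster are skipped so the two mechanisms are reported disjointly
#'   per pair).
#' @param min_coverage,min_similarity Strict thresholds (default 0.75).
#' @return Data frame of segmental pairs with coverage and similarity.
#' @export
call_segmental <- function(family, tandem_clusters = list(),
                           min_coverage = 0.75, min_similarity = 0.75) {
  family <- .family_frame(family)
  n <- nrow(family)
  same_cluster <- function(a, b) {
    any(vapply(tandem_clusters, function(cl) all(c(a, b) %in% cl), logical(1)))
  }
  rows <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      if (same_cluster(family$name[i], family$name[j])) next
      aln <- global_align(family$protein[i], family$protein[j])
      if (aln$coverage > min_coverage && aln$similarity > min_similarity) {
        rows[[length(rows) + 1L]] <- data.frame(
          a = family$name[i], b = family$name[j],
          chromosome_a = family$chromosome[i],
          chromosome_b = family$chromosome[j],
          coverage = aln$coverage, similarity = aln$similarity,
          identity = aln$identity, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), chromosome_a = integer(),
               chromosome_b = integer(), coverage = numeric(),
               similarity = numeric(), identity = numeric(),
               stringsAsFactors = FALSE)
}

#' Summarize duplication calls
#'
#' @param tandem Result of [call_tandem()].
#' @param segmental Result of [call_segmental()].
#' @param family_size Number of genes in the family.
#' @return List with per-mechanism gene counts, the overlap (genes carrying
#'   both labels), and `pct_duplicated` = 100 * |union| / family size.
#' @export
duplication_summary <- function(tandem, segmental, family_size) {
  tgenes <- unique(unlist(tandem$clusters))
  sgenes <- unique(c(segmental$a, segmental$b))
  uni <- union(tgenes, sgenes)
  list(
    n_tandem_genes = length(tgenes),
    n_segmental_genes = length(sgenes),
    tandem_genes = sort(tgenes),
    segmental_genes = sort(sgenes),
    overlap = sort(intersect(tgenes, sgenes)),
    n_duplicated = length(uni),
    pct_duplicated = if (family_size > 0) 100 * length(uni) / family_size else 0
  )
}
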