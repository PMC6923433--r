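# Candidate identification by three routes (domain evidence, local-alignment
# homology at E <= 1e-10, annotation keyword search), redundancy removal and
# subfamily-based naming.

#' Domain-evidence candidate screen
#'
#' Mode (a): a precomputed tabular domain-hit file (columns `protein_id`,
#' `domain`, `evalue`) from an external profile search. Mode (b), the
#' internal fallback: proteins matching at least `min_boxes` distinct
#' histidine-box patterns (see [scan_hboxes()]) are taken as carrying
#' domain evidence. The mode used is recorded in the result.
#'
#' @param proteome Named character vector of protein sequences (ids carry
#'   the locus with a ".N" splice suffix).
#' @param domain_hits Optional domain-hit data frame (mode a).
#' @param patterns Compiled motif patterns for mode (b); defaults to all
#'   packaged H-box patterns.
#' @param min_boxes Distinct patterns required in fallback mode.
#' @return List with `loci` (character vector), `mode`
#'   (`"hit_table"`/`"hbox_fallback"`), and `evidence` (per-protein detail).
#' @export
domain_screen <- function(proteome = NULL, domain_hits = NULL,
                          patterns = NULL, min_boxes = 2L) {
  if (!is.null(domain_hits)) {
    stopifnot(all(c("protein_id", "domain", "evalue") %in% names(domain_hits)))
    loci <- unique(locus_of_transcript(domain_hits$protein_id))
    return(list(loci = loci, mode = "hit_table", evidence = domain_hits))
  }
  if (is.null(proteome)) {
    stop("configuration error: neither a domain-hit table nor a proteome ",
         "for the H-box fallback was supplied")
  }
  if (is.null(patterns)) patterns <- hbox_patterns()
  n_boxes <- vapply(names(proteome), function(id) {
    sc <- scan_hboxes(proteome[[id]], patterns)
    length(unique(sc$hits$pattern))
  }, integer(1))
  keep <- names(proteome)[n_boxes >= min_boxes]
  list(loci = unique(locus_of_transcript(keep)), mode = "hbox_fallback",
       evidence = data.frame(protein_id = names(proteome),
                             n_box_patterns = n_boxes,
                             stringsAsFactors = FALSE))
}

#' Homology candidate screen with Karlin-Altschul E-values
#'
#' Smith-Waterman local alignment of every proteome entry against each
#' query; the best E-value across queries is kept and the entry passes iff
#' E <= `evalue_max` (default 1e-10, the BLASTP cutoff used for
#' family surveys).
#'
#' @param queries Named character vector of query proteins (e.g. the
#'   Arabidopsis subfamily representatives).
#' @param proteome Named character vector of target proteins.
#' @param evalue_max Inclusion threshold.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Data frame `protein_id`, `locus_id`, `best_evalue`,
#'   `matched_query` for passing entries.
#' @export
homology_screen <- function(queries, proteome, evalue_max = 1e-10,
                            lambda = 0.267, K = 0.041) {
  if (!length(queries)) stop("empty query set")
  stopifnot(!is.null(names(queries)), !is.null(names(proteome)))
  rows <- lapply(names(proteome), function(id) {
    ev <- vapply(names(queries), function(q) {
      local_align_evalue(queries[[q]], proteome[[id]],
                         lambda = lambda, K = K)$evalue
    }, numeric(1))
    best <- which.min(ev)
    data.frame(protein_id = id, locus_id = locus_of_transcript(id),
               best_evalue = ev[best], matched_query = names(queries)[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$best_evalue <= evalue_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keyword candidate screen
#'
#' Case-insensitive substring match of `phrase` against the functional
#' annotation description of each locus.
#'
#' @param annotation Data frame with columns `locus_id`, `description`.
#' @param phrase Search phrase (default "fatty acid desaturase").
#' @return Character vector of matching locus ids.
#' @export
keyword_screen <- function(annotation, phrase = "fatty acid desaturase") {
  stopifnot(all(c("locus_id", "description") %in% names(annotation)))
  hit <- grepl(phrase, annotation$description, ignore.case = TRUE,
               fixed = FALSE)
  unique(annotation$locus_id[hit])
}

#' Merge evidence sets and remove redundancy
#'
#' Takes the union of candidate loci over all evidence routes, then keeps
#' one representative transcript per locus: the longest protein, ties
#' broken by the lowest ".N" splice suffix. Manually included loci (the
#' published precedent: a truncated member undetectable by domain search
#' but retained on literature evidence) are added with a `manual_include`
#' flag; a manual id absent from the proteome is an error.
#'
#' @param evidence_sets Named list of character vectors of locus ids (e.g.
#'   `list(domain = ..., homology = ..., keyword = ...)`).
#' @param proteome Named character vector of proteins (ids = transcript
#'   ids).
#' @param manual_include Character vector of locus ids to force-include.
#' @return Data frame `locus_id`, `protein_id` (representative),
#'   `protein`, `length`, `sources` (comma string), `manual_include`.
#' @export
merge_and_deduplicate <- function(evidence_sets, proteome,
                                  manual_include = character()) {
  stopifnot(length(evidence_sets) >= 1L, !is.null(names(proteome)))
  prot_loci <- locus_of_transcript(names(proteome))
  if (length(manual_include)) {
    absent <- setdiff(manual_include, prot_loci)
    if (length(absent)) {
      stop("manual include id(s) absent from proteome: ",
           paste(absent, collapse = ", "))
    }
  }
  loci <- sort(unique(c(unlist(evidence_sets, use.names = FALSE),
                        manual_include)))
  rows <- lapply(loci, function(lc) {
    ids <- names(proteome)[prot_loci == lc]
    if (!length(ids)) return(NULL)  # evidence locus without protein record
    len <- nchar(proteome[ids])
    suffix <- suppressWarnings(
      as.integer(sub(".*\\.(\\d+)$", "\\1", ids)))
    suffix[is.na(suffix)] <- 1L
    o <- order(-len, suffix)
    rep_id <- ids[o[1L]]
    src <- names(evidence_sets)[vapply(evidence_sets, function(s) lc %in% s,
                                       logical(1))]
    if (lc %in% manual_include) src <- union(src, "manual")
    src <- sort(unique(src))  # canonical order: merge is order-independent
    data.frame(locus_id = lc, protein_id = rep_id,
               protein = unname(proteome[[rep_id]]),
               length = nchar(proteome[[rep_id]]),
               sources = paste(src, collapse = ","),
               manual_include = lc %in% manual_include,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign subfamily-based gene names
#'
#' Names follow `"<prefix><SUBFAMILY>-<k>"`, numbered within each subfamily
#' by (chromosome, start) ascending; singleton subfamilies are left
#' unnumbered (e.g. a lone plastidial omega-6 desaturase is just
#' `OsFAD6`). A user override map is applied last; duplicate override
#' names are an error. "/" characters in subfamily labels are dropped in
#' names (FAD3/7/8 -> OsFAD378-k by default, typically overridden with the
#' historical per-gene names).
#'
#' @param candidates Data frame with columns `locus_id`, `subfamily`,
#'   `chromosome`, `start`.
#' @param prefix Species prefix (default "Os").
#' @param overrides Named character vector locus_id -> final name.
#' @return `candidates` with a `name` column added.
#' @export
assign_family_names <- function(candidates, prefix = "Os", overrides = NULL) {
  stopifnot(all(c("locus_id", "subfamily", "chromosome", "start") %in%
                  names(candidates)))
  if (anyNA(candidates$subfamily)) stop("every candidate needs a subfamily")
  o <- order(candidates$subfamily, candidates$chromosome, candidates$start)
  candidates$name <- NA_character_
  for (sf in unique(candidates$subfamily)) {
    idx <- o[candidates$subfamily[o] == sf]
    label <- paste0(prefix, gsub("/", "", sf))
    candidates$name[idx] <- if (length(idx) == 1L) label else
      paste0(label, "-", seq_along(idx))
  }
  if (!is.null(overrides)) {
    if (anyDuplicated(overrides)) stop("duplicate override names")
    hit <- match(names(overrides), candidates$locus_id)
    if (anyNA(hit)) {
      stop("override for unknown locus: ",
           paste(names(overrides)[is.na(hit)], collapse = ", "))
    }
    candidates$name[hit] <- unname(overrides)
  }
  if (anyDuplicated(candidates$name)) stop("duplicate gene names after naming")
  candidates
}
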