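# End-to-end orchestration: identification -> characterization -> phylogeny
# -> duplication -> promoters (-> expression when matrices are supplied),
# with a machine-readable report and full parameter provenance.

.load_input <- function(x, loader) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) loader(x) else x
}

#' Run the full gene-family survey
#'
#' Stages run in dependency order: candidate identification (domain
#' evidence, homology screen, keyword screen; union by locus, one
#' representative transcript per locus), subfamily assignment against
#' anchor sequences, naming, protein characterization and H-box scan,
#' gene structure and chromosomal distribution, NJ phylogeny with
#' bootstrap supports, tandem/segmental duplication calling, and promoter
#' element scanning. Reruns with identical inputs and seed are
#' byte-identical.
#'
#' @param inputs List with components `proteome` (named character vector or
#'   FASTA path), `annotation` (`gene_annotation` or GFF3 path),
#'   `genome` (named character vector or FASTA path),
#'   `annotation_table` (data frame `locus_id`, `description`, or TSV
#'   path), and optionally `domain_hits`, `queries` (named character
#'   vector of query/anchor proteins), `anchors` (data frame `anchor_id`,
#'   `subfamily`), `manual_include`, `elements`, `expression` (list `mat`,
#'   `meta`), `name_overrides`.
#' @param params List of stage parameters; recognized entries (with
#'   defaults): `evalue_max` (1e-10), `max_intervening` (4),
#'   `min_identity` (0.5), `min_coverage` (0.75), `min_similarity` (0.75),
#'   `bootstrap` (100), `seed` (1), `promoter_length` (2000), `tau_high`,
#'   `tau_low`, `f_high` (0.8), `keyword` ("fatty acid desaturase"),
#'   `name_prefix` ("Os"), `run_phylogeny` (TRUE), `run_promoter` (TRUE).
#' @param out_dir Optional output directory; when given, the report and
#'   stage tables are written there.
#' @return A `survey_report` list: `family` roster, `features`,
#'   `structure`, `chromosomes`, `phylogeny` (Newick string with
#'   supports), `subfamily_assignment`, `duplication`, `promoter`,
#'   `expression`, `provenance`.
#' @export
run_pipeline <- function(inputs, params = list(), out_dir = NULL) {
  p <- utils::modifyList(list(
    evalue_max = 1e-10, max_intervening = 4L, min_identity = 0.5,
    min_coverage = 0.75, min_similarity = 0.75, bootstrap = 100L,
    seed = 1L, promoter_length = 2000L, tau_high = NULL, tau_low = NULL,
    f_high = 0.8, keyword = "fatty acid desaturase", name_prefix = "Os",
    run_phylogeny = TRUE, run_promoter = TRUE), params)

  proteome <- .load_input(inputs$proteome, read_fasta)
  annotation <- .load_input(inputs$annotation, read_gff3)
  genome <- if (!is.null(inputs$genome)) .load_input(inputs$genome, read_fasta)
  ann_tab <- .load_input(inputs$annotation_table, read_tsv_file)
  if (is.null(proteome) || is.null(annotation)) {
    stop("pipeline requires at least a proteome and a GFF3 annotation")
  }

  ## -- identification -------------------------------------------------------
  evidence <- list()
  dom <- domain_screen(proteome = proteome, domain_hits = inputs$domain_hits)
  evidence$domain <- dom$loci
  hom <- NULL
  if (!is.null(inputs$queries)) {
    hom <- homology_screen(inputs$queries, proteome,
                           evalue_max = p$evalue_max)
    evidence$homology <- unique(hom$locus_id)
  }
  if (!is.null(ann_tab)) {
    evidence$keyword <- keyword_screen(ann_tab, p$keyword)
  }
  candidates <- merge_and_deduplicate(evidence, proteome,
                                      manual_include = inputs$manual_include %||%
                                        character())
  if (is.null(candidates) || !nrow(candidates)) {
    stop("identification produced no candidates")
  }
  go <- annotation$gene_order
  hit <- match(candidates$locus_id, go$locus_id)
  if (anyNA(hit)) {
    stop("candidate locus missing from annotation: ",
         paste(candidates$locus_id[is.na(hit)], collapse = ", "))
  }
  candidates$chromosome <- go$chromosome[hit]
  candidates$start <- go$start[hit]
  candidates$end <- go$end[hit]
  candidates$strand <- go$strand[hit]
  candidates$ordinal <- go$ordinal[hit]

  ## -- subfamily assignment + phylogeny -------------------------------------
  tree_newick <- NULL; assignment <- NULL; msa <- NULL
  if (isTRUE(p$run_phylogeny) && !is.null(inputs$queries) &&
      !is.null(inputs$anchors)) {
    seqs <- c(stats::setNames(candidates$protein, candidates$locus_id),
              inputs$queries)
    msa <- progressive_align(seqs)
    d <- poisson_distance(msa)
    assignment <- assign_subfamilies(d, inputs$anchors)
    candidates$subfamily <- assignment$subfamily[
      match(candidates$locus_id, assignment$gene)]
  }
  if (is.null(candidates$subfamily)) {
    candidates$subfamily <- "unassigned"
  }
  candidates <- assign_family_names(candidates, prefix = p$name_prefix,
                                    overrides = inputs$name_overrides)
  if (!is.null(msa)) {
    # tree over the named family members plus anchors
    relabel <- msa
    relabel$rows <- stats::setNames(
      msa$rows, ifelse(msa$taxa %in% candidates$locus_id,
                       candidates$name[match(msa$taxa, candidates$locus_id)],
                       msa$taxa))
    relabel$taxa <- names(relabel$rows)
    tree <- bootstrap_support(relabel, B = p$bootstrap, seed = p$seed)
    tree_newick <- ape::write.tree(tree, digits = 10)
  }

  ## -- features -------------------------------------------------------------
  feats <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
    st <- tryCatch(protein_stats(candidates$protein[i]),
                   error = function(e) list(length = nchar(candidates$protein[i]),
                                            mw = NA_real_, pi = NA_real_))
    sf <- candidates$subfamily[i]
    complete <- NA
    if (sf %in% hbox_patterns(compiled = FALSE)$subfamily) {
      tab <- hbox_patterns(sf, compiled = FALSE)
      tab <- tab[tab$box %in% c("1", "2", "3"), , drop = FALSE]
      pats <- lapply(seq_len(nrow(tab)), function(k)
        compile_hbox_pattern(tab$pattern[k],
                             name = paste0(sf, ".box", tab$box[k])))
      complete <- scan_hboxes(candidates$protein[i], pats)$complete
    }
    data.frame(name = candidates$name[i], length = st$length, mw = st$mw,
               pi = st$pi, hbox_complete = complete, stringsAsFactors = FALSE)
  }))

  ## -- structure + chromosome distribution ----------------------------------
  fam_models <- annotation$models[
    vapply(annotation$models, function(m)
      m$mrna_id %in% candidates$protein_id, logical(1))]
  struct <- structure_report(fam_models)
  struct$name <- candidates$name[match(struct$locus_id, candidates$locus_id)]
  chrdist <- chromosome_distribution(candidates$chromosome,
                                     n_chromosomes = max(go$chromosome))

  ## -- duplication ----------------------------------------------------------
  tandem <- call_tandem(candidates, max_intervening = p$max_intervening,
                        min_identity = p$min_identity)
  segmental <- call_segmental(candidates, tandem$clusters,
                              min_coverage = p$min_coverage,
                              min_similarity = p$min_similarity)
  dup <- duplication_summary(tandem, segmental, nrow(candidates))

  ## -- promoters ------------------------------------------------------------
  promoter <- NULL
  if (isTRUE(p$run_promoter) && !is.null(genome)) {
    elements <- inputs$elements %||% cis_element_table()
    hits_by_gene <- list()
    for (i in seq_len(nrow(candidates))) {
      model <- annotation$models[[candidates$protein_id[i]]]
      prom <- extract_promoter(genome, model, length = p$promoter_length)
      hits_by_gene[[candidates$name[i]]] <- scan_elements(prom, elements)
    }
    promoter <- list(hits = hits_by_gene,
                     summary = summarize_elements(hits_by_gene, elements))
  }

  ## -- expression (optional) ------------------------------------------------
  expression <- NULL
  if (!is.null(inputs$expression)) {
    ex <- inputs$expression
    means <- average_log2(ex$mat, ex$meta)
    cats <- stats::setNames(ex$meta$category, ex$meta$tissue)
    cats <- cats[!duplicated(names(cats))]
    expression <- list(
      means = means,
      groups = classify_groups(means, cats, tau_high = p$tau_high,
                               tau_low = p$tau_low, f_high = p$f_high))
  }

  report <- structure(list(
    family = candidates[, setdiff(names(candidates), "protein")],
    features = feats, structure = struct, chromosomes = chrdist,
    phylogeny = tree_newick, subfamily_assignment = assignment,
    duplication = list(tandem = tandem, segmental = segmental,
                       summary = dup),
    promoter = promoter, expression = expression,
    provenance = list(
      package = "famsurvey",
      version = as.character(utils::packageVersion("famsurvey")),
      params = p,
      n_proteome = length(proteome),
      n_annotated_genes = nrow(go),
      evidence_counts = lapply(evidence, length))),
    class = "survey_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.survey_report <- function(x, ...) {
  cat("survey_report:", nrow(x$family), "family genes;",
      x$duplication$summary$n_tandem_genes, "tandem /",
      x$duplication$summary$n_segmental_genes, "segmental duplicated (",
      sprintf("%.1f%%", x$duplication$summary$pct_duplicated), ")\n")
  invisible(x)
}

#' Write a survey report to disk
#'
#' Emits `family.tsv`, `features.tsv`, `structure.tsv`, `duplication.tsv`,
#' `tree.nwk` (when present) and `report.json` under `dir`.
#'
#' @param report A `survey_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(report$family, file.path(dir, "family.tsv"))
  write_tsv_file(report$features, file.path(dir, "features.tsv"))
  write_tsv_file(report$structure, file.path(dir, "structure.tsv"))
  if (nrow(report$duplication$segmental)) {
    write_tsv_file(report$duplication$segmental,
                   file.path(dir, "segmental.tsv"))
  }
  if (!is.null(report$phylogeny)) {
    writeLines(report$phylogeny, file.path(dir, "tree.nwk"))
  }
  json <- list(
    family = report$family,
    chromosomes = list(counts = as.list(report$chromosomes$counts),
                       missing = report$chromosomes$missing),
    duplication = list(
      tandem_clusters = report$duplication$tandem$clusters,
      n_tandem_genes = report$duplication$summary$n_tandem_genes,
      n_segmental_genes = report$duplication$summary$n_segmental_genes,
      pct_duplicated = report$duplication$summary$pct_duplicated),
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
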