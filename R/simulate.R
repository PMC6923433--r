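# Seeded synthetic-data generator: annotated multi-chromosome genomes
# carrying a planted desaturase-like gene family (tandem arrays, diverged
# segmental duplicate pairs, histidine boxes, promoters with planted
# cis-elements), tissue expression matrices with four group archetypes, and
# qPCR Ct tables with known fold changes. Every planted feature is recorded
# in a machine-readable truth record so downstream classifiers can be scored
# for recall and precision without any external download.

.residues <- names(.aa_masses)

# residues substituting residue r with BLOSUM62 score <= 0 (never r itself);
# mutations drawn from these sets leave the positive-substitution fraction
# equal to the retained-position fraction, so planted similarity targets are
# hit directly.
.nonpositive_subs <- function() {
  B <- .blosum62()
  sets <- lapply(.residues, function(r) {
    cand <- setdiff(.residues, r)
    cand[B[r, cand] <= 0]
  })
  names(sets) <- .residues
  sets
}

.random_protein <- function(len, first_m = FALSE) {
  s <- sample(.residues, len, replace = TRUE)
  if (first_m) s[1L] <- "M"
  paste(s, collapse = "")
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# realize one concrete instance of a compiled motif pattern
.realize_pattern <- function(pat) {
  paste(vapply(pat$tokens, function(tok) {
    if (is.null(tok)) sample(.residues, 1L) else
      tok[sample.int(length(tok), 1L)]
  }, character(1)), collapse = "")
}

# independent regex matcher used for truth computation and rejection repair
# (scan_hboxes itself stays the route under test)
.hbox_regex <- function(pat) {
  paste0("(?=", paste(vapply(pat$tokens, function(tok) {
    if (is.null(tok)) "." else if (length(tok) == 1L) tok else
      paste0("[", paste(tok, collapse = ""), "]")
  }, character(1)), collapse = ""), ")")
}

.regex_hits0 <- function(seq, rx) {
  m <- gregexpr(rx, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m) - 1L
}

# mutate sequence so that no pattern matches outside its protected window
.repair_protein <- function(seq, patterns, protected, expected, max_iter = 200L) {
  rx <- lapply(patterns, .hbox_regex)
  plen <- vapply(patterns, function(p) length(p$tokens), integer(1))
  for (iter in seq_len(max_iter)) {
    offending <- NULL
    for (k in seq_along(patterns)) {
      hits <- .regex_hits0(seq, rx[[k]])
      exp_k <- expected$start0[expected$pattern == patterns[[k]]$name]
      bad <- setdiff(hits, exp_k)
      if (length(bad)) {
        offending <- c(bad[1L] + 1L, plen[k]); break
      }
      if (!all(exp_k %in% hits)) {
        stop("planted motif lost during repair; pattern ",
             patterns[[k]]$name)
      }
    }
    if (is.null(offending)) return(seq)
    span <- seq.int(offending[1L], offending[1L] + offending[2L] - 1L)
    span <- setdiff(span, protected)
    if (!length(span)) stop("cannot repair accidental motif inside a planted window")
    at <- sample(span, 1L)
    substr(seq, at, at) <- sample(.residues, 1L)
  }
  stop("motif rejection sampling did not converge")
}

#' Simulate proteins carrying planted histidine boxes
#'
#' Each protein contains each of the subfamily's box patterns exactly once,
#' at recorded 0-based offsets; background residues are rejection-repaired
#' so no pattern matches anywhere else. `n = 0` returns an empty set.
#'
#' @param subfamily Subfamily label with packaged patterns (see
#'   [hbox_patterns()]).
#' @param n Number of proteins.
#' @param length Protein length (residues); must exceed the planted
#'   pattern footprint.
#' @param seed Mandatory integer seed.
#' @param patterns Compiled patterns to plant; defaults to the subfamily's
#'   canonical boxes (generic core rows excluded from planting).
#' @return List with `proteins` (named character) and `truth` (data frame
#'   `protein`, `pattern`, `start0`).
#' @export
simulate_proteins_with_boxes <- function(subfamily, n, length = 300L, seed,
                                         patterns = NULL) {
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  if (is.null(patterns)) {
    tab <- hbox_patterns(subfamily, compiled = FALSE)
    tab <- tab[tab$box %in% c("1", "2", "3"), , drop = FALSE]
    patterns <- lapply(seq_len(nrow(tab)), function(i) {
      compile_hbox_pattern(tab$pattern[i],
                           name = paste0(tab$subfamily[i], ".box", tab$box[i]))
    })
  }
  plen <- vapply(patterns, function(p) base::length(p$tokens), integer(1))
  if (length < sum(plen) + 5L * base::length(patterns)) {
    stop("protein length ", length, " too short for planted patterns")
  }
  if (n == 0L) {
    return(list(proteins = stats::setNames(character(), character()),
                truth = data.frame(protein = character(), pattern = character(),
                                   start0 = integer(), stringsAsFactors = FALSE)))
  }
  # spread boxes over the first ~70% so downstream truncations keep them
  anchors <- floor(length * seq(0.1, 0.62, length.out = base::length(patterns)))
  proteins <- character(n)
  truth <- list()
  for (i in seq_len(n)) {
    repeat {
      seq <- .random_protein(length, first_m = TRUE)
      prot <- integer()
      exp <- data.frame(pattern = character(), start0 = integer(),
                        stringsAsFactors = FALSE)
      for (k in seq_along(patterns)) {
        at <- anchors[k] + 1L
        inst <- .realize_pattern(patterns[[k]])
        substr(seq, at, at + plen[k] - 1L) <- inst
        prot <- c(prot, seq.int(at, at + plen[k] - 1L))
        exp <- rbind(exp, data.frame(pattern = patterns[[k]]$name,
                                     start0 = at - 1L, stringsAsFactors = FALSE))
      }
      seq <- tryCatch(.repair_protein(seq, patterns, c(1L, prot), exp),
                      error = function(e) NULL)
      if (!is.null(seq)) break
    }
    proteins[i] <- seq
    truth[[i]] <- cbind(protein = paste0(subfamily, "_", i), exp)
  }
  names(proteins) <- paste0(subfamily, "_", seq_len(n))
  list(proteins = proteins, truth = do.call(rbind, truth))
}

# mutate `m_frac` of the sequence (outside protected positions) using
# non-positive BLOSUM62 substitutions
.mutate_protein <- function(seq, m_frac, protected = integer(), subs) {
  L <- nchar(seq)
  m <- round(m_frac * L)
  pool <- setdiff(seq_len(L), protected)
  if (m > base::length(pool)) stop("mutation load exceeds mutable positions")
  if (m == 0L) return(seq)
  at <- sample(pool, m)
  aa <- strsplit(seq, "")[[1L]]
  aa[at] <- vapply(aa[at], function(r) sample(subs[[r]], 1L), character(1))
  paste(aa, collapse = "")
}

## ---------------------------------------------------------------------------
## family simulation config

#' Configuration for the synthetic family genome
#'
#' Defaults describe a 20-member family in six subfamilies spread over six
#' chromosomes, containing one 3-gene tandem array (2 intervening genes,
#' pairwise identity 0.6 along the duplication chain), one 2-gene tandem
#' array, and two diverged segmental duplicate pairs planted at coverage
#' and similarity 0.85 -- a structure with 5 tandem and 4 segmental genes,
#' i.e. 45% of the family duplicated. All randomness flows from `seed`.
#'
#' @param seed Mandatory integer seed.
#' @param n_chromosomes,n_background_genes Genome shape.
#' @param protein_length Family protein length (residues).
#' @param background_protein_length Background protein length.
#' @param subfamilies Named integer vector: members per subfamily.
#' @param base_divergence Mutation fraction of each member from its
#'   subfamily ancestor.
#' @param tandem_specs List of lists `(subfamily, size, intervening,
#'   identity)`.
#' @param segmental_specs List of lists `(subfamily, coverage, similarity)`.
#' @param tolerance Verification tolerance on planted identity / coverage /
#'   similarity.
#' @param splice_variant_gene Family gene index (emission order) receiving a
#'   second, shorter splice variant when that gene is intronless (0
#'   disables).
#' @return A `family_sim_config` list.
#' @export
family_sim_config <- function(seed,
                              n_chromosomes = 6L,
                              n_background_genes = 40L,
                              protein_length = 300L,
                              background_protein_length = 80L,
                              subfamilies = c(FAB2 = 9L, FAD2 = 4L,
                                              "FAD3/7/8" = 4L, FAD6 = 1L,
                                              DES1 = 1L, SLD1 = 1L),
                              base_divergence = 0.25,
                              tandem_specs = list(
                                list(subfamily = "FAD2", size = 3L,
                                     intervening = 2L, identity = 0.6),
                                list(subfamily = "FAB2", size = 2L,
                                     intervening = 1L, identity = 0.6)),
                              segmental_specs = list(
                                list(subfamily = "FAB2", coverage = 0.85,
                                     similarity = 0.85),
                                list(subfamily = "FAD3/7/8", coverage = 0.85,
                                     similarity = 0.85)),
                              tolerance = 0.03,
                              splice_variant_gene = 3L) {
  if (missing(seed)) stop("an explicit seed is required (no hidden entropy)")
  for (ts in tandem_specs) {
    if (ts$identity <= 0 || ts$identity > 1) stop("tandem identity not in (0,1]")
    if (subfamilies[[ts$subfamily]] < ts$size) {
      stop("subfamily ", ts$subfamily, " too small for tandem spec")
    }
  }
  for (ss in segmental_specs) {
    if (ss$coverage <= 0 || ss$coverage > 1 || ss$similarity <= 0 ||
        ss$similarity > 1) {
      stop("segmental coverage/similarity must lie in (0,1]")
    }
  }
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 n_background_genes = n_background_genes,
                 protein_length = protein_length,
                 background_protein_length = background_protein_length,
                 subfamilies = subfamilies, base_divergence = base_divergence,
                 tandem_specs = tandem_specs,
                 segmental_specs = segmental_specs, tolerance = tolerance,
                 splice_variant_gene = splice_variant_gene),
            class = "family_sim_config")
}

## internal: build family proteins honouring tandem/segmental targets --------

.build_family_proteins <- function(cfg, max_retry = 40L) {
  subs <- .nonpositive_subs()
  L <- cfg$protein_length
  members <- list()  # per subfamily: list of protein strings
  ancestors <- character()
  boxtruth <- list()
  protected <- list()
  # all subfamily ancestors descend from one root so the family alignment
  # stays colinear (substitution-only evolution; complete-deletion columns
  # survive for the distance phylogeny)
  root <- .random_protein(L, first_m = TRUE)
  for (sf in names(cfg$subfamilies)) {
    n <- cfg$subfamilies[[sf]]
    tab <- hbox_patterns(sf, compiled = FALSE)
    tab <- tab[tab$box %in% c("1", "2", "3"), , drop = FALSE]
    pats <- lapply(seq_len(nrow(tab)), function(i) {
      compile_hbox_pattern(tab$pattern[i], name = paste0(sf, ".box", tab$box[i]))
    })
    plen <- vapply(pats, function(p) length(p$tokens), integer(1))
    anchors <- floor(L * seq(0.1, 0.62, length.out = length(pats)))
    # subfamily ancestor: diverged copy of the root with its boxes planted
    anc <- .mutate_protein(root, 0.35, 1L, subs)
    prot_pos <- 1L
    exp <- data.frame(pattern = character(), start0 = integer(),
                      stringsAsFactors = FALSE)
    for (k in seq_along(pats)) {
      at <- anchors[k] + 1L
      substr(anc, at, at + plen[k] - 1L) <- .realize_pattern(pats[[k]])
      prot_pos <- c(prot_pos, seq.int(at, at + plen[k] - 1L))
      exp <- rbind(exp, data.frame(pattern = pats[[k]]$name, start0 = at - 1L,
                                   stringsAsFactors = FALSE))
    }
    anc <- .repair_protein(anc, pats, prot_pos, exp)
    mem <- vector("list", n)
    for (i in seq_len(n)) {
      mem[[i]] <- .mutate_protein(anc, cfg$base_divergence, prot_pos, subs)
    }
    members[[sf]] <- mem
    ancestors[[sf]] <- anc
    boxtruth[[sf]] <- exp
    protected[[sf]] <- prot_pos
  }

  # tandem chains: re-derive members along a chain so consecutive pairs hit
  # the identity target (verified with the alignment module, resampled)
  tandem_members <- list()
  for (ts in cfg$tandem_specs) {
    sf <- ts$subfamily
    idx <- seq_len(ts$size)  # first `size` members of the subfamily
    # reserve the *last* members of the subfamily for tandem arrays so the
    # independent members keep low indices
    idx <- seq.int(cfg$subfamilies[[sf]] - ts$size + 1L, cfg$subfamilies[[sf]])
    for (j in seq_along(idx)[-1L]) {
      prev <- members[[sf]][[idx[j - 1L]]]
      ok <- FALSE
      for (r in seq_len(max_retry)) {
        cand <- .mutate_protein(prev, 1 - ts$identity, protected[[sf]], subs)
        aln <- global_align(prev, cand)
        if (abs(aln$identity - ts$identity) <= cfg$tolerance) {
          members[[sf]][[idx[j]]] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop("unsatisfiable tandem identity target for ", sf)
    }
    tandem_members[[length(tandem_members) + 1L]] <-
      list(subfamily = sf, member_idx = idx, spec = ts)
  }

  # segmental pairs: B = truncated, mutated copy of A, verified against the
  # coverage/similarity targets
  seg_members <- list()
  seg_used <- stats::setNames(rep(0L, length(cfg$subfamilies)),
                              names(cfg$subfamilies))
  for (ss in cfg$segmental_specs) {
    sf <- ss$subfamily
    a_idx <- 1L + seg_used[[sf]] * 2L
    b_idx <- a_idx + 1L
    seg_used[[sf]] <- seg_used[[sf]] + 1L
    A <- members[[sf]][[a_idx]]
    keep <- round(ss$coverage * nchar(A))
    prot_b <- protected[[sf]][protected[[sf]] <= keep]
    ok <- FALSE
    for (r in seq_len(max_retry)) {
      B <- substr(A, 1L, keep)
      B <- .mutate_protein(B, 1 - ss$similarity, prot_b, subs)
      aln <- global_align(A, B)
      if (abs(aln$coverage - ss$coverage) <= cfg$tolerance &&
          abs(aln$similarity - ss$similarity) <= cfg$tolerance) {
        members[[sf]][[b_idx]] <- B; ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("unsatisfiable segmental coverage/similarity target for ", sf)
    }
    seg_members[[length(seg_members) + 1L]] <-
      list(subfamily = sf, a_idx = a_idx, b_idx = b_idx, spec = ss)
  }
  list(members = members, ancestors = ancestors, boxtruth = boxtruth,
       tandem = tandem_members, segmental = seg_members)
}

## internal: genome assembly --------------------------------------------------

.codon_table <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "AGA"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  E = c("GAA", "GAG"), Q = c("CAA", "CAG"), G = c("GGT", "GGC", "GGA"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC"), L = c("CTT", "CTC", "CTG"),
  K = c("AAA", "AAG"), M = "ATG", F = c("TTT", "TTC"),
  P = c("CCT", "CCC", "CCA"), S = c("TCT", "TCC", "AGC"),
  T = c("ACT", "ACC", "ACA"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTG")
)

.protein_to_cds <- function(protein) {
  aa <- strsplit(protein, "")[[1L]]
  codons <- vapply(aa, function(r) {
    opts <- .codon_table[[r]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), "TAA")
}

.iupac_regex_map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]",
                      Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
                      M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]",
                      V = "[ACG]", N = "[ACGT]")

.iupac_regex <- function(consensus) {
  paste0("(?=", paste(.iupac_regex_map[strsplit(consensus, "")[[1L]]],
                      collapse = ""), ")")
}

.revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

# all element hits in a promoter, found with the independent regex matcher
# (positions are 1-based template coordinates)
.element_hits_regex <- function(seq, elements) {
  out <- list()
  for (k in seq_len(nrow(elements))) {
    cons <- elements$consensus[k]
    for (strand in c("template", "complementary")) {
      pat <- if (strand == "template") cons else .revcomp(cons)
      hits <- .regex_hits0(seq, .iupac_regex(pat)) + 1L
      if (length(hits)) {
        out[[length(out) + 1L]] <- data.frame(
          element = elements$name[k], pos1 = hits, strand = strand,
          width = nchar(cons), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(element = character(), pos1 = integer(), strand = character(),
               width = integer(), stringsAsFactors = FALSE)
}

# build a 2-kb promoter with planted elements; background is repaired until
# the only hits are those lying wholly within planted windows.
# plant: data.frame(element, strand); returns list(seq, truth)
.build_promoter <- function(plant, elements, prom_len = 2000L,
                            max_iter = 400L) {
  seq <- .random_dna(prom_len)
  windows <- integer()
  if (nrow(plant)) {
    elements$width <- nchar(elements$consensus)
    w <- elements$width[match(plant$element, elements$name)]
    # non-overlapping positions with padding
    repeat {
      pos <- sort(sample.int(prom_len - max(w) - 2L, nrow(plant)))
      if (nrow(plant) == 1L || all(diff(pos) > max(w) + 2L)) break
    }
    plant$pos1 <- pos
    for (i in seq_len(nrow(plant))) {
      cons <- elements$consensus[match(plant$element[i], elements$name)]
      inst <- if (plant$strand[i] == "template") cons else .revcomp(cons)
      # concrete instance of an IUPAC consensus
      inst <- paste(vapply(strsplit(inst, "")[[1L]], function(c0) {
        opts <- strsplit(gsub("[\\[\\]]", "", .iupac_regex_map[[c0]]), "")[[1L]]
        opts[sample.int(length(opts), 1L)]
      }, character(1)), collapse = "")
      substr(seq, plant$pos1[i], plant$pos1[i] + nchar(inst) - 1L) <- inst
      windows <- c(windows, seq.int(plant$pos1[i], plant$pos1[i] + nchar(inst) - 1L))
    }
  }
  for (iter in seq_len(max_iter)) {
    hits <- .element_hits_regex(seq, elements)
    inside <- vapply(seq_len(nrow(hits)), function(i) {
      all(seq.int(hits$pos1[i], hits$pos1[i] + hits$width[i] - 1L) %in% windows)
    }, logical(1))
    if (all(inside)) {
      truth <- hits
      truth$position <- truth$pos1 - prom_len - 1L
      return(list(seq = seq, truth = truth[, c("element", "position", "strand")]))
    }
    bad <- which(!inside)[1L]
    span <- setdiff(seq.int(hits$pos1[bad], hits$pos1[bad] + hits$width[bad] - 1L),
                    windows)
    at <- span[sample.int(length(span), 1L)]
    substr(seq, at, at) <- sample(c("A", "C", "G", "T"), 1L)
  }
  stop("promoter rejection sampling did not converge")
}

# assemble one gene region in local 5'->3' orientation.
# returns list(seq, features = data.frame(type, start, end, local phase info),
# cds_chunks, promoter window length)
.build_gene_region <- function(cds, n_introns, utr5 = 60L, utr3 = 60L,
                               promoter_seq = NULL, promoter_len = 150L) {
  # when a planted promoter is supplied it is the full ATG-upstream window,
  # so the 5'UTR (which lies inside that window) is carved from its tail
  if (is.null(promoter_seq)) {
    prom <- .random_dna(promoter_len)
    u5 <- if (utr5 > 0L) .random_dna(utr5) else ""
  } else {
    stopifnot(nchar(promoter_seq) > utr5)
    u5 <- if (utr5 > 0L)
      substr(promoter_seq, nchar(promoter_seq) - utr5 + 1L,
             nchar(promoter_seq)) else ""
    prom <- substr(promoter_seq, 1L, nchar(promoter_seq) - utr5)
  }
  Lc <- nchar(cds)
  # split CDS into n_introns + 1 chunks at interior points
  if (n_introns > 0L) {
    cuts <- sort(sample(seq.int(30L, Lc - 30L), n_introns))
    bounds <- c(0L, cuts, Lc)
  } else {
    bounds <- c(0L, Lc)
  }
  chunks <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
  introns <- if (n_introns > 0L) {
    vapply(seq_len(n_introns), function(i)
      paste0("GT", .random_dna(sample(80:180, 1L)), "AG"), character(1))
  } else character()
  cds_iv <- matrix(0L, nrow = length(chunks), ncol = 2L)
  cursor <- nchar(prom)
  pieces <- c(prom, u5)
  cursor <- cursor + nchar(u5)
  utr5_iv <- if (utr5 > 0L) c(nchar(prom) + 1L, cursor) else NULL
  for (i in seq_along(chunks)) {
    pieces <- c(pieces, chunks[i])
    cds_iv[i, ] <- c(cursor + 1L, cursor + nchar(chunks[i]))
    cursor <- cursor + nchar(chunks[i])
    if (i <= length(introns)) {
      pieces <- c(pieces, introns[i])
      cursor <- cursor + nchar(introns[i])
    }
  }
  u3 <- if (utr3 > 0L) .random_dna(utr3) else ""
  utr3_iv <- if (utr3 > 0L) c(cursor + 1L, cursor + nchar(u3)) else NULL
  pieces <- c(pieces, u3)
  cursor <- cursor + nchar(u3)
  # exons: first CDS chunk extended by contiguous 5'UTR, last by 3'UTR
  exon_iv <- cds_iv
  if (!is.null(utr5_iv)) exon_iv[1L, 1L] <- utr5_iv[1L]
  if (!is.null(utr3_iv)) exon_iv[nrow(exon_iv), 2L] <- utr3_iv[2L]
  list(seq = paste(pieces, collapse = ""), length = cursor,
       tx_start = if (!is.null(utr5_iv)) utr5_iv[1L] else cds_iv[1L, 1L],
       tx_end = if (!is.null(utr3_iv)) utr3_iv[2L] else cds_iv[nrow(cds_iv), 2L],
       cds_iv = cds_iv, exon_iv = exon_iv, utr5_iv = utr5_iv,
       utr3_iv = utr3_iv)
}

## default placement plan for the 20-member roster ---------------------------

.default_placement <- function(cfg, built) {
  # rows: subfamily, member index, chromosome, role
  plan <- list()
  add <- function(sf, m, chr) {
    plan[[length(plan) + 1L]] <<- data.frame(
      subfamily = sf, member = m, chromosome = chr, stringsAsFactors = FALSE)
  }
  tandem_idx <- list()
  for (tm in built$tandem) tandem_idx[[tm$subfamily]] <-
    c(tandem_idx[[tm$subfamily]], tm$member_idx)
  seg_idx <- list()
  for (sg in built$segmental) seg_idx[[sg$subfamily]] <-
    rbind(seg_idx[[sg$subfamily]], c(sg$a_idx, sg$b_idx))

  chr <- 0L
  nextchr <- function() { chr <<- if (chr >= cfg$n_chromosomes) 1L else chr + 1L; chr }
  # tandem arrays first: all members of one array on one chromosome
  for (tm in built$tandem) {
    c0 <- nextchr()
    for (m in tm$member_idx) add(tm$subfamily, m, c0)
  }
  # segmental pairs on two different chromosomes
  for (sg in built$segmental) {
    ca <- nextchr(); cb <- nextchr()
    if (ca == cb) cb <- nextchr()
    add(sg$subfamily, sg$a_idx, ca)
    add(sg$subfamily, sg$b_idx, cb)
  }
  # remaining members round-robin
  for (sf in names(cfg$subfamilies)) {
    placed <- unlist(lapply(plan, function(p)
      if (p$subfamily[1] == sf) p$member else NULL))
    for (m in setdiff(seq_len(cfg$subfamilies[[sf]]), placed)) {
      add(sf, m, nextchr())
    }
  }
  do.call(rbind, plan)
}

## main simulator -------------------------------------------------------------

#' Simulate an annotated genome with a planted gene family
#'
#' Generates a multi-chromosome genome FASTA, a GFF3 annotation, a proteome
#' FASTA, a functional-annotation table, an external-style domain-hit
#' table, and a truth record listing every planted feature: tandem
#' clusters (satisfying the "< 5 intervening genes, > 50% protein
#' identity" criterion when so configured), segmental duplicate pairs hit
#' to their coverage/similarity targets within the configured tolerance
#' (verified with [global_align()] before emission, resampling mutations
#' until satisfied), histidine-box positions, and planted promoter
#' cis-elements on both strands. Deterministic given `config$seed`.
#'
#' @param config A [family_sim_config()].
#' @param promoter_plant Optional data frame (`gene_index`, `element`,
#'   `strand`) of elements to plant in family promoters; `NULL` uses a
#'   default plan covering nine genes (multiple ABRE copies for all but
#'   one, plus stress/hormone elements on both strands).
#' @return List with `genome`, `proteome`, `queries` (subfamily ancestor
#'   proteins usable as homology-screen queries and phylogeny anchors),
#'   `gff` (text lines), `annotation` (locus descriptions), `domain_hits`,
#'   `family` (roster with names, loci, proteins) and `truth`.
#' @export
simulate_family_genome <- function(config, promoter_plant = NULL) {
  stopifnot(inherits(config, "family_sim_config"))
  set.seed(config$seed)
  elements <- cis_element_table()
  elements$width <- nchar(elements$consensus)
  built <- .build_family_proteins(config)
  plan <- .default_placement(config, built)
  n_family <- nrow(plan)

  if (is.null(promoter_plant)) {
    promoter_plant <- do.call(rbind, lapply(seq_len(min(9L, n_family)), function(i) {
      base <- if (i == 4L) {
        # one gene deliberately lacks multiple ABRE copies
        data.frame(element = c("ABRE", "MBS", "LTR"),
                   strand = c("template", "complementary", "template"),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(
          element = c("ABRE", "ABRE", "ARE", "MBS",
                      if (i == 1L) "CGTCA-motif" else "GARE-motif"),
          strand = c("template", "complementary", "complementary",
                     "template", "template"),
          stringsAsFactors = FALSE)
      }
      cbind(gene_index = i, base)
    }))
  }

  # per-chromosome gene queues: family genes interleaved with background
  all_pats <- hbox_patterns()
  bg_protein <- function() {
    s <- .random_protein(config$background_protein_length)
    .repair_protein(s, all_pats, integer(),
                    data.frame(pattern = character(), start0 = integer(),
                               stringsAsFactors = FALSE))
  }

  genome <- character(config$n_chromosomes)
  gff <- c("##gff-version 3")
  proteome <- character(); prot_ids <- character()
  ann_rows <- list(); roster_rows <- list()
  promoter_truth <- list()
  gene_counter <- stats::setNames(rep(0L, config$n_chromosomes),
                                  seq_len(config$n_chromosomes))
  fam_global_idx <- 0L

  # intron-count cycle for family genes: includes intronless members and a
  # deep 7-intron structure; two members lack UTRs
  intron_cycle <- c(1L, 2L, 0L, 7L, 3L, 1L, 0L, 2L, 9L, 1L)

  for (chr in seq_len(config$n_chromosomes)) {
    fam_here <- plan[plan$chromosome == chr, , drop = FALSE]
    # order: keep tandem arrays contiguous in plan order
    items <- list()
    n_bg <- config$n_background_genes
    bg_left <- n_bg
    # leading background
    lead <- min(3L, bg_left); bg_left <- bg_left - lead
    for (k in seq_len(lead)) items[[length(items) + 1L]] <- list(type = "bg")
    prev_sf <- NULL
    for (r in seq_len(nrow(fam_here))) {
      if (r > 1L) {
        # intervening genes: tandem spec separation within an array,
        # otherwise a wide gap
        same_array <- FALSE
        for (tm in built$tandem) {
          if (tm$subfamily == fam_here$subfamily[r] &&
              tm$subfamily == fam_here$subfamily[r - 1L] &&
              fam_here$member[r] %in% tm$member_idx &&
              fam_here$member[r - 1L] %in% tm$member_idx) {
            gap <- tm$spec$intervening
            same_array <- TRUE
          }
        }
        if (!same_array) gap <- 8L
        gap <- min(gap, bg_left); bg_left <- bg_left - gap
        for (k in seq_len(gap)) items[[length(items) + 1L]] <- list(type = "bg")
      }
      items[[length(items) + 1L]] <- list(type = "fam", row = fam_here[r, ])
    }
    for (k in seq_len(bg_left)) items[[length(items) + 1L]] <- list(type = "bg")

    cursor <- 0L
    pieces <- character()
    seqid <- paste0("Chr", chr)
    for (it in items) {
      gene_counter[chr] <- gene_counter[chr] + 1L
      locus <- sprintf("LOC_Os%02dg%05d", chr, 10L * gene_counter[chr])
      strand <- if (gene_counter[chr] %% 7L == 0L) "-" else "+"
      if (it$type == "bg") {
        prot <- bg_protein()
        cds <- .protein_to_cds(prot)
        reg <- .build_gene_region(cds, n_introns = 0L, utr5 = 0L, utr3 = 0L,
                                  promoter_len = 120L)
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          locus_id = locus, description = "expressed protein",
          stringsAsFactors = FALSE)
        pid <- paste0(locus, ".1")
        proteome <- c(proteome, prot); prot_ids <- c(prot_ids, pid)
        regions <- list(list(mrna = pid, reg = reg, protein = prot))
      } else {
        fam_global_idx <- fam_global_idx + 1L
        sf <- it$row$subfamily; m <- it$row$member
        prot <- built$members[[sf]][[m]]
        cds <- .protein_to_cds(prot)
        ni <- intron_cycle[(fam_global_idx - 1L) %% length(intron_cycle) + 1L]
        no_utr <- fam_global_idx %in% c(3L, 7L)
        plant <- promoter_plant[promoter_plant$gene_index == fam_global_idx, ,
                                drop = FALSE]
        pr <- .build_promoter(plant[, c("element", "strand"), drop = FALSE],
                              elements)
        reg <- .build_gene_region(cds, n_introns = ni,
                                  utr5 = if (no_utr) 0L else 60L,
                                  utr3 = if (no_utr) 0L else 60L,
                                  promoter_seq = pr$seq)
        pid <- paste0(locus, ".1")
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          locus_id = locus, description = "putative fatty acid desaturase",
          stringsAsFactors = FALSE)
        proteome <- c(proteome, prot); prot_ids <- c(prot_ids, pid)
        regions <- list(list(mrna = pid, reg = reg, protein = prot))
        # splice variant: second, shorter model sharing the locus
        if (fam_global_idx == config$splice_variant_gene && ni == 0L) {
          short <- substr(prot, 1L, floor(nchar(prot) * 0.7))
          # same region; CDS truncated within the single exon
          reg2 <- reg
          reg2$cds_iv <- matrix(c(reg$cds_iv[1L, 1L],
                                  reg$cds_iv[1L, 1L] + 3L * nchar(short) - 1L),
                                nrow = 1L)
          reg2$exon_iv <- reg2$cds_iv
          reg2$utr5_iv <- NULL; reg2$utr3_iv <- NULL
          reg2$tx_start <- reg2$cds_iv[1L, 1L]
          reg2$tx_end <- reg2$cds_iv[1L, 2L]
          pid2 <- paste0(locus, ".2")
          proteome <- c(proteome, short); prot_ids <- c(prot_ids, pid2)
          regions[[2L]] <- list(mrna = pid2, reg = reg2, protein = short)
        }
        roster_rows[[length(roster_rows) + 1L]] <- data.frame(
          locus_id = locus, subfamily = sf, member = m,
          chromosome = chr, fam_index = fam_global_idx, strand = strand,
          protein_id = pid, stringsAsFactors = FALSE)
        if (nrow(pr$truth)) {
          promoter_truth[[length(promoter_truth) + 1L]] <-
            cbind(fam_index = fam_global_idx, locus_id = locus, pr$truth)
        }
      }
      # spacer then the gene region (reverse-complemented on minus strand)
      spacer <- .random_dna(100L)
      pieces <- c(pieces, spacer)
      cursor <- cursor + 100L
      reg0 <- regions[[1L]]$reg
      R <- reg0$length
      region_seq <- reg0$seq
      if (strand == "-") {
        region_seq <- .revcomp(region_seq)
      }
      pieces <- c(pieces, region_seq)
      gmap <- function(iv) {  # local interval -> genomic
        if (is.null(iv)) return(NULL)
        iv <- matrix(iv, ncol = 2L)
        if (strand == "+") iv + cursor else
          cbind(cursor + R - iv[, 2L] + 1L, cursor + R - iv[, 1L] + 1L)
      }
      # gene feature spans all transcripts of the locus
      tx_b <- range(unlist(lapply(regions, function(x)
        gmap(c(x$reg$tx_start, x$reg$tx_end)))))
      gff <- c(gff, sprintf("%s\tfamsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                            seqid, tx_b[1L], tx_b[2L], strand, locus))
      for (tr in regions) {
        rg <- tr$reg
        tb <- gmap(c(rg$tx_start, rg$tx_end))
        gff <- c(gff, sprintf("%s\tfamsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                              seqid, min(tb), max(tb), strand, tr$mrna, locus))
        feat <- function(type, iv) {
          g <- gmap(iv)
          if (is.null(g)) return()
          g <- g[order(g[, 1L]), , drop = FALSE]
          for (q in seq_len(nrow(g))) {
            gff <<- c(gff, sprintf("%s\tfamsim\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                                   seqid, type, g[q, 1L], g[q, 2L], strand,
                                   tr$mrna))
          }
        }
        feat("exon", rg$exon_iv)
        feat("CDS", rg$cds_iv)
        feat("five_prime_UTR", rg$utr5_iv)
        feat("three_prime_UTR", rg$utr3_iv)
      }
      cursor <- cursor + R
    }
    pieces <- c(pieces, .random_dna(200L))
    genome[chr] <- paste(pieces, collapse = "")
  }
  names(genome) <- paste0("Chr", seq_len(config$n_chromosomes))
  names(proteome) <- prot_ids
  annotation <- do.call(rbind, ann_rows)
  roster <- do.call(rbind, roster_rows)

  # name family genes positionally within subfamilies; attach coordinates
  gene_lines <- grep("\tgene\t", gff, value = TRUE)
  parse_gene <- function(l) {
    f <- strsplit(l, "\t")[[1L]]
    data.frame(locus_id = sub("ID=", "", f[9L]), start = as.integer(f[4L]),
               end = as.integer(f[5L]), stringsAsFactors = FALSE)
  }
  coords <- do.call(rbind, lapply(gene_lines, parse_gene))
  roster$start <- coords$start[match(roster$locus_id, coords$locus_id)]
  roster$end <- coords$end[match(roster$locus_id, coords$locus_id)]
  roster <- assign_family_names(roster)
  roster$protein <- unname(proteome[roster$protein_id])

  # genome-wide ordinals (by construction genes are emitted in start order)
  ords <- stats::ave(coords$start,
                     locus_chromosome(coords$locus_id), FUN = rank)
  roster$ordinal <- as.integer(ords[match(roster$locus_id, coords$locus_id)])

  name_of_member <- function(sf, m) {
    roster$name[roster$subfamily == sf & roster$member == m]
  }
  tandem_truth <- lapply(built$tandem, function(tm) {
    sort(vapply(tm$member_idx, function(m) name_of_member(tm$subfamily, m),
                character(1)))
  })
  segmental_truth <- do.call(rbind, lapply(built$segmental, function(sg) {
    data.frame(a = name_of_member(sg$subfamily, sg$a_idx),
               b = name_of_member(sg$subfamily, sg$b_idx),
               coverage = sg$spec$coverage, similarity = sg$spec$similarity,
               stringsAsFactors = FALSE)
  }))
  prom_truth <- if (length(promoter_truth)) {
    pt <- do.call(rbind, promoter_truth)
    pt$gene <- roster$name[match(pt$locus_id, roster$locus_id)]
    pt[, c("gene", "locus_id", "element", "position", "strand")]
  } else NULL

  box_truth <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
    sf <- roster$subfamily[i]
    exp <- built$boxtruth[[sf]]
    cbind(protein_id = roster$protein_id[i], exp)
  }))

  # subfamily ancestors double as homology-screen queries and phylogeny
  # anchors (synthetic stand-ins for the Arabidopsis representatives)
  queries <- stats::setNames(
    unlist(built$ancestors),
    paste0("ANC_", gsub("/", "", names(config$subfamilies))))
  anchors <- data.frame(anchor_id = names(queries),
                        subfamily = names(config$subfamilies),
                        stringsAsFactors = FALSE)

  domain_hits <- data.frame(protein_id = roster$protein_id,
                            domain = "PF00487",
                            evalue = 1e-30, stringsAsFactors = FALSE)

  truth <- list(seed = config$seed,
                family = roster[, c("name", "locus_id", "subfamily",
                                    "chromosome", "start", "end", "strand",
                                    "ordinal", "protein_id")],
                tandem_clusters = tandem_truth,
                segmental_pairs = segmental_truth,
                hbox = box_truth,
                promoter_elements = prom_truth)
  list(genome = genome, gff = gff, proteome = proteome,
       annotation = annotation, domain_hits = domain_hits,
       family = roster, queries = queries, anchors = anchors, truth = truth,
       config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `proteome.fa`, `annotation.tsv`,
#' `domain_hits.tsv` and `truth.json` under `dir`.
#'
#' @param sim Result of [simulate_family_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  writeLines(sim$gff, file.path(dir, "genes.gff3"))
  write_fasta(sim$proteome, file.path(dir, "proteome.fa"))
  write_tsv_file(sim$annotation, file.path(dir, "annotation.tsv"))
  write_tsv_file(sim$domain_hits, file.path(dir, "domain_hits.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

## expression / qPCR simulators ----------------------------------------------

#' Default tissue panel for expression simulation
#'
#' Sixteen organs/tissues across vegetative and reproductive development
#' (roots, leaf blades, sheaths/stems at both stages; inflorescence stages,
#' anthers, pistils, lemmas, paleae, ovaries, embryos, endosperm).
#'
#' @return Named character vector tissue -> category.
#' @export
default_tissue_panel <- function() {
  c(VR = "vegetative", VL = "vegetative", VS = "vegetative",
    RR = "reproductive", RL = "reproductive", RS = "reproductive",
    I1 = "reproductive", I2 = "reproductive", I3 = "reproductive",
    An = "reproductive", Pi = "reproductive", Le = "reproductive",
    Pa = "reproductive", Ov = "reproductive", Em = "reproductive",
    En = "reproductive")
}

#' Simulate a tissue x gene expression matrix with planted group archetypes
#'
#' Archetypes on a log2 scale (levels 10 / 6 / 2): group I is high in all
#' tissues; group II is high in a few particular tissues spanning both
#' developmental categories and intermediate elsewhere; group III is high
#' in exactly one category and off in the other; group IV is low
#' everywhere. With the recommended thresholds (`tau_high = 8`,
#' `tau_low = 4`, recorded in the truth) the noiseless archetypes classify
#' exactly to their planted groups.
#'
#' @param spec Data frame `gene`, `group` (`"I".."IV"`); `NULL` plants a
#'   default 20-gene panel (5/4/6/5 genes in groups I--IV).
#' @param seed Mandatory integer seed.
#' @param tissues Named tissue -> category vector.
#' @param replicates Replicates per tissue.
#' @param noise_sd Gaussian replicate noise (log2 units).
#' @return List with `mat` (genes x samples), `meta` (sample metadata),
#'   `truth` (spec), `tau_high`, `tau_low`.
#' @export
simulate_expression <- function(spec = NULL, seed,
                                tissues = default_tissue_panel(),
                                replicates = 3L, noise_sd = 0.3) {
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  if (is.null(spec)) {
    spec <- data.frame(
      gene = sprintf("gene%02d", 1:20),
      group = rep(c("I", "II", "III", "IV"), times = c(5L, 4L, 6L, 5L)),
      stringsAsFactors = FALSE)
  }
  hi <- 10; mid <- 6; lo <- 2
  veg <- names(tissues)[tissues == "vegetative"]
  rep_t <- names(tissues)[tissues == "reproductive"]
  archetype <- function(group, i) {
    v <- stats::setNames(rep(lo, length(tissues)), names(tissues))
    if (group == "I") v[] <- hi
    if (group == "II") {
      v[] <- mid
      picks <- c(veg[1L + (i %% length(veg))], rep_t[1L + (i %% length(rep_t))],
                 rep_t[1L + ((i + 3L) %% length(rep_t))])
      v[picks] <- hi
    }
    if (group == "III") {
      # high in one developmental category only; for the (larger)
      # reproductive category a subset of organs carries the signal so the
      # tissue fraction stays below the group-I cutoff
      if (i %% 2L == 0L) v[veg] <- hi else
        v[rep_t[seq_len(min(6L, length(rep_t)))]] <- hi
    }
    v
  }
  meta <- expand.grid(tissue = names(tissues), replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample <- paste0(meta$tissue, "_r", meta$replicate)
  meta$category <- unname(tissues[meta$tissue])
  mat <- matrix(0, nrow = nrow(spec), ncol = nrow(meta),
                dimnames = list(spec$gene, meta$sample))
  for (i in seq_len(nrow(spec))) {
    mu <- archetype(spec$group[i], i)
    mat[i, ] <- mu[meta$tissue] + stats::rnorm(nrow(meta), 0, noise_sd)
  }
  list(mat = mat, meta = meta, truth = spec, tau_high = 8, tau_low = 4)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' The reference gene has constant true expression; target Ct values are
#' shifted by -log2(fold) relative to the untreated control (calibrator),
#' so the expected 2^-ddCt equals the planted fold change exactly at zero
#' Ct noise.
#'
#' @param spec Data frame `gene`, `treatment`, `time`, `fold`; `NULL`
#'   plants a small default panel.
#' @param seed Mandatory integer seed.
#' @param replicates Technical replicates per (gene, sample).
#' @param ct_noise_sd Gaussian Ct noise.
#' @param reference Reference gene id.
#' @param base_ct,ref_ct Baseline Ct of targets / reference.
#' @return List with `ct` (long table: gene, sample, treatment, time,
#'   replicate, ct), `calibrator` (sample id), `reference`, `truth`.
#' @export
simulate_qpcr <- function(spec = NULL, seed, replicates = 3L,
                          ct_noise_sd = 0, reference = "Os03g0234200",
                          base_ct = 26, ref_ct = 20) {
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  if (is.null(spec)) {
    spec <- expand.grid(gene = sprintf("gene%02d", 1:6),
                        treatment = c("ABA", "GA"), time = c(3, 24),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    spec$fold <- rep(c(4, 0.25, 1, 8, 0.5, 1), length.out = nrow(spec))
  }
  samples <- unique(spec[, c("treatment", "time")])
  samples$sample <- paste0(samples$treatment, "_", samples$time, "h")
  rows <- list()
  add <- function(gene, sample, treatment, time, ctv) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, sample = sample, treatment = treatment, time = time,
      replicate = seq_len(replicates),
      ct = ctv + stats::rnorm(replicates, 0, ct_noise_sd),
      stringsAsFactors = FALSE)
  }
  genes <- unique(spec$gene)
  # calibrator: untreated control
  for (g in genes) add(g, "control", "control", 0, base_ct)
  add(reference, "control", "control", 0, ref_ct)
  for (s in seq_len(nrow(samples))) {
    sm <- samples$sample[s]
    add(reference, sm, samples$treatment[s], samples$time[s], ref_ct)
    for (g in genes) {
      fold <- spec$fold[spec$gene == g & spec$treatment == samples$treatment[s] &
                          spec$time == samples$time[s]]
      if (!length(fold)) fold <- 1
      add(g, sm, samples$treatment[s], samples$time[s], base_ct - log2(fold))
    }
  }
  list(ct = do.call(rbind, rows), calibrator = "control",
       reference = reference, truth = spec)
}
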