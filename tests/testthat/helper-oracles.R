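# Independent oracles and shared fixtures for the test suite.

# brute-force position-by-position motif matcher (oracle for scan_hboxes)
brute_scan <- function(protein, patterns) {
  aa <- strsplit(protein, "")[[1L]]
  n <- length(aa)
  rows <- list()
  for (pat in patterns) {
    L <- length(pat$tokens)
    if (L > n) next
    for (at in seq_len(n - L + 1L)) {
      ok <- TRUE
      for (k in seq_len(L)) {
        tok <- pat$tokens[[k]]
        if (!is.null(tok) && !aa[at + k - 1L] %in% tok) { ok <- FALSE; break }
      }
      if (ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          pattern = pat$name, start0 = at - 1L,
          match = substr(protein, at, at + L - 1L), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pattern = character(), start0 = integer(), match = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start0, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive enumeration of all global alignments with affine gap scoring
# (gap of length L costs open + L * ext), no dynamic programming reuse:
# plain recursion over the three column types.
enum_global_score <- function(a, b, submat, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(av)) {  # gap in b
      cost <- if (prev == "X") ext else open + ext
      best <- max(best, -cost + rec(i + 1L, j, "X"))
    }
    if (j <= length(bv)) {  # gap in a
      cost <- if (prev == "Y") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_protein_seq <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
        collapse = "")
}

# small synthetic family used by several files (memoized per session)
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- family_sim_config(
      seed = 7L, n_chromosomes = 4L, n_background_genes = 12L,
      subfamilies = c(FAB2 = 3L, FAD2 = 3L, DES1 = 1L),
      tandem_specs = list(list(subfamily = "FAD2", size = 3L,
                               intervening = 2L, identity = 0.6)),
      segmental_specs = list(list(subfamily = "FAB2", coverage = 0.85,
                                  similarity = 0.85)))
    .fixture_env$small <- simulate_family_genome(cfg)
  }
  .fixture_env$small
}

default_sim <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- simulate_family_genome(family_sim_config(seed = 101L))
  }
  .fixture_env$default
}

default_sim_annotation <- function() {
  if (is.null(.fixture_env$default_ann)) {
    gf <- tempfile(fileext = ".gff3")
    writeLines(default_sim()$gff, gf)
    .fixture_env$default_ann <- read_gff3(gf)
  }
  .fixture_env$default_ann
}

# tissue category map for the default expression panel
tissue_categories <- function() {
  tp <- default_tissue_panel()
  tp
}
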