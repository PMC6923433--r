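# Protein characterization (length, molecular weight, isoelectric point)
# and degenerate histidine-box motif scanning.

# Average residue masses (Da); a peptide's mass is the residue sum plus one
# water (18.0153 Da).
.aa_masses <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.0153

# EMBOSS pKa values used for the isoelectric point; recorded in stats output
# so downstream reports can state the table used.
.pka <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

.net_charge <- function(pH, counts) {
  pos <- 1 / (1 + 10^(pH - .pka$nterm)) +
    sum(counts[names(.pka$positive)] / (1 + 10^(pH - .pka$positive)))
  neg <- 1 / (1 + 10^(.pka$cterm - pH)) +
    sum(counts[names(.pka$negative)] / (1 + 10^(.pka$negative - pH)))
  pos - neg
}

#' Protein length, molecular weight and isoelectric point
#'
#' Molecular weight is the sum of average residue masses plus one water
#' (18.0153 Da). The isoelectric point is found by bisection on the net
#' charge at tolerance 1e-4 pH units, using the EMBOSS pKa set
#' (N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
#' Y 10.1).
#'
#' @param sequence One amino-acid sequence (string over the 20-residue
#'   alphabet). `X` or other ambiguity codes are an error: mass and charge
#'   are undefined for them, and the offending positions are listed.
#' @return List with `length` (residues), `mw` (Da), `pi`, and `pka_table`
#'   (`"EMBOSS"`).
#' @examples
#' protein_stats("G")$mw  # 75.07 Da
#' @export
protein_stats <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty protein sequence")
  aa <- strsplit(sequence, "")[[1L]]
  bad <- which(!aa %in% names(.aa_masses))
  if (length(bad)) {
    stop("invalid/ambiguous residue(s) '", paste(unique(aa[bad]), collapse = ","),
         "' at position(s) ", paste(bad, collapse = ","),
         ": molecular weight and pI are undefined")
  }
  counts <- table(factor(aa, levels = names(.aa_masses)))
  counts <- stats::setNames(as.numeric(counts), names(.aa_masses))
  mw <- sum(counts * .aa_masses) + .water_mass
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (.net_charge(mid, counts) > 0) lo <- mid else hi <- mid
  }
  list(length = length(aa), mw = mw, pi = (lo + hi) / 2, pka_table = "EMBOSS")
}

#' Compile a histidine-box pattern string
#'
#' Pattern grammar: uppercase residue letters are literals; `X` is a
#' wildcard matching any residue; a parenthesized letter immediately after
#' a residue, as in `"E(K)"`, makes a two-way alternative set \{E, K\}.
#'
#' @param pattern_string Pattern, e.g. `"WT(S)AE(K)ENR(H)HG"` or `"GHDCXH"`.
#' @param name Optional pattern name.
#' @return A `motif_pattern`: list with `name`, `pattern`, and `tokens`
#'   (list of allowed-residue character vectors; `NULL` marks a wildcard).
#' @export
compile_hbox_pattern <- function(pattern_string, name = pattern_string) {
  stopifnot(is.character(pattern_string), length(pattern_string) == 1L)
  chars <- strsplit(pattern_string, "")[[1L]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      if (i + 2L > length(chars) || chars[i + 2L] != ")" ||
          !grepl("^[A-Z]$", chars[i + 1L])) {
        stop("pattern grammar error at column ", i,
             ": malformed alternative in '", pattern_string, "'")
      }
      if (!length(tokens) || is.null(tokens[[length(tokens)]]) ||
          length(tokens[[length(tokens)]]) != 1L) {
        stop("pattern grammar error at column ", i,
             ": '(", chars[i + 1L], ")' has no preceding literal residue")
      }
      tokens[[length(tokens)]] <- c(tokens[[length(tokens)]], chars[i + 1L])
      i <- i + 3L
    } else if (ch == "X") {
      tokens[length(tokens) + 1L] <- list(NULL)  # wildcard token
      i <- i + 1L
    } else if (grepl("^[A-WYZ]$", ch)) {
      tokens[[length(tokens) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("pattern grammar error at column ", i, ": unexpected character '",
           ch, "' in '", pattern_string, "'")
    }
  }
  if (!length(tokens)) stop("empty pattern")
  structure(list(name = name, pattern = pattern_string, tokens = tokens),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern", x$name, "(", length(x$tokens), "tokens )\n")
  invisible(x)
}

# does `pattern` match aa characters starting at 1-based offset `at`?
.pattern_matches_at <- function(tokens, aa, at) {
  for (k in seq_along(tokens)) {
    tok <- tokens[[k]]
    if (is.null(tok)) next
    if (!aa[at + k - 1L] %in% tok) return(FALSE)
  }
  TRUE
}

#' Scan a protein for histidine-box motifs
#'
#' Reports every occurrence of every pattern (overlaps allowed), ordered
#' by start offset. Offsets are 0-based, matching the exported TSV column
#' `start0`. The completeness flag is `TRUE` iff every supplied pattern
#' matches at least once; membrane desaturases missing one of their three
#' boxes (C-terminal truncation) come out incomplete.
#'
#' @param protein One amino-acid sequence (string).
#' @param patterns List of compiled `motif_pattern`s (see
#'   [compile_hbox_pattern()]), or a character vector of pattern strings.
#' @return List with `hits` (data frame: `pattern`, `start0`, `match`) and
#'   `complete` (logical).
#' @export
scan_hboxes <- function(protein, patterns) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (is.character(patterns)) {
    patterns <- lapply(patterns, compile_hbox_pattern)
  }
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  n <- nchar(protein)
  rows <- list()
  matched <- logical(length(patterns))
  for (p in seq_along(patterns)) {
    pat <- patterns[[p]]
    L <- length(pat$tokens)
    if (L > n) next
    # overlap-tolerant matching via a zero-width lookahead regex
    starts0 <- .regex_hits0(protein, .hbox_regex(pat))
    starts0 <- starts0[starts0 + L <= n]
    if (length(starts0)) {
      matched[p] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = pat$name, start0 = starts0,
        match = substring(protein, starts0 + 1L, starts0 + L),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pattern = character(), start0 = integer(), match = character(),
               stringsAsFactors = FALSE)
  hits <- hits[order(hits$start0, hits$pattern), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, complete = all(matched))
}

#' Packaged histidine-box pattern table
#'
#' The conserved H-box patterns of the six desaturase subfamilies
#' (soluble stearoyl-ACP desaturases carry two boxes; membrane desaturases
#' carry three), shipped as a TSV and compiled on load. The FAD2 subfamily
#' additionally carries the generic third-box core `HVXHH`.
#'
#' @param subfamily Optional subfamily label to filter on
#'   (e.g. `"FAB2"`, `"FAD2"`, `"FAD3/7/8"`).
#' @param compiled If `TRUE` (default) return compiled `motif_pattern`s;
#'   otherwise the raw table.
#' @return A list of `motif_pattern`s (names `"<subfamily>.box<k>"`), or the
#'   raw data frame.
#' @export
hbox_patterns <- function(subfamily = NULL, compiled = TRUE) {
  path <- system.file("extdata", "hbox_patterns.tsv", package = "famsurvey")
  tab <- read_tsv_file(path)
  if (!is.null(subfamily)) {
    tab <- tab[tab$subfamily %in% subfamily, , drop = FALSE]
    if (!nrow(tab)) stop("no packaged H-box patterns for subfamily ", subfamily)
  }
  if (!compiled) return(tab)
  pats <- lapply(seq_len(nrow(tab)), function(i) {
    compile_hbox_pattern(tab$pattern[i],
                         name = paste0(tab$subfamily[i], ".box", tab$box[i]))
  })
  names(pats) <- vapply(pats, `[[`, character(1), "name")
  pats
}
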