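# Distance phylogeny of family proteins: multiple alignment, Poisson-corrected
# distances under complete deletion, neighbor joining with bootstrap supports,
# and anchor-based subfamily assignment.

#' Build a multiple alignment object from aligned sequences
#'
#' Validates equal row lengths and records the complete-deletion column
#' mask (columns containing no gap in any row). All distance computations
#' in this package are restricted to that mask.
#'
#' @param aligned Named character vector of equal-length gapped sequences.
#' @return A `multiple_alignment`: list with `taxa`, `rows` (named character
#'   vector), `ncol`, and `mask` (integer indices of gap-free columns).
#' @export
as_multiple_alignment <- function(aligned) {
  stopifnot(is.character(aligned), !is.null(names(aligned)))
  if (length(aligned) < 2L) stop("need at least two sequences")
  L <- unique(nchar(aligned))
  if (length(L) != 1L) stop("aligned rows differ in length")
  mat <- do.call(rbind, strsplit(aligned, ""))
  mask <- which(colSums(mat == "-") == 0L)
  structure(list(taxa = names(aligned), rows = aligned, ncol = L, mask = mask),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("multiple_alignment:", length(x$taxa), "taxa,", x$ncol, "columns,",
      length(x$mask), "complete-deletion columns\n")
  invisible(x)
}

#' Align protein sequences with MAFFT
#'
#' Multiple sequence alignment via the `mafft` command-line aligner
#' (deterministic with default settings). Pre-aligned FASTA input can
#' bypass this step entirely through [as_multiple_alignment()].
#'
#' @param sequences Named character vector of (unaligned) protein sequences.
#' @return A `multiple_alignment`.
#' @export
progressive_align <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  if (length(sequences) < 2L) stop("need at least two sequences to align")
  if (Sys.which("mafft") == "") {
    stop("the 'mafft' executable is required for progressive_align(); ",
         "supply a pre-aligned FASTA via as_multiple_alignment() instead")
  }
  tin <- tempfile(fileext = ".fa"); tout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  write_fasta(sequences, tin)
  status <- suppressWarnings(
    system2("mafft", c("--auto", "--amino", "--quiet", shQuote(tin)),
            stdout = tout, stderr = FALSE))
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  aligned <- read_fasta(tout)
  aligned <- aligned[names(sequences)]
  as_multiple_alignment(aligned)
}

# observed proportion of differing residues over a set of columns
.p_distance <- function(mat, cols) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (!length(cols)) stop("no complete-deletion columns available")
  sub <- mat[, cols, drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      p <- mean(sub[i, ] != sub[j, ])
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Poisson-corrected distance matrix
#'
#' Computes the proportion `p` of differing residues over the
#' complete-deletion columns and corrects for multiple hits with
#' `d = -ln(1 - p)`. Saturated pairs (`p = 1`) are capped at `d_max`
#' with a warning.
#'
#' @param msa A `multiple_alignment`.
#' @param d_max Cap applied where the correction diverges.
#' @return Symmetric numeric matrix of distances with zero diagonal.
#' @export
poisson_distance <- function(msa, d_max = 10) {
  stopifnot(inherits(msa, "multiple_alignment"))
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  rownames(mat) <- msa$taxa
  p <- .p_distance(mat, msa$mask)
  d <- -log(1 - p)
  if (any(!is.finite(d))) {
    warning("saturated pair(s) (p = 1) capped at d_max = ", d_max)
    d[!is.finite(d)] <- d_max
  }
  d[d > d_max] <- d_max
  diag(d) <- 0
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix. At each
#' step the pair minimizing the Q criterion is joined; exact ties are
#' broken by the lexicographically smallest (sorted) label pair, so the
#' result is invariant under input taxon order. Negative branch lengths
#' are clamped to zero for display (a standard convention).
#'
#' @param d Symmetric distance matrix with taxa as dimnames (n >= 3).
#' @return An unrooted `phylo` tree ([ape::read.tree()] format).
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix needs taxon names as dimnames")
  newick <- labels          # growing subtree strings, parallel to matrix rows
  D <- d
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      lab <- sort(c(rownames(D)[ij[1]], rownames(D)[ij[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    nm <- paste0("(", newick[i], ":", fmt(li), ",", newick[j], ":", fmt(lj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    lbl <- c(rownames(D)[keep], paste0("u", n))
    dimnames(D2) <- list(lbl, lbl)
    newick <- c(newick[keep], nm)
    D <- D2
  }
  # final trifurcation: closed-form lengths
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- paste0("(", newick[1], ":", fmt(l1), ",", newick[2], ":", fmt(l2),
                ",", newick[3], ":", fmt(l3), ");")
  ape::read.tree(text = txt)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples complete-deletion columns with replacement, recomputes the
#' Poisson-corrected NJ tree per replicate and reports, for each internal
#' edge of the full-data tree, the percentage of replicates containing its
#' bipartition. Resampling indexes columns only, so supports are invariant
#' under taxon-order permutation at a fixed seed.
#'
#' @param msa A `multiple_alignment`.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (mandatory; no hidden entropy).
#' @param d_max Passed to [poisson_distance()].
#' @return The NJ `phylo` tree with integer percentage supports in
#'   `node.label` (root label empty).
#' @export
bootstrap_support <- function(msa, B = 100L, seed, d_max = 10) {
  stopifnot(inherits(msa, "multiple_alignment"), B >= 1L)
  if (missing(seed)) stop("an explicit seed is required")
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  rownames(mat) <- msa$taxa
  base <- nj_tree(poisson_distance(msa, d_max = d_max))
  cols <- msa$mask
  set.seed(seed)
  idx <- matrix(sample.int(length(cols), length(cols) * B, replace = TRUE),
                nrow = B)
  reps <- lapply(seq_len(B), function(b) {
    p <- .p_distance(mat, cols[idx[b, ]])
    d <- suppressWarnings(-log(1 - p))
    d[!is.finite(d) | d > d_max] <- d_max
    diag(d) <- 0
    nj_tree(d)
  })
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / B)
  # first internal node is the (unrooted) root of the stored representation;
  # it carries no meaningful bipartition
  support[1L] <- NA
  base$node.label <- ifelse(is.na(support), "", as.character(support))
  base
}

#' Assign genes to subfamilies by nearest anchor group
#'
#' Each non-anchor taxon is assigned the subfamily whose anchor sequences
#' have the minimum average distance to it. A tie within `1e-9` leaves the
#' gene unassigned with a warning.
#'
#' @param d Distance matrix over genes and anchor taxa.
#' @param anchors Data frame with columns `anchor_id`, `subfamily`.
#' @return Data frame `gene`, `subfamily` (`NA` where ambiguous), and the
#'   winning average distance `dist`.
#' @export
assign_subfamilies <- function(d, anchors) {
  stopifnot(is.matrix(d), all(c("anchor_id", "subfamily") %in% names(anchors)))
  missing_anchor <- setdiff(anchors$anchor_id, rownames(d))
  if (length(missing_anchor)) {
    stop("anchor(s) not in distance matrix: ",
         paste(missing_anchor, collapse = ", "))
  }
  genes <- setdiff(rownames(d), anchors$anchor_id)
  groups <- split(anchors$anchor_id, anchors$subfamily)
  res <- lapply(genes, function(g) {
    avg <- vapply(groups, function(a) mean(d[g, a]), numeric(1))
    o <- order(avg)
    if (length(avg) > 1L && abs(avg[o[1L]] - avg[o[2L]]) < 1e-9) {
      warning("gene ", g, " equidistant to subfamilies ",
              names(avg)[o[1L]], " and ", names(avg)[o[2L]], "; unassigned")
      return(data.frame(gene = g, subfamily = NA_character_,
                        dist = avg[o[1L]], stringsAsFactors = FALSE))
    }
    data.frame(gene = g, subfamily = names(avg)[o[1L]], dist = avg[o[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
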