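# Expression analyses: tissue expression-group classification, stress
# differential expression, hormone fold-change response calls, and
# 2^-ddCt quantification of qPCR Ct tables.

#' Average log2 signal per tissue
#'
#' @param mat Genes x samples matrix of log2 signals.
#' @param meta Sample metadata data frame with columns `sample`, `tissue`
#'   (and typically `category`); `meta$sample` must cover `colnames(mat)`.
#' @return Genes x tissues matrix of arithmetic means of the log2 values.
#' @export
average_log2 <- function(mat, meta) {
  stopifnot(is.matrix(mat), all(colnames(mat) %in% meta$sample))
  if (any(!is.finite(mat))) stop("expression matrix contains non-finite values")
  tissues <- unique(meta$tissue[match(colnames(mat), meta$sample)])
  out <- sapply(tissues, function(ti) {
    cols <- meta$sample[meta$tissue == ti]
    cols <- intersect(colnames(mat), cols)
    if (!length(cols)) stop("tissue without samples: ", ti)
    rowMeans(mat[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), tissues))
  out
}

#' Classify genes into four tissue expression groups
#'
#' Rules are evaluated in order: group IV if the maximum tissue mean is
#' below `tau_low`; group I if at least `f_high` of the tissues are at or
#' above `tau_high`; group III if all tissues at or above `tau_high` fall
#' in exactly one category (vegetative or reproductive) and there is at
#' least one such tissue; otherwise group II (relatively high expression
#' in particular tissues spanning both categories). Unset thresholds
#' default to the 70th/30th percentiles of all tissue means, a rule suited
#' to transcriptome-scale matrices; the thresholds used are recorded in
#' every call.
#'
#' @param means Genes x tissues mean log2 matrix (see [average_log2()]).
#' @param categories Named character vector mapping tissue ->
#'   `"vegetative"`/`"reproductive"`.
#' @param tau_high,tau_low Expression thresholds (log2 scale).
#' @param f_high Tissue fraction required for group I.
#' @return Data frame `gene`, `group` (`"I".."IV"`), `max_mean`,
#'   `frac_high`, `tau_high`, `tau_low`.
#' @export
classify_groups <- function(means, categories, tau_high = NULL,
                            tau_low = NULL, f_high = 0.8) {
  stopifnot(is.matrix(means), all(colnames(means) %in% names(categories)))
  if (is.null(tau_high)) tau_high <- stats::quantile(means, 0.7, names = FALSE)
  if (is.null(tau_low)) tau_low <- stats::quantile(means, 0.3, names = FALSE)
  cat_of <- categories[colnames(means)]
  rows <- lapply(rownames(means), function(g) {
    v <- means[g, ]
    high <- v >= tau_high
    group <- if (max(v) < tau_low) {
      "IV"
    } else if (mean(high) >= f_high) {
      "I"
    } else if (any(high) && length(unique(cat_of[high])) == 1L) {
      "III"
    } else {
      "II"
    }
    data.frame(gene = g, group = group, max_mean = max(v),
               frac_high = mean(high), tau_high = tau_high, tau_low = tau_low,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stress differential-expression calls
#'
#' Welch two-sample two-sided t-test on log2 signals per gene, control vs
#' treated; a gene is called iff the raw p-value is below `alpha` (no
#' multiple-testing correction), with direction from the sign of the mean
#' difference. Degenerate zero-variance arms with equal means yield no
#' call.
#'
#' @param control,treated Genes x replicates matrices of log2 signals with
#'   matching row order.
#' @param alpha Significance level (default 0.05).
#' @return Data frame `gene`, `log2fc` (treated - control), `p`,
#'   `direction` (`"up"`, `"down"`, `"none"`).
#' @export
stress_de <- function(control, treated, alpha = 0.05) {
  stopifnot(is.matrix(control), is.matrix(treated),
            nrow(control) == nrow(treated))
  if (ncol(control) < 2L || ncol(treated) < 2L) {
    stop("need >= 2 replicates per arm")
  }
  rows <- lapply(seq_len(nrow(control)), function(i) {
    x <- control[i, ]; y <- treated[i, ]
    lfc <- mean(y) - mean(x)
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (lfc == 0) 1 else 0
    } else {
      stats::t.test(y, x, var.equal = FALSE)$p.value
    }
    dir <- if (p < alpha && lfc != 0) {
      if (lfc > 0) "up" else "down"
    } else "none"
    data.frame(gene = rownames(control)[i] %||% as.character(i),
               log2fc = lfc, p = p, direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hormone response calls from control-normalized relative quantities
#'
#' The control at every time point is normalized to 1; a gene is called up
#' at a time point iff RQ > `high` (default 2, i.e. > 2-fold) and down iff
#' RQ < `low` (default 0.5, i.e. < 50%), both strict. The
#' `early_responsive` flag marks genes called at the 3 h time point for at
#' least one treatment.
#'
#' @param rq Data frame with columns `gene`, `treatment`, `time` (hours),
#'   `rq` (relative quantity, > 0).
#' @param low,high Strict fold-change thresholds.
#' @param early_time Time point defining the early-response flag.
#' @return List with `calls` (rq plus `direction`) and `early` (data frame
#'   `gene`, `early_responsive`).
#' @export
hormone_response <- function(rq, low = 0.5, high = 2.0, early_time = 3) {
  stopifnot(all(c("gene", "treatment", "time", "rq") %in% names(rq)))
  if (any(rq$rq <= 0)) stop("relative quantities must be positive")
  calls <- rq
  calls$direction <- ifelse(rq$rq > high, "up",
                            ifelse(rq$rq < low, "down", "none"))
  early_tab <- calls[calls$time == early_time & calls$direction != "none", ]
  genes <- unique(calls$gene)
  early <- data.frame(gene = genes,
                      early_responsive = genes %in% early_tab$gene,
                      stringsAsFactors = FALSE)
  list(calls = calls, early = early)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = mean Ct of the target minus mean Ct of the reference
#' gene over replicates; ddCt subtracts the calibrator sample's dCt, and
#' RQ = 2^-ddCt. The replicate standard deviation of the target Ct is
#' propagated to an RQ range.
#'
#' @param ct Long-format Ct table: columns `gene`, `sample`, `replicate`,
#'   `ct` (optionally `treatment`, `time`, carried through).
#' @param reference Reference gene id (default the rice ubiquitin gene
#'   Os03g0234200); must be present in every sample.
#' @param calibrator Calibrator sample id.
#' @return Data frame `gene`, `sample`, `dct`, `ddct`, `rq`, `rq_lo`,
#'   `rq_hi` (one row per non-reference gene per sample).
#' @export
ddct <- function(ct, reference = "Os03g0234200", calibrator) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (missing(calibrator)) stop("a calibrator sample id is required")
  samples <- unique(ct$sample)
  if (!calibrator %in% samples) stop("calibrator sample not in table")
  ref_mean <- sapply(samples, function(s) {
    v <- ct$ct[ct$sample == s & ct$gene == reference]
    if (!length(v)) stop("reference gene ", reference, " missing in sample ", s)
    mean(v)
  })
  genes <- setdiff(unique(ct$gene), reference)
  rows <- list()
  for (g in genes) {
    dct <- sapply(samples, function(s) {
      v <- ct$ct[ct$sample == s & ct$gene == g]
      if (!length(v)) return(NA_real_)
      mean(v) - ref_mean[[s]]
    })
    sdct <- sapply(samples, function(s) {
      v <- ct$ct[ct$sample == s & ct$gene == g]
      if (length(v) > 1L) stats::sd(v) else 0
    })
    if (is.na(dct[[calibrator]])) {
      stop("gene ", g, " absent from calibrator sample")
    }
    for (s in samples[!is.na(dct[samples])]) {
      dd <- dct[[s]] - dct[[calibrator]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample = s, dct = dct[[s]], ddct = dd, rq = 2^(-dd),
        rq_lo = 2^(-(dd + sdct[[s]])), rq_hi = 2^(-(dd - sdct[[s]])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
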