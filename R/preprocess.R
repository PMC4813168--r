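#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) to share the same distribution of values: the
#' per-rank means across columns. Within-column rank order is preserved; tied
#' values receive the mean of the reference values across their tied ranks.
#'
#' @param x numeric matrix (features x samples) with finite entries.
#' @return matrix of the same shape and dimnames; the `"stage"` attribute, if
#'   present, is carried over.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("input must be a finite numeric matrix")
  if (ncol(x) < 1L) stop("input must have at least one column")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  attr(out, "stage") <- attr(x, "stage")
  out
}

#' Summarize probe-level values to gene level by median polish
#'
#' For every gene, fits Tukey's additive median-polish decomposition
#' (overall + probe effect + sample effect + residual) to the gene's
#' probe x sample submatrix and reports overall + sample effect as the gene's
#' expression, the standard robust multi-probe summarization.
#'
#' @param values numeric matrix (probes x samples), rownames are probe ids.
#' @param probe_map data frame with columns `probe` and `gene`; every probe
#'   maps to at most one gene.
#' @param maxiter,eps median-polish iteration cap and convergence tolerance.
#' @return numeric matrix (genes x samples); the `"stage"` attribute of
#'   `values`, if present, is carried over.
#' @export
median_polish_summarize <- function(values, probe_map, maxiter = 10L,
                                    eps = 1e-6) {
  values <- as.matrix(values)
  if (!all(c("probe", "gene") %in% names(probe_map)))
    stop("probe_map needs columns 'probe' and 'gene'")
  probe_map$probe <- as.character(probe_map$probe)
  probe_map$gene <- as.character(probe_map$gene)
  if (anyDuplicated(probe_map$probe))
    stop("a probe may map to at most one gene")
  missing <- setdiff(probe_map$probe, rownames(values))
  if (length(missing) > 0L)
    stop("probes absent from the value matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  genes <- sort(unique(probe_map$gene))
  by_gene <- split(probe_map$probe, probe_map$gene)
  out <- matrix(NA_real_, length(genes), ncol(values),
                dimnames = list(genes, colnames(values)))
  for (g in genes) {
    sub <- values[by_gene[[g]], , drop = FALSE]
    if (nrow(sub) == 0L) stop("gene with no probes: ", g)
    if (nrow(sub) == 1L || ncol(sub) == 1L && nrow(sub) == 1L) {
      out[g, ] <- sub[1L, ]
    } else {
      mp <- stats::medpolish(sub, eps = eps, maxiter = maxiter,
                             trace.iter = FALSE)
      out[g, ] <- mp$overall + mp$col
    }
  }
  attr(out, "stage") <- attr(values, "stage")
  out
}

#' Fraction of differentially expressed genes between two stages
#'
#' Welch two-sample t-test per shared gene, Bonferroni correction over the
#' tested genes, and the fraction of genes whose corrected p-value is at most
#' `alpha`.
#'
#' @param a,b numeric expression matrices (genes x samples) with >= 2 samples
#'   each; gene sets must overlap.
#' @param alpha significance level applied to the corrected p-values.
#' @return list with `fraction` (in \[0, 1\]), `p_values` (raw, named by
#'   gene) and `p_adjusted` (Bonferroni).
#' @export
deg_fraction <- function(a, b, alpha = 0.05) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each stage needs at least two samples")
  genes <- intersect(rownames(a), rownames(b))
  if (length(genes) == 0L) stop("the two matrices share no genes")
  p <- vapply(genes, function(g) {
    tryCatch(stats::t.test(a[g, ], b[g, ])$p.value,
             error = function(e) 1)  # constant profiles: no evidence
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "bonferroni")
  list(fraction = mean(padj <= alpha), p_values = p, p_adjusted = padj)
}
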