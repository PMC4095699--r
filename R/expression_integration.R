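#' Copy-number / expression Pearson correlation gate
#'
#' Exact Pearson correlation between per-sample copy number at a locus and
#' log2 expression, with the two-sided p-value from the t transform on
#' n - 2 degrees of freedom.  The gate is one-directional: significant iff
#' r > 0.4 and p <= 0.05.  Zero variance in either vector yields an
#' indeterminate (not significant) result rather than an error.
#'
#' @param cn_values Numeric per-sample copy numbers.
#' @param expr_values Numeric per-sample log2 expression.
#' @param r_min,p_max Gate thresholds (defaults 0.4 and 0.05).
#' @param gene Optional gene label carried through.
#' @return List with `gene`, `r`, `p_value`, `significant`, `n`.
#' @export
cn_expression_correlation <- function(cn_values, expr_values,
                                      r_min = 0.4, p_max = 0.05,
                                      gene = NA_character_) {
  stopifnot(length(cn_values) == length(expr_values),
            length(cn_values) >= 3L)
  ok <- is.finite(cn_values) & is.finite(expr_values)
  cn_values <- cn_values[ok]; expr_values <- expr_values[ok]
  n <- length(cn_values)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(cn_values) == 0 || stats::sd(expr_values) == 0) {
    return(list(gene = gene, r = NA_real_, p_value = NA_real_,
                significant = FALSE, n = n))
  }
  r <- stats::cor(cn_values, expr_values)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(gene = gene, r = r, p_value = p,
       significant = r > r_min && p <= p_max, n = n)
}

#' Welch underexpression test
#'
#' Welch unequal-variance t test between a case group and a reference
#' group (two-sided), with fold change computed on the linear scale as
#' mean(reference) / mean(case), so that "fold change >= 1.5" means at
#' least 1.5-fold lower expression in the cases.  Underexpressed iff
#' p <= 0.05 and fold change >= 1.5.
#'
#' @param case_expr,reference_expr Numeric vectors (each n >= 2), linear
#'   scale.
#' @param p_max,fc_min Rule thresholds.
#' @return List with `t`, `df`, `p_value`, `fold_change`, `underexpressed`.
#' @export
underexpression_test <- function(case_expr, reference_expr,
                                 p_max = 0.05, fc_min = 1.5) {
  if (length(case_expr) < 2L || length(reference_expr) < 2L) {
    stop("each group needs at least 2 observations")
  }
  tt <- stats::t.test(case_expr, reference_expr)  # Welch by default
  fc <- mean(reference_expr) / mean(case_expr)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, fold_change = fc,
       underexpressed = tt$p.value <= p_max && fc >= fc_min)
}

#' Relative expression from qPCR Ct values
#'
#' Delta-Ct method against a reference gene (e.g. TBP) assuming 100%
#' amplification efficiency: `2^-(ct_target - ct_reference)`.
#'
#' @param ct_target,ct_reference Positive Ct values (vectors recycle).
#' @return Numeric relative expression.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  stopifnot(all(ct_target > 0), all(ct_reference > 0))
  2^(-(ct_target - ct_reference))
}

#' Correlate copy number with expression for a panel of gene loci
#'
#' Convenience wrapper: looks up each gene's copy number per sample with
#' [cn_at_locus()] and applies [cn_expression_correlation()] against the
#' matching expression row.
#'
#' @param profiles List of [segment_profile()] objects.
#' @param expr Genes x samples expression matrix (log2).
#' @param loci `data.frame(gene, chrom, pos)`.
#' @param map The `snp_map`.
#' @param r_min,p_max Gate thresholds.
#' @return `data.frame(gene, r, p_value, significant, n)`.
#' @export
correlate_panel <- function(profiles, expr, loci, map = default_snp_map(),
                            r_min = 0.4, p_max = 0.05) {
  stopifnot(all(c("gene", "chrom", "pos") %in% names(loci)))
  ids <- vapply(profiles, function(p) p$sample, character(1))
  stopifnot(all(ids %in% colnames(expr)))
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    g <- loci$gene[i]
    if (!g %in% rownames(expr)) stop("gene ", g, " not in expression matrix")
    cn <- vapply(profiles, function(p) {
      as.numeric(cn_at_locus(p, loci$chrom[i], loci$pos[i], map))
    }, numeric(1))
    res <- cn_expression_correlation(cn, expr[g, ids], r_min, p_max,
                                     gene = g)
    data.frame(gene = g, r = res$r, p_value = res$p_value,
               significant = res$significant, n = res$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
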