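#' Collect promoter methylation-change vs expression-change points
#'
#' One point per (site, nearest gene): sites that lie upstream of their
#' nearest gene's TSS (signed distance in `[-upstream_bp, 0)`), pass the depth
#' filter in both groups, change methylation by at least `cutoff` in absolute
#' value, and whose gene has an expression record. The expression change is
#' `log2((fpkm_b + pseudocount) / (fpkm_a + pseudocount))`.
#'
#' @param calls_a,calls_b methylation call tables (`site_id`, `m`,
#'   `passes_filter`).
#' @param assignments feature assignments from [assign_features()]
#'   (`site_id`, `nearest_gene`, `tss_distance`).
#' @param expression data.frame (`gene_id`, `fpkm_a`, `fpkm_b`).
#' @param upstream_bp upstream window size in bp.
#' @param cutoff minimum absolute methylation change (default 0.25).
#' @param pseudocount added to FPKM before the log ratio.
#' @return data.frame: `site_id`, `gene_id`, `delta_m`, `delta_expr`. May be
#'   empty.
#' @export
collect_meth_expr_points <- function(calls_a, calls_b, assignments, expression,
                                     upstream_bp = 2000L, cutoff = 0.25,
                                     pseudocount = 1) {
  pass <- function(x) x[x$passes_filter, c("site_id", "m")]
  a <- pass(calls_a); b <- pass(calls_b)
  m <- merge(a, b, by = "site_id", suffixes = c("_a", "_b"))
  m <- merge(m, assignments[, c("site_id", "nearest_gene", "tss_distance")],
             by = "site_id")
  m$delta_m <- m$m_b - m$m_a
  m <- m[m$tss_distance >= -upstream_bp & m$tss_distance < 0 &
           abs(m$delta_m) >= cutoff, , drop = FALSE]
  m <- merge(m, expression, by.x = "nearest_gene", by.y = "gene_id")
  m$delta_expr <- log2((m$fpkm_b + pseudocount) / (m$fpkm_a + pseudocount))
  out <- data.frame(site_id = m$site_id, gene_id = m$nearest_gene,
                    delta_m = m$delta_m, delta_expr = m$delta_expr,
                    stringsAsFactors = FALSE)
  out[order(out$site_id), , drop = FALSE]
}

#' Pearson correlation of methylation change vs expression change
#'
#' Two-sided P value from the t transform `t = r * sqrt((n-2)/(1-r^2))` with
#' `n - 2` degrees of freedom (the classical Pearson correlation test).
#'
#' @param points data.frame with `delta_m` and `delta_expr`.
#' @return list: `r`, `p`, `n`.
#' @export
correlate_meth_expr <- function(points) {
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points for a correlation", call. = FALSE)
  if (stats::sd(points$delta_m) == 0 || stats::sd(points$delta_expr) == 0)
    stop("zero variance in a coordinate", call. = FALSE)
  ct <- stats::cor.test(points$delta_m, points$delta_expr, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Scatter plot of methylation change vs expression change
#'
#' Base-graphics scatter mirroring the promoter methylation / expression
#' figure, with the least-squares line and the correlation in the title.
#'
#' @param points data.frame with `delta_m` and `delta_expr`.
#' @param ... passed to [plot()].
#' @return invisibly, the [correlate_meth_expr()] result.
#' @export
plot_meth_expr <- function(points, ...) {
  cr <- correlate_meth_expr(points)
  plot(points$delta_m, points$delta_expr,
       xlab = "methylation change (group B - group A)",
       ylab = "log2 expression change",
       main = sprintf("Pearson r = %.3f, P = %.2g, n = %d", cr$r, cr$p, cr$n),
       pch = 19, col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(stats::lm(delta_expr ~ delta_m, data = points), col = "red")
  invisible(cr)
}

#' Relative expression by the 2^-(ddCt) method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; `ddCt` is the difference
#' of group mean dCt (treated minus control) and the fold change is
#' `2^(-ddCt)`. The P value is a two-sample Student t-test (equal variances)
#' on the replicate dCt values. If both groups' dCt values are constant and
#' equal, the fold change is 1 and `p = 1`.
#'
#' @param ct_target_treated,ct_ref_treated replicate Ct values for the target
#'   and reference gene in the treated group.
#' @param ct_target_control,ct_ref_control the same for the control group.
#' @return list: `fold`, `ddct`, `p`, `dct_treated`, `dct_control`.
#' @export
relative_expression_ddct <- function(ct_target_treated, ct_ref_treated,
                                     ct_target_control, ct_ref_control) {
  if (length(ct_target_treated) != length(ct_ref_treated) ||
      length(ct_target_control) != length(ct_ref_control))
    stop("target and reference Ct vectors must pair up per replicate",
         call. = FALSE)
  if (any(!is.finite(c(ct_ref_treated, ct_ref_control))))
    stop("missing reference-gene Ct", call. = FALSE)
  dct_t <- ct_target_treated - ct_ref_treated
  dct_c <- ct_target_control - ct_ref_control
  ddct <- mean(dct_t) - mean(dct_c)
  p <- if (stats::sd(dct_t) == 0 && stats::sd(dct_c) == 0) {
    if (mean(dct_t) == mean(dct_c)) 1 else 0
  } else {
    stats::t.test(dct_t, dct_c, var.equal = TRUE)$p.value
  }
  list(fold = 2^(-ddct), ddct = ddct, p = p,
       dct_treated = dct_t, dct_control = dct_c)
}

#' Methylation fraction from HpaII-digestion qPCR
#'
#' Methylated templates are protected from HpaII digestion, so the fraction
#' surviving digestion is `2^(Ct_mock - Ct_HpaII)`. Values above 1 (assay
#' noise) are reported as-is with a warning flag, not clamped.
#'
#' @param ct_mock,ct_hpaii Ct of the mock-digested and HpaII-digested
#'   reactions (vectorized).
#' @return data.frame: `fraction`, `above_one`.
#' @export
hpaii_qpcr_fraction <- function(ct_mock, ct_hpaii) {
  frac <- 2^(ct_mock - ct_hpaii)
  above <- frac > 1
  if (any(above))
    warning(sprintf("%d methylation fractions exceed 1 (assay noise)",
                    sum(above)))
  data.frame(fraction = frac, above_one = above)
}
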