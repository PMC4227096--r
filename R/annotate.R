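## Signed TSS distance in transcription orientation: negative = upstream.
tss_distance <- function(pos, tss, strand) {
  if (strand == "+") pos - tss else tss - pos
}

#' CpG-island context of genomic positions
#'
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @param cgis data.frame of islands (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param shore_bp shore width: within `shore_bp` of an island but not inside
#'   one.
#' @return character vector: "island", "shore" or "open_sea".
#' @export
cgi_context <- function(chrom, pos, cgis, shore_bp = 2000L) {
  ctx <- rep("open_sea", length(pos))
  if (is.null(cgis) || nrow(cgis) == 0) return(ctx)
  sites_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  isl_gr <- GenomicRanges::GRanges(cgis$chrom,
                                   IRanges::IRanges(cgis$start + 1L, cgis$end))
  shore_gr <- GenomicRanges::GRanges(
    cgis$chrom,
    IRanges::IRanges(pmax(1L, cgis$start + 1L - shore_bp), cgis$end + shore_bp))
  in_shore <- IRanges::overlapsAny(sites_gr, shore_gr)
  in_isl <- IRanges::overlapsAny(sites_gr, isl_gr)
  ctx[in_shore] <- "shore"
  ctx[in_isl] <- "island"
  ctx
}

#' Assign CCGG sites to gene features and CpG-island context
#'
#' Feature precedence is promoter > exon > intron > intergenic, where the
#' promoter is the `promoter_bp` bases upstream of the TSS in transcription
#' orientation (`[TSS - promoter_bp, TSS)` in signed-distance terms). A site
#' overlapping any gene's promoter is a promoter site regardless of other
#' overlaps. The nearest gene is the one with the smallest absolute TSS
#' distance (ties broken by lexicographic gene id); the signed distance is
#' negative upstream of the TSS.
#'
#' @param sites data.frame (`site_id`, `chrom`, `pos`), 0-based positions.
#' @param genes gene models as in `mscc_genome$genes` (`gene_id`, `chrom`,
#'   `strand`, `start`, `end` 1-based closed, `tss` 0-based).
#' @param exons exon table (`gene_id`, `chrom`, `start`, `end` 1-based closed).
#' @param cgis CpG island BED-style data.frame, 0-based half-open.
#' @param promoter_bp promoter width upstream of the TSS.
#' @param shore_bp CGI shore width.
#' @param chrom_lengths optional named vector; sites outside bounds are an
#'   error when provided.
#' @return data.frame: `site_id`, `feature`, `nearest_gene`, `tss_distance`,
#'   `cgi_context`.
#' @export
assign_features <- function(sites, genes, exons, cgis,
                            promoter_bp = 2000L, shore_bp = 2000L,
                            chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    bad <- sites$pos < 0 | sites$pos >= chrom_lengths[sites$chrom]
    if (any(bad))
      stop(sprintf("%d sites beyond chromosome bounds (first: %s)",
                   sum(bad), sites$site_id[which(bad)[1]]), call. = FALSE)
  }
  n <- nrow(sites)
  sites_gr <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos + 1L, width = 1L))

  ## promoter intervals, 0-based half-open -> GRanges 1-based closed
  prom_start0 <- ifelse(genes$strand == "+", genes$tss - promoter_bp,
                        genes$tss + 1L)
  prom_end0 <- ifelse(genes$strand == "+", genes$tss, genes$tss + 1L + promoter_bp)
  prom_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, prom_start0 + 1L), pmax(0L, prom_end0)))
  exon_gr <- GenomicRanges::GRanges(exons$chrom,
                                    IRanges::IRanges(exons$start, exons$end))
  body_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))

  feature <- rep("intergenic", n)
  feature[IRanges::overlapsAny(sites_gr, body_gr)] <- "intron"
  feature[IRanges::overlapsAny(sites_gr, exon_gr)] <- "exon"
  feature[IRanges::overlapsAny(sites_gr, prom_gr)] <- "promoter"

  nearest_gene <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  gsplit <- split(seq_len(nrow(genes)), genes$chrom)
  for (ch in names(gsplit)) {
    gi <- gsplit[[ch]]
    si <- which(sites$chrom == ch)
    if (!length(si)) next
    g <- genes[gi, , drop = FALSE]
    ## order genes so ties in |distance| resolve to lexicographic gene id
    g <- g[order(g$gene_id), , drop = FALSE]
    dmat <- outer(sites$pos[si], g$tss, "-")
    dmat <- sweep(dmat, 2, ifelse(g$strand == "+", 1L, -1L), "*")
    best <- apply(abs(dmat), 1L, which.min)
    nearest_gene[si] <- g$gene_id[best]
    dist[si] <- dmat[cbind(seq_along(si), best)]
  }
  data.frame(site_id = sites$site_id, feature = feature,
             nearest_gene = nearest_gene, tss_distance = dist,
             cgi_context = cgi_context(sites$chrom, sites$pos, cgis, shore_bp),
             stringsAsFactors = FALSE)
}

#' Methylation meta-profile around transcription start sites
#'
#' Every passing site contributes its methylation level to the distance bin of
#' each gene whose TSS lies within `span` (meta-profile convention: one site
#' can contribute to several genes). Bins with no sites are `NA`; the smoothed
#' curve is a centered moving average over `smooth_k` bins, ignoring missing
#' bins.
#'
#' @param calls methylation call table (`site_id`, `chrom`, `pos`, `m`,
#'   `passes_filter`).
#' @param genes gene models with `chrom`, `strand`, `tss`.
#' @param span half-width (bp) of the window around each TSS.
#' @param bin_bp bin width in bp.
#' @param smooth_k moving-average window (odd, >= 1).
#' @return data.frame: `bin_start`, `bin_end` (signed bp relative to TSS),
#'   `mean_m`, `n_sites`, `smoothed_m`.
#' @export
tss_profile <- function(calls, genes, span = 10000L, bin_bp = 100L,
                        smooth_k = 5L) {
  if (smooth_k < 1L || smooth_k %% 2L == 0L)
    stop("smooth_k must be an odd integer >= 1", call. = FALSE)
  if ("passes_filter" %in% names(calls))
    calls <- calls[calls$passes_filter, , drop = FALSE]
  edges <- seq(-span, span, by = bin_bp)
  nb <- length(edges) - 1L
  acc_m <- numeric(nb); acc_n <- integer(nb)
  for (i in seq_len(nrow(genes))) {
    sub <- calls[calls$chrom == genes$chrom[i], , drop = FALSE]
    if (!nrow(sub)) next
    d <- tss_distance(sub$pos, genes$tss[i], genes$strand[i])
    sel <- d >= -span & d <= span
    if (!any(sel)) next
    b <- pmin(nb, (d[sel] + span) %/% bin_bp + 1L)
    acc_m <- acc_m + as.numeric(tapply(sub$m[sel], factor(b, levels = seq_len(nb)),
                                       sum, default = 0))
    acc_n <- acc_n + as.integer(table(factor(b, levels = seq_len(nb))))
  }
  if (all(acc_n == 0))
    stop("no passing site within the span of any TSS", call. = FALSE)
  mean_m <- ifelse(acc_n > 0, acc_m / acc_n, NA_real_)
  half <- (smooth_k - 1L) %/% 2L
  smoothed <- vapply(seq_len(nb), function(i) {
    w <- mean_m[max(1L, i - half):min(nb, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             mean_m = mean_m, n_sites = acc_n, smoothed_m = smoothed)
}
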