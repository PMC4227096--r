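#' Normalize the two MSCC libraries with spike-in standards
#'
#' Both libraries receive the same spike-in standard DNA, so any difference in
#' their summed standard counts reflects library size / efficiency rather than
#' methylation. The inverse library is rescaled onto the HpaII library by
#' `s = sum(standard HpaII counts) / sum(standard inverse counts)`; HpaII
#' counts are left unchanged. Any common rescaling leaves the methylation
#' level invariant, so the summed-ratio estimator is the minimal-assumption
#' choice.
#'
#' @param counts data.frame with `hpa_count` and `inv_count` columns.
#' @param spikeins data.frame with `hpa_count` and `inv_count` columns for the
#'   standards.
#' @return list: `scale` (the factor `s`) and `counts` with added `hpa_norm`
#'   and `inv_norm` columns.
#' @export
normalize_libraries <- function(counts, spikeins) {
  tot_hpa <- sum(spikeins$hpa_count)
  tot_inv <- sum(spikeins$inv_count)
  if (tot_hpa <= 0 || tot_inv <= 0)
    stop("zero total spike-in count in a library; normalization impossible",
         call. = FALSE)
  s <- tot_hpa / tot_inv
  counts$hpa_norm <- counts$hpa_count
  counts$inv_norm <- counts$inv_count * s
  list(scale = s, counts = counts)
}

#' Call per-site methylation levels from normalized counts
#'
#' The methylation level of a site is the normalized inverse-library fraction
#' `m = inv' / (hpa' + inv')`: inverse-library reads come from methylated
#' (CmCGG/ChmCGG) fragments, HpaII reads from unmethylated ones. Sites with
#' zero normalized depth carry no information and are dropped (tallied in the
#' `n_dropped` attribute). The depth filter is strict: a site passes only if
#' its combined raw reads exceed `min_depth`.
#'
#' @param counts data.frame with `site_id`, `hpa_count`, `inv_count`,
#'   `hpa_norm`, `inv_norm` (see [normalize_libraries()]).
#' @param min_depth raw combined-read threshold; sites with
#'   `hpa_count + inv_count > min_depth` pass.
#' @return data.frame of methylation calls: `site_id`, `m`, `raw_depth`,
#'   `norm_depth`, `passes_filter`; attribute `n_dropped` counts zero-depth
#'   sites removed.
#' @export
call_site_methylation <- function(counts, min_depth = 40) {
  need <- c("site_id", "hpa_count", "inv_count", "hpa_norm", "inv_norm")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$hpa_count < 0 | counts$inv_count < 0))
    stop("negative counts", call. = FALSE)
  norm_depth <- counts$hpa_norm + counts$inv_norm
  drop <- norm_depth == 0
  kept <- counts[!drop, , drop = FALSE]
  calls <- data.frame(
    site_id = kept$site_id,
    m = kept$inv_norm / (kept$hpa_norm + kept$inv_norm),
    raw_depth = kept$hpa_count + kept$inv_count,
    norm_depth = kept$hpa_norm + kept$inv_norm,
    passes_filter = (kept$hpa_count + kept$inv_count) > min_depth,
    stringsAsFactors = FALSE)
  extra <- intersect(c("chrom", "pos"), names(kept))
  for (cl in extra) calls[[cl]] <- kept[[cl]]
  attr(calls, "n_dropped") <- sum(drop)
  calls
}

#' MSCC quantification in one step
#'
#' Convenience wrapper: spike-in normalization followed by site-level
#' methylation calling.
#'
#' @inheritParams normalize_libraries
#' @inheritParams call_site_methylation
#' @return the call table of [call_site_methylation()], with the spike-in
#'   scale factor attached as attribute `scale`.
#' @export
mscc_methylation <- function(counts, spikeins, min_depth = 40) {
  norm <- normalize_libraries(counts, spikeins)
  calls <- call_site_methylation(norm$counts, min_depth = min_depth)
  attr(calls, "scale") <- norm$scale
  calls
}

#' Write methylation calls as a BEDGraph track
#'
#' 0-based half-open single-base intervals with the methylation level as the
#' track value; only passing sites are written by default.
#'
#' @param calls a call table with `chrom`, `pos`, `m`, `passes_filter`.
#' @param path output file.
#' @param passing_only write only sites passing the depth filter.
#' @return invisibly, the number of records written.
#' @export
write_bedgraph <- function(calls, path, passing_only = TRUE) {
  stopifnot(all(c("chrom", "pos", "m") %in% names(calls)))
  x <- if (passing_only && "passes_filter" %in% names(calls))
    calls[calls$passes_filter, , drop = FALSE] else calls
  df <- data.frame(x$chrom, x$pos, x$pos + 1L, signif(x$m, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}
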