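#' Enumerate analysis units: sliding windows and CpG islands
#'
#' Scans each chromosome with consecutive `window_bp` windows overlapping by
#' `overlap_bp` (step `window_bp - overlap_bp`; only full windows are kept)
#' and adds every CpG island as an additional unit. Units retain only the
#' supplied (already depth-filtered) sites; units with fewer than `min_sites`
#' sequenced sites are dropped and tallied, implementing the "more than 3
#' sequenced CpGs" rule.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param sites data.frame (`site_id`, `chrom`, `pos`) of sites sequenced and
#'   passing in both groups.
#' @param cgis optional CpG island data.frame (`chrom`, `start`, `end`),
#'   0-based half-open.
#' @param window_bp window width (default 200).
#' @param overlap_bp overlap between adjacent windows (default 50, i.e. step
#'   150).
#' @param min_sites minimum sequenced sites per unit (default 4, ">3").
#' @return list: `units` data.frame (`unit_id`, `kind`, `chrom`, `start`,
#'   `end`, `n_sites`), `members` data.frame (`unit_id`, `site_id`),
#'   `n_dropped` units discarded for too few sites.
#' @export
enumerate_units <- function(chrom_lengths, sites, cgis = NULL,
                            window_bp = 200L, overlap_bp = 50L,
                            min_sites = 4L) {
  if (overlap_bp >= window_bp || overlap_bp < 0)
    stop("need window_bp > overlap_bp >= 0", call. = FALSE)
  step <- window_bp - overlap_bp
  win <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    if (len < window_bp) next
    starts <- seq(0L, len - window_bp, by = step)
    win[[ch]] <- data.frame(kind = "window", chrom = ch, start = starts,
                            end = starts + window_bp, stringsAsFactors = FALSE)
  }
  units <- if (length(win)) do.call(rbind, win) else
    data.frame(kind = character(0), chrom = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  if (!is.null(cgis) && nrow(cgis) > 0) {
    units <- rbind(units,
                   data.frame(kind = "cgi", chrom = cgis$chrom,
                              start = cgis$start, end = cgis$end,
                              stringsAsFactors = FALSE))
  }
  rownames(units) <- NULL
  units$unit_id <- sprintf("%s_%s_%d_%d", units$kind, units$chrom,
                           units$start, units$end)

  if (nrow(units) == 0 || nrow(sites) == 0) {
    return(list(units = cbind(units[0, ], n_sites = integer(0)),
                members = data.frame(unit_id = character(0),
                                     site_id = character(0)),
                n_dropped = nrow(units)))
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L, width = 1L))
  unit_gr <- GenomicRanges::GRanges(units$chrom,
                                    IRanges::IRanges(units$start + 1L, units$end))
  ov <- GenomicRanges::findOverlaps(unit_gr, site_gr)
  members <- data.frame(
    unit_id = units$unit_id[S4Vectors::queryHits(ov)],
    site_id = sites$site_id[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)
  n_sites <- table(members$unit_id)
  units$n_sites <- as.integer(n_sites[units$unit_id])
  units$n_sites[is.na(units$n_sites)] <- 0L
  keep <- units$n_sites >= min_sites
  dropped <- sum(!keep)
  units <- units[keep, c("unit_id", "kind", "chrom", "start", "end", "n_sites")]
  rownames(units) <- NULL
  members <- members[members$unit_id %in% units$unit_id, , drop = FALSE]
  list(units = units, members = members, n_dropped = dropped)
}

#' Compare analysis units between two groups by paired t-tests
#'
#' For each unit, the methylation levels of its member sites are paired by
#' site across the two groups and tested with a paired Student t-test on
#' `d = m_B - m_A` (df = n-1, two-sided). Sites missing in either group are
#' excluded before the site-count check. If all paired differences are
#' identical (zero variance), the comparison is flagged degenerate with
#' `p = 1` when the common difference is 0 and `p = 0` otherwise.
#'
#' @param units a list from [enumerate_units()] (or any list with `units` and
#'   `members` of the same shape).
#' @param calls_a,calls_b methylation call tables (`site_id`, `m`, optionally
#'   `passes_filter` which is applied).
#' @param min_sites minimum paired sites per unit after intersection.
#' @return data.frame: `unit_id`, `kind`, `chrom`, `start`, `end`, `n_sites`,
#'   `mean_a`, `mean_b`, `delta`, `t_stat`, `p_value`, `degenerate`. Units
#'   with fewer than `min_sites` paired sites are skipped; the number skipped
#'   is in attribute `n_skipped`.
#' @export
compare_units <- function(units, calls_a, calls_b, min_sites = 4L) {
  filt <- function(x) if ("passes_filter" %in% names(x))
    x[x$passes_filter, , drop = FALSE] else x
  calls_a <- filt(calls_a); calls_b <- filt(calls_b)
  ma <- stats::setNames(calls_a$m, calls_a$site_id)
  mb <- stats::setNames(calls_b$m, calls_b$site_id)
  mem <- units$members
  mem$m_a <- ma[mem$site_id]
  mem$m_b <- mb[mem$site_id]
  mem <- mem[!is.na(mem$m_a) & !is.na(mem$m_b), , drop = FALSE]
  res <- lapply(split(mem, mem$unit_id), function(u) {
    n <- nrow(u)
    if (n < min_sites) return(NULL)
    d <- u$m_b - u$m_a
    md <- mean(d); sdd <- stats::sd(d)
    ## all-identical differences up to floating-point noise
    if (n >= 2 && sdd <= 1e-12 * max(1, abs(md))) {
      tt <- if (md == 0) 0 else sign(md) * Inf
      p <- if (md == 0) 1 else 0
      deg <- TRUE
    } else {
      tt <- md / (sdd / sqrt(n))
      p <- 2 * stats::pt(-abs(tt), df = n - 1)
      deg <- FALSE
    }
    data.frame(unit_id = u$unit_id[1], n_sites = n,
               mean_a = mean(u$m_a), mean_b = mean(u$m_b),
               delta = md, t_stat = tt, p_value = p, degenerate = deg,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(unit_id = character(0), n_sites = integer(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      delta = numeric(0), t_stat = numeric(0),
                      p_value = numeric(0), degenerate = logical(0),
                      stringsAsFactors = FALSE)
  meta <- units$units[, c("unit_id", "kind", "chrom", "start", "end")]
  out <- merge(meta, out, by = "unit_id", sort = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Call differentially methylated units
#'
#' A unit is significant when its absolute mean methylation change exceeds
#' `delta_cutoff` (default 25%) and its paired-t P value is below `p_cutoff`
#' (default 0.05), mirroring the raw-P rule of the original scan. A
#' Benjamini-Hochberg column is added for reference but does not gate
#' significance. Overlapping significant windows are additionally merged into
#' maximal intervals.
#'
#' @param comparisons output of [compare_units()].
#' @param delta_cutoff minimum absolute methylation change.
#' @param p_cutoff maximum paired-t P value.
#' @return list: `comparisons` (with `p_bh` and `significant` columns),
#'   `significant` (sorted by P then |delta| descending), `merged`
#'   (per-chromosome maximal intervals covered by significant units).
#' @export
call_dmrs <- function(comparisons, delta_cutoff = 0.25, p_cutoff = 0.05) {
  comparisons$p_bh <- stats::p.adjust(comparisons$p_value, method = "BH")
  comparisons$significant <- abs(comparisons$delta) > delta_cutoff &
    comparisons$p_value < p_cutoff
  sig <- comparisons[comparisons$significant, , drop = FALSE]
  sig <- sig[order(sig$p_value, -abs(sig$delta)), , drop = FALSE]
  rownames(sig) <- NULL
  merged <- if (nrow(sig)) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sig$chrom, IRanges::IRanges(sig$start + 1L, sig$end)))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  }
  list(comparisons = comparisons, significant = sig, merged = merged)
}

#' Write significant units as BED
#'
#' Score column is `-log10(p)` (capped at 1000 for p = 0), name is the unit
#' id.
#'
#' @param significant the `significant` table from [call_dmrs()].
#' @param path output BED path.
#' @return invisibly the number of records written.
#' @export
write_dmr_bed <- function(significant, path) {
  score <- ifelse(significant$p_value > 0,
                  pmin(1000, -log10(significant$p_value)), 1000)
  df <- data.frame(significant$chrom, significant$start, significant$end,
                   significant$unit_id, round(score, 3))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}
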