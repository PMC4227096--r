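#' Simulate per-site true methylation for two groups
#'
#' Draws a true methylation level for every CCGG site from a Beta distribution
#' chosen by its CpG-island context (island, shore, open sea), reproducing the
#' canonical pattern of hypomethylated islands, hypermethylated open sea and
#' intermediate shores. Group B equals group A except inside planted
#' differentially-methylated units, where the configured shift `dm` is applied.
#' To guarantee the planted shift is achieved exactly, baseline methylation of
#' sites inside planted units is resampled from the feasible range
#' (documented in the methods vignette); the result is clipped to \[0,1\]
#' defensively.
#'
#' @param genome an `mscc_genome` object with at least one CCGG site.
#' @param config a [sim_config()] object; `config$planted_dmrs` may name
#'   units (chrom, start, end, dm).
#' @param shore_bp shore width (bp) used for context assignment.
#' @return a list of class `mscc_truth`: `sites` data.frame (`site_id`,
#'   `chrom`, `pos`, `context`, `m_a`, `m_b`, `in_dmr`) and `dmr_units`.
#' @export
simulate_methylome <- function(genome, config, shore_bp = 2000L) {
  validate_sim_config(config)
  sites <- genome$ccgg_sites
  if (nrow(sites) == 0) stop("genome has no CCGG sites", call. = FALSE)
  withr::with_seed(config$seed + 1L, {
    ctx <- cgi_context(sites$chrom, sites$pos, genome$cgis, shore_bp = shore_bp)
    shapes <- list(island = config$beta_island, shore = config$beta_shore,
                   open_sea = config$beta_sea)
    m_a <- numeric(nrow(sites))
    for (cx in names(shapes)) {
      i <- ctx == cx
      if (any(i)) m_a[i] <- stats::rbeta(sum(i), shapes[[cx]][1], shapes[[cx]][2])
    }
    m_b <- m_a
    in_dmr <- rep(FALSE, nrow(sites))
    pd <- config$planted_dmrs
    if (!is.null(pd) && nrow(pd) > 0) {
      for (k in seq_len(nrow(pd))) {
        hit <- sites$chrom == pd$chrom[k] &
          sites$pos >= pd$start[k] & sites$pos < pd$end[k]
        if (!any(hit))
          stop(sprintf("planted unit %s:%d-%d contains no CCGG site",
                       pd$chrom[k], pd$start[k], pd$end[k]), call. = FALSE)
        dm <- pd$dm[k]
        lo <- max(0.02, 0.02 - dm)
        hi <- min(0.98, 0.98 - dm)
        m_a[hit] <- stats::runif(sum(hit), lo, hi)
        m_b[hit] <- m_a[hit] + dm
        in_dmr[hit] <- TRUE
      }
    }
    m_b <- pmin(1, pmax(0, m_b))
    truth <- data.frame(site_id = sites$site_id, chrom = sites$chrom,
                        pos = sites$pos, context = ctx,
                        m_a = m_a, m_b = m_b, in_dmr = in_dmr,
                        stringsAsFactors = FALSE)
    structure(list(sites = truth,
                   dmr_units = if (is.null(pd)) {
                     data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), dm = numeric(0))
                   } else pd),
              class = "mscc_truth")
  })
}

#' Pick candidate DMR units to plant in a synthetic genome
#'
#' Selects mutually non-overlapping windows from the scanner's own window
#' grid (width `width`, overlap `overlap_bp`) that contain more than
#' `min_sites` CCGG sites, so the downstream caller's sensitivity is well
#' defined: every planted unit is exactly one scan window.
#'
#' @param genome an `mscc_genome` object.
#' @param n number of units to select.
#' @param dm methylation shift to assign to every selected unit.
#' @param width unit width in bp.
#' @param overlap_bp overlap of the scan grid the units are drawn from.
#' @param min_sites the scanner's minimum sequenced sites per unit;
#'   site-rich windows are preferred so depth-filter attrition rarely drops
#'   a planted unit.
#' @param seed RNG seed for the selection.
#' @return data.frame (`chrom`, `start`, `end`, `dm`) suitable for
#'   `sim_config(planted_dmrs = ...)`.
#' @export
select_dmr_units <- function(genome, n, dm = 0.3, width = 200L,
                             overlap_bp = 50L, min_sites = 4L, seed = 1L) {
  units <- enumerate_units(genome$chrom_lengths, sites = genome$ccgg_sites,
                           cgis = NULL, window_bp = width,
                           overlap_bp = overlap_bp,
                           min_sites = min_sites)$units
  withr::with_seed(seed, {
    ord <- sample.int(nrow(units))
  })
  ## greedy pick of mutually non-overlapping units on the scanner's own grid,
  ## preferring site-rich windows (robust to depth-filter attrition)
  ord <- ord[order(-units$n_sites[ord])]  # stable: ties stay shuffled
  pick <- list()
  for (i in ord) {
    u <- units[i, ]
    clash <- any(vapply(pick, function(p)
      p$chrom == u$chrom && p$start < u$end && u$start < p$end, logical(1)))
    if (!clash) pick[[length(pick) + 1L]] <- u
    if (length(pick) == n) break
  }
  if (length(pick) < n)
    stop(sprintf("only %d non-overlapping units with >= %d sites; cannot plant %d",
                 length(pick), min_sites, n), call. = FALSE)
  pick <- do.call(rbind, pick)
  data.frame(chrom = pick$chrom, start = pick$start, end = pick$end, dm = dm,
             stringsAsFactors = FALSE)
}

#' Simulate unit-structured methylomes without a genome
#'
#' Lays `n_units` analysis units (width `unit_bp`, non-overlapping) on a
#' single synthetic chromosome with `sites_per_unit` CCGG sites each, plants a
#' methylation shift `dm` in the first `n_dmr` units, and returns true
#' methylomes for two groups. This is the generator used for caller
#' sensitivity / specificity studies where genome-scale realism is not needed.
#' Null-unit baselines are uniform on (0.05, 0.95); planted-unit baselines are
#' drawn so the full shift fits in \[0,1\].
#'
#' @param n_units total number of units.
#' @param n_dmr number of units (taken from the start) with a planted shift.
#' @param sites_per_unit CCGG sites per unit.
#' @param dm planted methylation shift (group B minus group A).
#' @param unit_bp unit width in bp.
#' @param seed RNG seed.
#' @return list: `sites` (site_id, unit_id, chrom, pos, m_a, m_b), `units`
#'   (unit_id, chrom, start, end, is_dmr, dm).
#' @export
simulate_unit_methylomes <- function(n_units, n_dmr, sites_per_unit = 6L,
                                     dm = 0.3, unit_bp = 200L, seed = 1L) {
  stopifnot(n_dmr <= n_units, sites_per_unit >= 1L)
  withr::with_seed(seed, {
    starts <- (seq_len(n_units) - 1L) * (unit_bp + 200L)
    units <- data.frame(unit_id = sprintf("unit%05d", seq_len(n_units)),
                        kind = "window", chrom = "chrU",
                        start = starts, end = starts + unit_bp,
                        is_dmr = seq_len(n_units) <= n_dmr, dm = 0,
                        stringsAsFactors = FALSE)
    units$dm[units$is_dmr] <- dm
    offs <- round(seq(10, unit_bp - 10, length.out = sites_per_unit))
    pos <- rep(starts, each = sites_per_unit) + rep(offs, n_units)
    uid <- rep(units$unit_id, each = sites_per_unit)
    is_dmr <- rep(units$is_dmr, each = sites_per_unit)
    m_a <- stats::runif(length(pos), 0.05, 0.95)
    if (any(is_dmr)) {
      lo <- max(0.02, 0.02 - dm); hi <- min(0.98, 0.98 - dm)
      m_a[is_dmr] <- stats::runif(sum(is_dmr), lo, hi)
    }
    m_b <- m_a + ifelse(is_dmr, dm, 0)
    m_b <- pmin(1, pmax(0, m_b))
    sites <- data.frame(site_id = sprintf("s%06d", seq_along(pos)),
                        unit_id = uid, chrom = "chrU", pos = pos,
                        m_a = m_a, m_b = m_b, stringsAsFactors = FALSE)
    list(sites = sites, units = units)
  })
}
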