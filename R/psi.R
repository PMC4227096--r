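## Junction-read model for an exon-skipping event: the inclusion isoform
## spans two junctions, the exclusion isoform one, so at percent-spliced-in
## psi an observed junction read is inclusion-type with probability
## f(psi) = 2*psi / (1 + psi).

psi_grid_points <- function(grid_n = 2001L) seq(0, 1, length.out = grid_n)

## log binomial kernel I*log f + E*log(1-f) with the 0*log(0) = 0 convention
psi_loglik <- function(incl, excl, psi) {
  f <- 2 * psi / (1 + psi)
  t1 <- if (incl == 0) rep(0, length(f)) else incl * log(f)
  t2 <- if (excl == 0) rep(0, length(f)) else excl * log1p(-f)
  t1 + t2
}

## log trapezoid quadrature weights on a uniform grid over [0,1]
psi_logweights <- function(grid_n = 2001L) {
  h <- 1 / (grid_n - 1)
  log(c(h / 2, rep(h, grid_n - 2L), h / 2))
}

logsumexp <- function(x) {
  m <- max(x[is.finite(x)], -Inf)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Estimate percent-spliced-in (Psi) from junction read counts
#'
#' Bayesian estimate under the two-inclusion-junction read model: likelihood
#' `Binomial(I; I+E, 2*psi/(1+psi))` with a uniform prior on psi, evaluated on
#' a fixed uniform grid. Reports the posterior mean, a central credible
#' interval from posterior quantiles, and the closed-form point estimate
#' `psi_tilde = (I/2) / (I/2 + E)` obtained by inverting the read-type
#' fraction.
#'
#' @param incl inclusion junction reads (summed over the two inclusion
#'   junctions).
#' @param excl exclusion junction reads.
#' @param grid_n number of grid points (default 2001).
#' @param conf credible-interval mass (default 0.95).
#' @return list: `psi_hat` (posterior mean), `lo`, `hi`, `psi_point`
#'   (closed form), `n_reads`.
#' @export
estimate_psi <- function(incl, excl, grid_n = 2001L, conf = 0.95) {
  if (incl < 0 || excl < 0) stop("negative read counts", call. = FALSE)
  if (incl + excl < 1) stop("no junction reads: psi is undefined", call. = FALSE)
  psi <- psi_grid_points(grid_n)
  ll <- psi_loglik(incl, excl, psi)
  w <- exp(ll - max(ll[is.finite(ll)]))
  w <- w / sum(w)
  psi_hat <- sum(w * psi)
  cw <- cumsum(w)
  a <- (1 - conf) / 2
  lo <- psi[which(cw >= a)[1]]
  hi <- psi[which(cw >= 1 - a)[1]]
  list(psi_hat = psi_hat, lo = lo, hi = hi,
       psi_point = (incl / 2) / (incl / 2 + excl),
       n_reads = incl + excl)
}

#' Bayes factor for differential exon skipping between two groups
#'
#' Compares the evidence for independent psi values in the two groups
#' (uniform priors) against a single shared psi (uniform prior), with all
#' evidences computed by trapezoid integration of the binomial junction-read
#' likelihood over the same fixed grid, accumulated in log space. `delta_psi`
#' is the difference of the groups' posterior means (group B minus group A).
#'
#' @param incl_a,excl_a junction reads in group A (e.g. saline).
#' @param incl_b,excl_b junction reads in group B (e.g. morphine).
#' @param grid_n number of grid points (default 2001).
#' @return list: `psi_a`, `psi_b`, `delta_psi`, `log_bf` (natural log),
#'   `bayes_factor`.
#' @export
psi_bayes_factor <- function(incl_a, excl_a, incl_b, excl_b, grid_n = 2001L) {
  if (incl_a + excl_a < 1 || incl_b + excl_b < 1)
    stop("each group needs at least one junction read", call. = FALSE)
  psi <- psi_grid_points(grid_n)
  lw <- psi_logweights(grid_n)
  ll_a <- psi_loglik(incl_a, excl_a, psi)
  ll_b <- psi_loglik(incl_b, excl_b, psi)
  log_m1 <- logsumexp(ll_a + lw) + logsumexp(ll_b + lw)
  log_m0 <- logsumexp(ll_a + ll_b + lw)
  log_bf <- log_m1 - log_m0
  est_a <- estimate_psi(incl_a, excl_a, grid_n)
  est_b <- estimate_psi(incl_b, excl_b, grid_n)
  list(psi_a = est_a$psi_hat, psi_b = est_b$psi_hat,
       delta_psi = est_b$psi_hat - est_a$psi_hat,
       log_bf = log_bf, bayes_factor = exp(log_bf))
}

#' Score a table of exon-skipping events
#'
#' Applies [psi_bayes_factor()] to every event of a long-format junction
#' count table with exactly two groups.
#'
#' @param counts data.frame (`event_id`, `group`, `inclusion_reads`,
#'   `exclusion_reads`).
#' @param group_a,group_b the two group labels; `delta_psi` is B minus A
#'   (treatment minus control: positive = more exon inclusion under
#'   treatment).
#' @param grid_n grid size for the posterior computations.
#' @return data.frame: `event_id`, per-group read totals, `psi_a`, `psi_b`,
#'   `delta_psi`, `log_bf`, `bayes_factor`.
#' @export
score_skipping_events <- function(counts, group_a, group_b, grid_n = 2001L) {
  need <- c("event_id", "group", "inclusion_reads", "exclusion_reads")
  stopifnot(all(need %in% names(counts)))
  ev <- unique(counts$event_id)
  rows <- lapply(ev, function(e) {
    a <- counts[counts$event_id == e & counts$group == group_a, ]
    b <- counts[counts$event_id == e & counts$group == group_b, ]
    if (nrow(a) != 1 || nrow(b) != 1)
      stop(sprintf("event %s needs exactly one row per group", e), call. = FALSE)
    r <- psi_bayes_factor(a$inclusion_reads, a$exclusion_reads,
                          b$inclusion_reads, b$exclusion_reads, grid_n)
    data.frame(event_id = e,
               reads_a = a$inclusion_reads + a$exclusion_reads,
               reads_b = b$inclusion_reads + b$exclusion_reads,
               psi_a = r$psi_a, psi_b = r$psi_b, delta_psi = r$delta_psi,
               log_bf = r$log_bf, bayes_factor = r$bayes_factor,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter differential exon-skipping events
#'
#' Keeps events whose Bayes factor meets the (strict, conservative) threshold
#' and which have at least `min_reads` junction reads in both groups; sorted
#' by Bayes factor descending.
#'
#' @param results output of [score_skipping_events()].
#' @param bf_threshold minimum Bayes factor (default 1000).
#' @param min_reads minimum junction reads per group (default 20).
#' @return the filtered, sorted data.frame.
#' @export
call_des <- function(results, bf_threshold = 1000, min_reads = 20L) {
  keep <- results$bayes_factor >= bf_threshold &
    results$reads_a >= min_reads & results$reads_b >= min_reads
  out <- results[keep, , drop = FALSE]
  out <- out[order(-out$bayes_factor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse a coordinate-triplet exon-skipping event id
#'
#' Event ids of the form
#' `chrN:start:end:strand@chrN:start:end:strand@chrN:start:end:strand`
#' (upstream exon, alternative exon, downstream exon).
#'
#' @param event_id a single event-id string.
#' @return data.frame with one row per exon block: `chrom`, `start`, `end`,
#'   `strand`, `role`.
#' @export
parse_event_id <- function(event_id) {
  stopifnot(length(event_id) == 1L)
  blocks <- strsplit(event_id, "@", fixed = TRUE)[[1]]
  if (length(blocks) != 3L)
    stop("event id must have three @-separated exon blocks", call. = FALSE)
  parts <- strsplit(blocks, ":", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) != 4L))
    stop("each exon block must be chrom:start:end:strand", call. = FALSE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             start = as.integer(vapply(parts, `[`, "", 2L)),
             end = as.integer(vapply(parts, `[`, "", 3L)),
             strand = vapply(parts, `[`, "", 4L),
             role = c("upstream", "alternative", "downstream"),
             stringsAsFactors = FALSE)
}
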