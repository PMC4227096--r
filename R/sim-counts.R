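#' Simulate MSCC two-library tag counts for one sample
#'
#' For each site the total sequencing depth is negative-binomial
#' (overdispersed relative to Poisson, stressing the depth filter); the
#' inverse-library count (reads from methylated CmCGG/ChmCGG fragments) is
#' binomial in the true methylation level, and the HpaII-library count
#' (unmethylated CCGG fragments) is the remainder. Each library's counts are
#' then scaled by that library's global efficiency factor, emulating the
#' library-size/efficiency imbalance that spike-in normalization corrects.
#' Spike-in standard counts are Poisson around the configured mean and scaled
#' by the same factors.
#'
#' @param truth_sites data.frame with columns `site_id` and `m` (true
#'   methylation in \[0,1\]); see [simulate_methylome()].
#' @param config a [sim_config()] object (`depth_mean`, `depth_size`,
#'   `efficiency`, `n_spikeins`, `spikein_mean`).
#' @param seed RNG seed for this sample (defaults to `config$seed`).
#' @return list of class `mscc_sample`: `counts` data.frame (`site_id`,
#'   `hpa_count`, `inv_count`, `true_depth`), `spikeins` data.frame
#'   (`standard_id`, `hpa_count`, `inv_count`).
#' @export
simulate_mscc_counts <- function(truth_sites, config, seed = config$seed) {
  stopifnot(all(c("site_id", "m") %in% names(truth_sites)))
  m <- truth_sites$m
  if (any(m < 0 | m > 1)) stop("true methylation outside [0,1]", call. = FALSE)
  eff <- config$efficiency
  withr::with_seed(seed, {
    n <- length(m)
    depth <- stats::rnbinom(n, size = config$depth_size, mu = config$depth_mean)
    inv <- stats::rbinom(n, depth, m)
    hpa <- depth - inv
    counts <- data.frame(
      site_id = truth_sites$site_id,
      hpa_count = as.integer(round(hpa * eff[["hpa"]])),
      inv_count = as.integer(round(inv * eff[["inv"]])),
      true_depth = depth,
      stringsAsFactors = FALSE)
    base <- stats::rpois(2L * config$n_spikeins, config$spikein_mean)
    spike <- data.frame(
      standard_id = sprintf("std%02d", seq_len(config$n_spikeins)),
      hpa_count = as.integer(round(base[seq_len(config$n_spikeins)] * eff[["hpa"]])),
      inv_count = as.integer(round(
        base[config$n_spikeins + seq_len(config$n_spikeins)] * eff[["inv"]])),
      stringsAsFactors = FALSE)
    structure(list(counts = counts, spikeins = spike), class = "mscc_sample")
  })
}

#' Simulate a gene expression table coupled to promoter methylation change
#'
#' The log2 fold change of each gene is `slope * mean promoter delta-m` plus
#' Gaussian noise, emulating the weak negative coupling between promoter
#' methylation gain and expression. Baseline FPKM is log-normal.
#'
#' @param truth an `mscc_truth` object (per-site `m_a`, `m_b`).
#' @param genome an `mscc_genome` object (for TSS positions).
#' @param config a [sim_config()] object (`expr_slope`, `expr_noise_sd`,
#'   `upstream_bp`, `fpkm_meanlog`, `fpkm_sdlog`).
#' @return data.frame: `gene_id`, `fpkm_a`, `fpkm_b`, `true_log2fc`,
#'   `promoter_dm` (0 for genes with no upstream site).
#' @export
simulate_expression <- function(truth, genome, config) {
  g <- genome$genes
  s <- truth$sites
  withr::with_seed(config$seed + 2L, {
    dm <- vapply(seq_len(nrow(g)), function(i) {
      d <- tss_distance(s$pos[s$chrom == g$chrom[i]], g$tss[i], g$strand[i])
      sel <- d >= -config$upstream_bp & d < 0
      if (!any(sel)) return(0)
      ss <- s[s$chrom == g$chrom[i], ][sel, ]
      mean(ss$m_b - ss$m_a)
    }, numeric(1))
    l2fc <- config$expr_slope * dm +
      stats::rnorm(nrow(g), 0, config$expr_noise_sd)
    fpkm_a <- stats::rlnorm(nrow(g), config$fpkm_meanlog, config$fpkm_sdlog)
    data.frame(gene_id = g$gene_id, fpkm_a = fpkm_a,
               fpkm_b = fpkm_a * 2^l2fc, true_log2fc = l2fc,
               promoter_dm = dm, stringsAsFactors = FALSE)
  })
}

#' Simulate junction reads for exon-skipping events
#'
#' Under the two-inclusion-junction read geometry (an inclusion isoform
#' contributes two junctions, the exclusion isoform one), a junction read is
#' inclusion-type with probability `2*psi/(1+psi)`. Inclusion reads are
#' binomial in that probability at the configured total depth.
#'
#' @param psi_truth data.frame (`event_id`, `group`, `psi`), true
#'   percent-spliced-in per event per group.
#' @param n_reads total junction reads per event per group (recycled).
#' @param seed RNG seed.
#' @return data.frame: `event_id`, `group`, `inclusion_reads`,
#'   `exclusion_reads`, `true_psi`.
#' @export
simulate_junction_reads <- function(psi_truth, n_reads = 500L, seed = 1L) {
  stopifnot(all(c("event_id", "group", "psi") %in% names(psi_truth)))
  if (any(psi_truth$psi < 0 | psi_truth$psi > 1))
    stop("true psi outside [0,1]", call. = FALSE)
  withr::with_seed(seed, {
    n <- rep_len(as.integer(n_reads), nrow(psi_truth))
    p_incl <- 2 * psi_truth$psi / (1 + psi_truth$psi)
    incl <- stats::rbinom(nrow(psi_truth), n, p_incl)
    data.frame(event_id = psi_truth$event_id, group = psi_truth$group,
               inclusion_reads = incl, exclusion_reads = n - incl,
               true_psi = psi_truth$psi, stringsAsFactors = FALSE)
  })
}

#' Simulate conditioned-place-preference session logs
#'
#' Per animal and phase, the 900-second session is partitioned between the
#' drug-paired compartment, the saline-paired compartment and the central
#' passage by a Dirichlet draw. In the post-conditioning phase the morphine
#' group's mean drug-side share is raised by `cpp_effect` (capped at 0.95);
#' saline animals keep the baseline allocation.
#'
#' @param config a [sim_config()] object (`n_morphine`, `n_saline`,
#'   `session_s`, `drug_pref_pre`, `passage_frac`, `cpp_effect`,
#'   `cpp_concentration`).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return data.frame: `animal_id`, `group`, `phase`, `drug_s`, `saline_s`,
#'   `passage_s`; times per row sum to `session_s`.
#' @export
simulate_cpp_sessions <- function(config, seed = config$seed) {
  withr::with_seed(seed, {
    animals <- data.frame(
      animal_id = c(sprintf("M%02d", seq_len(config$n_morphine)),
                    sprintf("S%02d", seq_len(config$n_saline))),
      group = c(rep("morphine", config$n_morphine),
                rep("saline", config$n_saline)),
      stringsAsFactors = FALSE)
    rdirich <- function(alpha) {
      x <- stats::rgamma(length(alpha), shape = alpha)
      x / sum(x)
    }
    rows <- list()
    for (i in seq_len(nrow(animals))) {
      for (phase in c("pre", "post")) {
        p_drug <- config$drug_pref_pre
        if (phase == "post" && animals$group[i] == "morphine")
          p_drug <- min(0.95, p_drug + config$cpp_effect)
        p_pass <- min(config$passage_frac, (1 - p_drug) / 2)
        alpha <- config$cpp_concentration *
          c(p_drug, 1 - p_drug - p_pass, p_pass)
        w <- rdirich(alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = animals$animal_id[i], group = animals$group[i],
          phase = phase,
          drug_s = w[1] * config$session_s,
          saline_s = w[2] * config$session_s,
          passage_s = w[3] * config$session_s,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
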