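#' Methylation-recovery study
#'
#' Simulates sites with a bimodal (island/shore/open-sea-like) true
#' methylation mixture, runs the full MSCC quantification path, and measures
#' accuracy. Two sub-studies: (i) equal library efficiencies, where RMSE over
#' passing sites is reported; (ii) an imbalanced inverse library (efficiency
#' 0.5), where the mean bias is reported with and without spike-in
#' normalization.
#'
#' @param n_sites number of simulated CCGG sites.
#' @param depth mean sequencing depth per site.
#' @param seed RNG seed.
#' @return list: `rmse` (equal efficiencies, passing sites),
#'   `bias_normalized`, `bias_unnormalized` (mean of estimate minus truth
#'   under efficiencies 1.0 / 0.5), `n_sites`.
#' @export
study_methylation_recovery <- function(n_sites = 10000L, depth = 60,
                                       seed = 1L) {
  m <- withr::with_seed(seed, {
    ctx <- sample(1:3, n_sites, replace = TRUE, prob = c(0.3, 0.2, 0.5))
    ifelse(ctx == 1, stats::rbeta(n_sites, 0.5, 10),
           ifelse(ctx == 2, stats::rbeta(n_sites, 2, 2),
                  stats::rbeta(n_sites, 10, 0.5)))
  })
  ids <- sprintf("s%06d", seq_len(n_sites))
  truth <- data.frame(site_id = ids, m = m)

  cfg_eq <- sim_config(seed = seed, depth_mean = depth)
  smp <- simulate_mscc_counts(truth, cfg_eq, seed = seed + 1L)
  calls <- mscc_methylation(smp$counts, smp$spikeins)
  idx <- match(calls$site_id, ids)
  pass <- calls$passes_filter
  rmse <- sqrt(mean((calls$m[pass] - m[idx][pass])^2))

  cfg_im <- sim_config(seed = seed, depth_mean = depth,
                       efficiency = c(hpa = 1, inv = 0.5))
  smp2 <- simulate_mscc_counts(truth, cfg_im, seed = seed + 2L)
  calls2 <- mscc_methylation(smp2$counts, smp2$spikeins)
  idx2 <- match(calls2$site_id, ids)
  bias_norm <- mean(calls2$m - m[idx2])
  raw <- smp2$counts
  raw$hpa_norm <- raw$hpa_count
  raw$inv_norm <- raw$inv_count
  calls2u <- call_site_methylation(raw)
  idx2u <- match(calls2u$site_id, ids)
  bias_unnorm <- mean(calls2u$m - m[idx2u])

  list(rmse = rmse, bias_normalized = bias_norm,
       bias_unnormalized = bias_unnorm, n_sites = n_sites)
}

#' Differential-methylation caller recovery study
#'
#' Plants `n_dmr` shifted units among `n_null` null units
#' ([simulate_unit_methylomes()]), simulates MSCC counts for both groups,
#' quantifies methylation through the full path, and runs the paired-t unit
#' scan with the default 25% / P<0.05 rule. Sensitivity is the fraction of
#' planted units called; the null call rate is the fraction of null units
#' called (untested units count as not called).
#'
#' @param n_null,n_dmr null and planted unit counts.
#' @param sites_per_unit CCGG sites per unit.
#' @param dm planted methylation shift.
#' @param depth mean sequencing depth.
#' @param seed RNG seed.
#' @return list: `sensitivity`, `null_call_rate`, `n_tested`, `n_called`.
#' @export
study_dmr_recovery <- function(n_null = 5000L, n_dmr = 50L,
                               sites_per_unit = 6L, dm = 0.3, depth = 60,
                               seed = 1L) {
  um <- simulate_unit_methylomes(n_units = n_null + n_dmr, n_dmr = n_dmr,
                                 sites_per_unit = sites_per_unit, dm = dm,
                                 seed = seed)
  cfg <- sim_config(seed = seed, depth_mean = depth)
  calls <- lapply(c(a = "m_a", b = "m_b"), function(col) {
    smp <- simulate_mscc_counts(
      data.frame(site_id = um$sites$site_id, m = um$sites[[col]]),
      cfg, seed = seed + match(col, c("m_a", "m_b")))
    mscc_methylation(smp$counts, smp$spikeins)
  })
  units <- list(units = um$units,
                members = data.frame(unit_id = um$sites$unit_id,
                                     site_id = um$sites$site_id,
                                     stringsAsFactors = FALSE))
  cmp <- compare_units(units, calls$a, calls$b)
  dm_call <- call_dmrs(cmp)
  called <- dm_call$comparisons$unit_id[dm_call$comparisons$significant]
  planted <- um$units$unit_id[um$units$is_dmr]
  nulls <- um$units$unit_id[!um$units$is_dmr]
  list(sensitivity = mean(planted %in% called),
       null_call_rate = mean(nulls %in% called),
       n_tested = nrow(cmp), n_called = length(called))
}

#' Psi posterior-mean accuracy study
#'
#' For each true psi on a grid, repeatedly simulates junction reads under the
#' two-junction read model and measures the absolute error of the posterior
#' mean.
#'
#' @param psi_values true psi grid.
#' @param n_reads junction reads per replicate.
#' @param reps replicates per psi value.
#' @param seed RNG seed.
#' @return list: `mean_abs_error` (averaged over the grid and replicates),
#'   `per_psi` named vector.
#' @export
study_psi_accuracy <- function(psi_values = seq(0.1, 0.9, by = 0.1),
                               n_reads = 200L, reps = 50L, seed = 1L) {
  per <- vapply(seq_along(psi_values), function(i) {
    psi <- psi_values[i]
    tr <- data.frame(event_id = sprintf("e%03d", seq_len(reps)),
                     group = "g", psi = psi)
    jr <- simulate_junction_reads(tr, n_reads, seed = seed + i)
    errs <- vapply(seq_len(reps), function(k)
      abs(estimate_psi(jr$inclusion_reads[k], jr$exclusion_reads[k])$psi_hat -
            psi), numeric(1))
    mean(errs)
  }, numeric(1))
  list(mean_abs_error = mean(per),
       per_psi = stats::setNames(per, psi_values))
}

#' Differential exon-skipping detection power study
#'
#' Replicated two-group simulations at fixed true psi values; an event is
#' called when its Bayes factor reaches `bf_threshold`.
#'
#' @param psi_a,psi_b true psi per group (equal values give the null rate).
#' @param n_reads junction reads per group.
#' @param reps number of replicates.
#' @param bf_threshold calling threshold.
#' @param seed RNG seed.
#' @return list: `call_rate`, `reps`.
#' @export
study_des_power <- function(psi_a = 0.25, psi_b = 0.75, n_reads = 500L,
                            reps = 100L, bf_threshold = 1000, seed = 1L) {
  tr <- rbind(data.frame(event_id = sprintf("r%03d", seq_len(reps)),
                         group = "a", psi = psi_a),
              data.frame(event_id = sprintf("r%03d", seq_len(reps)),
                         group = "b", psi = psi_b))
  jr <- simulate_junction_reads(tr, n_reads, seed = seed)
  res <- score_skipping_events(jr, "a", "b")
  list(call_rate = mean(res$bayes_factor >= bf_threshold), reps = reps)
}

#' Methylation-expression coupling recovery study
#'
#' Repeated simulations of promoter methylation changes coupled to expression
#' (slope `expr_slope`, Gaussian noise), pushed through feature assignment,
#' point collection (25% cutoff) and the Pearson correlation test. Reports
#' how often the recovered correlation is negative with p below `p_cutoff`.
#'
#' @param n_runs number of replicates.
#' @param n_genes genes (one upstream CpG site each) per replicate.
#' @param expr_slope,expr_noise_sd coupling parameters.
#' @param p_cutoff significance threshold on the correlation test.
#' @param seed RNG seed.
#' @return list: `sign_recovery_rate`, `mean_r`, `n_runs`.
#' @export
study_meth_expr_recovery <- function(n_runs = 100L, n_genes = 200L,
                                     expr_slope = -2, expr_noise_sd = 0.5,
                                     p_cutoff = 0.01, seed = 1L) {
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      chrom = "chr1", strand = "+",
                      start = seq_len(n_genes) * 10000L + 1L,
                      end = seq_len(n_genes) * 10000L + 3000L,
                      tss = seq_len(n_genes) * 10000L)
  sites <- data.frame(site_id = sprintf("s%03d", seq_len(n_genes)),
                      chrom = "chr1", pos = seq_len(n_genes) * 10000L - 500L)
  ann <- assign_features(
    sites, genes,
    data.frame(gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0)),
    data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  hits <- 0L; rs <- numeric(n_runs)
  for (k in seq_len(n_runs)) {
    dm <- withr::with_seed(seed + 7L * k, stats::runif(n_genes, -0.6, 0.6))
    truth <- list(sites = data.frame(site_id = sites$site_id, chrom = "chr1",
                                     pos = sites$pos, m_a = 0.4,
                                     m_b = pmin(1, pmax(0, 0.4 + dm))))
    cfg <- sim_config(seed = seed + 7L * k + 1L, expr_slope = expr_slope,
                      expr_noise_sd = expr_noise_sd)
    expr <- simulate_expression(truth, list(genes = genes), cfg)
    calls_a <- data.frame(site_id = sites$site_id, m = truth$sites$m_a,
                          passes_filter = TRUE)
    calls_b <- data.frame(site_id = sites$site_id, m = truth$sites$m_b,
                          passes_filter = TRUE)
    pts <- collect_meth_expr_points(calls_a, calls_b, ann,
                                    data.frame(gene_id = expr$gene_id,
                                               fpkm_a = expr$fpkm_a,
                                               fpkm_b = expr$fpkm_b))
    cr <- correlate_meth_expr(pts)
    rs[k] <- cr$r
    if (cr$r < 0 && cr$p < p_cutoff) hits <- hits + 1L
  }
  list(sign_recovery_rate = hits / n_runs, mean_r = mean(rs),
       n_runs = n_runs)
}

#' Behavioral-test calibration study
#'
#' Replicated CPP simulations at a configured conditioning effect; reports
#' how often the morphine group's paired post-vs-pre t-test rejects at
#' `alpha`. With `effect = 0` this is the type-I error; with the default
#' effect it is the power at the configured group size.
#'
#' @param effect conditioning effect (drug-side share increase).
#' @param n_reps number of replicate experiments.
#' @param n_morphine morphine-group size.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list: `rejection_rate`, `n_reps`.
#' @export
study_cpp_calibration <- function(effect = 0.57, n_reps = 100L,
                                  n_morphine = 6L, alpha = 0.05, seed = 1L) {
  cfg <- sim_config(seed = seed, cpp_effect = effect,
                    n_morphine = n_morphine, n_saline = 2L)
  rej <- 0L
  for (k in seq_len(n_reps)) {
    s <- simulate_cpp_sessions(cfg, seed = seed + k)
    pref <- assess_preference(s)
    p <- pref$tests$p[pref$tests$group == "morphine"]
    if (p < alpha) rej <- rej + 1L
  }
  list(rejection_rate = rej / n_reps, n_reps = n_reps)
}
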