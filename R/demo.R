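#' Run the full synthetic demonstration pipeline
#'
#' Chains every stage of the workflow on synthetic data with known ground
#' truth: genome generation, two-group methylome simulation with planted
#' differentially methylated units, MSCC count simulation and spike-in
#' normalized methylation calling, feature/CGI annotation with a TSS
#' meta-profile, the window/CGI differential-methylation scan, exon-skipping
#' Psi/Bayes-factor scoring, promoter methylation-expression integration, and
#' conditioned-place-preference scoring. All artifacts are written under
#' `dir` (FASTA/GTF/BED/TSV/BEDGraph plus a JSON-like run manifest) and a
#' summary of recovery statistics is returned. With a fixed seed the entire
#' run is byte-reproducible.
#'
#' @param seed integer seed driving every stage.
#' @param dir output directory.
#' @param config optional [sim_config()]; its seed is overridden by `seed`.
#' @param n_dmr number of differentially methylated units to plant.
#' @param quiet suppress progress messages.
#' @return invisibly, a list of summary statistics (also written to
#'   `summary.txt`).
#' @export
run_demo <- function(seed = 1L, dir = tempfile("mscc_demo"), config = NULL,
                     n_dmr = 10L, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- sim_config()
  config$seed <- as.integer(seed)

  say("generating synthetic genome (seed %d)", config$seed)
  genome <- generate_genome(config)
  write_genome(genome, dir)

  config$planted_dmrs <- select_dmr_units(genome, n = n_dmr, dm = 0.3,
                                          seed = config$seed + 10L)
  truth <- simulate_methylome(genome, config)

  say("simulating MSCC counts and calling methylation")
  calls <- list()
  for (g in c("a", "b")) {
    ts <- data.frame(site_id = truth$sites$site_id,
                     m = truth$sites[[paste0("m_", g)]])
    sample_g <- simulate_mscc_counts(ts, config,
                                     seed = config$seed + ifelse(g == "a", 20L, 21L))
    cl <- mscc_methylation(sample_g$counts, sample_g$spikeins)
    cl <- merge(cl, truth$sites[, c("site_id", "chrom", "pos")], by = "site_id")
    calls[[g]] <- cl
    utils::write.table(cl, file.path(dir, sprintf("methylation_calls_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bedgraph(cl, file.path(dir, sprintf("methylation_%s.bedgraph", g)))
  }

  say("annotating sites and building the TSS meta-profile")
  ann <- assign_features(genome$ccgg_sites, genome$genes, genome$exons,
                         genome$cgis, chrom_lengths = genome$chrom_lengths)
  utils::write.table(ann, file.path(dir, "feature_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- tss_profile(calls$a, genome$genes)
  utils::write.table(prof, file.path(dir, "tss_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ctx_mean <- tapply(calls$a$m[calls$a$passes_filter],
                     ann$cgi_context[match(calls$a$site_id[calls$a$passes_filter],
                                           ann$site_id)], mean)

  say("scanning for differentially methylated units")
  pass_both <- intersect(calls$a$site_id[calls$a$passes_filter],
                         calls$b$site_id[calls$b$passes_filter])
  sites_pass <- genome$ccgg_sites[genome$ccgg_sites$site_id %in% pass_both, ]
  units <- enumerate_units(genome$chrom_lengths, sites_pass, genome$cgis)
  cmp <- compare_units(units, calls$a, calls$b)
  dmrs <- call_dmrs(cmp)
  utils::write.table(dmrs$comparisons, file.path(dir, "unit_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_dmr_bed(dmrs$significant, file.path(dir, "significant_units.bed"))

  ## recovery against the planted truth
  planted_gr <- GenomicRanges::GRanges(
    config$planted_dmrs$chrom,
    IRanges::IRanges(config$planted_dmrs$start + 1L, config$planted_dmrs$end))
  cmp_gr <- GenomicRanges::GRanges(cmp$chrom,
                                   IRanges::IRanges(cmp$start + 1L, cmp$end))
  overlaps_planted <- IRanges::overlapsAny(cmp_gr, planted_gr)
  sig <- dmrs$comparisons$significant
  planted_hit <- IRanges::overlapsAny(planted_gr, cmp_gr[sig])
  sensitivity <- mean(planted_hit)
  null_rate <- if (any(!overlaps_planted)) mean(sig[!overlaps_planted]) else 0

  say("scoring exon-skipping events")
  psi_truth <- config$psi_truth
  if (is.null(psi_truth)) {
    psi_truth <- rbind(
      data.frame(event_id = sprintf("event%02d", 1:10),
                 group = "saline", psi = c(0.3, 0.5, 0.7, rep(0.5, 7))),
      data.frame(event_id = sprintf("event%02d", 1:10),
                 group = "morphine", psi = c(0.8, 0.9, 0.2, rep(0.5, 7))))
  }
  jr <- simulate_junction_reads(psi_truth, config$junction_reads,
                                seed = config$seed + 30L)
  utils::write.table(jr, file.path(dir, "junction_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  des <- score_skipping_events(jr, group_a = "saline", group_b = "morphine")
  des_called <- call_des(des)
  utils::write.table(des, file.path(dir, "skipping_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("integrating methylation and expression changes")
  expr <- simulate_expression(truth, genome, config)
  utils::write.table(expr, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pts <- collect_meth_expr_points(calls$a, calls$b, ann,
                                  data.frame(gene_id = expr$gene_id,
                                             fpkm_a = expr$fpkm_a,
                                             fpkm_b = expr$fpkm_b))
  corr <- if (nrow(pts) >= 3 && stats::sd(pts$delta_m) > 0 &&
              stats::sd(pts$delta_expr) > 0)
    correlate_meth_expr(pts) else list(r = NA_real_, p = NA_real_, n = nrow(pts))

  say("scoring conditioned place preference")
  cpp <- simulate_cpp_sessions(config, seed = config$seed + 40L)
  utils::write.table(cpp, file.path(dir, "cpp_sessions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  screen <- screen_unconditioned_preference(cpp)
  keep_animals <- screen$animal_id[!screen$excluded]
  kept <- cpp[cpp$animal_id %in% keep_animals, , drop = FALSE]
  ## a group reduced below 2 animals by the screen cannot be tested
  grp_n <- table(unique(kept[, c("animal_id", "group")])$group)
  testable <- names(grp_n)[grp_n >= 2]
  pref <- assess_preference(kept[kept$group %in% testable, , drop = FALSE])
  utils::write.table(pref$summary, file.path(dir, "cpp_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p_of <- function(g) if (g %in% pref$tests$group)
    pref$tests$p[pref$tests$group == g] else NA_real_

  m_truth <- stats::setNames(truth$sites$m_a, truth$sites$site_id)
  pa <- calls$a[calls$a$passes_filter, ]
  summary <- list(
    seed = config$seed,
    n_ccgg_sites = nrow(genome$ccgg_sites),
    n_passing_sites = nrow(pa),
    methylation_rmse = sqrt(mean((pa$m - m_truth[pa$site_id])^2)),
    context_mean_island = unname(ctx_mean["island"]),
    context_mean_shore = unname(ctx_mean["shore"]),
    context_mean_open_sea = unname(ctx_mean["open_sea"]),
    n_units_tested = nrow(cmp),
    n_significant_units = sum(sig),
    dmr_sensitivity = sensitivity,
    dmr_null_rate = null_rate,
    n_des_called = nrow(des_called),
    meth_expr_r = corr$r,
    meth_expr_p = corr$p,
    meth_expr_n = corr$n,
    cpp_p_morphine = p_of("morphine"),
    cpp_p_saline = p_of("saline")
  )
  lines <- vapply(names(summary), function(k)
    sprintf("%s\t%s", k, format(summary[[k]], digits = 10)), character(1))
  writeLines(lines, file.path(dir, "summary.txt"))
  manifest <- c("{",
                sprintf('  "package": "msccflow",'),
                sprintf('  "seed": %d,', config$seed),
                sprintf('  "min_depth": 40, "delta_cutoff": 0.25, "p_cutoff": 0.05,'),
                sprintf('  "bf_threshold": 1000, "screen_threshold_s": 540'),
                "}")
  writeLines(manifest, file.path(dir, "run_manifest.json"))
  say("done: %d CCGG sites, %d/%d planted units recovered, %d DES called",
      summary$n_ccgg_sites, sum(planted_hit), n_dmr, summary$n_des_called)
  invisible(summary)
}
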