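test_that("fully methylated sites give zero HpaII counts at unit efficiency", {
  cfg <- sim_config(seed = 1)
  smp <- simulate_mscc_counts(data.frame(site_id = sprintf("s%d", 1:500),
                                         m = rep(1, 500)), cfg)
  expect_true(all(smp$counts$hpa_count == 0))
  # library counts partition the drawn depth before efficiency scaling
  expect_equal(smp$counts$hpa_count + smp$counts$inv_count,
               smp$counts$true_depth)
})

test_that("aggregated inverse fraction converges to the methylation level", {
  cfg <- sim_config(seed = 2, depth_mean = 100, depth_size = 50)
  n <- 10000
  smp <- simulate_mscc_counts(data.frame(site_id = sprintf("s%d", 1:n),
                                         m = rep(0.5, n)), cfg)
  tot <- sum(smp$counts$true_depth)
  frac <- sum(smp$counts$inv_count) / tot
  se <- sqrt(0.25 / tot)
  expect_lt(abs(frac - 0.5), 3 * se + 1e-6)
})

test_that("library efficiencies surface in the spike-in count ratio", {
  cfg <- sim_config(seed = 3, efficiency = c(hpa = 1, inv = 0.5),
                    n_spikeins = 20L, spikein_mean = 5000)
  smp <- simulate_mscc_counts(data.frame(site_id = "s1", m = 0.5), cfg)
  ratio <- sum(smp$spikeins$hpa_count) / sum(smp$spikeins$inv_count)
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("count simulation is reproducible under a fixed seed", {
  cfg <- sim_config(seed = 4)
  ts <- data.frame(site_id = sprintf("s%d", 1:100), m = runif(100))
  expect_identical(simulate_mscc_counts(ts, cfg, seed = 9),
                   simulate_mscc_counts(ts, cfg, seed = 9))
})

test_that("junction-read simulation respects the two-junction read model", {
  tr1 <- data.frame(event_id = "e1", group = "g", psi = 1)
  jr1 <- simulate_junction_reads(tr1, n_reads = 1000, seed = 1)
  expect_equal(jr1$exclusion_reads, 0L)
  tr0 <- data.frame(event_id = "e1", group = "g", psi = 0)
  jr0 <- simulate_junction_reads(tr0, n_reads = 1000, seed = 1)
  expect_equal(jr0$inclusion_reads, 0L)
  # at psi = 0.5 the inclusion-read fraction tends to 2*0.5/1.5 = 2/3
  trh <- data.frame(event_id = "e1", group = "g", psi = 0.5)
  jrh <- simulate_junction_reads(trh, n_reads = 100000, seed = 2)
  frac <- jrh$inclusion_reads / 100000
  expect_lt(abs(frac - 2 / 3), 3 * sqrt(2 / 9 / 100000))
  expect_error(simulate_junction_reads(
    data.frame(event_id = "e", group = "g", psi = 1.2)), "outside")
})

test_that("expression coupling is exact without noise and recoverable with it", {
  genome <- list(genes = data.frame(gene_id = "geneA", chrom = "chr1",
                                    strand = "+", start = 5001L, end = 8000L,
                                    tss = 5000L))
  truth <- list(sites = data.frame(site_id = "s1", chrom = "chr1",
                                   pos = 4500L, m_a = 0.2, m_b = 0.7))
  cfg <- sim_config(seed = 5, expr_slope = -2, expr_noise_sd = 0)
  e <- simulate_expression(truth, genome, cfg)
  expect_equal(e$true_log2fc, -1)           # -2 * 0.5
  expect_equal(e$promoter_dm, 0.5)
  expect_equal(log2(e$fpkm_b / e$fpkm_a), -1)

  # slope recovery by least squares across 200 genes
  n <- 200
  genes <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
                      strand = "+", start = (1:n) * 10000L + 1L,
                      end = (1:n) * 10000L + 3000L, tss = (1:n) * 10000L)
  dm <- withr::with_seed(6, runif(n, -0.5, 0.5))
  sites <- data.frame(site_id = sprintf("s%03d", 1:n), chrom = "chr1",
                      pos = (1:n) * 10000L - 500L, m_a = 0.4,
                      m_b = 0.4 + dm)
  cfg2 <- sim_config(seed = 7, expr_slope = -2, expr_noise_sd = 0.1)
  e2 <- simulate_expression(list(sites = sites), list(genes = genes), cfg2)
  fit <- lm(e2$true_log2fc ~ e2$promoter_dm)
  expect_lt(abs(coef(fit)[2] - (-2)), 0.2)
})

test_that("CPP sessions partition the configured session length", {
  cfg <- sim_config(seed = 8)
  s <- simulate_cpp_sessions(cfg)
  expect_equal(nrow(s), 2L * (cfg$n_morphine + cfg$n_saline))
  expect_true(all(abs(s$drug_s + s$saline_s + s$passage_s - 900) < 1e-9))
  expect_true(all(s$drug_s >= 0 & s$saline_s >= 0 & s$passage_s >= 0))
  # null effect: pre and post allocations share the same expectation
  cfg0 <- sim_config(seed = 9, cpp_effect = 0, n_morphine = 300L)
  s0 <- simulate_cpp_sessions(cfg0)
  m <- s0[s0$group == "morphine", ]
  expect_lt(abs(mean(m$drug_s[m$phase == "post"]) -
                  mean(m$drug_s[m$phase == "pre"])), 20)
})
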