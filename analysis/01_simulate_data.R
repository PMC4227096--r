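#!/usr/bin/env Rscript
# Simulate the synthetic two-group study: genome, methylomes with planted
# DMR units, MSCC tag counts + spike-ins for both groups, a coupled
# expression table, junction reads for exon-skipping events, and CPP session
# logs. Everything downstream (02-07) reads from results/data/.

library(msccflow)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260919L

cfg <- sim_config(seed = seed)
message("simulating genome: ", cfg$n_chroms, " x ", cfg$chrom_length, " bp")
genome <- generate_genome(cfg)
write_genome(genome, out)
message("  ", nrow(genome$ccgg_sites), " CCGG sites, ",
        nrow(genome$genes), " genes, ", nrow(genome$cgis), " CpG islands")

cfg$planted_dmrs <- select_dmr_units(genome, n = 10L, dm = 0.3,
                                     seed = seed + 1L)
truth <- simulate_methylome(genome, cfg)
write.table(truth$sites, file.path(out, "true_methylome.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cfg$planted_dmrs, file.path(out, "planted_dmrs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("planted ", nrow(cfg$planted_dmrs), " DMR units (delta m = 0.30)")

for (g in c("a", "b")) {
  ts <- data.frame(site_id = truth$sites$site_id,
                   m = truth$sites[[paste0("m_", g)]])
  smp <- simulate_mscc_counts(ts, cfg,
                              seed = seed + ifelse(g == "a", 2L, 3L))
  counts <- merge(smp$counts, truth$sites[, c("site_id", "chrom", "pos")],
                  by = "site_id")
  write.table(counts[, c("site_id", "chrom", "pos", "hpa_count", "inv_count")],
              file.path(out, sprintf("mscc_counts_%s.tsv", g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(smp$spikeins, file.path(out, sprintf("spikeins_%s.tsv", g)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
message("wrote MSCC count + spike-in tables for groups a (control) and b (treated)")

expr <- simulate_expression(truth, genome, cfg)
write.table(expr, file.path(out, "expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

psi_truth <- rbind(
  data.frame(event_id = sprintf("event%02d", 1:12), group = "saline",
             psi = c(0.2, 0.3, 0.7, 0.25, rep(0.5, 8))),
  data.frame(event_id = sprintf("event%02d", 1:12), group = "morphine",
             psi = c(0.7, 0.8, 0.2, 0.75, rep(0.5, 8))))
jr <- simulate_junction_reads(psi_truth, n_reads = cfg$junction_reads,
                              seed = seed + 4L)
write.table(jr, file.path(out, "junction_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("simulated junction reads for ", 12, " exon-skipping events ",
        "(4 with a true shift)")

cpp <- simulate_cpp_sessions(cfg, seed = seed + 5L)
write.table(cpp, file.path(out, "cpp_sessions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("simulated CPP sessions for ", cfg$n_morphine, " morphine + ",
        cfg$n_saline, " saline animals")
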