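#!/usr/bin/env Rscript
# Map methylation calls onto gene features and CpG-island context, and build
# the TSS-relative methylation meta-profile.

library(msccflow)

dat <- "results/data"
out <- "results/annotation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gtf <- rtracklayer::import(file.path(dat, "genes.gtf"))
gg <- gtf[gtf$type == "gene"]
genes <- data.frame(gene_id = gg$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(gg)),
                    strand = as.character(BiocGenerics::strand(gg)),
                    start = BiocGenerics::start(gg),
                    end = BiocGenerics::end(gg))
genes$tss <- ifelse(genes$strand == "+", genes$start - 1L, genes$end - 1L)
ee <- gtf[gtf$type == "exon"]
exons <- data.frame(gene_id = ee$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(ee)),
                    start = BiocGenerics::start(ee),
                    end = BiocGenerics::end(ee))
bed <- rtracklayer::import(file.path(dat, "cgi.bed"))
cgis <- data.frame(chrom = as.character(GenomicRanges::seqnames(bed)),
                   start = BiocGenerics::start(bed) - 1L,
                   end = BiocGenerics::end(bed))

sites <- read.delim(file.path(dat, "true_methylome.tsv"))[,
  c("site_id", "chrom", "pos")]
ann <- assign_features(sites, genes, exons, cgis)
write.table(ann, file.path(out, "feature_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("feature distribution:")
print(round(prop.table(table(ann$feature)), 3))
message("CGI context distribution:")
print(round(prop.table(table(ann$cgi_context)), 3))

calls <- read.delim("results/methylation/calls_a.tsv")
ctx <- ann$cgi_context[match(calls$site_id, ann$site_id)]
mu <- tapply(calls$m[calls$passes_filter], ctx[calls$passes_filter], mean)
message(sprintf("mean methylation: island %.3f < shore %.3f < open sea %.3f",
                mu[["island"]], mu[["shore"]], mu[["open_sea"]]))
stopifnot(mu[["island"]] < mu[["shore"]], mu[["shore"]] < mu[["open_sea"]])

prof <- tss_profile(calls, genes)
write.table(prof, file.path(out, "tss_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
near <- abs((prof$bin_start + prof$bin_end) / 2) <= 1000
message(sprintf("TSS dip: min smoothed m within +/-1 kb = %.3f vs %.3f outside",
                min(prof$smoothed_m[near], na.rm = TRUE),
                min(prof$smoothed_m[!near], na.rm = TRUE)))

png(file.path(out, "tss_profile.png"), width = 700, height = 450)
mid <- (prof$bin_start + prof$bin_end) / 2
plot(mid, prof$mean_m, pch = 16, cex = 0.5, col = "grey60",
     xlab = "distance to TSS (bp)", ylab = "mean methylation",
     main = "Methylation around transcription start sites")
lines(mid, prof$smoothed_m, col = "firebrick", lwd = 2)
dev.off()
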