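# Shared fixtures built in code (no stored data files).

# Minimal mscc_genome-like object from hand-written sequences; CCGG sites are
# found by an independent base-R scan (gregexpr), not the package's scanner.
toy_genome <- function(seqs, genes = NULL, exons = NULL, cgis = NULL) {
  sites <- do.call(rbind, lapply(names(seqs), function(ch) {
    hits <- gregexpr("CCGG", seqs[[ch]], fixed = TRUE)[[1]]
    if (hits[1] == -1) return(NULL)
    data.frame(chrom = ch, pos = as.integer(hits) - 1L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(sites))
    sites <- data.frame(chrom = character(0), pos = integer(0))
  sites$site_id <- if (nrow(sites)) sprintf("%s_%d", sites$chrom, sites$pos)
    else character(0)
  empty_genes <- data.frame(gene_id = character(0), chrom = character(0),
                            strand = character(0), start = integer(0),
                            end = integer(0), tss = integer(0))
  empty_exons <- data.frame(gene_id = character(0), chrom = character(0),
                            start = integer(0), end = integer(0))
  empty_cgis <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0))
  structure(list(
    sequences = seqs,
    chrom_lengths = vapply(seqs, nchar, integer(1)),
    genes = if (is.null(genes)) empty_genes else genes,
    exons = if (is.null(exons)) empty_exons else exons,
    cgis = if (is.null(cgis)) empty_cgis else cgis,
    ccgg_sites = sites[, c("site_id", "chrom", "pos")]
  ), class = "mscc_genome")
}

# random non-CCGG background sequence with CCGG planted at given 0-based pos
seq_with_ccgg <- function(len, pos0, seed = 1) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    while (grepl("CCGG", s, fixed = TRUE))
      s <- sub("CCGG", "CAGG", s, fixed = TRUE)
    for (p in pos0) substr(s, p + 1, p + 4) <- "CCGG"
    s
  })
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL),
                function(v) paste(rev(v), collapse = ""), character(1)))
}

# quantify one group from true per-site methylation through the full path
quantify_truth <- function(m, site_id = sprintf("s%06d", seq_along(m)),
                           cfg = sim_config(), seed = 1L, min_depth = 40) {
  smp <- simulate_mscc_counts(data.frame(site_id = site_id, m = m),
                              cfg, seed = seed)
  mscc_methylation(smp$counts, smp$spikeins, min_depth = min_depth)
}
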