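#' Generate a synthetic genome with genes, CpG islands and CCGG sites
#'
#' Builds a toy reference for end-to-end validation of the MSCC workflow:
#' random chromosome sequences scrubbed of spontaneous CCGG occurrences, gene
#' models (three exons each), non-overlapping CpG islands (a configurable
#' fraction placed over promoters), and HpaII recognition sites (`CCGG`)
#' planted at a background density everywhere plus an extra density inside
#' islands. The recorded site list is obtained by re-scanning the final
#' sequence, so every recorded position is guaranteed to carry a literal
#' `CCGG`.
#'
#' Coordinates: CCGG positions and CGI intervals are 0-based (half-open for
#' intervals, BED convention); gene and exon intervals are 1-based closed (GTF
#' convention); `tss` is 0-based.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `mscc_genome`: list with `sequences`
#'   (named character vector), `chrom_lengths`, `genes`, `exons`, `cgis`,
#'   `ccgg_sites` data frames.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, .generate_genome_impl(config))
}

.generate_genome_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  len <- cfg$chrom_length

  seqs <- vapply(chroms, function(ch) scrub_ccgg(random_dna(len)), character(1))

  ## gene placement: sequential with random gaps, round-robin over chromosomes
  gene_len <- sample(seq(cfg$gene_length[1], cfg$gene_length[2]), cfg$n_genes,
                     replace = TRUE)
  per_chrom <- split(seq_len(cfg$n_genes),
                     rep_len(seq_len(cfg$n_chroms), cfg$n_genes))
  genes <- list(); exons <- list()
  for (ci in seq_along(per_chrom)) {
    idx <- per_chrom[[ci]]
    min_gap <- 500L
    need <- sum(gene_len[idx]) + min_gap * (length(idx) + 1L)
    if (need > len)
      stop(sprintf("chromosome %s (%d bp) too short for %d genes (need ~%d bp)",
                   chroms[ci], len, length(idx), need), call. = FALSE)
    slack <- len - sum(gene_len[idx])
    gaps <- as.integer(stats::rmultinom(1, slack - min_gap * (length(idx) + 1L),
                                 rep(1, length(idx) + 1L))) + min_gap
    pos <- 1L
    for (k in seq_along(idx)) {
      i <- idx[k]
      start <- pos + gaps[k]
      end <- start + gene_len[i] - 1L
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("gene%03d", i)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, chrom = chroms[ci], strand = strand,
        start = start, end = end,
        tss = if (strand == "+") start - 1L else end - 1L,
        stringsAsFactors = FALSE)
      ## three exons: first/last anchored at the gene ends
      b1 <- start + as.integer(gene_len[i] * 0.2)
      b2 <- start + as.integer(gene_len[i] * 0.45)
      b3 <- start + as.integer(gene_len[i] * 0.7)
      exons[[length(exons) + 1L]] <- data.frame(
        gene_id = gid, chrom = chroms[ci],
        start = c(start, b2, b3 + 200L),
        end = c(b1, b3 - 1L, end),
        stringsAsFactors = FALSE)
      pos <- end
    }
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)

  ## CpG islands: a fraction over promoters, the rest placed at random;
  ## overlaps resolved by dropping later intervals (kept sorted).
  cgis <- list()
  n_prom <- min(nrow(genes), round(cfg$promoter_cgi_frac * cfg$n_cgis))
  if (n_prom > 0) {
    gi <- sample(seq_len(nrow(genes)), n_prom)
    w <- sample(seq(cfg$cgi_length[1], cfg$cgi_length[2]), n_prom, replace = TRUE)
    cgis[[1]] <- data.frame(chrom = genes$chrom[gi],
                            start = pmax(0L, genes$tss[gi] - w %/% 2L),
                            end = pmin(len, genes$tss[gi] + w %/% 2L),
                            stringsAsFactors = FALSE)
  }
  n_rand <- cfg$n_cgis - n_prom
  if (n_rand > 0) {
    w <- sample(seq(cfg$cgi_length[1], cfg$cgi_length[2]), n_rand, replace = TRUE)
    st <- vapply(w, function(wi) sample.int(len - wi, 1L), integer(1))
    cgis[[length(cgis) + 1L]] <- data.frame(
      chrom = sample(chroms, n_rand, replace = TRUE),
      start = st, end = st + w, stringsAsFactors = FALSE)
  }
  cgis <- if (length(cgis)) do.call(rbind, cgis) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  cgis <- cgis[order(cgis$chrom, cgis$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(cgis))
  if (nrow(cgis) > 1) {
    for (i in 2:nrow(cgis)) {
      prev <- max(which(keep[seq_len(i - 1)]))
      if (cgis$chrom[i] == cgis$chrom[prev] && cgis$start[i] < cgis$end[prev])
        keep[i] <- FALSE
    }
  }
  cgis <- cgis[keep, , drop = FALSE]
  rownames(cgis) <- NULL

  ## plant CCGG motifs: background density genome-wide, extra inside islands
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    s <- seqs[[ch]]
    n_bg <- stats::rpois(1, cfg$ccgg_per_kb * len / 1000)
    pos0 <- if (n_bg > 0) sample.int(len - 40L, n_bg) + 15L else integer(0)
    isl <- cgis[cgis$chrom == ch, , drop = FALSE]
    if (nrow(isl) > 0 && cfg$cgi_ccgg_per_kb > 0) {
      for (k in seq_len(nrow(isl))) {
        wk <- isl$end[k] - isl$start[k]
        nk <- stats::rpois(1, cfg$cgi_ccgg_per_kb * wk / 1000)
        if (nk > 0)
          pos0 <- c(pos0, isl$start[k] + sample.int(max(wk - 4L, 1L), nk,
                                                    replace = TRUE))
      }
    }
    pos0 <- sort(unique(pos0))
    pos0 <- pos0[pos0 >= 16L & pos0 <= len - 20L]
    if (length(pos0) > 1) pos0 <- pos0[c(TRUE, diff(pos0) >= 4L)]
    if (length(pos0)) {
      for (p in pos0) substr(s, p + 1L, p + 4L) <- "CCGG"
    }
    seqs[[ch]] <- s
  }

  ## authoritative site list: re-scan the final sequences
  sites <- do.call(rbind, lapply(chroms, function(ch) {
    hits <- Biostrings::matchPattern("CCGG", Biostrings::DNAString(seqs[[ch]]))
    if (length(hits) == 0) return(NULL)
    data.frame(chrom = ch, pos = BiocGenerics::start(hits) - 1L,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(sites) && nrow(sites)) {
    sites$site_id <- sprintf("%s_%d", sites$chrom, sites$pos)
    sites <- sites[, c("site_id", "chrom", "pos")]
  } else {
    sites <- data.frame(site_id = character(0), chrom = character(0),
                        pos = integer(0), stringsAsFactors = FALSE)
  }

  structure(list(
    sequences = seqs,
    chrom_lengths = stats::setNames(rep(len, length(chroms)), chroms),
    genes = genes, exons = exons, cgis = cgis, ccgg_sites = sites
  ), class = "mscc_genome")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## remove spontaneous CCGG occurrences so planted density is controlled
scrub_ccgg <- function(s) {
  while (grepl("CCGG", s, fixed = TRUE)) s <- gsub("CCGG", "CAGG", s, fixed = TRUE)
  s
}

#' Write a synthetic genome to standard files
#'
#' Emits the chromosome sequences as FASTA, the gene/exon models as GTF
#' (1-based closed) and the CpG islands as BED (0-based half-open).
#'
#' @param genome an `mscc_genome` object.
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "genes.gtf")
  bed <- file.path(dir, "cgi.bed")
  dna <- Biostrings::DNAStringSet(unlist(genome$sequences))
  names(dna) <- names(genome$sequences)
  Biostrings::writeXStringSet(dna, fa)

  g <- genome$genes
  e <- merge(genome$exons, g[, c("gene_id", "strand")], by = "gene_id")
  gr <- GenomicRanges::GRanges(
    seqnames = c(g$chrom, e$chrom),
    ranges = IRanges::IRanges(start = c(g$start, e$start), end = c(g$end, e$end)),
    strand = c(g$strand, e$strand),
    type = c(rep("gene", nrow(g)), rep("exon", nrow(e))),
    gene_id = c(g$gene_id, e$gene_id),
    source = "msccflow")
  rtracklayer::export(gr, gtf, format = "gtf")

  cg <- GenomicRanges::GRanges(
    seqnames = genome$cgis$chrom,
    ranges = IRanges::IRanges(start = genome$cgis$start + 1L,
                              end = genome$cgis$end))
  rtracklayer::export(cg, bed, format = "bed")
  invisible(c(fasta = fa, gtf = gtf, bed = bed))
}
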