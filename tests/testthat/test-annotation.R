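simple_annotation <- function() {
  genes <- data.frame(gene_id = c("geneA", "geneB"), chrom = "chr1",
                      strand = c("+", "-"),
                      start = c(5001L, 20001L), end = c(8000L, 23000L),
                      tss = c(5000L, 22999L), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("geneA", "geneA", "geneB"), chrom = "chr1",
                      start = c(5001L, 7001L, 20001L),
                      end = c(5600L, 8000L, 23000L), stringsAsFactors = FALSE)
  cgis <- data.frame(chrom = "chr1", start = 4500L, end = 5500L,
                     stringsAsFactors = FALSE)
  list(genes = genes, exons = exons, cgis = cgis)
}

test_that("feature assignment follows promoter > exon > intron > intergenic", {
  ann <- simple_annotation()
  sites <- data.frame(site_id = c("up500", "inexon", "inintron", "far",
                                  "minusup"),
                      chrom = "chr1",
                      pos = c(4500L, 5200L, 6500L, 15000L, 23500L))
  fa <- assign_features(sites, ann$genes, ann$exons, ann$cgis,
                        chrom_lengths = c(chr1 = 40000L))
  got <- setNames(fa$feature, fa$site_id)
  # 500 bp upstream of a + TSS: promoter wins over the exon overlap
  expect_equal(got[["up500"]], "promoter")
  expect_equal(fa$tss_distance[fa$site_id == "up500"], -500L)
  expect_equal(got[["inexon"]], "exon")
  expect_equal(got[["inintron"]], "intron")
  expect_equal(got[["far"]], "intergenic")
  # minus-strand gene: genomically downstream of the gene = upstream of TSS
  expect_equal(got[["minusup"]], "promoter")
  expect_equal(fa$tss_distance[fa$site_id == "minusup"], -501L)
  # CGI context independent of gene feature
  expect_equal(fa$cgi_context[fa$site_id == "up500"], "island")
  expect_equal(fa$cgi_context[fa$site_id == "inintron"], "shore")
  expect_equal(fa$cgi_context[fa$site_id == "far"], "open_sea")
  # categories partition all sites
  expect_equal(sum(table(fa$feature)), nrow(sites))
  expect_error(assign_features(data.frame(site_id = "x", chrom = "chr1",
                                          pos = 50000L),
                               ann$genes, ann$exons, ann$cgis,
                               chrom_lengths = c(chr1 = 40000L)),
               "beyond")
})

test_that("feature assignment matches a brute-force per-site scan", {
  withr::with_seed(31, {
    n_genes <- 6
    genes <- data.frame(gene_id = sprintf("g%02d", 1:n_genes), chrom = "chr1",
                        strand = sample(c("+", "-"), n_genes, TRUE),
                        start = sort(sample(1000:9000, n_genes)) , end = 0L,
                        stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(300:800, n_genes)
    genes$tss <- ifelse(genes$strand == "+", genes$start - 1L, genes$end - 1L)
    exons <- do.call(rbind, lapply(1:n_genes, function(i) {
      w <- genes$end[i] - genes$start[i]
      data.frame(gene_id = genes$gene_id[i], chrom = "chr1",
                 start = c(genes$start[i], genes$start[i] + w %/% 2L),
                 end = c(genes$start[i] + w %/% 3L, genes$end[i]))
    }))
    cgis <- data.frame(chrom = "chr1",
                       start = c(1500L, 6000L), end = c(2000L, 6400L))
    sites <- data.frame(site_id = sprintf("s%03d", 1:200), chrom = "chr1",
                        pos = sample(0:9999, 200))
  })
  fa <- assign_features(sites, genes, exons, cgis, promoter_bp = 1000L,
                        shore_bp = 500L)

  brute <- vapply(seq_len(nrow(sites)), function(i) {
    p <- sites$pos[i]
    in_prom <- in_exon <- in_body <- FALSE
    for (j in seq_len(nrow(genes))) {
      d <- if (genes$strand[j] == "+") p - genes$tss[j] else genes$tss[j] - p
      if (d >= -1000 && d < 0) in_prom <- TRUE
      if (p >= genes$start[j] - 1L && p <= genes$end[j] - 1L) in_body <- TRUE
    }
    for (j in seq_len(nrow(exons)))
      if (p >= exons$start[j] - 1L && p <= exons$end[j] - 1L) in_exon <- TRUE
    if (in_prom) "promoter" else if (in_exon) "exon"
    else if (in_body) "intron" else "intergenic"
  }, character(1))
  expect_equal(fa$feature, brute)

  brute_ctx <- vapply(sites$pos, function(p) {
    if (any(p >= cgis$start & p < cgis$end)) "island"
    else if (any(p >= cgis$start - 500L & p < cgis$end + 500L)) "shore"
    else "open_sea"
  }, character(1))
  expect_equal(fa$cgi_context, brute_ctx)
})

test_that("TSS profile bins signed distances by transcription orientation", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = c("chr1", "chr2"),
                      strand = c("+", "-"), start = c(5001L, 5001L),
                      end = c(8000L, 8000L), tss = c(5000L, 7999L))
  calls <- data.frame(site_id = c("at_tss", "minus_up"),
                      chrom = c("chr1", "chr2"), pos = c(5000L, 8099L),
                      m = c(0.1, 0.9), passes_filter = TRUE)
  prof <- tss_profile(calls, genes, span = 1000L, bin_bp = 100L, smooth_k = 1L)
  # site exactly at a + TSS lands in the bin containing distance 0
  bin0 <- prof[prof$bin_start <= 0 & prof$bin_end > 0, ]
  expect_equal(bin0$mean_m, 0.1)
  # minus-strand gene, site 100 bp genomically right of the TSS -> -100
  binm <- prof[prof$bin_start <= -100 & prof$bin_end > -100, ]
  expect_equal(binm$mean_m, 0.9)
  expect_error(tss_profile(calls, genes, smooth_k = 2L), "odd")
  expect_error(tss_profile(calls, genes, smooth_k = 0L), "odd")
})

test_that("TSS profile is invariant to strand relabeling with coordinate mirroring", {
  L <- 20000L
  withr::with_seed(32, {
    pos <- sort(sample(0:(L - 1L), 60))
    m <- runif(60)
  })
  genes_f <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                        start = 9001L, end = 12000L, tss = 9000L)
  calls_f <- data.frame(site_id = sprintf("s%d", seq_along(pos)),
                        chrom = "chr1", pos = pos, m = m,
                        passes_filter = TRUE)
  genes_r <- data.frame(gene_id = "g", chrom = "chr1", strand = "-",
                        start = L - 12000L + 1L, end = L - 9001L + 1L,
                        tss = L - 1L - 9000L)
  calls_r <- calls_f
  calls_r$pos <- L - 1L - pos
  p_f <- tss_profile(calls_f, genes_f, span = 2000L, bin_bp = 100L)
  p_r <- tss_profile(calls_r, genes_r, span = 2000L, bin_bp = 100L)
  expect_equal(p_f$mean_m, p_r$mean_m)
  expect_equal(p_f$n_sites, p_r$n_sites)
})

test_that("hypomethylated promoters carve a dip into the smoothed TSS profile", {
  cfg <- sim_config(seed = 33, n_chroms = 2, chrom_length = 150000L,
                    n_genes = 30L, n_cgis = 30L, promoter_cgi_frac = 0.9)
  g <- generate_genome(cfg)
  tr <- simulate_methylome(g, cfg)
  calls <- data.frame(site_id = tr$sites$site_id, chrom = tr$sites$chrom,
                      pos = tr$sites$pos, m = tr$sites$m_a,
                      passes_filter = TRUE)
  prof <- tss_profile(calls, g$genes, span = 10000L, bin_bp = 100L,
                      smooth_k = 5L)
  sm <- prof$smoothed_m
  near <- abs((prof$bin_start + prof$bin_end) / 2) <= 1000
  expect_lt(min(sm[near], na.rm = TRUE), min(sm[!near], na.rm = TRUE))
})
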