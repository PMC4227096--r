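test_that("point collection applies the upstream window and 25% cutoff by hand rules", {
  assignments <- data.frame(
    site_id = sprintf("s%d", 1:6),
    feature = "promoter",
    nearest_gene = sprintf("g%d", 1:6),
    tss_distance = c(-500L, -500L, 100L, -500L, -2500L, -500L),
    cgi_context = "open_sea", stringsAsFactors = FALSE)
  calls_a <- data.frame(site_id = sprintf("s%d", 1:6),
                        m = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2),
                        passes_filter = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  calls_b <- data.frame(site_id = sprintf("s%d", 1:6),
                        m = c(0.6, 0.4, 0.6, 0.6, 0.6, 0.6),
                        passes_filter = TRUE)
  expression <- data.frame(gene_id = sprintf("g%d", c(1:4, 6)),
                           fpkm_a = 10, fpkm_b = 5)
  pts <- collect_meth_expr_points(calls_a, calls_b, assignments, expression)
  # manual filtering: s2 fails the 25% cutoff, s3 is downstream, s5 beyond
  # the upstream window, s6 fails the depth filter, g5 lacks expression;
  # only s1 and s4 survive
  expect_equal(pts$site_id, c("s1", "s4"))
  expect_equal(pts$delta_m, c(0.4, 0.4))
  expect_equal(pts$delta_expr, rep(log2(6 / 11), 2))
})

test_that("correlation matches the covariance formula and handles exact lines", {
  withr::with_seed(61, {
    for (k in 1:10) {
      n <- sample(10:50, 1)
      pts <- data.frame(delta_m = rnorm(n), delta_expr = rnorm(n))
      got <- correlate_meth_expr(pts)
      x <- pts$delta_m; y <- pts$delta_expr
      r_ref <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      t_ref <- r_ref * sqrt((n - 2) / (1 - r_ref^2))
      p_ref <- 2 * pt(-abs(t_ref), n - 2)
      expect_equal(got$r, r_ref, tolerance = 1e-12)
      expect_equal(got$p, p_ref, tolerance = 1e-12)
    }
  })
  line <- data.frame(delta_m = c(0.1, 0.2, 0.3, 0.4),
                     delta_expr = -2 * c(0.1, 0.2, 0.3, 0.4))
  got <- correlate_meth_expr(line)
  expect_equal(got$r, -1)
  four <- data.frame(delta_m = c(0.3, 0.4, 0.5, -0.3),
                     delta_expr = c(-1.0, -1.5, -2.2, 0.9))
  x <- four$delta_m; y <- four$delta_expr
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_meth_expr(four)$r, r_ref, tolerance = 1e-12)
  expect_lt(correlate_meth_expr(four)$r, -0.98)
  expect_error(correlate_meth_expr(line[1:2, ]), "at least 3")
  flat <- data.frame(delta_m = c(1, 1, 1), delta_expr = c(1, 2, 3))
  expect_error(correlate_meth_expr(flat), "zero variance")
})

test_that("ddCt relative expression follows the 2^-(ddCt) identities", {
  # ddCt = 0 -> fold 1
  r0 <- relative_expression_ddct(c(10, 10), c(8, 8), c(12, 12), c(10, 10))
  expect_equal(r0$fold, 1)
  # mean dCt treated 2, control 4 -> ddCt -2 -> fold 4
  r <- relative_expression_ddct(c(12, 12), c(10, 10), c(18, 18), c(14, 14))
  expect_equal(r$fold, 4)
  # identical groups: fold 1, p 1
  ri <- relative_expression_ddct(c(10, 10), c(8, 8), c(10, 10), c(8, 8))
  expect_equal(ri$fold, 1)
  expect_equal(ri$p, 1)
  # shifting every treated dCt by +1 halves the fold change
  withr::with_seed(62, {
    tt <- rnorm(4, 12); tr <- rnorm(4, 10)
    ct <- rnorm(4, 13); cr <- rnorm(4, 10)
  })
  f1 <- relative_expression_ddct(tt, tr, ct, cr)$fold
  f2 <- relative_expression_ddct(tt + 1, tr, ct, cr)$fold
  expect_equal(f2, f1 / 2)
  expect_error(relative_expression_ddct(c(10, 10), c(8, NA), c(1, 1), c(1, 1)),
               "reference")
  # p value agrees with the two-sample Student t-test on replicate dCt
  ref <- t.test(tt - tr, ct - cr, var.equal = TRUE)$p.value
  expect_equal(relative_expression_ddct(tt, tr, ct, cr)$p, ref)
})

test_that("HpaII-qPCR fraction is 2^(Ct_mock - Ct_HpaII), unclamped", {
  expect_equal(hpaii_qpcr_fraction(20, 20)$fraction, 1)
  expect_equal(hpaii_qpcr_fraction(20, 21)$fraction, 0.5)
  expect_warning(res <- hpaii_qpcr_fraction(21, 20), "exceed 1")
  expect_equal(res$fraction, 2)
  expect_true(res$above_one)
})

test_that("the configured negative coupling is recovered through the module chain", {
  n <- 200
  genes <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
                      strand = "+", start = (1:n) * 10000L + 1L,
                      end = (1:n) * 10000L + 3000L, tss = (1:n) * 10000L)
  sites <- data.frame(site_id = sprintf("s%03d", 1:n), chrom = "chr1",
                      pos = (1:n) * 10000L - 500L)
  empty_exons <- data.frame(gene_id = character(0), chrom = character(0),
                            start = integer(0), end = integer(0))
  ann <- assign_features(sites, genes, empty_exons,
                         data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0)))
  withr::with_seed(63, {
    dm <- runif(n, -0.6, 0.6)
    truth <- list(sites = data.frame(site_id = sites$site_id, chrom = "chr1",
                                     pos = sites$pos, m_a = 0.4,
                                     m_b = pmin(1, pmax(0, 0.4 + dm))))
  })
  cfg <- sim_config(seed = 64, expr_slope = -2, expr_noise_sd = 0.5)
  expr <- simulate_expression(truth, list(genes = genes), cfg)
  calls_a <- data.frame(site_id = sites$site_id, m = truth$sites$m_a,
                        passes_filter = TRUE)
  calls_b <- data.frame(site_id = sites$site_id, m = truth$sites$m_b,
                        passes_filter = TRUE)
  pts <- collect_meth_expr_points(calls_a, calls_b, ann,
                                  data.frame(gene_id = expr$gene_id,
                                             fpkm_a = expr$fpkm_a,
                                             fpkm_b = expr$fpkm_b))
  expect_gt(nrow(pts), 50)
  got <- correlate_meth_expr(pts)
  expect_lt(got$r, 0)
  expect_lt(got$p, 0.01)
})
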