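unit_fixture <- function(sites, lens = c(chrU = 100000L), cgis = NULL, ...) {
  enumerate_units(lens, sites, cgis, ...)
}

test_that("window enumeration uses step 150 and keeps only full windows", {
  sites <- data.frame(site_id = "s1", chrom = "chr1", pos = 10L)
  u <- enumerate_units(c(chr1 = 1000L), sites, min_sites = 0L)
  win <- u$units[u$units$kind == "window", ]
  expect_equal(win$start, c(0L, 150L, 300L, 450L, 600L, 750L))
  expect_true(all(win$end - win$start == 200L))

  u2 <- enumerate_units(c(chr1 = 199L), sites, min_sites = 0L)
  expect_equal(nrow(u2$units[u2$units$kind == "window", ]), 0L)

  expect_error(enumerate_units(c(chr1 = 1000L), sites, overlap_bp = 200L),
               "window_bp > overlap_bp")
})

test_that("units with three or fewer sequenced sites are dropped", {
  sites <- data.frame(site_id = sprintf("s%d", 1:7), chrom = "chr1",
                      pos = c(10L, 20L, 30L, 400L, 410L, 420L, 430L))
  u <- enumerate_units(c(chr1 = 600L), sites)
  # window 0-200 has 3 sites -> dropped; window 300-500 has 4 -> kept
  expect_false(any(u$units$start == 0L))
  expect_true(any(u$units$start == 300L & u$units$n_sites == 4L))
  expect_gt(u$n_dropped, 0L)
})

test_that("window enumeration matches a brute-force position scan", {
  withr::with_seed(41, {
    sites <- data.frame(site_id = sprintf("s%03d", 1:150), chrom = "chrT",
                        pos = sort(sample(0:9999, 150)))
  })
  cgis <- data.frame(chrom = "chrT", start = c(1000L, 7000L),
                     end = c(1600L, 7800L))
  u <- enumerate_units(c(chrT = 10000L), sites, cgis)

  # oracle: every possible start, explicit membership count
  oracle <- list()
  for (s0 in seq(0L, 10000L - 200L, by = 150L)) {
    n <- sum(sites$pos >= s0 & sites$pos < s0 + 200L)
    if (n >= 4L)
      oracle[[length(oracle) + 1L]] <- c(kind = "window", start = s0, n = n)
  }
  for (k in 1:2) {
    n <- sum(sites$pos >= cgis$start[k] & sites$pos < cgis$end[k])
    if (n >= 4L)
      oracle[[length(oracle) + 1L]] <- c(kind = "cgi", start = cgis$start[k],
                                         n = n)
  }
  odf <- as.data.frame(do.call(rbind, oracle), stringsAsFactors = FALSE)
  odf$start <- as.integer(odf$start); odf$n <- as.integer(odf$n)
  got <- u$units[order(u$units$kind, u$units$start), ]
  odf <- odf[order(odf$kind, odf$start), ]
  expect_equal(got$kind, odf$kind)
  expect_equal(got$start, odf$start)
  expect_equal(got$n_sites, odf$n)
})

make_calls <- function(ids, m) {
  data.frame(site_id = ids, m = m, passes_filter = TRUE,
             stringsAsFactors = FALSE)
}

test_that("paired unit comparison reproduces the hand-computed t-test", {
  sites <- data.frame(site_id = sprintf("s%d", 1:4), chrom = "chr1",
                      pos = c(10L, 50L, 90L, 130L))
  u <- enumerate_units(c(chr1 = 200L), sites)
  a <- make_calls(sites$site_id, c(0.9, 0.8, 0.85, 0.95))
  b <- make_calls(sites$site_id, c(0.4, 0.35, 0.3, 0.5))
  cmp <- compare_units(u, a, b)
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$delta, -0.4875)
  expect_equal(cmp$t_stat, -20.3670857468, tolerance = 1e-9)
  expect_equal(cmp$p_value, 2.5877828823e-04, tolerance = 1e-9)
  # identical vectors: delta 0, p 1, degenerate
  cmp0 <- compare_units(u, a, a)
  expect_equal(cmp0$delta, 0)
  expect_equal(cmp0$p_value, 1)
  expect_true(cmp0$degenerate)
  # constant offset: zero variance of differences, nonzero mean -> p = 0
  b_off <- make_calls(sites$site_id, a$m - 0.3)
  cmp_off <- compare_units(u, a, b_off)
  expect_equal(cmp_off$p_value, 0)
  expect_true(cmp_off$degenerate)
})

test_that("vectorized paired t matches stats::t.test on 1000 random units", {
  withr::with_seed(42, {
    n_units <- 1000L
    sizes <- sample(4:10, n_units, replace = TRUE)
    pos <- integer(0); uid_sites <- character(0)
    offset <- 0L
    ma <- mb <- numeric(0)
    starts <- integer(n_units)
    for (i in seq_len(n_units)) {
      starts[i] <- offset
      pos <- c(pos, offset + seq(10L, 190L, length.out = sizes[i]))
      ma <- c(ma, runif(sizes[i]))
      mb <- c(mb, runif(sizes[i]))
      offset <- offset + 400L
    }
  })
  sites <- data.frame(site_id = sprintf("s%05d", seq_along(pos)),
                      chrom = "chrT", pos = as.integer(pos))
  u <- enumerate_units(c(chrT = offset + 400L), sites,
                       window_bp = 200L, overlap_bp = 0L)
  a <- make_calls(sites$site_id, ma)
  b <- make_calls(sites$site_id, mb)
  cmp <- compare_units(u, a, b)
  # every non-empty window corresponds to one planted unit
  expect_equal(nrow(cmp), n_units)
  ref <- vapply(seq_len(nrow(cmp)), function(i) {
    idx <- sites$pos >= cmp$start[i] & sites$pos < cmp$end[i]
    tt <- t.test(mb[idx], ma[idx], paired = TRUE)
    c(tt$statistic, tt$p.value)
  }, numeric(2))
  expect_lt(max(abs(cmp$t_stat - ref[1, ])), 1e-10)
  expect_lt(max(abs(cmp$p_value - ref[2, ])), 1e-10)
})

test_that("swapping group labels negates delta and preserves p", {
  withr::with_seed(43, {
    sites <- data.frame(site_id = sprintf("s%d", 1:20), chrom = "chr1",
                        pos = sort(sample(0:190, 20)))
    a <- make_calls(sites$site_id, runif(20))
    b <- make_calls(sites$site_id, runif(20))
  })
  u <- enumerate_units(c(chr1 = 200L), sites)
  ab <- compare_units(u, a, b)
  ba <- compare_units(u, b, a)
  expect_equal(ab$delta, -ba$delta)
  expect_identical(ab$p_value, ba$p_value)
})

test_that("significance needs both the 25% shift and P < 0.05", {
  cmp <- data.frame(unit_id = c("u1", "u2", "u3"), kind = "window",
                    chrom = "chr1", start = c(0L, 300L, 600L),
                    end = c(200L, 500L, 800L), n_sites = 5L,
                    mean_a = 0.5, mean_b = 0.5,
                    delta = c(0.30, 0.30, 0.10),
                    t_stat = 1, p_value = c(0.01, 0.20, 0.001),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  dm <- call_dmrs(cmp)
  expect_equal(dm$significant$unit_id, "u1")
  expect_true("p_bh" %in% names(dm$comparisons))
  expect_equal(dm$merged$start, 0L)
})

test_that("sites missing in either group are excluded before the site-count check", {
  sites <- data.frame(site_id = sprintf("s%d", 1:5), chrom = "chr1",
                      pos = c(10L, 50L, 90L, 130L, 170L))
  u <- enumerate_units(c(chr1 = 200L), sites)
  a <- make_calls(sites$site_id, rep(0.5, 5))
  b <- make_calls(sites$site_id[1:3], rep(0.8, 3))  # only 3 shared sites
  cmp <- compare_units(u, a, b)
  expect_equal(nrow(cmp), 0L)
  expect_equal(attr(cmp, "n_skipped"), 1L)
})
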