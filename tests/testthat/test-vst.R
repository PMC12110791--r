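pm2 <- function(n1 = 3, n2 = 3, labels = c("P1", "P2")) {
  data.frame(sample_id = paste0("s", seq_len(n1 + n2)),
             population = rep(labels, c(n1, n2)), stringsAsFactors = FALSE)
}

mat_rows <- function(..., popmap) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0("cnvr_", seq_along(rows)), popmap$sample_id)
  m
}

test_that("zero within-population variance with distinct means gives Vst = 1", {
  pm <- pm2()
  m <- mat_rows(c(2, 2, 2, 4, 4, 4), popmap = pm)
  rec <- vst_pairwise(m, pm, c("P1", "P2"))
  expect_equal(rec$vs, 0)
  expect_equal(rec$vt, 1)
  expect_equal(rec$vst, 1)
})

test_that("an invariant locus (Vt = 0) has Vst defined as 0", {
  pm <- pm2()
  m <- mat_rows(rep(2, 6), popmap = pm)
  rec <- vst_pairwise(m, pm, c("P1", "P2"))
  expect_equal(rec$vt, 0)
  expect_equal(rec$vst, 0)
})

test_that("the hand-computed divisor-n case reproduces", {
  pm <- pm2()
  m <- mat_rows(c(2, 2, 3, 4, 4, 5), popmap = pm)
  rec <- vst_pairwise(m, pm, c("P1", "P2"))
  expect_equal(rec$vt, 11 / 9, tolerance = 1e-12)   # 1.2222
  expect_equal(rec$vs, 2 / 9, tolerance = 1e-12)    # 0.2222
  expect_equal(rec$vst, 9 / 11, tolerance = 1e-12)  # 0.8182
})

test_that("Vst is invariant to population label order, CN shift, and CN scale", {
  set.seed(4)
  pm <- pm2(4, 5)
  m <- mat_rows(runif(9, 0, 6), runif(9, 0, 6), runif(9, 0, 6), popmap = pm)
  a <- vst_pairwise(m, pm, c("P1", "P2"))
  b <- vst_pairwise(m, pm, c("P2", "P1"))
  expect_equal(a$vst, b$vst)
  expect_equal(a$pop_a, b$pop_a)  # labels reported lexicographically
  shift <- vst_pairwise(m + 3, pm, c("P1", "P2"))
  expect_equal(shift$vst, a$vst, tolerance = 1e-12)
  scaled <- vst_pairwise(m * 2.5, pm, c("P1", "P2"))
  expect_equal(scaled$vst, a$vst, tolerance = 1e-12)
})

test_that("vst_pairwise matches the brute-force two-pass oracle on random matrices", {
  set.seed(2024)
  for (rep in 1:100) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    nr <- sample(1:50, 1)
    pm <- pm2(n1, n2)
    m <- matrix(round(runif(nr * (n1 + n2), 0, 6), 3), nrow = nr,
                dimnames = list(paste0("cnvr_", seq_len(nr)), pm$sample_id))
    rec <- vst_pairwise(m, pm, c("P1", "P2"))
    oracle <- vapply(seq_len(nr), function(i)
      oracle_vst(m[i, 1:n1], m[i, n1 + 1:n2]), numeric(1))
    expect_lt(max(abs(rec$vst - oracle)), 1e-12)
  }
})

test_that("populations missing or too small are rejected", {
  pm <- pm2(1, 5)
  m <- matrix(2, 2, 6, dimnames = list(c("a", "b"), pm$sample_id))
  expect_error(vst_pairwise(m, pm, c("P1", "P2")), ">= 2 samples")
  expect_error(vst_pairwise(m, pm, c("P1", "P9")), ">= 2 samples")
})

test_that("mean_vst averages with negatives included and rejects empty input", {
  rec <- data.frame(vst = c(1, 0, -0.5))
  expect_equal(mean_vst(rec), 1 / 6)
  expect_equal(mean_vst(data.frame(vst = 0.37)), 0.37)
  expect_error(mean_vst(data.frame(vst = numeric(0))), "no Vst records")
})

test_that("top-fraction outlier calling takes ceil(fraction * N) records", {
  set.seed(10)
  rec <- data.frame(cnvr_id = paste0("c", 1:100), vst = runif(100))
  oc <- call_outliers(rec, outlier_policy(top_fraction = 0.05))
  expect_length(oc$outliers, 5L)
  expect_equal(sort(oc$outliers),
               sort(rec$cnvr_id[order(rec$vst, decreasing = TRUE)[1:5]]))
  expect_equal(oc$threshold, sort(rec$vst, decreasing = TRUE)[5])
  oc7 <- call_outliers(rec[1:7, ], outlier_policy(top_fraction = 0.05))
  expect_length(oc7$outliers, 1L)  # ceil(0.35)
})

test_that("percentile mode uses interpolated quantiles and strict exceedance", {
  rec <- data.frame(cnvr_id = paste0("c", 1:5), vst = c(0.1, 0.2, 0.3, 0.4, 0.9))
  oc <- call_outliers(rec, outlier_policy(mode = "percentile_threshold",
                                          percentile = 50))
  expect_equal(oc$threshold, 0.3)
  expect_equal(sort(oc$outliers), c("c4", "c5"))
  # degenerate distribution: nothing strictly exceeds its own percentile
  flat <- data.frame(cnvr_id = paste0("c", 1:10), vst = rep(0.4, 10))
  oc2 <- call_outliers(flat, outlier_policy(mode = "percentile_threshold",
                                            percentile = 98))
  expect_length(oc2$outliers, 0L)
})

test_that("percentile ranks lie in (0,100] and order with vst", {
  pm <- pm2()
  m <- mat_rows(c(2, 2, 2, 4, 4, 4), rep(2, 6), c(2, 2, 3, 4, 4, 5),
                popmap = pm)
  rec <- vst_pairwise(m, pm, c("P1", "P2"))
  expect_true(all(rec$percentile_rank > 0 & rec$percentile_rank <= 100))
  expect_equal(order(rec$vst), order(rec$percentile_rank))
})

test_that("outlier genes are the deduplicated union over outlier CNVRs", {
  ctx <- data.frame(cnvr_id = c("c1", "c2", "c3"),
                    context = factor(c("exonic", "intergenic", "intronic")),
                    stringsAsFactors = FALSE)
  ctx$genes_within_1kb <- list(c("gB", "gA"), character(0), c("gA", "gC"))
  expect_equal(outlier_genes(c("c1", "c3"), ctx), c("gA", "gB", "gC"))
  expect_equal(outlier_genes("c2", ctx), character(0))
})

test_that("manhattan table carries chromosome and midpoint per CNVR", {
  cnvrs <- data.frame(cnvr_id = c("c1", "c2"), chrom = c("chr1", "chr2"),
                      start = c(100, 501), end = c(300, 1000),
                      stringsAsFactors = FALSE)
  rec <- data.frame(cnvr_id = c("c1", "c2"), pop_a = "P1", pop_b = "P2",
                    vt = 1, vs = 0, vst = c(1, 0.5), percentile_rank = c(100, 50),
                    stringsAsFactors = FALSE)
  mt <- vst_manhattan_table(rec, cnvrs)
  expect_equal(mt$midpoint, c(200, 750))
  expect_equal(mt$chrom, c("chr1", "chr2"))
})
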