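toy_genes <- function() {
  gene_models(
    genes = data.frame(
      gene_id = c("gA", "gB", "gC"),
      gene_name = c("A", "B", "C"),
      chrom = "chr1",
      start = c(10000, 14000, 60000),
      end = c(13000, 20000, 65000),
      strand = c("+", "-", "+"),
      biotype = "protein_coding", stringsAsFactors = FALSE),
    exons = data.frame(
      gene_id = c("gA", "gA", "gB", "gC"),
      start = c(10000, 12500, 18000, 60000),
      end = c(10500, 13000, 19000, 61000), stringsAsFactors = FALSE)
  )
}

cnvr_at <- function(start, end, id = "cnvr_1") {
  data.frame(cnvr_id = id, chrom = "chr1", start = start, end = end,
             cnvr_class = "gain", n_carriers = 1L, n_calls = 1L,
             stringsAsFactors = FALSE)
}

test_that("context precedence: exonic > intronic > upstream > downstream > intergenic", {
  cnvrs <- rbind(
    cnvr_at(10100, 10300, "c_exonic"),      # inside exon of gA
    cnvr_at(11000, 12000, "c_intronic"),    # gA body, no exon
    cnvr_at(9200, 9800, "c_upstream"),      # within 1 kb 5' of gA (+)
    cnvr_at(20200, 20800, "c_upstream2"),   # within 1 kb 5' of gB (-)
    cnvr_at(13100, 14500, "c_down_vs_up"),  # 3' flank of gA but in gB's body
    cnvr_at(40000, 41000, "c_intergenic")
  )
  ctx <- classify_context(cnvrs, toy_genes())
  got <- setNames(as.character(ctx$context), ctx$cnvr_id)
  expect_equal(got[["c_exonic"]], "exonic")
  expect_equal(got[["c_intronic"]], "intronic")
  expect_equal(got[["c_upstream"]], "upstream")
  expect_equal(got[["c_upstream2"]], "upstream")
  # [13100,14500) is downstream of gA but overlaps gB's body -> intronic wins
  expect_equal(got[["c_down_vs_up"]], "intronic")
  expect_equal(got[["c_intergenic"]], "intergenic")
})

test_that("downstream label applies when only the 3' flank is touched", {
  # gC is +-strand [60000,65000); [65200,65800) sits in its 3' flank
  ctx <- classify_context(cnvr_at(65200, 65800), toy_genes())
  expect_equal(as.character(ctx$context), "downstream")
})

test_that("exonic precedence coexists with multi-gene assignment", {
  # overlaps an exon of gA and the intron of gB (they overlap in [14000,20000)?
  # no: gA ends 13000; use a region spanning gA's exon2 and gB's body)
  ctx <- classify_context(cnvr_at(12600, 15000), toy_genes())
  expect_equal(as.character(ctx$context), "exonic")
  expect_equal(ctx$genes_within_1kb[[1]], c("gA", "gB"))
})

test_that("gene assignment uses the span inflated by the flank on both sides", {
  ctx <- classify_context(cnvr_at(9100, 9500), toy_genes(), flank = 1000)
  expect_equal(ctx$genes_within_1kb[[1]], "gA")
  ctx2 <- classify_context(cnvr_at(8500, 8900), toy_genes(), flank = 1000)
  expect_equal(ctx2$genes_within_1kb[[1]], character(0))
})

test_that("context categories partition random CNVR sets", {
  set.seed(14)
  starts <- sort(sample.int(9e4, 40))
  cnvrs <- do.call(rbind, lapply(seq_along(starts), function(i)
    cnvr_at(starts[i], starts[i] + sample(200:3000, 1), paste0("c", i))))
  ctx <- classify_context(cnvrs, toy_genes())
  expect_equal(sum(table(ctx$context)), nrow(cnvrs))
  expect_false(anyNA(ctx$context))
})

test_that("QTLs spanning 5 Mb or more are excluded before intersection", {
  cnvrs <- cnvr_at(1000000, 1002000)
  qtls <- data.frame(
    qtl_id = c("q_wide", "q_narrow"), trait_name = c("T1", "T2"),
    chrom = "chr1", start = c(0, 900000), end = c(6e6, 1100000),
    stringsAsFactors = FALSE)
  res <- intersect_qtl(cnvrs, qtls)
  expect_equal(res$pairs$qtl_id, "q_narrow")
  expect_equal(res$pairs$overlap_bp, 2000)
  # with a larger cap the wide QTL is admitted too
  res2 <- intersect_qtl(cnvrs, qtls, max_qtl_span = 1e7)
  expect_equal(sort(res2$pairs$qtl_id), c("q_narrow", "q_wide"))
})

test_that("one CNVR inside two QTLs yields two pairs and 1/2 summary counts", {
  cnvrs <- cnvr_at(50000, 52000)
  qtls <- data.frame(qtl_id = c("q1", "q2"), trait_name = c("T1", "T2"),
                     chrom = "chr1", start = c(0, 40000),
                     end = c(100000, 90000), stringsAsFactors = FALSE)
  res <- intersect_qtl(cnvrs, qtls)
  expect_equal(nrow(res$pairs), 2L)
  expect_equal(res$summary$n_cnvrs_overlapping, 1L)
  expect_equal(res$summary$n_qtls_overlapped, 2L)
})

test_that("disjoint CNVR and QTL sets intersect to nothing", {
  res <- intersect_qtl(cnvr_at(0, 1000),
                       data.frame(qtl_id = "q1", trait_name = "T",
                                  chrom = "chr1", start = 5000, end = 9000,
                                  stringsAsFactors = FALSE))
  expect_equal(nrow(res$pairs), 0L)
  expect_equal(res$summary$n_cnvrs_overlapping, 0L)
})

test_that("QTL intersection matches an all-pairs brute-force scan", {
  set.seed(8)
  for (rep in 1:25) {
    nc <- sample(5:40, 1); nq <- sample(3:30, 1)
    cs <- sample.int(9e5, nc)
    cnvrs <- do.call(rbind, lapply(seq_len(nc), function(i)
      cnvr_at(cs[i], cs[i] + sample(500:20000, 1), paste0("c", i))))
    qs <- sample.int(9e5, nq)
    qtls <- data.frame(qtl_id = paste0("q", seq_len(nq)), trait_name = "T",
                       chrom = "chr1", start = qs,
                       end = qs + sample(1e4:6e6, nq, replace = TRUE),
                       stringsAsFactors = FALSE)
    res <- intersect_qtl(cnvrs, qtls)
    # brute force
    expected <- 0L
    for (i in seq_len(nc)) {
      for (j in seq_len(nq)) {
        if (qtls$end[j] - qtls$start[j] >= 5e6) next
        ov <- min(cnvrs$end[i], qtls$end[j]) - max(cnvrs$start[i], qtls$start[j])
        if (ov >= 1) {
          expected <- expected + 1L
          hit <- res$pairs$cnvr_id == cnvrs$cnvr_id[i] &
            res$pairs$qtl_id == qtls$qtl_id[j]
          expect_equal(sum(hit), 1L)
          expect_equal(res$pairs$overlap_bp[hit], ov)
        }
      }
    }
    expect_equal(nrow(res$pairs), expected)
  }
})

test_that("hypergeometric p matches the closed form in the all-overlap case", {
  bg <- paste0("g", 1:20)
  gs <- bg[1:5]
  tm <- data.frame(term_id = "t1", term_name = "term one", gene_id = gs,
                   stringsAsFactors = FALSE)
  res <- enrich_terms(gs, tm, bg)
  expect_equal(res$p, 1 / choose(20, 5))
  expect_equal(res$k, 5L)
  expect_equal(res$K, 5L)
})

test_that("a term covering the whole background is not enriched (p = 1)", {
  bg <- paste0("g", 1:12)
  tm <- data.frame(term_id = "t1", term_name = "everything", gene_id = bg,
                   stringsAsFactors = FALSE)
  res <- enrich_terms(bg[1:4], tm, bg)
  expect_equal(res$p, 1)
})

test_that("enrichment p-values match the exact combinatorial oracle for N <= 30", {
  set.seed(3)
  for (rep in 1:20) {
    N <- sample(8:30, 1)
    bg <- paste0("g", seq_len(N))
    n <- sample(2:(N - 1), 1)
    gs <- sample(bg, n)
    terms <- do.call(rbind, lapply(1:4, function(t)
      data.frame(term_id = paste0("t", t), term_name = paste0("term", t),
                 gene_id = sample(bg, sample(2:N, 1)),
                 stringsAsFactors = FALSE)))
    res <- enrich_terms(gs, terms, bg)
    for (i in seq_len(nrow(res))) {
      expect_lt(abs(res$p[i] -
                      oracle_hyper_upper(res$k[i], res$K[i], N, n)), 1e-12)
    }
    expect_true(all(res$q >= res$p - 1e-15))
    expect_false(is.unsorted(res$p))
  }
})

test_that("identical term compositions get identical p and q", {
  bg <- paste0("g", 1:15)
  gs <- bg[1:6]
  tm <- rbind(
    data.frame(term_id = "t1", term_name = "one", gene_id = bg[1:5]),
    data.frame(term_id = "t2", term_name = "two", gene_id = bg[1:5])
  )
  res <- enrich_terms(gs, tm, bg)
  expect_equal(res$p[1], res$p[2])
  expect_equal(res$q[1], res$q[2])
})

test_that("enrichment input contracts are enforced", {
  expect_error(enrich_terms("g1", data.frame(term_id = "t", term_name = "t",
                                             gene_id = "g1"), character(0)),
               "background gene set is empty")
  expect_error(enrich_terms("gX", data.frame(term_id = "t", term_name = "t",
                                             gene_id = "g1"),
                            c("g1", "g2")),
               "not in the background")
})
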