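test_that("overlapping calls from different samples union into one mixed CNVR", {
  calls <- rbind(make_calls(100, 500, "DUP", sample_id = "A"),
                 make_calls(400, 900, "DEL", sample_id = "B"))
  cnvrs <- build_cnvrs(calls)
  expect_equal(nrow(cnvrs), 1L)
  expect_equal(cnvrs$start, 100)
  expect_equal(cnvrs$end, 900)
  expect_equal(cnvrs$cnvr_class, "both")
  expect_equal(cnvrs$n_carriers, 2L)
  expect_equal(sort(names(cnvrs$carriers[[1]])), c("A", "B"))
})

test_that("abutting half-open calls share no base and stay separate", {
  calls <- rbind(make_calls(100, 200, "DUP"), make_calls(200, 300, "DUP"))
  cnvrs <- build_cnvrs(calls)
  expect_equal(nrow(cnvrs), 2L)
  expect_equal(cnvrs$start, c(100, 200))
})

test_that("regions beyond their class length cap are discarded, not truncated", {
  calls <- rbind(
    make_calls(0, 60000, "DEL", sample_id = "A"),        # loss, 60 kb > 50 kb
    make_calls(100000, 160000, "DUP", sample_id = "A"),  # gain, 60 kb <= 500 kb
    make_calls(300000, 330000, "DEL", sample_id = "B")   # loss, 30 kb ok
  )
  cnvrs <- build_cnvrs(calls)
  expect_equal(nrow(cnvrs), 2L)
  expect_equal(attr(cnvrs, "n_discarded"), 1L)
  expect_equal(cnvrs$cnvr_class, c("gain", "loss"))
  expect_equal(cnvrs$cnvr_id, c("cnvr_1", "cnvr_2"))  # renumbered in order
})

test_that("CNVR construction is order-invariant and yields disjoint sorted regions", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    starts <- sample.int(8e4, n)
    calls <- make_calls(starts, starts + sample(500:6000, n, replace = TRUE),
                        sample(c("DEL", "DUP"), n, replace = TRUE),
                        sample_id = sample(letters[1:5], n, replace = TRUE))
    a <- build_cnvrs(calls)
    b <- build_cnvrs(calls[sample.int(n), ])
    expect_equal(a, b)
    if (nrow(a) > 1L) {
      expect_true(all(a$start[-1] >= a$end[-nrow(a)]))  # disjoint, sorted
    }
  }
})

test_that("CNVR regions equal the per-base coverage oracle on toy chromosomes", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    starts <- sample.int(9e4, n)
    calls <- make_calls(starts, pmin(starts + sample(200:8000, n, replace = TRUE), 1e5),
                        sample(c("DEL", "DUP"), n, replace = TRUE),
                        sample_id = sample(letters[1:4], n, replace = TRUE))
    expected <- oracle_regions(calls, 1e5)
    # no length cap so the comparison covers the raw union
    got <- build_cnvrs(calls, length_policy(1e9, 1e9, 1e9))
    expect_equal(got$start, expected$start)
    expect_equal(got$end, expected$end)
    expect_equal(got$cnvr_class, expected$cnvr_class)
  }
})

test_that("kept plus discarded regions partition the pre-filter set", {
  set.seed(13)
  n <- 60
  starts <- sample.int(5e5, n)
  calls <- make_calls(starts, starts + sample(1000:80000, n, replace = TRUE),
                      sample(c("DEL", "DUP"), n, replace = TRUE))
  unfiltered <- build_cnvrs(calls, length_policy(1e9, 1e9, 1e9))
  filtered <- build_cnvrs(calls, length_policy())
  expect_equal(nrow(filtered) + attr(filtered, "n_discarded"), nrow(unfiltered))
})

test_that("landscape summary arithmetic: totals, fraction, and bins", {
  cnvrs <- data.frame(
    cnvr_id = paste0("cnvr_", 1:3), chrom = "chr1",
    start = c(0, 10000, 50000), end = c(1000, 13000, 58000),
    cnvr_class = c("gain", "loss", "both"),
    n_carriers = 1L, n_calls = 1L, stringsAsFactors = FALSE
  )
  s <- summarize_landscape(cnvrs, genome_layout("chr1", 1e6))
  expect_equal(s$n_total, 3L)
  expect_equal(s$n_gain + s$n_loss + s$n_both, s$n_total)
  expect_equal(s$total_len, 12000)
  expect_equal(s$genome_fraction, 0.012)
  expect_equal(s$mean_len, 4000)
  expect_equal(unname(s$size_class_counts), c(1L, 1L, 1L, 0L))
  expect_equal(sum(s$size_class_counts), s$n_total)
})

test_that("a 2000 bp region falls in the [2,5kb) bin (half-open bins)", {
  cnvrs <- data.frame(cnvr_id = "cnvr_1", chrom = "chr1", start = 0,
                      end = 2000, cnvr_class = "gain", n_carriers = 1L,
                      n_calls = 1L, stringsAsFactors = FALSE)
  s <- summarize_landscape(cnvrs, genome_layout("chr1", 1e6))
  expect_equal(unname(s$size_class_counts), c(0L, 1L, 0L, 0L))
})

test_that("mean length is floored to integer bp (3557 from the 36.8 Mb / 10349 case)", {
  # one region whose length makes total/count non-integer, mirroring how a
  # cohort mean of 36,814,051 bp over 10,349 regions prints as 3557
  expect_equal(floor(36814051 / 10349), 3557)
  cnvrs <- data.frame(cnvr_id = paste0("cnvr_", 1:4), chrom = "chr1",
                      start = c(0, 5000, 11000, 17000),
                      end = c(1001, 6002, 12003, 18003),
                      cnvr_class = "gain", n_carriers = 1L, n_calls = 1L,
                      stringsAsFactors = FALSE)
  s <- summarize_landscape(cnvrs, genome_layout("chr1", 1e6))
  expect_equal(s$mean_len, floor(s$mean_len_exact))
  expect_false(s$mean_len == s$mean_len_exact)
})

test_that("an empty CNVR set summarises to zeros with the empty flag", {
  no_calls <- make_calls(numeric(0), numeric(0), character(0), character(0),
                         character(0), character(0), pval = numeric(0),
                         q0 = numeric(0), est_cn = numeric(0))
  empty <- build_cnvrs(no_calls)
  s <- summarize_landscape(empty, genome_layout("chr1", 1e6))
  expect_true(s$empty)
  expect_equal(s$n_total, 0L)
  expect_equal(s$mean_len, 0)
})
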