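test_that("window statistics match the printed formula on designed cases", {
  # 200 bp of CG repeats: #C = #G = #CpG = 100 -> Obs/Exp = 100*200/10000
  ws <- window_stats(dna_seq("x", strrep("CG", 100)), 200, 1)
  expect_equal(nrow(ws), 1L)
  expect_equal(ws$gc_percent, 100)
  expect_equal(ws$obs_exp, 2)
  # all-A window: zero-denominator convention
  wa <- window_stats(dna_seq("a", strrep("A", 200)), 200, 1)
  expect_equal(wa$gc_percent, 0)
  expect_equal(wa$obs_exp, 0)
  # 600-bp promoter at window 200, step 1 -> 401 windows
  set.seed(2)
  w6 <- window_stats(dna_seq("p", random_dna(600)), 200, 1)
  expect_equal(nrow(w6), 401L)
  expect_equal(w6$start[1], 0L)
  expect_equal(w6$end[401], 600L)
})

test_that("sequences shorter than the window are rejected, N windows flagged", {
  expect_error(window_stats(dna_seq("s", strrep("A", 100)), 200),
               "minimum length is 200")
  s <- paste0(strrep("A", 100), "N", strrep("A", 299))  # N at 0-based 100
  ws <- window_stats(dna_seq("n", s), 200, 1)
  expect_true(any(ws$skipped))
  expect_true(all(ws$skipped[ws$start <= 100 & ws$end > 100]))
  expect_false(ws$skipped[ws$start == 101])
})

test_that("window statistics equal a naive recount", {
  set.seed(9)
  for (i in 1:200) {
    s <- random_dna(200, prob = c(0.2, 0.3, 0.3, 0.2))
    ws <- window_stats(dna_seq("x", s), 200, 1)
    o <- oracle_cpg_window(s)
    expect_equal(ws$gc_percent, o$gc_percent, tolerance = 1e-12)
    expect_equal(ws$obs_exp, o$obs_exp, tolerance = 1e-12)
    # bounds: CpG count cannot exceed min(#C, #G)
    expect_gte(ws$obs_exp, 0)
    expect_lte(ws$gc_percent, 100)
  }
})

test_that("statistics are invariant under reverse complement", {
  set.seed(21)
  for (i in 1:50) {
    s <- random_dna(260)
    ws <- window_stats(dna_seq("x", s), 200, 1)
    wr <- window_stats(dna_seq("y", reverse_complement(s)), 200, 1)
    # window at start k maps to the mirrored window
    expect_equal(ws$gc_percent, rev(wr$gc_percent), tolerance = 1e-12)
    expect_equal(ws$obs_exp, rev(wr$obs_exp), tolerance = 1e-12)
  }
})

test_that("island calling applies strict thresholds and merges spans", {
  stats <- data.frame(start = c(0, 1, 2, 50, 300),
                      end = c(200, 201, 202, 250, 500),
                      gc_percent = c(55, 50, 55, 55, 60),
                      obs_exp = c(0.65, 0.65, 0.6, 0.7, 0.8),
                      skipped = FALSE)
  isl <- call_islands(stats)
  # window 2 fails gc == 50 exactly, window 3 fails obs_exp == 0.6 exactly;
  # windows 1 and 4 overlap -> merged; window 5 separate
  expect_equal(nrow(isl), 2L)
  expect_equal(isl$start, c(0, 300))
  expect_equal(isl$end, c(250, 500))
  expect_equal(isl$n_windows, c(2L, 1L))
  expect_equal(call_islands(stats[stats$gc_percent <= 50, , drop = FALSE]),
               call_islands(data.frame(start = integer(0), end = integer(0),
                                       gc_percent = numeric(0),
                                       obs_exp = numeric(0),
                                       skipped = logical(0))))
})

test_that("planted high-CpG blocks are recovered as single islands", {
  for (sd in 1:30) {
    p <- make_cpg_promoter(length = 600L, island_start = 150L,
                           island_len = 300L, island_gc = 65,
                           island_obs_exp = 0.9, background_gc = 35,
                           seed = sd)
    isl <- call_islands(window_stats(p$seq))
    expect_equal(nrow(isl), 1L)
    expect_lt(isl$start, p$truth$island_end)
    expect_gt(isl$end, p$truth$island_start)
  }
})

test_that("per-gene summaries report extremes and island counts", {
  s <- dna_seq("u", strrep("ACGT", 100))  # uniform composition
  ws <- window_stats(s)
  expect_equal(min(ws$gc_percent), max(ws$gc_percent))
  summ <- cpg_summary("GENE", ws, call_islands(ws))
  expect_equal(summ$min_gc, summ$max_gc)
  two <- data.frame(start = c(0, 1), end = c(200, 201),
                    gc_percent = c(40, 60), obs_exp = c(0.5, 0.7),
                    skipped = FALSE)
  s2 <- cpg_summary("G2", two, call_islands(two))
  expect_equal(s2$min_gc, 40)
  expect_equal(s2$max_gc, 60)
  expect_equal(s2$n_islands, 1L)
  # report-shaped row: gene id plus four statistics and the island count
  expect_named(s2, c("gene_id", "min_gc", "max_gc", "min_obs_exp",
                     "max_obs_exp", "n_islands"))
})
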