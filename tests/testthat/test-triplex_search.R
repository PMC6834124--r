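test_that("a poly-U third strand on an A-tract gives the closed-form score", {
  third <- rna_seq("t", strrep("U", 22))
  # A-tract flanked by C-rich background on the given strand
  dup <- dna_seq("d", paste0(strrep("C", 40), strrep("A", 22), strrep("C", 40)))
  hits <- find_triplex_sites(third, dup)
  direct <- hits[hits$orientation == "direct" & hits$purine_strand == "given", ]
  expect_true(any(direct$target_start == 40 & direct$hit_score == 22 * 8))
  expect_true(all(hits$hit_score > 140 & hits$hit_energy < -140))
  # U.G:C is not canonical in either code: no hits on a pure G/C duplex
  dup2 <- dna_seq("e", strrep("C", 100))
  expect_equal(nrow(find_triplex_sites(third, dup2)), 0L)
  expect_error(find_triplex_sites(third, dna_seq("s", "ACGT")), "longer")
})

test_that("the scan equals independent per-register re-scoring", {
  set.seed(17)
  for (r in 1:8) {
    third <- random_rna(22)
    dup <- random_dna(250)
    # lowered thresholds so the comparison set is non-trivial
    hits <- find_triplex_sites(rna_seq("t", third), dna_seq("d", dup),
                               score_threshold = 40, energy_threshold = -40)
    o <- oracle_triplex_scan(third, dup, 40, -40)
    expect_equal(nrow(hits), if (is.null(o)) 0L else nrow(o))
    if (!is.null(o)) {
      key <- function(df) sort(paste(df$orientation, df$target_start,
                                     df$purine_strand, df$hit_score,
                                     df$hit_energy))
      expect_identical(key(hits), key(o))
    }
  }
})

test_that("register scores are additive and damage is monotone", {
  set.seed(23)
  third <- strsplit(random_rna(22), "")[[1]]
  tract <- vapply(third, function(b)
    switch(b, U = "A", C = "G", G = "G", A = "A"), character(1))
  full <- oracle_register_score(third, tract, "parallel")
  left <- oracle_register_score(third[1:10], tract[1:10], "parallel")
  right <- oracle_register_score(third[11:22], tract[11:22], "parallel")
  expect_equal(full$score, left$score + right$score)
  expect_equal(full$energy, left$energy + right$energy)
  # perturbing one canonical triplet to non-canonical: score down, energy up
  expect_equal(full$score, 176)
  for (k in c(1, 11, 22)) {
    broken <- tract
    broken[k] <- "T"  # pyrimidine duplex base is never canonical
    hurt <- oracle_register_score(third, broken, "parallel")
    expect_lt(hurt$score, full$score)
    expect_gt(hurt$energy, full$energy)
  }
})

test_that("default thresholds pass perfect registers and fail 3+ mismatches", {
  # perfect 22-mer: 176 > 140 and -176 < -140
  third <- strsplit(random_triplex_third("direct"), "")[[1]]
  tract <- vapply(third, function(b)
    switch(b, U = "A", C = "G", G = "G", A = "A"), character(1))
  r0 <- oracle_register_score(third, tract, "parallel")
  expect_true(r0$score > 140 && r0$energy < -140)
  # 1 and 2 mismatches still pass, 3 fail (16-point score step per triplet)
  for (m in 1:4) {
    broken <- tract
    broken[seq_len(m)] <- "T"
    rm <- oracle_register_score(third, broken, "parallel")
    if (m <= 2) expect_true(rm$score > 140 && rm$energy < -140)
    else expect_false(rm$score > 140 && rm$energy < -140)
  }
})

test_that("planted sites are recovered exactly with no false positives", {
  set.seed(512)
  for (sd in 1:30) {
    k <- sd %% 4
    orient <- if (sd %% 2 == 0) "direct" else "indirect"
    third <- rna_seq("t", random_triplex_third(orient))
    sites <- if (k > 0)
      data.frame(pos = c(60, 260, 460)[seq_len(k)], orientation = orient)
    else data.frame(pos = integer(0), orientation = character(0))
    tp <- make_triplex_promoter(third, sites, seed = sd)
    h <- find_triplex_sites(third, tp$seq)
    expect_identical(
      sort(paste(h$target_start, h$target_end, h$orientation)),
      sort(paste(tp$truth$start, tp$truth$end, tp$truth$orientation)))
    if (nrow(h)) expect_true(all(h$purine_strand == "given"))
  }
})

test_that("grading follows the background percentile convention", {
  set.seed(5)
  third <- rna_seq("t", random_triplex_third("direct"))
  tp <- make_triplex_promoter(third, data.frame(pos = 100,
                                                orientation = "direct"),
                              seed = 8)
  hits <- find_triplex_sites(third, tp$seq)
  bg <- triplex_background(third, tp$seq, n = 1000, seed = 4)
  expect_length(bg, 1000L)
  graded <- grade_hits(hits, bg)
  expect_true(all(graded$grade == 5L))        # above the sample maximum
  expect_gt(min(hits$hit_score), max(bg))
  # synthetic hits swept across the background range vs direct computation
  fake <- hits[rep(1, 5), ]
  fake$hit_score <- quantile(bg, c(0.5, 0.8, 0.92, 0.97, 1), names = FALSE)
  g <- grade_hits(fake, bg)$grade
  expected <- vapply(fake$hit_score, function(s) {
    p <- mean(bg <= s)
    if (p >= 0.99) 5L else if (p >= 0.95) 4L else if (p >= 0.90) 3L
    else if (p >= 0.75) 2L else 1L
  }, integer(1))
  expect_identical(g, expected)
  # constant background equal to the hit score -> fraction <= value is 1
  const <- rep(150, 1000)
  h1 <- hits[1, ]; h1$hit_score <- 150
  expect_equal(grade_hits(h1, const)$grade, 5L)
  h2 <- hits[1, ]; h2$hit_score <- 149
  expect_equal(grade_hits(h2, const)$grade, 1L)
  expect_error(grade_hits(hits, numeric(0)), "empty")
  expect_error(grade_hits(hits, bg[1:100]), ">= 1000")
})

test_that("background is deterministic and composition-preserving", {
  set.seed(1)
  third <- rna_seq("t", random_rna(22))
  dup <- dna_seq("d", random_dna(200))
  b1 <- triplex_background(third, dup, n = 50, seed = 3)
  b2 <- triplex_background(third, dup, n = 50, seed = 3)
  expect_identical(b1, b2)
  dimers <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  for (i in 1:25) {
    sh <- dinucleotide_shuffle(third$seq)
    expect_identical(dimers(sh), dimers(third$seq))
  }
})

test_that("the summary matrix renders signed hit-count notation", {
  hits <- data.frame(
    mirna_id = c(rep("m1", 4), rep("m1", 4), "m2"),
    gene_id = c(rep("KRAS", 4), rep("EGFR", 4), "APC"),
    orientation = c(rep("indirect", 4), "indirect", "indirect", "indirect",
                    "direct", "direct"),
    stringsAsFactors = FALSE)
  sm <- summarize_matrix(hits, c("m1", "m2", "m3"), c("KRAS", "EGFR", "APC"))
  r <- render_triplex_matrix(sm)
  expect_equal(r["m1", "KRAS"], "-4")
  expect_equal(r["m1", "EGFR"], "-3/+1")
  expect_equal(r["m2", "APC"], "+1")
  expect_equal(r["m3", "KRAS"], "0")
  expect_equal(sm$n_direct["m1", "EGFR"], 1L)
  expect_equal(sm$n_indirect["m1", "EGFR"], 3L)
})
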