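model <- default_energy_model()

test_that("sequences that cannot pair fold to the open structure", {
  f <- fold_mfe(rna_seq("a", "AAAAAAAAAA"), model)
  expect_equal(f$dot_bracket, "..........")
  expect_equal(f$energy, 0)
  expect_equal(nrow(f$pairs), 0L)
  # complementary but below the minimum hairpin loop
  g <- fold_mfe(rna_seq("g", "GC"), model)
  expect_equal(g$energy, 0)
  expect_equal(nrow(g$pairs), 0L)
  expect_error(fold_mfe(rna_seq("x", "ACBD")), "invalid character")
})

test_that("dot-bracket conversion round-trips", {
  set.seed(31)
  for (i in 1:25) {
    s <- rna_seq("x", random_rna(sample(10:18, 1)))
    f <- fold_suboptimal(s, model, 2)
    for (st in f$structures) {
      expect_identical(dotbracket_to_pairs(st$dot_bracket),
                       st$pairs[order(st$pairs[, 1]), , drop = FALSE])
    }
  }
})

test_that("MFE equals the brute-force minimum over all nested structures", {
  # spot sample; the acceptance suite runs the exhaustive version
  set.seed(101)
  for (i in 1:60) {
    s <- random_rna(sample(5:14, 1))
    o <- oracle_fold(s, model)
    f <- fold_mfe(rna_seq("x", s), model)
    expect_equal(f$energy, o$mfe, tolerance = 1e-12)
    # and the reported structure scores to its reported energy
    expect_equal(oracle_score(strsplit(s, "")[[1]], f$pairs, model),
                 f$energy, tolerance = 1e-12)
  }
  # the spec'd hairpin example
  s <- "GGGGAAAACCCC"
  expect_equal(fold_mfe(rna_seq("x", s), model)$energy,
               oracle_fold(s, model)$mfe)
})

test_that("suboptimal enumeration matches the oracle spectrum", {
  set.seed(55)
  for (i in 1:25) {
    s <- random_rna(sample(8:13, 1))
    o <- oracle_fold(s, model)
    for (w in c(0, 1.5, 4)) {
      f <- fold_suboptimal(rna_seq("x", s), model, w)
      expect_equal(f$structure_count,
                   sum(o$energies <= min(o$energies) + w + 1e-9))
      # retained energies all within window, sorted ascending
      es <- vapply(f$structures, `[[`, numeric(1), "energy")
      expect_true(all(diff(es) >= -1e-12))
      expect_true(all(es <= f$mfe + w + 1e-9))
      expect_false(any(duplicated(vapply(f$structures, `[[`, character(1),
                                         "dot_bracket"))))
    }
  }
})

test_that("structure count never decreases with the energy window", {
  set.seed(77)
  for (i in 1:15) {
    s <- rna_seq("x", random_rna(22))
    counts <- vapply(c(0, 0.5, 1, 2), function(w)
      fold_suboptimal(s, model, w)$structure_count, numeric(1))
    expect_false(is.unsorted(counts))
    expect_gte(counts[1], 1)
  }
})

test_that("retained structures respect pairing constraints", {
  set.seed(13)
  for (i in 1:15) {
    s <- rna_seq("x", random_rna(16))
    bases <- strsplit(s$seq, "")[[1]]
    f <- fold_suboptimal(s, model, 3)
    expect_lte(f$mfe, 0)
    for (st in f$structures) {
      p <- st$pairs
      if (!nrow(p)) next
      # legal pair types, min loop, each index once, no pseudoknots
      expect_true(all(oracle_pairable(bases[p[, 1]], bases[p[, 2]])))
      expect_true(all(p[, 2] - p[, 1] >= model$min_loop + 1L))
      expect_false(any(duplicated(c(p))))
      for (r in seq_len(nrow(p))) for (q in seq_len(nrow(p))) {
        if (r == q) next
        crossing <- p[r, 1] < p[q, 1] && p[q, 1] < p[r, 2] &&
          p[r, 2] < p[q, 2]
        expect_false(crossing)
      }
    }
  }
})

test_that("planted GC hairpins are recovered", {
  for (sd in 1:40) {
    stem <- 3L + sd %% 3L
    h <- make_hairpin_rna(stem, 4L, 22L, seed = sd)
    f <- fold_mfe(h$seq, model)
    found <- sum(paste(h$truth[, 1], h$truth[, 2]) %in%
                   paste(f$pairs[, 1], f$pairs[, 2]))
    expect_gte(found, stem - 1L)
  }
  # the 12-nt example
  h <- make_hairpin_rna(4L, 4L, 12L, seed = 1)
  f <- fold_mfe(h$seq, model)
  expect_gte(sum(paste(h$truth[, 1], h$truth[, 2]) %in%
                   paste(f$pairs[, 1], f$pairs[, 2])), 3L)
})

test_that("dot plot counts pair frequencies over retained structures", {
  # open-only fold -> all-zero matrix
  f0 <- fold_suboptimal(rna_seq("a", "AAAAAAAA"), model, 0)
  expect_true(all(dot_plot(f0) == 0))
  # shared pairs counted once per structure containing them
  set.seed(3)
  s <- rna_seq("x", random_rna(18))
  f <- fold_suboptimal(s, model, 3)
  m <- dot_plot(f)
  union_pairs <- which(f$pair_matrix, arr.ind = TRUE)
  expect_setequal(paste(union_pairs[, 1], union_pairs[, 2]),
                  paste(which(m > 0, arr.ind = TRUE)[, 1],
                        which(m > 0, arr.ind = TRUE)[, 2]))
  for (st in f$structures) {
    if (nrow(st$pairs)) {
      counted <- m[st$pairs]
      expect_true(all(counted >= 1))
    }
  }
  expect_equal(sum(m), sum(vapply(f$structures,
                                  function(x) nrow(x$pairs), numeric(1))))
  # plot file is written
  png_file <- withr::local_tempfile(fileext = ".png")
  dot_plot(f, png_file)
  expect_true(file.exists(png_file) && file.size(png_file) > 0)
})

test_that("stability ranks follow ascending free energy", {
  mk <- function(id, e) {
    structure(list(sequence = rna_seq(id, "AAAA"), mfe = e),
              class = "fold_result")
  }
  expect_equal(stability_rank(list(mk("a", -3.3), mk("c", -2.3),
                                   mk("b", -2.8))),
               c("a", "b", "c"))
  expect_equal(stability_rank(list(mk("solo", -1))), "solo")
  expect_equal(stability_rank(list(mk("z", -2), mk("a", -2))), c("a", "z"))
})

test_that("differing stem strengths yield one single- and several multi-structure folds", {
  # synthetic analog of a panel where one microRNA has a unique fold and
  # the rest populate their energy window with suboptimal structures
  b <- make_demo_bundle(withr::local_tempdir(), seed = 1)
  mirnas <- read_fasta(b$mirna_fasta, "RNA")
  counts <- vapply(mirnas, function(m)
    fold_suboptimal(m, model)$structure_count, numeric(1))
  expect_gte(sum(counts == 1), 1)
  expect_gte(sum(counts > 1), 2)
})
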