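# Seeded synthetic-data generators.
#
# Each generator is a pure function of (seed, params) and returns, next to
# the sequence or file it builds, a `truth` record sufficient to score
# recovery by the corresponding analysis stage without re-deriving it.
# These fixtures stand in for mature microRNA sequences and promoter
# regions that real studies pull from external databases.

#' Generate an RNA with a planted hairpin
#'
#' Plants a stem of `stem_len` Watson-Crick pairs around an A-loop of
#' `loop_len` bases. The 5' flank is poly-A (inert: it pairs with nothing
#' else in the molecule, so the planted stem is the only stable helix) and
#' the 3' flank is AG-random biased toward G; the composition asymmetry
#' between the flanks keeps the molecule from reading as a triplex
#' register in the reversed orientation when the same RNA is used with
#' \code{\link{make_triplex_promoter}}. With
#' \code{stem_len = 0} the whole sequence is uniform random and the truth
#' is empty.
#'
#' @param stem_len Number of planted pairs (0 for none).
#' @param loop_len Loop length in bases (>= 3).
#' @param total_len Total sequence length; must fit
#'   \code{2*stem_len + loop_len}.
#' @param seed Integer seed.
#' @param stem_seq Optional explicit 5' stem sequence (length
#'   \code{stem_len}, bases ACGU); default samples G/C.
#' @return List with \code{seq} (an \code{\link{rna_seq}}) and \code{truth}
#'   (2-column matrix of planted pair indices, 1-based).
#' @export
make_hairpin_rna <- function(stem_len, loop_len = 4L, total_len = 22L,
                             seed = 1L, stem_seq = NULL) {
  stem_len <- as.integer(stem_len)
  stopifnot(stem_len >= 0L, loop_len >= 3L,
            2L * stem_len + loop_len <= total_len || stem_len == 0L)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  with_seed(seed, {
    if (stem_len == 0L) {
      s <- paste(sample(c("A", "C", "G", "U"), total_len, replace = TRUE),
                 collapse = "")
      return(list(seq = rna_seq(sprintf("hairpin_s0_%d", seed), s),
                  truth = matrix(integer(0), 0, 2)))
    }
    if (is.null(stem_seq)) {
      stem5 <- sample(c("G", "C"), stem_len, replace = TRUE)
    } else {
      stem5 <- strsplit(toupper(stem_seq), "")[[1]]
      stopifnot(length(stem5) == stem_len, all(stem5 %in% names(comp)))
    }
    stem3 <- rev(unname(comp[stem5]))
    rest <- total_len - 2L * stem_len - loop_len
    a <- rest %/% 2L
    b <- rest - a
    flank5 <- rep("A", a)  # inert: cannot pair with the stem, loop or 3' flank
    # 3' flank: AG-random without adjacent G (isolated G can only form a
    # lone, energetically unfavourable pair, so the planted stem stays the
    # only stable helix)
    flank3 <- character(b)
    prev_g <- TRUE  # no G directly after the stem either
    for (q in seq_len(b)) {
      flank3[q] <- if (prev_g) "A" else sample(c("G", "A"), 1,
                                               prob = c(0.6, 0.4))
      prev_g <- flank3[q] == "G"
    }
    s <- paste(c(flank5, stem5, rep("A", loop_len), stem3, flank3),
               collapse = "")
    i <- a + seq_len(stem_len)
    j <- a + 2L * stem_len + loop_len + 1L - seq_len(stem_len)
    list(seq = rna_seq(sprintf("hairpin_s%d_%d", stem_len, seed), s),
         truth = cbind(i, j))
  })
}

# First-order Markov DNA of length n with target GC% and CpG obs/exp:
# stationary base probabilities are (GC-symmetric) from gc, and the C->G
# transition is scaled so that #CG * N / (#C * #G) lands near obs_exp.
markov_dna <- function(n, gc_percent, obs_exp) {
  g <- gc_percent / 100
  pi0 <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  bases <- names(pi0)
  P <- matrix(pi0, 4, 4, byrow = TRUE, dimnames = list(bases, bases))
  pcg <- min(0.95, obs_exp * pi0["G"])
  delta <- pi0["G"] - pcg
  others <- c("A", "C", "T")
  P["C", "G"] <- pcg
  P["C", others] <- pi0[others] + delta * pi0[others] / sum(pi0[others])
  out <- character(n)
  out[1] <- sample(bases, 1, prob = pi0)
  for (k in 2:n) out[k] <- sample(bases, 1, prob = P[out[k - 1], ])
  paste(out, collapse = "")
}

# realized GC% and obs/exp of a whole sequence
seq_cpg_stats <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  nc <- sum(ch == "C"); ng <- sum(ch == "G")
  ncg <- sum(ch[-n] == "C" & ch[-1] == "G")
  list(gc = 100 * (nc + ng) / n,
       obs_exp = if (nc > 0 && ng > 0) ncg * n / (nc * ng) else 0)
}

#' Generate a promoter with a planted CpG island
#'
#' Island and background are sampled from first-order Markov chains tuned
#' to the requested GC\% and observed/expected CpG ratio; the island draw
#' is re-sampled (deterministically under the seed) until its realized
#' composition is within 4 GC points and 0.15 Obs/Exp of the request.
#'
#' @param length Total promoter length (default 600).
#' @param island_start 0-based island start.
#' @param island_len Island length (>= 200).
#' @param island_gc,island_obs_exp Island composition targets (GC in
#'   percent).
#' @param background_gc,background_obs_exp Background composition targets
#'   (defaults 35\% and 0.3).
#' @param seed Integer seed.
#' @return List with \code{seq} (a \code{\link{dna_seq}}) and \code{truth}
#'   (list: island_start, island_end, realized gc and obs_exp).
#' @export
make_cpg_promoter <- function(length = 600L, island_start = 150L,
                              island_len = 300L, island_gc = 65,
                              island_obs_exp = 0.9, background_gc = 35,
                              background_obs_exp = 0.3, seed = 1L) {
  stopifnot(island_len >= 200L, island_start >= 0L,
            island_start + island_len <= length)
  with_seed(seed, {
    best <- NULL
    for (try in 1:50) {
      isl <- markov_dna(island_len, island_gc, island_obs_exp)
      st <- seq_cpg_stats(isl)
      err <- max(abs(st$gc - island_gc) / 4, abs(st$obs_exp - island_obs_exp) / 0.15)
      if (is.null(best) || err < best$err)
        best <- list(isl = isl, st = st, err = err)
      if (err <= 1) break
    }
    isl <- best$isl
    pre <- if (island_start > 0L)
      markov_dna(island_start, background_gc, background_obs_exp) else ""
    post_len <- length - island_start - island_len
    post <- if (post_len > 0L)
      markov_dna(post_len, background_gc, background_obs_exp) else ""
    s <- paste0(pre, isl, post)
    list(seq = dna_seq(sprintf("cpg_promoter_%d", seed), s),
         truth = list(island_start = island_start,
                      island_end = island_start + island_len,
                      gc = best$st$gc, obs_exp = best$st$obs_exp))
  })
}

# canonical purine partner of a third-strand base, per orientation;
# bases without a canonical partner fall back to "A" (a mismatch)
triplex_partner <- function(base, orientation) {
  par <- c(U = "A", C = "G", G = "G", A = "A")
  anti <- c(A = "A", U = "A", G = "G", C = "A")  # C has no canonical partner
  if (orientation == "direct") unname(par[base]) else unname(anti[base])
}

#' Generate a promoter with planted triplex target tracts
#'
#' At each requested position, writes the purine tract that forms
#' all-canonical triplets with the given third strand in the requested
#' orientation (third-strand bases without a canonical partner in that
#' orientation - C under reverse Hoogsteen - are planted as mismatches; if
#' that makes the planted register fail the default thresholds the call
#' errors). Elsewhere the background is pyrimidine-biased random DNA.
#'
#' @param third An \code{\link{rna_seq}} third strand.
#' @param sites Data.frame with columns \code{pos} (0-based start) and
#'   \code{orientation} ("direct"/"indirect"); sites must not overlap.
#' @param length Promoter length (default 600).
#' @param seed Integer seed.
#' @param code Triplet code used to sanity-check planted registers.
#' @return List with \code{seq} (a \code{\link{dna_seq}}) and \code{truth}
#'   (data.frame: start, end, orientation, purine_strand).
#' @export
make_triplex_promoter <- function(third, sites, length = 600L, seed = 1L,
                                  code = default_triplet_code()) {
  if (!inherits(third, "rna_seq")) third <- rna_seq("third", third)
  L <- third$length
  sites <- as.data.frame(sites)
  if (nrow(sites)) {
    stopifnot(all(sites$pos >= 0), all(sites$pos + L <= length),
              all(sites$orientation %in% c("direct", "indirect")))
    o <- order(sites$pos)
    sites <- sites[o, , drop = FALSE]
    if (nrow(sites) > 1 &&
        any(sites$pos[-1] < (sites$pos + L)[-nrow(sites)]))
      stop("planted sites overlap", call. = FALSE)
  }
  tb <- strsplit(third$seq, "")[[1]]
  with_seed(seed, {
    bg <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c(0.2, 0.3, 0.2, 0.3))
    # pyrimidine spacers around each tract first (tracts may overwrite
    # them): a register shifted off a planted site then always crosses
    # pyrimidine duplex bases, which no triplet code accepts, so shifted
    # registers cannot pass the thresholds
    for (r in seq_len(nrow(sites))) {
      sp <- c(sites$pos[r] - 2:0, sites$pos[r] + L + 1:3)  # 1-based
      sp <- sp[sp >= 1 & sp <= length]
      bg[sp] <- sample(c("C", "T"), base::length(sp), replace = TRUE)
    }
    for (r in seq_len(nrow(sites))) {
      ord <- if (sites$orientation[r] == "direct") tb else rev(tb)
      tract <- vapply(ord, triplex_partner, character(1),
                      orientation = sites$orientation[r])
      # planted register must pass the default thresholds in the requested
      # orientation and fail them in the other one (else the truth record
      # would be ambiguous)
      reg_score <- function(orientation) {
        oc <- if (orientation == "direct") "parallel" else "antiparallel"
        to <- if (orientation == "direct") tb else rev(tb)
        c(score = sum(code[[oc]]$weight[cbind(to, tract)]),
          energy = sum(code[[oc]]$energy[cbind(to, tract)]))
      }
      want <- reg_score(sites$orientation[r])
      if (!(want["score"] > 140 && want["energy"] < -140))
        stop(sprintf(
          "planted %s register for '%s' cannot pass default thresholds (score %.0f, energy %.0f); too many third-strand bases lack a canonical partner",
          sites$orientation[r], third$id, want["score"], want["energy"]),
          call. = FALSE)
      other <- reg_score(setdiff(c("direct", "indirect"),
                                 sites$orientation[r]))
      if (other["score"] > 140 && other["energy"] < -140)
        stop(sprintf(
          "planted %s tract for '%s' would also register as a %s hit (purine pattern nearly symmetric under reversal); choose a different third strand",
          sites$orientation[r], third$id,
          setdiff(c("direct", "indirect"), sites$orientation[r])),
          call. = FALSE)
      bg[sites$pos[r] + seq_len(L)] <- tract
    }
    # no register overlapping a planted tract other than the planted one
    # may pass the thresholds. Offsets beyond +/-2 always cross the full
    # 3-bp pyrimidine spacer (>= 3 guaranteed mismatches, 128 < 140), so
    # checking offsets -2..2 in both orientations is exhaustive; these
    # registers touch only tract and spacer bases, making the check a
    # deterministic property of the third strand alone.
    for (r in seq_len(nrow(sites))) {
      for (s in -2:2) {
        lo <- sites$pos[r] + s + 1L          # 1-based register start
        if (lo < 1L || lo + L - 1L > length) next
        seg <- bg[lo:(lo + L - 1L)]
        for (orientation in c("direct", "indirect")) {
          if (s == 0L && orientation == sites$orientation[r]) next
          oc <- if (orientation == "direct") "parallel" else "antiparallel"
          to <- if (orientation == "direct") tb else rev(tb)
          sc <- sum(code[[oc]]$weight[cbind(to, seg)])
          en <- sum(code[[oc]]$energy[cbind(to, seg)])
          if (sc > 140 && en < -140)
            stop(sprintf(
              "planted %s tract for '%s' would also register as a %s hit at offset %d; choose a third strand with a less regular purine pattern",
              sites$orientation[r], third$id, orientation, s), call. = FALSE)
        }
      }
    }
    truth <- if (nrow(sites)) {
      data.frame(start = as.integer(sites$pos),
                 end = as.integer(sites$pos + L),
                 orientation = sites$orientation,
                 purine_strand = "given", stringsAsFactors = FALSE)
    } else {
      data.frame(start = integer(0), end = integer(0),
                 orientation = character(0), purine_strand = character(0))
    }
    list(seq = dna_seq(sprintf("triplex_promoter_%d", seed),
                       paste(bg, collapse = "")),
         truth = truth)
  })
}

#' Write a synthetic somatic-event table
#'
#' Encodes the colorectal-cancer staging facts the pipeline is expected to
#' recover - APC specific to the early stage; GNAS metastatic; KRAS
#' early/late/drug-resistance; EGFR drug-induced/drug-resistance; the
#' temporal chains APC -> TP53 -> TCF7L2 and CASP8 -> KRAS -> PIK3CA - plus
#' seeded random filler genes whose names never collide with the seven
#' target genes or the chain genes.
#'
#' @param path Output TSV path.
#' @param seed Integer seed (controls the filler rows only).
#' @param n_filler Number of filler genes.
#' @return List with \code{path} and \code{truth} (list of stage sets and
#'   expected temporal paths).
#' @export
make_event_table <- function(path, seed = 1L, n_filler = 5L) {
  core <- data.frame(
    gene = c("APC", "TP53", "TCF7L2", "CASP8", "KRAS", "PIK3CA", "GNAS",
             "EGFR", "IGF1R"),
    stage = c("early", "", "", "", "early;late;drug-resistance", "",
              "metastatic", "drug-induced;drug-resistance", ""),
    variant_type = c("alteration;mutation;methylation;CNV-loss;LOH",
                     "mutation", "mutation", "mutation", "mutation",
                     "mutation", "mutation", "mutation", "alteration"),
    antecedent_of = c("TP53", "TCF7L2", "", "KRAS", "PIK3CA", "", "", "",
                      ""),
    stringsAsFactors = FALSE)
  filler <- with_seed(seed, {
    data.frame(
      gene = sprintf("FG%02d", seq_len(n_filler)),
      stage = vapply(seq_len(n_filler), function(i)
        paste(sample(STAGE_VOCAB, sample(1:2, 1)), collapse = ";"),
        character(1)),
      variant_type = vapply(seq_len(n_filler), function(i)
        sample(VARIANT_VOCAB, 1), character(1)),
      antecedent_of = "", stringsAsFactors = FALSE)
  })
  write.table(rbind(core, filler), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(path = path,
       truth = list(stages = list(APC = "early", GNAS = "metastatic",
                                  KRAS = c("early", "late", "drug-resistance")),
                    paths = list(c("APC", "TP53", "TCF7L2"),
                                 c("CASP8", "KRAS", "PIK3CA"))))
}

#' Write a synthetic interaction edge list
#'
#' Edge weights per interaction kind are fixed so the composition
#' percentages are exactly 43.83 (genetic), 26.28 (shared-domain), 14.23
#' (physical), 10.14 (co-expression), 3.89 (pathway) and 1.63 (predicted).
#' Among the target genes only APC and CASP8 are co-expressed.
#'
#' @param path Output TSV path.
#' @param seed Integer seed (kept for interface symmetry; the edge list is
#'   deterministic).
#' @return List with \code{path} and \code{truth} (named vector of expected
#'   composition percentages).
#' @export
make_edge_list <- function(path, seed = 1L) {
  edges <- rbind(
    data.frame(gene_a = c("APC", "GNAS", "KRAS", "TCF7L2"),
               gene_b = c("KCTD1", "ADCY6", "EGFR", "IGF1R"),
               kind = "genetic", weight = c(1500, 1300, 900, 683)),
    data.frame(gene_a = c("KRAS", "EGFR", "IGF1R"),
               gene_b = c("EGFR", "IGF1R", "CASP8"),
               kind = "shared-domain", weight = c(1000, 900, 728)),
    data.frame(gene_a = c("APC", "TCF7L2"), gene_b = c("TCF7L2", "KRAS"),
               kind = "physical", weight = c(800, 623)),
    data.frame(gene_a = c("APC", "BCL2"), gene_b = c("CASP8", "MAPK1"),
               kind = "co-expression", weight = c(600, 414)),
    data.frame(gene_a = "EGFR", gene_b = "KRAS", kind = "pathway",
               weight = 389),
    data.frame(gene_a = "GNAS", gene_b = "IGF1R", kind = "predicted",
               weight = 163))
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- c(genetic = 43.83, `shared-domain` = 26.28, physical = 14.23,
             `co-expression` = 10.14, pathway = 3.89, predicted = 1.63)
  list(path = path, truth = truth)
}

#' Write the demo dataset (five microRNAs, seven promoters)
#'
#' A paper-shaped bundle for the end-to-end run: five 20-22 nt microRNAs
#' with planted hairpins of varying stem strength, seven 600-bp target-gene
#' promoters with planted CpG islands, triplex tracts planted for a subset
#' of microRNA/gene pairs, an event table and an interaction edge list.
#' All files are plain text; a JSON sidecar records the planted truth.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return List of file paths plus the combined \code{truth}, invisibly.
#' @export
make_demo_bundle <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  mir_specs <- list(
    `mir-1` = list(stem = 5L, loop = 4L, total = 22L, stem_seq = "AUGGC"),
    `mir-2` = list(stem = 0L, loop = 4L, total = 22L, stem_seq = NULL),
    `mir-3` = list(stem = 3L, loop = 4L, total = 22L, stem_seq = "GGA"),
    `mir-4` = list(stem = 3L, loop = 4L, total = 20L, stem_seq = "AGC"),
    `mir-5` = list(stem = 6L, loop = 4L, total = 22L, stem_seq = "GCGGCG"))
  mirnas <- list()
  hairpin_truth <- list()
  for (i in seq_along(mir_specs)) {
    sp <- mir_specs[[i]]
    h <- make_hairpin_rna(sp$stem, sp$loop, sp$total, seed = seed + i,
                          stem_seq = sp$stem_seq)
    h$seq$id <- names(mir_specs)[i]
    mirnas[[names(mir_specs)[i]]] <- h$seq
    hairpin_truth[[names(mir_specs)[i]]] <- h$truth
  }
  # island composition targets per promoter (GC%, obs/exp)
  island_params <- list(
    APC = c(58, 0.75), KRAS = c(78, 1.10), TCF7L2 = c(65, 0.90),
    EGFR = c(57, 0.80), IGF1R = c(75, 1.15), CASP8 = c(69, 0.70),
    GNAS = c(69, 0.75))
  # planted triplex sites: gene -> list of (mirna, pos, orientation)
  plant <- list(
    TCF7L2 = list(c("mir-1", "480", "direct"), c("mir-1", "540", "direct")),
    KRAS = list(c("mir-3", "520", "indirect")),
    APC = list(c("mir-5", "500", "direct")),
    CASP8 = list(c("mir-5", "520", "direct")))
  promoters <- list()
  site_truth <- list()
  for (i in seq_along(island_params)) {
    gene <- names(island_params)[i]
    p <- make_cpg_promoter(length = 600L, island_start = 120L,
                           island_len = 300L,
                           island_gc = island_params[[gene]][1],
                           island_obs_exp = island_params[[gene]][2],
                           seed = seed + 100L + i)
    s <- strsplit(p$seq$seq, "")[[1]]
    for (pl in plant[[gene]]) {
      third <- mirnas[[pl[1]]]
      pos <- as.integer(pl[2])
      tb <- strsplit(third$seq, "")[[1]]
      ord <- if (pl[3] == "direct") tb else rev(tb)
      tract <- vapply(ord, triplex_partner, character(1),
                      orientation = pl[3])
      sp <- c(pos - 2:0, pos + third$length + 1:3)
      sp <- sp[sp >= 1 & sp <= 600]
      s[sp] <- rep(c("C", "T"), length.out = length(sp))
      s[pos + seq_len(third$length)] <- tract
      site_truth[[length(site_truth) + 1L]] <- data.frame(
        mirna_id = pl[1], gene_id = paste0(gene, "_promoter"),
        start = pos, end = pos + third$length, orientation = pl[3],
        stringsAsFactors = FALSE)
    }
    promoters[[gene]] <- dna_seq(paste0(gene, "_promoter"),
                                 paste(s, collapse = ""))
  }
  paths <- list(
    mirna_fasta = file.path(dir, "mirnas.fasta"),
    promoter_fasta = file.path(dir, "promoters.fasta"),
    event_table = file.path(dir, "events.tsv"),
    edge_list = file.path(dir, "edges.tsv"),
    truth_json = file.path(dir, "truth.json"))
  write_fasta(mirnas, paths$mirna_fasta)
  write_fasta(promoters, paths$promoter_fasta)
  ev <- make_event_table(paths$event_table, seed = seed)
  el <- make_edge_list(paths$edge_list, seed = seed)
  truth <- list(
    hairpin_pairs = lapply(hairpin_truth, function(m)
      if (nrow(m)) unname(as.matrix(m)) else NULL),
    islands = lapply(names(island_params), function(g)
      list(gene = g, start = 120, end = 420)),
    triplex_sites = if (length(site_truth)) do.call(rbind, site_truth)
                    else NULL,
    stages = ev$truth$stages, composition = as.list(el$truth))
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, list(truth = truth)))
}
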