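# Independent oracles used to validate the package's algorithms.
# These deliberately share nothing with the implementation path: structures
# are enumerated by recursion over intervals and scored by explicit loop
# decomposition; CpG statistics are recounted naively; triplex registers
# are re-scored one at a time.

# ---- folding oracle --------------------------------------------------------

# all pair types, as base-character lookups
oracle_pairable <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

# enumerate every nested structure (list of 2-col pair matrices) on bases
# [i, j] honoring min hairpin loop; includes the empty structure
oracle_enumerate <- function(bases, min_loop = 3L) {
  n <- length(bases)
  memo <- new.env()
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > j) return(list(matrix(integer(0), 0, 2)))
    out <- list()
    # i unpaired
    for (s in rec(i + 1L, j)) out[[length(out) + 1L]] <- s
    # i paired with k
    ks <- if (i + min_loop + 1L <= j) seq.int(i + min_loop + 1L, j)
          else integer(0)
    for (k in ks) {
      if (oracle_pairable(bases[i], bases[k])) {
        inner <- rec(i + 1L, k - 1L)
        outer <- rec(k + 1L, j)
        for (si in inner) for (so in outer) {
          out[[length(out) + 1L]] <- rbind(c(i, k), si, so)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# score a structure by explicit loop decomposition under `model`.
# Convention (shared with the implementation's definition, not its code):
# each pair not stacked on its inner side gets the terminal AU/GU penalty
# once; each pair not stacked on its outer side gets it once more.
oracle_score <- function(bases, pairs, model) {
  if (nrow(pairs) == 0L) return(0)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  partner <- integer(length(bases))
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  pt <- function(i, j) paste0(bases[i], bases[j])
  au <- function(i, j)
    if (pt(i, j) %in% c("AU", "UA", "GU", "UG")) model$terminal_au else 0
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # children: pairs (k,l) directly inside (i,j)
    children <- NULL
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k) {
        children <- rbind(children, c(k, partner[k]))
        k <- partner[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    nch <- if (is.null(children)) 0L else nrow(children)
    if (nch == 0L) {
      total <- total + loop_penalty(model, "hairpin", j - i - 1L) + au(i, j)
    } else if (nch == 1L) {
      k <- children[1, 1]; l <- children[1, 2]
      b1 <- k - i - 1L; b2 <- j - l - 1L
      if (b1 == 0L && b2 == 0L) {
        total <- total + model$stack[pt(i, j), pt(k, l)]
      } else if (b1 == 0L || b2 == 0L) {
        total <- total + loop_penalty(model, "bulge", b1 + b2) +
          au(i, j) + au(k, l)
      } else {
        total <- total + loop_penalty(model, "internal", b1 + b2) +
          au(i, j) + au(k, l)
      }
    } else {
      total <- total + model$ml_close + model$ml_branch * (nch + 1L) +
        model$ml_unpaired * unpaired + au(i, j) +
        sum(vapply(seq_len(nch), function(q)
          au(children[q, 1], children[q, 2]), numeric(1)))
    }
  }
  # external loop: outer-end penalty for every top-level helix
  covered <- rep(FALSE, length(bases))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!covered[i]) {
      total <- total + au(i, j)
      covered[i:j] <- TRUE
    }
  }
  total
}

# brute-force minimum free energy and full energy spectrum
oracle_fold <- function(seq_chr, model) {
  bases <- strsplit(seq_chr, "")[[1]]
  structs <- oracle_enumerate(bases, model$min_loop)
  energies <- vapply(structs, function(p) oracle_score(bases, p, model),
                     numeric(1))
  list(mfe = min(energies), energies = energies, structures = structs)
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
random_dna <- function(n, prob = NULL)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")

# all 4^n RNA sequences of length n
all_rna_seqs <- function(n) {
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "U")), n))
  apply(grid, 1, paste, collapse = "")
}

# ---- CpG oracle ------------------------------------------------------------

# naive recount of one window's statistics straight from the printed formula
oracle_cpg_window <- function(wseq) {
  nc <- lengths(regmatches(wseq, gregexpr("C", wseq)))
  ng <- lengths(regmatches(wseq, gregexpr("G", wseq)))
  # overlapping CG count via lookahead
  ncg <- lengths(regmatches(wseq, gregexpr("C(?=G)", wseq, perl = TRUE)))
  n <- nchar(wseq)
  list(gc_percent = 100 * (nc + ng) / n,
       obs_exp = if (nc > 0 && ng > 0) ncg * n / (nc * ng) else 0)
}

# ---- triplex oracle --------------------------------------------------------

oracle_triplex_canonical <- function(third_base, purine_base, orientation) {
  key <- paste0(third_base, purine_base)
  if (orientation == "parallel") key %in% c("UA", "CG", "GG", "AA")
  else key %in% c("AA", "UA", "GG")
}

# score one register the slow way: third strand (RNA chars, 5'->3'),
# purine strand segment (DNA chars, 5'->3'), orientation
oracle_register_score <- function(third, segment, orientation,
                                  wc = 8, wo = -8, ec = -8, eo = 4) {
  L <- length(third)
  tt <- if (orientation == "parallel") third else rev(third)
  canon <- vapply(seq_len(L), function(k)
    oracle_triplex_canonical(tt[k], segment[k], orientation), logical(1))
  list(score = sum(ifelse(canon, wc, wo)),
       energy = sum(ifelse(canon, ec, eo)))
}

# full naive scan over all registers / strands / orientations, returning
# hits that pass the thresholds, on given-strand coordinates
oracle_triplex_scan <- function(third_chr, duplex_chr, score_thr = 140,
                                energy_thr = -140) {
  third <- strsplit(third_chr, "")[[1]]
  L <- length(third)
  n <- nchar(duplex_chr)
  comp <- chartr("ACGT", "TGCA", duplex_chr)
  rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  out <- NULL
  for (strand in c("given", "complement")) {
    p <- strsplit(if (strand == "given") duplex_chr else rc, "")[[1]]
    for (orientation in c("parallel", "antiparallel")) {
      for (i in seq_len(n - L + 1L)) {
        seg <- p[i:(i + L - 1L)]
        r <- oracle_register_score(third, seg, orientation)
        if (r$score > score_thr && r$energy < energy_thr) {
          start0 <- if (strand == "given") i - 1L else n - i - L + 1L
          out <- rbind(out, data.frame(
            orientation = if (orientation == "parallel") "direct"
                          else "indirect",
            target_start = start0, purine_strand = strand,
            hit_score = r$score, hit_energy = r$energy,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  out
}
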