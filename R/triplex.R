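# Triplex-forming site search between a microRNA third strand and duplex
# promoter DNA.
#
# Triplets are written third-base . purine-base : pyrimidine-base. Canonical
# triplets: parallel (Hoogsteen, "direct" binding) U.A:T, C.G:C (protonated,
# no pH modelling), G.G:C, A.A:T; antiparallel (reverse Hoogsteen,
# "indirect") A.A:T, U.A:T, G.G:C. Every ungapped full-length register of
# the third strand is scored against the purine strand of the duplex; both
# the given promoter strand and its complement are tested as the
# purine-carrying strand, and coordinates are always reported on the given
# strand. hit_score sums the per-triplet weights, hit_energy the per-triplet
# energies; a register is retained only if hit_score > score_threshold AND
# hit_energy < energy_threshold (both strict, matching the published
# cutoffs score > 140 and energy < -140).

#' Default triplet code (weights and energies)
#'
#' Canonical triplets score +8 (weight) and -8 (energy); every other
#' third-base/duplex-base combination scores -8 and +4. Calibrated so a
#' perfect 22-triplet register scores 176 > 140 with energy -176 < -140,
#' while any register with three or more non-canonical triplets fails the
#' default thresholds. Tables are configuration: edit the returned object
#' to re-weight.
#'
#' @param weight_canonical,weight_other Per-triplet score contributions.
#' @param energy_canonical,energy_other Per-triplet energy contributions.
#' @return An object of class \code{triplet_code}: for each orientation a
#'   4x4 weight and energy matrix (rows = third-strand RNA base ACGU,
#'   columns = duplex purine-strand DNA base ACGT).
#' @export
default_triplet_code <- function(weight_canonical = 8, weight_other = -8,
                                 energy_canonical = -8, energy_other = 4) {
  canonical <- list(
    parallel = rbind(c("U", "A"), c("C", "G"), c("G", "G"), c("A", "A")),
    antiparallel = rbind(c("A", "A"), c("U", "A"), c("G", "G")))
  mk <- function(orient) {
    w <- matrix(weight_other, 4, 4,
                dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "T")))
    e <- matrix(energy_other, 4, 4, dimnames = dimnames(w))
    w[canonical[[orient]]] <- weight_canonical
    e[canonical[[orient]]] <- energy_canonical
    list(weight = w, energy = e)
  }
  structure(list(parallel = mk("parallel"), antiparallel = mk("antiparallel"),
                 canonical = canonical),
            class = "triplet_code")
}

# integer-encode sequences against a fixed alphabet; 0 for anything else (N)
encode_seq <- function(s, alphabet) {
  m <- match(strsplit(s, "")[[1]], alphabet)
  m[is.na(m)] <- 0L
  m
}

# score every register of an encoded third strand against an encoded purine
# strand; returns numeric vector (one value per register start). Registers
# touching an unencodable base (N) get -Inf.
scan_registers <- function(third_idx, pur_idx, mat) {
  L <- length(third_idx)
  n <- length(pur_idx)
  nreg <- n - L + 1L
  if (nreg < 1L) return(numeric(0))
  sc <- numeric(nreg)
  ok <- rep(TRUE, nreg)
  for (k in seq_len(L)) {
    seg <- pur_idx[k:(k + nreg - 1L)]
    bad <- seg == 0L | third_idx[k] == 0L
    ok <- ok & !bad
    seg[bad] <- 1L
    sc <- sc + mat[third_idx[k], seg]
  }
  sc[!ok] <- -Inf
  sc
}

#' Find triplex-forming sites
#'
#' Scans every ungapped register of the third strand against both strands
#' of the duplex in both orientations and keeps registers that pass both
#' thresholds. Registers containing an N base on the duplex are skipped.
#'
#' @param third An \code{\link{rna_seq}} microRNA (the third strand).
#' @param duplex A \code{\link{dna_seq}} promoter (the given strand of the
#'   duplex).
#' @param code A \code{\link{default_triplet_code}} object.
#' @param score_threshold Minimum hit score, strict (default 140).
#' @param energy_threshold Maximum hit energy, strict (default -140).
#' @return A data.frame of hits sorted by \code{hit_score} descending:
#'   mirna_id, gene_id, orientation ("direct"/"indirect"), target_start,
#'   target_end (0-based half-open on the given strand), purine_strand
#'   ("given"/"complement"), hit_score, hit_energy, grade (NA until
#'   \code{\link{grade_hits}}).
#' @export
find_triplex_sites <- function(third, duplex, code = default_triplet_code(),
                               score_threshold = 140,
                               energy_threshold = -140) {
  if (!inherits(third, "rna_seq")) third <- rna_seq("third", third)
  if (!inherits(duplex, "dna_seq")) duplex <- dna_seq("duplex", duplex)
  L <- third$length
  n <- duplex$length
  if (L > n)
    stop("third strand longer than duplex", call. = FALSE)
  stopifnot(is.finite(score_threshold), is.finite(energy_threshold))
  t_fwd <- encode_seq(third$seq, c("A", "C", "G", "U"))
  t_rev <- rev(t_fwd)
  strands <- list(given = encode_seq(duplex$seq, c("A", "C", "G", "T")),
                  complement = encode_seq(seq_string(reverse_complement(duplex)),
                                          c("A", "C", "G", "T")))
  rows <- list()
  for (strand in names(strands)) {
    p <- strands[[strand]]
    for (orient in c("parallel", "antiparallel")) {
      tt <- if (orient == "parallel") t_fwd else t_rev
      sc <- scan_registers(tt, p, code[[orient]]$weight)
      en <- scan_registers(tt, p, code[[orient]]$energy)
      pass <- which(is.finite(sc) & sc > score_threshold & en < energy_threshold)
      if (length(pass)) {
        # map register start (1-based on scanned strand) to given-strand coords
        if (strand == "given") {
          start0 <- pass - 1L
        } else {
          start0 <- n - pass - L + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = third$id, gene_id = duplex$id,
          orientation = if (orient == "parallel") "direct" else "indirect",
          target_start = start0, target_end = start0 + L,
          purine_strand = strand, hit_score = sc[pass], hit_energy = en[pass],
          grade = NA_integer_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      orientation = character(0), target_start = integer(0),
                      target_end = integer(0), purine_strand = character(0),
                      hit_score = numeric(0), hit_energy = numeric(0),
                      grade = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$hit_score, out$target_start, out$orientation,
                   out$purine_strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: returns a random sequence with exactly the
#' same dinucleotide (and hence mononucleotide) composition, first and last
#' base fixed. Used to build composition-controlled score backgrounds.
#'
#' @param s Character scalar sequence.
#' @return Shuffled character scalar.
#' @export
dinucleotide_shuffle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n <= 3L) return(s)
  syms <- unique(ch)
  if (length(syms) == 1L) return(s)
  last <- ch[n]
  # edge lists: for each symbol, the multiset of successors
  succ <- split(ch[-1], factor(ch[-n], levels = syms))
  repeat {
    # pick a random "last exit" edge per vertex (except the terminal one)
    # and check they form an arborescence toward the terminal vertex
    last_edge <- vapply(syms, function(v) {
      if (v == last && !length(succ[[v]])) return(NA_character_)
      if (!length(succ[[v]])) return(NA_character_)
      sample(succ[[v]], 1L)
    }, character(1))
    reach <- function(v) {   # follow last edges; must reach `last`
      seen <- character(0)
      while (!is.na(v) && v != last && !(v %in% seen)) {
        seen <- c(seen, v)
        v <- unname(last_edge[[v]])
      }
      identical(v, last)
    }
    ok <- all(vapply(syms[syms != last], function(v) {
      !length(succ[[v]]) || reach(v)
    }, logical(1)))
    if (ok) break
  }
  # shuffle the remaining edges, append the chosen last edge
  walk_succ <- lapply(syms, function(v) {
    e <- succ[[v]]
    if (v != last && !is.na(last_edge[v])) {
      drop <- match(last_edge[v], e)
      rest <- e[-drop]
      c(sample(rest), last_edge[v])
    } else {
      sample(e)
    }
  })
  names(walk_succ) <- syms
  ptr <- setNames(rep(1L, length(syms)), syms)
  out <- character(n)
  out[1] <- ch[1]
  v <- ch[1]
  for (k in 2:n) {
    nxt <- walk_succ[[v]][ptr[v]]
    ptr[v] <- ptr[v] + 1L
    out[k] <- nxt
    v <- nxt
  }
  paste(out, collapse = "")
}

#' Best background score of shuffled third strands
#'
#' For each of \code{n} dinucleotide-preserving shuffles of the third
#' strand, the best register score over both strands and both orientations
#' against the same duplex.
#'
#' @inheritParams find_triplex_sites
#' @param n Number of shuffles (background sample size).
#' @param seed Integer seed for reproducibility.
#' @return Numeric vector of length \code{n}.
#' @export
triplex_background <- function(third, duplex, code = default_triplet_code(),
                               n = 1000L, seed = 1L) {
  if (!inherits(third, "rna_seq")) third <- rna_seq("third", third)
  if (!inherits(duplex, "dna_seq")) duplex <- dna_seq("duplex", duplex)
  strands <- list(encode_seq(duplex$seq, c("A", "C", "G", "T")),
                  encode_seq(seq_string(reverse_complement(duplex)),
                             c("A", "C", "G", "T")))
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      sh <- dinucleotide_shuffle(third$seq)
      tf <- encode_seq(sh, c("A", "C", "G", "U"))
      best <- -Inf
      for (p in strands) {
        for (o in c("parallel", "antiparallel")) {
          tt <- if (o == "parallel") tf else rev(tf)
          sc <- scan_registers(tt, p, code[[o]]$weight)
          sc <- sc[is.finite(sc)]
          if (length(sc)) best <- max(best, max(sc))
        }
      }
      best
    }, numeric(1))
  })
}

#' Grade triplex hits against a score background
#'
#' Percentile convention: the percentile of a hit is the fraction of
#' background scores less than or equal to the hit score. Grade 5 at or
#' above the 99th percentile, then 4 (95th), 3 (90th), 2 (75th), else 1.
#'
#' @param hits Data.frame from \code{\link{find_triplex_sites}}.
#' @param background Numeric background score sample (>= 1000 values for
#'   stable grading; shorter samples are an error).
#' @return \code{hits} with the \code{grade} column filled.
#' @export
grade_hits <- function(hits, background) {
  if (!length(background)) stop("empty background sample", call. = FALSE)
  if (length(background) < 1000L)
    stop("background sample size must be >= 1000", call. = FALSE)
  if (!nrow(hits)) return(hits)
  perc <- vapply(hits$hit_score, function(s) mean(background <= s), numeric(1))
  hits$grade <- ifelse(perc >= 0.99, 5L,
                ifelse(perc >= 0.95, 4L,
                ifelse(perc >= 0.90, 3L,
                ifelse(perc >= 0.75, 2L, 1L))))
  hits
}

#' Signed hit-count summary matrix
#'
#' Dense microRNA x gene matrix of retained hit counts by orientation.
#'
#' @param hits Data.frame of retained hits.
#' @param mirnas Character vector of microRNA ids (matrix rows).
#' @param genes Character vector of gene ids (matrix columns).
#' @return An object of class \code{triplex_summary}: list with integer
#'   matrices \code{n_direct} and \code{n_indirect}.
#' @export
summarize_matrix <- function(hits, mirnas, genes) {
  nd <- matrix(0L, length(mirnas), length(genes),
               dimnames = list(mirnas, genes))
  ni <- nd
  if (nrow(hits)) {
    for (r in seq_len(nrow(hits))) {
      m <- hits$mirna_id[r]; g <- hits$gene_id[r]
      if (!(m %in% mirnas) || !(g %in% genes)) next
      if (hits$orientation[r] == "direct") nd[m, g] <- nd[m, g] + 1L
      else ni[m, g] <- ni[m, g] + 1L
    }
  }
  structure(list(n_direct = nd, n_indirect = ni), class = "triplex_summary")
}

#' Render a triplex summary in signed notation
#'
#' \code{"+n"} for n direct (Hoogsteen) hits, \code{"-n"} for n indirect
#' (reverse Hoogsteen) hits, \code{"0"} for none, and \code{"-a/+b"} when a
#' cell has both.
#'
#' @param summary A \code{triplex_summary}.
#' @return Character matrix with the same dimnames.
#' @export
render_triplex_matrix <- function(summary) {
  stopifnot(inherits(summary, "triplex_summary"))
  nd <- summary$n_direct; ni <- summary$n_indirect
  out <- matrix("0", nrow(nd), ncol(nd), dimnames = dimnames(nd))
  out[nd > 0 & ni == 0] <- paste0("+", nd[nd > 0 & ni == 0])
  out[ni > 0 & nd == 0] <- paste0("-", ni[ni > 0 & nd == 0])
  both <- nd > 0 & ni > 0
  out[both] <- paste0("-", ni[both], "/+", nd[both])
  out
}

#' @export
print.triplex_summary <- function(x, ...) {
  print(render_triplex_matrix(x), quote = FALSE)
  invisible(x)
}
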