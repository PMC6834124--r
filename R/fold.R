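# Minimum-free-energy RNA secondary structure prediction and suboptimal
# enumeration.
#
# Zuker-style dynamic programming over pseudoknot-free structures with
# hairpin / stack / bulge / internal / affine-multiloop terms, plus a
# threshold-complete traceback that enumerates every structure with energy
# <= MFE + energy_window. Decompositions are unambiguous (each structure is
# generated exactly once); a dot-bracket dedup is applied as insurance.
#
# Energy bookkeeping convention shared with the brute-force oracle used in
# the tests: each pair that is not stacked on its inner side receives the
# terminal AU/GU penalty once, and each pair not stacked on its outer side
# receives it once more (so a lone AU pair is penalized twice). In the DP
# the inner-end penalty lives inside V's hairpin/interior/multiloop cases
# and the outer-end penalty is added wherever V is consumed (external loop,
# multiloop component, interior-loop inner pair) except in the stack case.

# ---- structure helpers -----------------------------------------------------

#' Convert a pair list to dot-bracket notation
#' @param pairs Two-column integer matrix of 1-based pair indices (i < j),
#'   or NULL/empty for the open structure.
#' @param n Sequence length.
#' @return A dot-bracket string of length \code{n}.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' Parse dot-bracket notation into a pair matrix
#' @param db A dot-bracket string (only \code{.()} characters).
#' @return Two-column integer matrix of 1-based pairs, ordered by opening
#'   position.
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  open <- integer(0)
  out <- NULL
  for (k in seq_along(ch)) {
    if (ch[k] == "(") open <- c(open, k)
    else if (ch[k] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket", call. = FALSE)
      out <- rbind(out, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced dot-bracket", call. = FALSE)
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  out[order(out[, 1]), , drop = FALSE]
}

new_structure <- function(pairs, n, energy) {
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(pairs = pairs, dot_bracket = pairs_to_dotbracket(pairs, n),
                 energy = energy), class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("%s (%.2f kcal/mol)\n", x$dot_bracket, x$energy))
  invisible(x)
}

# ---- DP matrices -----------------------------------------------------------

# Fill V / M / M1 / W for an integer-encoded sequence. Returns an
# environment holding the matrices plus the lookup tables the traceback
# needs. Indices are 1-based; W has an extra leading element for W[0].
fold_matrices <- function(bases, model) {
  n <- length(bases)
  minl <- model$min_loop
  span0 <- minl + 1L  # minimum j - i for a pair
  INF <- Inf

  # pair-type and AU-penalty lookups for every (i, j)
  pt <- matrix(NA_character_, n, n)
  if (n >= span0 + 1L) {
    for (d in span0:(n - 1L)) {
      i <- seq_len(n - d)
      pt[cbind(i, i + d)] <- pair_type(bases[i], bases[i + d])
    }
  }
  aum <- matrix(0, n, n)
  aum[!is.na(pt) & pt %in% AU_LIKE] <- model$terminal_au

  V <- matrix(INF, n, n)
  M <- matrix(INF, n, n)
  M1 <- matrix(INF, n, n)

  # list of pairable (k, l), used to vectorize the interior-loop search
  pk <- which(!is.na(pt), arr.ind = TRUE)
  pk <- pk[pk[, 1] < pk[, 2], , drop = FALSE]

  bcost <- function(b1, b2) {
    # two-loop cost given unpaired counts on each side (b1 + b2 >= 1)
    tot <- b1 + b2
    ifelse(b1 == 0L | b2 == 0L, loop_penalty(model, "bulge", tot),
           loop_penalty(model, "internal", tot))
  }

  a <- model$ml_close; b <- model$ml_branch; cc <- model$ml_unpaired

  if (n >= span0 + 1L) {
    for (d in span0:(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        ptij <- pt[i, j]
        if (!is.na(ptij)) {
          best <- loop_penalty(model, "hairpin", d - 1L) + aum[i, j]
          # stack
          if (d >= span0 + 2L && !is.na(pt[i + 1L, j - 1L]) &&
              is.finite(V[i + 1L, j - 1L])) {
            best <- min(best,
                        model$stack[ptij, pt[i + 1L, j - 1L]] + V[i + 1L, j - 1L])
          }
          # bulge / internal loops
          if (nrow(pk)) {
            sel <- pk[, 1] > i & pk[, 2] < j &
              (pk[, 1] - i - 1L) + (j - pk[, 2] - 1L) >= 1L
            if (any(sel)) {
              kk <- pk[sel, 1]; ll <- pk[sel, 2]
              vv <- V[cbind(kk, ll)]
              fin <- is.finite(vv)
              if (any(fin)) {
                kk <- kk[fin]; ll <- ll[fin]; vv <- vv[fin]
                cand <- bcost(kk - i - 1L, j - ll - 1L) +
                  aum[i, j] + aum[cbind(kk, ll)] + vv
                best <- min(best, min(cand))
              }
            }
          }
          # multiloop: last inner branch starts at k
          if (d >= 2L * span0 + 3L) {
            ks <- (i + 2L):(j - 2L)
            mm <- M[i + 1L, ks - 1L]
            m1 <- M1[cbind(ks, rep.int(j - 1L, length(ks)))]
            cand <- mm + m1
            if (any(is.finite(cand))) {
              best <- min(best, a + b + aum[i, j] + min(cand))
            }
          }
          V[i, j] <- best
        }
        # M1[i, j]: exactly one branch (i, l), trailing bases unpaired
        ls <- (i + span0):j
        ls <- ls[ls <= n]
        if (length(ls)) {
          vv <- V[cbind(rep.int(i, length(ls)), ls)]
          cand <- vv + b + aum[cbind(rep.int(i, length(ls)), ls)] + cc * (j - ls)
          M1[i, j] <- min(cand, INF)
        }
        # M[i, j]: >= 1 branch, last branch (k, j) or j unpaired
        cands <- INF
        if (j - 1L >= i) cands <- M[i, j - 1L] + cc
        ks <- i:(j - span0)
        ks <- ks[ks >= 1L]
        if (length(ks)) {
          vv <- V[cbind(ks, rep.int(j, length(ks)))]
          auv <- aum[cbind(ks, rep.int(j, length(ks)))]
          cands <- min(cands, min(vv + b + auv + cc * (ks - i), INF))
          ks2 <- ks[ks >= i + span0 + 2L]
          if (length(ks2)) {
            vv2 <- V[cbind(ks2, rep.int(j, length(ks2)))]
            auv2 <- aum[cbind(ks2, rep.int(j, length(ks2)))]
            cands <- min(cands, min(M[i, ks2 - 1L] + vv2 + b + auv2, INF))
          }
        }
        M[i, j] <- cands
      }
    }
  }

  W <- numeric(n + 1L)  # W[j + 1] is energy of best structure on 1..j
  for (j in seq_len(n)) {
    best <- W[j]
    ks <- seq_len(max(0L, j - span0))
    if (length(ks)) {
      vv <- V[cbind(ks, rep.int(j, length(ks)))]
      fin <- is.finite(vv)
      if (any(fin)) {
        best <- min(best, min(W[ks[fin]] + vv[fin] +
                                aum[cbind(ks[fin], rep.int(j, sum(fin)))]))
      }
    }
    W[j + 1L] <- best
  }

  list(V = V, M = M, M1 = M1, W = W, pt = pt, aum = aum, n = n,
       span0 = span0, model = model)
}

# ---- suboptimal traceback --------------------------------------------------

# Enumerate every structure with energy <= threshold. Tasks are integer
# triples (code, i, j) with code 1=W(j), 2=V(i,j), 3=M(i,j), 4=M1(i,j).
enumerate_structures <- function(mats, threshold) {
  V <- mats$V; M <- mats$M; M1 <- mats$M1; W <- mats$W
  pt <- mats$pt; aum <- mats$aum; n <- mats$n; span0 <- mats$span0
  model <- mats$model
  a <- model$ml_close; b <- model$ml_branch; cc <- model$ml_unpaired
  eps <- 1e-9
  tval <- function(task) {
    switch(task[1],
           W[task[3] + 1L],
           V[task[2], task[3]],
           M[task[2], task[3]],
           M1[task[2], task[3]])
  }
  results <- list()
  # state: list(tasks = list of c(code,i,j), e, rest (= sum tval(tasks)), pairs)
  stack <- list(list(tasks = list(c(1L, 0L, n)), e = 0,
                     rest = W[n + 1L], pairs = list()))
  push <- function(st, task, delta, newtasks, pair, restm) {
    e2 <- st$e + delta
    nb <- sum(vapply(newtasks, tval, numeric(1)))
    if (e2 + restm + nb <= threshold + eps) {
      st$e <- e2
      st$rest <- restm + nb
      st$tasks <- c(st$tasks[-length(st$tasks)], newtasks)
      if (!is.null(pair)) st$pairs <- c(st$pairs, list(pair))
      stack[[length(stack) + 1L]] <<- st
    }
  }
  while (length(stack)) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (!length(st$tasks)) {
      results[[length(results) + 1L]] <- st
      next
    }
    task <- st$tasks[[length(st$tasks)]]
    restm <- st$rest - tval(task)
    code <- task[1]; i <- task[2]; j <- task[3]
    if (code == 1L) {            # W(j)
      if (j == 0L) {
        push(st, task, 0, list(), NULL, restm)
      } else {
        push(st, task, 0, list(c(1L, 0L, j - 1L)), NULL, restm)
        for (k in seq_len(max(0L, j - span0))) {
          if (is.finite(V[k, j])) {
            push(st, task, aum[k, j],
                 list(c(1L, 0L, k - 1L), c(2L, k, j)), c(k, j), restm)
          }
        }
      }
    } else if (code == 2L) {     # V(i, j)
      d <- j - i
      ptij <- pt[i, j]
      push(st, task, loop_penalty(model, "hairpin", d - 1L) + aum[i, j],
           list(), NULL, restm)
      if (d >= span0 + 2L && !is.na(pt[i + 1L, j - 1L]) &&
          is.finite(V[i + 1L, j - 1L])) {
        push(st, task, model$stack[ptij, pt[i + 1L, j - 1L]],
             list(c(2L, i + 1L, j - 1L)), c(i + 1L, j - 1L), restm)
      }
      for (k in (i + 1L):(j - 1L)) {
        if (k + span0 > j - 1L) break
        for (l in (k + span0):(j - 1L)) {
          b1 <- k - i - 1L; b2 <- j - l - 1L
          if (b1 + b2 >= 1L && !is.na(pt[k, l]) && is.finite(V[k, l])) {
            lc <- if (b1 == 0L || b2 == 0L)
              loop_penalty(model, "bulge", b1 + b2)
            else loop_penalty(model, "internal", b1 + b2)
            push(st, task, lc + aum[i, j] + aum[k, l],
                 list(c(2L, k, l)), c(k, l), restm)
          }
        }
      }
      if (d >= 2L * span0 + 3L) {
        for (k in (i + 2L):(j - 2L)) {
          if (is.finite(M[i + 1L, k - 1L]) && is.finite(M1[k, j - 1L])) {
            push(st, task, a + b + aum[i, j],
                 list(c(3L, i + 1L, k - 1L), c(4L, k, j - 1L)), NULL, restm)
          }
        }
      }
    } else if (code == 3L) {     # M(i, j)
      if (j - 1L >= i && is.finite(M[i, j - 1L])) {
        push(st, task, cc, list(c(3L, i, j - 1L)), NULL, restm)
      }
      for (k in i:(j - span0)) {
        if (k < 1L) next
        if (is.finite(V[k, j])) {
          push(st, task, b + aum[k, j] + cc * (k - i),
               list(c(2L, k, j)), c(k, j), restm)
          if (k >= i + span0 + 2L && is.finite(M[i, k - 1L])) {
            push(st, task, b + aum[k, j],
                 list(c(3L, i, k - 1L), c(2L, k, j)), c(k, j), restm)
          }
        }
      }
    } else {                     # M1(i, j)
      for (l in (i + span0):j) {
        if (l > n) break
        if (is.finite(V[i, l])) {
          push(st, task, b + aum[i, l] + cc * (j - l),
               list(c(2L, i, l)), c(i, l), restm)
        }
      }
    }
  }
  results
}

# ---- public API ------------------------------------------------------------

#' Fold an RNA sequence to its minimum-free-energy structure
#'
#' Pseudoknot-free dynamic programming under the nearest-neighbour model;
#' hairpin loops have at least \code{model$min_loop} unpaired bases, GU
#' wobble pairs are allowed and lone pairs are not prohibited. The open
#' (unpaired) structure has energy 0, so the MFE is never positive.
#'
#' @param seq An \code{\link{rna_seq}} (or RNA character scalar).
#' @param model An \code{\link{default_energy_model}} object.
#' @return A \code{secondary_structure}: \code{pairs} (2-column matrix of
#'   1-based indices), \code{dot_bracket}, \code{energy} (kcal/mol).
#' @examples
#' fold_mfe(rna_seq("x", "GGGGGAAAACCCCC"))
#' @export
fold_mfe <- function(seq, model = default_energy_model()) {
  fold_suboptimal(seq, model, energy_window = 0)$structures[[1]]
}

#' Enumerate optimal and suboptimal secondary structures
#'
#' Returns every pseudoknot-free structure whose energy is within
#' \code{energy_window} kcal/mol of the minimum free energy, deduplicated
#' by pair set and sorted by energy (ties broken lexicographically by
#' dot-bracket). With \code{energy_window = 0} the result is the set of
#' co-optimal MFE structures.
#'
#' @inheritParams fold_mfe
#' @param energy_window Enumeration window above the MFE in kcal/mol;
#'   \code{NULL} uses the default 5\% of |MFE| with a 1.0 kcal/mol floor.
#' @return A \code{fold_result}: \code{sequence}, \code{structures} (list of
#'   \code{secondary_structure}), \code{structure_count}, \code{mfe},
#'   \code{energy_window}, and \code{pair_matrix} (logical union of pairs
#'   over retained structures).
#' @export
fold_suboptimal <- function(seq, model = default_energy_model(),
                            energy_window = NULL) {
  if (!inherits(seq, "rna_seq")) seq <- rna_seq("seq", seq)
  bases <- strsplit(seq$seq, "")[[1]]
  n <- length(bases)
  if (n > 10000L) stop("sequence longer than 10,000 nt", call. = FALSE)
  mats <- fold_matrices(bases, model)
  mfe <- mats$W[n + 1L]
  if (is.null(energy_window)) energy_window <- max(1.0, 0.05 * abs(mfe))
  if (energy_window < 0) stop("energy_window must be >= 0", call. = FALSE)
  raw <- enumerate_structures(mats, mfe + energy_window)
  structs <- lapply(raw, function(st) {
    pairs <- if (length(st$pairs)) do.call(rbind, st$pairs)
             else matrix(integer(0), 0, 2)
    new_structure(pairs, n, st$e)
  })
  dbs <- vapply(structs, function(s) s$dot_bracket, character(1))
  keep <- !duplicated(dbs)
  structs <- structs[keep]
  dbs <- dbs[keep]
  es <- vapply(structs, function(s) s$energy, numeric(1))
  ord <- order(es, dbs, method = "radix")  # radix = byte order, locale-stable
  structs <- structs[ord]
  pm <- matrix(FALSE, n, n)
  for (s in structs) {
    if (nrow(s$pairs)) pm[s$pairs] <- TRUE
  }
  structure(list(sequence = seq, structures = structs,
                 structure_count = length(structs), mfe = structs[[1]]$energy,
                 energy_window = energy_window, pair_matrix = pm),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("Fold of %s (%d nt): MFE %.2f kcal/mol, %d structure(s) within %.2f kcal/mol\n",
              x$sequence$id, x$sequence$length, x$mfe, x$structure_count,
              x$energy_window))
  for (s in head(x$structures, 5)) print(s)
  if (x$structure_count > 5) cat("...\n")
  invisible(x)
}

#' Pair-frequency (dot-plot) matrix of a fold
#'
#' \code{M[i, j]} counts the retained structures containing pair (i, j)
#' (upper triangle); the plot renders the symmetrized matrix, the classic
#' superposition of all retained optimal and suboptimal foldings.
#'
#' @param fold A \code{fold_result}.
#' @param file Optional path of a PNG to write.
#' @return The count matrix, invisibly if \code{file} is given.
#' @export
dot_plot <- function(fold, file = NULL) {
  stopifnot(inherits(fold, "fold_result"), fold$structure_count >= 1)
  n <- fold$sequence$length
  m <- matrix(0L, n, n)
  for (s in fold$structures) {
    if (nrow(s$pairs)) m[s$pairs] <- m[s$pairs] + 1L
  }
  if (!is.null(file)) {
    png(file, width = 480, height = 480)
    on.exit(dev.off(), add = TRUE)
    sym <- m + t(m)
    image(seq_len(n), seq_len(n), t(sym[n:1, , drop = FALSE]),
          col = c("white", rev(grDevices::heat.colors(max(1, max(sym))))),
          xlab = "position j", ylab = "position i", axes = FALSE,
          main = sprintf("%s: %d structure(s)", fold$sequence$id,
                         fold$structure_count))
    axis(1); axis(2, at = seq_len(n), labels = rev(seq_len(n)), las = 2)
    return(invisible(m))
  }
  m
}

#' Rank folded microRNAs by thermodynamic stability
#'
#' Lower minimum free energy means a more stable fold; ties are broken by
#' sequence id.
#'
#' @param folds List of \code{fold_result} objects.
#' @return Character vector of sequence ids, most stable first.
#' @export
stability_rank <- function(folds) {
  stopifnot(length(folds) >= 1)
  ids <- vapply(folds, function(f) f$sequence$id, character(1))
  mfes <- vapply(folds, function(f) f$mfe, numeric(1))
  ids[order(mfes, ids)]
}

#' Write folds in Vienna dot-bracket format
#'
#' For each fold, a record of header, sequence, and one dot-bracket line per
#' retained structure with its energy in parentheses.
#'
#' @param folds List of \code{fold_result} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dotbracket <- function(folds, path) {
  lines <- unlist(lapply(folds, function(f) {
    c(paste0(">", f$sequence$id), f$sequence$seq,
      vapply(f$structures, function(s)
        sprintf("%s (%.2f)", s$dot_bracket, s$energy), character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}
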