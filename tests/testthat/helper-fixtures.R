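# Shared fixture builders for the test suite.

# Draw a third strand whose planted tract is unambiguous between the two
# orientations: direct planting needs >= 3 C bases (C has no canonical
# reverse-Hoogsteen partner, so the reversed reading fails); indirect
# planting needs <= 2 C (so the planted register still passes) and a
# G-position pattern asymmetric under reversal (>= 3 mismatch positions in
# the direct reading of the tract).
random_triplex_third <- function(orientation, len = 22L) {
  repeat {
    alph <- if (orientation == "indirect") c("A", "U", "G")
            else c("A", "C", "G", "U")
    s <- sample(alph, len, TRUE)
    if (orientation == "direct") {
      if (sum(s == "C") < 3) next
    } else {
      g <- s == "G"
      if (sum(s == "C") > 2 || sum(xor(g, rev(g))) < 6) next
    }
    third <- rna_seq("t", paste(s, collapse = ""))
    # the generator rejects third strands whose planted tract would also
    # register at a shifted or cross-orientation read; screen with a probe
    ok <- tryCatch({
      make_triplex_promoter(third,
                            data.frame(pos = 50, orientation = orientation),
                            length = 100L, seed = 1L)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(third$seq)
  }
}

# tiny in-memory genome for promoter tests
fixture_genome <- function(seed = 1, n = 1000L) {
  with_seed <- function(sd, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(sd); force(code)
  }
  with_seed(seed, {
    list(chr1 = dna_seq("chr1", random_dna(n)),
         chr2 = dna_seq("chr2", random_dna(n)))
  })
}

# minimal event-table TSV mirroring the colorectal-cancer staging facts
write_event_fixture <- function(path) {
  writeLines(c(
    "gene\tstage\tvariant_type\tantecedent_of",
    "APC\tearly\tLOH;mutation\tTP53",
    "TP53\t\tmutation\tTCF7L2",
    "TCF7L2\t\tmutation\t",
    "CASP8\t\tmutation\tKRAS",
    "KRAS\tearly;late;drug-resistance\tmutation\tPIK3CA",
    "GNAS\tmetastatic\tmutation\t",
    "EGFR\tdrug-induced;drug-resistance\tmutation\t"), path)
  path
}
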