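# Nearest-neighbour thermodynamic model (37 C free energies, kcal/mol).
#
# The numeric tables ship as versioned TSV files under inst/extdata:
#   nn_stacks.tsv      outer_pair, inner_pair, dg  (6x6 pair-on-pair stacks,
#                      rotationally symmetric; Watson-Crick values follow the
#                      published nearest-neighbour set, GU-wobble entries are
#                      package defaults of plausible magnitude)
#   loop_penalties.tsv type, size, dg (hairpin/bulge/internal initiation)
# Loop penalties beyond the tabulated range are extrapolated with the usual
# Jacobson-Stockmayer log term: dg(n) = dg(n_max) + 1.75*RT*log(n/n_max).

PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")
AU_LIKE <- c("AU", "UA", "GU", "UG")
RT37 <- 0.0019872 * 310.15  # kcal/mol at 37 C

#' Default RNA folding energy model
#'
#' Loads the nearest-neighbour stack table and loop-initiation penalties
#' shipped with the package and attaches the multiloop affine parameters,
#' the terminal AU/GU helix-end penalty and the minimum hairpin loop size.
#'
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param terminal_au Penalty (kcal/mol) per AU- or GU-closed helix end
#'   (default 0.45).
#' @param ml_close,ml_branch,ml_unpaired Multiloop affine parameters:
#'   closing penalty, per-branch penalty, per-unpaired-base penalty
#'   (defaults 3.4, 0.4, 0).
#' @return An object of class \code{energy_model}.
#' @export
default_energy_model <- function(min_loop = 3L, terminal_au = 0.45,
                                 ml_close = 3.4, ml_branch = 0.4,
                                 ml_unpaired = 0.0) {
  stacks <- read.delim(system.file("extdata", "nn_stacks.tsv",
                                   package = "mirtriplex"))
  loops <- read.delim(system.file("extdata", "loop_penalties.tsv",
                                  package = "mirtriplex"))
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack[cbind(stacks$outer_pair, stacks$inner_pair)] <- stacks$dg
  pick <- function(type) {
    x <- loops[loops$type == type, ]
    setNames(x$dg, x$size)
  }
  m <- structure(list(
    stack = stack,
    hairpin = pick("hairpin"),
    bulge = pick("bulge"),
    internal = pick("internal"),
    ml_close = ml_close, ml_branch = ml_branch, ml_unpaired = ml_unpaired,
    terminal_au = terminal_au, min_loop = as.integer(min_loop),
    temperature_C = 37), class = "energy_model")
  m
}

#' Loop initiation penalty with log extrapolation
#'
#' @param model An \code{energy_model}.
#' @param type \code{"hairpin"}, \code{"bulge"} or \code{"internal"}.
#' @param size Loop size in unpaired bases (vectorized).
#' @return Penalty in kcal/mol.
#' @export
loop_penalty <- function(model, type, size) {
  tab <- model[[type]]
  sizes <- as.integer(names(tab))
  smax <- max(sizes)
  out <- numeric(length(size))
  inside <- size <= smax
  out[inside] <- unname(tab[as.character(size[inside])])
  if (any(!inside)) {
    out[!inside] <- unname(tab[as.character(smax)]) +
      1.75 * RT37 * log(size[!inside] / smax)
  }
  out
}

#' Base-pair type of two RNA bases
#'
#' @param a,b Single uppercase RNA bases.
#' @return One of \code{"AU","UA","CG","GC","GU","UG"}, or \code{NA} if the
#'   two bases cannot pair.
#' @export
pair_type <- function(a, b) {
  p <- paste0(a, b)
  ifelse(p %in% PAIR_TYPES, p, NA_character_)
}

# terminal AU/GU penalty for a pair type (NA-safe: NA -> 0)
au_penalty <- function(model, pt) {
  ifelse(!is.na(pt) & pt %in% AU_LIKE, model$terminal_au, 0)
}
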