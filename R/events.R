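# Stage-specific somatic-event networks and interaction-network composition.
#
# Event tables are TSV exports with columns gene, stage, variant_type and an
# optional antecedent_of column (semicolon/comma-separated lists allowed).
# Stage and variant vocabularies are closed: unknown tokens are errors, not
# silently kept. Interaction edge lists are TSV with gene_a, gene_b, kind
# and an optional weight (default 1).

STAGE_VOCAB <- c("early", "late", "relapse", "metastatic", "drug-induced",
                 "drug-resistance")
VARIANT_VOCAB <- c("mutation", "methylation", "LOH", "CNV-loss", "CNV-gain",
                   "alteration")
INTERACTION_VOCAB <- c("co-expression", "genetic", "physical",
                       "shared-domain", "pathway", "predicted")
TARGET_GENES <- c("APC", "GNAS", "EGFR", "TCF7L2", "KRAS", "IGF1R", "CASP8")

split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x) || x == ".") return(character(0))
  trimws(strsplit(x, "[,;]")[[1]])
}

#' Load a somatic-event table
#'
#' Rows with the same gene are merged (union of stages, variants and
#' antecedent links). Genes appearing only as link endpoints get nodes with
#' empty stage/variant sets.
#'
#' @param path TSV with columns \code{gene}, \code{stage},
#'   \code{variant_type} and optionally \code{antecedent_of} (each of the
#'   last three may hold a \code{;}- or \code{,}-separated list, or be
#'   empty).
#' @param target_genes Genes flagged \code{is_target} in the node table.
#' @return List with \code{nodes} (data.frame: gene, stages, variant_types
#'   as \code{;}-joined strings, is_target) and \code{edges} (data.frame:
#'   antecedent, subsequent, mechanism).
#' @export
load_event_table <- function(path, target_genes = TARGET_GENES) {
  df <- read.delim(path, colClasses = "character")
  need <- c("gene", "stage", "variant_type")
  if (!all(need %in% names(df)))
    stop("event table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"antecedent_of" %in% names(df)) df$antecedent_of <- ""
  genes <- unique(df$gene)
  stages <- lapply(genes, function(g)
    unique(unlist(lapply(df$stage[df$gene == g], split_tokens))))
  variants <- lapply(genes, function(g)
    unique(unlist(lapply(df$variant_type[df$gene == g], split_tokens))))
  bad_s <- setdiff(unlist(stages), STAGE_VOCAB)
  if (length(bad_s))
    stop("unknown stage token(s): ", paste(bad_s, collapse = ", "),
         "; valid stages: ", paste(STAGE_VOCAB, collapse = ", "),
         call. = FALSE)
  bad_v <- setdiff(unlist(variants), VARIANT_VOCAB)
  if (length(bad_v))
    stop("unknown variant token(s): ", paste(bad_v, collapse = ", "),
         "; valid variant types: ", paste(VARIANT_VOCAB, collapse = ", "),
         call. = FALSE)
  edges <- do.call(rbind, lapply(seq_len(nrow(df)), function(r) {
    subs <- split_tokens(df$antecedent_of[r])
    if (!length(subs)) return(NULL)
    data.frame(antecedent = df$gene[r], subsequent = subs,
               mechanism = paste(split_tokens(df$variant_type[r]),
                                 collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(antecedent = character(0), subsequent = character(0),
                        mechanism = character(0), stringsAsFactors = FALSE)
  edges <- unique(edges)
  if (any(edges$antecedent == edges$subsequent))
    stop("self-loop temporal edge(s) not allowed", call. = FALSE)
  # nodes for link-only genes
  linked <- setdiff(edges$subsequent, genes)
  all_genes <- c(genes, linked)
  nodes <- data.frame(
    gene = all_genes,
    stages = c(vapply(stages, paste, character(1), collapse = ";"),
               rep("", length(linked))),
    variant_types = c(vapply(variants, paste, character(1), collapse = ";"),
                      rep("", length(linked))),
    is_target = all_genes %in% target_genes,
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

#' Stage set of a gene
#'
#' @param gene Gene symbol.
#' @param nodes Node table from \code{\link{load_event_table}}.
#' @return Character vector of stages (possibly empty).
#' @export
stage_of <- function(gene, nodes) {
  i <- match(gene, nodes$gene)
  if (is.na(i)) stop("unknown gene: ", gene, call. = FALSE)
  split_tokens(nodes$stages[i])
}

#' Shortest temporal path between two genes
#'
#' Breadth-first search over the directed antecedent-to-subsequent edges;
#' among equally short paths the one reached by expanding neighbours in
#' lexicographic order wins.
#'
#' @param a,b Gene symbols (source, destination).
#' @param edges Edge table from \code{\link{load_event_table}}.
#' @return Character vector of genes from \code{a} to \code{b}, or
#'   \code{NULL} when no directed path exists.
#' @export
temporal_path <- function(a, b, edges) {
  if (a == b) return(a)
  adj <- split(edges$subsequent, edges$antecedent)
  adj <- lapply(adj, function(x) sort(unique(x), method = "radix"))
  parent <- c()
  visited <- a
  queue <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!(w %in% visited)) {
        parent[w] <- v
        if (w == b) {
          path <- w
          while (path[1] != a) path <- c(parent[[path[1]]], path)
          return(unname(path))
        }
        visited <- c(visited, w)
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

#' Load an interaction edge list
#'
#' @param path TSV with columns \code{gene_a}, \code{gene_b}, \code{kind}
#'   and optional \code{weight} (default 1). Edges are undirected.
#' @return A data.frame with those four columns.
#' @export
load_edge_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "kind")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"weight" %in% names(df)) df$weight <- 1
  bad <- setdiff(unique(df$kind), INTERACTION_VOCAB)
  if (length(bad))
    stop("unknown interaction kind(s): ", paste(bad, collapse = ", "),
         "; valid kinds: ", paste(INTERACTION_VOCAB, collapse = ", "),
         call. = FALSE)
  if (any(df$weight < 0)) stop("negative edge weight", call. = FALSE)
  df[, c("gene_a", "gene_b", "kind", "weight")]
}

#' Interaction-network composition
#'
#' Percentage of total edge weight per interaction kind. Percentages sum to
#' 100 (within 1e-9); report at two decimals.
#'
#' @param edges Data.frame from \code{\link{load_edge_list}} (or with the
#'   same columns; missing \code{weight} defaults to 1).
#' @return Named numeric vector of percentages, sorted descending.
#' @export
edge_composition <- function(edges) {
  if (!nrow(edges)) stop("empty edge list", call. = FALSE)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  w <- tapply(edges$weight, edges$kind, sum)
  pct <- 100 * w / sum(w)
  sort(c(pct), decreasing = TRUE)
}

#' Export an event network for Cytoscape
#'
#' SIF: one \code{antecedent\\tantecedent_of\\tsubsequent} line per edge,
#' plus single-column lines for isolated genes. GraphML (via igraph)
#' carries stage/variant/is_target vertex attributes and the mechanism edge
#' attribute, and round-trips through \code{\link{import_network}}.
#'
#' @param network List with \code{nodes} and \code{edges} as produced by
#'   \code{\link{load_event_table}}.
#' @param path Output file path.
#' @param format \code{"SIF"} or \code{"GraphML"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(network, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  nodes <- network$nodes; edges <- network$edges
  if (!nrow(nodes)) stop("empty node set", call. = FALSE)
  if (format == "SIF") {
    lines <- character(0)
    if (nrow(edges))
      lines <- sprintf("%s\tantecedent_of\t%s", edges$antecedent,
                       edges$subsequent)
    isolated <- setdiff(nodes$gene, c(edges$antecedent, edges$subsequent))
    writeLines(c(lines, isolated), path)
  } else {
    g <- igraph::graph_from_data_frame(
      d = edges[, c("antecedent", "subsequent", "mechanism"), drop = FALSE],
      directed = TRUE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a GraphML event network
#'
#' Inverse of \code{\link{export_network}} for GraphML output.
#'
#' @param path GraphML file written by \code{\link{export_network}}.
#' @return List with \code{nodes} and \code{edges}.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    gene = igraph::vertex_attr(g, "name"),
    stages = igraph::vertex_attr(g, "stages"),
    variant_types = igraph::vertex_attr(g, "variant_types"),
    is_target = as.logical(igraph::vertex_attr(g, "is_target")),
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    antecedent = el[, 1], subsequent = el[, 2],
    mechanism = if (igraph::ecount(g)) igraph::edge_attr(g, "mechanism")
                else character(0),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
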